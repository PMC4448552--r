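# Toy domain seed alignments (synthetic)

These are SYNTHETIC toy seed alignments, one per domain kind (lox, srcr,
pkd, kringle, plat, mam, sushi), generated once from a fixed random draw:
each file holds 10 ungapped rows derived from a common consensus with ~25%
substitutions. They stand in for curated Pfam-style seeds so that profile
construction, scanning and the simulator are fully self-contained; a user
can substitute real seed alignments (e.g. the Pfam lysyl-oxidase family
seed) in the same aligned-FASTA format.

The lox seed embeds the human copper-talon motif WEWHSCHQHYHSMD at
positions 35-48 of every row, a lysine at position 70 and a tyrosine at
position 85 (the LTQ pair), so catalytic assessment has fixed reference
coordinates.
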