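# Species-tree fixture (synthetic)

`tol_consensus_fixture.nwk` is a SYNTHETIC, hand-written consensus
cladogram of major clades (bacteria as outgroup; unit branch lengths) for
demonstrating Dollo gain/loss reconstruction when no user species tree is
supplied. It is a plausible fixture, not a published phylogeny.
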