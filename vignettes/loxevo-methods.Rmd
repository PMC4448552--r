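---
title: "Methods: tracing lysyl oxidase evolution with loxevo"
author: "loxevo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracing lysyl oxidase evolution with loxevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loxevo)
```

# The problem

Lysyl oxidases (LOX) are copper-dependent amine oxidases that cross-link
collagens and elastin in the animal extracellular matrix.  The family is
defined operationally by a conserved C-terminal catalytic domain; the
N-terminal regions vary widely (signal peptides, propeptides, proline-rich
regions, SRCR repeats, transmembrane anchors and other accessory domains),
and this domain-architecture diversity, together with duplications, losses
and occasional horizontal transfers, encodes the family's evolutionary
history.  `loxevo` implements the complete comparative-genomics workflow
for such a family: retrieve candidate domains from proteomes with profile
hidden Markov models, annotate architectures, classify catalytic
competence, infer gene trees with support values and convergence
diagnostics, detect candidate horizontal transfers with reciprocal-hit
networks, and reconstruct gains and losses on a species tree by Dollo
parsimony.

Real studies of this kind consume hundreds of proteomes and external
predictors.  `loxevo` instead ships a synthetic-proteome generator that
plants every one of those evolutionary signals with a machine-readable
ground truth, so each stage — and the composed pipeline — can be validated
against known answers on a desk scale.

# Profile HMM retrieval

Profiles are built from seed alignments (toy synthetic seeds are bundled;
real ones can be substituted).  Columns with gap fraction < 0.5 become
match columns; sequences get Henikoff position-based weights normalised to
mean 1.  Match emissions mix the column's weighted residue frequencies
with a uniform background, `e = (f_obs + pc * bg)/(1 + pc)` with
`pc = 1` by default.  Mixing at the frequency level (rather than adding
pseudocounts to raw counts) keeps the mismatch penalty near −1 bit per
column, which is what lets the scanner recover homologs that have drifted
to 40–55% identity — the regime divergent domain repeats actually occupy;
count-level pseudocounts with ten seed rows would push the penalty to −3.5
bits and silently lose such copies.  Transitions are estimated from the
seed paths with a uniform pseudocount of mass `pc` over target states.

Scanning is local, Plan7-style: uniform entry over match columns, an
explicit exit transition from every match state, inserts emitting at
background odds.  This defines a proper probability distribution over
single-domain paths, which is what the brute-force enumeration oracle in
the tests sums over; Viterbi and forward implementations agree with the
oracle to 1e-12 bits on toy profiles.  Multi-domain proteins are handled
by iterative masking (accept best hit, mask its envelope with `X`,
rescan), then a greedy cross-profile decomposition accepts hits in
decreasing bit score, rejecting overlaps above 10 residues.

E-values come from a per-profile Gumbel fit (method of moments) to forward
scores of 200 seeded i.i.d. background sequences, scaled by the number of
proteins searched.  The method-of-moments fit pins the fitted mean to the
sample mean, so the exceedance at the null mean is exactly
`1 − exp(−exp(−γ)) ≈ 0.43` — a useful self-check.  The default inclusion
threshold is `E ≤ 1e-5` (configurable; the reporting threshold used in
published scans of this kind is rarely stated).

# Annotation heuristics

Dedicated predictors for signal peptides and transmembrane helices are
replaced by documented hydropathy heuristics, each threshold a
configurable parameter:

* **Transmembrane helix**: Kyte–Doolittle window of 19; windows with mean
  ≥ 1.6 merged; merged span kept if ≥ 15 residues.
* **Signal peptide**: an 8-residue window with mean hydropathy ≥ 2.0
  starting within residues 1–12, plus an `[AGSV]-x-[AGS]` cleavage motif
  ending in positions 15–35; the region ends at the first such motif.
* **Proline-rich region**: 25-residue windows with Pro fraction ≥ 0.25,
  merged, then clipped against the signal peptide and accepted domain
  hits.
* **Propeptide**: any unannotated stretch of ≥ 50 residues that precedes
  a domain or feature and is not proline-rich.  The narrower rule — only
  the stretch after the signal peptide — cannot represent architectures
  in which a propeptide follows a proline-rich region (the LOXL5-type
  layout), so the rule is applied between every pair of adjacent
  annotated regions.

Architectures are canonicalised N→C with run-length collapsing
(`SP+4xSRCR+LOX`); a transmembrane region overlapping a domain is placed
after the token it overlaps.

# Catalytic competence

Catalytic activity of a LOX domain requires the copper-binding histidine
core (the "copper talon", `WEWHSCHQHYHSMD` in human LOX, histidines at
motif offsets 4, 7, 9, 11) and the lysine/tyrosine pair that forms the
lysyl tyrosyl quinone (LTQ) cofactor.  Mutagenesis evidence shows the
first histidine is dispensable, so the classifier requires the **three**
core histidines plus LTQ K and Y.  The motif is located in a de-gapped
reference row and projected through the alignment's gap structure;
a gap at a located column counts as residue-absent (conservative).  The
verdict depends only on the five located columns — permuting all other
columns never changes it.

# Alignment and phylogenetics

The progressive aligner (pairwise Needleman–Wunsch with affine gaps,
BLOSUM62, open 10 / extend 0.5, gap of length L costing `open + L·ext`;
Kimura-corrected distances `d = −ln(1 − p − p²/5)` capped at `p = 0.85`;
UPGMA guide tree; profile–profile merging; optional leave-one-out
refinement) is a documented simplified stand-in for consistency-based
aligners such as MAFFT L-INS-i, and is not expected to reproduce their
column counts.  Input order is canonicalised by id, so results are
order-independent.

Likelihoods use Felsenstein pruning over compressed site patterns with the
published WAG/LG/JTT exchangeabilities (bundled as plain-text tables with
provenance headers) or a Poisson model; among-site rate variation uses
Yang's discrete gamma with 4 mean-of-bin categories (cross-checked against
an independent implementation), optionally with an invariant-site class
(variable-site rates rescaled by `1/(1−p_inv)` so branch lengths keep
their units) and `+F` empirical frequencies (Laplace +1, counted as 19
parameters in AIC).  Branch lengths are optimised by cyclic bracketed
univariate search (tolerance 1e-6, passes until ΔlnL < 1e-4); topology
search is NNI hill-climbing from a neighbor-joining start with optional
random multi-start (default 1 start, configurable — large multi-start is
the published practice, a single NJ start is sufficient at the scales the
tests use).  Model selection fits each candidate on a fixed NJ topology
and ranks by `AIC = −2lnL + 2k`.  Bootstrap support resamples columns with
replacement (seeded) and analyses each replicate by NJ (optionally NNI).

Pruning is validated against exhaustive state enumeration on 5-tip trees
(1e-10), against a 2-tip closed form, and against re-rooting invariance
(1e-9); degenerate limits (saturation, gamma shape → ∞) are asserted.

# Tree-sample agreement (bpcomp-style)

Bipartitions are canonicalised as the split side not containing the
reference tip (lexicographically smallest label); trivial splits are
excluded.  `maxdiff(A, B)` is the maximum absolute difference of split
frequencies over the **union** of observed splits (the convention of the
bpcomp diagnostic; using the intersection would hide splits private to one
sample).  The convergence scan fixes the ingested samples and scans
burn-in 1%…50% in 1% steps (the generation dimension of the original
procedure collapses once finished samples are ingested), picks the
minimising burn-in (smallest on ties, retaining the most trees), and
declares convergence below the conventional 0.1 threshold; subsampling
stride defaults to 10.  Majority-rule consensus includes splits with
frequency > 0.5 and labels them with `100 × frequency`.

# Reciprocal-hit network

All-versus-all Smith–Waterman (same scoring as above; the raw score is
validated against a quadratic DP oracle), Karlin–Altschul statistics
(`bits = (λS − ln K)/ln 2`, `E = m·n·2^{−bits}`, defaults λ = 0.267,
K = 0.041 — the conventional gapped BLOSUM62 parameters), and an
undirected edge wherever both directions pass the threshold.  The default
threshold is `E ≤ 1e-10`; reciprocal *any*-hit is the default
interpretation, with a reciprocal-best-hit mode for sensitivity analysis.
Connected components are summarised by clade composition; a component
containing more than one top-level clade ("mixed") is the horizontal
transfer signal.

# Dollo parsimony and reconciliation

Each character (family or domain-feature presence) is gained exactly once,
at the MRCA of the taxa carrying it unless constrained deeper; losses are
the roots of the maximal all-absent subtrees inside the gain clade — a
unique minimal set given the gain node (verified against exhaustive
enumeration on 8-tip trees).  `?` entries constrain neither side.  Because
tip-state parsimony alone would misplace a family born of a duplication at
the family's own MRCA rather than at the duplication, gain nodes can be
constrained by gene-tree reconciliation: a family clade's gain is the
species-tree LCA of its own species united with those of its sister
*family* clade.  This requires the family to be monophyletic in the
(rooted) gene tree; the pre-duplication outgroup lineage is left
unassigned.

# The synthetic generator and its presets

Sequences evolve site-wise under WAG with discrete-gamma rates
(shape 0.8, categories fixed per site at the root and inherited); indels
are off by default, so planted coordinates stay valid.  Features are
realised from fixed building blocks: signal peptides as
`MKK + 10 hydrophobics + ASA` (detectable by construction), proline-rich
regions as 30-residue P-alternating stretches, transmembrane anchors as
25 hydrophobics, propeptides as 60 featureless residues, domains as rows
sampled from the bundled seeds, 12-residue linkers in between.  Strong
purifying selection is emulated by holding invariant the positions that
define each feature class (the whole signal peptide and TM anchor, the
prolines, and — in LOX domains — the four copper-talon histidines and the
LTQ K/Y); everything else drifts freely.  This is deliberately idealised:
real proteins gain and lose residues, detectors face noisier signals, and
passing tests on these data demonstrate correctness of the machinery, not
field performance on real proteomes.

The presets encode the scenarios the pipeline must recover: seven
vertebrate family types realising exactly five architectures (the fifth,
membrane-associated SRCR class is a simulator convention); one eumetazoan
stem duplication with a cnidarian loss of one paralog; two anciently
diverged bacterial LOX subfamilies with two independent bacteria→archaea
transfers (subfamily divergence 6 substitutions/site at uniform rates, so
only the invariant catalytic residues remain shared — keeping the two
resulting mixed components disconnected at `E ≤ 1e-10`); three
family-founding duplications on the sponge stem with the first family
retained only in calcareous sponges; and a catalytic panel of one
competent domain plus four knockouts (first histidine; three core
histidines; LTQ lysine; LTQ tyrosine) with competence flags 1,1,0,0,0.
Horizontal transfer replaces any same-family gene in the recipient (the
simplest semantics; within-genome competition is not modelled).  A fixed
master seed makes every bundle bit-identical.

# Worked example

```{r example, eval = FALSE}
run <- run_pipeline(list(preset = "vertebrate_repertoire", seed = 42))
run$summary
#   n_proteins n_lox_hits n_architectures n_mixed_components n_competent ...
#           42         42               5                  1          42
sort(unique(run$annotation$architectures$architecture))
# "4xSRCR+LOX+TM" "SP+4xSRCR+LOX" "SP+PROPEP+LOX" "SP+PRORICH+LOX"
# "SP+PRORICH+PROPEP+LOX"
```

# Problem sizes and numerical choices

The shipped tests and the acceptance script run on deliberately small
instances, chosen as the smallest sizes at which each signal is
comfortably recoverable: 4–8 taxa per preset, 45–100-residue domains,
alignments of 300–1000 columns for likelihood recovery, 20-replicate
majority votes for the duplication count, 30-replicate bootstrap samples
for the convergence scan, 200-sequence null samples for E-value
calibration.  Tie-breaks are deterministic everywhere (leftmost/smallest
index); negative NJ branch estimates are clamped to zero; optimisation
tolerances are 1e-6 on lengths and 1e-4 on log-likelihood; all randomness
flows from one master seed through labelled, counter-based derivation so
inserting a stage never shifts another stage's draws.

# Known limitations

The aligner is not L-INS-i and will not reproduce published column counts;
the annotation heuristics are not SignalP/TMHMM and are only validated on
the generator's idealised signals; Bayesian tree sampling itself is out of
scope (only the bpcomp-style diagnostics over ingested samples are
provided); E-value calibration is empirical and per-profile, not
Karlin–Altschul theory for HMMs; and the Dollo machinery assumes the
species tree is given.
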