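# loxevo

Evolutionary analysis of lysyl oxidase (LOX) domain repertoires.

Lysyl oxidases are copper-dependent amine oxidases that cross-link
collagens and elastin in the animal extracellular matrix.  The family is
defined by a conserved catalytic domain whose activity requires the
copper-binding histidine core (the "copper talon",
`WEWHSCHQHYHSMD` in human LOX, with three essential histidines) and the
lysine/tyrosine pair forming the lysyl tyrosyl quinone (LTQ) cofactor.
Around that domain, proteins carry very different N-terminal equipment —
signal peptides, propeptides, proline-rich regions, SRCR repeats,
transmembrane anchors — and the history of the family is written in those
architectures: duplications that founded the animal LOX superfamilies,
losses in individual lineages, and horizontal transfers between
prokaryotes.

`loxevo` is an R package for reconstructing that history, for LOX or any
family with the same shape of evidence:

* **Retrieval** — profile hidden Markov models built from seed
  alignments; local Viterbi/forward scanning in log2-odds space; empirical
  Gumbel E-values; greedy multi-domain decomposition
  (`build_profile`, `viterbi_scan`, `forward_score`, `scan_proteome`).
* **Annotation** — hydropathy-based signal-peptide and transmembrane
  calls, proline-rich and propeptide regions, canonical architecture
  strings like `SP+4xSRCR+LOX` (`annotate_proteins`).
* **Catalytic competence** — classification from the three core copper
  histidines plus LTQ K/Y, with the first motif histidine treated as
  dispensable (`assess_alignment`).
* **Phylogenetics** — progressive alignment; maximum likelihood with
  WAG/LG/JTT (+Γ, +I, +F), Felsenstein pruning, NNI search, AIC model
  selection, nonparametric bootstrap (`progressive_align`, `tree_loglik`,
  `nni_search`, `select_model`, `bootstrap_support`).
* **Convergence diagnostics** — bipartition frequencies, the maxdiff
  statistic between tree samples with a 1–50% burn-in scan against the
  conventional 0.1 threshold, majority-rule consensus
  (`maxdiff`, `convergence_scan`, `majority_consensus`).
* **Horizontal transfer** — Smith–Waterman reciprocal-hit networks with
  Karlin–Altschul E-values; clade-mixed components as the HGT signal
  (`reciprocal_network`, `components_and_clusters`).
* **Gain/loss history** — Dollo parsimony on a species tree with
  duplication-aware gain placement via gene-tree reconciliation
  (`dollo_reconstruct`, `reconcile_gain_nodes`, `event_report`).
* **Synthetic truth** — a proteome simulator that evolves multi-domain
  genes along a species tree and plants duplications, losses, transfers
  and catalytic knockouts with a machine-readable event log
  (`simulate_species_tree`, `evolve_repertoire`, `preset`).

## A worked example

```r
library(loxevo)
run <- run_pipeline(list(preset = "vertebrate_repertoire", seed = 42))
run$summary
#   n_proteins n_lox_hits n_architectures n_mixed_components n_competent n_non_competent
#           42         42               5                  1          42               0
sort(unique(run$annotation$architectures$architecture))
# [1] "4xSRCR+LOX+TM"  "SP+4xSRCR+LOX"  "SP+PROPEP+LOX"  "SP+PRORICH+LOX"
# [5] "SP+PRORICH+PROPEP+LOX"
```

The preset plants seven vertebrate LOX family types (canonical LOX,
LOXL1, the fish LOXL5, the SRCR-bearing LOXL2/L3/L4, and a
membrane-associated SRCR variant) across six genomes.  The scan finds all
42 LOX domains, annotation reassembles exactly the five planted domain
architectures — the SRCR-class proteins carrying their four N-terminal
SRCR repeats — and every domain keeps its catalytic residues, so all 42
are classified competent.  The single "mixed" network component simply
reflects that vertebrate and cephalochordate homologs find each other, as
they should; in the `prokaryote_hgt` preset the analogous count is 2,
one component per planted bacteria→archaea transfer.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/loxevo.R simulate --preset prokaryote_hgt --seed 7 --out out/
Rscript inst/cli/loxevo.R run --preset prokaryote_hgt --seed 7 --out out/
```

## What the package does not do

It does not download proteomes or wrap external tools (HMMER, MAFFT,
RAxML, PhyloBayes, SignalP, TMHMM, BLAST); its aligner and annotation
heuristics are documented simplified stand-ins, validated on synthetic
data with planted truth, not replicas of those programs.  Bayesian MCMC
sampling itself is out of scope — only the bpcomp-style convergence
diagnostics over ingested tree samples.
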