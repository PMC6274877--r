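---
title: "Methods: gene-family evolutionary analysis with famevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family evolutionary analysis with famevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famevol)
library(ape)
```

famevol re-implements, as a tested and reusable pipeline, the comparative
analysis typically applied to a plant gene family such as the malate
dehydrogenase (MDH) genes of apple and its Rosaceae relatives: protein
characterization, family identification across proteomes, phylogeny,
duplication/loss inference, selection tests on codon alignments,
promoter cis-element analysis, and expression summarization. Every stage
consumes standard formats (FASTA, GFF3, Newick, TSV) and every stochastic
stage takes an explicit integer seed. Because the original gene sets are
draft-genome downloads that are not redistributable here, the package
ships simulators that generate each stage's inputs together with a
ground-truth event log, and the test suite exercises the pipeline
end-to-end against those logs.

## Protein physicochemical properties

`computeProperties()` reports length, molecular weight, theoretical pI,
GRAVY, instability index and aliphatic index.

* **Molecular weight** is the sum of average (not monoisotopic) residue
  masses plus one water (18.015 Da), reported in kDa, matching the scale
  of the common web calculators.
* **pI** is the unique root of the net-charge function. Positive groups
  (N-terminus, Lys, Arg, His) contribute $1/(1+10^{pH-pK})$ and negative
  groups (C-terminus, Asp, Glu, Cys, Tyr) contribute
  $-1/(1+10^{pK-pH})$, with the Bjellqvist pK set including the
  residue-specific N-terminal values. The charge is strictly decreasing
  in pH, so bisection on [0, 14] (tolerance 1e-4 pH units) finds the
  unique bracketed root.
* **GRAVY** is the mean Kyte–Doolittle hydropathy.
* **Instability index** uses the Guruprasad dipeptide weights:
  $\frac{10}{L}\sum_{k=1}^{L-1} \mathrm{DIWV}(x_k, x_{k+1})$. The 10/L
  scaling (rather than 10/(L-1)) follows the original publication and
  the common calculators. It is undefined (NA) for single residues.
* **Aliphatic index** is
  $X_{Ala} + 2.9\,X_{Val} + 3.9\,(X_{Ile}+X_{Leu})$ in mole percent.

Terminal side-chain pK adjustments beyond the standard Bjellqvist
treatment are not applied; this matches the default behavior of the
usual web tool. Tests check MW additivity, charge monotonicity, GRAVY
permutation invariance, and agreement with an independently coded
formula oracle to 1e-6.

## Family identification by reciprocal best hits

Heuristic database search is replaced by exact Smith–Waterman local
alignment (BLOSUM62, affine gaps open 11 / extend 1, via Biostrings), a
deliberate choice: at the scale of gene-family analysis (hundreds of
sequences) exactness and determinism are worth more than speed, and no
external binary is needed. `reciprocalBestHits()` reports (a, b) only if
each is the other's unique best scorer; ties are broken
lexicographically with a warning so runs are reproducible.
`familyExpand()` closes the RBH seed pairs transitively and admits
within-species paralogs whose raw score reaches a configurable floor
(default 50 — the underlying study states no threshold, so the default
is explicit and conservative).

## Phylogeny

`pDistance()` implements p-distances under pairwise deletion (each pair
compared over the columns where both rows are non-gap), the setting
reported for the family tree we emulate, together with 1000 bootstrap
replicates. `njTree()` is a from-scratch Saitou–Nei neighbor joining
with the Q-criterion, lowest-index tie-breaks, and negative branch
estimates clamped to zero with a message; `ape::nj` serves only as an
independent cross-check in the tests, never as the implementation.
`bootstrapSupport()` resamples columns with replacement, rebuilds the
tree, and scores each internal bipartition; a replicate in which some
pair shares no columns is redrawn (at most 10 times). Supports are
percentages on internal nodes.

Rooting is not stated in the study we follow, so downstream stages use
midpoint rooting by default (`midpointRoot()`), with any user-supplied
rooted tree accepted via Newick import. `assignClades()` marks the
maximal subtrees whose subtending branch reaches a support threshold
(default 50%, the usual display rule) and labels them I, II, ... in
depth-first order from the root — the labeling is a convention, not a
biological claim.

Maximum-likelihood (JTT) tree building is intentionally out of scope:
the NJ analysis is fully specified by its published settings, and an
externally built ML tree can be imported.

## Reconciliation: duplications, ages, losses

`lcaReconcile()` formalizes the clade-inspection rules as standard LCA
mapping: each gene-tree node maps to the species-tree LCA of its
descendants' species; an internal node is a duplication when it maps to
the same species-tree node as one of its children. A duplication
mapping to a terminal species branch is **recent** (a within-species
duplication); one mapping to an ancestral node predates the radiation
and is **old**. `findSisterPairs()` reports same-species cherries, the
signature of tandem/recent duplication.

Loss counting follows the per-clade unit of the emulated study — each
clade is expected to contain every species, and `inferLosses()` records
one loss per species absent from a clade — rather than the embedding
loss count of classical reconciliation. Weakly supported branches can be
collapsed first (`collapseBelow`); at a soft polytomy a duplication is
only inferred when a species repeats among the children.

Event counts depend on the rooting of the gene tree; reconciliation is
performed on the midpoint-rooted tree unless the caller roots otherwise.

## Selection analysis

`ng86KaKs()` implements Nei–Gojobori (1986) counting: per-codon
synonymous site fractions (changes to stop codons count as
nonsynonymous, so every codon carries 3 sites), averaging over the two
sequences; observed differences decomposed over all minimal mutational
paths with equal weights, excluding paths through stop codons (with a
fallback to all paths when every path is blocked); Jukes–Cantor
correction $d = -\frac{3}{4}\ln(1-\frac{4}{3}p)$, with a "saturated"
error at $p \ge 3/4$ and a missing omega when Ks = 0.

`mlPairwiseOmega()` and `branchModelLrt()` use the Goldman–Yang codon
model: 61 sense-codon states, zero rate for multi-nucleotide changes,
kappa-scaled transitions, omega-scaled nonsynonymous changes, target
codon frequency factors, and the matrix scaled to mean rate 1 at
equilibrium (branch lengths are expected substitutions per codon).
Codon frequencies default to F3x4 estimated from the data — the common
codeml default; the frequency model of the emulated analysis is not
stated. Likelihoods are computed by Felsenstein pruning in C++
(RcppArmadillo): the chain is time-reversible, so one symmetric
eigendecomposition per omega class yields all branch transition
matrices, and per-pattern log rescaling guards underflow. The pruning
path is validated against exhaustive summation over all internal-state
assignments of 3-leaf instances (to 1e-8) and the simulator's kernel
against an independent matrix exponential.

The branch-model test fits the one-ratio model (single omega) and the
two-ratio model (background omega1 / foreground omega2) by bounded
quasi-Newton (L-BFGS-B in log-parameter space; bounds omega in
[1e-4, 20], kappa in [0.1, 20], t in [1e-6, 20]; lnL tolerance 1e-6)
with multi-start over omega in {0.1, 0.5, 1.5} — exploratory passes at
loose tolerance, then a polishing pass from the best start. The
statistic $2\Delta\ln L = 2(\ln L_1 - \ln L_0)$ is referred to
chi-square with df = 1. A two-ratio fit falling below the one-ratio fit
by more than 1e-4 triggers refitting from a wider start grid and then an
error; small negative statistics are clamped to zero. Gap or ambiguous
codon columns are deleted completely before counting or likelihood
(PAL2NAL-style). Pairwise Ka and Ks are derived from the fitted matrix
by dividing the synonymous/nonsynonymous substitution flows by the site
fractions evaluated at omega = 1; with this convention dN/dS equals the
fitted omega.

`cladeOmegaCompare()` collects within-clade pairwise omega values,
ranks clade means, and applies Welch two-sample t-tests, mirroring the
published comparison of evolutionary rates between clades. Which ML
variant of the pairwise calculator the original analysis used is not
documented; GY94 is implemented here, and printed two-decimal ratios
should be compared with that caveat.

## Promoters, motifs, SNPs

The promoter is defined as 1800 bp (1.8 kb) immediately upstream of the
translation start on the coding strand — gene models rarely annotate a
transcription start site, so the ATG anchors the window; it is truncated
with a warning at contig edges. `scanMotifs()` expands IUPAC-degenerate
patterns (via Biostrings) on both strands by default, reporting every
overlapping hit with plus-strand coordinates; an entry like
"TCTCTTA/CAATTG" in a motif table is treated as two patterns sharing a
name. "N cis-elements identified" counts distinct motif names with at
least one hit, because published motif tables list element types, not
occurrences. `classifySnps()` assigns promoter/exon/intron purely by
coordinates and re-checks each overlapping motif hit with the alternate
allele substituted: a SNP alters a motif only when the new base violates
the IUPAC code at that position.

## Expression

`rpkm()` applies RPKM(g,s) = counts * 1e9 / (length * libSize).
`ddct()` implements the 2^-ddCt method with replicate averaging and the
replicate SD of dCt reported per cell; the calibrator defaults to the
first sample (the emulated study does not name its calibrator tissue),
and the calibrator column is exactly 1 by construction.
`clusterOrder()` reproduces heatmap-style reporting: log2(x+1)
transform (the pseudo-count handles the zeros present in both RPKM and
qPCR tables), average-linkage hierarchical clustering on Euclidean
distances, deterministic leaf order. Figures themselves are out of
scope; the package emits clustered matrices and orderings.
`expressionVsSeries()` reduces the qualitative "expression tracks
metabolite content" comparison to per-gene Pearson correlations against
the metabolite series.

## Simulators and what the tests do (and do not) show

`simulateGeneFamily()` runs independent per-lineage Poisson duplication
(rate lambda) and loss (rate mu) processes along a species tree — the
standard birth–death gene-family model. The returned gene tree is the
observable (pruned) one. The truth log records every surviving
duplication with the age class an ideal topology-based observer would
assign (recent when the surviving descendants span one species), and
flags as non-detectable the duplications whose two surviving sides map
to non-comparable parts of the species tree — no reconciliation method
can recover those from topology, and the recovery tests exclude them.
These truth-log classifications are computed with simulator-local set
arithmetic, independent of the inference code they validate.

`evolveCodons()` shares the GY94 rate-matrix construction with the
selection module — deliberately, so simulation and inference agree on
the model — and is therefore validated against an independent
matrix-exponential oracle and an empirical stationarity check, to avoid
self-confirmation. `generatePromoter()` plants concrete instances of
IUPAC motifs at non-overlapping positions on random strands and places
SNPs per region. `generateCountsAndCt()` draws negative-binomial counts
around RPKM-consistent means and normal Ct replicates around
offset - log2(relative expression).

Default study conditions used by the tests and the acceptance script:
a 4-taxon quartet with terminal branches 0.15 and internal branch 0.2
substitutions/codon (a realistic within-family divergence), alignments
of 300 codons (branch tests) or 500 codons (pairwise), kappa = 2,
purifying omega 0.2–0.3, duplication/loss rates 0.3/0.1 per lineage per
time unit on a 4-species Rosaceae-like tree, 1.8 kb promoters, three
qPCR replicates. The LRT null calibration uses 200 simulated datasets
and the power and recovery checks 30–100 datasets; these sizes give
stable Monte-Carlo estimates while keeping the default suite quick to
run.

What passing these tests does **not** show: real proteomes contain
low-complexity and repetitive sequence that can defeat RBH; real
alignments contain indels and alignment error, while the codon
simulator introduces none; real promoters are not i.i.d. background, so
chance motif hits are more structured than the simulator's; and the
birth–death model has no rate heterogeneity across lineages. Results on
the simulated conditions demonstrate correctness of the algorithms, not
robustness to those real-data pathologies.

## Numerical choices and degenerate inputs

* NJ Q-ties break to the lowest row-major index pair; equal-distance
  matrices therefore resolve identically across runs.
* Negative NJ branch estimates are clamped to 0 (logged); additive
  inputs are reproduced to 1e-9.
* Bootstrap replicates with an incomparable pair are redrawn, at most
  10 times, then error.
* The codon likelihood rescales partials per pattern; a zero site
  likelihood returns -1e12 rather than -Inf so optimizers can recover.
* Identical CDS pairs: NG86 gives Ka = Ks = 0 with omega missing; the
  ML pairwise fit reports t = 0 and omega missing rather than an
  unidentifiable estimate.
* Single-row matrices cluster to the identity ordering; length-1
  proteins have an undefined (NA) instability index.
* F3x4 frequencies of absent states are floored at 1e-8 and
  renormalized so the rate matrix stays irreducible.

## Scope

No de novo motif discovery (only scanning of a supplied motif table),
no multiple-sequence-alignment construction (the pipeline consumes
pre-aligned FASTA; pairwise alignment exists only for RBH scoring), no
ML tree building, no read alignment (expression starts from a count
matrix), no probabilistic reconciliation, no site or branch-site
selection models, and no figure rendering — tables and orderings are
the outputs.
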