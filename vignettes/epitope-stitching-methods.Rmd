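---
title: "Methods: epitope-prioritized library design and phage-level reactivity scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epitope-prioritized library design and phage-level reactivity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(epistitch)
```

## The problem

PhIP-Seq profiles serum antibody repertoires by displaying peptide libraries
on phage, immunoprecipitating with serum, and sequencing the enriched
population. Uniform tiling (56-residue peptides overlapping by 28) covers a
proteome about 1.8-fold but wastes most synthesis and sequencing capacity on
non-reactive peptides; for proteomes the size of the gut phageome it is
intractable outright. `epistitch` compresses a proteome into a compact
library by (i) scoring every 15-residue window of each protein with a
composition-based epitope classifier, (ii) keeping non-overlapping windows
with epitope probability above a cutoff, and (iii) stitching three such
windows into one 55-residue construct joined by GGGGS linkers, encoded as a
single 200-nt synthesis oligo. Downstream, peptide-level reactivity is
aggregated per phage with a permutation z-score.

## Composition features

A peptide is represented by 556 raw counts: 20 single amino-acid counts,
400 ordered adjacent amino-acid pair counts, 11 counts over the DIAMOND
reduced alphabet (the 11-group clustering used for seed matching in
homology search: {K,R,E,D,Q,N}, {S,T,A}, {I,L,V} and eight singletons),
121 ordered adjacent DIAMOND-pair counts, and 4 side-chain-class counts
(positive {K,R,H}, negative {D,E}, polar uncharged {S,T,N,Q,C,Y}, nonpolar
{G,A,V,L,I,P,F,M,W}). Counts are not length-normalized: the classifier is
trained per peptide length, so raw counts carry the same information and
keep the feature semantics simple (a 15-mer single-letter feature maxes out
at 15). The assignment of cysteine and tyrosine to the polar uncharged
class follows the common textbook partition that leaves exactly four
classes; it is configurable through `alphabetScheme(sidechainClasses =)`
because conventions differ at exactly these two residues. Feature order is
fixed (alphabetical within blocks) so serialized models remain valid.

Positional encodings are deliberately absent: composition alone carries the
discriminative signal for public linear epitopes, and omitting positions
keeps the model length-generalizable.

## Epitope classifier

Training data come from scan libraries: 56-mer "wildtype" peptides with
known reactivity, tiled into k-mers (k = 15...45, step 5) and triple-alanine
variants. A 15-mer is a positive example when at least two samples show a
positive log hit-fold-change; negatives are 15-mers with no reactivity in
any sample, ranked by descending count in bead-only (mock) IPs — a high
bead count demonstrates the peptide displays and amplifies well, so its
non-reactivity is biological rather than technical. Ties in bead count are
broken lexicographically by sequence for determinism. The negative set is
truncated to the positive count, giving a balanced set.

The classifier is a 100-tree impurity-split random forest
(`randomForest`), all other hyperparameters at package defaults, seed fixed
(default 42). The epitope probability of a window is the fraction of trees
voting "epitope". Because scan k-mers of one wildtype are near-duplicates,
train/test splits assign whole wildtype groups: groups are drawn in seeded
random order into the test set until it holds at least the requested
fraction (default 5%) of examples. Peptides longer than the model's length
are scored as the mean over all step-1 windows.

AUC is computed as the normalized Mann–Whitney U statistic with midranks
for ties (equivalently, trapezoidal integration of the empirical ROC).

## Library design

* **Tiling** (`mode = "tiling"`): 56-mers starting every 28 residues; if
  the last regular tile stops short of the C-terminus, one extra full tile
  ending exactly at the C-terminus is appended. Proteins shorter than 56
  residues are skipped with a warning. Coordinates are 0-based half-open
  internally; manifests also carry 1-based display starts.
* **Epitope selection** (`selectEpitopes`): greedy — repeatedly take the
  highest-probability window above the cutoff (default 0.5) that does not
  overlap an already selected window; equal probabilities are broken by the
  smaller start. The cutoff applies to all members including the first
  triple, since proteins with fewer than three predicted epitopes are
  dropped from the stitched design.
* **Deduplication**: identical 15-mers selected from several protein
  groups become one catalog entry whose group and phage memberships are
  unions; the merged probability is the maximum over occurrences (the
  epitope's best evidence; the original report does not state the rule).
  Deduplication happens after per-group selection and before position
  assignment: a shared epitope participates in each group's peptide
  formation, and identical stitched constructs are synthesized once.
* **Position assignment**: with m ranked epitopes a group yields
  n = floor(m/3) constructs; construct j carries ranks (j, n+j, 2n+j), so
  the strongest epitopes occupy first positions of distinct constructs,
  maximizing independently reactive peptides per protein. Leftover ranks
  beyond 3n are discarded.
* Selection operates on the first protein of each cluster (`group_id`), the
  cluster representative; clusters themselves are consumed from upstream
  (e.g. 95%-identity clustering), never computed here.

The coverage statistic counts displayed epitope-bearing residues — 56 per
tile, 45 (3×15) per stitched construct, 15 per lone epitope peptide —
divided by the summed representative protein length.

## Oligo encoding

Reverse translation samples, per residue, among codons whose E. coli K-12
usage fraction is at least 0.1, proportionally to the renormalized
fractions (the shipped TSV is user-replaceable). EcoRI (GAATTC) and
HindIII (AAGCTT) sites — the cloning enzymes — are eliminated by
resampling synonymous codons overlapping each occurrence, translation
invariant, with bounded retries. Stitched 55-mers receive one terminal
stop (56 codons, 168 nt); 56-mer tiles encode to 168 nt directly; 15-mer
epitope peptides are padded to 168 nt with three stop codons plus
pseudo-random filler that avoids the two restriction motifs and
homopolymer runs over 8 nt (synthesis practicality). Padding is placed 3'
of the coding region: stop codons must terminate the displayed ORF, so a
5' pad would corrupt the peptide (a `padEnd = "5p"` dialect exists for
compatibility). A 16-nt PCR prefix and suffix complete the 200-nt oligo.
Each peptide's random stream is seeded from the library seed plus a hash
of its sequence, so identical manifests are byte-identical and duplicate
peptides encode identically. An alternative 120-nt dialect pads with a
fixed linker DNA prefix instead.

## Reactivity analysis

A peptide is a **hit** in a sample when, relative to mock IPs, its count
exceeds 15, its fold change exceeds 5 and its p-value is below 0.001 (all
strict). Fold changes and p-values normally come from an upstream count
model; `simpleFoldTest` provides a pluggable stand-in — pseudocounted
ratio to the mock-estimated expected count with an upper-tail Poisson
p-value, using median-ratio size factors so that a strongly enriched
peptide subset does not deflate everyone else's fold change. A peptide is
**reactive** when its log hit-fold-change is positive in at least one
sample; the reactive fraction is the headline efficiency statistic.

**PhARscore.** For each phage with at least 25 peptides, per sample, the
observed mean log2 fold change of the phage's peptides is standardized
against the empirical mean and SD of 1000 equally sized random peptide
sets drawn without replacement from the current null pool (null
distributions are shared between phages of equal set size; a null SD below
1e-12 yields score 0). The procedure iterates at most 7 times: peptides of
phages scoring above 1 leave the pool and scores are recomputed, stopping
when no new phage passes. A peptide serving several phages stays in the
pool until all its owners are removed. Removal is per-sample by default;
`globalRemoval = TRUE` removes a phage everywhere once its mean score
across samples passes the threshold. The z-score of a single phage×sample
cell is approximately standard normal under exchangeability, so ~16% of
null cells exceed 1 by chance; per-sample removal therefore ratchets under
a pure null, while phage-level (mean-across-samples) removal and detection
is stable — which is why the package's own evaluations detect phages by
mean PhARscore > 1 under `globalRemoval`, matching how mean PhARscores are
used for phage-level comparisons.

**Alanine profiles.** For each scan curve (wildtype × reactive sample) the
difference wildtype − variant over the 54 triple-substitution positions is
thresholded (default 1, log2 units); curves with no above-noise region or
more than one contiguous region (multi-epitope) are excluded; the rest are
aligned on the disruption mass center and averaged. The reported width is
the smallest centered span holding 80% of the positive mass of the mean
curve. A width-w epitope hit by a 3-residue substitution window produces a
disruption plateau of w+2 positions (the convolution of the epitope
indicator with the window), which the tests use as the independent oracle.

## Synthetic study conditions

The generator (`synthConfig`) encodes one fixed set of study conditions
used by all tests: 50 phages × 10 proteins of 150–400 residues (uniform
background composition), 5% of proteins shared verbatim across phages;
planted epitopes of width 14 — the span covering 80% of the mean
alanine-disruption curve in real scan data — at 3 per 100 residues, with
multiplicative log-enrichments inside epitopes (K +1.2; R/D/E +0.6;
S/T/A +0.9; N/Q +0.3; I/L/V/F/M/W −0.8, then renormalized), the direction
the classifier's feature-importance analysis identifies; a 20-sample
cohort with per-epitope seroprevalence 0.3; 20% of phages immunogenic;
negative-binomial counts at mean depth 100 with dispersion 0.25 (variance
mu + 0.25 mu²), 8 mock replicates, 20-fold enrichment of reactive
peptides. Scan reactivity requires full containment of the epitope in the
sub-peptide; alanine variants lose reactivity iff the substituted triplet
intersects the epitope; effect sizes are N(3, 0.5) on the log-hfc scale
with a 0.002 false-positive rate.

What the generator does **not** emulate: phylogenetic structure among
phages, natural amino-acid background composition (uniform by default,
configurable), affinity maturation or epitope competition, read-level
artifacts, and the sparse epitope density of real proteomes. The last
point matters for one statistic: with one planted epitope per 33 residues
nearly every 56-mer tile contains an epitope, so the reactive-fraction gap
between tiled and stitched designs is far smaller here than in real
screens, where most tiles are empty. Passing tests therefore demonstrate
correctness of the machinery and recoverability of planted signal, not
real-data effect sizes; cohort-dependent quantities (published AUCs,
reactive-fraction improvements, clusterings) require the original external
cohorts and are out of scope.

## Problem sizes and numerical choices

The test and acceptance workloads use: 2,000 balanced training examples
(seed 7) for the classifier checks with a 5% grouped hold-out; a
50-phage × 20-sample screen for scoring; 500–1000 permutation draws;
1,000–10,000 peptide sweeps for featurizer and encoding laws; tiling
oracle equivalence over all protein lengths 56–400. Zero-variance null
guards, strict threshold inequalities, lexicographic and
smaller-start tie-breaks, and per-peptide hashed RNG streams are the
numerical conventions; degenerate inputs (single-class training data,
single-wildtype splits, empty manifests, proteins shorter than a tile or
window) raise explicit errors or warnings rather than silent results.

## Known limitations

* The classifier sees only composition; epitopes defined by structure or
  discontinuous segments are invisible to it.
* Stitched constructs assume the GGGGS linkers are immunologically inert;
  junction-spanning artifacts are not modeled.
* PhARscore eligibility (≥ 25 peptides) leaves small phages unscored in
  compressed designs, and proteins with fewer than three predicted
  epitopes are absent from stitched libraries entirely — both faithful to
  the method and both real sensitivity costs.
* `simpleFoldTest` is a calibrated stand-in, not a replacement for a full
  overdispersed count model with per-peptide dispersion estimation.
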