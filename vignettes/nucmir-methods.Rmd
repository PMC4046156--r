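---
title: "Models and methods behind nucmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nucmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucmir)
```

# Scope

`nucmir` implements the computational side of a study design that profiles
microRNA behaviour across the four stages of mouse granulopoiesis (LSK
progenitors, promyelocytes, myelocytes, granulocytes): panel RT-qPCR (TLDA)
CT matrices for whole cells and for nuclear/cytoplasmic fractions, a
microarray-style mRNA expression matrix, and sequence sets (3'UTRs, mature
miRNAs, pri-miRNA transcripts). Four analysis arms sit on top of these
inputs, plus a synthetic-data module that generates all of them with known
ground truth so every stage is testable without external data.

# CT-based expression

All quantification is on the CT (cycle threshold) scale. With 100%
amplification efficiency one cycle is one doubling, so the relative
expression of a test sample against a reference is
$E = 2^{\,CT_{ref} - CT_{test}}$; `relative_expression()` exposes the
efficiency as a parameter (default 2.0) but applies no efficiency
correction, since cell-equivalent TLDA inputs compare directly.

Three conventions matter and are fixed throughout:

* **Undetermined reactions** (no amplification by the end of the run) are
  `NA`, deliberately distinct from CT = 40. They are excluded from
  replicate means and never imputed: imputing the cycle cap would
  fabricate signal exactly where the fractionation arm is most
  sensitive (weak nuclear expression).
* **Replicates are collapsed by arithmetic mean CT**, i.e. the geometric
  mean of linear expression, the conventional qPCR treatment. The number
  of contributing replicates is recorded per collapsed cell.
* **Detectability** is CT < 30 in at least one cell type (strict
  inequality); the high-expression tier for clustering is CT < 25. Both
  are parameters.

Differential expression between stages uses the inclusive 2-fold rule:
fold $= 2^{CT_{ref}-CT_{test}} \ge 2$ or $\le 0.5$, evaluated for every
ordered pair of stages among detectable assays. Where replicate ΔCT
vectors are available, `wilcoxon_delta_ct()` provides the two-sided
signed-rank test: zeros dropped, mid-ranks for ties, and an exact null
distribution (computed by the shift convolution over all $2^n$ sign
assignments) for $n \le 25$ without ties, with a tie- and
continuity-corrected normal approximation beyond.

Clustering of the highly expressed, differentially regulated assays works
on row-centred negative CT profiles (so larger = more expressed, and the
shared scale is ΔCT cycles). The distance is Pearson correlation distance
$1 - r$ with average linkage — a shape-based choice appropriate when
trajectories, not absolute levels, define co-regulation; Euclidean
distance and other linkages are available. An assay qualifies when it is
below 25 cycles somewhere and passes differential expression in at least
one stage pair ("between two or more stages"); the comparison count is a
parameter.

Cross-dataset (e.g. cross-species) concordance reports the Spearman rank
correlation of matched log2 fold changes together with the $R^2$ of the
linear fold–fold fit, because published figures sometimes print the one
alongside the other; direction-agreement counts are tabulated among
entities passing the fold filter in the first dataset. Name matching
strips three-letter species prefixes and is case-insensitive.

# Moderated t for the mRNA arm

The mRNA arm tests log2 expression between two stages (three replicates
each by default) with an empirical-Bayes moderated t. Gene-wise variances
$s_g^2$ (pooled, $d_g = n_1 + n_2 - 2$) are modelled as
$s_g^2 \sim s_0^2 F(d_g, d_0)$. On the log scale,
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$ has mean
$\log s_0^2 - \psi(d_0/2) + \log(d_0/2)$ and variance
$\psi'(d_g/2) + \psi'(d_0/2)$, so $d_0$ comes from inverting the trigamma
function on the excess spread of $e_g$ (Newton iteration) and $s_0^2$
from the corrected mean. When the observed spread does not exceed
chi-square sampling noise the prior is taken as infinitely informative
and $s_0^2$ is the plain mean of the variances. The posterior variance
$\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ always lies between
$s_0^2$ and $s_g^2$; the statistic
$t_g = \hat\beta_g / (\tilde{s}_g \sqrt{1/n_1 + 1/n_2})$ is referred to
$t_{d_0 + d_g}$. Significance combines $p \le 0.05$ with fold $\ge 2$, on
raw p-values by default (matching the reported thresholds of this kind of
analysis); Benjamini–Hochberg adjustment is available behind a flag.
Genes with zero variance are excluded from prior fitting, and a
`prior_df_override` argument exposes the two limits ($d_0 = 0$: ordinary
t; $d_0 = \infty$: fully pooled variance), which the test suite uses for
calibration checks against an independent implementation.

# Seed-match target inference

Canonical site types follow the TargetScan conventions, defined on the
UTR read 5'→3' against the miRNA seed (positions 2–8) read antiparallel:

* **7mer-m8** — reverse complement of miRNA positions 2–8;
* **7mer-A1** — reverse complement of positions 2–7 followed by a genomic
  `A`, required regardless of the miRNA's first nucleotide;
* **8mer** — the 7mer-m8 followed by that `A`.

Overlapping calls at one locus collapse to the strongest type
(8mer > 7mer-m8 > 7mer-A1); machine coordinates are 0-based half-open,
and scanning is invariant to DNA vs RNA input alphabets. Target pairs
combine a miRNA passing the fold filter, a gene passing fold ≥ 2 and
moderated $p \le 0.05$, opposite directions of change, and at least one
site in the gene's 3'UTR. Stage-specific pairing keeps pairs whose miRNA
peaks, and whose gene bottoms out, in the same stage, with exact ties
excluded as uninformative. Conservation-based filtering is deliberately
not implemented (the underlying conservation method is out of scope); a
user-supplied whitelist and a known-validated annotation hook stand in.

# Duplex screening of pri-miRNA transcripts

Nuclear-enriched miRNAs are screened against pri-miRNA transcripts with
an intermolecular duplex minimum-free-energy dynamic program. The energy
model is intentionally minimal and fully embedded: a nearest-neighbour
stacking table over the six pair types (Watson–Crick doublets at
published ΔG°37 values; G:U-containing doublets at representative values
completed under strand-flip symmetry), affine penalties
$3.3 + 0.5\ell$ kcal/mol for bulges ($\ell \le 4$) and
$1.5 + 0.5(\ell_1+\ell_2)$ for internal loops ($\ell_1+\ell_2 \le 6$), no
helix-initiation, dangling-end or terminal-mismatch terms, and no
intramolecular structure. The loop caps reflect typical miRNA-duplex
loop sizes and simultaneously bound the DP transition neighbourhood. A
lone base pair scores 0, so an MFE of 0 means "no stabilizing duplex".
Because the model is a simplified stand-in for full physics-based duplex
predictors, absolute energies differ from those tools and the −30
kcal/mol candidate cutoff is exposed as a calibratable parameter rather
than treated as portable.

The DP state is (query position, target position) for the 3'-most pair
of a duplex; stacked extensions add the doublet energy, loop extensions
add their penalty, and the optimum over all cells (against 0) is exact
under the model — the test suite proves equality with exhaustive
enumeration over all legal pairings on small instances. Transcripts are
scanned in 60-nt windows every 10 nt (plus a final flushed window), with
ties going to the first window.

Statistical calibration uses dinucleotide-preserving shuffles of the
transcript (Altschul–Erickson: a random last-edge arborescence over the
dinucleotide transition multigraph, then a random Eulerian walk), which
conserve dinucleotide counts exactly and hence the stacking statistics
of the null. The best MFE is recomputed per shuffle (200 by default), a
Gumbel distribution is moment-matched to the shuffled minima, and both
$P(\text{null MFE} \le \text{observed})$ under that fit and the
rank-based empirical p-value $(1 + \#\{null \le obs\})/(n+1)$ are
reported; filtering uses the empirical p, whose resolution is bounded by
$1/(n_{shuffles}+1)$. Candidates require MFE < −30 kcal/mol and
$p < 0.05$ (both strict), and are annotated with whether the nuclear
miRNA's trajectory and its target's mature-miRNA trajectory move in
opposite directions between the compared stages.

# Fractionation and nuclear-enrichment calling

Fractions are assumed cell-equivalent (equal volumes from one lysate
split), so nuclear and cytoplasmic CTs compare directly and the N:C
ratio is $2^{\,CT_{cyto} - CT_{nuc}}$. Marker QC requires nuclear
markers (SnoRNA-like) enriched ≥ 4-fold in the nuclear fraction and
cytoplasmic markers (Y1-like) ≥ 2-fold in the cytoplasmic fraction —
thresholds set below the 8–56× and 4–9× ranges such markers typically
show, so QC fails only on genuinely compromised fractionations.

Most miRNA signal in the nuclear fraction of these designs is
cytoplasmic carry-over. Under a pure carry-over model at fraction
$\alpha$, nuclear CT is cytoplasmic CT plus $\log_2(1/\alpha)$;
`contamination_regression()` fits nuclear on cytoplasmic CT by OLS over
detectable non-marker assays and reports $2^{-intercept}$ as the implied
contamination fraction. Note the intercept is an extrapolation ~24
cycles outside the data: with a handful of genuinely nuclear assays in
the panel, small slope tilts move single-fit intercepts by several
tenths of a cycle, so replicate designs should summarize across fits.

Enrichment calling assesses assays in the nucleus: not detectable unless
nuclear CT < 30 somewhere; `cytoplasmic` at ratio ≤ 0.1; `candidate`
above 0.1; and `nuclear_enriched` when, additionally, a one-sided Welch
t-test of the assay's per-replicate log2 ratios against the pooled
replicates of cytoplasmic control miRNAs gives $p < 0.05$. Controls
default to the ten detectable assays with the consistently lowest N:C
ratio (ranked by their maximum ratio across cell types) and are
user-overridable; ratios above 1 are flagged. Ranking uses
replicate-collapsed CTs; testing uses per-replicate ratios.

A calibration caveat worth stating plainly: when the true contamination
fraction coincides with the 0.1 ratio threshold, half of the null assays
sit above the candidate gate by chance, and with three replicates the
control comparison has ~2 degrees of freedom, so the per-test false
positive rate at raw α = 0.05 is of order 10% and a 200-assay panel will
produce tens of false `nuclear_enriched` calls. No p-threshold fixes
this — with df ≈ 2 even a true N:C of 2 cannot reach Bonferroni-scale
p-values. In practice the rule is reliable only when contamination is
well below the ratio threshold, when more replicates are available, or
when calls are confirmed by follow-up assays; the package keeps the
published rule as the default and leaves the thresholds as parameters.

# The synthetic-data generators

`simulate_ct_experiment()` draws whole-cell baseline CTs uniform on
[20, 29] (the typical observed range), applies planted differential
effects along a monotone stage trajectory reaching the full fold change
(default 4-fold, half up, half down) in the last stage, mirrors the
whole-cell values into the cytoplasmic fraction, and sets nuclear linear
abundance to `contamination_fraction` (default 0.1) times cytoplasmic
for null assays and `true_nc_ratio` (default 2) for planted
nuclear-enriched assays. CT noise is Gaussian on the cycle scale
(default sd 0.25 cycles, i.e. multiplicative lognormal on abundance,
matching qPCR error behaviour), and values beyond the 35-cycle detection
limit are censored to undetermined — censoring removes, never alters.
Markers are planted inside the 8–56× and 4–9× enrichment ranges with
baselines shared between the paired fractions.

`simulate_transcriptome()` emits random-sequence UTRs (default 200–800
nt), one planted site of a random canonical type per true pair at a
recorded position, and a two-group expression matrix in which target
genes change 1.5 log2 units opposite in sign to their miRNA, with 0.25
log2 replicate noise. Non-target genes carry no planted site: accidental
seed matches for the planted differential miRNAs are audited after
generation and scrubbed by a single-base mutation, each scrub recorded
in the ground truth (a site that cannot be mutated without touching a
planted site is left and recorded as residual). This makes the planted
truth exhaustive, so end-to-end precision measures the pipeline
machinery rather than the unavoidable background rate of chance 7-mers —
on real UTRs, anti-correlated expression plus a chance seed match is a
genuine false-positive mode that this synthetic test intentionally does
not exhibit. `simulate_pri_targets()` plants exact or few-mismatch
reverse complements of nuclear miRNAs in random pri-miRNA transcripts
(0.5–2 kb) at recorded positions.

What the generators do **not** emulate: probe cross-hybridization,
amplification-efficiency variation, batch effects, UTR length/composition
biases, correlated co-expression structure, or conservation. Passing
tests therefore demonstrate correctness of the computations and
recoverability of planted signal at realistic noise — not performance on
real tissue data.

# Problem sizes and numerical choices

The shipped tests and the reproduction script run at deliberate desk
scale: 1000 random seed-scan instances (UTRs to 2 kb), 500 exhaustive
duplex enumerations (query ≤ 8 nt, window ≤ 12 nt), 100-run recovery
experiments at 200 assays, a 10,000-gene null for t calibration, and a
300 miRNA × 500 gene target-inference experiment with 30 planted pairs.
Further choices: all logs are base 2; CT validity is [0, 40]; exact
signed-rank enumeration switches to the normal approximation above
n = 25 or under ties; trigamma inversion iterates Newton to relative
1e-10; duplex ties resolve to the first window; clustering of a
zero-variance profile treats its correlations as 0; and every stochastic
routine consumes R's RNG so a single `set.seed()` (or the pipeline's
`seed` field) makes runs byte-reproducible.

# Known limitations

* The duplex energy model is a documented simplification; its absolute
  energies, and therefore the −30 kcal/mol cutoff, are internal to the
  package.
* Nuclear-enrichment calling inherits the statistical fragility described
  above whenever contamination approaches the ratio threshold.
* No multiple-testing correction is applied by default anywhere, by
  design fidelity to raw-threshold reporting; BH is available.
* Conservation filtering and context-type site scoring are out of scope.
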