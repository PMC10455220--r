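---
title: "From treatment transcriptomes to ranked drug combinations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From treatment transcriptomes to ranked drug combinations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergyseek)
```

# The problem

First-line acute myeloid leukemia (AML) therapy combines cytarabine with an
anthracycline such as daunorubicin, yet individual cell lines — and patients —
differ sharply in their response. synergyseek implements a strategy for
finding drugs that could restore sensitivity in a resistant line: compare the
transcriptional response to treatment between drug-sensitive and
drug-resistant cell lines, distill the changes unique to each into a
*resistance* signature and a *response* signature, search a library of
perturbagen expression profiles for agents that reverse the former while
mimicking the latter, and validate predicted combinations by Bliss
independence on dose–response matrices, finally asking which genomic
alterations shift the observed synergy.

The pipeline starts from a gene-level count matrix; read QC, alignment and
quantification are out of scope.

# Differential expression

Counts are normalized with trimmed-mean-of-M-values (TMM) factors: the
reference sample is the one whose 75th-percentile count fraction is closest
to the mean of those fractions, per-gene log2 proportion ratios (M) and mean
log2 abundances (A) are trimmed at 30% and 5% respectively, and the factor is
2 raised to the precision-weighted mean of the surviving M values, rescaled
so factors have geometric mean 1. The implementation is checked against
`edgeR::calcNormFactors` on random count matrices in the test suite.

Replicates within a (cell line, treatment) condition are **pooled after
normalization**: each sample is scaled to the common geometric-mean effective
library size, summed within its group, and rounded. Testing uses a
fixed-dispersion negative-binomial exact test, conditional on the total
$t = a + b$ of the two pooled group counts. Both pooled counts are modelled
as NB with conditional mean $t/2$; the two-sided p-value sums the
probabilities of all splits no more likely than the observed one
(minimum-likelihood tails; a doubled-tail variant is available via
`method = "double"` — the two differ in how ties are counted). With
dispersion 0 this reduces to the conditional Binomial$(t, 1/2)$ test, which
is how the test is verified against exhaustive enumeration.

Because a sum of $n$ iid NB variates with common dispersion $\phi$ has
dispersion $\phi/n$, the pooled test runs at
$\phi \cdot 2/(n_\text{treat} + n_\text{ref})$. The default per-sample
dispersion is $\phi = 0.16$ (biological coefficient of variation 0.4), the
standard conservative choice for human cell-line data when replicate
structure cannot support tagwise estimation; it is a configuration knob, not
an estimate. We deliberately do not reproduce quantile-adjusted
conditional-likelihood dispersion machinery.

Fold changes are computed on counts-per-million with a 0.5-CPM pseudo-count
(avoiding infinities at zero counts). A gene is called differentially
expressed when $|\log_2 FC| > 1$ **strictly** and FDR $< 0.05$ strictly,
with Benjamini–Hochberg adjustment per contrast.

# Signature construction

The resistance profile collects changes seen in the resistant line after the
drug alone and absent from every sensitive line under both the drug and the
combination:

$$\text{up} = \text{up}(R, \text{drug}) \setminus
  \bigcup_{s,\ c \in \{\text{drug}, \text{combo}\}} \text{up}(s, c)$$

and analogously for down-regulations. Three readings of the construction were
genuinely open; we fixed them as follows and exposed the alternatives as
flags:

* **Direction-specific exclusion.** Absence is judged per direction: a
  gene induced in the resistant line and *repressed* in a sensitive line
  stays in the profile — only the same change elsewhere removes a gene. This is assertable set algebra and is
  tested as an identity.
* **Monotherapy-only resistance profile** by default — the profile is
  built from the resistant line's single-drug condition; `strict = TRUE`
  also excludes the resistant line's combination changes.
* **Response profile presence rule.** The default requires presence in all
  four sensitive-condition sets (both sensitive lines × {drug, combo}),
  the stricter of the two tenable definitions of a change common to the
  sensitive lines; `relaxed = TRUE` intersects the drug conditions only.

Overlap tallies between DE sets are reported with three denominators (first
set, second set, union of the stratum) so percentages are never ambiguous.
Pathway over-representation uses the one-sided hypergeometric upper tail
with BH adjustment; the universe defaults to the genes actually tested for
DE rather than the genome — the standard bias control.

# Connectivity scoring

The scoring engine follows the published Connectivity Map convention
(enrichment score, two-sided WTCS, sign-stratified NCS). For a
query gene set against a reference signature of $N$ ranked genes, the
enrichment score (ES) is the signed maximum deviation of a running sum that
rises by $|s|^w / \sum |s|^w$ at query hits and falls by $1/(N - n_{hit})$
at misses. The default weight is $w = 0$ (pure Kolmogorov–Smirnov steps),
which keeps the statistic exactly checkable against a brute-force oracle
over *all* query subsets at small $N$; $w = 1$ is available. On an exact tie
between the positive and negative deviation the positive one is returned.

The two-sided score combines the up- and down-set ES:
$\text{WTCS} = (ES_{up} - ES_{down})/2$ when the two disagree in sign, else
0; an empty set passes the other set's score through (down-set negated).
Normalization is sign-stratified within each (cell line, perturbagen type)
group: each WTCS is divided by the mean |WTCS| of the same-signed group
members, so the mean magnitude within each sign stratum is 1 and scores are
comparable across cell lines and perturbagen types.

Partner prediction keeps perturbagens with NCS $\le -1$ against the
resistance profile **and** NCS $\ge +1$ against the response profile in at
least one cell line. The threshold 1 defines what counts as an observed
transcriptional effect in a cell line: it is the natural unit after
sign-stratified normalization, and no alternative cut has a stronger
justification. Three filters remove ambiguous discoveries:

1. targets whose knockdown and overexpression signatures score with the
   same sign against the resistance profile are discarded (a direction-less
   association cannot be acted on);
2. perturbagens scoring in the same direction against both profiles at
   threshold magnitude are discarded;
3. compounds are kept only when a knockdown signature of their annotated
   target is sign-concordant with them — unannotated compounds are dropped.
   Requiring an inhibitor to transcriptionally resemble loss of its own
   target enriches true positives; it trades recall for precision and is
   the main reason decoy compounds essentially never survive to the
   ranking.

Candidates are aggregated into classes by target annotation and ranked by
the number of supporting cell lines, breaking ties by |mean NCS vs. the
resistance profile| and then class name, so output order is deterministic.

# Bliss synergy

Viability matrices are anchored to the untreated control (scaled so the
(0,0) cell is 100%). Percent viability converts to fractional inhibition
clamped to $[0,1]$ — growth stimulation above 100% viability counts as zero
inhibition. For every combination cell the Bliss-expected inhibition is
$y_A + y_B - y_A y_B$ from the same-row/column monotherapy cells, and the
excess is reported ×100 so scores are commensurable with published percent
values. The matrix score is the plain arithmetic mean of the excess over
combination cells: no baseline correction, outlier correction or
curve-fitting smoothing is applied, which keeps the estimator unbiased for
the planted effect in simulation and makes no assumptions the data cannot
support. A score above 0 is labelled synergistic, below 0 antagonistic, and
exactly 0 additive (the boundary case the classification rule leaves open).
Class-level aggregation averages member combinations per (cell line, class)
and counts synergistic/antagonistic cell lines per class, the computation
used for large public combination screens.

# Genomic association

Each binary alteration with at least 3 mutant and 3 wild-type lines (the
panel-screening convention) is tested by
fixed-effects ANOVA of synergy on mutation status, optionally adjusted for a
categorical covariate such as tissue (off by default for transparency — both
modes are exposed because the original covariate set is unstated). With a
binary factor and no covariate, $F = t^2$ of the pooled two-sample t-test —
an identity the tests verify to 1e-10. Effect size is Cohen's d with pooled
standard deviation.

Multiplicity is handled with Storey–Tibshirani q-values: $\hat\pi_0(\lambda)
= \#\{p > \lambda\}/(n(1-\lambda))$ on the grid $\lambda = 0.05, \dots,
0.95$, smoothed by a natural cubic spline with 3 degrees of freedom and
evaluated at $\lambda = 0.95$, clamped to $(0,1]$. Forcing $\pi_0 = 1$
reproduces BH exactly (tested as an identity). Significance uses the
screening defaults $p < 0.001$ and $q < 0.25$. The top/bottom 50% synergy
split labels the top $\lceil n/2 \rceil$ lines "higher", breaking boundary
ties by cell-line name so output is deterministic.

# The synthetic-data generator

Every downstream stage is tested against generated data with planted ground
truth; all generators are pure functions of (config, seed), with fixed
offsets separating the sub-streams of the count, library, dose and mutation
generators.

**Counts.** Three cell lines (one resistant, two sensitive) × four
treatments (DMSO reference, two monotherapies, combination) × 3 replicates;
2000 genes with log-normal baseline means and NB noise at dispersion 0.16.
79% of planted background changes are inductions, matching the observed
dominance of gene induction under these treatments. A resistance program
(60 up / 30 down) is planted only in the resistant line's drug condition; a
response program (40 up / 10 down) in every sensitive line's drug and combo
conditions; shared per-treatment response genes are planted in *all* lines
so profile subtraction has real work to do. Planted |log2FC| is
2.5 + Exp(1). The floor 2.5 was set by a power analysis carried out before
any recovery test was run: at 3 replicates and BCV 0.4 the per-condition
call probability at the floor is ≈0.99, so the four-way intersection
defining the response profile retains ≥95% of its genes — the recovery
property the generator is designed to make measurable. Planted genes are
drawn from genes with baseline mean ≥ 20 so recovery reflects the planted
effect rather than counting noise. Program sizes (tens of genes, with the
response repression set the smallest at 10 genes) mirror the strong
asymmetry such contrasts produce while keeping every recovery *fraction*
estimable.

What the generator does **not** emulate: transcriptome-wide correlation
structure, batch effects, varying library-composition biases, or
gene-length effects. Passing recovery tests therefore demonstrates that the
inference machinery is calibrated for the model it assumes, not that real
RNA-seq data meet those assumptions.

**Library.** Reference signatures are N(0,1) score vectors over the same
gene universe for two library cell lines. Planted reverser compounds place
resistance-up genes at the bottom and response-up genes at the top (score
magnitudes 4 + Exp(1)); each has a concordant target-gene knockdown and a
discordant overexpression partner, exercising the target-concordance filter
positively. Decoy compounds are unannotated; decoy KD/OE pairs are
independent noise except for a planted "ambiguous" subset whose KD and OE
are both concordant — the ambiguity filter must remove exactly these.

**Dose matrices.** Monotherapies follow Hill curves on a 5×3 dose grid
(plus the control row/column); combination viability is Bliss-expected
viability minus the planted delta (default 15 percent) plus N(0, 3%) noise,
clamped to [0, 120]. Curve maxima are capped at 0.5/0.4 so the expected
combination viability stays ≥5 noise standard deviations above the clamp —
otherwise censoring at 0 would bias delta recovery. With no noise the Bliss
score returns the planted delta exactly.

**Mutations.** Independent Bernoulli(0.3) alterations over 30 cell lines
and 20 genes; synergy is N(0,1) shifted by d = 3 in carriers of the planted
gene. At these sizes the planted association is detected with ≥95% power
while the p < 0.001 screen keeps the per-scan family-wise false-alarm rate
under 5% — both measured over seed batches, not asserted from theory.

# Problem sizes and numerical choices

The recovery experiments run at the design above (2000 genes, 36 samples)
with seed batches of 50 (partner ranking), 100 (Bliss noise recovery,
association power) and 500 (association null calibration); these sizes give
Monte-Carlo standard errors comfortably below the margins being tested.
Exact-test p-values are floored at the smallest positive double; enrichment
ties resolve to the positive deviation within 1e-12; signature rank ties
break by ascending gene symbol; all writers emit sorted rows so repeated
runs diff cleanly.

# Known limitations

* The NB exact test uses one fixed dispersion for all genes; genes with
  atypically high biological variability will be anticonservative.
* The connectivity engine scores a local library; percentile-based summary
  scores against a large touchstone population are out of scope.
* The Bliss estimator applies no monotherapy curve fitting, so a noisy
  monotherapy row propagates into every cell of its column.
* ORA treats gene sets as flat lists; ontology structure is ignored.
* The association scan assumes homoscedastic synergy scores across mutation
  groups; it inherits ANOVA's sensitivity to heavy tails at small group
  sizes.
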