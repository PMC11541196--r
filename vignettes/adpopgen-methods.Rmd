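---
title: "Models and methods in adpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in adpopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

adpopgen implements the allele-frequency toolkit used to analyse
low-coverage ancient-DNA time transects: pseudohaploid genotypes,
f-statistics with block-jackknife errors, rank-based continuity tests and
admixture-proportion models on systems of f4 statistics, X-versus-autosome
sex-bias inference, admixture dating from ancestry-covariance decay, and
post-processing of identity-by-descent (IBD) segments. This vignette
explains the models, the tunable parameters and their defaults, the
numerical choices, and what the shipped simulations do and do not
demonstrate.

## Data model

A `genotype_matrix` holds sites x individuals alternate-allele dosage codes
(0/1/2, `NA` missing) with a genetic map (centimorgans) per site. Ancient
individuals are typically *pseudohaploid*: one sequencing read is drawn per
site and its allele recorded as a homozygous code (0/2), the EIGENSTRAT
convention. A per-individual ploidy flag keeps the allele accounting honest
downstream: a pseudohaploid individual contributes one observed allele per
non-missing site to group frequencies, a diploid two. On disk the package
reads and writes plain-text EIGENSTRAT (`.geno`/`.snp`/`.ind`; genetic
positions in Morgans in the `.snp`, converted to cM at the I/O boundary;
missing code 9). Packed binary EIGENSTRAT is out of scope.

## Block jackknife

All standard errors are leave-one-block-out jackknives over blocks of
`width_cm = 5` centimorgans (`partition_blocks()`), the conventional width
that makes blocks effectively independent given human-scale linkage
disequilibrium. Blocks are greedy left-to-right within chromosomes and never
span a chromosome boundary. Scalar statistics use the weighted
(Busing-style) delete-one estimator with block weights equal to contributed
site counts; vectorized f4 systems use the unweighted delete-one covariance,
adequate because blocks are near-equal in genetic width. When no genetic map
exists the partition falls back to 5 Mb physical windows with a warning.

## f-statistics

Per site with group frequencies $p$:

* $f_2(A,B)$: $(p_A-p_B)^2$, optionally bias-corrected by subtracting
  $p(1-p)/(n-1)$ for each group ($n$ = observed allele count; sites with
  $n<2$ in a corrected group are dropped).
* $f_3(C;A,B)$: $(p_C-p_A)(p_C-p_B)$, corrected for the target $C$ only.
  Significantly negative values diagnose $C$ as admixed; with a distant
  outgroup as $C$ the statistic measures shared drift between $A$ and $B$.
* $f_4(A,B;C,D)$: $(p_A-p_B)(p_C-p_D)$, unbiased as-is. Zero under treeness
  of the unrooted topology $(A,B),(C,D)$; for
  $f_4(\text{Outgroup}, X; P_1, P_2)$, positive values indicate excess
  affinity of $X$ to $P_2$, negative to $P_1$, with $|Z|>3$ the usual
  significance convention.
* FST: Hudson's ratio-of-sums, numerator the corrected $(p_A-p_B)^2$,
  denominator $p_A(1-p_B)+p_B(1-p_A)$, with the jackknife applied to the
  ratio. `inbreed = TRUE` counts sample sizes in individuals rather than
  alleles, the safe accounting for pseudohaploid data.

Two site-selection modes exist. `"allsnps"` (default for the admixture
models, mirroring common qpAdm practice) lets each statistic use every site
at which its own populations are defined. `"intersection"` (default for
standalone statistics) restricts to sites defined in *every* group of the
frequency table, which makes the algebraic identities among f-statistics
(e.g. $f_3(C;A,B)=\tfrac12[f_2(A,C)+f_2(B,C)-f_2(A,B)]$, f4 additivity)
exact and is the right mode for matrix-wide comparisons.

## Rank tests and admixture models

`build_f4_matrix()` computes $X_{ij} = f_4(l_1, l_{i+1}; r_1, r_{j+1})$ for
a left set (targets/sources) against a right set (outgroups), retaining the
per-block leave-one-out replicates. The number of independent ancestry waves
relating left to right equals the rank of $E[X]$; `rank_test(fm, k)` fits
the best rank-$k$ approximation $AB'$ by alternating generalized least
squares under the jackknife covariance $Q$ of $\mathrm{vec}(X)$ and refers
the residual quadratic form to $(|L|-1-k)(|R|-1-k)$ degrees of freedom. Rank
0 with a two-population left set is the clade/continuity test: the pair is
consistent with forming a clade relative to the right set when $p > 0.01$.

**p-value calibration.** $Q$ is itself estimated from $g$ jackknife blocks,
so the quadratic form $x'Q^{-1}x$ is not asymptotically chi-square at
moderate $g$: for $q$ degrees of freedom it follows the Hotelling-type
scaled F law $\frac{q(g-1)}{g-q}F_{q,\,g-q}$. With twenty 5 cM blocks and
$q=3$ the raw chi-square cut at $p=0.01$ has true size of roughly 0.04,
which would make continuity tests anti-conservative exactly where ancient-DNA
panels are small. The package therefore reports the F-calibrated p-value as
`p_value` (and the asymptotic chi-square one as `p_chisq`). Under a
simulated true clade (100k sites, 20 blocks) the F-calibrated test has
empirical size 0.01 at the 0.01 rule and uniform p-values; this is computed
by the test suite.

`estimate_admixture()` models the target's f4 vector
$y_j(P)=f_4(P,r_1;r_{j+1},r_1)$ as $y(\text{target})=\sum_i a_i\,
y(\text{source}_i)$ with $\sum a_i = 1$, solved by GLS under the jackknife
covariance of the residual (iterating between the weights and the covariance
they imply). The residual chi-square with $(|R|-1)-(|S|-1)$ degrees of
freedom gives the model-fit p-value (F-calibrated as above). Weight standard
errors come from delete-one-block *re-estimation of the whole procedure*:
each replicate rebuilds the f4 matrix, its covariance (from delete-two block
sums) and the GLS solve from the remaining blocks. Re-estimating the
covariance inside the jackknife matters: holding it fixed understates the
weight uncertainty, because the GLS weights inherit noise from the estimated
covariance. One-source models reduce to the rank-0 clade test of target with
source.

`model_selection_ladder()` applies the published selection rule: evaluate
all 1-source, then 2-source, then 3-source models and return the first
complexity level containing a model with $p > 0.01$ and feasible weights
(all within $[0,1]$); within a level the highest p wins, and the full ladder
is returned for the record.

## Sex-biased admixture

`sex_bias()` runs the admixture model twice — autosomal sites and
X-chromosome sites, blocks re-partitioned within each subset (5 cM on X as
well) — and compares the focal-source proportions $p_A$ (autosomes) and
$p_X$ (X) with

$$Z = \frac{p_A - p_X}{\sqrt{\sigma_A^2 + \sigma_X^2}},$$

negative when the focal ancestry is enriched on the X, i.e. female-biased
admixture. Under a single pulse with female and male source-side
contributions $s_f, s_m$, expectations are $p_A = (s_f+s_m)/2$ and
$p_X = (2s_f+s_m)/3$ (females carry two of three X chromosomes), inverted as
$s_f = 3p_X - 2p_A$, $s_m = 4p_A - 3p_X$. The ratio $s_f/s_m$ carries a
delta-method standard error; solutions outside $[0,1]$ are flagged
non-physical, never clamped. A default of at least 2,000 X sites is required
for the X-side fit. The single-pulse assumption is inherited from the
method; multi-pulse sex-bias models are out of scope.

## Admixture dating

After a pulse $n$ generations ago, ancestry correlation between loci decays
as $e^{-n d}$ with genetic distance $d$ in Morgans. `ancestry_covariance()`
accumulates, for every intra-chromosomal site pair, the weighted covariance
$\mathrm{mean}_i\, w_s w_t r_{s,i} r_{t,i}$ (weights $w_s = p^A_s - p^B_s$
the source frequency contrast; residuals $r_{s,i}$ the individual's allele
dose minus the target mean) into distance bins of 0.001 Morgans (the
conventional bin size). `fit_decay()` then fits $A e^{-nd} + c$ by weighted
nonlinear least squares (weights = pair counts, via `minpack.lm`), with:

* fit window 0.005–1.0 Morgans by default — the shortest bins are excluded
  because unmodelled background LD dominates there;
* a fitted affine offset $c$ absorbing residual long-range covariance;
* start values from a log-linear regression, and a "no decay detected"
  result (never a spurious date) when the fitted rate or amplitude is
  non-positive;
* standard errors by delete-one-chromosome jackknife.

Generations convert to years at 29 years/generation (the dating convention;
contexts that need a generation *time* for age models conventionally use 30,
which is why the constant is an explicit argument, not hard-wired), plus the
sampling age in years before present for ancient targets. Pseudohaploid
targets halve the covariance amplitude but not its decay rate, so dates
remain valid with reduced power.

## Genotyping-level statistics

* `call_pseudohaploid()`: reads failing `min_baseq`/`min_mapq` (defaults
  30/30) are dropped; in `standard` mode bases within `trim_bp` (default 2)
  of a read end are clipped; in `single_strand` mode forward-strand reads at
  C/T SNPs and reverse-strand reads at G/A SNPs are ignored, which removes
  post-mortem deamination products of non-UDG single-stranded libraries by
  construction. Among surviving reads matching ref or alt, one is drawn
  uniformly (seeded).
* `merge_libraries()`: per-sample call merging; primary non-missing calls
  are never overwritten, fills apply only at missing sites, conflicts are
  counted and reported.
* `determine_sex()`: X and Y per-site read rates normalized by autosomal
  coverage; XX expects (1, 0), XY (0.5, 0.5). A call requires both rates
  within 3 Poisson SEs of one model and outside 3 SEs of the other —
  anything else is UNKNOWN. The 3-SE rule is this package's choice; the
  literature states the expectations, not thresholds.
* `pairwise_mismatch()` (kinship screening) haploidizes diploid columns with
  one seeded allele draw per site so pseudohaploid and diploid pairs are
  comparable; duplicates show about half the unrelated-pair rate.
  `conditional_nucleotide_diversity()` reports the within-group pairwise
  rates (box-plot-ready) and their mean — a comparative diversity measure on
  an ascertained panel, not an absolute estimate. A transversions-only
  option exists for damage-robust comparisons.
* `heterozygosity()` is the autosomal heterozygote fraction of a diploid
  (e.g. imputed) individual and refuses pseudohaploid input, where it is
  undefined.

## IBD post-processing

The package consumes segment tables from an external detector (RefinedIBD
dialect) and applies the published rules, in the published order: (1) drop
segments shorter than 1 cM (closed threshold: exactly 1 cM is kept); (2)
merge adjacent same-pair same-chromosome segments when the gap is strictly
shorter than 0.6 cM *and* contains at most one discordant homozygote
(opposite homozygous genotypes of the pair strictly inside the open gap;
heterozygous and missing sites never count), iterated until stable —
the operation is idempotent; (3) aggregate per-pair segment counts and
summed lengths. The strict 0.6 boundary is guarded against floating-point
representation so an exact-0.6 gap never merges. Discordance is counted on
diploid genotype codes; with no genotypes supplied only the width rule
applies (with a message).

## The synthetic-data generator

Frequency-level simulation keeps every expectation closed-form, which is why
it is the default oracle substrate (a coalescent simulator would be a second
oracle, not a requirement):

* ancestral frequencies Uniform(0.05, 0.95); each branch with drift $F$
  draws the child from Beta$(p(1-F)/F, (1-p)(1-F)/F)$ (Balding–Nichols), so
  $E[(p_1-p_2)^2] = (F_1+F_2)\,p_0(1-p_0)$ for two descendants — the basis
  of the drift-consistency checks (corrected $f_2$, and Hudson FST
  $\approx (F_1+F_2)/2$);
* admixture pulses mix leaf frequencies, $\alpha p_A + (1-\alpha) p_B$; a
  sex-biased pulse uses $(2s_f+s_m)/3$ on X-flagged sites;
* genotypes are Binomial(2, p) (diploid) or a Bernoulli allele recorded
  homozygous (pseudohaploid); a site is missing when a
  Poisson(mean coverage) draw is zero;
* ancestry tracts follow a Markov process with Poisson switch points at
  rate = generations per Morgan, state A with probability $\alpha$ at the
  origin and at each switch — giving the $e^{-nd}$ ancestry covariance the
  dating stage fits, with allele draws from source-specific frequencies per
  tract;
* pileups draw Poisson-depth reads from the true alleles; with probability
  $\delta$ a C on the forward strand (G on reverse) within 3 bp of a read
  end is flipped C→T (G→A) and flagged, only where the product is the site's
  other allele so observed bases stay within {ref, alt};
* the IBD fixture plants known post-merge segments and re-splits them with
  clean narrow gaps (must re-merge), wide gaps and discordant gaps (must
  stay split), and sub-1 cM fragments (must be filtered), alongside the
  matching genotypes.

The default tree ships one deeply diverged basal leaf (drift 0.4) and two
source clades each with a sister right-set leaf (drifts 0.05); the default
map is 10 chromosomes x 100 cM, i.e. about two hundred 5 cM blocks, and the
default sampling design is 10 pseudohaploid individuals per leaf. Shipped
test sizes (chosen as realistic desk-scale panels): 100k sites for null
calibration and rank structure on a 4 x 25 cM map (twenty 5 cM blocks), 50k
sites for drift and recovery checks, 20 diploids x 30 chromosomes x 600
sites for dating.

What the simulations do **not** emulate: background LD beyond admixture LD,
realistic human demography and recombination-map heterogeneity, sequencing
error beyond terminal deamination, reference/ascertainment bias, and
contamination. Passing tests therefore validate the estimators under their
own model assumptions; they do not certify behaviour on real capture data,
where ascertainment and LD effects are known to matter.

## Numerical choices and limitations

* Covariances are inverted via Cholesky; a numerically singular covariance
  gets a ridge $\lambda = 10^{-6}\,\overline{\mathrm{diag}}$ with a logged
  message.
* The rank-$k$ alternating GLS stops when the chi-square changes by less
  than $10^{-10}$ (300-iteration cap), initialized from the SVD of $X$.
* The weight solve iterates weights and residual covariance to a $10^{-12}$
  fixed point (50-iteration cap); weights sum to one exactly by
  construction.
* Exact-zero expectations (duplicate populations, identical sources in the
  dating weights, f4 of a repeated population) are exact in code, not just
  in expectation, and are asserted as such in the tests.
* The pairwise ancestry-covariance accumulator is O(sites² per chromosome)
  in memory and time; it is intended for panel-scale site counts per
  chromosome (hundreds to a few thousand), not whole-genome sequence data.
* Rank tests need $g$ blocks well above the matrix dimension; with
  $g \le q+1$ the code falls back to the asymptotic chi-square p-value.
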