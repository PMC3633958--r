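---
title: "GMDR: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GMDR: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmdr)
```

## The method

Generalized multifactor dimensionality reduction (GMDR) looks for joint
genotype effects — epistasis — that single-SNP association scans miss.  It
generalizes MDR, which pools the $3^k$ genotype cells of a $k$-SNP
combination into a single high-risk/low-risk attribute, by replacing the
case/control labels with a per-subject *score statistic*, so that covariates
can be adjusted for and quantitative traits analysed with the same
machinery.  The analysis has three stages:

1. **Scores.** A generalized linear model of the phenotype on the covariates
   (intercept always included) is fitted — logistic for binary traits,
   ordinary least squares for quantitative, log-link Poisson for counts —
   and each subject's score is the response residual $s_i = y_i -
   \hat\mu_i$.  For a canonical link this is proportional to the subject's
   contribution to the GLM score equation, and with an intercept the scores
   sum to zero.  With no covariates and a balanced binary trait the scores
   are exactly $\pm 1/2$, and the whole procedure reduces to classical MDR.

2. **Cross-validated cell classification.** Subjects are split into $K$
   folds ($K = 10$ by default).  For a combination of $k$ SNPs, each subject
   falls in one of $3^k$ genotype cells.  On each training set (all folds
   but one) a cell is labelled **high-risk** iff the sum of training scores
   in it is strictly positive.  The combination's *training accuracy* is the
   score-weighted balanced accuracy
   $$\mathrm{acc} = \tfrac12\Big[
     \frac{\sum_{i \in H,\, s_i > 0} s_i}{\sum_{s_i > 0} s_i} +
     \frac{\sum_{i \in L,\, s_i < 0} |s_i|}{\sum_{s_i < 0} |s_i|}
   \Big],$$
   where $H$ and $L$ are the subjects whose cell is high- and low-risk.
   When scores are $\pm c$ this is exactly MDR's balanced accuracy (mean of
   sensitivity and specificity).  Per fold, the `top_n` combinations by
   training accuracy are selected; the **cross-validation consistency**
   (CVC) of a combination is the number of folds selecting it, and
   candidates are retained when CVC exceeds $K/2$ (strict).

3. **Testing accuracy and significance.** The same formula evaluated on the
   held-out fold gives the per-fold testing accuracy; its mean over the $K$
   folds is the model's *observed testing accuracy*.  Significance comes
   from a permutation test: scores are permuted across subjects $N$ times
   (genotypes and folds fixed), all cell models are re-fitted and the
   testing accuracy re-averaged; $p = M/N$ with $M$ the number of permuted
   accuracies at least as high as the observed one.  When $M = 0$ the
   result is reported as the bound $< 1/N$.

Around the core sit SNP quality control, a physical-distance filter, a
staged two-way-then-conditioned multi-order search, and core-SNP detection;
`run_pipeline()` chains them.

## Conventions the literature leaves open

The accuracy formula above and several tie rules are not uniquely fixed by
the method's verbal description, so the package declares them explicitly;
they are its single most important documented assumptions.

* **Risk threshold 0.** Valid because computed scores are mean zero
  (intercept in the GLM).  User-supplied scores (`load_scores()`) are taken
  verbatim, so they should be centred by the user.
* **Ties and unseen cells.** A cell whose training score sum is exactly 0 is
  low-risk; a cell unoccupied in training is treated as low-risk at testing
  time.  Both choices are deterministic and conservative toward the null;
  `unseen = "exclude"` instead drops such subjects from the testing
  denominator.
* **Vacuous classes.** If an evaluation set contains no positive-score (or
  no negative-score) subjects, the corresponding term of the accuracy is set
  to $1/2$, keeping the statistic defined on tiny folds.
* **Ranking ties** are broken lexicographically by SNP index tuple, for bit
  reproducibility.
* **Residual type.** For non-normal families the "residual" is the response
  residual $y - \hat\mu$, consistent with the normal case and with the GLM
  score interpretation; deviance/Pearson residuals are not offered because
  the classification is not invariant to that choice and the score-equation
  argument singles out $y - \hat\mu$.
* **Folds.** Sizes differ by at most one.  For binary traits folds are
  stratified by case/control status by default (standard MDR practice);
  stratification uses a carried-offset round robin so each stratum *and*
  the total stay balanced.  Fold labels are 1..K.
* **Permutation streams.** Each combination's permutations are drawn from
  an independent stream seeded by (master seed, SNP tuple), so p-values do
  not depend on evaluation order.  The $\ge$ comparison uses a $10^{-12}$
  tolerance to absorb floating-point jitter; an exactly-equal permuted
  accuracy (e.g. all-zero scores) therefore counts toward $M$, giving
  $p = 1$ in the fully degenerate case.  Folds are *not* re-drawn per
  permutation.  `estimator = "add_one"` gives $(M+1)/(N+1)$ for users who
  want a proper estimator instead of the $M/N$ convention with its
  $< 1/N$ bound.

## Quality control and the staged search

QC removes SNPs with missing-call rate $> 0.10$, minor allele frequency
$< 0.05$, or Hardy–Weinberg p-value $< 0.001$; all comparisons are strict,
so MAF exactly 0.05 survives.  For binary traits, missingness and MAF must
pass in cases and in controls separately, and HWE is tested in controls
only (disease association itself distorts HWE in cases); for quantitative
traits all filters use the full sample.  The HWE test is the exact
conditional test — enumeration over heterozygote counts with allele totals
fixed — which is well defined at the small counts where the filter bites; a
chi-square alternative is available (`hwe_method = "chisq"`).  Filters are
applied in the order missingness → MAF → HWE and the first failing rule is
recorded, but the kept set does not depend on the order.

The search first enumerates all pairs, skipping any pair on the same
chromosome closer than 1 Mb (strict: exactly 1 Mb passes) — a guard against
interactions that merely reflect linkage disequilibrium.  Higher orders
(3–5) are not searched exhaustively; they are *conditioned* on the unique
SNPs harvested from the per-fold top pair selections (`harvest_top_snps()`),
with the same fold assignment reused across orders for comparability.  The
final report keeps models with CVC at or above `final_cvc_min` and p-value
at or below `final_p_max`, where a bound $< 1/N$ qualifies iff $1/N$ meets
the threshold.  A **core SNP** is one appearing in at least
`core_min_models` distinct significant models at any orders; the rule is
parameterized because it is only ever described verbally, and the report
records the rule used.

## The synthetic-data generator

`simulate_genotypes()` draws independent Hardy–Weinberg genotypes at given
MAFs; `simulate_phenotype()` layers a penetrance table (binary) or cell
mean-shift (quantitative) over chosen loci, optional standard-normal
covariates with linear/logistic effects, and a null model with a set
prevalence.  The canonical planted interaction is the two-locus XOR
(checkerboard) model — penetrance `high` when exactly one locus is
heterozygous — because at MAF 0.5 it has zero marginal effects, so
detecting it exercises pure interaction detection rather than main effects.

What the generator does **not** emulate: linkage disequilibrium (loci are
independent; the distance filter is exercised through positions, not
correlation), population structure and relatedness, genotyping-batch
artefacts, and case/control ascertainment.  Passing tests therefore show
the machinery is correct under clean exchangeable sampling, not that real
GWAS confounding is handled — that is what the QC stage and the user's
study design are for.

## Numerical and scale choices

All randomness flows from one master seed, fanned out to named substreams
(folds, per-combination permutations, simulator) through a small modular
hash, so full pipelines are reproducible byte-for-byte and invariant to the
input row order of subjects (the pipeline sorts subjects by id on load).
The permutation engine evaluates permutations in vectorized blocks (cell
sums via grouped row sums, training sums by the total-minus-fold identity),
which keeps $10^4$ permutations of a pair at $n$ in the hundreds well under
a second; the genome-scale default of $10^7$ permutations is reachable by
setting `n_perm` where the compute budget allows.

The package's own validation studies use desk-scale problem sizes chosen to
make their statistical verdicts sharp: oracle equivalence on 200 random
instances ($n \le 50$, $k \le 3$, tolerance $10^{-12}$); null calibration
on 200 replicate datasets ($n = 300$, 10 SNPs, 200 permutations) with the
empirical rejection rate checked against its binomial 99% interval;
planted-XOR recovery at $n = 800$, 20 SNPs (noise-free: recovery certain;
penetrance 0.9/0.1: at least 95% of replicates).  The exact HWE test is
checked against a full-enumeration oracle for every count triple up to
$n = 30$.

## Known limitations

* Exhaustive enumeration is materialized in memory; at hundreds of
  thousands of SNPs (or order 5 over hundreds of SNPs) a streaming,
  compiled or accelerator-based enumeration would be needed — out of scope
  here.
* Missing genotypes are never imputed; subjects missing any SNP of a
  combination are excluded for that combination only, so effective sample
  size varies slightly across combinations.
* The p-value of a *selected* (top-ranked) model is not uniform under the
  null — selection biases it downward; calibration holds for pre-specified
  combinations, which is what the null-calibration study uses.
* X-chromosome coding, dosage genotypes and phased haplotypes are not
  supported.
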