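---
title: "Detecting treatment-reversed aging signatures: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting treatment-reversed aging signatures: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reverta)
```

`reverta` implements the transcriptome side of a late-life intervention
study: does a treatment given to old animals move gene expression back
toward the young state, and is that effect contingent on a specific gene
being present? This vignette is the package's account of the underlying
statistics — what is computed, which conventions were chosen where several
were defensible, and what a passing test does and does not establish.

## Expression quantification and filtering

Counts are normalised to RPKM (reads per kilobase of exon model per million
mapped reads),

$$\mathrm{RPKM}_{gs} = \frac{10^9 \, c_{gs}}{L_g \, N_s},$$

with $L_g$ the exon-model length in bp and $N_s$ the library size. The
library size is taken as the **column sum of the analysed count matrix**;
true mapping depth is not available once a matrix has been subset, and
per-matrix sums keep an analysis self-contained. The cost is a mild
compositionality: very large planted (or real) expression changes shift the
column sums themselves, which slightly displaces all other genes' RPKM in
the affected samples. With realistically sized matrices (tens of thousands
of genes, of which a few hundred respond) the displacement is negligible;
in small simulated panels it is measurable (see *Simulator scope* below).

Detection filtering keeps gene $g$ when $\mathrm{RPKM}_{gs} > 4$ (strict) in
at least 50% of samples (inclusive). Both thresholds are arguments
(`filter_expressed(threshold, min_fraction)`); the defaults are the
convention in aging-muscle transcriptome studies, which retain roughly
6.2–6.4 thousand genes per tissue. The filter is applied once per tissue
across all samples entering the analysis (all groups pooled), and it is
idempotent.

## The per-gene contrast

The publications this pipeline mirrors report RPKM-level p-values without
naming a test. We adopt a two-sided Welch unequal-variance t-test on
$\log_2(\mathrm{RPKM}+1)$, with the log2 fold change defined as the
difference of transformed group means (comparison − reference). Rationale:
it operates at the level the data are described (RPKM, not counts), it
needs no dispersion fitting, and the classifiers downstream only consume
(log2FC, p, q) triples — so a count-model statistic can be substituted
without touching anything else. The pseudocount (1) keeps zero-RPKM genes
finite and shrinks fold changes of barely expressed genes.

Degenerate inputs are resolved deterministically: zero variance in both
groups gives p = 1 when the means agree (log2FC = 0) and p = 0 when they
differ.

Multiple testing uses the Benjamini–Hochberg step-up rule, authored in the
package (it is the primitive the DEG definitions hang on) and cross-checked
in the tests against both a quadratic-time evaluation of the definition and
`stats::p.adjust`: with p-values sorted ascending,
$q_{(i)} = \min_{j \ge i} p_{(j)} m / j$, capped at 1, in the original
order. Ties share the larger index's factor through the running minimum.

## The reversal classifier

Given three contrasts over one gene universe — set 1: aged-vehicle vs
young; set 2: aged-treated vs aged-vehicle; set 3: aged-treated vs young —
a gene is

* `not_aging_deg` if $q^{(1)} \ge 0.1$;
* otherwise an aging DEG with direction $\mathrm{sign}(\mathrm{log2FC}^{(1)})$;
* `reverted` if additionally $p^{(2)} < 0.05$ with
  $\mathrm{sign}(\mathrm{log2FC}^{(2)}) = -\mathrm{sign}(\mathrm{log2FC}^{(1)})$
  and $p^{(3)} > 0.05$;
* `aging_not_reverted` otherwise.

Conventions worth stating:

* **All inequalities are strict**, exactly as the thresholds are written
  ("FDR < 0.1", "p < 0.05", "p > 0.05"); equality at a boundary fails.
* **Reversal is sign opposition only.** No magnitude of reversal is
  required; a gene that overshoots far past the young level still counts if
  criterion 3 does not catch it.
* **Criterion 3 is acceptance of the null.** "p > 0.05" treats failure to
  detect a treated-vs-young difference as evidence of equivalence. That is
  a known statistical weakness — low power *helps* a gene pass — and it is
  kept because it is the published rule. A proper equivalence (TOST) bound
  would be the principled replacement.
* Sets 2 and 3 use raw p-values; the FDR adjustment applies to the set-1
  DEG definition only. Both choices are arguments.
* A gene whose set-2 p passes with a log2FC of exactly 0 has no reversal
  sign and is classified `aging_not_reverted`, with a note.

## The genotype-dependence partition

From a wild-type × knockout factorial (each on vehicle or treatment), the
wild-type treatment contrast defines DEGs at FDR < 0.2; each DEG is then
labelled by the knockout treatment contrast: `dependent` when the knockout
shows no response (p > 0.05), `independent` when the response persists
(p < 0.05). A knockout p exactly at the threshold is called `dependent`
(the conservative reading: absence of clear evidence that the response
persists), with a note. The same acceptance-of-null caveat as criterion 3
applies to the `dependent` label.

`summarize_partition()` reports counts and percentages with explicit
denominators: category percentages of the DEG total (e.g. 72 of 91 DEGs
dependent = 79.1%), and — when a gene-to-label map is supplied — label
percentages *within each called category* (e.g. 53 metabolism genes of 72
dependent = 73.6%). Percentages are rounded to one decimal; an empty DEG
set yields `NA` percentages, not an error.

## Lifespan analysis

Kaplan–Meier curves come from `survival::survfit`; the package adds the
study-level arithmetic. The KM median is the smallest time with survivor
estimate ≤ 0.5 — on fully observed data this is the empirical median
(lower median for even n). Maximum lifespan is the single longest observed
death time, censored times excluded; a top-decile mean is deliberately not
the default because published comparisons name single extreme values.
Changes are reported as treated − reference and 100 × delta/reference, full
precision retained, one decimal for display.

The log-rank (Mantel–Cox) statistic is hand-coded (hypergeometric variance,
1-df chi-square) because the exact small-sample variant needs the statistic
inside a permutation loop; it is cross-checked against
`survival::survdiff` in the tests. `exact = TRUE` enumerates all
$\binom{n}{n_A}$ arm-label assignments and reports the proportion with a
chi-square at least the observed one.

## Simulator scope

The generator's defaults are a stated world, fixed once:

| parameter | default | why |
|---|---|---|
| baseline log2-RPKM | U(2.5, 9) | the expressed-transcriptome stratum: real analyses keep only filter-passing genes (~6k of ~20k), so effects are planted where they are detectable |
| dispersion φ | 0.05 | typical inter-replicate variability for inbred-mouse tissue RNA-seq; Var = μ + φμ² |
| effect size | 2 log2 units | a strong but realistic aging signature |
| library size | log-normal, mean 5 × 10⁶, CV 0.1 | moderate depth with realistic spread |
| gene length | U(500, 5000) bp | the bulk of the mammalian exon-model length distribution |
| groups | 5/group; young = 3 mo, old = 26 mo | the usual late-life cohort layout |
| survival | Weibull, shape 6, median 25.95 mo, shift +2.25 mo, follow-up 40 mo | shape 6 gives the steep old-age mortality of laboratory mice; the medians mirror a published vehicle/treated pair; Weibull (not Gompertz) because the median inverts in closed form |

One field was added to the design beyond the obvious ones: the fraction of
genes treatment-responsive in wild type (`frac_treatment`), from which
`frac_dependent` carves the knockout-ablated subset — without it the
factorial world is not generable. Class sizes round by `floor`; leftovers
carry no effect. Aging direction and treatment direction are random ±1 per
gene; reversal is full by default (`reversal_fraction = 1`), partial
reversal being unquantified in the literature this mirrors.

What the simulator does **not** emulate: batch effects, isoform structure,
length-dependent biases, correlated gene modules, or realistic panel size.
The last one matters quantitatively: planting ±2-log2 shifts in 10% of a
2000-gene panel moves the column-sum library sizes by several percent
(asymmetrically, because $2^{+2}$ adds more mass than $2^{-2}$ removes),
which a ~20k-gene matrix would not suffer. Consequently the false-DEG
fraction at FDR 0.2 in the factorial world runs above the nominal
$\pi_0 q \approx 0.18$, and since a truth-null DEG's knockout contrast is
null, such genes land in the `dependent` bin with probability ≈ 0.95. Even
in a perfectly calibrated world the expected dependent share under a
no-dependence truth is therefore ≈ 17%, and in the simulated panel it is
higher still — so the tests bound it at 30% and separately assert the
scientifically meaningful statement: genes with a genuinely retained
knockout response are almost never called dependent. A green recovery test
therefore establishes that the classifiers rank and label *planted* effects
correctly at the stated power, not that the FDR of the DEG step transfers
to the dependence labels.

## Numerical conventions, in one place

* Strict threshold comparisons throughout; dependence tie → `dependent`.
* BH: stable sort, running minimum, cap at 1.
* z-scores: sample SD (n − 1); constant rows → all-zero with a warning.
* PCA: samples are observations; gene dimensions centred, not scaled
  (inputs are typically already z-scored); SVD via `prcomp`.
* KM median: first time with survivor ≤ 0.5 (+10⁻¹² slack for float ties);
  all-censored arm → `NA` with a message, never an exception.
* Percentages: one decimal; months: two decimals for display.
* Determinism: simulation is a pure function of (spec, seed); the pipelines
  contain no randomness, and reruns produce byte-identical files (the
  provenance record deliberately excludes timestamps).

## Limitations

The Welch-on-RPKM statistic discards count-level information that
negative-binomial models (DESeq2, edgeR, limma-voom) would use; it is the
faithful-to-source default, not the recommendation for new designs. The
reversal and dependence calls inherit every weakness of accept-the-null
screening. And the published gene counts these analyses echo (141- and
41-gene reverted sets, a 91-gene DEG partition) depend on unreleased data;
the package reproduces the *procedure* and its printed arithmetic, and
validates recovery on simulated worlds with known truth instead.
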