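#' Specify a synthetic bulk RNA-seq experiment
#'
#' A `design_spec` describes the groups, planted effect structure and noise
#' model for [simulate_experiment()]. Counts are negative binomial with
#' variance \eqn{\mu + \phi \mu^2}; planted effects are log2-unit shifts in
#' group means. Three effect classes can be planted:
#'
#' * **aging genes** (`frac_aging` of all genes) shift by `+/- effect_size`
#'   in every aged group (age >= 18 months);
#' * **reverted genes** (`frac_reverted` of the aging genes) additionally
#'   receive the opposite shift in aged, treated groups, so treatment moves
#'   them back toward the young level (`reversal_fraction` scales how far);
#' * **treatment-responsive genes** (`frac_treatment` of all genes, drawn
#'   from the non-aging pool) shift by `+/- effect_size` in treated groups;
#'   `frac_dependent` of them lose that shift in knockout-genotype groups
#'   (genotype-dependent), the rest keep it (genotype-independent).
#'
#' Class counts are `floor(fraction * pool size)`; leftover genes carry no
#' effect.
#'
#' @param groups Data frame with columns `group`, `n`, `age_months`,
#'   `genotype` (`"WT"` or `"mcKO"`), `treatment` (`"none"`, `"Veh"` or
#'   `"Hes"`). Each group needs `n >= 2` samples.
#' @param n_genes Number of genes to simulate.
#' @param frac_aging Fraction of genes with an aging effect.
#' @param frac_reverted Fraction of aging genes whose effect is reversed by
#'   treatment.
#' @param frac_treatment Fraction of genes treatment-responsive in wild type
#'   (factorial designs; drawn from the non-aging pool).
#' @param frac_dependent Fraction of treatment-responsive genes whose
#'   treatment effect is ablated in the knockout genotype.
#' @param effect_size Planted mean shift in log2 units.
#' @param dispersion Negative-binomial dispersion phi (variance mu + phi mu^2).
#' @param libsize_mean,libsize_cv Mean and coefficient of variation of the
#'   log-normal library-size distribution (target sequencing depth in reads).
#' @param length_range_bp Length-2 vector, min/max exon-model length in bp;
#'   gene lengths are uniform on this range.
#' @param baseline_log2_range Length-2 vector, range of baseline log2-RPKM
#'   expression levels (uniform). The default starts above the conventional
#'   RPKM > 4 detection threshold so simulated genes represent the expressed
#'   transcriptome that survives filtering.
#' @param reversal_fraction How much of the aging shift treatment undoes in
#'   reverted genes (1 = full reversal).
#' @param tissue Tissue label written to the sample sheet.
#' @param seed Integer seed; the same spec and seed give bit-identical data.
#'
#' @return A list of class `design_spec`.
#' @seealso [reversal_design()], [dependence_design()], [simulate_experiment()]
#' @export
design_spec <- function(groups,
                        n_genes = 2000,
                        frac_aging = 0.10,
                        frac_reverted = 0.50,
                        frac_treatment = 0,
                        frac_dependent = 0.50,
                        effect_size = 2,
                        dispersion = 0.05,
                        libsize_mean = 5e6,
                        libsize_cv = 0.1,
                        length_range_bp = c(500, 5000),
                        baseline_log2_range = c(2.5, 9),
                        reversal_fraction = 1,
                        tissue = "gastrocnemius",
                        seed = 1L) {
  groups <- as_tibble(groups)
  check_columns(groups, c("group", "n", "age_months", "genotype", "treatment"),
                "`groups`")
  if (nrow(groups) < 2L) abort("`groups` must define at least two groups.")
  if (anyDuplicated(groups$group)) abort("`groups` has duplicated group labels.")
  if (any(groups$n < 2L)) {
    bad <- groups$group[groups$n < 2L]
    abort(sprintf("`n` must be >= 2 per group; offending group(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  if (!all(groups$genotype %in% c("WT", "mcKO"))) {
    abort("`genotype` must be 'WT' or 'mcKO'.")
  }
  if (!all(groups$treatment %in% c("none", "Veh", "Hes"))) {
    abort("`treatment` must be 'none', 'Veh' or 'Hes'.")
  }
  check_positive(n_genes, "n_genes")
  for (f in c("frac_aging", "frac_reverted", "frac_treatment", "frac_dependent",
              "reversal_fraction")) {
    check_fraction(get(f), f)
  }
  check_positive(effect_size, "effect_size", strict = FALSE)
  check_positive(dispersion, "dispersion")
  check_positive(libsize_mean, "libsize_mean")
  check_positive(libsize_cv, "libsize_cv", strict = FALSE)
  if (length(length_range_bp) != 2L || any(length_range_bp < 1) ||
      length_range_bp[1] > length_range_bp[2]) {
    abort("`length_range_bp` must be c(min, max) with 1 <= min <= max.")
  }
  if (length(baseline_log2_range) != 2L ||
      baseline_log2_range[1] > baseline_log2_range[2]) {
    abort("`baseline_log2_range` must be c(min, max) with min <= max.")
  }
  n_aging <- floor(frac_aging * n_genes)
  if (floor(frac_treatment * n_genes) > n_genes - n_aging) {
    abort("`frac_treatment`: not enough non-aging genes for the requested fraction.")
  }
  structure(
    list(groups = groups, n_genes = as.integer(n_genes),
         frac_aging = frac_aging, frac_reverted = frac_reverted,
         frac_treatment = frac_treatment, frac_dependent = frac_dependent,
         effect_size = effect_size, dispersion = dispersion,
         libsize_mean = libsize_mean, libsize_cv = libsize_cv,
         length_range_bp = length_range_bp,
         baseline_log2_range = baseline_log2_range,
         reversal_fraction = reversal_fraction,
         tissue = tissue, seed = as.integer(seed)),
    class = "design_spec"
  )
}

#' Three-group aging/treatment design (young, aged-vehicle, aged-treated)
#'
#' Convenience constructor for the design behind the reversal classifier:
#' young wild-type controls plus aged wild-type mice on vehicle or on
#' treatment. Aging effects and their (partial) reversal are planted;
#' no factorial genotype structure.
#'
#' @param n_per_group Samples per group.
#' @param frac_treatment Fraction of genes treatment-responsive in wild type
#'   (0 here: treatment effects enter only through reversal of aging genes).
#' @param ... Passed on to [design_spec()] to override defaults.
#' @return A `design_spec`.
#' @export
reversal_design <- function(n_per_group = 5, frac_treatment = 0, ...) {
  groups <- tibble(
    group = c("young", "old_veh", "old_hes"),
    n = n_per_group,
    age_months = c(3, 26, 26),
    genotype = "WT",
    treatment = c("none", "Veh", "Hes")
  )
  design_spec(groups = groups, frac_treatment = frac_treatment, ...)
}

#' Four-group wild-type x knockout factorial design
#'
#' Convenience constructor for the genotype-dependence design: wild-type and
#' muscle-specific knockout animals, each on vehicle or treatment, all at one
#' age. Treatment-responsive genes are planted in wild type and a fraction of
#' them lose their response in the knockout.
#'
#' @inheritParams reversal_design
#' @param frac_aging,frac_reverted No aging structure in this design by
#'   default (all animals share one age).
#' @param frac_treatment Fraction of genes treatment-responsive in wild type.
#' @return A `design_spec`.
#' @export
dependence_design <- function(n_per_group = 5, frac_aging = 0,
                              frac_reverted = 0, frac_treatment = 0.10, ...) {
  groups <- tibble(
    group = c("wt_veh", "wt_hes", "ko_veh", "ko_hes"),
    n = n_per_group,
    age_months = 7,
    genotype = c("WT", "WT", "mcKO", "mcKO"),
    treatment = c("Veh", "Hes", "Veh", "Hes")
  )
  design_spec(groups = groups, frac_aging = frac_aging,
              frac_reverted = frac_reverted,
              frac_treatment = frac_treatment, ...)
}

#' Parameters for the Weibull lifespan simulator
#'
#' Lifetimes are Weibull with the scale chosen so the theoretical median
#' equals `baseline_median_months` (plus `treatment_median_shift_months` in
#' the treated arm). Deaths beyond `max_follow_up_months` are censored there.
#'
#' @param baseline_median_months Control-arm theoretical median lifespan.
#' @param treatment_median_shift_months Added to the treated arm's median.
#' @param shape Weibull shape; larger values concentrate deaths around the
#'   median, as seen in laboratory-mouse cohorts.
#' @param max_follow_up_months Administrative censoring time.
#' @param seed Integer seed.
#' @return A list of class `survival_params`.
#' @export
survival_params <- function(baseline_median_months = 25.95,
                            treatment_median_shift_months = 2.25,
                            shape = 6,
                            max_follow_up_months = 40,
                            seed = 1L) {
  check_positive(baseline_median_months, "baseline_median_months")
  if (!is.numeric(treatment_median_shift_months) ||
      length(treatment_median_shift_months) != 1L ||
      !is.finite(treatment_median_shift_months)) {
    abort("`treatment_median_shift_months` must be a single finite number.")
  }
  check_positive(shape, "shape")
  check_positive(max_follow_up_months, "max_follow_up_months")
  if (baseline_median_months + treatment_median_shift_months <= 0) {
    abort("treated-arm median (baseline + shift) must be positive.")
  }
  structure(
    list(baseline_median_months = baseline_median_months,
         treatment_median_shift_months = treatment_median_shift_months,
         shape = shape, max_follow_up_months = max_follow_up_months,
         seed = as.integer(seed)),
    class = "survival_params"
  )
}
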