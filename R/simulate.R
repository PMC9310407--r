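#' Simulate a bulk RNA-seq count experiment with planted truth
#'
#' Draws a gene-by-sample negative-binomial count matrix whose group means
#' encode the planted aging, reversal and genotype-dependence structure of a
#' [design_spec()], together with the gene annotation (exon-model lengths),
#' sample sheet and per-gene ground-truth labels needed to score the
#' downstream classifiers.
#'
#' Counts for gene g in sample s are NB with mean
#' \deqn{\mu_{gs} = 2^{b_g + \delta_{g,k(s)}} \times \mathrm{length_{kb}}(g)
#'   \times \mathrm{libsize}(s) / 10^6,}
#' i.e. a baseline log2-RPKM `b_g` plus the planted group shift, converted to
#' expected reads through the RPKM formula. Library sizes are log-normal with
#' the spec's mean and CV; gene lengths are uniform on `length_range_bp`.
#' A group is "aged" when its `age_months >= 18`.
#'
#' @param spec A [design_spec()].
#' @return A list of class `sim_experiment` with elements
#'   \describe{
#'     \item{counts}{tibble: `gene_id` + one integer column per sample.}
#'     \item{annotation}{tibble: `gene_id`, `length_bp`.}
#'     \item{sample_sheet}{tibble: `sample_id`, `group`, `age_months`,
#'       `genotype`, `treatment`, `tissue`.}
#'     \item{truth}{tibble: `gene_id`, `aging_direction` (up/down/none),
#'       `reverted` (logical), `dependence` (dependent/independent/none).}
#'   }
#' @examples
#' sim <- simulate_experiment(reversal_design(n_genes = 200, seed = 7))
#' table(sim$truth$aging_direction)
#' @export
simulate_experiment <- function(spec) {
  if (!inherits(spec, "design_spec")) {
    abort("`spec` must be a design_spec object.")
  }
  groups <- spec$groups
  n_genes <- spec$n_genes
  gene_id <- sprintf("g%05d", seq_len(n_genes))

  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  length_bp <- as.integer(round(runif(n_genes, spec$length_range_bp[1],
                                      spec$length_range_bp[2])))
  baseline <- runif(n_genes, spec$baseline_log2_range[1],
                    spec$baseline_log2_range[2])

  # Planted class assignment: floor rounding, leftover genes carry no effect.
  n_aging <- floor(spec$frac_aging * n_genes)
  n_rev <- floor(spec$frac_reverted * n_aging)
  n_trt <- floor(spec$frac_treatment * n_genes)
  n_dep <- floor(spec$frac_dependent * n_trt)

  idx <- sample.int(n_genes)
  aging_idx <- idx[seq_len(n_aging)]
  rev_idx <- aging_idx[seq_len(n_rev)]
  trt_idx <- idx[n_aging + seq_len(n_trt)]
  dep_idx <- trt_idx[seq_len(n_dep)]

  aging_dir <- integer(n_genes)
  aging_dir[aging_idx] <- sample(c(-1L, 1L), n_aging, replace = TRUE)
  reverted <- logical(n_genes)
  reverted[rev_idx] <- TRUE
  trt_dir <- integer(n_genes)
  trt_dir[trt_idx] <- sample(c(-1L, 1L), n_trt, replace = TRUE)
  dependent <- logical(n_genes)
  dependent[dep_idx] <- TRUE

  sample_sheet <- tidyr::uncount(groups, weights = .data$n, .id = "rep")
  sample_sheet <- dplyr::mutate(
    sample_sheet,
    sample_id = paste0(.data$group, "_", .data$rep),
    tissue = spec$tissue
  )
  sample_sheet <- dplyr::select(
    sample_sheet, "sample_id", "group", "age_months", "genotype",
    "treatment", "tissue"
  )
  n_samples <- nrow(sample_sheet)

  libsize_sdlog <- sqrt(log1p(spec$libsize_cv^2))
  libsize <- rlnorm(n_samples,
                    meanlog = log(spec$libsize_mean) - libsize_sdlog^2 / 2,
                    sdlog = libsize_sdlog)

  # Per-group log2 shifts: aging effect in aged groups, reversal in aged
  # treated groups, treatment response in treated groups (ablated in the
  # knockout for dependent genes).
  is_old <- sample_sheet$age_months >= 18
  is_hes <- sample_sheet$treatment == "Hes"
  is_ko <- sample_sheet$genotype == "mcKO"
  es <- spec$effect_size

  delta <- matrix(0, n_genes, n_samples)
  if (any(is_old)) {
    delta[, is_old] <- delta[, is_old] + aging_dir * es
  }
  if (any(is_old & is_hes)) {
    sel <- is_old & is_hes
    delta[, sel] <- delta[, sel] -
      reverted * aging_dir * es * spec$reversal_fraction
  }
  if (any(is_hes)) {
    trt_effect <- outer(trt_dir * es, rep(1, sum(is_hes)))
    ko_hes <- is_ko[is_hes]
    if (any(ko_hes)) trt_effect[dependent, ko_hes] <- 0
    delta[, is_hes] <- delta[, is_hes] + trt_effect
  }

  mu <- 2^(baseline + delta) * (length_bp / 1e3) *
    rep(libsize / 1e6, each = n_genes)
  counts <- matrix(
    rnbinom(n_genes * n_samples, size = 1 / spec$dispersion, mu = mu),
    n_genes, n_samples,
    dimnames = list(gene_id, sample_sheet$sample_id)
  )

  truth <- tibble(
    gene_id = gene_id,
    aging_direction = dplyr::case_when(
      aging_dir > 0 ~ "up", aging_dir < 0 ~ "down", .default = "none"
    ),
    reverted = reverted,
    dependence = dplyr::case_when(
      trt_dir != 0 & dependent ~ "dependent",
      trt_dir != 0 & !dependent ~ "independent",
      .default = "none"
    )
  )

  structure(
    list(counts = matrix_to_expr(counts),
         annotation = tibble(gene_id = gene_id, length_bp = length_bp),
         sample_sheet = sample_sheet,
         truth = truth,
         spec = spec),
    class = "sim_experiment"
  )
}

#' Simulate two-arm mouse lifespan data
#'
#' Weibull lifetimes per arm, with each arm's scale solved from the target
#' median: \eqn{\lambda = m / (\log 2)^{1/k}} for median m and shape k.
#' Deaths beyond the follow-up horizon are administratively censored.
#'
#' @param n_control,n_treated Animals per arm (>= 1).
#' @param params A [survival_params()].
#' @param arm_labels Length-2 character: labels for the control and treated
#'   arms, in that order.
#' @return A tibble with columns `animal_id`, `arm`, `time_months`, `event`
#'   (1 = death observed, 0 = censored).
#' @examples
#' surv <- simulate_survival(8, 19, survival_params(seed = 3))
#' dplyr::count(surv, arm, event)
#' @export
simulate_survival <- function(n_control, n_treated, params,
                              arm_labels = c("Veh", "Hes")) {
  if (!inherits(params, "survival_params")) {
    abort("`params` must be a survival_params object.")
  }
  if (!is.numeric(n_control) || n_control < 1 ||
      !is.numeric(n_treated) || n_treated < 1) {
    abort("`n_control` and `n_treated` must be >= 1.")
  }
  if (length(arm_labels) != 2L) abort("`arm_labels` must have length 2.")
  set.seed(params$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  k <- params$shape
  medians <- c(params$baseline_median_months,
               params$baseline_median_months +
                 params$treatment_median_shift_months)
  scales <- medians / log(2)^(1 / k)
  n <- c(as.integer(n_control), as.integer(n_treated))
  out <- purrr::map2(seq_along(n), n, function(a, na) {
    t <- rweibull(na, shape = k, scale = scales[a])
    tibble(
      arm = arm_labels[a],
      time_months = pmin(t, params$max_follow_up_months),
      event = as.integer(t <= params$max_follow_up_months)
    )
  })
  out <- dplyr::bind_rows(out)
  dplyr::mutate(out,
                animal_id = sprintf("m%03d", dplyr::row_number()),
                .before = 1)
}
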