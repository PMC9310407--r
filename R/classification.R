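#' Classify genes as reversed by treatment
#'
#' The three-criterion reversal (rejuvenation) call over a shared gene
#' universe, given the three contrasts of the aging design:
#' \itemize{
#'   \item set1 — aged-vehicle vs young: a gene is an aging DEG when its BH
#'     q-value is strictly below `fdr_set1`; the aging direction is the sign
#'     of its set1 log2 fold change.
#'   \item set2 — aged-treated vs aged-vehicle: the treatment response must
#'     be significant at raw `p < p_set2` **and** oppose the aging direction
#'     (strict sign opposition of the log2 fold changes).
#'   \item set3 — aged-treated vs young: the treated animals must be
#'     statistically indistinguishable from young ones, raw `p > p_set3`.
#' }
#' Genes failing criterion 1 are `not_aging_deg`; aging DEGs failing 2 or 3
#' are `aging_not_reverted`; genes passing all three are `reverted`. All
#' comparisons are strict, exactly as the thresholds are written.
#'
#' @param set1,set2,set3 `contrast_tbl` objects over the same gene universe,
#'   oriented as described above.
#' @param fdr_set1 FDR threshold for the aging DEG call (default 0.1).
#' @param p_set2 Raw-p threshold for the treatment response (default 0.05).
#' @param p_set3 Raw-p floor for young-vs-treated indistinguishability
#'   (default 0.05).
#' @return A `reversal_call`: tibble with `gene_id`, `category`
#'   (`not_aging_deg` / `aging_not_reverted` / `reverted`), `aging_direction`
#'   (`up` / `down` / `none`) and the per-set `log2_fc`, `p_raw`, `q_bh`
#'   columns (suffixed `_set1`..`_set3`); thresholds stored as attributes.
#' @export
classify_reversal <- function(set1, set2, set3,
                              fdr_set1 = 0.1, p_set2 = 0.05, p_set3 = 0.05) {
  for (th in c(fdr_set1, p_set2, p_set3)) check_fraction(th, "threshold")
  check_universes(list(set1 = set1, set2 = set2, set3 = set3))
  d <- dplyr::bind_cols(
    set1,
    setNames(set2[c("log2_fc", "p_raw", "q_bh")],
             c("log2_fc_set2", "p_raw_set2", "q_bh_set2")),
    setNames(set3[c("log2_fc", "p_raw", "q_bh")],
             c("log2_fc_set3", "p_raw_set3", "q_bh_set3"))
  )
  d <- dplyr::rename(d, log2_fc_set1 = "log2_fc", p_raw_set1 = "p_raw",
                     q_bh_set1 = "q_bh")

  is_aging <- d$q_bh_set1 < fdr_set1
  dir1 <- sign(d$log2_fc_set1)
  opposes <- sign(d$log2_fc_set2) == -dir1 & sign(d$log2_fc_set2) != 0
  flat_hit <- is_aging & d$p_raw_set2 < p_set2 & sign(d$log2_fc_set2) == 0
  if (any(flat_hit)) {
    inform(sprintf(
      "%d gene(s) passed the set2 p threshold with a zero log2 fold change; classified aging_not_reverted (no reversal sign).",
      sum(flat_hit)))
  }
  reverted <- is_aging & d$p_raw_set2 < p_set2 & opposes & d$p_raw_set3 > p_set3
  category <- dplyr::case_when(
    !is_aging ~ "not_aging_deg",
    reverted ~ "reverted",
    .default = "aging_not_reverted"
  )
  out <- dplyr::mutate(
    d,
    category = factor(category,
                      levels = c("not_aging_deg", "aging_not_reverted",
                                 "reverted")),
    aging_direction = dplyr::case_when(
      !is_aging ~ "none", dir1 > 0 ~ "up", dir1 < 0 ~ "down",
      .default = "none"
    ),
    .after = "gene_id"
  )
  # partition and sign-opposition invariants, asserted on every run
  stopifnot(!anyNA(out$category),
            all(sign(out$log2_fc_set1[out$category == "reverted"]) *
                  sign(out$log2_fc_set2[out$category == "reverted"]) < 0))
  structure(out,
            thresholds = list(fdr_set1 = fdr_set1, p_set2 = p_set2,
                              p_set3 = p_set3),
            class = c("reversal_call", class(tibble())))
}

#' Partition treatment DEGs into genotype-dependent and -independent sets
#'
#' From the wild-type and knockout treatment contrasts of a factorial design:
#' a gene is a treatment DEG when its wild-type BH q-value is strictly below
#' `fdr_deg`. A DEG is *dependent* on the knocked-out gene when the knockout
#' animals show no treatment response (raw `p > p_ko` in the knockout
#' contrast) and *independent* when the response persists (`p < p_ko`). A
#' knockout p-value exactly equal to `p_ko` is called dependent, with a note.
#'
#' @param wt `contrast_tbl`, treated vs vehicle in wild type.
#' @param ko `contrast_tbl`, treated vs vehicle in the knockout, same
#'   universe.
#' @param fdr_deg FDR threshold for the wild-type DEG call (default 0.2).
#' @param p_ko Raw-p threshold splitting dependent from independent
#'   (default 0.05).
#' @return A `dependence_call`: tibble with `gene_id`, `category`
#'   (`not_deg` / `dependent` / `independent`), `wt_direction` (`up` /
#'   `down` for DEGs, NA otherwise) and the per-contrast statistics
#'   (suffixed `_wt`, `_ko`).
#' @export
classify_dependence <- function(wt, ko, fdr_deg = 0.2, p_ko = 0.05) {
  check_fraction(fdr_deg, "fdr_deg")
  check_fraction(p_ko, "p_ko")
  check_universes(list(wt = wt, ko = ko))
  d <- dplyr::bind_cols(
    dplyr::rename(wt, log2_fc_wt = "log2_fc", p_raw_wt = "p_raw",
                  q_bh_wt = "q_bh"),
    setNames(ko[c("log2_fc", "p_raw", "q_bh")],
             c("log2_fc_ko", "p_raw_ko", "q_bh_ko"))
  )
  is_deg <- d$q_bh_wt < fdr_deg
  tie <- is_deg & d$p_raw_ko == p_ko
  if (any(tie)) {
    inform(sprintf(
      "%d DEG(s) with knockout p exactly at the threshold; called dependent.",
      sum(tie)))
  }
  category <- dplyr::case_when(
    !is_deg ~ "not_deg",
    d$p_raw_ko < p_ko ~ "independent",
    .default = "dependent"
  )
  out <- dplyr::mutate(
    d,
    category = factor(category,
                      levels = c("not_deg", "dependent", "independent")),
    wt_direction = dplyr::if_else(
      is_deg, dplyr::if_else(.data$log2_fc_wt >= 0, "up", "down"),
      NA_character_),
    .after = "gene_id"
  )
  stopifnot(!anyNA(out$category))
  structure(out,
            thresholds = list(fdr_deg = fdr_deg, p_ko = p_ko),
            class = c("dependence_call", class(tibble())))
}

# Shared-universe check: identical gene sets and order, else an error listing
# the symmetric difference.
check_universes <- function(tables) {
  for (nm in names(tables)) {
    t <- tables[[nm]]
    if (!is.data.frame(t) ||
        !all(c("gene_id", "log2_fc", "p_raw", "q_bh") %in% names(t))) {
      abort(sprintf("`%s` must be a contrast table with gene_id, log2_fc, p_raw, q_bh.", nm))
    }
  }
  ref <- tables[[1]]$gene_id
  for (nm in names(tables)[-1]) {
    g <- tables[[nm]]$gene_id
    extra <- union(setdiff(g, ref), setdiff(ref, g))
    if (length(extra)) {
      abort(sprintf(
        "Contrast tables disagree on the gene universe (%s vs %s); symmetric difference: %s%s.",
        names(tables)[1], nm, paste(head(extra, 10), collapse = ", "),
        if (length(extra) > 10) ", ..." else ""))
    }
    if (!identical(g, ref)) {
      abort(sprintf("Contrast tables `%s` and `%s` list the same genes in different orders.",
                    names(tables)[1], nm))
    }
  }
  invisible(TRUE)
}

#' Summarise a classification into counts and percentages
#'
#' Tabulates a [classify_reversal()] or [classify_dependence()] result.
#' For dependence calls, the dependent/independent percentages are taken of
#' the DEG total (e.g. 72 of 91 DEGs = 79.1%); for reversal calls the
#' category percentages are of the whole universe. An optional gene-to-label
#' map additionally tabulates labels within the called set (reverted genes,
#' or DEGs), with that set's size as denominator. Percentages are rounded to
#' one decimal; an empty denominator yields an `NA` percentage rather than
#' an error.
#'
#' @param calls A `reversal_call` or `dependence_call`.
#' @param labels Optional gene-to-label map: a tibble with `gene_id` and
#'   `label`, or a named character vector (names = gene ids).
#' @return Tibble with `category`, `label` (NA for category rows), `n`,
#'   `denom`, `pct`.
#' @export
summarize_partition <- function(calls, labels = NULL) {
  if (!inherits(calls, c("reversal_call", "dependence_call"))) {
    abort("`calls` must come from classify_reversal() or classify_dependence().")
  }
  if (nrow(calls) == 0L) abort("`calls` is empty.")
  dependence <- inherits(calls, "dependence_call")
  counts <- dplyr::count(as_tibble(calls), .data$category, .drop = FALSE)
  if (dependence) {
    n_deg <- sum(counts$n[counts$category != "not_deg"])
    denom <- ifelse(counts$category == "not_deg", nrow(calls), n_deg)
    label_sets <- list(dependent = calls$gene_id[calls$category == "dependent"],
                       independent = calls$gene_id[calls$category == "independent"])
  } else {
    denom <- rep(nrow(calls), nrow(counts))
    label_sets <- list(reverted = calls$gene_id[calls$category == "reverted"])
  }
  out <- dplyr::mutate(counts,
                       label = NA_character_, denom = denom,
                       pct = ifelse(denom > 0, round(100 * .data$n / denom, 1),
                                    NA_real_),
                       category = as.character(.data$category))
  out <- dplyr::select(out, "category", "label", "n", "denom", "pct")
  if (!is.null(labels)) {
    if (is.character(labels) && !is.null(names(labels))) {
      labels <- tibble(gene_id = names(labels), label = unname(labels))
    }
    check_columns(labels, c("gene_id", "label"), "`labels`")
    # label percentages are taken within each called category (e.g.
    # 53 metabolism genes of 72 dependent DEGs = 73.6%)
    for (cat in names(label_sets)) {
      set <- label_sets[[cat]]
      sub <- dplyr::filter(labels, .data$gene_id %in% set)
      if (nrow(sub) == 0L) next
      sub_counts <- dplyr::count(sub, .data$label)
      sub_out <- dplyr::transmute(
        sub_counts,
        category = cat, label = .data$label, n = .data$n,
        denom = length(set),
        pct = ifelse(length(set) > 0, round(100 * .data$n / length(set), 1),
                     NA_real_))
      out <- dplyr::bind_rows(out, sub_out)
    }
  }
  out
}
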