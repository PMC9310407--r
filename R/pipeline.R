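#' Run the reversal analysis end to end
#'
#' RPKM quantification, expression filtering, the three pairwise contrasts of
#' the aging design (aged-vehicle vs young, aged-treated vs aged-vehicle,
#' aged-treated vs young), the three-criterion reversal classifier and the
#' partition summary. When `outdir` is given, every intermediate is written
#' (RPKM TSV, retained-gene list, contrast TSVs, calls TSV, summary and
#' provenance JSON). When planted `truth` labels are supplied, a
#' truth-vs-call confusion matrix and sensitivity/false-call rates over the
#' retained universe are added to the result.
#'
#' The pipeline is purely deterministic in its inputs: re-running on the same
#' files yields byte-identical outputs.
#'
#' @param counts,annotation,sample_sheet Tibbles as produced by
#'   [simulate_experiment()] or read with [read_counts()] and friends.
#' @param young,old_veh,old_hes Group labels in the sample sheet for the
#'   young controls, aged vehicle and aged treated animals.
#' @param filter_threshold,filter_min_fraction Passed to
#'   [filter_expressed()].
#' @param fdr_set1,p_set2,p_set3 Passed to [classify_reversal()].
#' @param truth Optional truth tibble from the simulator.
#' @param outdir Optional output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return A list of class `reversal_pipeline`: `retained`, `contrasts`
#'   (named list of `contrast_tbl`), `calls`, `summary`, optional
#'   `confusion` and `recovery`, and `provenance`.
#' @export
run_reversal_pipeline <- function(counts, annotation, sample_sheet,
                                  young = "young", old_veh = "old_veh",
                                  old_hes = "old_hes",
                                  filter_threshold = 4,
                                  filter_min_fraction = 0.5,
                                  fdr_set1 = 0.1, p_set2 = 0.05,
                                  p_set3 = 0.05,
                                  truth = NULL, outdir = NULL,
                                  quiet = FALSE) {
  stage <- stage_runner(quiet)
  rpkm <- stage("rpkm", compute_rpkm(counts, annotation))
  retained <- stage("filter", filter_expressed(
    rpkm, threshold = filter_threshold,
    min_fraction = filter_min_fraction, quiet = quiet))
  contrasts <- stage("contrasts", list(
    set1 = contrast_test(rpkm, sample_sheet, young, old_veh,
                         genes = retained, name = "old_veh_vs_young"),
    set2 = contrast_test(rpkm, sample_sheet, old_veh, old_hes,
                         genes = retained, name = "old_hes_vs_old_veh"),
    set3 = contrast_test(rpkm, sample_sheet, young, old_hes,
                         genes = retained, name = "old_hes_vs_young")
  ))
  calls <- stage("classify", classify_reversal(
    contrasts$set1, contrasts$set2, contrasts$set3,
    fdr_set1 = fdr_set1, p_set2 = p_set2, p_set3 = p_set3))
  summary <- summarize_partition(calls)

  res <- list(retained = retained, contrasts = contrasts, calls = calls,
              summary = summary)
  if (!is.null(truth)) {
    res <- c(res, score_reversal_recovery(calls, truth))
  }
  res$provenance <- provenance_record(
    "reversal",
    params = list(young = young, old_veh = old_veh, old_hes = old_hes,
                  filter_threshold = filter_threshold,
                  filter_min_fraction = filter_min_fraction,
                  fdr_set1 = fdr_set1, p_set2 = p_set2, p_set3 = p_set3),
    inputs = list(counts = counts, annotation = annotation,
                  sample_sheet = sample_sheet),
    retained = length(retained))
  res <- structure(res, class = "reversal_pipeline")
  if (!is.null(outdir)) {
    write_pipeline_outputs(res, rpkm, outdir)
  }
  res
}

#' Run the genotype-dependence analysis end to end
#'
#' RPKM quantification, expression filtering, the wild-type and knockout
#' treatment contrasts of the factorial design, the dependent/independent
#' DEG partition and its summary. Interface mirrors
#' [run_reversal_pipeline()].
#'
#' @inheritParams run_reversal_pipeline
#' @param wt_veh,wt_hes,ko_veh,ko_hes Group labels for the four factorial
#'   cells.
#' @param fdr_deg,p_ko Passed to [classify_dependence()].
#' @return A list of class `dependence_pipeline`.
#' @export
run_dependence_pipeline <- function(counts, annotation, sample_sheet,
                                    wt_veh = "wt_veh", wt_hes = "wt_hes",
                                    ko_veh = "ko_veh", ko_hes = "ko_hes",
                                    filter_threshold = 4,
                                    filter_min_fraction = 0.5,
                                    fdr_deg = 0.2, p_ko = 0.05,
                                    truth = NULL, outdir = NULL,
                                    quiet = FALSE) {
  stage <- stage_runner(quiet)
  rpkm <- stage("rpkm", compute_rpkm(counts, annotation))
  retained <- stage("filter", filter_expressed(
    rpkm, threshold = filter_threshold,
    min_fraction = filter_min_fraction, quiet = quiet))
  contrasts <- stage("contrasts", list(
    wt = contrast_test(rpkm, sample_sheet, wt_veh, wt_hes,
                       genes = retained, name = "wt_hes_vs_wt_veh"),
    ko = contrast_test(rpkm, sample_sheet, ko_veh, ko_hes,
                       genes = retained, name = "ko_hes_vs_ko_veh")
  ))
  calls <- stage("classify", classify_dependence(
    contrasts$wt, contrasts$ko, fdr_deg = fdr_deg, p_ko = p_ko))
  summary <- summarize_partition(calls)

  res <- list(retained = retained, contrasts = contrasts, calls = calls,
              summary = summary)
  if (!is.null(truth)) {
    res <- c(res, score_dependence_recovery(calls, truth))
  }
  res$provenance <- provenance_record(
    "dependence",
    params = list(wt_veh = wt_veh, wt_hes = wt_hes, ko_veh = ko_veh,
                  ko_hes = ko_hes, filter_threshold = filter_threshold,
                  filter_min_fraction = filter_min_fraction,
                  fdr_deg = fdr_deg, p_ko = p_ko),
    inputs = list(counts = counts, annotation = annotation,
                  sample_sheet = sample_sheet),
    retained = length(retained))
  res <- structure(res, class = "dependence_pipeline")
  if (!is.null(outdir)) {
    write_pipeline_outputs(res, rpkm, outdir)
  }
  res
}

stage_runner <- function(quiet) {
  function(label, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", label, conditionMessage(e)),
            parent = e)
    })
    if (!quiet) {
      inform(sprintf("[%s] done in %.2fs", label,
                     as.numeric(Sys.time() - t0, units = "secs")))
    }
    out
  }
}

# Machine-readable record sufficient to reproduce a run: package version,
# parameter set, and a content hash of the inputs. No timestamps, so a rerun
# on identical inputs is byte-identical.
provenance_record <- function(flow, params, inputs, retained) {
  list(flow = flow,
       package = "reverta",
       version = as.character(utils::packageVersion("reverta")),
       params = params,
       input_hash = rlang::hash(inputs),
       retained_genes = retained)
}

score_reversal_recovery <- function(calls, truth) {
  check_columns(truth, c("gene_id", "aging_direction", "reverted"), "`truth`")
  t <- dplyr::inner_join(
    tibble(gene_id = calls$gene_id, called = calls$category == "reverted"),
    truth, by = "gene_id")
  confusion <- dplyr::count(t, planted = .data$reverted, called = .data$called)
  n_planted <- sum(t$reverted)
  n_called <- sum(t$called)
  list(confusion = confusion,
       recovery = tibble(
         sensitivity = if (n_planted > 0) {
           sum(t$called & t$reverted) / n_planted
         } else NA_real_,
         false_call_rate = if (n_called > 0) {
           sum(t$called & !t$reverted) / n_called
         } else NA_real_))
}

score_dependence_recovery <- function(calls, truth) {
  check_columns(truth, c("gene_id", "dependence"), "`truth`")
  t <- dplyr::inner_join(
    tibble(gene_id = calls$gene_id, called = as.character(calls$category)),
    truth, by = "gene_id")
  deg <- t[t$called != "not_deg", , drop = FALSE]
  planted <- deg[deg$dependence != "none", , drop = FALSE]
  confusion <- dplyr::count(t, planted = .data$dependence,
                            called = .data$called)
  rate <- function(d, label) {
    sub <- d[d$dependence == label, , drop = FALSE]
    if (nrow(sub) > 0) mean(sub$called == label) else NA_real_
  }
  list(confusion = confusion,
       recovery = tibble(
         deg_concordance = if (nrow(planted) > 0) {
           mean(planted$called == planted$dependence)
         } else NA_real_,
         dependent_recall = rate(deg, "dependent"),
         independent_recall = rate(deg, "independent"),
         n_deg = nrow(deg),
         n_deg_planted = nrow(planted)))
}

write_pipeline_outputs <- function(res, rpkm, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(rpkm, file.path(outdir, "rpkm.tsv"))
  writeLines(res$retained, file.path(outdir, "retained_genes.txt"))
  for (nm in names(res$contrasts)) {
    write_contrast(res$contrasts[[nm]],
                   file.path(outdir, sprintf("contrast_%s.tsv", nm)))
  }
  readr::write_tsv(as_tibble(res$calls), file.path(outdir, "calls.tsv"))
  jsonlite::write_json(
    list(summary = res$summary,
         thresholds = attr(res$calls, "thresholds"),
         provenance = res$provenance),
    file.path(outdir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(res$recovery)) {
    readr::write_tsv(res$confusion, file.path(outdir, "confusion.tsv"))
    readr::write_tsv(res$recovery, file.path(outdir, "recovery.tsv"))
  }
  invisible(outdir)
}

#' @export
print.reversal_pipeline <- function(x, ...) {
  cat(sprintf("Reversal pipeline: %d genes retained\n", length(x$retained)))
  print(x$summary)
  if (!is.null(x$recovery)) print(x$recovery)
  invisible(x)
}

#' @export
print.dependence_pipeline <- function(x, ...) {
  cat(sprintf("Dependence pipeline: %d genes retained\n", length(x$retained)))
  print(x$summary)
  if (!is.null(x$recovery)) print(x$recovery)
  invisible(x)
}
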