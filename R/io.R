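# Readers and writers for the plain-text interchange formats: TSV matrices
# with genes as rows, TSV metadata tables, CSV survival records. Readers
# validate the schema and reject malformed values with the offending
# row/column named; writers round-trip losslessly.

#' Read / write a count matrix
#'
#' Tab-separated, genes as rows, first column `gene_id`, remaining columns
#' one per sample. Counts must be non-negative integers; the reader reports
#' the first offending cell.
#'
#' @param path File path.
#' @return `read_counts()`: tibble `gene_id` + integer sample columns.
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  check_columns(x, "gene_id", basename(path))
  if (ncol(x) < 2L) abort(sprintf("%s has no sample columns.", basename(path)))
  for (col in setdiff(names(x), "gene_id")) {
    v <- x[[col]]
    num <- if (is.numeric(v)) v else suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(num) | num < 0 | num != round(num))
    if (length(bad)) {
      abort(sprintf("%s: invalid count at row %d, column '%s' (%s).",
                    basename(path), bad[1], col, format(v[bad[1]])))
    }
    x[[col]] <- as.integer(num)
  }
  x
}

#' @param counts Count tibble as returned by [simulate_experiment()].
#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  expr_to_matrix(counts, "counts") # validates
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read / write gene annotation (gene_id, length_bp)
#' @param path File path.
#' @export
read_gene_annotation <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  check_columns(x, c("gene_id", "length_bp"), basename(path))
  if (any(x$length_bp < 1 | x$length_bp != round(x$length_bp))) {
    abort(sprintf("%s: length_bp must be positive integers.", basename(path)))
  }
  x
}

#' @param annotation Annotation tibble.
#' @rdname read_gene_annotation
#' @export
write_gene_annotation <- function(annotation, path) {
  check_columns(annotation, c("gene_id", "length_bp"), "`annotation`")
  readr::write_tsv(annotation, path)
  invisible(path)
}

#' Read / write a sample sheet
#' @param path File path.
#' @export
read_sample_sheet <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  check_columns(x, c("sample_id", "group", "age_months", "genotype",
                     "treatment", "tissue"), basename(path))
  if (anyDuplicated(x$sample_id)) {
    abort(sprintf("%s: duplicated sample_id.", basename(path)))
  }
  x
}

#' @param sample_sheet Sample-sheet tibble.
#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sample_sheet, path) {
  check_columns(sample_sheet, c("sample_id", "group", "age_months",
                                "genotype", "treatment", "tissue"),
                "`sample_sheet`")
  readr::write_tsv(sample_sheet, path)
  invisible(path)
}

#' Read / write truth labels from the simulator
#' @param path File path.
#' @export
read_truth <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  check_columns(x, c("gene_id", "aging_direction", "reverted", "dependence"),
                basename(path))
  x$reverted <- as.logical(x$reverted)
  x
}

#' @param truth Truth tibble.
#' @rdname read_truth
#' @export
write_truth <- function(truth, path) {
  check_columns(truth, c("gene_id", "aging_direction", "reverted",
                         "dependence"), "`truth`")
  readr::write_tsv(truth, path)
  invisible(path)
}

#' Read / write per-animal survival records (CSV)
#' @param path File path.
#' @export
read_survival <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  check_columns(x, c("animal_id", "arm", "time_months", "event"),
                basename(path))
  check_survival_data(x)
  x
}

#' @param data Survival tibble.
#' @rdname read_survival
#' @export
write_survival <- function(data, path) {
  check_columns(data, c("animal_id", "arm", "time_months", "event"),
                "survival data")
  readr::write_csv(data, path)
  invisible(path)
}

#' Read / write a contrast table
#'
#' TSV with columns `gene_id`, `log2_fc`, `p_raw`, `q_bh`; the contrast name
#' travels in a `# contrast: <name>` comment line at the top of the file.
#'
#' @param path File path.
#' @export
read_contrast <- function(path) {
  first <- readLines(path, n = 1L)
  name <- if (startsWith(first, "# contrast:")) {
    trimws(sub("^# contrast:", "", first))
  } else {
    NA_character_
  }
  x <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  check_columns(x, c("gene_id", "log2_fc", "p_raw", "q_bh"), basename(path))
  new_contrast_tbl(x, contrast = name)
}

#' @param contrast A `contrast_tbl`.
#' @rdname read_contrast
#' @export
write_contrast <- function(contrast, path) {
  check_columns(contrast, c("gene_id", "log2_fc", "p_raw", "q_bh"),
                "`contrast`")
  name <- attr(contrast, "contrast") %||% "unnamed"
  writeLines(sprintf("# contrast: %s", name), path)
  readr::write_tsv(as_tibble(contrast), path, append = TRUE, col_names = TRUE)
  invisible(path)
}
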