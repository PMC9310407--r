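# Hand-built contrast triples exercising each branch of the reversal rule.
reversal_fixture <- function() {
  genes <- c("rev_up", "rev_down", "not_deg", "same_dir", "set3_fails",
             "set2_ns")
  set1 <- make_contrast(
    genes,
    log2_fc = c(2, -1.5, 0.2, 2, 2, 2),
    p_raw = c(0.001, 0.001, 0.4, 0.001, 0.001, 0.001),
    q_bh = c(0.05, 0.05, 0.5, 0.05, 0.05, 0.05))
  set2 <- make_contrast(
    genes,
    log2_fc = c(-1.5, 1.2, -1, 1.0, -2, -2),
    p_raw = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.3))
  set3 <- make_contrast(
    genes,
    log2_fc = c(0.1, -0.1, 0, 3, 2, 1),
    p_raw = c(0.4, 0.6, 0.9, 0.4, 0.01, 0.5))
  list(set1 = set1, set2 = set2, set3 = set3)
}

test_that("classify_reversal applies the three criteria with strict cuts", {
  f <- reversal_fixture()
  calls <- classify_reversal(f$set1, f$set2, f$set3)
  got <- setNames(as.character(calls$category), calls$gene_id)
  expect_equal(got[["rev_up"]], "reverted")       # q1<.1, p2<.05 opposite, p3>.05
  expect_equal(got[["rev_down"]], "reverted")
  expect_equal(got[["not_deg"]], "not_aging_deg") # criterion 1 fails
  expect_equal(got[["same_dir"]], "aging_not_reverted")  # sign rule
  expect_equal(got[["set3_fails"]], "aging_not_reverted")
  expect_equal(got[["set2_ns"]], "aging_not_reverted")
  expect_equal(setNames(calls$aging_direction, calls$gene_id)[["rev_down"]],
               "down")
  expect_equal(setNames(calls$aging_direction, calls$gene_id)[["not_deg"]],
               "none")
})

test_that("threshold boundaries are strict and categories partition the universe", {
  g <- c("at_fdr", "at_p2", "at_p3")
  set1 <- make_contrast(g, c(2, 2, 2), c(0.01, 0.01, 0.01),
                        q_bh = c(0.1, 0.05, 0.05))
  set2 <- make_contrast(g, c(-1, -1, -1), c(0.01, 0.05, 0.01))
  set3 <- make_contrast(g, c(0, 0, 0), c(0.5, 0.5, 0.05))
  calls <- classify_reversal(set1, set2, set3)
  got <- setNames(as.character(calls$category), calls$gene_id)
  expect_equal(got[["at_fdr"]], "not_aging_deg")       # q == 0.1 fails FDR<0.1
  expect_equal(got[["at_p2"]], "aging_not_reverted")   # p == 0.05 fails p<0.05
  expect_equal(got[["at_p3"]], "aging_not_reverted")   # p == 0.05 fails p>0.05
  expect_true(all(table(calls$category)[c("not_aging_deg",
                                          "aging_not_reverted",
                                          "reverted")] >= 0))
  expect_equal(sum(table(calls$category)), length(g))
})

test_that("zero set2 fold change with a passing p is not called reverted", {
  set1 <- make_contrast("g", 2, 0.001, 0.01)
  set2 <- make_contrast("g", 0, 0.01)
  set3 <- make_contrast("g", 0, 0.5)
  expect_message(calls <- classify_reversal(set1, set2, set3), "zero log2")
  expect_equal(as.character(calls$category), "aging_not_reverted")
})

test_that("mismatched universes raise an error listing the difference", {
  f <- reversal_fixture()
  bad <- f$set2[-2, ]
  expect_error(classify_reversal(f$set1, bad, f$set3), "rev_down")
  expect_error(classify_dependence(f$set1, bad), "rev_down")
})

test_that("relaxing the set-1 FDR never removes genes from the aging set", {
  set.seed(31)
  n <- 300
  g <- sprintf("g%03d", 1:n)
  s1 <- make_contrast(g, rnorm(n), runif(n), runif(n))
  s2 <- make_contrast(g, rnorm(n), runif(n))
  s3 <- make_contrast(g, rnorm(n), runif(n))
  strict <- classify_reversal(s1, s2, s3, fdr_set1 = 0.05)
  loose <- classify_reversal(s1, s2, s3, fdr_set1 = 0.3)
  aging_strict <- strict$gene_id[strict$category != "not_aging_deg"]
  aging_loose <- loose$gene_id[loose$category != "not_aging_deg"]
  expect_true(all(aging_strict %in% aging_loose))
  # reverted genes always oppose the aging direction
  rev <- loose[loose$category == "reverted", ]
  expect_true(all(sign(rev$log2_fc_set1) * sign(rev$log2_fc_set2) < 0))
})

test_that("classify_dependence splits DEGs on the knockout p-value", {
  g <- c("dep", "indep", "null", "tie")
  wt <- make_contrast(g, c(1, 1, 0.1, -1), c(0.001, 0.001, 0.6, 0.001),
                      q_bh = c(0.1, 0.1, 0.7, 0.1))
  ko <- make_contrast(g, c(0.05, 0.9, 0.1, 0), c(0.3, 0.01, 0.5, 0.05))
  expect_message(calls <- classify_dependence(wt, ko), "exactly at")
  got <- setNames(as.character(calls$category), calls$gene_id)
  expect_equal(got[["dep"]], "dependent")     # q_wt = 0.1 < 0.2, p_ko = 0.3
  expect_equal(got[["indep"]], "independent") # p_ko = 0.01
  expect_equal(got[["null"]], "not_deg")
  expect_equal(got[["tie"]], "dependent")     # tie rule
  expect_equal(setNames(calls$wt_direction, calls$gene_id)[["dep"]], "up")
  expect_true(is.na(setNames(calls$wt_direction, calls$gene_id)[["null"]]))
})

test_that("classify_dependence is equivariant under gene reordering", {
  set.seed(55)
  n <- 100
  g <- sprintf("g%03d", 1:n)
  wt <- make_contrast(g, rnorm(n), runif(n), runif(n))
  ko <- make_contrast(g, rnorm(n), runif(n))
  a <- classify_dependence(wt, ko)
  perm <- sample(n)
  b <- classify_dependence(wt[perm, ], ko[perm, ])
  expect_equal(dplyr::arrange(as.data.frame(b), gene_id),
               dplyr::arrange(as.data.frame(a), gene_id))
})

test_that("summarize_partition reproduces the canonical percentages", {
  # 91 DEGs: 72 dependent, 19 independent, plus 29 background genes
  g <- sprintf("g%03d", 1:120)
  q_wt <- c(rep(0.01, 91), rep(0.9, 29))
  p_ko <- c(rep(0.5, 72), rep(0.001, 19), rep(0.5, 29))
  wt <- make_contrast(g, rep(1, 120), rep(0.001, 120), q_bh = q_wt)
  ko <- make_contrast(g, rep(0, 120), p_ko)
  calls <- classify_dependence(wt, ko)
  s <- summarize_partition(calls)
  expect_equal(s$n[s$category == "dependent"], 72L)
  expect_equal(s$denom[s$category == "dependent"], 91L)
  expect_equal(s$pct[s$category == "dependent"], 79.1)
  expect_equal(s$pct[s$category == "independent"], 20.9)
  expect_equal(round(s$pct[s$category == "dependent"]), 79)
  expect_equal(round(s$pct[s$category == "independent"]), 21)

  # 53 of the 72 dependent genes labelled metabolism -> 73.6%
  labels <- tibble::tibble(gene_id = g[1:53], label = "metabolism")
  s2 <- summarize_partition(calls, labels = labels)
  met <- s2[!is.na(s2$label) & s2$label == "metabolism" &
              s2$category == "dependent", ]
  expect_equal(met$n, 53L)
  expect_equal(met$denom, 72L)
  expect_equal(met$pct, 73.6)
})

test_that("summarize_partition handles single-category and empty-DEG cases", {
  g <- c("a", "b")
  wt <- make_contrast(g, c(1, 1), c(0.9, 0.9), q_bh = c(0.9, 0.9))
  ko <- make_contrast(g, c(0, 0), c(0.5, 0.5))
  s <- summarize_partition(classify_dependence(wt, ko))
  expect_equal(s$n[s$category == "not_deg"], 2L)
  expect_equal(s$pct[s$category == "not_deg"], 100.0)
  # empty DEG set: counts 0 with undefined (NA) percentages, no error
  expect_true(all(is.na(s$pct[s$category %in% c("dependent", "independent")])))
  expect_true(all(s$n[s$category %in% c("dependent", "independent")] == 0L))
})
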