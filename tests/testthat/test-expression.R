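test_that("compute_rpkm applies the RPKM formula", {
  # sample 1 library = 10 + 100 + 999890 = 1e6 reads exactly
  rpkm <- compute_rpkm(tiny_counts(), tiny_annotation())
  expect_equal(rpkm$s1[1], 1e9 * 10 / (2000 * 1e6))   # = 5
  expect_equal(rpkm$s1[1], 5)
  expect_equal(rpkm$s1[2], 1e9 * 100 / (500 * 1e6))   # = 200
  # zero counts give zero RPKM
  counts0 <- tiny_counts()
  counts0$s1[1] <- 0L
  expect_equal(compute_rpkm(counts0, tiny_annotation())$s1[1], 0)
})

test_that("compute_rpkm is invariant under per-sample count scaling", {
  counts <- tiny_counts()
  doubled <- counts
  doubled$s1 <- doubled$s1 * 2L
  expect_equal(compute_rpkm(doubled, tiny_annotation())$s1,
               compute_rpkm(counts, tiny_annotation())$s1)
  # and strictly proportional to counts at fixed length and library
  sim <- simulate_experiment(reversal_design(n_genes = 50, seed = 1))
  r <- compute_rpkm(sim$counts, sim$annotation)
  m <- as.matrix(sim$counts[-1])
  expect_equal(as.matrix(r[-1]),
               1e9 * m / outer(sim$annotation$length_bp, colSums(m)),
               ignore_attr = TRUE)
})

test_that("compute_rpkm rejects bad inputs naming the offender", {
  expect_error(compute_rpkm(tiny_counts(), tiny_annotation()[1:2, ]), "gC")
  zero <- tiny_counts()
  zero$s2 <- 0L
  expect_error(compute_rpkm(zero, tiny_annotation()), "s2")
})

test_that("filter_expressed applies strict > threshold and >= fraction", {
  rpkm <- tibble::tibble(
    gene_id = c("half", "at_threshold", "expressed", "silent"),
    s1 = c(5, 4, 50, 0), s2 = c(5, 4, 60, 1),
    s3 = c(0, 4, 70, 2), s4 = c(0, 4, 80, 3)
  )
  kept <- filter_expressed(rpkm, quiet = TRUE)
  expect_identical(kept, c("half", "expressed"))  # 2/4 = 50% passes; 4 !> 4
})

test_that("filter_expressed matches the brute-force oracle and is idempotent", {
  set.seed(42)
  rpkm <- tibble::as_tibble(
    matrix(rexp(1000 * 12, rate = 0.2), 1000, 12,
           dimnames = list(NULL, paste0("s", 1:12))))
  rpkm <- dplyr::bind_cols(tibble::tibble(gene_id = sprintf("g%04d", 1:1000)),
                           rpkm)
  kept <- filter_expressed(rpkm, quiet = TRUE)
  expect_identical(kept, filter_oracle(rpkm))
  again <- filter_expressed(rpkm[rpkm$gene_id %in% kept, ], quiet = TRUE)
  expect_identical(again, kept)
  expect_message(filter_expressed(rpkm), "retained")
})

test_that("zscore_rows standardises rows and zeroes constant ones", {
  x <- tibble::tibble(gene_id = c("a", "b"), s1 = c(1, 7), s2 = c(2, 7),
                      s3 = c(3, 7))
  expect_warning(z <- zscore_rows(x), "constant")
  zm <- as.matrix(z[-1])
  expect_equal(unname(zm[1, ]), (c(1, 2, 3) - 2) / 1)
  expect_equal(unname(zm[2, ]), c(0, 0, 0))
  expect_error(zscore_rows(x[, 1:2]), "two samples")
})

test_that("zscore_rows agrees with per-row recomputation on random data", {
  set.seed(7)
  x <- dplyr::bind_cols(
    tibble::tibble(gene_id = paste0("g", 1:50)),
    tibble::as_tibble(matrix(rnorm(50 * 8), 50, 8,
                             dimnames = list(NULL, paste0("s", 1:8)))))
  z <- as.matrix(zscore_rows(x)[-1])
  for (i in c(1, 17, 50)) {
    v <- as.numeric(x[i, -1])
    expect_equal(unname(z[i, ]), (v - mean(v)) / sd(v))
  }
  expect_true(all(abs(rowMeans(z)) < 1e-10))
  expect_equal(unname(apply(z, 1, sd)), rep(1, 50))
})

test_that("pca_scores matches an independent eigendecomposition", {
  x <- tibble::tibble(gene_id = c("a", "b", "c"),
                      s1 = c(1, 4, 2), s2 = c(2, 0, 5), s3 = c(6, 1, 3))
  p <- pca_scores(x, n_components = 2)
  # eigen-oracle on the sample covariance of centred sample vectors
  m <- t(as.matrix(x[-1]))
  mc <- scale(m, center = TRUE, scale = FALSE)
  ev <- eigen(cov(mc))
  expect_equal(p$var_explained$var_explained,
               (ev$values / sum(ev$values))[1:2])
  expect_equal(abs(as.matrix(p$scores[-1])), abs(mc %*% ev$vectors[, 1:2]),
               ignore_attr = TRUE)
})

test_that("pca_scores properties: rank-1 dominance and orthogonality", {
  base <- c(1, 2, 3, 4, 5)
  x <- dplyr::bind_cols(
    tibble::tibble(gene_id = paste0("g", 1:5)),
    tibble::as_tibble(outer(base, c(1, 2, 3, 4)) |>
                        `colnames<-`(paste0("s", 1:4))))
  p1 <- pca_scores(x, 2)
  expect_gt(p1$var_explained$var_explained[1], 0.999)
  set.seed(1)
  xr <- dplyr::bind_cols(
    tibble::tibble(gene_id = paste0("g", 1:20)),
    tibble::as_tibble(matrix(rnorm(20 * 6), 20, 6,
                             dimnames = list(NULL, paste0("s", 1:6)))))
  p2 <- pca_scores(xr, 3)
  l <- as.matrix(p2$loadings[-1])
  off <- crossprod(l) - diag(3)
  expect_lt(max(abs(off)), 1e-10)
  expect_true(all(diff(p2$var_explained$var_explained) <= 1e-12))
  expect_lte(sum(p2$var_explained$var_explained), 1 + 1e-12)
  expect_error(pca_scores(xr, 7), "n_components")
})
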