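# Small in-code fixtures shared across test files.

# A contrast table as the classifiers consume it (plain tibble suffices).
make_contrast <- function(gene_id, log2_fc, p_raw, q_bh = p_raw) {
  tibble::tibble(gene_id = gene_id, log2_fc = log2_fc,
                 p_raw = p_raw, q_bh = q_bh)
}

# Tiny count experiment with hand-picked numbers for formula checks.
tiny_counts <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    s1 = c(10L, 100L, 999890L),
    s2 = c(20L, 200L, 1999780L)
  )
}

tiny_annotation <- function() {
  tibble::tibble(gene_id = c("gA", "gB", "gC"),
                 length_bp = c(2000L, 500L, 1000L))
}

# Brute-force oracle for the expression filter: per-gene double loop over
# samples, independent of the vectorised implementation.
filter_oracle <- function(rpkm, threshold = 4, min_fraction = 0.5) {
  keep <- character(0)
  for (i in seq_len(nrow(rpkm))) {
    vals <- as.numeric(rpkm[i, -1])
    n_above <- 0
    for (v in vals) if (v > threshold) n_above <- n_above + 1
    if (n_above / length(vals) >= min_fraction) {
      keep <- c(keep, rpkm$gene_id[i])
    }
  }
  keep
}

# O(m^2) evaluation of the BH step-up definition: q_(i) = min over j >= i of
# p_(j) * m / j, in original order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, ps[j] * m / j)
    qs[i] <- min(best, 1)
  }
  out <- numeric(m)
  out[o] <- qs
  out
}

# Independently coded product-limit (Kaplan-Meier) step function.
km_oracle <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(times))
  for (i in seq_along(times)) {
    t <- times[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  list(time = times, surv = surv,
       median = if (any(surv <= 0.5 + 1e-12)) {
         min(times[surv <= 0.5 + 1e-12])
       } else NA_real_)
}
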