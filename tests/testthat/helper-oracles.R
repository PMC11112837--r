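# Independent brute-force oracles, kept free of the package's own
# matrix-algebra implementations.

# weighted kappa by explicit double loops over cells
brute_kappa <- function(counts, w) {
  k <- nrow(counts)
  n <- sum(counts)
  po <- 0; pe <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    po <- po + w[i, j] * counts[i, j] / n
    pe <- pe + w[i, j] * (sum(counts[i, ]) / n) * (sum(counts[, j]) / n)
  }
  (po - pe) / (1 - pe)
}

# Spearman rho as Pearson correlation of average ranks
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# random non-degenerate k x k count table
random_table <- function(k = 4L, n = 200L) {
  repeat {
    m <- matrix(stats::rpois(k * k, 3) + sample(0:2, k * k, TRUE), k, k)
    # reject tables where kappa is undefined (expected agreement ~ 1)
    r <- rowSums(m) / sum(m); cc <- colSums(m) / sum(m)
    if (sum(m) > 0 && sum(diag(r %o% cc)) < 0.999) return(m)
  }
}

# exact coverage of a CI method by full binomial enumeration
exact_coverage <- function(n, p, method = "clopper_pearson", level = 0.95) {
  cov <- 0
  for (x in 0:n) {
    ci <- binomial_ci(x, n, method, level)
    if (ci[1] <= p && p <= ci[2]) cov <- cov + stats::dbinom(x, n, p)
  }
  cov
}

# AI confusion matrix with prescribed binary sensitivity/specificity
confusion_sens_spec <- function(sens = 0.9, spec = 0.95) {
  rbind(c(spec, c(0.6, 0.3, 0.1) * (1 - spec)),
        c(1 - sens, c(0.8, 0.15, 0.05) * sens),
        c(1 - sens, c(0.1, 0.85, 0.05) * sens),
        c(1 - sens, c(0.05, 0.15, 0.8) * sens))
}
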