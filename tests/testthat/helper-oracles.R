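# Independent oracles and small fixture builders used across the suite.

# Textbook Pearson correlation from the covariance/sd definition.
pearson_oracle <- function(x, y) {
  n <- length(x)
  cov_xy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  cov_xy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
              sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# One-sided over-representation p-value by explicit enumeration of all 2x2
# tables with the given margins, probabilities from choose() products.
fisher_oracle <- function(a, b, s_d, r) {
  K <- a + s_d          # database pairs in universe
  n <- a + b            # detected pairs
  N <- a + b + s_d + r  # universe size
  xs <- max(0, n - (N - K)):min(n, K)
  probs <- choose(K, xs) * choose(N - K, n - xs)
  probs <- probs / sum(probs)
  sum(probs[xs >= a])
}

# First right-singular vector of the row-standardized member matrix via an
# eigendecomposition of the sample crossproduct (independent of svd()).
eigengene_oracle <- function(values) {
  mu <- rowMeans(values)
  sd_pop <- sqrt(rowMeans((values - mu)^2))
  z <- (values - mu) / sd_pop
  z <- z[sd_pop > 0, , drop = FALSE]
  v <- eigen(crossprod(z), symmetric = TRUE)$vectors[, 1L]
  # same orientation convention as the package (including the fallback for
  # a PC orthogonal to the mean profile)
  m <- colMeans(z)
  r <- suppressWarnings(cor(v, m))
  if (!is.na(r) && abs(r) > 1e-10) {
    if (r < 0) v <- -v
  } else {
    nz <- which(abs(v) > 1e-12)
    if (length(nz) && v[nz[1L]] < 0) v <- -v
  }
  v
}

# Quick expression_matrix from a plain matrix (default names filled in).
make_expr <- function(values, kind = "gene", normalized = TRUE) {
  if (is.null(rownames(values))) {
    rownames(values) <- paste0(if (kind == "gene") "g" else "m",
                               seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  }
  expression_matrix(values, kind = kind, normalized = normalized)
}

# Contingency table literal.
ct <- function(a, b, s_d, r) {
  structure(list(a = a, b = b, S_d = s_d, R = r),
            class = "contingency_table")
}

# Run the core analysis on a generated dataset bundle.
analyze_dataset <- function(ds, ...) {
  mtp_analysis(ds$genes, ds$mirnas, ds$gene_modules, ds$mirna_modules,
               ds$dems, ds$degs, ds$db, ...)
}
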