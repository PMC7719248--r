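# Independent brute-force oracles, written with explicit loops and sums so
# they share no code path with the package implementations.

bf_mean <- function(x) sum(unname(x)) / length(x)

bf_sd <- function(x) {
  x <- unname(x)
  m <- bf_mean(x)
  acc <- 0
  for (v in x) acc <- acc + (v - m)^2
  sqrt(acc / (length(x) - 1))
}

bf_pairwise_v <- function(mat) {
  n <- nrow(mat)
  V <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j == k) next
    diffs <- numeric(ncol(mat))
    for (s in seq_len(ncol(mat))) diffs[s] <- mat[k, s] - mat[j, s]
    V[j, k] <- bf_sd(diffs)
  }
  V
}

bf_m_values <- function(V) {
  out <- numeric(nrow(V))
  names(out) <- rownames(V)
  for (j in seq_len(nrow(V))) {
    acc <- 0
    for (k in seq_len(ncol(V))) if (k != j) acc <- acc + V[j, k]
    out[j] <- acc / (nrow(V) - 1)
  }
  out
}

bf_geo_mean <- function(x) prod(unname(x))^(1 / length(x))

bf_pearson <- function(x, y) {
  x <- unname(x); y <- unname(y)
  mx <- bf_mean(x); my <- bf_mean(y)
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_along(x)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

bf_ccc <- function(x, y) {
  x <- unname(x); y <- unname(y)
  mx <- bf_mean(x); my <- bf_mean(y)
  n <- length(x)
  sxy <- 0; sx <- 0; sy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sx <- sx + (x[i] - mx)^2
    sy <- sy + (y[i] - my)^2
  }
  sxy <- sxy / (n - 1); sx <- sx / (n - 1); sy <- sy / (n - 1)
  2 * sxy / (sx + sy + (mx - my)^2)
}

# Intergroup differences by direct evaluation of the double-centering
# definition, one cell at a time.
bf_intergroup_d <- function(mat, groups) {
  groups <- as.factor(groups)
  gl <- levels(groups)
  I <- nrow(mat)
  ybar <- matrix(0, I, length(gl), dimnames = list(rownames(mat), gl))
  for (i in seq_len(I)) for (g in seq_along(gl))
    ybar[i, g] <- bf_mean(mat[i, groups == gl[g]])
  z <- ybar
  for (g in seq_along(gl)) z[, g] <- ybar[, g] - bf_mean(ybar[, g])
  d <- z
  for (i in seq_len(I)) d[i, ] <- z[i, ] - bf_mean(z[i, ])
  d
}

# Small random Ct fixture (complete, collapsed).
random_ct <- function(n_genes, n_samples, seed, sd = 0.8) {
  set.seed(seed)
  vals <- matrix(stats::rnorm(n_genes * n_samples, mean = 25, sd = sd),
                 n_genes, n_samples,
                 dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                 sprintf("s%02d", seq_len(n_samples))))
  ct_matrix(vals)
}
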