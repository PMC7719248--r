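#' geNorm pairwise variation matrix
#'
#' For each pair of candidate genes (j, k), the pairwise variation
#' \eqn{V_{jk}} is the sample standard deviation across samples of the Ct
#' difference \eqn{Ct_k - Ct_j} — the SD of the log2 expression ratio under
#' 100\% amplification efficiency. A constant ratio (perfect co-regulation or
#' shared technical variation) gives V = 0. Computed on pairwise-complete
#' samples; every pair needs at least 3 complete samples.
#'
#' @param m a collapsed [ct_matrix] with >= 2 genes.
#' @return symmetric matrix V with zero diagonal, in cycles.
#' @export
pairwise_variation <- function(m) {
  stopifnot(inherits(m, "ct_matrix"))
  if (has_replicates(m)) stop("collapse technical replicates first")
  if (nrow(m) < 2L) stop("pairwise variation needs >= 2 genes")
  vals <- unclass_ct(m)
  g <- rownames(vals)
  n <- nrow(vals)
  V <- matrix(0, n, n, dimnames = list(g, g))
  for (j in seq_len(n - 1L)) for (k in (j + 1L):n) {
    d <- vals[k, ] - vals[j, ]
    d <- d[!is.na(d)]
    if (length(d) < 3L)
      stop(sprintf("pair (%s, %s) has < 3 pairwise-complete samples",
                   g[j], g[k]))
    V[j, k] <- V[k, j] <- stats::sd(d)
  }
  V
}

#' geNorm M values from a pairwise variation matrix
#'
#' The gene-stability measure M of gene j is the average of its pairwise
#' variations against all other genes:
#' \eqn{M_j = \sum_{k \ne j} V_{jk} / (n - 1)}. Lower M means greater
#' stability.
#'
#' @param V symmetric pairwise-variation matrix with zero diagonal.
#' @return named vector of M values (cycles).
#' @export
m_values <- function(V) {
  if (!is.matrix(V) || nrow(V) != ncol(V)) stop("V must be a square matrix")
  if (nrow(V) < 2L) stop("M values need >= 2 genes")
  (rowSums(V)) / (nrow(V) - 1L)
}

#' geNorm stability analysis with iterative exclusion
#'
#' Computes the full-set M value for every candidate, then repeatedly removes
#' the gene with the highest M (ties broken towards the lexicographically last
#' gene id) and recomputes M on the reduced set, until two genes remain. The
#' exclusion order (least to most stable as removed) plus the final pair
#' define the stability ranking; the final two genes cannot be ordered by the
#' pairwise criterion and share rank 1.
#'
#' @param m a collapsed [ct_matrix] with >= 3 genes.
#' @return an object of class `genorm`: list with `m_values` (full candidate
#'   set), `pairwise_v`, `exclusion_order`, `final_pair` and `rank` (named
#'   integer; the final pair both get 1).
#' @examples
#' set.seed(1)
#' ct <- matrix(25 + rnorm(40, sd = 0.3), 4, 10,
#'              dimnames = list(paste0("miR-", 1:4), paste0("s", 1:10)))
#' fit <- genorm(ct_matrix(ct))
#' fit$m_values
#' @export
genorm <- function(m) {
  stopifnot(inherits(m, "ct_matrix"))
  if (nrow(m) < 3L) stop("geNorm ranking needs >= 3 genes")
  V <- pairwise_variation(m)
  M_full <- m_values(V)
  genes <- rownames(V)
  Vcur <- V
  exclusion <- character()
  while (nrow(Vcur) > 2L) {
    Mcur <- m_values(Vcur)
    worst <- max(Mcur)
    cand <- names(Mcur)[Mcur == worst]
    drop <- sort(cand)[length(cand)]           # tie: lexicographically last
    exclusion <- c(exclusion, drop)
    keep <- setdiff(rownames(Vcur), drop)
    Vcur <- Vcur[keep, keep, drop = FALSE]
  }
  final_pair <- rownames(Vcur)
  rank <- stats::setNames(integer(length(genes)), genes)
  rank[final_pair] <- 1L
  if (length(exclusion))
    rank[rev(exclusion)] <- 2L + seq_along(exclusion)
  structure(list(m_values = M_full, pairwise_v = V,
                 exclusion_order = exclusion, final_pair = final_pair,
                 rank = rank),
            class = "genorm")
}

#' @export
print.genorm <- function(x, ...) {
  cat("geNorm stability analysis\n")
  ord <- order(x$rank, names(x$rank))
  df <- data.frame(gene_id = names(x$rank)[ord],
                   M = unname(x$m_values[names(x$rank)[ord]]),
                   rank = unname(x$rank[ord]))
  print.data.frame(df, row.names = FALSE, digits = 4)
  cat("most stable pair:", paste(x$final_pair, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.genorm <- function(object, ...) {
  cat(sprintf("geNorm on %d genes; M range %.3f .. %.3f cycles\n",
              length(object$m_values), min(object$m_values),
              max(object$m_values)))
  cat("exclusion order (first = least stable):",
      paste(object$exclusion_order, collapse = " > "), "\n")
  invisible(object)
}

#' @export
plot.genorm <- function(x, ...) {
  ord <- order(x$m_values, decreasing = TRUE)
  graphics::barplot(x$m_values[ord], las = 2, ylab = "geNorm M (cycles)",
                    main = "geNorm gene stability", ...)
  invisible(x)
}

#' @rdname write_results
#' @export
write_results.genorm <- function(result, path, ...) {
  genes <- names(result$m_values)
  df <- data.frame(gene_id = genes,
                   M_full_set = unname(result$m_values),
                   rank = unname(result$rank[genes]))
  write_csv_plain(df[order(df$rank, df$gene_id), ], path)
}

#' Pairwise variation of cumulative normalization factors
#'
#' The V(n/n+1) diagnostic for choosing how many reference genes to use: for
#' the n most stable genes (per [genorm()] ranking) the log2 normalization
#' factor is the mean Ct over those genes; V(n/n+1) is the SD across samples
#' of the difference between consecutive factors. Values below ~0.15 are
#' conventionally taken to mean the (n+1)-th gene adds nothing. A convenience
#' diagnostic, not part of the core ranking workflow.
#'
#' @param m a collapsed, complete [ct_matrix] with >= 3 genes.
#' @param fit optionally a precomputed [genorm()] result for `m`.
#' @return named vector `V2/3`, `V3/4`, ... (cycles).
#' @export
genorm_vn <- function(m, fit = genorm(m)) {
  genes <- names(sort(rank_with_ties(fit)))
  vals <- unclass_ct(m)[genes, , drop = FALSE]
  n <- length(genes)
  out <- numeric(n - 2L)
  names(out) <- paste0("V", 2:(n - 1L), "/", 3:n)
  for (k in 2:(n - 1L)) {
    nf_k  <- colMeans(vals[seq_len(k), , drop = FALSE])
    nf_k1 <- colMeans(vals[seq_len(k + 1L), , drop = FALSE])
    out[k - 1L] <- stats::sd(nf_k - nf_k1)
  }
  out
}

# geNorm ranking as average ranks (final pair -> 1.5, 1.5) for consensus use.
rank_with_ties <- function(fit) {
  key <- fit$rank
  stats::setNames(rank(key, ties.method = "average"), names(key))
}
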