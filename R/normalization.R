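#' Global mean-centering of a Ct matrix
#'
#' Normalizes each sample to its global mean: the per-sample average Ct over
#' all analyzed genes. The centered value
#' \eqn{\Delta Ct_{ij} = Ct_{ij} - \bar{Ct}_{\cdot j}} cancels any additive
#' per-sample technical offset (extraction yield, reverse-transcription
#' efficiency), which is what makes the per-gene standard deviation of
#' \eqn{\Delta Ct} a measure of a gene's intrinsic variability.
#'
#' @param m a collapsed [ct_matrix] with at least 2 genes. The per-sample mean
#'   is taken over the non-missing genes in that sample.
#' @return an object of class `ct_norm`: list with `delta_ct` (matrix),
#'   `global_mean` (named per-sample vector), `gene_ids`, `sample_ids`.
#' @export
global_mean_center <- function(m) {
  stopifnot(inherits(m, "ct_matrix"))
  if (has_replicates(m)) stop("collapse technical replicates before centering")
  if (nrow(m) < 2L) stop("global mean-centering needs >= 2 genes")
  vals <- unclass_ct(m)
  gm <- colMeans(vals, na.rm = TRUE)
  structure(list(delta_ct = sweep(vals, 2L, gm, "-"),
                 global_mean = gm,
                 gene_ids = rownames(vals),
                 sample_ids = colnames(vals)),
            class = "ct_norm")
}

#' @export
print.ct_norm <- function(x, ...) {
  cat(sprintf("Mean-centered Ct: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  cat("  per-sample global mean Ct range: ",
      paste(round(range(x$global_mean), 2), collapse = " .. "), "\n")
  invisible(x)
}

#' Rank genes by the standard deviation of their centered Ct
#'
#' The mean-centering selection criterion: genes whose \eqn{\Delta Ct} varies
#' least across samples are the least variable relative to the overall
#' expression level. Uses the sample standard deviation (n-1 denominator).
#' Genes with fewer than 3 non-missing values are excluded from the ranking
#' and reported in the `"excluded"` attribute.
#'
#' @param nm a `ct_norm` object from [global_mean_center()].
#' @return data frame `gene_id`, `sd_delta_ct`, sorted ascending (ties broken
#'   by gene id).
#' @export
sd_ranking <- function(nm) {
  stopifnot(inherits(nm, "ct_norm"))
  n_ok <- rowSums(!is.na(nm$delta_ct))
  sds <- apply(nm$delta_ct, 1L, stats::sd, na.rm = TRUE)
  excl <- nm$gene_ids[n_ok < 3L]
  keep <- n_ok >= 3L
  out <- data.frame(gene_id = nm$gene_ids[keep],
                    sd_delta_ct = unname(sds[keep]))
  out <- out[order(out$sd_delta_ct, out$gene_id), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- excl
  out
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between two measurement series, penalizing location and scale
#' shifts as well as imperfect correlation:
#' \deqn{\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#' Variances and covariance use n-1 denominators, so `lin_ccc(x, x)` is
#' exactly 1 for any n (the classical definition with n denominators only
#' rescales numerator and denominator alike when means are equal; with the
#' location term present the two conventions differ slightly and the n-1 form
#' is the one used throughout this package). Always
#' \eqn{|\rho_c| \le |r|} (Pearson), with equality iff means and variances
#' agree.
#'
#' @param x,y numeric vectors of equal length; only pairwise-complete entries
#'   are used and at least 3 complete pairs are required.
#' @return the concordance correlation, in `[-1, 1]`.
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("lin_ccc needs >= 3 complete pairs")
  x <- x[ok]; y <- y[ok]
  sx2 <- stats::var(x); sy2 <- stats::var(y); sxy <- stats::cov(x, y)
  denom <- sx2 + sy2 + (mean(x) - mean(y))^2
  if (denom == 0)
    stop("concordance undefined: both series constant with equal means")
  2 * sxy / denom
}

#' Concordance-correlation-restricted (CCR) candidate selection
#'
#' Scores every gene by how closely its raw Ct profile follows the per-sample
#' global mean of the expressed genes, using Lin's concordance correlation
#' coefficient, and selects a restricted set of mean-tracking genes: those
#' with \eqn{\rho_c \ge} `ccc_min`, capped at the `k_max` highest. Because the
#' CCC penalizes location shifts, a gene must both covary with and sit near
#' the global mean level to score highly. The returned table also carries each
#' gene's `sd_delta_ct` from mean-centering so that callers can intersect the
#' two selection criteria (see [run_ec_pipeline()], which takes the
#' intersection of the `k_max` smallest-SD genes and the CCC rule).
#'
#' @param m a complete, collapsed [ct_matrix] (pass it through
#'   [require_complete_genes()] first).
#' @param ccc_min minimum concordance with the global mean profile
#'   (default 0.9).
#' @param k_max cap on the number of selected genes (default 10).
#' @param refine if `TRUE`, one refinement pass is run: the mean profile is
#'   recomputed over the first-pass selection and genes are re-scored against
#'   it. Off by default; the single pass against the all-gene mean is the
#'   primary definition.
#' @return a `candidate_set`: data frame `gene_id`, `sd_delta_ct`,
#'   `ccc_vs_mean`, `selected`, with the thresholds in attributes.
#' @export
ccr_select <- function(m, ccc_min = 0.9, k_max = 10, refine = FALSE) {
  stopifnot(inherits(m, "ct_matrix"))
  nm <- global_mean_center(m)
  vals <- unclass_ct(m)
  ccc <- apply(vals, 1L, lin_ccc, y = nm$global_mean)
  if (refine) {
    sel0 <- select_by_ccc(ccc, ccc_min, k_max)
    if (any(sel0)) {
      mean_sel <- colMeans(vals[sel0, , drop = FALSE], na.rm = TRUE)
      ccc <- apply(vals, 1L, lin_ccc, y = mean_sel)
    }
  }
  sel <- select_by_ccc(ccc, ccc_min, k_max)
  if (!any(sel))
    warning("no gene reaches ccc_min = ", ccc_min, "; empty candidate set")
  sds <- apply(nm$delta_ct, 1L, stats::sd, na.rm = TRUE)
  out <- data.frame(gene_id = rownames(vals),
                    sd_delta_ct = unname(sds),
                    ccc_vs_mean = unname(ccc),
                    selected = unname(sel))
  rownames(out) <- NULL
  structure(out, ccc_min = ccc_min, k_max = k_max, refine = refine,
            class = c("candidate_set", "data.frame"))
}

select_by_ccc <- function(ccc, ccc_min, k_max) {
  names(ccc) <- names(ccc) %||% as.character(seq_along(ccc))
  pass <- which(ccc >= ccc_min)
  if (length(pass) > k_max)
    pass <- pass[order(-ccc[pass], names(ccc)[pass])][seq_len(k_max)]
  sel <- rep(FALSE, length(ccc))
  sel[pass] <- TRUE
  sel
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("CCR candidate set: %d of %d genes selected (ccc_min = %g, k_max = %d)\n",
              sum(x$selected), nrow(x), attr(x, "ccc_min"), attr(x, "k_max")))
  sel <- x[x$selected, , drop = FALSE]
  if (nrow(sel)) {
    sel <- sel[order(-sel$ccc_vs_mean, sel$gene_id), ]
    print.data.frame(sel, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
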