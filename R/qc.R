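#' Determination-level Ct quality filtering
#'
#' Applies the array/assay quality rules used when screening plasma miRNA
#' profiles: a determination is deleted when its Ct is at or above the
#' detection threshold (`ct_max`, default 35 cycles), when the instrument
#' reported it as undetected, or when it was flagged as having an irregular
#' amplification curve (the curve judgment is an input flag, made upstream by
#' inspection, never computed here). Each removed determination is counted
#' once, with precedence irregular_curve > undetected > threshold, so the
#' report is deterministic.
#'
#' @param m a [ct_matrix].
#' @param flags a determination flag table; defaults to `ct_flags(m)`.
#' @param ct_max detection threshold in cycles, in `(0, 45]`; values with
#'   `Ct >= ct_max` are removed (the bound is inclusive).
#' @return a list with elements `ct` (filtered [ct_matrix], flags cleared) and
#'   `report` (a `qc_report`).
#' @seealso [collapse_replicates()], [require_complete_genes()]
#' @export
apply_ct_filters <- function(m, flags = ct_flags(m), ct_max = 35) {
  stopifnot(inherits(m, "ct_matrix"))
  if (!is.numeric(ct_max) || length(ct_max) != 1L || ct_max <= 0 || ct_max > 45)
    stop("ct_max must be a single value in (0, 45]")
  vals <- unclass_ct(m)
  rep <- attr(m, "replicate")
  sid <- attr(m, "sample_ids")

  irr <- und <- matrix(FALSE, nrow(vals), ncol(vals))
  if (!is.null(flags) && nrow(flags)) {
    ri <- match(flags$gene_id, rownames(vals))
    colkey <- paste(sid, if (is.null(rep)) NA_character_ else rep)
    ci <- match(paste(flags$sample_id,
                      if (is.null(rep)) NA_character_ else flags$replicate),
                colkey)
    keep <- !is.na(ri) & !is.na(ci)
    idx <- cbind(ri[keep], ci[keep])
    irr[idx[flags$flag[keep] == "irregular_curve", , drop = FALSE]] <- TRUE
    und[idx[flags$flag[keep] == "undetected", , drop = FALSE]] <- TRUE
  }
  und <- und & !irr
  thr <- !is.na(vals) & vals >= ct_max & !irr & !und
  vals[irr | und | thr] <- NA_real_

  report <- qc_report(
    n_total = length(vals),
    n_removed_ct_threshold = sum(thr),
    n_removed_undetected = sum(und),
    n_removed_irregular = sum(irr),
    n_missing_unflagged = sum(is.na(vals)) - sum(thr | und | irr),
    n_retained = sum(!is.na(vals)),
    genes_dropped = character())
  list(ct = ct_matrix(vals, sample_ids = sid, replicate = rep),
       report = report)
}

qc_report <- function(n_total, n_removed_ct_threshold, n_removed_undetected,
                      n_removed_irregular, n_missing_unflagged, n_retained,
                      genes_dropped = character()) {
  structure(list(n_total = n_total,
                 n_removed_ct_threshold = n_removed_ct_threshold,
                 n_removed_undetected = n_removed_undetected,
                 n_removed_irregular = n_removed_irregular,
                 n_missing_unflagged = n_missing_unflagged,
                 n_retained = n_retained,
                 genes_dropped = genes_dropped),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Ct quality-control report\n")
  cat(sprintf("  determinations:          %d\n", x$n_total))
  cat(sprintf("  retained:                %d\n", x$n_retained))
  cat(sprintf("  removed, Ct >= threshold:%d\n", x$n_removed_ct_threshold))
  cat(sprintf("  removed, undetected:     %d\n", x$n_removed_undetected))
  cat(sprintf("  removed, irregular curve:%d\n", x$n_removed_irregular))
  cat(sprintf("  missing (unflagged):     %d\n", x$n_missing_unflagged))
  if (length(x$genes_dropped))
    cat("  genes dropped (completeness): ",
        paste(x$genes_dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname write_results
#' @export
write_results.qc_report <- function(result, path, ...) {
  scalars <- result[names(result) != "genes_dropped"]
  df <- data.frame(key = c(names(scalars), "genes_dropped"),
                   value = c(unlist(scalars),
                             paste(result$genes_dropped, collapse = ";")))
  write_csv_plain(df, path)
}

#' Collapse technical replicates
#'
#' Validation-stage assays are typically run in duplicate; this collapses the
#' replicate columns of an uncollapsed [ct_matrix] to one value per
#' (gene, sample). Pairs whose replicate range exceeds `max_spread` cycles are
#' reported as discordant but still collapsed (the filter is deliberately
#' conservative: discordance is a warning signal, not an automatic removal).
#'
#' @param m an uncollapsed [ct_matrix] (replicate labels present).
#' @param method collapse by `"mean"` (default) or `"median"` over the
#'   non-missing replicates.
#' @param max_spread discordance threshold in cycles (default 1.0).
#' @return a list with `ct` (collapsed [ct_matrix]) and `discordant`
#'   (data frame `gene_id`, `sample_id`, `spread`).
#' @export
collapse_replicates <- function(m, method = c("mean", "median"),
                                max_spread = 1.0) {
  stopifnot(inherits(m, "ct_matrix"))
  method <- match.arg(method)
  if (!has_replicates(m)) stop("matrix has no replicate labels to collapse")
  fun <- if (method == "mean") mean else stats::median
  sid <- attr(m, "sample_ids")
  samples <- unique(sid)
  vals <- unclass_ct(m)
  out <- matrix(NA_real_, nrow(vals), length(samples),
                dimnames = list(rownames(vals), samples))
  disc <- list()
  for (s in samples) {
    block <- vals[, sid == s, drop = FALSE]
    out[, s] <- apply(block, 1L, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else fun(v)
    })
    spread <- apply(block, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L) 0 else diff(range(v))
    })
    bad <- which(spread > max_spread)
    if (length(bad))
      disc[[s]] <- data.frame(gene_id = rownames(vals)[bad], sample_id = s,
                              spread = unname(spread[bad]))
  }
  disc <- if (length(disc)) do.call(rbind, c(disc, make.row.names = FALSE))
  else data.frame(gene_id = character(), sample_id = character(),
                  spread = numeric())
  list(ct = ct_matrix(out, sample_ids = samples), discordant = disc)
}

#' Keep genes detected in a minimum fraction of samples
#'
#' Candidate endogenous controls must be reliably expressed; with the default
#' `min_fraction = 1` a gene is kept only when it is detected in every sample
#' (a gene undetected in even one sample is dropped). With replicates, a
#' sample counts as detected when any replicate is non-missing.
#'
#' @param m a [ct_matrix].
#' @param min_fraction required detected fraction of samples, in `(0, 1]`.
#' @return a list with `ct` (filtered matrix) and `dropped` (gene ids).
#' @export
require_complete_genes <- function(m, min_fraction = 1.0) {
  stopifnot(inherits(m, "ct_matrix"))
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must be in (0, 1]")
  sid <- attr(m, "sample_ids")
  samples <- unique(sid)
  detected <- vapply(samples, function(s)
    rowSums(!is.na(unclass_ct(m)[, sid == s, drop = FALSE])) > 0,
    logical(nrow(m)))
  if (is.null(dim(detected))) detected <- matrix(detected, nrow = nrow(m))
  frac <- rowMeans(detected)
  keep <- frac >= min_fraction
  if (!any(keep))
    stop("no gene passes the completeness rule (min_fraction = ",
         min_fraction, ")")
  list(ct = m[keep, ], dropped = ct_genes(m)[!keep])
}
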