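#' BestKeeper descriptive statistics
#'
#' Per-gene descriptive statistics of the raw Ct values (BestKeeper operates
#' on raw crossing points, not centered values, so unlike geNorm its
#' statistics are sensitive to per-sample technical offsets): geometric mean,
#' arithmetic mean, min, max, a dispersion measure and the coefficient of
#' variation (100 * dispersion / arithmetic mean).
#'
#' @param m a collapsed [ct_matrix]; all Ct must be positive and each gene
#'   needs >= 3 non-missing values.
#' @param var_measure `"sd"` (default; the sample standard deviation) or
#'   `"mad"` (mean absolute deviation from the arithmetic mean, the dispersion
#'   used by some versions of the original BestKeeper tool). The choice is
#'   recorded in the result.
#' @return data frame `gene_id`, `geo_mean`, `ar_mean`, `min`, `max`, `sd`,
#'   `cv` (the `sd` column holds whichever dispersion was requested).
#' @export
descriptive_stats <- function(m, var_measure = c("sd", "mad")) {
  stopifnot(inherits(m, "ct_matrix"))
  var_measure <- match.arg(var_measure)
  vals <- unclass_ct(m)
  if (any(vals <= 0, na.rm = TRUE))
    stop("BestKeeper statistics require strictly positive Ct values")
  if (any(rowSums(!is.na(vals)) < 3L))
    stop("each gene needs >= 3 non-missing Ct values")
  disp <- function(v) {
    v <- v[!is.na(v)]
    if (var_measure == "sd") stats::sd(v) else mean(abs(v - mean(v)))
  }
  row_stat <- function(f) apply(vals, 1L, function(v) f(v[!is.na(v)]))
  ar <- row_stat(mean)
  s <- apply(vals, 1L, disp)
  out <- data.frame(gene_id = rownames(vals),
                    geo_mean = row_stat(function(v) exp(mean(log(v)))),
                    ar_mean = ar,
                    min = row_stat(min),
                    max = row_stat(max),
                    sd = s,
                    cv = 100 * s / ar)
  rownames(out) <- NULL
  attr(out, "var_measure") <- var_measure
  out
}

#' BestKeeper index
#'
#' The per-sample BestKeeper index is the geometric mean of the candidate
#' genes' Ct values in that sample.
#'
#' @param m a complete, collapsed [ct_matrix] (no missing values).
#' @return named per-sample numeric vector (cycles).
#' @export
bestkeeper_index <- function(m) {
  stopifnot(inherits(m, "ct_matrix"))
  vals <- unclass_ct(m)
  if (anyNA(vals))
    stop("BestKeeper index requires a complete matrix over the candidates")
  if (any(vals <= 0)) stop("Ct values must be positive")
  exp(colMeans(log(vals)))
}

#' Correlations of candidate genes with the BestKeeper index
#'
#' Pearson correlation of each gene's Ct profile with the index, with a
#' two-sided p-value from the t distribution on n-2 degrees of freedom, plus
#' the full gene-by-gene Pearson correlation matrix.
#'
#' @param m a complete, collapsed [ct_matrix] with >= 4 samples.
#' @param index per-sample index, defaults to [bestkeeper_index()] of `m`.
#' @return list with `r` (named vector), `p` (named vector), `pairwise_r`
#'   (matrix). Zero-variance genes get `NA` with a warning.
#' @export
index_correlations <- function(m, index = bestkeeper_index(m)) {
  stopifnot(inherits(m, "ct_matrix"))
  vals <- unclass_ct(m)
  if (ncol(vals) < 4L) stop("index correlations need >= 4 samples")
  if (length(index) != ncol(vals))
    stop("index length must match the number of samples")
  genes <- rownames(vals)
  r <- p <- stats::setNames(rep(NA_real_, length(genes)), genes)
  for (g in genes) {
    v <- vals[g, ]
    if (stats::sd(v) == 0) {
      warning("gene ", g, " has zero variance; correlation undefined")
      next
    }
    ht <- stats::cor.test(v, index, method = "pearson",
                          alternative = "two.sided")
    r[g] <- unname(ht$estimate)
    p[g] <- ht$p.value
  }
  suppressWarnings(pw <- stats::cor(t(vals)))
  list(r = r, p = p, pairwise_r = pw)
}

#' BestKeeper stability analysis
#'
#' Runs the full BestKeeper workflow on a candidate Ct matrix: descriptive
#' statistics, the per-sample index (geometric mean of candidate Ct values)
#' and each gene's Pearson correlation with the index. Genes whose dispersion
#' exceeds `sd_max` cycles are flagged `inconsistent` following BestKeeper's
#' published exclusion guidance; the remaining genes are ranked by descending
#' correlation with the index (ties by ascending dispersion, then gene id).
#'
#' @param m a complete, collapsed [ct_matrix] with >= 4 samples.
#' @param sd_max dispersion threshold in cycles for flagging (default 1.0).
#' @param var_measure passed to [descriptive_stats()].
#' @return an object of class `bestkeeper`: list with `stats` (per-gene table
#'   including `r_vs_index`, `p_vs_index`, `flagged`, `rank`; flagged genes
#'   have `NA` rank), `index`, `pairwise_r`, `sd_max`, `var_measure`.
#' @export
bestkeeper <- function(m, sd_max = 1.0, var_measure = c("sd", "mad")) {
  var_measure <- match.arg(var_measure)
  stats_df <- descriptive_stats(m, var_measure)
  index <- bestkeeper_index(m)
  corr <- index_correlations(m, index)
  stats_df$r_vs_index <- unname(corr$r[stats_df$gene_id])
  stats_df$p_vs_index <- unname(corr$p[stats_df$gene_id])
  stats_df$mean_pairwise_r <- unname(
    (rowSums(corr$pairwise_r) - 1) / (nrow(corr$pairwise_r) - 1))
  stats_df$flagged <- stats_df$sd > sd_max
  stats_df$rank <- NA_integer_
  ok <- !stats_df$flagged & !is.na(stats_df$r_vs_index)
  ord <- order(-stats_df$r_vs_index[ok], stats_df$sd[ok],
               stats_df$gene_id[ok])
  stats_df$rank[which(ok)[ord]] <- seq_len(sum(ok))
  structure(list(stats = stats_df, index = index,
                 pairwise_r = corr$pairwise_r,
                 sd_max = sd_max, var_measure = var_measure),
            class = "bestkeeper")
}

#' Ordered gene list from a BestKeeper result
#'
#' @param result a [bestkeeper()] object.
#' @param sd_max optionally re-apply the flagging threshold before ranking.
#' @return character vector of unflagged genes, most stable first.
#' @export
bestkeeper_rank <- function(result, sd_max = result$sd_max) {
  stopifnot(inherits(result, "bestkeeper"))
  st <- result$stats
  if (anyNA(st$r_vs_index[st$sd <= sd_max]))
    stop("r_vs_index missing for an unflagged gene")
  keep <- st$sd <= sd_max
  st <- st[keep, , drop = FALSE]
  st$gene_id[order(-st$r_vs_index, st$sd, st$gene_id)]
}

#' @export
print.bestkeeper <- function(x, ...) {
  cat(sprintf("BestKeeper analysis (%d genes, %d samples; dispersion = %s, sd_max = %g)\n",
              nrow(x$stats), length(x$index), x$var_measure, x$sd_max))
  st <- x$stats[order(is.na(x$stats$rank), x$stats$rank), ]
  print.data.frame(st[, c("gene_id", "geo_mean", "sd", "cv", "r_vs_index",
                          "p_vs_index", "flagged", "rank")],
                   row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.bestkeeper <- function(x, ...) {
  st <- x$stats[order(-x$stats$r_vs_index), ]
  graphics::barplot(stats::setNames(st$r_vs_index, st$gene_id), las = 2,
                    ylab = "Pearson r vs BestKeeper index",
                    main = "BestKeeper gene stability", ...)
  invisible(x)
}

#' @rdname write_results
#' @export
write_results.bestkeeper <- function(result, path, ...) {
  st <- result$stats
  df <- st[, c("gene_id", "geo_mean", "ar_mean", "min", "max", "sd", "cv",
               "r_vs_index", "p_vs_index", "mean_pairwise_r", "rank",
               "flagged")]
  write_csv_plain(df[order(is.na(df$rank), df$rank, df$gene_id), ], path)
}
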