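#' NormFinder intragroup variance estimates
#'
#' Model-based estimate of each gene's technical + biological variance within
#' each diagnostic group, under the additive model
#' \eqn{y_{igj} = \alpha_{ig} + \beta_{gj} + \varepsilon_{igj}} (gene effect +
#' per-sample effect + noise). Within each group the residuals are
#' double-centered, \eqn{r_{igj} = y_{igj} - \bar y_{ig\cdot} -
#' \bar y_{\cdot gj} + \bar y_{\cdot g \cdot}}, giving
#' \eqn{s^2_{ig} = \sum_j r^2_{igj} / (n_g - 1)}; because the per-sample
#' centering injects a share of every other gene's noise, the estimates are
#' unbiased across genes via
#' \eqn{\hat\sigma^2_{ig} = (s^2_{ig} - \bar s^2_g / (I - 1)) \cdot I/(I-2)},
#' floored at 0 (the subtraction can go negative at small n). The correction
#' divides by I-2, so at least 3 genes are required.
#'
#' @param m a complete, collapsed [ct_matrix] with >= 3 genes.
#' @param groups factor of group labels, one per sample (in column order), or
#'   an annotation data frame with `sample_id` and `group` columns.
#' @return matrix of variance estimates, genes x groups (cycles squared).
#' @export
intragroup_variances <- function(m, groups) {
  pg <- nf_prepare(m, groups)
  sigma2 <- vapply(levels(pg$groups), function(g) {
    y <- pg$vals[, pg$groups == g, drop = FALSE]
    r <- y - rowMeans(y) - rep(colMeans(y), each = nrow(y)) + mean(y)
    s2 <- rowSums(r^2) / (ncol(y) - 1L)
    pmax(0, (s2 - mean(s2) / (pg$I - 1L)) * pg$I / (pg$I - 2L))
  }, numeric(nrow(pg$vals)))
  dimnames(sigma2) <- list(rownames(pg$vals), levels(pg$groups))
  sigma2
}

nf_prepare <- function(m, groups) {
  stopifnot(inherits(m, "ct_matrix"))
  if (has_replicates(m)) stop("collapse technical replicates first")
  vals <- unclass_ct(m)
  if (anyNA(vals)) stop("NormFinder requires a complete candidate matrix")
  if (is.data.frame(groups)) groups <- annotation_groups(m, groups)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != ncol(vals))
    stop("'groups' must give one label per sample")
  I <- nrow(vals)
  if (I < 3L)
    stop("NormFinder needs >= 3 genes (variance unbiasing divides by I - 2)")
  ng <- table(groups)
  if (any(ng < 2L))
    stop("every group needs >= 2 samples; too small: ",
         paste(names(ng)[ng < 2L], collapse = ", "))
  list(vals = vals, groups = groups, I = I, ng = as.vector(ng))
}

#' NormFinder intergroup differences
#'
#' The systematic expression difference of each gene between diagnostic
#' groups, double-centered so that the differences sum to zero over genes
#' within each group and over groups within each gene:
#' \eqn{z_{ig} = \bar y_{ig\cdot} - \frac1I \sum_{i'} \bar y_{i'g\cdot}},
#' \eqn{d_{ig} = z_{ig} - \frac1G \sum_{g'} z_{ig'}}.
#'
#' @inheritParams intragroup_variances
#' @return matrix of raw intergroup differences, genes x groups (cycles).
#' @export
intergroup_differences <- function(m, groups) {
  pg <- nf_prepare(m, groups)
  if (nlevels(pg$groups) < 2L)
    stop("intergroup differences need >= 2 groups")
  gm <- vapply(levels(pg$groups), function(g)
    rowMeans(pg$vals[, pg$groups == g, drop = FALSE]),
    numeric(nrow(pg$vals)))
  z <- sweep(gm, 2L, colMeans(gm), "-")
  d <- sweep(z, 1L, rowMeans(z), "-")
  dimnames(d) <- list(rownames(pg$vals), levels(pg$groups))
  d
}

#' NormFinder stability values
#'
#' Combines each gene's intragroup variance and its shrunken intergroup
#' difference into a single stability value (lower = more stable). With
#' sampling variances \eqn{v_{ig} = \hat\sigma^2_{ig} / n_g}, the
#' between-gene variance of the intergroup differences is estimated as
#' \eqn{\hat\gamma^2 = \max(0, \sum d^2_{ig} / ((I-1)(G-1)) - \bar v)} (the
#' degrees of freedom reflect the two sum-to-zero constraints on d), the
#' differences are shrunk,
#' \eqn{\tilde d_{ig} = d_{ig}\,\hat\gamma^2 / (\hat\gamma^2 + v_{ig})}, and
#' \deqn{\rho_{ig} = |\tilde d_{ig}| +
#'   \sqrt{\hat\gamma^2 v_{ig} / (\hat\gamma^2 + v_{ig})}}
#' The stability value of gene i is the mean of \eqn{\rho_{ig}} over groups.
#' With a single group the intergroup terms are skipped and the value reduces
#' to \eqn{\sqrt{\hat\sigma^2_i / n}}, keeping units and interpretation
#' consistent. If \eqn{\hat\gamma^2 = 0} (no evidence of group differences
#' anywhere) all G >= 2 stability values are 0 and ranking falls back to gene
#' id; the intended use is on data where some gene shows a group effect.
#'
#' @inheritParams intragroup_variances
#' @return an object of class `normfinder`: list with `stability_value`
#'   (named vector), `sigma2_hat`, `d_raw`, `d_shrunk` (genes x groups
#'   matrices; NULL when G = 1), `gamma2_hat`, `groups_used`, `n_per_group`.
#' @export
normfinder <- function(m, groups) {
  pg <- nf_prepare(m, groups)
  sigma2 <- intragroup_variances(m, pg$groups)
  G <- nlevels(pg$groups)
  genes <- rownames(pg$vals)
  if (G == 1L) {
    stab <- sqrt(sigma2[, 1L] / pg$ng)
    return(structure(list(stability_value = stats::setNames(stab, genes),
                          sigma2_hat = sigma2, d_raw = NULL, d_shrunk = NULL,
                          gamma2_hat = 0,
                          groups_used = levels(pg$groups),
                          n_per_group = pg$ng),
                     class = "normfinder"))
  }
  d <- intergroup_differences(m, pg$groups)
  v <- sweep(sigma2, 2L, pg$ng, "/")
  gamma2 <- max(0, sum(d^2) / ((pg$I - 1L) * (G - 1L)) - mean(v))
  shrink <- d * 0                     # 0/0 guard: no signal, full shrinkage
  pos <- gamma2 + v > 0
  shrink[pos] <- gamma2 / (gamma2 + v[pos])
  d_shrunk <- d * shrink
  score <- abs(d_shrunk) + sqrt(v * shrink)
  structure(list(stability_value = stats::setNames(rowMeans(score), genes),
                 sigma2_hat = sigma2, d_raw = d, d_shrunk = d_shrunk,
                 gamma2_hat = gamma2, groups_used = levels(pg$groups),
                 n_per_group = pg$ng),
            class = "normfinder")
}

#' Ordered gene list from a NormFinder result
#'
#' @param result a [normfinder()] object.
#' @return character vector of genes by ascending stability value (ties by
#'   gene id), most stable first.
#' @export
normfinder_rank <- function(result) {
  stopifnot(inherits(result, "normfinder"))
  s <- result$stability_value
  names(s)[order(s, names(s))]
}

#' @export
print.normfinder <- function(x, ...) {
  cat(sprintf("NormFinder analysis (%d genes, groups: %s; gamma2 = %.4g)\n",
              length(x$stability_value),
              paste(x$groups_used, collapse = ", "), x$gamma2_hat))
  ord <- order(x$stability_value, names(x$stability_value))
  df <- data.frame(gene_id = names(x$stability_value)[ord],
                   stability_value = unname(x$stability_value[ord]))
  print.data.frame(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.normfinder <- function(x, ...) {
  s <- sort(x$stability_value, decreasing = TRUE)
  graphics::barplot(s, las = 2, ylab = "NormFinder stability value (cycles)",
                    main = "NormFinder gene stability", ...)
  invisible(x)
}

#' @rdname write_results
#' @export
write_results.normfinder <- function(result, path, ...) {
  genes <- names(result$stability_value)
  ord <- order(result$stability_value, genes)
  rk <- integer(length(genes))
  rk[ord] <- seq_along(ord)
  df <- data.frame(gene_id = genes,
                   stability_value = unname(result$stability_value),
                   rank = rk)
  for (g in result$groups_used) {
    df[[paste0("sigma2_hat.", g)]] <- result$sigma2_hat[genes, g]
    if (!is.null(result$d_raw)) {
      df[[paste0("d_raw.", g)]] <- result$d_raw[genes, g]
      df[[paste0("d_shrunk.", g)]] <- result$d_shrunk[genes, g]
    }
  }
  path <- check_writable(path)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gamma2_hat,%s", format_num(result$gamma2_hat)), con)
  utils::write.csv(df[ord, ], con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
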