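#' Pipeline configuration
#'
#' All thresholds used across the endogenous-control workflow, validated and
#' serializable as flat YAML. Unknown keys are rejected so that a typo in a
#' config file cannot silently fall back to a default.
#'
#' @param ct_max detection threshold in cycles (determinations with
#'   `Ct >= ct_max` are deleted; default 35).
#' @param min_fraction required detected fraction of samples per gene
#'   (default 1: detected in all samples).
#' @param ccc_min minimum concordance with the global mean (default 0.9).
#' @param k_max cap on candidates per selection criterion (default 10).
#' @param sd_max BestKeeper dispersion flagging threshold in cycles
#'   (default 1).
#' @param n_top_ecs size of the final endogenous-control panel (default 4).
#' @param combine_rule rank combination rule: `"geometric"` (default),
#'   `"arithmetic"` or `"borda"`.
#' @param kw_p_min optional Kruskal-Wallis p-value floor: candidates with
#'   `kw_p < kw_p_min` are excluded from the final panel. `NULL` (default)
#'   disables the filter; group-difference p-values are then reported as
#'   supporting evidence only.
#' @param seed optional integer seed recorded with the run.
#' @return an object of class `ec_config` (a named list).
#' @export
ec_config <- function(ct_max = 35, min_fraction = 1.0, ccc_min = 0.9,
                      k_max = 10, sd_max = 1.0, n_top_ecs = 4,
                      combine_rule = c("geometric", "arithmetic", "borda"),
                      kw_p_min = NULL, seed = NULL) {
  combine_rule <- match.arg(combine_rule)
  cfg <- list(ct_max = ct_max, min_fraction = min_fraction,
              ccc_min = ccc_min, k_max = as.integer(k_max),
              sd_max = sd_max, n_top_ecs = as.integer(n_top_ecs),
              combine_rule = combine_rule, kw_p_min = kw_p_min, seed = seed)
  stopifnot(cfg$ct_max > 0, cfg$ct_max <= 45,
            cfg$min_fraction > 0, cfg$min_fraction <= 1,
            cfg$ccc_min >= -1, cfg$ccc_min <= 1,
            cfg$k_max >= 1, cfg$sd_max > 0, cfg$n_top_ecs >= 1)
  structure(cfg, class = "ec_config")
}

#' @rdname ec_config
#' @param path YAML file with flat keys (a subset of the arguments above).
#' @export
read_ec_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(ec_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(ec_config, raw)
}

#' @rdname ec_config
#' @param config an `ec_config` to serialize.
#' @export
write_ec_config <- function(config, path) {
  yaml::write_yaml(unclass(config), check_writable(path))
  invisible(path)
}

#' Per-gene Kruskal-Wallis group-difference test
#'
#' Tests each candidate gene's Ct values for a difference between diagnostic
#' groups with the Kruskal-Wallis rank-sum test (chi-square approximation on
#' G-1 degrees of freedom with the average-rank tie correction, as in
#' [stats::kruskal.test()]). For a useful endogenous control one wants *no*
#' significant group difference. A gene whose values are all tied has H = 0
#' and p = 1 by convention.
#'
#' @param m a collapsed [ct_matrix].
#' @param groups factor per sample, or an annotation data frame with
#'   `sample_id` and `group`.
#' @return named vector of p-values, one per gene.
#' @export
group_difference_test <- function(m, groups) {
  stopifnot(inherits(m, "ct_matrix"))
  if (has_replicates(m)) stop("collapse technical replicates first")
  if (is.data.frame(groups)) groups <- annotation_groups(m, groups)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("group comparison needs >= 2 groups")
  ng <- table(groups)
  if (any(ng < 2L))
    stop("every group needs >= 2 samples; too small: ",
         paste(names(ng)[ng < 2L], collapse = ", "))
  vals <- unclass_ct(m)
  apply(vals, 1L, function(v) {
    ok <- !is.na(v)
    vv <- v[ok]
    if (length(unique(vv)) == 1L) return(1)   # all tied: H = 0
    stats::kruskal.test(vv, groups[ok])$p.value
  })
}

#' Consensus ranking across geNorm, BestKeeper and NormFinder
#'
#' Combines the three algorithms' stability orderings into one overall
#' ranking. Each algorithm contributes a rank vector over the same gene set
#' (ties share the mean rank): geNorm by exclusion order with the final pair
#' tied at the top, BestKeeper by descending correlation with its index
#' (over all genes; the dispersion flag is advisory and does not remove genes
#' here), NormFinder by ascending stability value. The default combination is
#' the geometric mean of the three ranks (the RefFinder-style convention);
#' arithmetic mean and Borda (rank sum) are available. Because only ranks are
#' consumed, the consensus is invariant to monotone transformations of the
#' underlying stability metrics.
#'
#' @param gn a [genorm()] result.
#' @param bk a [bestkeeper()] result.
#' @param nf a [normfinder()] result.
#' @param rule combination rule (see [ec_config()]).
#' @param n_top_ecs size of the selected endogenous-control panel.
#' @param kw_p optional named vector of per-gene group-difference p-values to
#'   carry into the report.
#' @param kw_p_min optional exclusion threshold on `kw_p` for panel selection.
#' @return an object of class `ec_consensus`: data frame with `gene_id`,
#'   `rank_genorm`, `rank_bestkeeper`, `rank_normfinder`, `combined_score`,
#'   `final_rank` and (if given) `kw_p`; the selected panel is in
#'   `attr(, "selected_ecs")`.
#' @export
combine_ranks <- function(gn, bk, nf,
                          rule = c("geometric", "arithmetic", "borda"),
                          n_top_ecs = 4, kw_p = NULL, kw_p_min = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(gn, "genorm"), inherits(bk, "bestkeeper"),
            inherits(nf, "normfinder"))
  genes <- sort(names(gn$m_values))
  check_gene_sets(genes, sort(bk$stats$gene_id), "BestKeeper")
  check_gene_sets(genes, sort(names(nf$stability_value)), "NormFinder")

  r_gn <- rank_with_ties(gn)[genes]
  r_bk <- stats::setNames(
    rank(-bk$stats$r_vs_index, ties.method = "average"),
    bk$stats$gene_id)[genes]
  r_nf <- stats::setNames(
    rank(nf$stability_value, ties.method = "average"),
    names(nf$stability_value))[genes]

  score <- switch(rule,
                  geometric  = (r_gn * r_bk * r_nf)^(1 / 3),
                  arithmetic = (r_gn + r_bk + r_nf) / 3,
                  borda      = r_gn + r_bk + r_nf)
  ord <- order(score, genes)
  out <- data.frame(gene_id = genes,
                    rank_genorm = unname(r_gn),
                    rank_bestkeeper = unname(r_bk),
                    rank_normfinder = unname(r_nf),
                    combined_score = unname(score))
  out$final_rank <- NA_integer_
  out$final_rank[ord] <- seq_along(ord)
  if (!is.null(kw_p)) out$kw_p <- unname(kw_p[genes])
  out <- out[order(out$final_rank), ]
  rownames(out) <- NULL
  eligible <- out$gene_id
  if (!is.null(kw_p_min) && !is.null(kw_p))
    eligible <- out$gene_id[!is.na(out$kw_p) & out$kw_p >= kw_p_min]
  structure(out, rule = rule,
            selected_ecs = utils::head(eligible, n_top_ecs),
            class = c("ec_consensus", "data.frame"))
}

check_gene_sets <- function(a, b, label) {
  if (!identical(a, b))
    stop(label, " gene set differs from geNorm's: only in one of them: ",
         paste(union(setdiff(a, b), setdiff(b, a)), collapse = ", "))
}

#' @export
print.ec_consensus <- function(x, ...) {
  cat(sprintf("Consensus endogenous-control ranking (%s mean of ranks)\n",
              attr(x, "rule")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat("selected ECs:", paste(attr(x, "selected_ecs"), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.ec_consensus <- function(x, ...) {
  graphics::barplot(stats::setNames(x$combined_score, x$gene_id), las = 2,
                    ylab = "combined rank score",
                    main = "Consensus EC ranking", ...)
  invisible(x)
}

#' @rdname write_results
#' @export
write_results.ec_consensus <- function(result, path, ...) {
  df <- as.data.frame(result)
  df$selected <- df$gene_id %in% attr(result, "selected_ecs")
  write_csv_plain(df, path)
}

#' Run the full endogenous-control identification pipeline
#'
#' Mirrors the two-cohort study design: candidate discovery on a screening
#' profile, stability validation on an independent cohort.
#' Stages: (1) QC on the screening matrix (Ct/flag filters, optional replicate
#' collapse, completeness rule); (2) candidate selection as the intersection
#' of the `k_max` smallest-SD genes after global mean-centering and the genes
#' passing the CCR concordance rule; (3) QC on the validation matrix,
#' restriction to the candidates (validation samples with a missing candidate
#' determination after QC are dropped and reported); (4) geNorm, BestKeeper,
#' NormFinder and the per-gene Kruskal-Wallis group test on the validation
#' candidates; (5) consensus ranking and panel selection. Any stage error is
#' re-raised with the stage name.
#'
#' @param screen screening-cohort [ct_matrix].
#' @param validate validation-cohort [ct_matrix].
#' @param validate_ann annotation data frame for the validation samples
#'   (`sample_id`, `group`).
#' @param config an [ec_config()].
#' @param out_dir optional output directory; when given, every stage result,
#'   the resolved config (`config_used.yaml`) and a short `log.txt` are
#'   written there (layout: qc_report.csv, candidates.csv, genorm.csv,
#'   bestkeeper.csv, normfinder.csv, consensus.csv).
#' @return an object of class `ec_pipeline`: list with `qc_screen`,
#'   `qc_validate`, `candidates`, `candidate_genes`, `genorm`, `bestkeeper`,
#'   `normfinder`, `kw_p`, `consensus`, `selected_ecs`, `config`,
#'   `dropped_validation_samples`.
#' @export
run_ec_pipeline <- function(screen, validate, validate_ann,
                            config = ec_config(), out_dir = NULL) {
  stopifnot(inherits(config, "ec_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }

  scr <- stage("qc_screen", {
    f <- apply_ct_filters(screen, ct_max = config$ct_max)
    m <- f$ct
    if (has_replicates(m)) m <- collapse_replicates(m)$ct
    cg <- require_complete_genes(m, config$min_fraction)
    f$report$genes_dropped <- cg$dropped
    list(ct = cg$ct, report = f$report)
  })

  cand <- stage("candidates", {
    cs <- ccr_select(scr$ct, ccc_min = config$ccc_min, k_max = config$k_max)
    by_sd <- cs$gene_id[order(cs$sd_delta_ct, cs$gene_id)]
    top_sd <- utils::head(by_sd, config$k_max)
    by_ccc <- cs$gene_id[cs$selected]
    genes <- intersect(top_sd, by_ccc)
    if (length(genes) < 3L)
      stop("fewer than 3 candidate genes selected (",
           paste(genes, collapse = ", "), ")")
    list(set = cs, genes = sort(genes))
  })

  val <- stage("qc_validate", {
    f <- apply_ct_filters(validate, ct_max = config$ct_max)
    m <- f$ct
    if (has_replicates(m)) m <- collapse_replicates(m)$ct
    missing_genes <- setdiff(cand$genes, ct_genes(m))
    if (length(missing_genes))
      stop("validation matrix lacks candidate gene(s): ",
           paste(missing_genes, collapse = ", "))
    m <- m[cand$genes, ]
    complete <- colSums(is.na(unclass_ct(m))) == 0L
    list(ct = m[, complete], report = f$report,
         dropped_samples = ct_samples(m)[!complete])
  })

  ann <- validate_annotation(validate_ann)
  gn <- stage("genorm", genorm(val$ct))
  bk <- stage("bestkeeper", bestkeeper(val$ct, sd_max = config$sd_max))
  nf <- stage("normfinder", normfinder(val$ct, ann))
  kw <- stage("group_test", group_difference_test(val$ct, ann))
  cons <- stage("consensus",
                combine_ranks(gn, bk, nf, rule = config$combine_rule,
                              n_top_ecs = config$n_top_ecs, kw_p = kw,
                              kw_p_min = config$kw_p_min))

  res <- structure(list(qc_screen = scr$report, qc_validate = val$report,
                        candidates = cand$set, candidate_genes = cand$genes,
                        genorm = gn, bestkeeper = bk, normfinder = nf,
                        kw_p = kw, consensus = cons,
                        selected_ecs = attr(cons, "selected_ecs"),
                        dropped_validation_samples = val$dropped_samples,
                        config = config),
                   class = "ec_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_results(res$qc_screen, file.path(out_dir, "qc_report.csv"))
  write_results(as.data.frame(res$candidates),
                file.path(out_dir, "candidates.csv"))
  write_results(res$genorm, file.path(out_dir, "genorm.csv"))
  write_results(res$bestkeeper, file.path(out_dir, "bestkeeper.csv"))
  write_results(res$normfinder, file.path(out_dir, "normfinder.csv"))
  write_results(res$consensus, file.path(out_dir, "consensus.csv"))
  write_ec_config(res$config, file.path(out_dir, "config_used.yaml"))
  writeLines(c(
    sprintf("ecmiR %s", as.character(utils::packageVersion("ecmiR"))),
    sprintf("candidates: %s", paste(res$candidate_genes, collapse = ", ")),
    sprintf("selected ECs: %s", paste(res$selected_ecs, collapse = ", ")),
    sprintf("dropped validation samples: %s",
            paste(res$dropped_validation_samples, collapse = ", "))),
    file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' @export
print.ec_pipeline <- function(x, ...) {
  cat("Endogenous-control identification pipeline\n")
  cat(sprintf("  candidates (%d): %s\n", length(x$candidate_genes),
              paste(x$candidate_genes, collapse = ", ")))
  cat(sprintf("  selected ECs (%d): %s\n", length(x$selected_ecs),
              paste(x$selected_ecs, collapse = ", ")))
  invisible(x)
}

#' @export
summary.ec_pipeline <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$consensus)
  invisible(object)
}
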