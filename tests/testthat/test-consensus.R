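# A small validation-style dataset whose three stability fits are reused
# across the consensus tests.
consensus_fixture <- function(seed = 5) {
  ds <- simulate_ct_dataset(sim_preset("recovery"), seed = seed)
  list(m = ds$ct, ann = ds$annotation,
       gn = genorm(ds$ct), bk = bestkeeper(ds$ct),
       nf = normfinder(ds$ct, ds$annotation))
}

test_that("combined score is the geometric mean of the three ranks", {
  fx <- consensus_fixture()
  cons <- combine_ranks(fx$gn, fx$bk, fx$nf)
  expect_setequal(cons$gene_id, names(fx$gn$m_values))
  # each rank column is a permutation of 1..n up to mean-rank ties
  for (col in c("rank_genorm", "rank_bestkeeper", "rank_normfinder"))
    expect_equal(sum(cons[[col]]), sum(seq_len(nrow(cons))))
  expect_equal(cons$combined_score,
               (cons$rank_genorm * cons$rank_bestkeeper *
                  cons$rank_normfinder)^(1 / 3),
               tolerance = 1e-12)
  expect_false(is.unsorted(cons$combined_score))
  # closed-form check of the combination rule on known ranks
  expect_equal((1 * 2 * 1)^(1 / 3), 1.2599, tolerance = 1e-4)
  expect_equal((2 * 1 * 3)^(1 / 3), 1.8171, tolerance = 1e-4)
  expect_equal((3 * 3 * 2)^(1 / 3), 2.6207, tolerance = 1e-4)

  borda <- combine_ranks(fx$gn, fx$bk, fx$nf, rule = "borda")
  expect_equal(borda$combined_score,
               borda$rank_genorm + borda$rank_bestkeeper +
                 borda$rank_normfinder)
})

test_that("consensus consumes ranks only and rejects mismatched gene sets", {
  fx <- consensus_fixture()
  cons1 <- combine_ranks(fx$gn, fx$bk, fx$nf)
  # monotone transformation of a stability metric leaves the consensus unchanged
  nf2 <- fx$nf
  nf2$stability_value <- exp(3 * nf2$stability_value)
  cons2 <- combine_ranks(fx$gn, fx$bk, nf2)
  expect_identical(cons1$gene_id, cons2$gene_id)
  expect_equal(cons1$combined_score, cons2$combined_score)

  nf3 <- fx$nf
  nf3$stability_value <- nf3$stability_value[-1]
  expect_error(combine_ranks(fx$gn, fx$bk, nf3), "miR-r01")
})

test_that("Kruskal-Wallis per-gene test matches stats::kruskal.test and handles full ties", {
  fx <- consensus_fixture()
  kw <- group_difference_test(fx$m, fx$ann)
  g <- ct_genes(fx$m)[3]
  expect_equal(unname(kw[g]),
               kruskal.test(unclass(fx$m)[g, ], fx$ann$group)$p.value)
  tied <- ct_matrix(matrix(25, 2, 8, dimnames = list(c("a", "b"),
                                                     sprintf("s%d", 1:8))))
  expect_equal(unname(group_difference_test(tied,
                                            factor(rep(c("x", "y"), 4)))),
               c(1, 1))
  expect_error(group_difference_test(fx$m, factor(rep("one", 100))),
               ">= 2 groups")
})

test_that("a 3-cycle group shift is detected with high power", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(1500 + s)
    v <- matrix(rnorm(100, 25, 1), 1, dimnames = list("g", sprintf("s%d", 1:100)))
    v[1, 76:100] <- v[1, 76:100] + 3
    p <- group_difference_test(ct_matrix(v), factor(rep(1:4, each = 25)))
    if (p < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 99L)
})

test_that("the pipeline recovers candidates, errors on missing genes, and reruns identically", {
  scr <- simulate_ct_dataset(sim_preset("screen_discovery"), seed = 31L)
  val <- simulate_ct_dataset(sim_preset("endtoend_validation"), seed = 32L)
  res <- run_ec_pipeline(scr$ct, val$ct, val$annotation)
  expect_true(all(sprintf("miR-s0%d", 1:4) %in% res$candidate_genes))
  expect_length(res$selected_ecs, 4L)
  expect_s3_class(res$consensus, "ec_consensus")
  expect_true(all(res$kw_p >= 0, res$kw_p <= 1))

  dropped <- val$ct[setdiff(ct_genes(val$ct), res$candidate_genes[1]), ]
  expect_error(run_ec_pipeline(scr$ct, dropped, val$annotation),
               paste0("qc_validate.*", res$candidate_genes[1]))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_ec_pipeline(scr$ct, val$ct, val$annotation, out_dir = d1)
  run_ec_pipeline(scr$ct, val$ct, val$annotation, out_dir = d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  expect_setequal(list.files(d1),
                  c("qc_report.csv", "candidates.csv", "genorm.csv",
                    "bestkeeper.csv", "normfinder.csv", "consensus.csv",
                    "config_used.yaml", "log.txt"))
})

test_that("config files round-trip and unknown keys are rejected", {
  cfg <- ec_config(ccc_min = 0.85, k_max = 8, combine_rule = "arithmetic")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_ec_config(cfg, f)
  cfg2 <- read_ec_config(f)
  expect_equal(unclass(cfg)[!vapply(cfg, is.null, TRUE)],
               unclass(cfg2)[!vapply(cfg2, is.null, TRUE)])
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("cc_min: 0.9", bad)
  expect_error(read_ec_config(bad), "unknown config key")
})
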