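three_gene_fixture <- function() {
  vals <- matrix(c(20, 21, 22,
                   25, 26, 27,
                   30, 28, 29), nrow = 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
  ct_matrix(vals)
}

test_that("global mean-centering matches direct arithmetic and cancels per-sample shifts", {
  nm <- global_mean_center(three_gene_fixture())
  expect_equal(unname(nm$global_mean), c(25, 25, 26))
  expect_equal(unname(nm$delta_ct),
               matrix(c(-5, -4, -4, 0, 1, 1, 5, 3, 3), 3, byrow = TRUE))
  expect_equal(unname(colSums(nm$delta_ct)), c(0, 0, 0), tolerance = 1e-9)

  one_gene <- ct_matrix(matrix(25, 1, 3, dimnames = list("g1", c("a", "b", "c"))))
  expect_error(global_mean_center(one_gene), ">= 2 genes")

  m <- random_ct(5, 8, seed = 42)
  shift <- stats::rnorm(8)
  shifted <- ct_matrix(unclass(m) + rep(shift, each = 5))
  expect_equal(global_mean_center(shifted)$delta_ct,
               global_mean_center(m)$delta_ct, tolerance = 1e-12)
})

test_that("two parallel genes center symmetrically about the mean", {
  vals <- matrix(c(20, 22, 24, 23, 25, 27), 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  nm <- global_mean_center(ct_matrix(vals))
  expect_equal(unname(nm$delta_ct[1, ]), rep(-1.5, 3))
  expect_equal(unname(nm$delta_ct[2, ]), rep(1.5, 3))
})

test_that("SD ranking sorts ascending with gene-id tie-break and excludes sparse genes", {
  rk <- sd_ranking(global_mean_center(three_gene_fixture()))
  expect_equal(rk$sd_delta_ct, c(sd(c(-5, -4, -4)), sd(c(0, 1, 1)),
                                 sd(c(5, 3, 3))))
  expect_identical(rk$gene_id, c("g1", "g2", "g3"))   # tie g1/g2 -> gene id
  expect_equal(rk$sd_delta_ct[3], 2 / sqrt(3), tolerance = 1e-12)

  m <- three_gene_fixture()
  vals <- unclass(m); vals["g3", 1:2] <- NA
  rk2 <- sd_ranking(global_mean_center(ct_matrix(vals)))
  expect_identical(attr(rk2, "excluded"), "g3")
  expect_identical(nrow(rk2), 2L)

  # constant-offset gene has zero delta-Ct SD and ranks first
  vals2 <- unclass(three_gene_fixture())
  cm <- colMeans(vals2)
  vals3 <- rbind(vals2, g0 = cm + 2)
  expect_identical(sd_ranking(global_mean_center(ct_matrix(vals3)))$gene_id[1],
                   "g0")
})

test_that("Lin's concordance matches its closed form and is bounded by Pearson r", {
  expect_equal(lin_ccc(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 3, 4)), 2 / 3, tolerance = 1e-12)
  x <- c(-2, -1, 0, 1, 2)
  expect_equal(lin_ccc(x, -x), -1.0)
  expect_error(lin_ccc(c(1, 1, 1), c(1, 1, 1)), "undefined")
  expect_error(lin_ccc(c(1, 2), c(1, 2)), ">= 3")

  set.seed(7)
  for (i in 1:25) {
    a <- rnorm(10); b <- 2 * a + rnorm(10, sd = 0.5) + i / 10
    expect_equal(lin_ccc(a, b), bf_ccc(a, b), tolerance = 1e-12)
    expect_lte(abs(lin_ccc(a, b)), abs(cor(a, b)) + 1e-12)
  }
})

test_that("CCR selection scores genes against the global mean profile", {
  m <- three_gene_fixture()
  vals <- unclass(m)
  # a gene equal to the mean of the others is a fixed point of the global
  # mean over the augmented set, so its concordance is exactly 1
  withmean <- ct_matrix(rbind(vals, gmean = colMeans(vals)))
  cs <- ccr_select(withmean, ccc_min = 0.9, k_max = 10)
  expect_equal(cs$ccc_vs_mean[cs$gene_id == "gmean"], 1.0, tolerance = 1e-9)
  expect_true(cs$selected[cs$gene_id == "gmean"])
  # the same profile with a large constant offset is penalized through the
  # location term of the concordance
  gm4 <- colMeans(rbind(vals, offset = colMeans(vals) + 8))
  expect_lt(lin_ccc(colMeans(vals) + 8, gm4), 0.9)
  cs2 <- suppressWarnings(
    ccr_select(ct_matrix(rbind(vals, offset = colMeans(vals) + 8)),
               ccc_min = 0.9, k_max = 10))
  expect_false(cs2$selected[cs2$gene_id == "offset"])
})

test_that("CCR selection is order-independent and finds planted mean-tracking genes", {
  cfg <- sim_config(50, c(AD = 19L),
                    mu = c(rep(25.5, 3), seq(19, 31, length.out = 47)),
                    sigma = c(rep(0.15, 3), seq(0.7, 1.4, length.out = 47)),
                    tau = 0.8, n_replicates = 1L, replicate_sd = 0,
                    gene_ids = c(sprintf("track%d", 1:3),
                                 sprintf("bg%02d", 1:47)))
  hits <- 0L
  for (s in 1:100) {
    ds <- simulate_ct_dataset(cfg, seed = s)
    cs <- suppressWarnings(ccr_select(ds$ct))
    top3 <- cs$gene_id[order(-cs$ccc_vs_mean)][1:3]
    if (setequal(top3, sprintf("track%d", 1:3))) hits <- hits + 1L
  }
  expect_gte(hits, 95L)

  ds <- simulate_ct_dataset(cfg, seed = 1)
  perm <- sample(ct_genes(ds$ct))
  cs1 <- suppressWarnings(ccr_select(ds$ct))
  cs2 <- suppressWarnings(ccr_select(ds$ct[perm, ]))
  ord <- function(x) x[order(x$gene_id), c("gene_id", "ccc_vs_mean", "selected")]
  expect_equal(ord(as.data.frame(cs1)), ord(as.data.frame(cs2)),
               ignore_attr = TRUE)
})
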