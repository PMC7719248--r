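test_that("descriptive statistics follow their closed forms", {
  vals <- matrix(c(25, 25, 25, 25,
                   20, 30, 20, 30,
                   22, 26, 21, 27), 3, byrow = TRUE,
                 dimnames = list(c("const", "wide", "mid"), sprintf("s%d", 1:4)))
  st <- descriptive_stats(ct_matrix(vals))
  cst <- st[st$gene_id == "const", ]
  expect_equal(cst$geo_mean, 25)
  expect_equal(cst$ar_mean, 25)
  expect_equal(cst$sd, 0)
  expect_equal(cst$cv, 0)
  wide <- st[st$gene_id == "wide", ]
  expect_equal(wide$geo_mean, sqrt(600), tolerance = 1e-12)   # (20*30)^(1/2)
  expect_equal(wide$ar_mean, 25)
  # AM-GM: geometric never exceeds arithmetic, strictly for non-constant genes
  expect_true(all(st$geo_mean <= st$ar_mean + 1e-12))
  expect_lt(wide$geo_mean, wide$ar_mean)
  expect_true(all(st$min <= st$geo_mean + 1e-9 &
                    st$geo_mean <= st$max + 1e-9))

  bad <- ct_matrix(matrix(c(0, 25, 25, 24, 25, 26), 2, byrow = TRUE,
                          dimnames = list(c("z", "k"), c("a", "b", "c"))))
  expect_error(descriptive_stats(bad), "positive")

  mad_st <- descriptive_stats(ct_matrix(vals), var_measure = "mad")
  expect_equal(mad_st$sd[mad_st$gene_id == "wide"], 5)   # mean |x - 25|
})

test_that("BestKeeper index is the per-sample geometric mean of candidates", {
  vals <- matrix(c(20, 20, 20, 30, 30, 30), 2, byrow = TRUE,
                 dimnames = list(c("lo", "hi"), c("s1", "s2", "s3")))
  idx <- bestkeeper_index(ct_matrix(vals))
  expect_equal(unname(idx), rep(sqrt(600), 3), tolerance = 1e-12)

  one <- ct_matrix(matrix(c(21, 23, 25), 1,
                          dimnames = list("g", c("s1", "s2", "s3"))))
  expect_equal(unname(bestkeeper_index(one)), c(21, 23, 25))

  m <- random_ct(5, 8, seed = 9)
  perm <- sample(ct_genes(m))
  expect_equal(bestkeeper_index(m), bestkeeper_index(m[perm, ]))
})

test_that("index correlations give r = 1 for an index-tracking gene and NA for constants", {
  set.seed(13)
  base <- rnorm(10, 25, 1)
  vals <- rbind(track = base, other = base + rnorm(10, sd = 0.2),
                third = base + rnorm(10, sd = 0.3))
  colnames(vals) <- sprintf("s%d", 1:10)
  m <- ct_matrix(vals)
  ic <- index_correlations(m, index = base)
  expect_equal(unname(ic$r["track"]), 1.0, tolerance = 1e-12)
  expect_equal(unname(diag(ic$pairwise_r)), rep(1, 3))
  expect_equal(ic$pairwise_r, t(ic$pairwise_r))

  vals2 <- rbind(vals, flat = rep(25, 10))
  expect_warning(ic2 <- index_correlations(ct_matrix(vals2)),
                 "zero variance")
  expect_true(is.na(ic2$r["flat"]))
})

test_that("a gene independent of the candidate panel correlates weakly with the index", {
  ids <- c(sprintf("core%d", 1:4), "lone")
  cfg <- sim_config(5, c(A = 50L), mu = rep(25, 5),
                    sigma = c(rep(0.2, 4), 1.0), tau = 0.8,
                    n_replicates = 1L, replicate_sd = 0, gene_ids = ids)
  weak <- 0L
  for (s in 1:100) {
    ds <- simulate_ct_dataset(cfg, seed = 400 + s)
    vals <- unclass(ds$ct)
    # remove the shared shift for the lone gene so it is truly independent
    vals["lone", ] <- 25 + rnorm(50, sd = 1.0)
    ic <- index_correlations(ct_matrix(vals))
    if (abs(ic$r["lone"]) < 0.5) weak <- weak + 1L
  }
  expect_gte(weak, 95L)
})

test_that("BestKeeper ranking orders by descending r, flags dispersion, and breaks ties by gene id", {
  set.seed(17)
  base <- rnorm(12, 25, 1)
  vals <- rbind(a = base + rnorm(12, sd = 0.1),
                b = base + rnorm(12, sd = 0.35),
                c = base + rnorm(12, sd = 0.8),
                d = base * 1.5 - 12 + rnorm(12, sd = 0.4))  # sd > 1: flagged
  colnames(vals) <- sprintf("s%d", 1:12)
  fit <- bestkeeper(ct_matrix(vals))
  st <- fit$stats
  expect_true(st$flagged[st$gene_id == "d"])
  expect_true(is.na(st$rank[st$gene_id == "d"]))
  ranked <- bestkeeper_rank(fit)
  expect_identical(ranked, st$gene_id[order(st$rank)][seq_along(ranked)])
  rs <- st$r_vs_index[match(ranked, st$gene_id)]
  expect_true(all(diff(rs) <= 1e-12))

  # identical genes: all r = 1, ordering falls back to gene id
  same <- ct_matrix(matrix(rep(base, 3), 3, byrow = TRUE,
                           dimnames = list(c("z", "y", "x"), sprintf("s%d", 1:12))))
  expect_identical(bestkeeper_rank(bestkeeper(same)), c("x", "y", "z"))
})

test_that("BestKeeper statistics are not shift-invariant, unlike mean-centering", {
  m <- random_ct(4, 10, seed = 23)
  shift <- rnorm(10, sd = 1.5)
  shifted <- ct_matrix(unclass(m) + rep(shift, each = 4))
  st0 <- descriptive_stats(m); st1 <- descriptive_stats(shifted)
  expect_gt(max(abs(st1$sd - st0$sd)), 1e-3)
  expect_gt(max(abs(bestkeeper_index(shifted) - bestkeeper_index(m))), 1e-3)
})

test_that("BestKeeper matches brute-force oracles on small instances", {
  for (seed in 1:12) {
    ng <- 2 + (seed %% 5)
    ns <- 5 + (seed %% 6)
    m <- random_ct(ng, ns, seed = 200 + seed)
    vals <- unclass(m)
    st <- descriptive_stats(m)
    idx <- bestkeeper_index(m)
    for (i in seq_len(ng)) {
      expect_equal(st$geo_mean[i], bf_geo_mean(vals[i, ]), tolerance = 1e-12)
      expect_equal(st$sd[i], bf_sd(vals[i, ]), tolerance = 1e-12)
    }
    for (j in seq_len(ns))
      expect_equal(unname(idx[j]), bf_geo_mean(vals[, j]), tolerance = 1e-12)
    ic <- index_correlations(m, idx)
    for (i in seq_len(ng))
      expect_equal(unname(ic$r[i]), bf_pearson(vals[i, ], idx),
                   tolerance = 1e-12)
  }
})
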