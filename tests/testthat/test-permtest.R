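test_that("null pool is the full group-by-complement distance block", {
  D <- toy_matrix()
  pool <- build_null_pool(D, c("A", "B"), c("C", "D", "E"))
  expect_length(pool$values, 6)
  expect_setequal(pool$values,
                  as.vector(unclass(D)[c("A", "B"), c("C", "D", "E")]))
  both <- build_null_pool(D, c("A", "B"), c("C", "D", "E"),
                          direction = "both")
  expect_length(both$values, 12)
  expect_error(build_null_pool(D, c("A", "B"), c("B", "C")),
               class = "bat_input_error")
  expect_error(build_null_pool(D, character(), "A"),
               class = "bat_input_error")
})

test_that("sample_null_median honours pool degeneracies", {
  expect_equal(sample_null_median(rep(3.5, 10), 4), 3.5)
  # exhaustive draw without replacement is the full-pool median
  expect_equal(sample_null_median(c(1, 2, 3, 4), 4), 2.5)
  expect_error(sample_null_median(c(1, 2), 3), class = "bat_input_error")
  # two-value pool, singleton sets: mean of sampled medians converges to 5
  set.seed(1)
  draws <- vapply(1:4000, function(i) sample_null_median(c(0, 10), 1),
                  numeric(1))
  expect_lt(abs(mean(draws) - 5), 3 * 5 / sqrt(4000))
})

test_that("empirical_p counts ties as extreme and reports all estimators", {
  res <- empirical_p(2, c(1, 2, 2, 3, 4), tail = "le")
  expect_equal(res$n_extreme, 3L)
  expect_equal(res$p_raw, 3 / 5)
  expect_equal(res$p_adj, 4 / 6)
  res_ge <- empirical_p(2, c(1, 2, 2, 3, 4), tail = "ge")
  expect_equal(res_ge$n_extreme, 4L)
  # observed equal to every draw: all ties extreme
  expect_equal(empirical_p(1, rep(1, 10), "le")$p_raw, 1)
  # zero exceedance: p_raw 0, bound string, ci_low 0
  res0 <- empirical_p(4.72, rep(10, 1e4), "le")
  expect_equal(res0$n_extreme, 0L)
  expect_equal(res0$p_raw, 0)
  expect_equal(res0$p_adj, 1 / (1e4 + 1))
  expect_match(res0$p_report, "p < 0.0001", fixed = TRUE)
  expect_equal(res0$ci_low, 0)
  expect_error(empirical_p(1, numeric()), class = "bat_input_error")
})

test_that("Clopper-Pearson interval matches its closed form at zero counts", {
  res <- empirical_p(1, rep(1, 1e6), "le")  # n_extreme = n_perm case
  expect_equal(res$ci_high, 1)
  res0 <- empirical_p(-1, rep(1, 1e6), "le")
  expect_lt(abs(res0$ci_high - (1 - 0.025^(1e-6))), 1e-9)
  # interior case agrees with binom.test
  res_mid <- empirical_p(2, c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), "le")
  bt <- binom.test(2, 10)$conf.int
  expect_equal(c(res_mid$ci_low, res_mid$ci_high), as.numeric(bt))
})

test_that("p-value invariants hold over random permutation results", {
  set.seed(99)
  for (i in 1:25) {
    draws <- rlnorm(sample(5:200, 1))
    obs <- rlnorm(1)
    res <- empirical_p(obs, draws, sample(c("le", "ge"), 1))
    expect_gte(res$p_adj, 1 / (res$n_perm + 1))
    expect_lte(res$p_raw, res$p_adj)
    expect_lte(res$ci_low, max(res$p_raw, res$ci_low))
    expect_gte(res$ci_high, res$p_raw)
    expect_equal(res$p_raw, res$n_extreme / res$n_perm)
  }
})

test_that("p_raw is monotone in the observed statistic under tail le", {
  set.seed(7)
  draws <- rlnorm(500)
  obs <- sort(rlnorm(20))
  p <- vapply(obs, function(o) empirical_p(o, draws, "le")$p_raw,
              numeric(1))
  expect_true(all(diff(p) >= 0))
})

test_that("closeness tests are seed-deterministic and use the right sizes", {
  sim <- simulate_distance_matrix(
    distance_sim_spec(n_genes = 120, module_size = 12, seed = 5))
  D <- sim$D
  grp <- sim$module[1:8]
  r1 <- within_group_closeness_test(D, grp, n_perm = 200, seed = 42,
                                    core = "CORE1")
  r2 <- within_group_closeness_test(D, grp, n_perm = 200, seed = 42,
                                    core = "CORE1")
  expect_identical(r1, r2)
  r3 <- within_group_closeness_test(D, grp, n_perm = 200, seed = 43,
                                    core = "CORE1")
  expect_identical(r1$observed, r3$observed)
  expect_false(identical(r1$n_extreme, r3$n_extreme) &&
                 identical(r1$seed, r3$seed))
  expect_equal(r1$set_sizes$distances, 8 * 7)
  expect_equal(r1$observed,
               median(pair_distances(D, grp, mode = "ordered_within")))
  # planted module sits closer than background, so p_adj is small
  expect_lte(r1$p_adj, 0.05)
})

test_that("cross-group test statistic is the candidate-to-known median", {
  sim <- simulate_distance_matrix(
    distance_sim_spec(n_genes = 150, module_size = 20, seed = 8))
  D <- sim$D
  known <- sim$module[1:10]
  cand <- sim$module[11:20]
  outside <- setdiff(genes(D), c(sim$module, "CORE1"))
  res <- cross_group_closeness_test(D, cand, known, outside,
                                    n_perm = 200, seed = 3, core = "CORE1")
  expect_equal(res$observed,
               median(pair_distances(D, cand, known, mode = "cross")))
  expect_equal(res$set_sizes$distances, 100)
  expect_lte(res$p_adj, 0.05)
  # degenerate single-gene groups: observed is that one distance
  res1 <- cross_group_closeness_test(D, cand[1], known[1], outside,
                                     n_perm = 50, seed = 2)
  expect_equal(res1$observed, D[cand[1], known[1]])
})

test_that("permutation results serialise to well-formed JSON", {
  res <- empirical_p(2, c(1, 2, 3), "le", seed = 7L,
                     set_sizes = list(group = 3))
  json <- permutation_result_json(res, test = "demo")
  parsed <- jsonlite::fromJSON(json)
  expect_equal(parsed$test, "demo")
  expect_equal(parsed$observed, 2)
  expect_equal(parsed$n_extreme, 2)
  expect_equal(parsed$ci95, c(res$ci_low, res$ci_high))
  path <- withr::local_tempfile(fileext = ".json")
  permutation_result_json(res, path)
  expect_equal(jsonlite::fromJSON(path)$p_adj, res$p_adj)
})
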