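test_that("collapse_probes drops ambiguous probes and takes nested medians", {
  s <- toy_study()
  # p1 -> A with sample values (1, 3): probe median 2; p2 maps to two
  # genes and is dropped, so B gets no value; p3 -> C median 5
  summ <- collapse_probes(s)
  expect_equal(as.numeric(summ[c("A", "C")]), c(2, 5))
  expect_false("B" %in% names(summ))
  expect_equal(attr(summ, "study_id"), "toy")
})

test_that("a gene's summary is the median over its probes", {
  vals <- matrix(c(1, 2, 10), 3, 1,
                 dimnames = list(c("p1", "p2", "p3"), "s1"))
  s <- expression_study("x", vals, list(p1 = "G", p2 = "G", p3 = "G"))
  expect_equal(as.numeric(collapse_probes(s)), 2)
  # pooled method takes one median over all probe-sample values, which
  # differs from the nested median when probes have unequal spread
  vals2 <- matrix(c(1, 2, 10, 20), 2, 2, byrow = TRUE,
                  dimnames = list(c("p1", "p2"), c("s1", "s2")))
  s2 <- expression_study("x", vals2, list(p1 = "G", p2 = "G"))
  expect_equal(as.numeric(collapse_probes(s2)), (1.5 + 15) / 2)
  expect_equal(as.numeric(collapse_probes(s2, method = "pooled")), 6)
})

test_that("collapse_probes is invariant to probe and sample order", {
  sim <- simulate_expression_study(
    expression_sim_spec(n_genes = 40, n_probes = 70, n_samples = 4,
                        planted_genes = 5, seed = 21))
  s <- sim$study
  p_ord <- rev(rownames(s$values))
  s_ord <- sample(colnames(s$values))
  shuffled <- expression_study(s$study_id,
                               s$values[p_ord, s_ord],
                               s$probe_map[p_ord])
  expect_equal(collapse_probes(s), collapse_probes(shuffled))
})

test_that("collapse_probes errors when no single-gene probe remains", {
  vals <- matrix(1, 1, 1, dimnames = list("p1", "s1"))
  s <- expression_study("x", vals, list(p1 = c("A", "B")))
  expect_error(collapse_probes(s), class = "bat_input_error")
})

test_that("top set uses the interpolated quantile with a strict cut", {
  v <- as.numeric(1:1000)
  names(v) <- sprintf("g%04d", 1:1000)
  top <- top_expression_set(v, 95)
  expect_length(top, 50)  # threshold 950.05, strictly greater
  expect_setequal(top, sprintf("g%04d", 951:1000))
  # N = 2: h = 1.95 puts the threshold at 9.5
  v2 <- c(lo = 0, hi = 10)
  expect_identical(top_expression_set(v2, 95), "hi")
  # all equal: nothing strictly above the threshold
  expect_length(top_expression_set(c(a = 1, b = 1, c = 1), 95), 0)
  expect_error(top_expression_set(v, 100), class = "bat_input_error")
})

test_that("union membership counts genes in the top of any study", {
  s1 <- structure(c(A = 1, B = 9, C = 2), study_id = "s1",
                  class = "gene_expr_summary")
  s2 <- structure(c(A = 9, B = 1, D = 2), study_id = "s2",
                  class = "gene_expr_summary")
  tops <- make_top_sets(list(s1, s2), percentile = 60)
  expect_setequal(tops$universe, c("A", "B", "C", "D"))
  expect_equal(union_membership_count(tops, c("A", "B")), 2)
  expect_equal(union_membership_count(tops, c("C", "D")), 0)
  expect_equal(union_membership_count(tops, character()), 0)
  # observed never exceeds min(|query|, |union of tops|)
  expect_lte(union_membership_count(tops, c("A", "B", "C", "D")),
             min(4, length(unique(unlist(tops$sets)))))
})

test_that("bundled candidate flags equal the biopsy membership count", {
  lists <- bundled_gene_lists()
  # treat the flag column as the two-biopsy-study top-set union it encodes
  flagged <- names(lists$biopsy_top_flags)[lists$biopsy_top_flags == 1]
  tops <- structure(list(percentile = 95,
                         sets = list(biopsies = flagged),
                         universe = lists$candidates),
                    class = "top_sets")
  expect_equal(union_membership_count(tops, lists$candidates),
               sum(lists$biopsy_top_flags))
})

test_that("enrichment test is deterministic and respects the universe", {
  sim <- simulate_expression_study(
    expression_sim_spec(n_genes = 300, n_probes = 400, planted_genes = 20,
                        seed = 12))
  tops <- make_top_sets(list(collapse_probes(sim$study)))
  query <- intersect(sim$planted, tops$universe)
  r1 <- expression_enrichment_test(query, tops, n_perm = 300, seed = 5)
  r2 <- expression_enrichment_test(query, tops, n_perm = 300, seed = 5)
  expect_identical(r1, r2)
  expect_equal(r1$observed, union_membership_count(tops, query))
  expect_equal(r1$tail, "ge")
  expect_error(expression_enrichment_test(c("NOT_A_GENE"), tops),
               class = "bat_input_error")
})

test_that("single-study null counts follow the hypergeometric law", {
  # small frame so every support point is well populated
  set.seed(2)
  universe <- sprintf("u%03d", 1:200)
  vals <- structure(stats::rnorm(200), names = universe,
                    study_id = "s", class = "gene_expr_summary")
  tops <- make_top_sets(list(vals), percentile = 90)
  K <- length(tops$sets[[1]])
  q <- 30
  query <- sample(universe, q)
  res <- expression_enrichment_test(query, tops, n_perm = 2e4, seed = 77)
  # the sampled exceedance proportion matches the closed-form tail
  p_exact <- stats::phyper(res$observed - 1, K, 200 - K, q,
                           lower.tail = FALSE)
  se <- sqrt(p_exact * (1 - p_exact) / res$n_perm)
  expect_lt(abs(res$p_raw - p_exact), 3 * se + 1e-12)
})

test_that("expression study TSV round trip preserves values and map", {
  sim <- simulate_expression_study(
    expression_sim_spec(n_genes = 20, n_probes = 30, n_samples = 3,
                        planted_genes = 2, seed = 4))
  s <- sim$study
  vp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("probe", colnames(s$values)), collapse = "\t"),
               vapply(rownames(s$values), function(p)
                 paste(c(p, sprintf("%.17g", s$values[p, ])),
                       collapse = "\t"), "")), vp)
  writeLines(c("probe\tgenes",
               vapply(names(s$probe_map), function(p)
                 paste(p, paste(s$probe_map[[p]], collapse = ","),
                       sep = "\t"), "")), mp)
  back <- read_expression_study(vp, mp, "roundtrip")
  expect_equal(back$values, s$values)
  expect_identical(back$probe_map, s$probe_map)
  expect_equal(collapse_probes(back)[names(collapse_probes(s))],
               collapse_probes(s), ignore_attr = TRUE)
})
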