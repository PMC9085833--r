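# Reproducible benchmark drivers over the synthetic generators: type-I
# calibration, power on planted structure, and additive-tree recovery.
# Replicate r of a run with root seed s uses simulation seed s + r and
# test seed s + 100000 + r, so replicates are independent but the whole
# run is reproducible from one integer.

#' Type-I calibration of the within-group closeness test
#'
#' Repeatedly simulates a null distance matrix (module distances drawn
#' from the same distribution as the background, so "module" is an
#' arbitrary label) and runs the within-group closeness test on the
#' labelled module. The null matrices draw every ordered pair
#' independently (`paired_directions = FALSE`): the observed statistic is
#' a median over ordered pairs, so exchangeability with the sampled null
#' sets requires the two directions of a pair to be independent — with
#' mirrored-base matrices the observed median has roughly twice the
#' variance of the null medians and the test is anti-conservative by
#' construction (see the vignette). Under the exchangeable null the
#' adjusted p-value is uniform on its grid, so the rejection rate at
#' level `alpha` should sit near `alpha`.
#'
#' @param n_rep Number of replicates.
#' @param n_perm Permutations per test.
#' @param seed Root seed.
#' @param alpha Nominal level. Default 0.05.
#' @param n_genes,module_size Null matrix dimensions. Defaults 300 / 12,
#'   small enough to repeat hundreds of times.
#' @return List with `p_adj` (vector of length `n_rep`) and `rate`
#'   (fraction with `p_adj <= alpha`).
#' @export
calibrate_within_test <- function(n_rep = 500, n_perm = 2000, seed = 1L,
                                  alpha = 0.05, n_genes = 300,
                                  module_size = 12) {
  p_adj <- vapply(seq_len(n_rep), function(r) {
    sim <- simulate_distance_matrix(distance_sim_spec(
      n_genes = n_genes, module_size = module_size,
      within_mu = log(9), within_sigma = 0.6,
      background_mu = log(9), background_sigma = 0.6,
      paired_directions = FALSE, seed = seed + r))
    within_group_closeness_test(sim$D, sim$module, n_perm = n_perm,
                                seed = seed + 100000L + r,
                                core = "CORE1")$p_adj
  }, numeric(1L))
  list(p_adj = p_adj, rate = mean(p_adj <= alpha))
}

#' Type-I calibration of the expression enrichment test
#'
#' Simulates one unplanted expression study, then repeatedly draws a
#' uniform random query set from the summarised-gene universe and tests
#' it for top-percentile enrichment. The count statistic is discrete, so
#' the attainable level sits below nominal; the default frame (query of
#' 360 from a 2000-gene universe with a 100-gene top set) puts the exact
#' expected rejection rate at 0.042 for `alpha = 0.05` and
#' `n_perm = 2000`, the closest the hypergeometric atoms allow (computed
#' from the closed-form null; see the vignette).
#'
#' @param n_rep,n_perm,seed,alpha As in [calibrate_within_test()].
#' @param n_genes Universe size. Default 2000.
#' @param query_size Genes per random query. Default 360.
#' @return List with `p_adj` and `rate`.
#' @export
calibrate_enrichment_test <- function(n_rep = 500, n_perm = 2000,
                                      seed = 1L, alpha = 0.05,
                                      n_genes = 2000, query_size = 360) {
  sim <- simulate_expression_study(expression_sim_spec(
    n_genes = n_genes, n_probes = round(1.5 * n_genes),
    multi_gene_probe_frac = 0, planted_genes = 1L, planted_shift = 0,
    seed = seed))
  tops <- make_top_sets(list(collapse_probes(sim$study)))
  p_adj <- vapply(seq_len(n_rep), function(r) {
    query <- with_seed(seed + r, sample(tops$universe, query_size))
    expression_enrichment_test(query, tops, n_perm = n_perm,
                               seed = seed + 100000L + r)$p_adj
  }, numeric(1L))
  list(p_adj = p_adj, rate = mean(p_adj <= alpha))
}

#' Power of the within-group test on the default planted module
#'
#' For each seed, simulates a planted-module matrix under the supplied
#' spec arguments (defaulting to the package's standard planted scenario:
#' 2000 genes, a 60-gene module at median distance 4.7 against a
#' background median of 9) and records the within-group closeness
#' p-value.
#'
#' @param n_seeds Number of simulation seeds.
#' @param n_perm Permutations per test.
#' @param seed Root seed.
#' @param alpha Detection threshold on `p_adj`. Default 0.001.
#' @param ... Overrides passed to [distance_sim_spec()].
#' @return List with `p_adj` and `rate` (fraction detected).
#' @export
power_within_test <- function(n_seeds = 100, n_perm = 2000, seed = 1L,
                              alpha = 0.001, ...) {
  p_adj <- vapply(seq_len(n_seeds), function(r) {
    sim <- simulate_distance_matrix(distance_sim_spec(seed = seed + r,
                                                      ...))
    within_group_closeness_test(sim$D, sim$module, n_perm = n_perm,
                                seed = seed + 100000L + r,
                                core = "CORE1")$p_adj
  }, numeric(1L))
  list(p_adj = p_adj, rate = mean(p_adj <= alpha))
}

#' Power of the enrichment test on a planted expression shift
#'
#' For each seed, simulates an expression study whose planted genes are
#' shifted upward (default 6 log-intensity units over a noise sd of 0.5)
#' and tests the planted set for top-percentile enrichment.
#'
#' @param n_seeds,n_perm,seed As in [power_within_test()].
#' @param alpha Detection threshold on `p_adj`. Default 0.01.
#' @param ... Overrides passed to [expression_sim_spec()].
#' @return List with `p_adj` and `rate`.
#' @export
power_enrichment_test <- function(n_seeds = 100, n_perm = 2000, seed = 1L,
                                  alpha = 0.01, ...) {
  p_adj <- vapply(seq_len(n_seeds), function(r) {
    sim <- simulate_expression_study(expression_sim_spec(seed = seed + r,
                                                         ...))
    tops <- make_top_sets(list(collapse_probes(sim$study)))
    query <- intersect(sim$planted, tops$universe)
    expression_enrichment_test(query, tops, n_perm = n_perm,
                               seed = seed + 100000L + r)$p_adj
  }, numeric(1L))
  list(p_adj = p_adj, rate = mean(p_adj <= alpha))
}

#' Additive-metric recovery benchmark for the neighbour-joining tree
#'
#' Draws random binary trees with branch lengths uniform on `[0.1, 2]`,
#' computes their leaf-to-leaf path-length matrices (an additive metric),
#' reconstructs each with [nj_tree()], and reports the Robinson-Foulds
#' distance to the true unrooted topology plus the maximum absolute
#' path-length error. On additive input both should be zero (up to
#' serialisation precision).
#'
#' @param n_trees Number of random trees. Default 50.
#' @param leaves Integer vector of admissible leaf counts; one is drawn
#'   per tree. Default `5:40`.
#' @param seed Root seed.
#' @return Data frame with columns `n_leaves`, `rf`, `path_err`.
#' @export
nj_recovery_benchmark <- function(n_trees = 50, leaves = 5:40, seed = 1L) {
  res <- with_seed(seed, lapply(seq_len(n_trees), function(i) {
    n <- if (length(leaves) == 1L) leaves else sample(leaves, 1L)
    tr <- ape::rtree(n)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
    dm <- stats::cophenetic(tr)
    o <- sort(rownames(dm))
    rec <- nj_tree(gene_dist(dm[o, o]))
    data.frame(n_leaves = n,
               rf = as.numeric(ape::dist.topo(ape::unroot(tr), rec)),
               path_err = max(abs(stats::cophenetic(rec)[o, o] -
                                    dm[o, o])))
  }))
  do.call(rbind, res)
}
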