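#' Build the null pool of distances for a closeness test
#'
#' The null pool is the collection of biological distances between a gene
#' group and a complement set (e.g. known BAT genes versus all other human
#' genes), from which random distance sets are drawn to form the null
#' distribution of the median. By default only the group-to-complement
#' direction is pooled, keeping the null on the same per-pair footing as
#' the observed cross statistic; `direction = "both"` pools both directions
#' of the (possibly asymmetric) matrix.
#'
#' @param D A [gene_dist] object.
#' @param group,complement Non-empty, disjoint gene sets, subsets of
#'   `genes(D)`.
#' @param direction `"one"` (group to complement, default) or `"both"`.
#' @return A `null_pool`: list with `values` (numeric vector of length
#'   `|group| * |complement|`, doubled for `"both"`) and `description`.
#' @export
build_null_pool <- function(D, group, complement,
                            direction = c("one", "both")) {
  direction <- match.arg(direction)
  if (!inherits(D, "gene_dist")) stop_input("D must be a gene_dist")
  if (length(group) == 0L || length(complement) == 0L)
    stop_input("group and complement must be non-empty")
  if (length(intersect(group, complement)) > 0L)
    stop_input("group and complement must be disjoint")
  g <- genes(D)
  if (!all(group %in% g) || !all(complement %in% g))
    stop_input("gene set contains symbols absent from the matrix")
  values <- as.vector(D[group, complement, drop = FALSE])
  if (direction == "both")
    values <- c(values, as.vector(D[complement, group, drop = FALSE]))
  structure(list(
    values = values,
    description = sprintf("%d group x %d complement distances (%s direction)",
                          length(group), length(complement),
                          if (direction == "one") "one" else "both")),
    class = "null_pool")
}

#' Median of one random distance set drawn from a null pool
#'
#' Draws `set_size` distances uniformly from the pool — without replacement
#' within the set by default, mirroring "a random set of distances" — and
#' returns their median. Randomness comes from the current RNG state; seed
#' control belongs to the calling test.
#'
#' @param pool A [build_null_pool()] result, or a bare numeric vector.
#' @param set_size Number of distances per random set.
#' @param replace Sample with replacement within a set? Default `FALSE`.
#' @return The median of the drawn set (a single number).
#' @export
sample_null_median <- function(pool, set_size, replace = FALSE) {
  values <- if (inherits(pool, "null_pool")) pool$values else pool
  if (!is.numeric(values) || length(values) == 0L)
    stop_input("null pool must be a non-empty numeric collection")
  if (set_size < 1L) stop_input("set_size must be >= 1")
  if (!replace && set_size > length(values))
    stop_input("set_size (%d) exceeds pool size (%d) without replacement",
               set_size, length(values))
  stats::median(values[sample.int(length(values), set_size,
                                  replace = replace)])
}

# 95% Clopper-Pearson interval for k extreme draws out of n.
clopper_pearson <- function(k, n, conf = 0.95) {
  a <- (1 - conf) / 2
  low <- if (k == 0L) 0 else stats::qbeta(a, k, n - k + 1)
  high <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(low, high)
}

#' Monte-Carlo p-value from an observed statistic and null draws
#'
#' Computes the permutation p-value as the proportion of null draws at
#' least as extreme as the observed statistic, with ties counting as
#' extreme ("equal or smaller" / "equal or greater"). Three estimates are
#' reported: the raw proportion `n_extreme / n_perm` (the classical
#' estimator), the bias-adjusted `(n_extreme + 1) / (n_perm + 1)` which is
#' never exactly zero, and a display string that renders `p < 1/n_perm`
#' when no null draw reaches the observed value. Uncertainty is a 95\%
#' Clopper-Pearson interval on the exceedance proportion.
#'
#' @param observed Observed statistic (a median distance or a count).
#' @param null_draws Numeric vector of statistics from the null.
#' @param tail `"le"`: extreme means `<= observed` (closeness tests);
#'   `"ge"`: extreme means `>= observed` (enrichment counts).
#' @param seed Seed recorded in the result for provenance (the draws are
#'   assumed already generated); `NA` if not applicable.
#' @param set_sizes Optional named sizes recorded in the result.
#' @return A `permutation_result` with fields `observed`, `n_perm`,
#'   `n_extreme`, `p_raw`, `p_adj`, `p_report`, `ci_low`, `ci_high`,
#'   `tail`, `seed`, `set_sizes`.
#' @export
empirical_p <- function(observed, null_draws, tail = c("le", "ge"),
                        seed = NA_integer_, set_sizes = NULL) {
  tail <- match.arg(tail)
  if (length(null_draws) == 0L) stop_input("no null draws supplied")
  if (!is.finite(observed)) stop_input("observed statistic must be finite")
  n_perm <- length(null_draws)
  n_extreme <- if (tail == "le") sum(null_draws <= observed)
               else sum(null_draws >= observed)
  ci <- clopper_pearson(n_extreme, n_perm)
  p_raw <- n_extreme / n_perm
  structure(list(
    observed = observed,
    n_perm = n_perm,
    n_extreme = as.integer(n_extreme),
    p_raw = p_raw,
    p_adj = (n_extreme + 1) / (n_perm + 1),
    p_report = if (n_extreme == 0L) sprintf("p < %.3g", 1 / n_perm)
               else sprintf("p = %.3g", p_raw),
    ci_low = ci[1L],
    ci_high = ci[2L],
    tail = tail,
    seed = seed,
    set_sizes = set_sizes),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result (tail %s): observed %.6g, %s (adj %.3g), 95%% CI [%.3g, %.3g], %d/%d extreme\n",
    x$tail, x$observed, x$p_report, x$p_adj, x$ci_low, x$ci_high,
    x$n_extreme, x$n_perm))
  invisible(x)
}

#' Serialise a permutation result to JSON
#'
#' @param x A `permutation_result`.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @param test Label stored in the `test` field.
#' @return The JSON string (invisibly when written to `path`).
#' @export
permutation_result_json <- function(x, path = NULL, test = "closeness") {
  if (!inherits(x, "permutation_result"))
    stop_input("x must be a permutation_result")
  obj <- list(test = test, observed = x$observed, n_perm = x$n_perm,
              n_extreme = x$n_extreme, p_raw = x$p_raw, p_adj = x$p_adj,
              p_report = x$p_report, ci95 = c(x$ci_low, x$ci_high),
              tail = x$tail, seed = x$seed, set_sizes = x$set_sizes)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path, useBytes = TRUE)
  invisible(json)
}

# Shared driver: median observed statistic vs sampled null medians.
run_closeness_test <- function(observed, pool, set_size, n_perm, seed,
                               replace, set_sizes, keep_null = FALSE) {
  if (n_perm < 1L) stop_input("n_perm must be >= 1")
  draws <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    sample_null_median(pool, set_size, replace = replace), numeric(1L)))
  res <- empirical_p(observed, draws, tail = "le", seed = seed,
                     set_sizes = set_sizes)
  if (keep_null) res$null_draws <- draws
  res
}

#' Within-group closeness permutation test
#'
#' Tests whether a gene group (e.g. the known BAT genes inside the
#' connectome) is biologically closer to itself than expected: the observed
#' statistic is the median of all ordered within-group distances
#' (`|group| * (|group| - 1)` values), and the null distribution is built
#' from medians of equally sized random sets of distances between the group
#' and other genes. The p-value is the proportion of random sets with a
#' median equal to or smaller than the observed one.
#'
#' @param D A [gene_dist] object.
#' @param group Gene set of size `>= 2`.
#' @param complement Null-pool complement; defaults to every matrix gene
#'   outside `group` (and outside `core`).
#' @param n_perm Number of random sets. Default `1e6` for parity with
#'   full-scale analyses; scale down for interactive work.
#' @param seed Integer seed; identical inputs and seed reproduce the result
#'   bit-exactly.
#' @param core Optional core gene, excluded from the null pool.
#' @param direction Pool direction, see [build_null_pool()].
#' @param replace Sample distances with replacement within a set? Default
#'   `FALSE`.
#' @param keep_null Attach the vector of null medians to the result (as
#'   `null_draws`)? Default `FALSE`.
#' @return A [empirical_p()] `permutation_result`.
#' @export
within_group_closeness_test <- function(D, group, complement = NULL,
                                        n_perm = 1e6, seed = 1L,
                                        core = NULL,
                                        direction = c("one", "both"),
                                        replace = FALSE,
                                        keep_null = FALSE) {
  direction <- match.arg(direction)
  if (length(group) < 2L) stop_input("group must contain at least 2 genes")
  if (is.null(complement))
    complement <- setdiff(genes(D), c(group, core))
  else
    complement <- setdiff(complement, c(core, group))
  observed <- stats::median(pair_distances(D, group, mode = "ordered_within"))
  pool <- build_null_pool(D, group, complement, direction = direction)
  set_size <- length(group) * (length(group) - 1L)
  run_closeness_test(observed, pool, set_size, n_perm, seed, replace,
                     set_sizes = list(group = length(group),
                                      complement = length(complement),
                                      distances = set_size),
                     keep_null = keep_null)
}

#' Cross-group closeness permutation test
#'
#' Tests whether candidate genes are biologically closer to the known genes
#' than random genes outside the connectome are: the observed statistic is
#' the median of the `|candidates| * |known|` candidate-to-known distances,
#' and the null medians come from equally sized random sets of
#' known-to-outside distances.
#'
#' @param D A [gene_dist] object.
#' @param candidates,known Non-empty disjoint gene sets inside the
#'   connectome.
#' @param outside Genes outside the connectome forming the null pool
#'   complement; defaults to all matrix genes not in `candidates`, `known`
#'   or `core`.
#' @param n_perm,seed,core,direction,replace As in
#'   [within_group_closeness_test()].
#' @param observed_direction Direction of the observed cross statistic:
#'   `"candidates_to_known"` (default), `"known_to_candidates"`, or
#'   `"average"` of both.
#' @param keep_null Attach the vector of null medians to the result?
#' @return A `permutation_result`.
#' @export
cross_group_closeness_test <- function(D, candidates, known, outside = NULL,
                                       n_perm = 1e6, seed = 1L, core = NULL,
                                       direction = c("one", "both"),
                                       observed_direction =
                                         c("candidates_to_known",
                                           "known_to_candidates",
                                           "average"),
                                       replace = FALSE,
                                       keep_null = FALSE) {
  direction <- match.arg(direction)
  observed_direction <- match.arg(observed_direction)
  if (length(candidates) == 0L || length(known) == 0L)
    stop_input("candidates and known must be non-empty")
  if (is.null(outside))
    outside <- setdiff(genes(D), c(candidates, known, core))
  else
    outside <- setdiff(outside, c(candidates, known, core))
  d_ck <- pair_distances(D, candidates, known, mode = "cross")
  observed <- switch(observed_direction,
    candidates_to_known = stats::median(d_ck),
    known_to_candidates = stats::median(
      pair_distances(D, known, candidates, mode = "cross")),
    average = stats::median(c(d_ck,
      pair_distances(D, known, candidates, mode = "cross"))))
  pool <- build_null_pool(D, known, outside, direction = direction)
  set_size <- length(candidates) * length(known)
  run_closeness_test(observed, pool, set_size, n_perm, seed, replace,
                     set_sizes = list(candidates = length(candidates),
                                      known = length(known),
                                      outside = length(outside),
                                      distances = set_size),
                     keep_null = keep_null)
}
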