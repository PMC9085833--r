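#' A processed microarray expression study
#'
#' Bundles a probe-by-sample matrix of processed log-intensities with the
#' probe-to-gene annotation map. Probes may map to zero genes (unannotated)
#' or to several genes (ambiguous); those are handled downstream by
#' [collapse_probes()].
#'
#' @param study_id Study label.
#' @param values Numeric matrix, rows = probes (unique rownames), columns =
#'   samples (`>= 1`), all values finite.
#' @param probe_map Named list, probe -> character vector of gene symbols;
#'   names must match `rownames(values)`.
#' @return An `expression_study` object.
#' @export
expression_study <- function(study_id, values, probe_map) {
  if (!is.matrix(values) || !is.numeric(values) || ncol(values) < 1L)
    stop_input("values must be a numeric matrix with >= 1 sample")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop_format("probe IDs must be unique rownames of the value matrix")
  if (any(!is.finite(values)))
    stop_format("non-finite expression value in study %s", study_id)
  if (!is.list(probe_map) ||
      !setequal(names(probe_map), rownames(values)))
    stop_format("probe_map must cover exactly the probes of the matrix")
  probe_map <- probe_map[rownames(values)]
  structure(list(study_id = as.character(study_id), values = values,
                 probe_map = probe_map),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study %s: %d probes x %d samples\n",
              x$study_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read an expression study from TSV files
#'
#' The value matrix is a TSV whose first column is the probe ID and whose
#' remaining columns are samples. The probe map is a two-column TSV
#' (`probe` TAB comma-separated gene symbols; an empty second field means
#' an unannotated probe).
#'
#' @param values_path Path to the probe x sample TSV.
#' @param map_path Path to the probe-map TSV.
#' @param study_id Study label.
#' @return An [expression_study] object.
#' @export
read_expression_study <- function(values_path, map_path, study_id) {
  df <- utils::read.table(values_path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  probes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- probes
  map_df <- utils::read.table(map_path, sep = "\t", header = TRUE,
                              quote = "", comment.char = "",
                              stringsAsFactors = FALSE,
                              colClasses = "character")
  map <- lapply(map_df[[2L]], function(s) {
    g <- trimws(strsplit(s, ",", fixed = TRUE)[[1L]])
    g[nzchar(g)]
  })
  names(map) <- as.character(map_df[[1L]])
  expression_study(study_id, m, map)
}

#' Collapse probe-level expression to one value per gene
#'
#' Probes annotated to several genes cannot be unambiguously assigned and
#' are removed, as are unannotated probes. Each remaining probe is
#' summarised by its median across samples, and each gene by the median of
#' its probes' summaries (`method = "two_stage"`, the default).
#' `method = "pooled"` instead takes a single median over all probe-sample
#' values of the gene.
#'
#' @param study An [expression_study].
#' @param method `"two_stage"` or `"pooled"`.
#' @return A `gene_expr_summary`: named numeric vector (genes sorted
#'   alphabetically) with attribute `study_id`.
#' @export
collapse_probes <- function(study, method = c("two_stage", "pooled")) {
  method <- match.arg(method)
  if (!inherits(study, "expression_study"))
    stop_input("study must be an expression_study")
  n_genes_per_probe <- lengths(study$probe_map)
  keep <- n_genes_per_probe == 1L
  if (!any(keep))
    stop_input("no single-gene probes remain in study %s", study$study_id)
  vals <- study$values[keep, , drop = FALSE]
  gene_of <- unlist(study$probe_map[keep], use.names = FALSE)
  out <- if (method == "two_stage") {
    probe_med <- apply(vals, 1L, stats::median)
    vapply(split(probe_med, gene_of), stats::median, numeric(1L))
  } else {
    vapply(split(seq_along(gene_of), gene_of), function(ix)
      stats::median(as.vector(vals[ix, , drop = FALSE])), numeric(1L))
  }
  out <- out[order(names(out))]
  structure(out, study_id = study$study_id, class = "gene_expr_summary")
}

#' Genes above an expression percentile
#'
#' The threshold is the linear-interpolation quantile of the summarised
#' values (order statistic position `h = (N - 1) p + 1`, R's type-7
#' default); genes strictly above the threshold form the top set. With all
#' values equal the set is empty, since nothing exceeds the threshold.
#'
#' @param summary A [collapse_probes()] result (or named numeric vector).
#' @param percentile Percentile in `(0, 100)`; default 95.
#' @return Character vector of gene symbols.
#' @export
top_expression_set <- function(summary, percentile = 95) {
  if (length(summary) == 0L) stop_input("empty expression summary")
  if (percentile <= 0 || percentile >= 100)
    stop_input("percentile must lie in (0, 100)")
  thr <- stats::quantile(as.numeric(summary), percentile / 100,
                         type = 7, names = FALSE)
  names(summary)[as.numeric(summary) > thr]
}

#' Per-study top-expression sets over a shared gene universe
#'
#' @param summaries List of [collapse_probes()] results (one per study).
#' @param percentile Percentile passed to [top_expression_set()].
#' @return A `top_sets`: list with `percentile`, `sets` (named per-study
#'   gene sets) and `universe` (sorted union of all summarised genes).
#' @export
make_top_sets <- function(summaries, percentile = 95) {
  if (length(summaries) == 0L) stop_input("no studies supplied")
  ids <- vapply(summaries, function(s) {
    id <- attr(s, "study_id")
    if (is.null(id)) NA_character_ else id
  }, "")
  if (any(is.na(ids))) ids[is.na(ids)] <- paste0("study", which(is.na(ids)))
  sets <- lapply(summaries, top_expression_set, percentile = percentile)
  names(sets) <- ids
  structure(list(percentile = percentile, sets = sets,
                 universe = sort(unique(unlist(lapply(summaries, names))))),
            class = "top_sets")
}

#' Count query genes in the top of expression of any study
#'
#' @param tops A [make_top_sets()] object.
#' @param query Gene set.
#' @return Integer: `|query` intersected with the union of the per-study
#'   top sets`|`.
#' @export
union_membership_count <- function(tops, query) {
  if (!inherits(tops, "top_sets")) stop_input("tops must be a top_sets")
  length(intersect(unique(query), unique(unlist(tops$sets))))
}

#' Top-percentile expression enrichment permutation test
#'
#' Tests whether a query gene set (e.g. the BAT connectome) contains more
#' genes in the top of expression of any study than random gene sets of
#' the same size drawn from the universe of summarised genes. The p-value
#' is the proportion of random sets with a count equal to or greater than
#' the observed one.
#'
#' @param query Gene set; must be contained in `universe`.
#' @param tops A [make_top_sets()] object.
#' @param universe Resampling universe; defaults to `tops$universe` (the
#'   genes that have an expression summary, not the whole genome).
#' @param n_perm Number of random sets. Default `1e6` for full-scale runs.
#' @param seed Integer seed.
#' @param keep_null Attach the vector of null counts to the result (as
#'   `null_draws`) for diagnostics? Default `FALSE`.
#' @return A `permutation_result` with `tail = "ge"`.
#' @export
expression_enrichment_test <- function(query, tops, universe = NULL,
                                       n_perm = 1e6, seed = 1L,
                                       keep_null = FALSE) {
  if (!inherits(tops, "top_sets")) stop_input("tops must be a top_sets")
  if (is.null(universe)) universe <- tops$universe
  query <- unique(query)
  if (!all(query %in% universe))
    stop_input("query contains %d gene(s) outside the universe",
               sum(!query %in% universe))
  if (n_perm < 1L) stop_input("n_perm must be >= 1")
  observed <- union_membership_count(tops, query)
  in_top <- universe %in% unlist(tops$sets)
  n_univ <- length(universe)
  q <- length(query)
  draws <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    sum(in_top[sample.int(n_univ, q)]), numeric(1L)))
  res <- empirical_p(observed, draws, tail = "ge", seed = seed,
                     set_sizes = list(query = q, universe = n_univ,
                                      union_top = sum(in_top)))
  if (keep_null) res$null_draws <- draws
  res
}
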