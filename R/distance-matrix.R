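#' Gene-labelled biological distance matrix
#'
#' Construct a `gene_dist` object: a square numeric matrix of non-negative
#' biological distances (dimensionless human-gene-connectome units) between
#' gene pairs. The matrix may be asymmetric — HGC distances are directed
#' shortest paths — and the diagonal is implicitly zero.
#'
#' @param m Square numeric matrix with identical, unique, non-empty row and
#'   column names (gene symbols). All off-diagonal entries must be finite
#'   and `>= 0`.
#' @return A `gene_dist` object (a classed numeric matrix).
#' @examples
#' m <- matrix(1, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' diag(m) <- 0
#' gene_dist(m)
#' @export
gene_dist <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m))
    stop_input("distance matrix must be a square numeric matrix")
  genes <- rownames(m)
  if (is.null(genes) || is.null(colnames(m)) || !identical(genes, colnames(m)))
    stop_format("row and column gene labels must be present and identical")
  genes <- trimws(genes)
  if (any(!nzchar(genes)))
    stop_format("empty gene symbol in distance matrix labels")
  if (anyDuplicated(genes))
    stop_format("duplicate gene symbol: %s",
                paste(unique(genes[duplicated(genes)]), collapse = ", "))
  dimnames(m) <- list(genes, genes)
  diag(m) <- 0
  if (any(!is.finite(m)))
    stop_format("non-finite distance value")
  if (any(m < 0))
    stop_format("negative distance value")
  structure(m, class = c("gene_dist", class(m)))
}

#' @export
print.gene_dist <- function(x, ...) {
  cat(sprintf("gene_dist: %d genes, %s\n", nrow(x),
              if (is_symmetric_dist(x)) "symmetric" else "asymmetric"))
  invisible(x)
}

#' Gene symbols of a distance matrix
#' @param x A `gene_dist` object.
#' @return Character vector of gene symbols, in matrix order.
#' @export
genes <- function(x) UseMethod("genes")

#' @export
genes.gene_dist <- function(x) rownames(x)

is_symmetric_dist <- function(x, tol = 1e-12) {
  max(abs(x - t(x))) <= tol
}

#' Read a distance matrix from TSV
#'
#' Two dialects are supported. `square`: a TSV whose header row and first
#' column carry the gene symbols, with the full matrix of distances in the
#' body. `long`: three columns `gene_a`, `gene_b`, `distance`, one ordered
#' pair per row; pairs present in only one direction are mirrored to create
#' the missing direction, so a symmetric matrix can be stored once.
#'
#' @param path Path to the TSV file (UTF-8, `.` decimal separator).
#' @param dialect `"square"` or `"long"`.
#' @return A [gene_dist] object.
#' @seealso [write_distance_matrix()]
#' @export
read_distance_matrix <- function(path, dialect = c("square", "long")) {
  dialect <- match.arg(dialect)
  if (dialect == "square") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, quote = "",
                            comment.char = "", stringsAsFactors = FALSE)
    syms <- trimws(as.character(df[[1L]]))
    if (anyDuplicated(syms))
      stop_format("duplicate gene symbol in %s", path)
    body <- df[, -1L, drop = FALSE]
    m <- suppressWarnings(as.matrix(vapply(body, as.numeric,
                                           numeric(nrow(body)))))
    if (nrow(body) == 1L) m <- matrix(m, nrow = 1L)
    if (any(is.na(m)))
      stop_format("non-numeric distance in %s", path)
    rownames(m) <- syms
    colnames(m) <- trimws(colnames(body))
    if (!identical(rownames(m), colnames(m)))
      stop_format("header and first-column gene symbols differ in %s", path)
    return(gene_dist(m))
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"))
  if (!all(c("gene_a", "gene_b", "distance") %in% names(df)))
    stop_format("long dialect needs columns gene_a, gene_b, distance (%s)",
                path)
  a <- trimws(df$gene_a); b <- trimws(df$gene_b); d <- df$distance
  if (any(is.na(d))) stop_format("non-numeric distance in %s", path)
  if (any(d < 0)) stop_format("negative distance in %s", path)
  if (anyDuplicated(paste0(a, "\r", b)))
    stop_format("duplicate ordered pair in %s", path)
  syms <- sort(unique(c(a, b)))
  m <- matrix(NA_real_, length(syms), length(syms),
              dimnames = list(syms, syms))
  m[cbind(a, b)] <- d
  # mirror pairs listed in one direction only
  miss <- is.na(m) & !is.na(t(m))
  m[miss] <- t(m)[miss]
  diag(m) <- 0
  if (any(is.na(m)))
    stop_format("missing gene pair(s) after mirroring in %s", path,
                class = "bat_completeness_error")
  gene_dist(m)
}

#' Write a distance matrix to TSV
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces every distance bit-exactly in both dialects.
#'
#' @param D A [gene_dist] object.
#' @param path Output path.
#' @param dialect `"square"` or `"long"` (long writes every ordered pair).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path, dialect = c("square", "long")) {
  dialect <- match.arg(dialect)
  g <- genes(D)
  fmt <- function(x) sprintf("%.17g", x)
  if (dialect == "square") {
    lines <- c(paste(c("gene", g), collapse = "\t"),
               vapply(seq_along(g), function(i)
                 paste(c(g[i], fmt(D[i, ])), collapse = "\t"), ""))
  } else {
    ij <- which(row(D) != col(D), arr.ind = TRUE)
    ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
    lines <- c("gene_a\tgene_b\tdistance",
               paste(g[ij[, 1L]], g[ij[, 2L]], fmt(D[ij]), sep = "\t"))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
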