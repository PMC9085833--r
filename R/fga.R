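#' Symmetrize an asymmetric distance matrix
#'
#' Neighbour joining needs a symmetric dissimilarity, but directed
#' biological distances need not satisfy `d(a,b) = d(b,a)`. This replaces
#' each ordered pair by the arithmetic mean of the two directions, an
#' unbiased, gene-order-independent choice; it is the identity on symmetric
#' input.
#'
#' @param D A [gene_dist] object.
#' @return A symmetric [gene_dist].
#' @export
symmetrize <- function(D) {
  if (!inherits(D, "gene_dist")) stop_input("D must be a gene_dist")
  gene_dist((unclass(D) + t(unclass(D))) / 2)
}

# Tie-break key order for candidate join pairs: lexicographic on the sorted
# (smallest-descendant-label) pair.
pick_join_pair <- function(Q, labels) {
  idx <- which(Q == min(Q), arr.ind = TRUE)
  idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
  lo <- pmin(labels[idx[, 1L]], labels[idx[, 2L]])
  hi <- pmax(labels[idx[, 1L]], labels[idx[, 2L]])
  idx[order(lo, hi)[1L], ]
}

clamp_pair <- function(li, lj, clamp) {
  if (clamp) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
  }
  c(li, lj)
}

fmt_bl <- function(x) sprintf("%.15g", x)

#' Functional genomic alignment tree by neighbour joining
#'
#' Builds the unrooted binary tree that clusters connectome genes by their
#' functional biological distances (the functional genomic alignment, FGA).
#' This is the classical Saitou-Nei agglomeration: at each step the pair
#' minimising `Q(i,j) = (r - 2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is
#' joined, with limb lengths from the standard formulas. Ties in `Q` are
#' broken deterministically by the lexicographically smallest joined pair,
#' children are ordered canonically (by smallest descendant label) before
#' serialisation, and negative limb lengths are by default clamped to zero
#' with the deficit moved to the sibling branch. The result groups genes by
#' functional proximity; it carries no evolutionary meaning.
#'
#' @param D_sym A symmetric [gene_dist] (see [symmetrize()]).
#' @param tree_genes Optional subset of genes to build the tree over;
#'   default all genes of `D_sym`. At least 3 genes are required.
#' @param clamp_negative Clamp negative branch lengths to zero? Default
#'   `TRUE`.
#' @return An [ape::read.tree()] `phylo` object (unrooted; `n - 2` internal
#'   nodes for `n` leaves).
#' @examples
#' m <- matrix(2, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' diag(m) <- 0
#' nj_tree(gene_dist(m))  # three branches of length 1
#' @export
nj_tree <- function(D_sym, tree_genes = NULL, clamp_negative = TRUE) {
  if (!inherits(D_sym, "gene_dist")) stop_input("D_sym must be a gene_dist")
  if (!is_symmetric_dist(D_sym, tol = 1e-9))
    stop_input("nj_tree requires a symmetric matrix; see symmetrize()")
  if (is.null(tree_genes)) tree_genes <- genes(D_sym)
  if (!all(tree_genes %in% genes(D_sym)))
    stop_input("tree_genes contains symbols absent from the matrix")
  n <- length(tree_genes)
  if (n < 3L) stop_input("neighbour joining needs at least 3 genes")
  dm <- unclass(D_sym)[tree_genes, tree_genes]
  labels <- tree_genes      # smallest descendant leaf per active node
  nwk <- tree_genes         # newick fragment per active node
  while (nrow(dm) > 3L) {
    m <- nrow(dm)
    r <- rowSums(dm)
    Q <- (m - 2) * dm - outer(r, r, `+`)
    diag(Q) <- Inf
    ij <- pick_join_pair(Q, labels)
    i <- ij[1L]; j <- ij[2L]
    li <- dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dm[i, j] - li
    ll <- clamp_pair(li, lj, clamp_negative)
    children <- order(c(labels[i], labels[j]))
    parts <- c(sprintf("%s:%s", nwk[i], fmt_bl(ll[1L])),
               sprintf("%s:%s", nwk[j], fmt_bl(ll[2L])))[children]
    new_nwk <- sprintf("(%s)", paste(parts, collapse = ","))
    new_lab <- min(labels[i], labels[j])
    du <- (dm[i, ] + dm[j, ] - dm[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    labels <- c(labels[keep], new_lab)
    nwk <- c(nwk[keep], new_nwk)
  }
  # final three lineages meet at the unrooted tree's trifurcation
  la <- (dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2
  lb <- (dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2
  lc <- (dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2
  lens <- c(la, lb, lc)
  if (clamp_negative) lens <- pmax(lens, 0)
  ord <- order(labels)
  newick <- sprintf("(%s);", paste(sprintf("%s:%s", nwk[ord],
                                           fmt_bl(lens[ord])),
                                   collapse = ","))
  ape::read.tree(text = newick)
}

#' Write an FGA tree to a Newick file
#'
#' @param tree A `phylo` object from [nj_tree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fga_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Leaf-annotation table for external tree plotting
#'
#' Emits one row per connectome gene with its class (`core`, `known` or
#' `candidate`), the conventional colouring of FGA fan plots.
#'
#' @param partition A [partition_connectome()] result.
#' @param path Optional TSV output path.
#' @return A data frame with columns `gene` and `class` (written to `path`
#'   when given).
#' @export
fga_annotation <- function(partition, path = NULL) {
  if (!inherits(partition, "gene_partition"))
    stop_input("partition must be a gene_partition")
  df <- data.frame(
    gene = c(partition$core, partition$known, partition$candidates),
    class = c("core", rep("known", length(partition$known)),
              rep("candidate", length(partition$candidates))),
    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  df
}
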