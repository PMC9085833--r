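# Small deterministic fixtures shared across test files.

toy_genes <- c("A", "B", "C", "D", "E")

# Asymmetric 5-gene matrix with hand-set values; d(X,Y) = base + 0.1 for
# the "forward" direction so asymmetry is visible everywhere.
toy_matrix <- function() {
  n <- length(toy_genes)
  m <- matrix(0, n, n, dimnames = list(toy_genes, toy_genes))
  base <- outer(seq_len(n), seq_len(n), function(i, j) abs(i - j) + 1)
  m[] <- base + 0.1 * (row(m) < col(m))
  diag(m) <- 0
  gene_dist(m)
}

# Cophenetic matrix of a random binary tree with branch lengths in
# [0.1, 2]: an additive metric whose true topology is known.
additive_case <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
  dm <- stats::cophenetic(tr)
  o <- sort(rownames(dm))
  list(tree = tr, D = gene_dist(dm[o, o]))
}

# A tiny expression study built by hand (3 probes, 2 samples).
toy_study <- function() {
  vals <- matrix(c(1, 3, 9, 9, 5, 5), nrow = 3, byrow = TRUE,
                 dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  expression_study("toy", vals,
                   list(p1 = "A", p2 = c("A", "B"), p3 = "C"))
}
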