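test_that("square and long TSV dialects round-trip bit-exactly", {
  D <- toy_matrix()
  for (dialect in c("square", "long")) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_distance_matrix(D, path, dialect = dialect)
    D2 <- read_distance_matrix(path, dialect = dialect)
    expect_identical(unclass(D2)[genes(D), genes(D)], unclass(D))
  }
})

test_that("long dialect mirrors one-directional pairs and keeps asymmetry", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tdistance", "a\tb\t2.0"), path)
  D <- read_distance_matrix(path, dialect = "long")
  expect_equal(D["a", "b"], 2)
  expect_equal(D["b", "a"], 2)

  writeLines(c("gene_a\tgene_b\tdistance", "a\tb\t1.0", "b\ta\t3.0"), path)
  D <- read_distance_matrix(path, dialect = "long")
  expect_equal(D["a", "b"], 1)
  expect_equal(D["b", "a"], 3)
})

test_that("malformed distance files raise format errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ta\ta", "a\t0\t1", "a\t1\t0"), path)
  expect_error(read_distance_matrix(path, "square"),
               class = "bat_format_error")
  writeLines(c("gene\ta\tb", "a\t0\tx", "b\t1\t0"), path)
  expect_error(read_distance_matrix(path, "square"),
               class = "bat_format_error")
  writeLines(c("gene_a\tgene_b\tdistance", "a\tb\t-1"), path)
  expect_error(read_distance_matrix(path, "long"),
               class = "bat_format_error")
  # three genes but only one pair: incomplete after mirroring
  writeLines(c("gene_a\tgene_b\tdistance", "a\tb\t1", "a\tc\t2"), path)
  expect_error(read_distance_matrix(path, "long"),
               class = "bat_completeness_error")
})

test_that("core ranking orders by p-value with deterministic tie-breaks", {
  rk <- core_ranking("U", c("b", "a", "c"), c(2, 5, 2), c(0.2, 0.2, 0.2))
  # equal p-values: ascending distance, then gene symbol
  expect_identical(rk$gene, c("U", "b", "c", "a"))
  expect_identical(rk$rank, 1:4)
  expect_equal(rk$distance[1], 0)
  expect_equal(rk$p_value[1], 0)
})

test_that("extract_connectome keeps ceiling(fraction * N) genes", {
  set.seed(11)
  n <- 500
  p <- sample(seq_len(n)) / n
  rk <- core_ranking("U", sprintf("g%03d", seq_len(n - 1)),
                     distance = p[-1] * 10, p_value = p[-1])
  got <- extract_connectome(rk, 0.01)
  expect_length(got, ceiling(0.01 * n))
  # brute-force oracle: core plus the smallest p-values
  df <- rk[order(rk$p_value), ]
  expect_setequal(got, df$gene[seq_len(ceiling(0.01 * n))])
  # identity case and ceiling behaviour across fractions
  expect_length(extract_connectome(rk, 1), n)
  for (f in c(0.003, 0.2, 0.5))
    expect_length(extract_connectome(rk, f), ceiling(f * n))
  expect_error(extract_connectome(rk, 0), class = "bat_input_error")
})

test_that("partition_connectome splits into disjoint known and candidates", {
  conn <- c("U", "a", "b", "c", "d")
  p <- partition_connectome(conn, c("b", "d", "zzz"), "U")
  expect_identical(p$known, c("b", "d"))
  expect_identical(p$candidates, c("a", "c"))
  expect_length(intersect(p$known, p$candidates), 0)
  expect_false("U" %in% c(p$known, p$candidates))
  # disjoint known list; degenerate single-gene connectome
  p2 <- partition_connectome(conn, "nope", "U")
  expect_length(p2$known, 0)
  expect_setequal(p2$candidates, c("a", "b", "c", "d"))
  p3 <- partition_connectome("U", character(), "U")
  expect_length(p3$known, 0)
  expect_length(p3$candidates, 0)
  expect_error(partition_connectome(c("a", "b"), "a", "U"),
               class = "bat_input_error")
})

test_that("pair_distances matches explicit double-loop enumeration", {
  D <- toy_matrix()
  for (A in list(c("A", "B"), c("B", "D", "E"), toy_genes)) {
    got <- pair_distances(D, A, mode = "ordered_within")
    expect_length(got, length(A) * (length(A) - 1))
    manual <- c()
    for (a in A) for (b in A) if (a != b) manual <- c(manual, D[a, b])
    expect_setequal(got, manual)
  }
  A <- c("A", "C"); B <- c("B", "D", "E")
  got <- pair_distances(D, A, B, mode = "cross")
  expect_length(got, length(A) * length(B))
  manual <- as.vector(sapply(B, function(b) sapply(A, function(a) D[a, b])))
  expect_equal(got, manual)
  # two-gene ordered case covers both directions of an asymmetric pair
  expect_setequal(pair_distances(D, c("A", "B"), mode = "ordered_within"),
                  c(D["A", "B"], D["B", "A"]))
})

test_that("cross pair multiset is direction-invariant on symmetric input", {
  D <- symmetrize(toy_matrix())
  a <- c("A", "B"); b <- c("C", "E")
  expect_setequal(pair_distances(D, a, b, "cross"),
                  pair_distances(D, b, a, "cross"))
})

test_that("pair_distances enforces its preconditions", {
  D <- toy_matrix()
  expect_error(pair_distances(D, "A", mode = "ordered_within"),
               class = "bat_input_error")
  expect_error(pair_distances(D, c("A", "B"), c("B", "C"), "cross"),
               class = "bat_input_error")
  expect_error(pair_distances(D, c("A", "ZZ"), mode = "ordered_within"),
               class = "bat_input_error")
})

test_that("gene lists are read with comments stripped and dropped symbols warned", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# header", "A", "  B ", "", "ZZZ"), path)
  gl <- read_gene_list(path)
  expect_identical(gl, c("A", "B", "ZZZ"))
  expect_warning(kept <- batconnectome:::match_genes(gl, toy_genes),
                 "absent from the matrix")
  expect_identical(kept, c("A", "B"))
})
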