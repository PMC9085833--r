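#' Specification for a planted-module synthetic distance matrix
#'
#' Describes a random asymmetric non-negative distance matrix with a
#' low-distance module planted around a core gene, emulating the structure
#' a real gene connectome shows: genes of one pathway sit at small mutual
#' biological distances against a larger background. Distances are
#' log-normal — non-negative, right-skewed, as expected for sums of
#' positive edge weights along network paths — with defaults placing the
#' within-module median near 4.7 and the background median near 9, the
#' scale observed for real connectome distances. Directional noise makes
#' the matrix asymmetric, as directed network distances are.
#'
#' @param n_genes Total genes including the core. Default 2000.
#' @param module_size Planted module size, excluding the core. Default 60.
#' @param core Core gene symbol. Default `"CORE1"`.
#' @param within_mu,within_sigma Log-scale mean/sd for module-module and
#'   core-module distances. Defaults `log(4.7)` and `0.6`.
#' @param background_mu,background_sigma Log-scale mean/sd for all other
#'   pairs. Defaults `log(9)` and `0.6`.
#' @param asymmetry_sd Sd of the additive per-direction Gaussian noise
#'   (0 gives a symmetric matrix). Default 0.3.
#' @param paired_directions If `TRUE` (default) the two directions of a
#'   pair share one base draw plus direction noise, as real directed
#'   network distances do; if `FALSE` every ordered pair is an independent
#'   log-normal draw, which makes all off-diagonal entries exchangeable —
#'   the null used for calibration studies of the ordered-pair median
#'   statistic (see the package vignette).
#' @param seed Integer seed.
#' @return A `distance_sim_spec` list.
#' @export
distance_sim_spec <- function(n_genes = 2000L, module_size = 60L,
                              core = "CORE1",
                              within_mu = log(4.7), within_sigma = 0.6,
                              background_mu = log(9),
                              background_sigma = 0.6,
                              asymmetry_sd = 0.3,
                              paired_directions = TRUE, seed = 1L) {
  if (n_genes < 3L) stop_input("n_genes must be >= 3")
  if (module_size < 1L || module_size >= n_genes)
    stop_input("module_size must satisfy 1 <= module_size < n_genes")
  if (within_sigma < 0 || background_sigma < 0 || asymmetry_sd < 0)
    stop_input("sigmas must be >= 0")
  structure(list(n_genes = as.integer(n_genes),
                 module_size = as.integer(module_size),
                 core = core, within_mu = within_mu,
                 within_sigma = within_sigma,
                 background_mu = background_mu,
                 background_sigma = background_sigma,
                 asymmetry_sd = asymmetry_sd,
                 paired_directions = isTRUE(paired_directions),
                 seed = as.integer(seed)),
            class = "distance_sim_spec")
}

#' Simulate a planted-module distance matrix
#'
#' Draws one symmetric log-normal base distance per unordered gene pair —
#' from the within-module distribution when both endpoints belong to the
#' planted module (or are the core), from the background distribution
#' otherwise — then adds independent Gaussian direction noise to each
#' ordered pair and truncates at zero. Identical spec and seed reproduce
#' the matrix exactly.
#'
#' @param spec A [distance_sim_spec()].
#' @return List with `D` (a [gene_dist]) and `module` (character vector of
#'   planted module genes, excluding the core).
#' @export
simulate_distance_matrix <- function(spec) {
  if (!inherits(spec, "distance_sim_spec"))
    stop_input("spec must be a distance_sim_spec")
  n <- spec$n_genes
  others <- sprintf("G%0*d", nchar(n), seq_len(n - 1L))
  gene_names <- c(spec$core, others)
  if (anyDuplicated(gene_names))
    stop_input("core symbol collides with generated gene names")
  with_seed(spec$seed, {
    module <- sort(sample(others, spec$module_size))
    in_mod <- gene_names %in% c(spec$core, module)
    if (spec$paired_directions) {
      # one base draw per unordered pair, mirrored, plus direction noise
      ut <- which(upper.tri(matrix(0, n, n)))
      both_mod <- outer(in_mod, in_mod, `&`)[ut]
      base_ut <- numeric(length(ut))
      base_ut[both_mod] <- stats::rlnorm(sum(both_mod), spec$within_mu,
                                         spec$within_sigma)
      base_ut[!both_mod] <- stats::rlnorm(sum(!both_mod),
                                          spec$background_mu,
                                          spec$background_sigma)
      base <- matrix(0, n, n)
      base[ut] <- base_ut
      base <- base + t(base)
      if (spec$asymmetry_sd > 0) {
        noise <- matrix(stats::rnorm(n * n, 0, spec$asymmetry_sd), n, n)
        diag(noise) <- 0
        base <- base + noise
      }
    } else {
      # every ordered pair independent: an exchangeable off-diagonal law
      off <- which(row(matrix(0, n, n)) != col(matrix(0, n, n)))
      both_mod <- outer(in_mod, in_mod, `&`)[off]
      vals <- numeric(length(off))
      vals[both_mod] <- stats::rlnorm(sum(both_mod), spec$within_mu,
                                      spec$within_sigma)
      vals[!both_mod] <- stats::rlnorm(sum(!both_mod), spec$background_mu,
                                       spec$background_sigma)
      base <- matrix(0, n, n)
      base[off] <- vals
    }
    base <- pmax(base, 0)
    diag(base) <- 0
    dimnames(base) <- list(gene_names, gene_names)
    list(D = gene_dist(base), module = module)
  })
}

#' Specification for a synthetic probe-level expression study
#'
#' Emulates a processed microarray: per-gene baseline log-intensities
#' around `Normal(7, 2)`, probes assigned round-robin to genes (so genes
#' can carry several probes), a fraction of probes ambiguously annotated
#' to two genes, and per-value Gaussian noise. A planted gene set is
#' shifted upward to create an excess of those genes in the top expression
#' percentile.
#'
#' @param n_genes,n_probes,n_samples Study dimensions (`n_probes >=
#'   n_genes`). Defaults 2000 genes, 3000 probes, 6 samples.
#' @param multi_gene_probe_frac Fraction of probes annotated to 2 genes,
#'   in `[0, 1)`. Default 0.1.
#' @param planted_genes Either a count (that many genes picked at random)
#'   or a character vector of gene symbols from `gene_names`. Default 60.
#' @param planted_shift Log-intensity added to planted genes. Default 6.
#' @param noise_sd Per-value noise sd. Default 0.5.
#' @param gene_names Optional gene symbols to use (length `n_genes`);
#'   default auto-generated, useful for pairing a study with a simulated
#'   distance matrix.
#' @param study_id Study label. Default `"sim_study"`.
#' @param seed Integer seed.
#' @return An `expression_sim_spec` list.
#' @export
expression_sim_spec <- function(n_genes = 2000L, n_probes = 3000L,
                                n_samples = 6L,
                                multi_gene_probe_frac = 0.1,
                                planted_genes = 60L, planted_shift = 6,
                                noise_sd = 0.5, gene_names = NULL,
                                study_id = "sim_study", seed = 1L) {
  if (n_genes < 2L) stop_input("n_genes must be >= 2")
  if (n_probes < n_genes) stop_input("n_probes must be >= n_genes")
  if (n_samples < 1L) stop_input("n_samples must be >= 1")
  if (multi_gene_probe_frac < 0 || multi_gene_probe_frac >= 1)
    stop_input("multi_gene_probe_frac must lie in [0, 1)")
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  if (!is.null(gene_names) && length(gene_names) != n_genes)
    stop_input("gene_names must have length n_genes")
  structure(list(n_genes = as.integer(n_genes),
                 n_probes = as.integer(n_probes),
                 n_samples = as.integer(n_samples),
                 multi_gene_probe_frac = multi_gene_probe_frac,
                 planted_genes = planted_genes,
                 planted_shift = planted_shift, noise_sd = noise_sd,
                 gene_names = gene_names, study_id = study_id,
                 seed = as.integer(seed)),
            class = "expression_sim_spec")
}

#' Simulate a probe-level expression study
#'
#' @param spec An [expression_sim_spec()].
#' @return List with `study` (an [expression_study]) and `planted`
#'   (character vector of planted gene symbols).
#' @export
simulate_expression_study <- function(spec) {
  if (!inherits(spec, "expression_sim_spec"))
    stop_input("spec must be an expression_sim_spec")
  n <- spec$n_genes
  gene_names <- spec$gene_names
  if (is.null(gene_names))
    gene_names <- sprintf("E%0*d", nchar(n), seq_len(n))
  with_seed(spec$seed, {
    planted <- spec$planted_genes
    if (is.numeric(planted) && length(planted) == 1L) {
      if (planted > n) stop_input("planted count exceeds n_genes")
      planted <- sort(sample(gene_names, planted))
    } else {
      planted <- as.character(planted)
      if (!all(planted %in% gene_names))
        stop_input("planted_genes contains symbols not in gene_names")
    }
    baseline <- stats::rnorm(n, 7, 2)
    names(baseline) <- gene_names
    baseline[planted] <- baseline[planted] + spec$planted_shift
    gene_idx <- ((seq_len(spec$n_probes) - 1L) %% n) + 1L
    probe_map <- lapply(gene_idx, function(i) gene_names[i])
    n_multi <- floor(spec$multi_gene_probe_frac * spec$n_probes)
    if (n_multi > 0L) {
      multi <- sample.int(spec$n_probes, n_multi)
      for (p in multi) {
        second <- (gene_idx[p] %% n) + 1L
        probe_map[[p]] <- gene_names[c(gene_idx[p], second)]
      }
    }
    probe_base <- vapply(probe_map, function(gs) mean(baseline[gs]),
                         numeric(1L))
    values <- matrix(probe_base, spec$n_probes, spec$n_samples) +
      matrix(stats::rnorm(spec$n_probes * spec$n_samples, 0, spec$noise_sd),
             spec$n_probes, spec$n_samples)
    rownames(values) <- sprintf("P%0*d", nchar(spec$n_probes),
                                seq_len(spec$n_probes))
    colnames(values) <- sprintf("S%02d", seq_len(spec$n_samples))
    names(probe_map) <- rownames(values)
    list(study = expression_study(spec$study_id, values, probe_map),
         planted = planted)
  })
}

# md5 digests frozen at packaging time; a mismatch means a corrupted
# installation.
.fixture_md5 <- c(
  known_bat_genes.txt = "575e49ae3cfa789cea37470a17a2c4e6",
  bat_candidate_genes.tsv = "7b4cceb2d427ce8b45cdd64156ef96de")

#' Bundled BAT gene-list fixtures
#'
#' Returns the packaged gene lists: the 61 literature-known BAT genes
#' (including UCP1 itself), the 107 novel BAT candidate genes, and the
#' candidates' binary high-expression flag (1 = above the 95th expression
#' percentile in at least one of the two BAT-biopsy microarray studies).
#' File integrity is verified against md5 checksums frozen at packaging
#' time.
#'
#' @return List with `known` (character, length 61), `candidates`
#'   (character, length 107) and `biopsy_top_flags` (named integer 0/1
#'   vector over the candidates).
#' @examples
#' lists <- bundled_gene_lists()
#' length(setdiff(lists$known, "UCP1"))  # 60
#' @export
bundled_gene_lists <- function() {
  paths <- vapply(names(.fixture_md5), function(f)
    system.file("extdata", f, package = "batconnectome", mustWork = TRUE),
    "")
  sums <- tools::md5sum(paths)
  bad <- sums != .fixture_md5
  if (any(bad))
    stop_format("bundled fixture corrupted: %s",
                paste(names(.fixture_md5)[bad], collapse = ", "))
  known <- read_gene_list(paths[[1L]])
  cand_df <- utils::read.table(paths[[2L]], sep = "\t", header = TRUE,
                               quote = "", comment.char = "",
                               stringsAsFactors = FALSE)
  flags <- as.integer(cand_df$high_expression_biopsy)
  names(flags) <- cand_df$gene
  list(known = known, candidates = cand_df$gene, biopsy_top_flags = flags)
}
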