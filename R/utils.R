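# Condition helpers: input errors (bad arguments / preconditions) vs format
# errors (malformed files). Both subclass "bat_error" so callers can catch
# everything from this package in one handler.

stop_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("bat_input_error", "bat_error")))
}

stop_format <- function(msg, ..., class = character()) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "bat_format_error", "bat_error")))
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, then
#' restores the caller's RNG state, so package functions are reproducible
#' without clobbering the session's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_input("seed must be a single non-missing number")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Read a plain-text gene list
#'
#' One symbol per line; blank lines and lines starting with `#` are ignored;
#' surrounding whitespace is stripped. Matching elsewhere in the package is
#' case-sensitive, so lists must use the same symbol casing as the distance
#' matrix.
#'
#' @param path Path to the list file.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (anyDuplicated(lines))
    stop_format("duplicate gene symbol in %s: %s", path,
                paste(unique(lines[duplicated(lines)]), collapse = ", "))
  lines
}

# Restrict a gene set to a universe, warning (not failing) about symbols the
# universe lacks, so published lists can be applied to partial matrices.
match_genes <- function(genes, universe, what = "gene list") {
  missing <- setdiff(genes, universe)
  if (length(missing) > 0L)
    warning(sprintf("%d symbol(s) in %s absent from the matrix and dropped: %s",
                    length(missing), what,
                    paste(utils::head(missing, 5L), collapse = ", ")),
            call. = FALSE)
  genes[genes %in% universe]
}
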