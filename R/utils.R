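#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rpois runif rbinom dnorm dexp median sd cor
#'   complete.cases pt qbinom setNames aggregate
#' @importFrom utils head tail write.table read.table combn
NULL

DNA_BASES <- c("A", "C", "G", "T")

## 0-based half-open substring: bases [start, end) of x.
ss0 <- function(x, start, end) substr(x, start + 1L, end)

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] operating
#' on plain character vectors (the package's internal sequence currency).
#'
#' @param x Character vector of DNA sequences over `A`, `C`, `G`, `T`, `N`.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("TATAG", "ACGT"))
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Sample n bases from a named probability vector (A/C/G/T), returned as a
## single string per element of `lengths`.
random_dna <- function(lengths, probs) {
  check_base_probs(probs)
  total <- sum(lengths)
  if (total == 0L) return(rep("", length(lengths)))
  bases <- sample(names(probs), total, replace = TRUE, prob = as.numeric(probs))
  idx <- rep(seq_along(lengths), lengths)
  vapply(split(bases, factor(idx, levels = seq_along(lengths))),
         paste0, character(1), collapse = "")
}

check_base_probs <- function(probs, what = "base probabilities") {
  if (is.null(names(probs)) || !setequal(names(probs), DNA_BASES))
    stop(what, " must be a numeric vector named A, C, G, T", call. = FALSE)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-6)
    stop(what, " must be non-negative and sum to 1", call. = FALSE)
  probs[DNA_BASES]
}

## Derive a stage-specific RNG seed from a master seed; kept below 2^31.
derive_seed <- function(seed, stage) {
  offs <- c(genomes = 11L, dna = 23L, srna = 37L, errors = 53L, assoc = 71L)
  off <- offs[[stage]]
  as.integer((as.numeric(seed) * 113 + off) %% 2147483647)
}

## Write a data.frame as a TSV with a header row.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

## Per-position base counts for a character matrix of single bases.
base_count_matrix <- function(mat) {
  apply(mat, 2, function(col) {
    tab <- table(factor(col, levels = DNA_BASES))
    as.integer(tab)
  })
}

## Split equal-length sequences into an n x width character matrix.
seq_matrix <- function(seqs) {
  w <- unique(nchar(seqs))
  if (length(w) != 1L)
    stop("sequences must all have the same length", call. = FALSE)
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = w, byrow = TRUE)
}
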