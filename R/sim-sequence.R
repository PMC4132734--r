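#' Generate an IES sequence with TA boundaries
#'
#' Builds the full stored sequence of an IES of one-TA length `length`:
#' `length + 2` bases that start and end with `TA`. The three bases inward of
#' each boundary TA are drawn from the end-model table for the length
#' stratum (the right end is generated on the reverse-complement strand, so
#' both ends share one orientation convention); all remaining interior bases
#' are i.i.d. from `interior_background`.
#'
#' @param length One-TA length in bp (`>= 26`).
#' @param end_model An [ies_end_model()].
#' @param interior_background Named base-probability vector for interior
#'   positions.
#' @return A single DNA string of `length + 2` characters.
#' @export
#' @examples
#' set.seed(1)
#' s <- generate_ies_sequence(28)
#' substr(s, 1, 2); substr(s, 29, 30)  # both boundary TAs
generate_ies_sequence <- function(length,
                                  end_model = ies_end_model(),
                                  interior_background =
                                    c(A = 0.4, C = 0.1, G = 0.1, T = 0.4)) {
  generate_ies_sequences(length, end_model, interior_background)
}

## Vectorised generator over a vector of lengths.
generate_ies_sequences <- function(lengths,
                                   end_model = ies_end_model(),
                                   interior_background =
                                     c(A = 0.4, C = 0.1, G = 0.1, T = 0.4)) {
  if (any(lengths < 26))
    stop("IES length must be >= 26 bp (one-TA convention)", call. = FALSE)
  interior_background <- check_base_probs(interior_background,
                                          "interior background")
  n <- length(lengths)
  if (n == 0L) return(character(0))
  interiors <- random_dna(lengths - 8L, interior_background)
  out <- character(n)
  for (i in seq_len(n)) {
    probs <- end_model_stratum(end_model, lengths[i])
    left <- vapply(probs, function(p)
      sample(names(p), 1L, prob = as.numeric(p)), character(1))
    right <- vapply(probs, function(p)
      sample(names(p), 1L, prob = as.numeric(p)), character(1))
    ## Right end read on the reverse complement: seq ends with
    ## revcomp(TA + right) = comp(r3) comp(r2) comp(r1) TA.
    right_block <- revcomp(paste0("TA", paste(right, collapse = "")))
    out[i] <- paste0("TA", paste(left, collapse = ""), interiors[i],
                     right_block)
  }
  out
}
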