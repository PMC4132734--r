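## Probability mass function of the IES length model over its support.
length_model_pmf <- function(model) {
  validate_length_model(model)
  support <- model$min_len:model$max_len
  w <- model$peak_decay^(seq_along(model$peak_centers) - 1)
  w <- w / sum(w)
  pmf <- numeric(length(support))
  if (model$peak_sd == 0) {
    for (k in seq_along(model$peak_centers)) {
      i <- match(model$peak_centers[k], support)
      if (!is.na(i)) pmf[i] <- pmf[i] + w[k]
    }
  } else {
    for (k in seq_along(model$peak_centers))
      pmf <- pmf + w[k] * dnorm(support, model$peak_centers[k], model$peak_sd)
  }
  if (sum(pmf) > 0) pmf <- (1 - model$tail_weight) * pmf / sum(pmf)
  last <- max(model$peak_centers)
  in_tail <- support > last
  if (model$tail_weight > 0 && any(in_tail)) {
    tail_pmf <- dexp(support[in_tail] - last, model$tail_rate)
    pmf[in_tail] <- pmf[in_tail] +
      model$tail_weight * tail_pmf / sum(tail_pmf)
  }
  forb <- support >= model$forbidden_window[1] &
    support <= model$forbidden_window[2]
  pmf[forb] <- pmf[forb] * model$forbidden_factor
  if (sum(pmf) <= 0)
    stop("length model has no probability mass on its support", call. = FALSE)
  data.frame(length = support, p = pmf / sum(pmf))
}

#' Sample IES lengths (one-TA convention)
#'
#' Draws from the discretised mixture model of IES lengths: Gaussian peaks
#' every ~10 bp with the first (modal) peak at 28 bp, multiplicative
#' depletion of the 38--46 bp "forbidden" window, and an exponential tail
#' beyond the last peak. Lengths are counted including exactly one of the two
#' boundary TA dinucleotides, so the minimum is 26 bp.
#'
#' Uses the current R random number stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param n Number of lengths to draw.
#' @param model An [ies_length_model()].
#' @return Integer vector of lengths in bp, all `>= model$min_len`.
#' @export
#' @examples
#' set.seed(1)
#' table(sample_ies_length(1000))[1:5]
sample_ies_length <- function(n, model = ies_length_model()) {
  pmf <- length_model_pmf(model)
  sample(pmf$length, n, replace = TRUE, prob = pmf$p)
}
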