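#' Sub-terminal base frequencies of IES ends
#'
#' Tallies the bases at positions 1--3 inward of the boundary TA (position 1
#' adjacent to the TA). With `end_policy = "both_ends_pooled"` the right end
#' is read on the reverse complement, so both ends share one orientation;
#' `"left_end_only"` uses only the 5' end. Sequences too short for a
#' position are skipped and counted in the `n_skipped` attribute.
#'
#' @param annotations IES annotation data.frame with `sequence` and `length`.
#' @param grouping Vector (length `nrow(annotations)`) of group keys, or the
#'   string `"length"` to group by one-TA length.
#' @param end_policy `"left_end_only"` or `"both_ends_pooled"`.
#' @return Data.frame `group`, `position`, `base`, `count`, `freq`, `n`.
#' @export
subterminal_frequencies <- function(annotations, grouping = "length",
                                    end_policy = c("left_end_only",
                                                   "both_ends_pooled")) {
  end_policy <- match.arg(end_policy)
  keys <- if (identical(grouping, "length")) annotations$length else grouping
  stopifnot(length(keys) == nrow(annotations))
  seqs <- annotations$sequence
  ends <- substr(seqs, 3L, 5L)                  # positions 1-3 after left TA
  key_all <- keys
  if (end_policy == "both_ends_pooled") {
    rev_ends <- substr(revcomp(seqs), 3L, 5L)
    ends <- c(ends, rev_ends)
    key_all <- c(keys, keys)
  }
  ## skip right-end positions that would overlap the left TA (len < 8 never
  ## happens for real IESs, but guard anyway)
  ok <- nchar(ends) == 3L
  n_skipped <- sum(!ok)
  ends <- ends[ok]; key_all <- key_all[ok]
  rows <- list()
  for (g in sort(unique(key_all))) {
    sel <- key_all == g
    n <- sum(sel)
    for (pos in 1:3) {
      b <- substr(ends[sel], pos, pos)
      tab <- table(factor(b, levels = DNA_BASES))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, position = pos, base = DNA_BASES,
        count = as.integer(tab), freq = as.integer(tab) / n, n = n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Exponentially weighted moving average
#'
#' Standard EWMA over an ordered series: with span `s`, the smoothing factor
#' is `alpha = 2 / (s + 1)`; `out[1] = x[1]` and
#' `out[i] = alpha * x[i] + (1 - alpha) * out[i - 1]`.
#'
#' @param x Numeric series in key order.
#' @param span Span (`>= 1`).
#' @return Numeric vector of the same length as `x`.
#' @export
#' @examples
#' ewma(c(0, 1), span = 5)   # second value 1/3
ewma <- function(x, span) {
  stopifnot(span >= 1)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  alpha <- 2 / (span + 1)
  out <- numeric(n)
  out[1] <- x[1]
  if (n > 1L) for (i in 2:n) out[i] <- alpha * x[i] + (1 - alpha) * out[i - 1]
  out
}

#' Relative-entropy sequence logo with a non-uniform background
#'
#' For each column of an aligned window, the total information is the
#' Kullback-Leibler divergence of the observed base frequencies `p` from the
#' background `q` in bits, `sum(p * log2(p / q))`, clamped at zero; letter
#' heights partition the total in proportion to `p`. This is the logo form
#' appropriate for a composition-biased genome, where enrichment is only
#' meaningful relative to a non-uniform background such as the IES-interior
#' frequencies A = T = 0.4, C = G = 0.1.
#'
#' @param sequences Character vector of equal-length aligned sequences.
#' @param background Named base-probability vector `q`.
#' @return Data.frame `position` (1-based column), `base`, `p`, `height`
#'   (bits), `total` (column information, bits).
#' @export
sequence_logo <- function(sequences,
                          background = c(A = 0.4, C = 0.1, G = 0.1, T = 0.4)) {
  background <- check_base_probs(background, "background")
  mat <- seq_matrix(sequences)
  n <- nrow(mat)
  rows <- list()
  for (col in seq_len(ncol(mat))) {
    tab <- table(factor(mat[, col], levels = DNA_BASES))
    p <- as.numeric(tab) / n
    names(p) <- DNA_BASES
    if (any(p > 0 & background == 0))
      stop(sprintf(
        "column %d: observed base with zero background probability", col),
        call. = FALSE)
    nz <- p > 0
    total <- max(0, sum(p[nz] * log2(p[nz] / background[nz])))
    rows[[col]] <- data.frame(position = col, base = DNA_BASES, p = p,
                              height = p * total, total = total,
                              row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Two-sample sequence logo
#'
#' Compares per-position base frequencies between two sequence groups using
#' a two-sample test on per-sequence presence/absence indicators (Welch's
#' t-test by default, pooled-variance optional), with Bonferroni correction
#' over positions x 4 bases. Direction is reported from the perspective of
#' group A: `enriched` where the base is more frequent in A.
#'
#' @param group_a,group_b Character vectors of equal-length aligned
#'   sequences (the window typically spans the IES end and flanking
#'   MAC-destined positions).
#' @param alpha Familywise significance level after Bonferroni correction.
#' @param test `"welch"` or `"pooled"`.
#' @return Data.frame `position`, `base`, `freq_a`, `freq_b`, `diff`,
#'   `direction`, `p_raw`, `p_bonferroni`, `significant`.
#' @export
two_sample_logo <- function(group_a, group_b, alpha = 1e-4,
                            test = c("welch", "pooled")) {
  test <- match.arg(test)
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  ma <- seq_matrix(group_a)
  mb <- seq_matrix(group_b)
  if (ncol(ma) != ncol(mb))
    stop("groups must share the same aligned window", call. = FALSE)
  na <- nrow(ma); nb <- nrow(mb)
  W <- ncol(ma)
  bonf <- W * 4L
  rows <- vector("list", W)
  for (col in seq_len(W)) {
    ca <- as.integer(table(factor(ma[, col], levels = DNA_BASES)))
    cb <- as.integer(table(factor(mb[, col], levels = DNA_BASES)))
    pa <- ca / na
    pb <- cb / nb
    ## variance of 0/1 indicators (unbiased)
    va <- if (na > 1) pa * (1 - pa) * na / (na - 1) else rep(0, 4)
    vb <- if (nb > 1) pb * (1 - pb) * nb / (nb - 1) else rep(0, 4)
    if (test == "welch") {
      se2 <- va / na + vb / nb
      df <- ifelse(se2 > 0,
                   se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
                   1)
    } else {
      sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
      se2 <- sp2 * (1 / na + 1 / nb)
      df <- rep(na + nb - 2, 4L)
    }
    tstat <- ifelse(se2 > 0, (pa - pb) / sqrt(se2), 0)
    p_raw <- ifelse(se2 > 0, 2 * pt(-abs(tstat), df),
                    ifelse(pa == pb, 1, 0))   # complete separation
    rows[[col]] <- data.frame(
      position = col, base = DNA_BASES, freq_a = pa, freq_b = pb,
      diff = pa - pb,
      direction = ifelse(pa >= pb, "enriched", "depleted"),
      p_raw = p_raw, p_bonferroni = pmin(1, p_raw * bonf),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_bonferroni < alpha
  rownames(out) <- NULL
  out
}

#' Sub-terminal base frequency versus retention score
#'
#' Within a narrow IES length window (which decouples retention score from
#' length), bins IESs by their retention score, computes sub-terminal base
#' frequencies per bin, smooths each (position, base) series with an EWMA
#' over bins, and marks the bins lying within `sd_trim` standard deviations
#' of the mean score, outside which trends are not interpreted.
#'
#' @param annotations IES annotation data.frame.
#' @param records Retention records (see [compute_irs()]).
#' @param length_window Length-2 vector of one-TA length bounds (inclusive).
#' @param irs_bin Retention-score bin width.
#' @param ewma_span EWMA span in bins.
#' @param sd_trim Trend window half-width in standard deviations.
#' @param end_policy Passed to [subterminal_frequencies()].
#' @return Data.frame `bin` (centre), `position`, `base`, `freq`, `smoothed`,
#'   `n`, `in_trend`.
#' @export
frequency_vs_irs <- function(annotations, records,
                             length_window = c(26L, 36L), irs_bin = 0.01,
                             ewma_span = 10, sd_trim = 2,
                             end_policy = "left_end_only") {
  m <- match(annotations$ies_id, records$ies_id)
  irs <- records$irs[m]
  keep <- !is.na(irs) & annotations$length >= length_window[1] &
    annotations$length <= length_window[2]
  if (!any(keep))
    return(data.frame(bin = numeric(0), position = integer(0),
                      base = character(0), freq = numeric(0),
                      smoothed = numeric(0), n = integer(0),
                      in_trend = logical(0), stringsAsFactors = FALSE))
  ann <- annotations[keep, , drop = FALSE]
  irs <- irs[keep]
  nb <- round(1 / irs_bin)
  bin_idx <- pmin(floor(irs / irs_bin) + 1L, nb)
  prof <- subterminal_frequencies(ann, grouping = bin_idx,
                                  end_policy = end_policy)
  mu <- mean(irs); sdev <- sd(irs)
  centres <- (as.numeric(sort(unique(bin_idx))) - 0.5) * irs_bin
  bins_present <- sort(unique(bin_idx))
  out <- list()
  for (pos in 1:3) for (b in DNA_BASES) {
    sel <- prof$position == pos & prof$base == b
    sub <- prof[sel, , drop = FALSE]
    sub <- sub[match(bins_present, sub$group), , drop = FALSE]
    sm <- ewma(sub$freq, ewma_span)
    out[[length(out) + 1L]] <- data.frame(
      bin = centres, position = pos, base = b, freq = sub$freq,
      smoothed = sm, n = sub$n,
      in_trend = if (is.na(sdev)) TRUE else
        abs(centres - mu) <= sd_trim * sdev,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
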