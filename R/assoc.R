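#' Find pairs of sequence-identical IESs
#'
#' Groups IESs by exact full-sequence identity (both TAs included) and emits
#' every unordered pair within a group, excluding pairs whose flanking
#' sequence over `flank_window` bases on each side is also identical — such
#' pairs cannot be told apart by their IES+ reads. Optional filters mirror
#' the usual analysis conditions: a minimum scaffold length and exclusion of
#' pairs in which a score is zero or below a fraction of a control score.
#'
#' @param annotations IES annotation data.frame.
#' @param mic_genome Named character vector of MAC+IES scaffolds (for
#'   flanking sequence and scaffold lengths).
#' @param scores Optional named numeric vector of scores (e.g. IRS) indexed
#'   by `ies_id`; attached as `score_x`/`score_y`.
#' @param control_scores Optional named numeric control scores used by
#'   `min_control_fraction`.
#' @param flank_window Flank width in bp used for distinguishability
#'   (typically the read length).
#' @param min_scaffold_len Keep only IESs on scaffolds at least this long.
#' @param exclude_zero Drop pairs in which either score is 0.
#' @param min_control_fraction If given with `control_scores`, keep only
#'   IESs whose score is at least this fraction of their control score.
#' @return Data.frame `ies_x`, `ies_y`, `scaffold_x`, `scaffold_y`,
#'   `same_scaffold`, `distance` (bp between elements on a shared scaffold,
#'   `NA` otherwise), plus `score_x`, `score_y` when `scores` is given.
#'   Indistinguishable pairs are counted in attribute
#'   `n_indistinguishable`.
#' @export
find_identical_pairs <- function(annotations, mic_genome, scores = NULL,
                                 control_scores = NULL, flank_window = 100L,
                                 min_scaffold_len = 0L, exclude_zero = FALSE,
                                 min_control_fraction = NULL) {
  ann <- annotations
  if (min_scaffold_len > 0L) {
    lens <- nchar(mic_genome)[ann$scaffold]
    ann <- ann[lens >= min_scaffold_len, , drop = FALSE]
  }
  groups <- split(seq_len(nrow(ann)), ann$sequence)
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  n_indist <- 0L
  rows <- list()
  for (g in groups) {
    prs <- combn(g, 2L)
    for (k in seq_len(ncol(prs))) {
      i <- prs[1, k]; j <- prs[2, k]
      fi <- flanks_of(ann[i, ], mic_genome, flank_window)
      fj <- flanks_of(ann[j, ], mic_genome, flank_window)
      if (identical(fi, fj)) { n_indist <- n_indist + 1L; next }
      same <- ann$scaffold[i] == ann$scaffold[j]
      dist <- if (same) {
        lo <- min(ann$start[i], ann$start[j])
        hi_i <- which.max(c(ann$start[i], ann$start[j]))
        hi_row <- c(i, j)[hi_i]
        max(ann$start[hi_row] -
              (lo + ann$length[c(i, j)[3 - hi_i]] + 2L), 0L)
      } else NA_integer_
      rows[[length(rows) + 1L]] <- data.frame(
        ies_x = ann$ies_id[i], ies_y = ann$ies_id[j],
        scaffold_x = ann$scaffold[i], scaffold_y = ann$scaffold[j],
        same_scaffold = same, distance = dist, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ies_x = character(0), ies_y = character(0),
               scaffold_x = character(0), scaffold_y = character(0),
               same_scaffold = logical(0), distance = integer(0),
               stringsAsFactors = FALSE)
  if (!is.null(scores)) {
    out$score_x <- unname(scores[out$ies_x])
    out$score_y <- unname(scores[out$ies_y])
    if (!is.null(min_control_fraction) && !is.null(control_scores)) {
      cx <- unname(control_scores[out$ies_x])
      cy <- unname(control_scores[out$ies_y])
      out <- out[!is.na(out$score_x) & !is.na(out$score_y) &
                   out$score_x >= min_control_fraction * cx &
                   out$score_y >= min_control_fraction * cy, , drop = FALSE]
    }
    if (exclude_zero)
      out <- out[!is.na(out$score_x) & !is.na(out$score_y) &
                   out$score_x > 0 & out$score_y > 0, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "n_indistinguishable") <- n_indist
  out
}

flanks_of <- function(a, mic_genome, w) {
  s <- mic_genome[[a$scaffold]]
  left <- ss0(s, max(a$start - w, 0L), a$start)
  e <- a$start + a$length + 2L
  right <- ss0(s, e, min(e + w, nchar(s)))
  c(left, right)
}

#' Correlate paired scores
#'
#' Pearson or Spearman correlation with a two-tailed p-value, via
#' [stats::cor.test()].
#'
#' @param x,y Numeric vectors of paired scores.
#' @param method `"pearson"` or `"spearman"`.
#' @return List `r`, `p`, `n`. Zero variance in either margin gives
#'   `r = NA` with a warning.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         alternative = "two.sided",
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Pairs of nearby IESs and their retention scores
#'
#' Emits pairs of IESs on the same scaffold separated by exactly
#' `n_intervening` other IESs (0 = immediate neighbours) and by at most
#' `max_gap` bp of intervening sequence, carrying their retention scores.
#'
#' @param annotations IES annotation data.frame.
#' @param records Retention records (see [compute_irs()]); undefined scores
#'   drop the pair.
#' @param n_intervening Number of IESs between the two members of a pair.
#' @param max_gap Maximum genomic distance in bp between the facing ends of
#'   the pair.
#' @return Data.frame `ies_x`, `ies_y`, `scaffold`, `distance`, `score_x`,
#'   `score_y`.
#' @export
adjacent_pairs <- function(annotations, records, n_intervening = 0L,
                           max_gap = Inf) {
  irs <- setNames(records$irs, records$ies_id)
  rows <- list()
  for (sc in unique(annotations$scaffold)) {
    ai <- which(annotations$scaffold == sc)
    ai <- ai[order(annotations$start[ai])]
    k <- n_intervening + 1L
    if (length(ai) <= k) next
    for (t in seq_len(length(ai) - k)) {
      i <- ai[t]; j <- ai[t + k]
      gap <- annotations$start[j] -
        (annotations$start[i] + annotations$length[i] + 2L)
      if (gap > max_gap) next
      sx <- irs[annotations$ies_id[i]]; sy <- irs[annotations$ies_id[j]]
      if (is.na(sx) || is.na(sy)) next
      rows[[length(rows) + 1L]] <- data.frame(
        ies_x = annotations$ies_id[i], ies_y = annotations$ies_id[j],
        scaffold = sc, distance = gap, score_x = unname(sx),
        score_y = unname(sy), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(ies_x = character(0), ies_y = character(0),
                      scaffold = character(0), distance = numeric(0),
                      score_x = numeric(0), score_y = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Random IES pairs as a null baseline
#'
#' Seeded random pairing of distinct IESs with defined scores, used as the
#' no-association baseline for adjacent-pair correlations.
#'
#' @param annotations IES annotation data.frame.
#' @param records Retention records.
#' @param n Number of pairs.
#' @param seed RNG seed.
#' @return Data.frame like [adjacent_pairs()] with `distance = NA`.
#' @export
random_pairs <- function(annotations, records, n = 1000L, seed = 1L) {
  set.seed(seed)
  irs <- setNames(records$irs, records$ies_id)
  ids <- annotations$ies_id[!is.na(irs[annotations$ies_id])]
  if (length(ids) < 2L) stop("need at least 2 scored IESs", call. = FALSE)
  i <- sample(ids, n, replace = TRUE)
  j <- sample(ids, n, replace = TRUE)
  keep <- i != j
  data.frame(ies_x = i[keep], ies_y = j[keep], scaffold = NA_character_,
             distance = NA_real_, score_x = unname(irs[i[keep]]),
             score_y = unname(irs[j[keep]]), stringsAsFactors = FALSE)
}
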