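#' Per-IES sRNA density for one size class
#'
#' Counts assigned sRNA reads of a given length per IES and converts counts
#' to densities (reads per base of one-TA IES length) and to normalised
#' densities per million size-range reads. The containment policy reflects
#' the two sRNA classes: iesRNA-like reads (27 nt default) must lie fully
#' within the IES interval, while boundary-spanning scnRNA-like reads
#' (25 nt) count if they overlap the interval by at least one base.
#'
#' @param assigned Assigned sRNA alignments (see [srna_two_stage_assign()]);
#'   only MAC+IES-space reads can match an IES interval.
#' @param annotations IES annotation data.frame.
#' @param size_class Read length in nt to count.
#' @param normalization_total Total 15--35 nt mapped reads in the sample
#'   (defaults to the attribute recorded by [srna_two_stage_assign()]).
#' @param policy `"contained"` or `"overlap"`; default `"contained"` for
#'   reads `>= 26` nt... see Details.
#' @details The default policy is `"contained"` for the iesRNA-typical 27 nt
#'   class and `"overlap"` for the scnRNA-typical 25 nt class; passing
#'   `policy` explicitly overrides this.
#' @return Data.frame `ies_id`, `size_class`, `count`, `density`,
#'   `norm_density`.
#' @export
per_ies_density <- function(assigned, annotations, size_class,
                            normalization_total =
                              attr(assigned, "normalization_total"),
                            policy = NULL) {
  if (is.null(policy))
    policy <- if (size_class == 25L) "overlap" else "contained"
  policy <- match.arg(policy, c("contained", "overlap"))
  if (is.null(normalization_total) || normalization_total <= 0)
    stop("normalization_total must be positive", call. = FALSE)
  reads <- assigned[assigned$length == size_class &
                      assigned$space == "mic", , drop = FALSE]
  counts <- integer(nrow(annotations))
  for (sc in unique(annotations$scaffold)) {
    ai <- which(annotations$scaffold == sc)
    ri <- which(reads$scaffold == sc)
    if (length(ai) == 0L || length(ri) == 0L) next
    ies_iv <- IRanges::IRanges(start = annotations$start[ai] + 1L,
                               width = annotations$length[ai] + 2L)
    rd_iv <- IRanges::IRanges(start = reads$start[ri] + 1L,
                              width = reads$end[ri] - reads$start[ri])
    type <- if (policy == "contained") "within" else "any"
    ov <- IRanges::findOverlaps(rd_iv, ies_iv, type = type)
    tab <- table(factor(S4Vectors::subjectHits(ov),
                        levels = seq_along(ai)))
    counts[ai] <- counts[ai] + as.integer(tab)
  }
  density <- counts / annotations$length
  data.frame(ies_id = annotations$ies_id, size_class = size_class,
             count = counts, density = density,
             norm_density = density / (normalization_total / 1e6),
             stringsAsFactors = FALSE)
}

#' Binned sRNA density versus retention score
#'
#' Joins per-IES densities with retention records, takes the bin statistic
#' (median by default) of density per retention-score interval of width
#' `bin`, smooths the binned series with an EWMA, and marks bins within
#' `sd_trim` standard deviations of the mean score. Densities above
#' `outlier_cap` can be excluded from the binned statistic (they remain in
#' the per-IES table).
#'
#' @param densities Output of [per_ies_density()].
#' @param records Retention records (see [compute_irs()]).
#' @param bin Retention-score bin width.
#' @param stat Bin statistic, `"median"` or `"mean"`.
#' @param ewma_span EWMA span in bins.
#' @param sd_trim Trend window half-width in standard deviations of the
#'   score distribution.
#' @param outlier_cap Optional density cap; `NULL` keeps all values.
#' @param value Density column to profile (`"density"` or `"norm_density"`).
#' @return Data.frame `bin` (centre), `value` (bin statistic), `smoothed`,
#'   `n`, `in_trend`.
#' @export
density_vs_irs <- function(densities, records, bin = 0.01,
                           stat = c("median", "mean"), ewma_span = 5,
                           sd_trim = 2, outlier_cap = NULL,
                           value = c("density", "norm_density")) {
  stat <- match.arg(stat)
  value <- match.arg(value)
  statf <- if (stat == "median") median else mean
  m <- match(densities$ies_id, records$ies_id)
  irs <- records$irs[m]
  d <- densities[[value]]
  keep <- !is.na(irs)
  if (!is.null(outlier_cap)) keep <- keep & d <= outlier_cap
  irs <- irs[keep]; d <- d[keep]
  if (length(d) == 0L)
    return(data.frame(bin = numeric(0), value = numeric(0),
                      smoothed = numeric(0), n = integer(0),
                      in_trend = logical(0)))
  nb <- round(1 / bin)
  idx <- pmin(floor(irs / bin) + 1L, nb)
  bins_present <- sort(unique(idx))
  val <- vapply(bins_present, function(b) statf(d[idx == b]), numeric(1))
  n <- vapply(bins_present, function(b) sum(idx == b), integer(1))
  centres <- (bins_present - 0.5) * bin
  mu <- mean(irs); sdev <- sd(irs)
  data.frame(bin = centres, value = val, smoothed = ewma(val, ewma_span),
             n = n,
             in_trend = if (is.na(sdev)) TRUE else
               abs(centres - mu) <= sd_trim * sdev)
}
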