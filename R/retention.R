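#' Classify a single read against one IES
#'
#' A read is `IES_plus` if its aligned span crosses an IES end in MAC+IES
#' space with at least `min_anchor` aligned bases on both sides of that end,
#' and `IES_minus` if, in MAC space, its span crosses the junction point with
#' at least `min_anchor` aligned bases on each side (the junction TA, which
#' lies on the right side of the point, must be fully contained). Reads lying
#' wholly inside the IES, not reaching an end, or on the wrong scaffold are
#' `uninformative`. A read crossing both ends of a short IES still counts
#' once.
#'
#' @param read One-row read data.frame (or list) with `scaffold`, `space`,
#'   `start`, `end` (0-based half-open aligned span).
#' @param annotation One-row IES annotation (see [build_genomes()]).
#' @param min_anchor Minimum aligned bases flanking the crossed end/junction.
#' @return One of `"IES_plus"`, `"IES_minus"`, `"uninformative"`.
#' @export
classify_read <- function(read, annotation, min_anchor = 5L) {
  stopifnot(min_anchor >= 1L)
  a <- min_anchor
  if (read$space == "mic") {
    if (read$scaffold != annotation$scaffold) return("uninformative")
    ends <- c(annotation$start, annotation$start + annotation$length)
    crosses <- (ends - read$start >= a) & (read$end - ends >= a)
    if (any(crosses)) return("IES_plus")
    return("uninformative")
  }
  if (read$space == "mac") {
    if (read$scaffold != annotation$mac_scaffold) return("uninformative")
    ## junction boundary point j, with the retained TA on its right side —
    ## the mirror of the IES+ boundary test (the read must still contain the
    ## full junction TA)
    j <- annotation$mac_junction
    if (j - read$start >= a && read$end - j >= max(a, 2L))
      return("IES_minus")
    return("uninformative")
  }
  "uninformative"
}

#' Compute IES retention scores from assigned alignments
#'
#' For every IES, counts reads supporting the retained form (`IES+`: reads
#' crossing an IES end in MAC+IES space) and the excised form (`IES-`: reads
#' crossing the MAC junction TA), each read contributing at most one count
#' per IES, and returns the retention score
#' `IRS = IES+ / (IES+ + IES-)`. IESs with no informative read have an
#' undefined (`NA`) score.
#'
#' @param reads Read data.frame (typically after [filter_unique_pairs()])
#'   with `scaffold`, `space`, `start`, `end`, `qname`.
#' @param annotations IES annotation data.frame.
#' @param min_anchor Minimum aligned bases flanking a crossed end/junction.
#' @param sample_label Optional label stored in the result.
#' @return A data.frame with one row per IES: `ies_id`, `ies_plus`,
#'   `ies_minus`, `irs`, `sample`.
#' @export
compute_irs <- function(reads, annotations, min_anchor = 5L,
                        sample_label = NA_character_) {
  stopifnot(min_anchor >= 1L)
  a <- min_anchor
  plus <- integer(nrow(annotations))
  minus <- integer(nrow(annotations))
  names(plus) <- names(minus) <- annotations$ies_id

  mic_reads <- reads[reads$space == "mic", , drop = FALSE]
  mac_reads <- reads[reads$space == "mac", , drop = FALSE]

  for (sc in unique(annotations$scaffold)) {
    ai <- which(annotations$scaffold == sc)
    ## IES+ : end point e must lie in [start + a, end - a] of a mic-space read
    ri <- which(mic_reads$scaffold == sc)
    if (length(ri) > 0L) {
      ends <- c(annotations$start[ai],
                annotations$start[ai] + annotations$length[ai])
      end_ies <- rep(ai, 2L)
      ## a boundary point e is crossed iff e in [start + a, end - a] (0-based);
      ## reads shorter than 2a yield an empty query window
      qs <- mic_reads$start[ri] + a + 1L
      q <- IRanges::IRanges(start = qs,
                            end = pmax(mic_reads$end[ri] - a + 1L, qs - 1L))
      pts <- IRanges::IRanges(start = ends + 1L, width = 1L)
      ov <- IRanges::findOverlaps(pts, q)
      if (length(ov) > 0L) {
        hit_ies <- end_ies[S4Vectors::queryHits(ov)]
        hit_read <- ri[S4Vectors::subjectHits(ov)]
        ## one count per (read, IES), crossing both ends counts once
        pairs <- unique(paste0(hit_read, "_", hit_ies))
        ies_of_pair <- as.integer(sub("^.*_", "", pairs))
        tab <- table(factor(ies_of_pair, levels = seq_len(nrow(annotations))))
        plus <- plus + as.integer(tab)
      }
    }
  }
  for (sc in unique(annotations$mac_scaffold)) {
    ai <- which(annotations$mac_scaffold == sc)
    ri <- which(mac_reads$scaffold == sc)
    if (length(ri) > 0L) {
      ## IES- : junction point j crossed with >= a bases left of j and the
      ## junction TA plus anchor on the right: start <= j - a and
      ## end - j >= max(a, 2)
      qs <- mac_reads$start[ri] + a + 1L
      qe <- mac_reads$end[ri] - max(a, 2L) + 1L
      q <- IRanges::IRanges(start = qs, end = pmax(qe, qs - 1L))
      pts <- IRanges::IRanges(start = annotations$mac_junction[ai] + 1L,
                              width = 1L)
      ov <- IRanges::findOverlaps(pts, q, type = "within")
      if (length(ov) > 0L) {
        hit_ies <- ai[S4Vectors::queryHits(ov)]
        hit_read <- ri[S4Vectors::subjectHits(ov)]
        pairs <- unique(paste0(hit_read, "_", hit_ies))
        ies_of_pair <- as.integer(sub("^.*_", "", pairs))
        tab <- table(factor(ies_of_pair, levels = seq_len(nrow(annotations))))
        minus <- minus + as.integer(tab)
      }
    }
  }
  total <- plus + minus
  irs <- ifelse(total > 0L, plus / total, NA_real_)
  data.frame(ies_id = annotations$ies_id, ies_plus = as.integer(plus),
             ies_minus = as.integer(minus), irs = irs,
             sample = sample_label, stringsAsFactors = FALSE)
}

#' Histogram of retention scores
#'
#' Bins defined scores over `[0, 1]` with right-closed final bin; records
#' with undefined IRS are excluded and reported via the `n_undefined`
#' attribute.
#'
#' @param records Output of [compute_irs()].
#' @param bin_width Bin width; must divide 1 evenly.
#' @return Data.frame `bin_low`, `bin_high`, `count`, with attribute
#'   `n_undefined`.
#' @export
irs_histogram <- function(records, bin_width = 0.02) {
  nb <- round(1 / bin_width)
  if (abs(nb * bin_width - 1) > 1e-9)
    stop("bin_width must divide 1 evenly", call. = FALSE)
  x <- records$irs
  n_undef <- sum(is.na(x))
  x <- x[!is.na(x)]
  idx <- pmin(floor(x / bin_width) + 1L, nb)   # right-closed final bin
  counts <- as.integer(table(factor(idx, levels = seq_len(nb))))
  out <- data.frame(bin_low = (seq_len(nb) - 1L) * bin_width,
                    bin_high = seq_len(nb) * bin_width, count = counts)
  attr(out, "n_undefined") <- n_undef
  out
}
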