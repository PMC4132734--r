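#' Extract within-read deletions from MAC-space alignments
#'
#' Walks each alignment's CIGAR and reports every deletion operation whose
#' length lies within `[min_len, max_len]` (default 5 bp to 10 kb). A
#' deletion whose deleted reference span contains `N` is flagged via
#' `contains_n` and excluded from downstream counting.
#'
#' @param reads Read data.frame in MAC space with `scaffold`, `start`,
#'   `cigar`, `qname`.
#' @param mac_genome Named character vector of MAC scaffolds.
#' @param min_len,max_len Deletion length bounds in bp.
#' @return Data.frame `qname`, `scaffold`, `del_start`, `del_end` (0-based
#'   half-open, as reported by the aligner), `length`, `contains_n`.
#' @export
extract_deletions <- function(reads, mac_genome, min_len = 5L,
                              max_len = 10000L) {
  has_del <- grepl("D", reads$cigar, fixed = TRUE)
  idx <- which(has_del)
  out <- list()
  k <- 0L
  for (i in idx) {
    ops <- cigar_ops(reads$cigar[i])
    p <- reads$start[i]
    for (r in seq_len(nrow(ops))) {
      if (ops$op[r] %in% c("M", "=", "X")) {
        p <- p + ops$len[r]
      } else if (ops$op[r] %in% c("D", "N")) {
        if (ops$len[r] >= min_len && ops$len[r] <= max_len) {
          k <- k + 1L
          out[[k]] <- list(qname = reads$qname[i],
                           scaffold = reads$scaffold[i],
                           del_start = p, del_end = p + ops$len[r])
        }
        p <- p + ops$len[r]
      }
    }
  }
  if (k == 0L)
    return(data.frame(qname = character(0), scaffold = character(0),
                      del_start = integer(0), del_end = integer(0),
                      length = integer(0), contains_n = logical(0),
                      stringsAsFactors = FALSE))
  df <- data.frame(qname = vapply(out, `[[`, character(1), "qname"),
                   scaffold = vapply(out, `[[`, character(1), "scaffold"),
                   del_start = as.integer(vapply(out, `[[`, numeric(1),
                                                 "del_start")),
                   del_end = as.integer(vapply(out, `[[`, numeric(1),
                                               "del_end")),
                   stringsAsFactors = FALSE)
  df$length <- df$del_end - df$del_start
  df$contains_n <- vapply(seq_len(nrow(df)), function(i)
    grepl("N", ss0(mac_genome[[df$scaffold[i]]], df$del_start[i],
                   df$del_end[i]), fixed = TRUE), logical(1))
  df
}

#' Canonically realign a deletion against the reference
#'
#' A deletion's placement is ambiguous whenever the base entering one end of
#' the deleted segment equals the base leaving the other; all such
#' shift-equivalent placements describe the same alternative sequence. This
#' function enumerates every placement and returns the leftmost one whose
#' deleted segment is TA-bounded. Two notions of TA-bounded are supported:
#' \describe{
#'   \item{`"ta_ta"` (default)}{the deleted segment starts with `TA` and ends
#'     with `TA`.}
#'   \item{`"excision"`}{the deleted segment starts with `TA` and the two
#'     reference bases immediately following it are `TA` (the junction TA
#'     retained by IES-like excision).}
#' }
#'
#' @param mac_genome Named character vector of MAC scaffolds.
#' @param scaffold Scaffold name.
#' @param del_start,del_end 0-based half-open deleted span as reported.
#' @param mode TA-boundary rule, `"ta_ta"` or `"excision"`.
#' @return List `del_start`, `del_end` (canonical placement: leftmost
#'   TA-bounded equivalent, or the leftmost equivalent placement when none is
#'   TA-bounded) and `ta_bounded` flag.
#' @export
#' @examples
#' g <- c(chr = "GGTACCCCTAGG")
#' realign_deletion(g, "chr", 2, 10)   # TA-bounded as reported
realign_deletion <- function(mac_genome, scaffold, del_start, del_end,
                             mode = c("ta_ta", "excision")) {
  mode <- match.arg(mode)
  ref <- mac_genome[[scaffold]]
  n <- nchar(ref)
  s <- as.integer(del_start)
  e <- as.integer(del_end)
  ## maximally left-shifted equivalent placement
  while (s > 0L && substr(ref, s, s) == substr(ref, e, e)) {
    s <- s - 1L; e <- e - 1L
  }
  leftmost <- c(s, e)
  ## walk right through all equivalent placements, take leftmost TA-bounded
  repeat {
    ok <- switch(mode,
      ta_ta = ss0(ref, s, s + 2L) == "TA" &&
        ss0(ref, e - 2L, e) == "TA",
      excision = ss0(ref, s, s + 2L) == "TA" &&
        e + 2L <= n && ss0(ref, e, e + 2L) == "TA")
    if (ok)
      return(list(del_start = s, del_end = e, ta_bounded = TRUE))
    if (e < n && substr(ref, s + 1L, s + 1L) == substr(ref, e + 1L, e + 1L)) {
      s <- s + 1L; e <- e + 1L
    } else break
  }
  ## no TA-bounded placement: canonicalise to the leftmost equivalent one
  list(del_start = leftmost[1], del_end = leftmost[2], ta_bounded = FALSE)
}

#' Realign, filter and merge a raw deletion set into TA-indels
#'
#' Applies [realign_deletion()] to every raw deletion, keeps TA-bounded ones
#' not flagged for `N` content, and merges identical canonical coordinates,
#' accumulating supporting read counts.
#'
#' @param deletions Output of [extract_deletions()].
#' @param mac_genome Named character vector of MAC scaffolds.
#' @param mode TA-boundary rule (see [realign_deletion()]).
#' @return Data.frame `scaffold`, `del_start`, `del_end`, `length`,
#'   `read_count`; attribute `n_reads_with_taindel` gives the read-level
#'   count before merging.
#' @export
collect_taindels <- function(deletions, mac_genome, mode = "ta_ta") {
  if (nrow(deletions) == 0L)
    return(structure(data.frame(scaffold = character(0),
                                del_start = integer(0), del_end = integer(0),
                                length = integer(0), read_count = integer(0),
                                stringsAsFactors = FALSE),
                     n_reads_with_taindel = 0L))
  can <- vapply(seq_len(nrow(deletions)), function(i) {
    r <- realign_deletion(mac_genome, deletions$scaffold[i],
                          deletions$del_start[i], deletions$del_end[i],
                          mode = mode)
    c(r$del_start, r$del_end, as.integer(r$ta_bounded))
  }, numeric(3))
  keep <- can[3, ] == 1 & !deletions$contains_n
  df <- data.frame(scaffold = deletions$scaffold[keep],
                   del_start = as.integer(can[1, keep]),
                   del_end = as.integer(can[2, keep]),
                   stringsAsFactors = FALSE)
  n_reads <- nrow(df)
  if (n_reads == 0L)
    return(structure(data.frame(scaffold = character(0),
                                del_start = integer(0), del_end = integer(0),
                                length = integer(0), read_count = integer(0),
                                stringsAsFactors = FALSE),
                     n_reads_with_taindel = 0L))
  key <- paste(df$scaffold, df$del_start, df$del_end, sep = ":")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- strsplit(agg$key, ":", fixed = TRUE)
  out <- data.frame(scaffold = vapply(parts, `[`, character(1), 1L),
                    del_start = as.integer(vapply(parts, `[`, character(1), 2L)),
                    del_end = as.integer(vapply(parts, `[`, character(1), 3L)),
                    read_count = agg$Freq, stringsAsFactors = FALSE)
  out$length <- out$del_end - out$del_start
  out <- out[order(out$scaffold, out$del_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out[, c("scaffold", "del_start", "del_end", "length",
                    "read_count")],
            n_reads_with_taindel = n_reads)
}

#' Classify a TA-indel as cryptic or alternative-boundary
#'
#' A canonical TA-bounded deletion is `alternative_boundary` when one of its
#' endpoints coincides (within `tol`) with an annotated IES junction on the
#' MAC genome — the excision extended an IES beyond its usual boundary —
#' and `cryptic` otherwise (excision of MAC-destined DNA away from any IES).
#'
#' @param taindels Data.frame with `scaffold`, `del_start`, `del_end`.
#' @param annotations IES annotation data.frame (uses `mac_scaffold`,
#'   `mac_junction`).
#' @param tol Matching tolerance in bp (default exact).
#' @return The input with a `klass` column added.
#' @export
classify_taindel <- function(taindels, annotations, tol = 0L) {
  klass <- rep("cryptic", nrow(taindels))
  for (sc in unique(taindels$scaffold)) {
    j <- annotations$mac_junction[annotations$mac_scaffold == sc]
    ri <- which(taindels$scaffold == sc)
    if (length(j) == 0L || length(ri) == 0L) next
    for (i in ri) {
      ## deletion starting at the junction TA or ending at its right edge
      if (min(abs(j - taindels$del_start[i])) <= tol ||
          min(abs((j + 2L) - taindels$del_end[i])) <= tol)
        klass[i] <- "alternative_boundary"
    }
  }
  taindels$klass <- klass
  taindels
}

#' Normalise TA-indel read counts to reads per million mapped
#'
#' @param taindel_read_count Number of reads carrying a TA-indel.
#' @param mapped_read_count Total mapped reads in the sample.
#' @return Reads with TA-indels per million mapped reads.
#' @export
normalize_taindels <- function(taindel_read_count, mapped_read_count) {
  if (any(mapped_read_count <= 0))
    stop("mapped read count must be positive", call. = FALSE)
  1e6 * taindel_read_count / mapped_read_count
}

#' Per-class TA-indel length histogram
#'
#' Tallies canonical TA-indel lengths (one-TA convention: `del_end -
#' del_start`) per class.
#'
#' @param taindels Classified TA-indel data.frame (see
#'   [classify_taindel()]).
#' @param weight Count unit: `"events"` (merged deletions) or `"reads"`
#'   (weighted by `read_count`).
#' @return Data.frame `length`, `klass`, `count`.
#' @export
taindel_length_histogram <- function(taindels, weight = c("events", "reads")) {
  weight <- match.arg(weight)
  if (nrow(taindels) == 0L)
    return(data.frame(length = integer(0), klass = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  w <- if (weight == "reads" && !is.null(taindels$read_count))
    taindels$read_count else rep(1L, nrow(taindels))
  agg <- aggregate(w, by = list(length = taindels$length,
                                klass = taindels$klass), FUN = sum)
  names(agg)[3] <- "count"
  agg <- agg[order(agg$klass, agg$length), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
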