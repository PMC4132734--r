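#' Plant TA-bounded excision errors and emit supporting reads
#'
#' Adds read pairs from molecules carrying low-frequency excision errors
#' relative to the MAC reference: *cryptic* deletions remove a TA-bounded
#' MAC-destined segment away from any IES junction, while
#' *alternative-boundary* deletions start at an annotated IES junction TA and
#' extend to a nearby TA in the flanking MAC-destined DNA. Every planted
#' deletion's span starts with `TA` and ends with `TA` on the MAC reference;
#' the recorded truth coordinates are the canonical (leftmost TA-bounded
#' shift-equivalent) placement, while the emitted read CIGARs use the
#' aligner-style maximally left-shifted placement.
#'
#' @param genomes Output of [build_genomes()].
#' @param config A [sim_config()]; uses `n_cryptic`, `n_alt_boundary`,
#'   `error_length_range`, `reads_per_error`, `read_len`.
#' @param reads Optional data.frame of reads (from [simulate_dna_reads()]) to
#'   append to; with zero error counts it is returned unchanged.
#' @return A list with `reads` (input reads plus error-supporting pairs) and
#'   `deletions`, a data.frame of planted truth: `scaffold`, `del_start`,
#'   `del_end` (0-based half-open canonical placement), `length`, `klass`.
#' @export
plant_excision_errors <- function(genomes, config = genomes$truth$config,
                                  reads = NULL) {
  if (is.null(reads)) reads <- empty_reads_df()
  set.seed(derive_seed(config$seed, "errors"))
  ann <- genomes$annotations
  rl <- config$read_len
  lr <- config$error_length_range
  if (config$n_cryptic == 0L && config$n_alt_boundary == 0L)
    return(list(reads = reads, deletions = data.frame(
      scaffold = character(0), del_start = integer(0), del_end = integer(0),
      length = integer(0), klass = character(0), stringsAsFactors = FALSE)))

  del <- list()
  for (sc in names(genomes$mac)) {
    ta <- as.integer(gregexpr("TA", genomes$mac[[sc]], fixed = TRUE)[[1]]) - 1L
    ta <- ta[ta > 0L]
    del[[sc]] <- list(ta = ta, junc = sort(ann$mac_junction[ann$scaffold == sc]))
  }
  scs <- names(genomes$mac)

  sample1 <- function(x) x[sample.int(length(x), 1L)]
  plant_one <- function(klass) {
    for (try in seq_len(2000L)) {
      sc <- sample1(scs)
      info <- del[[sc]]
      d <- sample1(seq(lr[1], lr[2]))
      if (klass == "cryptic") {
        i <- sample1(info$ta)
        ## keep clear of real junctions so classification stays cryptic
        if (length(info$junc) &&
            min(abs(c(info$junc - i, info$junc - (i + d)))) < 2L * rl) next
      } else {
        if (length(info$junc) == 0L) stop("no IES junctions to extend",
                                          call. = FALSE)
        i <- sample1(info$junc)
      }
      if (i + d > nchar(genomes$mac[[sc]]) - rl || i < rl) next
      if (ss0(genomes$mac[[sc]], i + d - 2L, i + d) == "TA")
        return(list(scaffold = sc, del_start = i, del_end = i + d,
                    klass = klass))
    }
    stop(sprintf("no eligible TA pair in length range [%d, %d] for %s errors",
                 lr[1], lr[2], klass), call. = FALSE)
  }

  n_err <- config$n_cryptic + config$n_alt_boundary
  klasses <- c(rep("cryptic", config$n_cryptic),
               rep("alternative_boundary", config$n_alt_boundary))
  out <- vector("list", n_err)
  rrec <- vector("list", n_err)
  for (e in seq_len(n_err)) {
    pl <- plant_one(klasses[e])
    mac <- genomes$mac[[pl$scaffold]]
    can <- realign_deletion(genomes$mac, pl$scaffold, pl$del_start, pl$del_end)
    out[[e]] <- data.frame(scaffold = pl$scaffold,
                           del_start = can$del_start, del_end = can$del_end,
                           length = pl$del_end - pl$del_start,
                           klass = pl$klass, stringsAsFactors = FALSE)
    ## aligner-style maximally left-shifted placement for the emitted CIGARs
    s <- pl$del_start; epos <- pl$del_end
    while (s > 0L && ss0(mac, s - 1L, s) == ss0(mac, epos - 1L, epos)) {
      s <- s - 1L; epos <- epos - 1L
    }
    dlen <- epos - s
    nr <- config$reads_per_error
    left <- pmin(pmax(round(runif(nr, 10, rl - 10)), 5L), rl - 5L)
    rs <- s - left
    m <- data.frame(
      qname = sprintf("%s_err%04d_r%d/1", pl$scaffold, e, seq_len(nr)),
      pair_id = sprintf("%s_err%04d_r%d", pl$scaffold, e, seq_len(nr)),
      mate = 1L, scaffold = pl$scaffold, space = "mac",
      start = as.integer(rs), end = as.integer(rs + rl + dlen),
      cigar = sprintf("%dM%dD%dM", left, dlen, rl - left),
      strand = "+", seq = NA_character_, unique = TRUE,
      stringsAsFactors = FALSE)
    rrec[[e]] <- m
  }
  err_reads <- do.call(rbind, rrec)
  err_reads$seq <- read_sequences(err_reads, genomes)
  ## mates of error pairs: plain flanking reads downstream of the deletion
  mates <- err_reads
  mates$mate <- 2L
  mates$qname <- sub("/1$", "/2", mates$qname)
  mates$strand <- "-"
  mates$start <- mates$end + 50L
  mates$end <- mates$start + rl
  mates$cigar <- sprintf("%dM", rl)
  ok <- mates$end <= nchar(genomes$mac[mates$scaffold])
  mates <- mates[ok, , drop = FALSE]
  mates$seq <- read_sequences(mates, genomes)
  all_reads <- rbind(reads, err_reads, mates)
  rownames(all_reads) <- NULL
  deletions <- do.call(rbind, out)
  rownames(deletions) <- NULL
  list(reads = all_reads, deletions = deletions)
}
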