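#' Read and write reference genomes as FASTA
#'
#' Genomes are represented as named character vectors of uppercase sequences.
#' `read_fasta()` uppercases on input and rejects duplicate or empty records;
#' `write_fasta()` round-trips names and sequences exactly.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: named character vector; `write_fasta()`: `path`,
#'   invisibly.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nms <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nms))
    stop("duplicate scaffold name(s) in FASTA: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  if (any(Biostrings::width(x) == 0L))
    stop("empty FASTA record(s): ",
         paste(nms[Biostrings::width(x) == 0L], collapse = ", "),
         call. = FALSE)
  out <- toupper(as.character(x))
  names(out) <- nms
  out
}

#' @param genome Named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Write and load IES annotations as GFF3
#'
#' Annotations are stored 1-based inclusive in GFF3 covering the full IES
#' sequence including both boundary TAs, with attributes `ID`, `ies_length`
#' (one-TA convention), `mac_scaffold` and `mac_junction` (0-based).
#' `load_annotations()` validates every record against the genome pair:
#' the annotated MIC span must equal the stored sequence, start and end with
#' `TA`, and excising `[start, start + length)` must locally reproduce the
#' MAC scaffold around the junction.
#'
#' @param annotations IES annotation data.frame (see [build_genomes()]).
#' @param path GFF3 file path.
#' @return `write_gff3()`: `path` invisibly; `load_annotations()`: a
#'   validated annotation data.frame.
#' @export
write_gff3 <- function(annotations, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotations$scaffold,
    ranges = IRanges::IRanges(start = annotations$start + 1L,
                              end = annotations$start + annotations$length + 2L),
    strand = "+")
  gr$source <- "iesr"
  gr$type <- "internal_eliminated_sequence"
  gr$ID <- annotations$ies_id
  gr$ies_length <- annotations$length
  gr$mac_scaffold <- annotations$mac_scaffold
  gr$mac_junction <- annotations$mac_junction
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' @param mic_genome,mac_genome Named character vectors (MAC+IES and MAC).
#' @rdname write_gff3
#' @export
load_annotations <- function(path, mic_genome, mac_genome) {
  gr <- rtracklayer::import.gff3(path)
  ann <- data.frame(
    ies_id = as.character(gr$ID),
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    length = as.integer(as.character(gr$ies_length)),
    mac_scaffold = as.character(gr$mac_scaffold),
    mac_junction = as.integer(as.character(gr$mac_junction)),
    stringsAsFactors = FALSE)
  missing_sc <- setdiff(ann$scaffold, names(mic_genome))
  if (length(missing_sc) > 0L)
    stop("annotation on missing scaffold(s): ",
         paste(missing_sc, collapse = ", "), call. = FALSE)
  ann$sequence <- character(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    mic <- mic_genome[[ann$scaffold[i]]]
    ann$sequence[i] <- ss0(mic, ann$start[i],
                           ann$start[i] + ann$length[i] + 2L)
  }
  validate_annotations(ann, mic_genome, mac_genome)
  ann[, c("ies_id", "scaffold", "start", "length", "sequence",
          "mac_scaffold", "mac_junction")]
}

#' Validate IES annotations against a genome pair
#'
#' @param annotations Annotation data.frame with `sequence`.
#' @param mic_genome,mac_genome Named character vectors.
#' @param flank_check Number of flanking bases compared around the junction.
#' @return The annotations, invisibly; stops with a per-record report on
#'   failure.
#' @export
validate_annotations <- function(annotations, mic_genome, mac_genome,
                                 flank_check = 25L) {
  bad <- character(0)
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    mic <- mic_genome[[a$scaffold]]
    mac <- mac_genome[[a$mac_scaffold]]
    if (is.null(mac)) { bad <- c(bad, sprintf("%s: missing MAC scaffold %s",
                                              a$ies_id, a$mac_scaffold)); next }
    s <- ss0(mic, a$start, a$start + a$length + 2L)
    if (s != a$sequence) { bad <- c(bad, sprintf(
      "%s: MIC span does not match stored sequence", a$ies_id)); next }
    if (substr(s, 1, 2) != "TA" ||
        substr(s, nchar(s) - 1L, nchar(s)) != "TA") {
      bad <- c(bad, sprintf("%s: boundary is not TA", a$ies_id)); next
    }
    j <- a$mac_junction
    if (ss0(mac, j, j + 2L) != "TA") {
      bad <- c(bad, sprintf("%s: MAC junction is not TA", a$ies_id)); next
    }
    wl <- min(flank_check, a$start, j)
    wr <- min(flank_check, nchar(mac) - j)
    left_ok <- ss0(mic, a$start - wl, a$start) == ss0(mac, j - wl, j)
    right_ok <- ss0(mic, a$start + a$length, a$start + a$length + wr) ==
      ss0(mac, j, j + wr)
    if (!left_ok || !right_ok)
      bad <- c(bad, sprintf("%s: excision does not reproduce MAC junction",
                            a$ies_id))
  }
  if (length(bad) > 0L)
    stop("annotation validation failed:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  invisible(annotations)
}

#' Write IES annotations as BED 6+2
#'
#' BED columns: scaffold, 0-based start, end (full sequence incl. both TAs),
#' name, score (one-TA length), strand, mac_scaffold, mac_junction.
#'
#' @inheritParams write_gff3
#' @export
write_bed <- function(annotations, path) {
  df <- data.frame(annotations$scaffold, annotations$start,
                   annotations$start + annotations$length + 2L,
                   annotations$ies_id, annotations$length, "+",
                   annotations$mac_scaffold, annotations$mac_junction)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write alignment records as SAM
#'
#' Emits a minimal, valid SAM file (with `@SQ` headers) from a read
#' data.frame, suitable for inspection with standard tools. Reads in MAC
#' space are written against the MAC reference and reads in MAC+IES space
#' against the MAC+IES reference, so callers typically write the two spaces
#' to separate files via `space`.
#'
#' @param reads Read data.frame (see [simulate_dna_reads()]).
#' @param genome Named character vector the records are expressed against.
#' @param path Output path.
#' @param space Which reads to keep (`"mac"` or `"mic"`); `NULL` keeps all.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, genome, path, space = NULL) {
  if (!is.null(space)) reads <- reads[reads$space == space, , drop = FALSE]
  reads <- reads[order(reads$scaffold, reads$start), , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)))
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  seqf <- ifelse(is.na(reads$seq), "*",
                 ifelse(reads$strand == "-", revcomp(reads$seq), reads$seq))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  reads$qname, flag, reads$scaffold, reads$start + 1L,
                  ifelse(reads$unique, 60L, 0L), reads$cigar, seqf)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write reads as FASTQ
#'
#' Minus-strand reads are reverse-complemented; qualities are constant.
#'
#' @param reads Read data.frame with `qname`, `seq` and optionally `strand`.
#' @param path Output path (plain text).
#' @param mate Optional mate number filter (1 or 2) for paired output.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, mate = NULL) {
  if (!is.null(mate)) reads <- reads[reads$mate == mate, , drop = FALSE]
  seqs <- reads$seq
  if (!is.null(reads$strand))
    seqs <- ifelse(reads$strand == "-", revcomp(seqs), seqs)
  qual <- vapply(nchar(seqs), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  writeLines(paste0("@", reads$qname, "\n", seqs, "\n+\n", qual), path)
  invisible(path)
}

#' Keep only read pairs in which both mates map uniquely
#'
#' Retains reads whose mate is present in the stream and whose pair has both
#' mates flagged unique. Orphan reads (mate absent) are dropped and counted.
#' The operation is idempotent.
#'
#' @param reads Read data.frame with `pair_id`, `mate` and `unique`.
#' @return The filtered data.frame; the number of dropped orphans is attached
#'   as attribute `n_orphans` and multi-mapping pair losses as
#'   `n_nonunique_pairs`.
#' @export
filter_unique_pairs <- function(reads) {
  n_mates <- tapply(reads$mate, reads$pair_id,
                    function(m) length(unique(m)))
  paired <- names(n_mates)[n_mates == 2L]
  is_paired <- reads$pair_id %in% paired
  n_orphans <- sum(!is_paired)
  all_unique <- tapply(reads$unique, reads$pair_id, all)
  good <- names(all_unique)[all_unique]
  keep <- is_paired & reads$pair_id %in% good
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_orphans") <- n_orphans
  attr(out, "n_nonunique_pairs") <- sum(is_paired & !keep) %/% 2L
  out
}

#' Two-stage assignment of sRNA reads to MAC then MAC+IES
#'
#' Implements the two-stage mapping rule for developmental sRNA data: a read
#' with an exact match on the MAC genome is assigned to MAC space; a read
#' absent from MAC but present on the MAC+IES genome is assigned there.
#' Reads matching more than one location in their assigned reference are
#' dropped. Per-length totals over the small-RNA size range (15--35 nt
#' inclusive by default) are recorded for normalisation.
#'
#' @param mac_hits,mic_hits Data.frames of exact-match alignments (`qname`,
#'   `scaffold`, `start`, `end`, `length`, `n_hits`).
#' @param size_range Inclusive length bounds of counted size classes.
#' @return A data.frame of assigned reads with a `space` column; attributes
#'   `length_totals` (named per-length counts within `size_range`) and
#'   `normalization_total` (their sum).
#' @export
srna_two_stage_assign <- function(mac_hits, mic_hits,
                                  size_range = c(15L, 35L)) {
  mac_hits$space <- "mac"
  stage2 <- mic_hits[!(mic_hits$qname %in% mac_hits$qname), , drop = FALSE]
  if (nrow(stage2) > 0L) stage2$space <- "mic"
  else stage2$space <- character(0)
  assigned <- rbind(mac_hits, stage2)
  assigned <- assigned[assigned$n_hits == 1L, , drop = FALSE]
  rownames(assigned) <- NULL
  in_range <- assigned$length >= size_range[1] &
    assigned$length <= size_range[2]
  tab <- table(factor(assigned$length[in_range],
                      levels = size_range[1]:size_range[2]))
  totals <- setNames(as.integer(tab), names(tab))
  attr(assigned, "length_totals") <- totals
  attr(assigned, "normalization_total") <- sum(totals)
  assigned
}
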