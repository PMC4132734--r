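## Per-scaffold junction bookkeeping used by the fragment walker.
scaffold_junctions <- function(annotations, truth, scaffold) {
  idx <- which(annotations$scaffold == scaffold)
  idx <- idx[order(annotations$mac_junction[idx])]
  rho <- truth$rho$rho[match(annotations$ies_id[idx], truth$rho$ies_id)]
  list(J = annotations$mac_junction[idx],
       L = annotations$length[idx],
       ies_id = annotations$ies_id[idx],
       rho = rho,
       cumL = cumsum(as.numeric(annotations$length[idx])))
}

empty_reads_df <- function() {
  data.frame(qname = character(0), pair_id = character(0), mate = integer(0),
             scaffold = character(0), space = character(0),
             start = integer(0), end = integer(0), cigar = character(0),
             strand = character(0), seq = character(0), unique = logical(0),
             stringsAsFactors = FALSE)
}

#' Simulate paired-end DNA-seq reads with known per-IES retention
#'
#' Each fragment is anchored by a MAC-destined span `[s, s + f)` with `s`
#' uniform and `f` drawn from the insert-length model (floored at twice the
#' read length so the two mate windows never overlap). For every IES
#' junction strictly inside the span, the fragment's molecule retains the
#' IES with probability rho (the IES's true retention fraction) and has it
#' excised otherwise, independently per fragment; retained IES sequence is
#' inserted between the anchors. Mate 1 reads forward from `s`, mate 2 reads
#' backward from `s + f`. Reads containing retained IES sequence are
#' reported in MAC+IES ("mic") space; reads of purely MAC-destined content
#' are reported in MAC space, where crossing an excised junction is
#' seamless. Because both mates are anchored at MAC-destined coordinates,
#' the retained and excised forms of a junction expose informative windows
#' of identical width, so the number of IES+ reads among the informative
#' reads of an IES is binomial in rho.
#'
#' @param genomes Output of [build_genomes()] (uses `mac`, `mic`,
#'   `annotations`, `truth`).
#' @param config A [sim_config()]; `coverage`, `read_len`, `insert_mean`,
#'   `insert_sd` and `base_error_rate` are used.
#' @param sequences If `FALSE`, skip read-sequence reconstruction (alignment
#'   coordinates only; faster).
#' @return A data.frame of truth alignments, one row per read: `qname`,
#'   `pair_id`, `mate`, `scaffold`, `space` (`"mac"` or `"mic"`), `start`,
#'   `end` (0-based half-open aligned span in the assigned space), `cigar`,
#'   `strand`, `seq` (reference-oriented; `NA` if `sequences = FALSE`),
#'   `unique`.
#' @export
simulate_dna_reads <- function(genomes, config = genomes$truth$config,
                               sequences = TRUE) {
  set.seed(derive_seed(config$seed, "dna"))
  ann <- genomes$annotations
  truth <- genomes$truth
  rl <- config$read_len
  per_scaffold <- vector("list", length(genomes$mac))
  for (si in seq_along(genomes$mac)) {
    sc <- names(genomes$mac)[si]
    mac_len <- nchar(genomes$mac[[sc]])
    jx <- scaffold_junctions(ann, truth, sc)
    n_frag <- ceiling(config$coverage * mac_len / (2 * rl))
    flen <- pmax(2L * rl,
                 round(rnorm(n_frag, config$insert_mean, config$insert_sd)))
    flen <- pmin(flen, mac_len)
    s <- floor(runif(n_frag, 0, mac_len - flen + 1))
    n <- 2L * n_frag
    space <- character(n); start <- integer(n); end <- integer(n)
    cigar <- character(n); pair <- integer(n); mate <- integer(n)
    for (fi in seq_len(n_frag)) {
      blocks <- walk_fragment(s[fi], flen[fi], jx)
      tot <- sum(blocks$len)
      m1 <- mate_record(blocks, 0L, rl)
      m2 <- mate_record(blocks, tot - rl, tot)
      i1 <- 2L * fi - 1L; i2 <- 2L * fi
      space[i1] <- m1$space; start[i1] <- m1$start; end[i1] <- m1$end
      cigar[i1] <- m1$cigar
      space[i2] <- m2$space; start[i2] <- m2$start; end[i2] <- m2$end
      cigar[i2] <- m2$cigar
      pair[c(i1, i2)] <- fi; mate[i1] <- 1L; mate[i2] <- 2L
    }
    per_scaffold[[si]] <- data.frame(
      pair_id = sprintf("%s_frag%06d", sc, pair), mate = mate, scaffold = sc,
      space = space, start = start, end = end, cigar = cigar,
      strand = ifelse(mate == 1L, "+", "-"), stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, per_scaffold)
  if (is.null(reads) || nrow(reads) == 0L) return(empty_reads_df())
  reads$qname <- paste0(reads$pair_id, "/", reads$mate)
  reads$unique <- TRUE
  reads$seq <- NA_character_
  if (sequences) {
    reads$seq <- read_sequences(reads, genomes)
    if (config$base_error_rate > 0)
      reads$seq <- add_base_errors(reads$seq, config$base_error_rate)
  }
  rownames(reads) <- NULL
  reads[, c("qname", "pair_id", "mate", "scaffold", "space", "start", "end",
            "cigar", "strand", "seq", "unique")]
}

## Walk the MAC-destined span [s, s + flen), drawing per-fragment retention
## for each junction strictly inside it and inserting retained IES blocks in
## full. Returns parallel vectors of MIC-space blocks
## (mic_start, len, is_ies, mac_start) in molecule order.
walk_fragment <- function(s, flen, jx) {
  p <- s
  fend <- s + flen
  bl_start <- integer(8L); bl_len <- integer(8L)
  bl_ies <- logical(8L); bl_mac <- integer(8L)
  kb <- 0L
  k <- findInterval(s, jx$J) + 1L   # first junction with J > s (J == s is past)
  nj <- length(jx$J)
  repeat {
    next_j <- if (k <= nj && jx$J[k] < fend) jx$J[k] else fend
    mac_chunk <- next_j - p
    if (mac_chunk > 0) {
      cum <- if (k > 1L) jx$cumL[k - 1L] else 0
      kb <- kb + 1L
      bl_start[kb] <- as.integer(p + cum); bl_len[kb] <- as.integer(mac_chunk)
      bl_ies[kb] <- FALSE; bl_mac[kb] <- as.integer(p)
      p <- next_j
    }
    if (p >= fend) break
    ## at junction jx$J[k] inside the span: decide retention for this molecule
    if (runif(1) < jx$rho[k]) {
      a <- jx$J[k] + (if (k > 1L) jx$cumL[k - 1L] else 0)
      kb <- kb + 1L
      bl_start[kb] <- as.integer(a); bl_len[kb] <- jx$L[k]
      bl_ies[kb] <- TRUE; bl_mac[kb] <- NA_integer_
    }
    k <- k + 1L
  }
  list(start = bl_start[seq_len(kb)], len = bl_len[seq_len(kb)],
       is_ies = bl_ies[seq_len(kb)], mac = bl_mac[seq_len(kb)])
}

## Extract the blocks covering molecule offsets [from, to) and build one
## mate's alignment record (list: space, start, end, cigar).
mate_record <- function(blocks, from, to) {
  offs <- cumsum(c(0L, blocks$len))
  nb <- length(blocks$len)
  sel <- which(offs[seq_len(nb)] < to & offs[-1] > from)
  st <- blocks$start[sel]; ln <- blocks$len[sel]
  ies <- blocks$is_ies[sel]; mc <- blocks$mac[sel]
  lead <- from - offs[sel[1]]
  if (lead > 0) {
    st[1] <- st[1] + lead
    if (!is.na(mc[1])) mc[1] <- mc[1] + lead
    ln[1] <- ln[1] - lead
  }
  excess <- offs[sel[length(sel)] + 1L] - to
  if (excess > 0) ln[length(ln)] <- ln[length(ln)] - excess
  if (any(ies)) {
    ## MAC+IES space: M blocks separated by D gaps at excised IESs
    nbl <- length(st)
    ops <- character(2L * nbl)
    ko <- 0L
    for (i in seq_len(nbl)) {
      if (i > 1L) {
        gap <- st[i] - (st[i - 1L] + ln[i - 1L])
        if (gap > 0) { ko <- ko + 1L; ops[ko] <- sprintf("%dD", gap) }
      }
      ko <- ko + 1L; ops[ko] <- sprintf("%dM", ln[i])
    }
    list(space = "mic", start = st[1], end = st[nbl] + ln[nbl],
         cigar = merge_cigar(ops[seq_len(ko)]))
  } else {
    ## pure MAC-destined content: contiguous in MAC space
    rl <- to - from
    list(space = "mac", start = mc[1], end = mc[1] + rl,
         cigar = sprintf("%dM", rl))
  }
}

merge_cigar <- function(ops) {
  if (length(ops) <= 1L) return(paste(ops, collapse = ""))
  lens <- as.integer(sub("[MD]$", "", ops))
  typ <- sub("^[0-9]+", "", ops)
  out_len <- integer(0); out_typ <- character(0)
  for (i in seq_along(ops)) {
    if (length(out_typ) > 0 && out_typ[length(out_typ)] == typ[i]) {
      out_len[length(out_len)] <- out_len[length(out_len)] + lens[i]
    } else {
      out_len <- c(out_len, lens[i]); out_typ <- c(out_typ, typ[i])
    }
  }
  paste0(out_len, out_typ, collapse = "")
}

## Reconstruct read sequences from the assigned space and CIGAR.
read_sequences <- function(reads, genomes) {
  n <- nrow(reads)
  seqs <- character(n)
  simple <- !grepl("D", reads$cigar, fixed = TRUE)
  for (sc in unique(reads$scaffold)) {
    for (sp in c("mac", "mic")) {
      ref <- if (sp == "mic") genomes$mic[[sc]] else genomes$mac[[sc]]
      sel <- reads$scaffold == sc & reads$space == sp
      easy <- sel & simple
      seqs[easy] <- substr(rep(ref, sum(easy)), reads$start[easy] + 1L,
                           reads$end[easy])
      hard <- which(sel & !simple)
      for (i in hard)
        seqs[i] <- cigar_query_seq(ref, reads$start[i], reads$cigar[i])
    }
  }
  seqs
}

## Query-side sequence implied by an M/D CIGAR anchored at ref pos `start`.
cigar_query_seq <- function(ref, start, cigar) {
  ops <- cigar_ops(cigar)
  p <- start
  parts <- character(0)
  for (i in seq_len(nrow(ops))) {
    if (ops$op[i] == "M") {
      parts <- c(parts, ss0(ref, p, p + ops$len[i]))
      p <- p + ops$len[i]
    } else if (ops$op[i] %in% c("D", "N")) {
      p <- p + ops$len[i]
    }
  }
  paste(parts, collapse = "")
}

cigar_ops <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  data.frame(len = as.integer(sub(".$", "", toks)),
             op = sub("^[0-9]+", "", toks), stringsAsFactors = FALSE)
}

add_base_errors <- function(seqs, rate) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (length(hit) == 0L) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(DNA_BASES, b), 1L), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
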