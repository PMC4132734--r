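#' Simulate scnRNA and iesRNA reads
#'
#' scnRNAs are fixed-length (default 25 nt) windows placed uniformly over the
#' MAC+IES scaffolds, so a fraction of them spans IES boundaries into
#' MAC-destined sequence. iesRNAs have lengths drawn over 21--31 nt (mode
#' 27 nt), lie entirely within IES intervals (a length longer than its IES is
#' resampled), and accumulate towards the two IES ends according to the
#' end-accumulation weight. Per-IES iesRNA counts are Poisson with a mean
#' that grows linearly in the IES's true retention fraction rho (see
#' [srna_model()]).
#'
#' @param genomes Output of [build_genomes()].
#' @param config A [sim_config()]; its `srna` model and `seed` are used.
#' @param sequences If `FALSE`, skip sequence extraction.
#' @return A data.frame of truth alignments in MAC+IES ("mic") space:
#'   `qname`, `class` (`"scnRNA"`/`"iesRNA"`), `scaffold`, `start`, `end`
#'   (0-based half-open), `length`, `ies_id` (`NA` for scnRNAs), `seq`.
#' @export
simulate_srna_reads <- function(genomes, config = genomes$truth$config,
                                sequences = TRUE) {
  set.seed(derive_seed(config$seed, "srna"))
  sm <- config$srna
  ann <- genomes$annotations
  truth <- genomes$truth

  ## scnRNAs: uniform fixed-length windows over the MAC+IES genome
  scn <- vector("list", length(genomes$mic))
  for (si in seq_along(genomes$mic)) {
    sc <- names(genomes$mic)[si]
    mic_len <- nchar(genomes$mic[[sc]])
    n <- ceiling(sm$scn_depth * mic_len / sm$scn_length)
    st <- floor(runif(n, 0, mic_len - sm$scn_length + 1))
    scn[[si]] <- data.frame(class = "scnRNA", scaffold = sc,
                            start = as.integer(st),
                            end = as.integer(st + sm$scn_length),
                            length = sm$scn_length, ies_id = NA_character_,
                            stringsAsFactors = FALSE)
  }
  scn <- do.call(rbind, scn)

  ## iesRNAs: per-IES Poisson counts, lengths 21-31 (mode 27), end-weighted
  ies <- NULL
  if (nrow(ann) > 0L) {
    rho <- truth$rho$rho[match(ann$ies_id, truth$rho$ies_id)]
    mu <- sm$abundance_scale * ann$length *
      (sm$abundance_base + sm$abundance_slope * rho)
    counts <- rpois(nrow(ann), mu)
    tot <- sum(counts)
    if (tot > 0L) {
      ai <- rep(seq_len(nrow(ann)), counts)
      full_len <- ann$length[ai] + 2L     # IES interval incl. both TAs
      len <- sample(sm$ies_lengths, tot, replace = TRUE,
                    prob = sm$ies_length_weights)
      bad <- which(len > full_len)
      while (length(bad) > 0L) {          # resample lengths too long to fit
        len[bad] <- sample(sm$ies_lengths, length(bad), replace = TRUE,
                           prob = sm$ies_length_weights)
        bad <- bad[len[bad] > full_len[bad]]
      }
      maxoff <- full_len - len
      u <- runif(tot)
      off <- integer(tot)
      near <- u < sm$end_weight
      ## end-proximal starts: within end_window of either IES end
      w <- pmin(sm$end_window, maxoff)
      side <- runif(tot) < 0.5
      off[near & side] <- floor(runif(sum(near & side)) *
                                  (w[near & side] + 1))
      off[near & !side] <- maxoff[near & !side] -
        floor(runif(sum(near & !side)) * (w[near & !side] + 1))
      off[!near] <- floor(runif(sum(!near)) * (maxoff[!near] + 1))
      st <- ann$start[ai] + off
      ies <- data.frame(class = "iesRNA", scaffold = ann$scaffold[ai],
                        start = as.integer(st), end = as.integer(st + len),
                        length = as.integer(len), ies_id = ann$ies_id[ai],
                        stringsAsFactors = FALSE)
    }
  }
  reads <- rbind(scn, ies)
  reads$qname <- sprintf("srna_%07d", seq_len(nrow(reads)))
  reads$seq <- NA_character_
  if (sequences) {
    for (sc in unique(reads$scaffold)) {
      sel <- reads$scaffold == sc
      reads$seq[sel] <- substr(rep(genomes$mic[[sc]], sum(sel)),
                               reads$start[sel] + 1L, reads$end[sel])
    }
  }
  rownames(reads) <- NULL
  reads[, c("qname", "class", "scaffold", "start", "end", "length", "ies_id",
            "seq")]
}

#' Project simulated sRNA reads onto MAC and MAC+IES alignment tables
#'
#' Emulates the alignment step of a two-stage sRNA mapping protocol using the
#' simulator's ground truth: a read whose span contains no IES-exclusive base
#' (positions `[start, start + length)` of any annotation) would match the
#' MAC genome and is reported there with lifted coordinates; all other reads
#' are reported on the MAC+IES genome. Reads lying entirely within an IES
#' whose sequence occurs at more than one locus are flagged as multi-mapping
#' (`n_hits = 2`).
#'
#' @param srna Output of [simulate_srna_reads()].
#' @param annotations IES annotation data.frame.
#' @return A list of two data.frames, `mac` and `mic`, each with `qname`,
#'   `scaffold`, `start`, `end`, `length`, `n_hits`.
#' @export
srna_truth_alignments <- function(srna, annotations) {
  ann <- annotations
  dup_seqs <- unique(ann$sequence[duplicated(ann$sequence)])
  in_mac <- rep(TRUE, nrow(srna))
  multi <- rep(FALSE, nrow(srna))
  for (sc in unique(srna$scaffold)) {
    ai <- which(ann$scaffold == sc)
    ri <- which(srna$scaffold == sc)
    if (length(ai) == 0L || length(ri) == 0L) next
    ## IES-exclusive interval: [start, start + length) in MIC space
    excl <- IRanges::IRanges(start = ann$start[ai] + 1L,
                             width = ann$length[ai])
    rr <- IRanges::IRanges(start = srna$start[ri] + 1L,
                           width = srna$length[ri])
    ov <- IRanges::overlapsAny(rr, excl)
    in_mac[ri][ov] <- FALSE
    if (length(dup_seqs) > 0L) {
      dup_ai <- ai[ann$sequence[ai] %in% dup_seqs]
      if (length(dup_ai) > 0L) {
        full <- IRanges::IRanges(start = ann$start[dup_ai] + 1L,
                                 width = ann$length[dup_ai] + 2L)
        within <- IRanges::overlapsAny(rr, full, type = "within")
        multi[ri][within] <- TRUE
      }
    }
  }
  lift <- lift_mic_to_mac(srna, ann)
  mac_tab <- data.frame(qname = srna$qname[in_mac],
                        scaffold = srna$scaffold[in_mac],
                        start = lift$start[in_mac], end = lift$end[in_mac],
                        length = srna$length[in_mac],
                        n_hits = 1L + as.integer(multi[in_mac]),
                        stringsAsFactors = FALSE)
  mic_tab <- data.frame(qname = srna$qname[!in_mac],
                        scaffold = srna$scaffold[!in_mac],
                        start = srna$start[!in_mac], end = srna$end[!in_mac],
                        length = srna$length[!in_mac],
                        n_hits = 1L + as.integer(multi[!in_mac]),
                        stringsAsFactors = FALSE)
  list(mac = mac_tab, mic = mic_tab)
}

## MAC coordinates of MIC-space spans containing only MAC-destined bases.
lift_mic_to_mac <- function(reads, ann) {
  start <- rep(NA_integer_, nrow(reads))
  end <- rep(NA_integer_, nrow(reads))
  for (sc in unique(reads$scaffold)) {
    ai <- which(ann$scaffold == sc)
    ri <- which(reads$scaffold == sc)
    if (length(ri) == 0L) next
    if (length(ai) == 0L) {
      start[ri] <- reads$start[ri]; end[ri] <- reads$end[ri]
      next
    }
    o <- order(ann$start[ai]); ai <- ai[o]
    mic_end <- ann$start[ai] + ann$length[ai]   # end of IES-exclusive block
    cumL <- cumsum(as.numeric(ann$length[ai]))
    k <- findInterval(reads$start[ri], mic_end)
    shift <- ifelse(k > 0, cumL[pmax(k, 1L)] * (k > 0), 0)
    start[ri] <- as.integer(reads$start[ri] - shift)
    end[ri] <- as.integer(start[ri] + (reads$end[ri] - reads$start[ri]))
  }
  list(start = start, end = end)
}
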