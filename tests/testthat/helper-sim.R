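## Shared small fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

## Small genome + reads used by several modules (1 scaffold, 30 IESs).
small_sim <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- sim_config(seed = 42L, n_scaffolds = 1, scaffold_len = 20000,
                      n_ies = 30, coverage = 30, n_identical_pairs = 2)
    g <- build_genomes(cfg)
    reads <- simulate_dna_reads(g, cfg)
    .fixtures$small <- list(cfg = cfg, genomes = g, reads = reads)
  }
  .fixtures$small
}

## One-row read record for classifier unit tests.
read_rec <- function(scaffold, space, start, end) {
  data.frame(qname = "r", pair_id = "r", mate = 1L, scaffold = scaffold,
             space = space, start = start, end = end,
             cigar = sprintf("%dM", end - start), strand = "+",
             seq = NA_character_, unique = TRUE, stringsAsFactors = FALSE)
}

## Minimal annotation row (consistent coordinates, synthetic sequence).
ann_rec <- function(ies_id = "ies1", scaffold = "s", start = 100L,
                    length = 30L, mac_junction = 100L,
                    sequence = NULL) {
  if (is.null(sequence))
    sequence <- paste0("TA", paste(rep("G", length - 2L), collapse = ""),
                       "TA")
  data.frame(ies_id = ies_id, scaffold = scaffold, start = start,
             length = length, sequence = sequence, mac_scaffold = scaffold,
             mac_junction = mac_junction, stringsAsFactors = FALSE)
}

## Independent brute-force quasi-IES oracle: substring scan plus full
## enumeration over all (left, right) index pairs.
brute_quasi <- function(genome, motif, min_len = 26L, max_len = 150L) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  rows <- list()
  for (sc in names(genome)) {
    s <- genome[[sc]]
    n <- nchar(s)
    if (n < 10L) next
    starts <- seq_len(n - 4L)
    words <- substring(s, starts, starts + 4L)
    left <- starts[words == motif] - 1L     # 0-based
    right_end <- starts[words == rc] + 4L   # 0-based exclusive end j
    for (i in left) for (j in right_end) {
      len <- j - 2L - i
      if (len >= min_len && len <= max_len)
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = sc, start = i, length = len, motif = motif,
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(scaffold = character(0), start = integer(0),
                      length = integer(0), motif = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$scaffold, out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_genome <- function(n_scaffolds, len,
                          probs = c(A = 0.4, C = 0.1, G = 0.1, T = 0.4)) {
  g <- vapply(seq_len(n_scaffolds), function(i)
    paste(sample(names(probs), len, replace = TRUE, prob = probs),
          collapse = ""), character(1))
  names(g) <- sprintf("rs_%d", seq_len(n_scaffolds))
  g
}
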