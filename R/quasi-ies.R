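#' Scan a genome for quasi-IESs flanked by perfect terminal inverted repeats
#'
#' A quasi-IES for motif `m` (length 5, starting `TA`, e.g. `TATAG`) is a
#' segment whose 5' end carries `m` and whose 3' end carries
#' `reverse-complement(m)` as a perfect terminal inverted repeat. For an
#' occurrence of the motif at `[i, i+5)` and of its reverse complement at
#' `[j-5, j)`, the one-TA length is `j - 2 - i`, so that the final two bases
#' of the inverted motif are the retained junction TA, matching the IES
#' length convention. All occurrences, including overlapping and nested
#' ones, are reported.
#'
#' @param genome Named character vector of scaffolds.
#' @param motif 5-base motif beginning with `TA`.
#' @param min_len,max_len One-TA length bounds in bp.
#' @return Data.frame `scaffold`, `start` (0-based, first base of the left
#'   TA), `length` (one-TA), `motif`.
#' @export
#' @examples
#' scan_quasi_ies(c(s = "GGTATAGAAAACTATAGG"), "TATAG", min_len = 5,
#'                max_len = 50)
scan_quasi_ies <- function(genome, motif, min_len = 26L, max_len = 150L) {
  if (nchar(motif) != 5L || substr(motif, 1, 2) != "TA")
    stop("motif must be 5 bases long and start with TA", call. = FALSE)
  rc <- revcomp(motif)
  out <- list()
  for (sc in names(genome)) {
    left <- find_all(genome[[sc]], motif)        # 0-based starts of motif
    right <- find_all(genome[[sc]], rc)          # 0-based starts of revcomp
    if (length(left) == 0L || length(right) == 0L) next
    right_end <- right + 5L                      # exclusive end j
    ## one-TA length j - 2 - i in [min_len, max_len]
    ## => j in [i + min_len + 2, i + max_len + 2]
    lo <- findInterval(left + min_len + 2L - 1L, right_end) + 1L
    hi <- findInterval(left + max_len + 2L, right_end)
    n_hits <- pmax(hi - lo + 1L, 0L)
    if (sum(n_hits) == 0L) next
    ii <- rep(seq_along(left), n_hits)
    jj <- unlist(lapply(which(n_hits > 0L), function(k) lo[k]:hi[k]))
    out[[sc]] <- data.frame(scaffold = sc, start = left[ii],
                            length = right_end[jj] - 2L - left[ii],
                            motif = motif, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(scaffold = character(0), start = integer(0),
                      length = integer(0), motif = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$scaffold, res$start, res$length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## All 0-based start positions of `pattern` in `x`, overlapping included.
find_all <- function(x, pattern) {
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(x))
  as.integer(Biostrings::start(hits)) - 1L
}

#' Per-length counts of quasi-IESs
#'
#' @param quasi Output of [scan_quasi_ies()].
#' @return Data.frame `length`, `count` (exact tally of one-TA lengths).
#' @export
quasi_length_profile <- function(quasi) {
  if (nrow(quasi) == 0L)
    return(data.frame(length = integer(0), count = integer(0)))
  tab <- table(quasi$length)
  data.frame(length = as.integer(names(tab)), count = as.integer(tab))
}

#' Expected quasi-IES counts per length
#'
#' Computes the number of quasi-IESs expected per one-TA length under a null
#' model of the genome sequence, either in closed form from independent
#' sites with the genome's base composition, or as the mean count over
#' dinucleotide-preserving shuffles of each scaffold.
#'
#' @param genome Named character vector of scaffolds.
#' @param motif 5-base motif beginning with `TA`.
#' @param lengths Integer vector of one-TA lengths to evaluate.
#' @param method `"closed_form"` or `"shuffle"`.
#' @param n_shuffles Number of shuffled genomes for `method = "shuffle"`.
#' @param seed RNG seed for shuffling.
#' @return Data.frame `length`, `expected`.
#' @export
expected_quasi_counts <- function(genome, motif, lengths,
                                  method = c("closed_form", "shuffle"),
                                  n_shuffles = 20L, seed = 1L) {
  method <- match.arg(method)
  if (nchar(motif) != 5L || substr(motif, 1, 2) != "TA")
    stop("motif must be 5 bases long and start with TA", call. = FALSE)
  if (method == "closed_form") {
    counts <- base_composition(genome)
    q <- counts / sum(counts)
    p_m <- prod(q[strsplit(motif, "")[[1]]])
    p_rc <- prod(q[strsplit(revcomp(motif), "")[[1]]])
    expected <- vapply(lengths, function(l) {
      ## footprint i .. i + l + 2 (j exclusive); positions per scaffold
      npos <- sum(pmax(nchar(genome) - (l + 2L) + 1L, 0L))
      npos * p_m * p_rc
    }, numeric(1))
    return(data.frame(length = as.integer(lengths), expected = expected))
  }
  if (n_shuffles < 1L)
    stop("n_shuffles must be >= 1 for method = \"shuffle\"", call. = FALSE)
  set.seed(seed)
  acc <- matrix(0, nrow = length(lengths), ncol = n_shuffles)
  for (r in seq_len(n_shuffles)) {
    shuf <- vapply(genome, shuffle_dinucleotide, character(1))
    names(shuf) <- names(genome)
    q <- scan_quasi_ies(shuf, motif, min_len = min(lengths),
                        max_len = max(lengths))
    tab <- table(factor(q$length, levels = lengths))
    acc[, r] <- as.integer(tab)
  }
  data.frame(length = as.integer(lengths), expected = rowMeans(acc))
}

base_composition <- function(genome) {
  tot <- c(A = 0, C = 0, G = 0, T = 0)
  for (s in genome) {
    tab <- table(strsplit(s, "")[[1]])
    for (b in DNA_BASES)
      if (!is.na(tab[b])) tot[b] <- tot[b] + tab[b]
  }
  tot
}

## Dinucleotide-preserving shuffle via a random Eulerian walk on the
## base-transition multigraph (Altschul-Erickson style).
shuffle_dinucleotide <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n < 3L) return(s)
  succ <- split(ch[-1], factor(ch[-n], levels = unique(ch)))
  ## shuffle successor lists, then rebuild by walking; retry on dead ends
  for (attempt in 1:50) {
    bag <- lapply(succ, sample)
    ptr <- setNames(rep(1L, length(bag)), names(bag))
    out <- character(n)
    out[1] <- ch[1]
    cur <- ch[1]
    ok <- TRUE
    for (i in 2:n) {
      lst <- bag[[cur]]
      p <- ptr[[cur]]
      if (is.null(lst) || p > length(lst)) { ok <- FALSE; break }
      nxt <- lst[p]
      ptr[[cur]] <- p + 1L
      out[i] <- nxt
      cur <- nxt
    }
    if (ok) return(paste(out, collapse = ""))
  }
  ## fall back to the identity if no complete walk was found
  s
}
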