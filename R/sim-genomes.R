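#' Build paired synthetic MAC and MAC+IES genomes
#'
#' Generates random MAC (somatic) scaffolds, draws IES lengths and sequences,
#' and inserts each IES at a TA site of the MAC scaffold to form the MAC+IES
#' (germline-like, "MIC") scaffolds. Insertion is arranged so that excising
#' `[start, start + length)` from the MIC scaffold reproduces the MAC
#' scaffold exactly: the right boundary TA of the IES is the retained MAC
#' junction TA. Optionally duplicates a configurable number of IES sequences
#' verbatim at a second locus.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{mac}{named character vector of MAC scaffolds}
#'     \item{mic}{named character vector of MAC+IES scaffolds}
#'     \item{annotations}{data.frame of IES annotations: `ies_id`, `scaffold`,
#'       `start` (0-based, first base of the left TA in MIC space), `length`
#'       (one-TA convention), `sequence` (with both TAs), `mac_scaffold`,
#'       `mac_junction` (0-based position of the junction TA's T on MAC)}
#'     \item{truth}{list with `rho` (data.frame `ies_id`, `rho`), the seed and
#'       the config}
#'   }
#' @export
#' @examples
#' g <- build_genomes(sim_config(seed = 1, n_scaffolds = 1,
#'                               scaffold_len = 20000, n_ies = 20))
#' nrow(g$annotations)
build_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genomes"))
  mac <- character(config$n_scaffolds)
  names(mac) <- sprintf("scaffold_%d", seq_len(config$n_scaffolds))
  ann_list <- vector("list", config$n_scaffolds)
  for (sc in seq_len(config$n_scaffolds)) {
    mac[sc] <- random_dna(config$scaffold_len, config$mac_background)
    if (config$n_ies == 0L) next
    ta_pos <- gregexpr("TA", mac[sc], fixed = TRUE)[[1]]
    ta_pos <- as.integer(ta_pos) - 1L  # 0-based position of the T
    ta_pos <- ta_pos[ta_pos >= config$min_flank &
                       ta_pos <= config$scaffold_len - config$min_flank]
    ## greedy spacing-constrained sample of junction sites
    cand <- sample(ta_pos)
    sites <- integer(0)
    for (p in cand) {
      if (length(sites) == config$n_ies) break
      if (all(abs(sites - p) >= config$min_ies_spacing))
        sites <- c(sites, p)
    }
    if (length(sites) < config$n_ies)
      stop(sprintf(
        "insufficient TA insertion sites on %s (%d found, %d requested)",
        names(mac)[sc], length(sites), config$n_ies), call. = FALSE)
    sites <- sort(sites)
    lens <- sample_ies_length(config$n_ies, config$length_model)
    seqs <- generate_ies_sequences(lens, config$end_model,
                                   config$interior_background)
    ann_list[[sc]] <- data.frame(
      ies_id = sprintf("IES.%s.%04d", names(mac)[sc], seq_along(sites)),
      scaffold = names(mac)[sc], mac_junction = sites, length = lens,
      sequence = seqs, stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, ann_list)
  if (is.null(ann))
    ann <- data.frame(ies_id = character(0), scaffold = character(0),
                      mac_junction = integer(0), length = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE)

  ## verbatim duplications for identical-pair analyses
  if (config$n_identical_pairs > 0L) {
    if (nrow(ann) < 2L * config$n_identical_pairs)
      stop("not enough IESs to plant the requested identical pairs",
           call. = FALSE)
    picks <- sample(nrow(ann), 2L * config$n_identical_pairs)
    donors <- picks[seq_len(config$n_identical_pairs)]
    recips <- picks[config$n_identical_pairs + seq_len(config$n_identical_pairs)]
    ann$sequence[recips] <- ann$sequence[donors]
    ann$length[recips] <- ann$length[donors]
  }

  ## assemble MIC scaffolds and MIC-space coordinates
  mic <- mac
  ann$start <- rep(NA_integer_, nrow(ann))
  ann$mac_scaffold <- ann$scaffold
  for (sc in names(mac)) {
    idx <- which(ann$scaffold == sc)
    if (length(idx) == 0L) next
    idx <- idx[order(ann$mac_junction[idx])]
    segs <- character(2L * length(idx) + 1L)
    prev <- 0L
    offset <- 0L
    for (k in seq_along(idx)) {
      i <- idx[k]
      j <- ann$mac_junction[i]
      segs[2L * k - 1L] <- ss0(mac[sc], prev, j)
      ## insert the IES minus its right TA (which is the MAC junction TA)
      segs[2L * k] <- ss0(ann$sequence[i], 0L, ann$length[i])
      ann$start[i] <- j + offset
      offset <- offset + ann$length[i]
      prev <- j
    }
    segs[2L * length(idx) + 1L] <- ss0(mac[sc], prev, nchar(mac[sc]))
    mic[sc] <- paste(segs, collapse = "")
  }

  rho <- switch(config$retention_model,
    uniform = runif(nrow(ann)),
    constant = rep(config$retention_value, nrow(ann)),
    table = {
      m <- match(ann$ies_id, config$retention_table$ies_id)
      if (anyNA(m))
        stop("retention_table is missing some simulated IESs", call. = FALSE)
      config$retention_table$rho[m]
    })
  truth <- list(rho = data.frame(ies_id = ann$ies_id, rho = rho,
                                 stringsAsFactors = FALSE),
                seed = config$seed, config = config)
  ann <- ann[, c("ies_id", "scaffold", "start", "length", "sequence",
                 "mac_scaffold", "mac_junction")]
  rownames(ann) <- NULL
  list(mac = mac, mic = mic, annotations = ann, truth = truth)
}

#' Excise annotated IESs from a MAC+IES genome
#'
#' Deletes `[start, start + length)` of every annotation from its MIC
#' scaffold. With a consistent annotation set the result is byte-identical to
#' the MAC genome.
#'
#' @param mic Named character vector of MAC+IES scaffolds.
#' @param annotations IES annotation data.frame (see [build_genomes()]).
#' @return Named character vector of excised scaffolds.
#' @export
excise_all <- function(mic, annotations) {
  out <- mic
  for (sc in names(mic)) {
    idx <- which(annotations$scaffold == sc)
    if (length(idx) == 0L) next
    idx <- idx[order(annotations$start[idx])]
    keep <- character(length(idx) + 1L)
    prev <- 0L
    for (k in seq_along(idx)) {
      i <- idx[k]
      keep[k] <- ss0(mic[sc], prev, annotations$start[i])
      prev <- annotations$start[i] + annotations$length[i]
    }
    keep[length(idx) + 1L] <- ss0(mic[sc], prev, nchar(mic[sc]))
    out[sc] <- paste(keep, collapse = "")
  }
  out
}
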