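#' Default IES length model
#'
#' Discretised Gaussian-mixture model of the IES length distribution
#' (one-TA convention): peaks every 10 bp starting at 28 bp with
#' geometrically decaying weights, a multiplicative depletion of the
#' "forbidden" 38--46 bp window, and an exponential long tail beyond the last
#' peak reaching 5 kb. Lengths below 26 bp have zero mass.
#'
#' The shape (peak period, mode, forbidden window, range) mirrors what is
#' known about *P. tetraurelia* IESs; the per-peak spread, weight decay and
#' tail law are not constrained by published summaries and are exposed here
#' as explicit knobs.
#'
#' @param peak_centers Integer vector of peak centres in bp.
#' @param peak_sd Per-peak standard deviation in bp (0 gives point masses).
#' @param peak_decay Geometric decay of successive peak weights.
#' @param forbidden_window Length-2 vector, depleted window in bp (inclusive).
#' @param forbidden_factor Multiplicative depletion in `[0, 1]`.
#' @param tail_weight Mixture weight of the exponential tail component.
#' @param tail_rate Rate of the exponential tail (per bp past the last peak).
#' @param min_len,max_len Support bounds in bp.
#' @return A list of class `ies_length_model`.
#' @export
ies_length_model <- function(peak_centers = 28 + 10 * (0:11),
                             peak_sd = 1.5,
                             peak_decay = 0.6,
                             forbidden_window = c(38, 46),
                             forbidden_factor = 0.2,
                             tail_weight = 0.01,
                             tail_rate = 1 / 400,
                             min_len = 26,
                             max_len = 5000) {
  m <- list(peak_centers = as.integer(peak_centers), peak_sd = peak_sd,
            peak_decay = peak_decay,
            forbidden_window = as.integer(forbidden_window),
            forbidden_factor = forbidden_factor, tail_weight = tail_weight,
            tail_rate = tail_rate, min_len = as.integer(min_len),
            max_len = as.integer(max_len))
  class(m) <- "ies_length_model"
  validate_length_model(m)
  m
}

validate_length_model <- function(m) {
  if (any(m$peak_centers < 26))
    stop("length model: peak centers must be >= 26 bp", call. = FALSE)
  if (m$peak_decay <= 0 || m$peak_sd < 0)
    stop("length model: weights must be positive and spread non-negative",
         call. = FALSE)
  if (m$forbidden_factor < 0 || m$forbidden_factor > 1)
    stop("length model: forbidden depletion factor must be in [0, 1]",
         call. = FALSE)
  if (m$tail_weight < 0 || m$tail_weight >= 1 || m$tail_rate <= 0)
    stop("length model: invalid tail component", call. = FALSE)
  if (m$min_len < 26 || m$max_len < m$min_len)
    stop("length model: invalid support bounds", call. = FALSE)
  invisible(m)
}

#' Default sub-terminal end model
#'
#' Base-probability tables for the three positions immediately inward of each
#' boundary TA, stratified by IES length. The short stratum favours a
#' `TAG`-like sub-terminus (T at position 1, A at position 2, G at position 3,
#' yielding the `TATAG` terminus typical of first-peak IESs); longer IESs
#' shift towards C at position 1 (`TACAG`-like termini).
#'
#' @param strata A list; each element has `max_len` (inclusive upper length
#'   bound of the stratum, `Inf` for the last) and `probs`, a list of three
#'   named base-probability vectors for sub-terminal positions 1--3.
#' @return A list of class `ies_end_model`.
#' @export
ies_end_model <- function(strata = NULL) {
  if (is.null(strata)) {
    strata <- list(
      list(max_len = 44,
           probs = list(
             c(A = 0.08, C = 0.05, G = 0.05, T = 0.82),
             c(A = 0.70, C = 0.08, G = 0.05, T = 0.17),
             c(A = 0.20, C = 0.10, G = 0.50, T = 0.20))),
      list(max_len = Inf,
           probs = list(
             c(A = 0.18, C = 0.40, G = 0.10, T = 0.32),
             c(A = 0.60, C = 0.10, G = 0.08, T = 0.22),
             c(A = 0.22, C = 0.12, G = 0.46, T = 0.20))))
  }
  for (s in strata) {
    if (length(s$probs) != 3L)
      stop("end model: each stratum needs probability tables for positions 1-3",
           call. = FALSE)
    for (p in s$probs) check_base_probs(p, "end model probabilities")
  }
  maxes <- vapply(strata, function(s) s$max_len, numeric(1))
  if (is.unsorted(maxes) || !is.infinite(maxes[length(maxes)]))
    stop("end model: strata must be ordered by max_len, last one Inf",
         call. = FALSE)
  structure(list(strata = strata), class = "ies_end_model")
}

end_model_stratum <- function(end_model, length) {
  maxes <- vapply(end_model$strata, function(s) s$max_len, numeric(1))
  end_model$strata[[which(length <= maxes)[1]]]$probs
}

#' Default sRNA model
#'
#' scnRNAs are fixed-length (25 nt) reads placed uniformly over the germline
#' (MAC+IES) genome; iesRNAs are 21--31 nt reads (mode 27 nt) confined to IES
#' intervals, with half of their starts drawn within `end_window` nt of
#' either IES end. Per-IES iesRNA counts are Poisson with mean
#' `abundance_scale * length * (abundance_base + abundance_slope * rho)`,
#' so that iesRNA density grows with the true retention fraction rho while
#' scnRNA density does not.
#'
#' @param scn_length scnRNA read length in nt.
#' @param scn_depth Fold coverage of the MAC+IES genome by scnRNA reads.
#' @param ies_lengths Support of the iesRNA length distribution in nt.
#' @param ies_length_weights Unnormalised weights over `ies_lengths`.
#' @param end_weight Probability that an iesRNA start is end-proximal.
#' @param end_window Size of the end-proximal start window in nt.
#' @param abundance_scale,abundance_base,abundance_slope Parameters of the
#'   per-IES iesRNA abundance law (reads per IES base).
#' @return A list of class `srna_model`.
#' @export
srna_model <- function(scn_length = 25L,
                       scn_depth = 10,
                       ies_lengths = 21:31,
                       ies_length_weights = c(1, 2, 4, 7, 10, 14, 18, 12, 7, 3, 1),
                       end_weight = 0.5,
                       end_window = 5L,
                       abundance_scale = 0.5,
                       abundance_base = 0.25,
                       abundance_slope = 0.75) {
  stopifnot(length(ies_lengths) == length(ies_length_weights),
            all(ies_length_weights >= 0), sum(ies_length_weights) > 0,
            end_weight >= 0, end_weight <= 1)
  structure(list(scn_length = as.integer(scn_length), scn_depth = scn_depth,
                 ies_lengths = as.integer(ies_lengths),
                 ies_length_weights = ies_length_weights,
                 end_weight = end_weight, end_window = as.integer(end_window),
                 abundance_scale = abundance_scale,
                 abundance_base = abundance_base,
                 abundance_slope = abundance_slope),
            class = "srna_model")
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic MIC/MAC genome, DNA-seq, sRNA-seq and
#' excision-error generator. Identical configurations (including `seed`)
#' produce bit-identical outputs.
#'
#' @param seed Integer master seed.
#' @param n_scaffolds Number of scaffolds.
#' @param scaffold_len MAC scaffold length in bp.
#' @param n_ies IESs per scaffold.
#' @param length_model An [ies_length_model()].
#' @param end_model An [ies_end_model()].
#' @param interior_background Base probabilities of IES interior positions
#'   (and, by default, of MAC-destined background sequence).
#' @param mac_background Base probabilities of MAC scaffold sequence;
#'   defaults to `interior_background`.
#' @param coverage DNA-seq fold coverage (read depth over MAC-destined bases).
#' @param read_len DNA-seq read length in nt.
#' @param insert_mean,insert_sd Fragment (insert) length mean and sd in bp.
#' @param base_error_rate Uniform substitution rate applied to read sequences
#'   (alignments keep their true coordinates).
#' @param retention_model One of `"uniform"` (rho ~ U(0,1) per IES),
#'   `"constant"` (all IESs share `retention_value`), or `"table"`
#'   (`retention_table` is a data.frame `ies_id`, `rho`).
#' @param retention_value Constant rho for `retention_model = "constant"`.
#' @param retention_table Per-IES rho table for `retention_model = "table"`.
#' @param srna An [srna_model()].
#' @param n_identical_pairs Number of IES sequences duplicated verbatim at a
#'   second locus (for identical-pair analyses).
#' @param n_cryptic,n_alt_boundary Counts of planted cryptic and
#'   alternative-boundary excision errors.
#' @param error_length_range Planted-deletion length range in bp.
#' @param reads_per_error Read pairs emitted per planted deletion.
#' @param min_ies_spacing Minimum MAC distance between junction sites in bp.
#' @param min_flank Minimum distance of a junction from a scaffold end in bp.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_scaffolds = 1, scaffold_len = 20000, n_ies = 40)
sim_config <- function(seed = 1L,
                       n_scaffolds = 2L,
                       scaffold_len = 60000L,
                       n_ies = 120L,
                       length_model = ies_length_model(),
                       end_model = ies_end_model(),
                       interior_background = c(A = 0.4, C = 0.1, G = 0.1, T = 0.4),
                       mac_background = NULL,
                       coverage = 25,
                       read_len = 100L,
                       insert_mean = 250,
                       insert_sd = 30,
                       base_error_rate = 0,
                       retention_model = c("uniform", "constant", "table"),
                       retention_value = 0.5,
                       retention_table = NULL,
                       srna = srna_model(),
                       n_identical_pairs = 0L,
                       n_cryptic = 0L,
                       n_alt_boundary = 0L,
                       error_length_range = c(26L, 30L),
                       reads_per_error = 2L,
                       min_ies_spacing = 150L,
                       min_flank = 300L) {
  retention_model <- match.arg(retention_model)
  interior_background <- check_base_probs(interior_background,
                                          "interior background")
  if (is.null(mac_background)) mac_background <- interior_background
  mac_background <- check_base_probs(mac_background, "MAC background")
  validate_length_model(length_model)
  if (retention_model == "constant" &&
      (retention_value < 0 || retention_value > 1))
    stop("retention_value must be in [0, 1]", call. = FALSE)
  if (retention_model == "table" && is.null(retention_table))
    stop("retention_model = \"table\" requires retention_table", call. = FALSE)
  if (n_cryptic < 0 || n_alt_boundary < 0)
    stop("planted error counts must be >= 0", call. = FALSE)
  structure(list(
    seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
    scaffold_len = as.integer(scaffold_len), n_ies = as.integer(n_ies),
    length_model = length_model, end_model = end_model,
    interior_background = interior_background, mac_background = mac_background,
    coverage = coverage, read_len = as.integer(read_len),
    insert_mean = insert_mean, insert_sd = insert_sd,
    base_error_rate = base_error_rate,
    retention_model = retention_model, retention_value = retention_value,
    retention_table = retention_table, srna = srna,
    n_identical_pairs = as.integer(n_identical_pairs),
    n_cryptic = as.integer(n_cryptic),
    n_alt_boundary = as.integer(n_alt_boundary),
    error_length_range = as.integer(error_length_range),
    reads_per_error = as.integer(reads_per_error),
    min_ies_spacing = as.integer(min_ies_spacing),
    min_flank = as.integer(min_flank)), class = "sim_config")
}

#' Load a simulation configuration from a YAML file
#'
#' The YAML file may set any argument of [sim_config()]; nested models are
#' given as argument lists for [ies_length_model()], [ies_end_model()] and
#' [srna_model()].
#'
#' @param path Path to a YAML file.
#' @return A `sim_config` object.
#' @export
load_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$length_model))
    raw$length_model <- do.call(ies_length_model, raw$length_model)
  if (!is.null(raw$end_model) && !inherits(raw$end_model, "ies_end_model"))
    raw$end_model <- do.call(ies_end_model, raw$end_model)
  if (!is.null(raw$srna)) raw$srna <- do.call(srna_model, raw$srna)
  for (nm in c("interior_background", "mac_background"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  do.call(sim_config, raw)
}
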