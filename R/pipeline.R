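#' Run the full synthetic-data analysis pipeline
#'
#' Executes every stage end to end on a synthetic dataset: genome/read
#' simulation, retention scoring, TA-indel detection, quasi-IES scanning,
#' end-base analytics, sRNA density profiling and IES-pair correlations.
#' All interchange files are TSV (plus FASTA/GFF3/SAM/FASTQ for the
#' simulated inputs) under `out_dir`, and a JSON manifest records the
#' configuration, seed, per-stage outputs and their checksums. Re-running
#' with the same configuration reproduces byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param quasi_motifs Motifs scanned for quasi-IESs.
#' @param write_reads Also write FASTQ/SAM read files (larger, optional).
#' @return The manifest, invisibly (list; also written as
#'   `manifest.json`).
#' @export
run_all <- function(config = sim_config(), out_dir = tempfile("iesr_run_"),
                    quasi_motifs = c("TATAG", "TACAG", "TATTG"),
                    write_reads = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage <- function(name, files) paths[[name]] <<- file.path(out_dir, files)

  ## 1 -- simulate
  genomes <- build_genomes(config)
  write_fasta(genomes$mac, file.path(out_dir, "mac.fa"))
  write_fasta(genomes$mic, file.path(out_dir, "mac_ies.fa"))
  write_gff3(genomes$annotations, file.path(out_dir, "ies.gff3"))
  write_bed(genomes$annotations, file.path(out_dir, "ies.bed"))
  write_tsv(genomes$truth$rho, file.path(out_dir, "truth_retention.tsv"))
  reads <- simulate_dna_reads(genomes, config)
  planted <- plant_excision_errors(genomes, config, reads = reads)
  reads <- planted$reads
  write_tsv(planted$deletions, file.path(out_dir, "truth_taindels.tsv"))
  srna <- simulate_srna_reads(genomes, config)
  sim_files <- c("mac.fa", "mac_ies.fa", "ies.gff3", "ies.bed",
                 "truth_retention.tsv", "truth_taindels.tsv")
  if (write_reads) {
    write_fastq(reads, file.path(out_dir, "dna_1.fastq"), mate = 1L)
    write_fastq(reads, file.path(out_dir, "dna_2.fastq"), mate = 2L)
    write_sam(reads, genomes$mac, file.path(out_dir, "dna_mac.sam"),
              space = "mac")
    write_sam(reads, genomes$mic, file.path(out_dir, "dna_mic.sam"),
              space = "mic")
    write_fastq(srna, file.path(out_dir, "srna.fastq"))
    sim_files <- c(sim_files, "dna_1.fastq", "dna_2.fastq", "dna_mac.sam",
                   "dna_mic.sam", "srna.fastq")
  }
  stage("simulate", sim_files)

  ## 2 -- retention scoring
  filtered <- filter_unique_pairs(reads)
  irs <- compute_irs(filtered, genomes$annotations, sample_label = "sim")
  write_tsv(irs, file.path(out_dir, "irs.tsv"))
  hist <- irs_histogram(irs)
  write_tsv(hist, file.path(out_dir, "irs_histogram.tsv"))
  stage("irs", c("irs.tsv", "irs_histogram.tsv"))

  ## 3 -- TA-indels
  mac_reads <- filtered[filtered$space == "mac", , drop = FALSE]
  dels <- extract_deletions(mac_reads, genomes$mac)
  ta <- collect_taindels(dels, genomes$mac)
  ta <- classify_taindel(ta, genomes$annotations)
  write_tsv(ta, file.path(out_dir, "taindels.tsv"))
  rate <- data.frame(
    klass = c("cryptic", "alternative_boundary", "all"),
    reads_per_million = c(
      normalize_taindels(sum(ta$read_count[ta$klass == "cryptic"]),
                         nrow(filtered)),
      normalize_taindels(sum(ta$read_count[ta$klass == "alternative_boundary"]),
                         nrow(filtered)),
      normalize_taindels(attr(ta, "n_reads_with_taindel"), nrow(filtered))))
  write_tsv(rate, file.path(out_dir, "taindel_rates.tsv"))
  write_tsv(taindel_length_histogram(ta),
            file.path(out_dir, "taindel_lengths.tsv"))
  stage("taindel", c("taindels.tsv", "taindel_rates.tsv",
                     "taindel_lengths.tsv"))

  ## 4 -- quasi-IESs
  qrows <- list()
  for (m in quasi_motifs) {
    q <- scan_quasi_ies(genomes$mac, m)
    prof <- quasi_length_profile(q)
    if (nrow(prof) > 0L) prof$motif <- m
    exp <- expected_quasi_counts(genomes$mac, m, lengths = 26:150)
    exp$motif <- m
    qrows[[m]] <- merge(exp, prof, by = c("motif", "length"), all.x = TRUE)
  }
  quasi <- do.call(rbind, qrows)
  quasi$count[is.na(quasi$count)] <- 0L
  quasi$obs_over_exp <- ifelse(quasi$expected > 0,
                               quasi$count / quasi$expected, NA_real_)
  write_tsv(quasi[, c("motif", "length", "count", "expected",
                      "obs_over_exp")],
            file.path(out_dir, "quasi_ies.tsv"))
  stage("quasiies", "quasi_ies.tsv")

  ## 5 -- end bases
  freq <- subterminal_frequencies(genomes$annotations)
  write_tsv(freq, file.path(out_dir, "subterminal_frequencies.tsv"))
  short <- genomes$annotations$length <= 36
  logo <- sequence_logo(substr(genomes$annotations$sequence[short], 1L, 13L),
                        background = config$interior_background)
  write_tsv(logo, file.path(out_dir, "logo_first_peak.tsv"))
  defined <- !is.na(irs$irs)
  lo_grp <- genomes$annotations$sequence[defined & irs$irs <= 0.2]
  hi_grp <- genomes$annotations$sequence[defined & irs$irs > 0.2]
  ends_files <- c("subterminal_frequencies.tsv", "logo_first_peak.tsv")
  if (length(lo_grp) >= 10L && length(hi_grp) >= 10L) {
    tsl <- two_sample_logo(substr(hi_grp, 1L, 13L), substr(lo_grp, 1L, 13L),
                           alpha = 0.05)
    write_tsv(tsl, file.path(out_dir, "two_sample_logo.tsv"))
    ends_files <- c(ends_files, "two_sample_logo.tsv")
  }
  fvi <- frequency_vs_irs(genomes$annotations, irs)
  write_tsv(fvi, file.path(out_dir, "frequency_vs_irs.tsv"))
  ends_files <- c(ends_files, "frequency_vs_irs.tsv")
  stage("endbases", ends_files)

  ## 6 -- sRNA densities
  tabs <- srna_truth_alignments(srna, genomes$annotations)
  assigned <- srna_two_stage_assign(tabs$mac, tabs$mic)
  d25 <- per_ies_density(assigned, genomes$annotations, 25L)
  d27 <- per_ies_density(assigned, genomes$annotations, 27L)
  write_tsv(rbind(d25, d27), file.path(out_dir, "srna_density.tsv"))
  p25 <- density_vs_irs(d25, irs)
  p27 <- density_vs_irs(d27, irs)
  p25$size_class <- 25L; p27$size_class <- 27L
  write_tsv(rbind(p25, p27), file.path(out_dir, "srna_density_vs_irs.tsv"))
  stage("srnadensity", c("srna_density.tsv", "srna_density_vs_irs.tsv"))

  ## 7 -- associations
  scores <- setNames(irs$irs, irs$ies_id)
  idp <- find_identical_pairs(genomes$annotations, genomes$mic,
                              scores = scores,
                              flank_window = config$read_len)
  write_tsv(idp, file.path(out_dir, "identical_pairs.tsv"))
  adj <- adjacent_pairs(genomes$annotations, irs)
  write_tsv(adj, file.path(out_dir, "adjacent_pairs.tsv"))
  cors <- list()
  if (nrow(idp) >= 3L && !all(is.na(idp$score_x)))
    cors$identical <- correlate(idp$score_x, idp$score_y)
  if (nrow(adj) >= 3L) cors$adjacent <- correlate(adj$score_x, adj$score_y)
  rnd <- random_pairs(genomes$annotations, irs,
                      seed = derive_seed(config$seed, "assoc"))
  cors$random <- correlate(rnd$score_x, rnd$score_y)
  cor_df <- do.call(rbind, lapply(names(cors), function(nm)
    data.frame(pair_set = nm, r = cors[[nm]]$r, p = cors[[nm]]$p,
               n = cors[[nm]]$n, stringsAsFactors = FALSE)))
  write_tsv(cor_df, file.path(out_dir, "correlations.tsv"))
  stage("assoc", c("identical_pairs.tsv", "adjacent_pairs.tsv",
                   "correlations.tsv"))

  manifest <- list(
    tool = "iesr", version = as.character(utils::packageVersion("iesr")),
    seed = config$seed,
    config = config_snapshot(config),
    stages = lapply(paths, function(p)
      list(files = basename(p),
           md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$out_dir <- out_dir
  invisible(manifest)
}

## JSON-serialisable view of a sim_config.
config_snapshot <- function(config) {
  snap <- config
  snap$length_model <- unclass(snap$length_model)
  snap$end_model <- rapply(unclass(snap$end_model), as.list, how = "replace")
  snap$srna <- unclass(snap$srna)
  unclass(snap)
}
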