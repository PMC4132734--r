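test_that("deletion extraction honours length bounds and N flagging", {
  g <- c(s = paste(rep("ACGT", 100), collapse = ""))
  reads <- rbind(read_rec("s", "mac", 0L, 54L),
                 read_rec("s", "mac", 100L, 230L),
                 read_rec("s", "mac", 300L, 350L))
  reads$cigar <- c("25M4D25M", "50M30D50M", "50M")
  reads$end <- reads$start +
    c(54L, 130L, 50L)
  reads$qname <- c("q4", "q30", "q0")
  dels <- extract_deletions(reads, g)
  ## the 4 bp deletion is below the 5 bp floor; the plain read has none
  expect_equal(dels$qname, "q30")
  expect_equal(dels$del_start, 150L)
  expect_equal(dels$del_end, 180L)
  ## N in the deleted span flags the record
  gn <- c(s = paste0(strrep("A", 150), strrep("N", 10), strrep("A", 240)))
  deln <- extract_deletions(reads[2, ], gn)
  expect_true(deln$contains_n)
  taN <- collect_taindels(deln, gn)
  expect_equal(nrow(taN), 0L)
})

test_that("realignment finds the TA-bounded placement of the worked example", {
  g <- c(chr = "GGTACCCCTAGG")
  r <- realign_deletion(g, "chr", 2L, 10L)
  expect_true(r$ta_bounded)
  expect_equal(c(r$del_start, r$del_end), c(2L, 10L))
  ## no TA-bounded shift-equivalent placement exists for a TA-free span
  g2 <- c(chr = "GGGCCCCCGGG")
  r2 <- realign_deletion(g2, "chr", 3L, 8L)
  expect_false(r2$ta_bounded)
  expect_equal(c(r2$del_start, r2$del_end), c(3L, 8L))
})

test_that("realignment is invariant over all shift-equivalent placements", {
  set.seed(61)
  for (rep in 1:25) {
    ref <- random_genome(1, 1000)[[1]]
    g <- c(chr = ref)
    s0 <- sample(100:800, 1)
    d <- sample(10:60, 1)
    base <- realign_deletion(g, "chr", s0, s0 + d)
    ## enumerate equivalent placements by brute force in both directions
    s <- s0
    while (s > 0 && substr(ref, s, s) == substr(ref, s + d, s + d)) s <- s - 1
    repeat {
      r <- realign_deletion(g, "chr", s, s + d)
      expect_identical(r[c("del_start", "del_end", "ta_bounded")],
                       base[c("del_start", "del_end", "ta_bounded")])
      if (substr(ref, s + 1, s + 1) == substr(ref, s + d + 1, s + d + 1) &&
          s + d + 1 <= nchar(ref)) s <- s + 1 else break
    }
  }
})

test_that("left-shifted reporting of planted deletions realigns to truth", {
  cfg <- sim_config(seed = 62, n_scaffolds = 1, scaffold_len = 20000,
                    n_ies = 25, coverage = 5, n_cryptic = 20,
                    n_alt_boundary = 10, reads_per_error = 2)
  g <- build_genomes(cfg)
  pe <- plant_excision_errors(g, cfg)
  dels <- extract_deletions(pe$reads[pe$reads$space == "mac", ], g$mac)
  ta <- collect_taindels(dels, g$mac)
  key_truth <- unique(paste(pe$deletions$scaffold, pe$deletions$del_start,
                            pe$deletions$del_end))
  key_found <- paste(ta$scaffold, ta$del_start, ta$del_end)
  expect_setequal(key_found, key_truth)
  ## zero error counts leave the read stream untouched
  cfg0 <- cfg; cfg0$n_cryptic <- 0L; cfg0$n_alt_boundary <- 0L
  reads <- simulate_dna_reads(g, cfg)
  pe0 <- plant_excision_errors(g, cfg0, reads)
  expect_identical(pe0$reads, reads)
  expect_equal(nrow(pe0$deletions), 0L)
})

test_that("classification separates junction-anchored from cryptic deletions", {
  ann <- ann_rec(start = 100L, length = 30L, mac_junction = 500L)
  tad <- data.frame(scaffold = "s",
                    del_start = c(500L, 470L, 900L),
                    del_end = c(530L, 502L, 930L),
                    length = 30L, read_count = 1L, stringsAsFactors = FALSE)
  out <- classify_taindel(tad, ann)
  ## starts at the junction TA; ends at the junction TA's right edge; neither
  expect_equal(out$klass,
               c("alternative_boundary", "alternative_boundary", "cryptic"))
  none <- classify_taindel(tad, ann_rec()[0, ])
  expect_true(all(none$klass == "cryptic"))
})

test_that("normalisation is reads per million and linear in counts", {
  expect_equal(normalize_taindels(42, 7e6), 6)
  expect_equal(normalize_taindels(0, 1e6), 0)
  expect_equal(normalize_taindels(2 * 42, 7e6), 2 * normalize_taindels(42, 7e6))
  expect_error(normalize_taindels(1, 0), "positive")
})

test_that("error-free simulations yield zero TA-indels", {
  f <- small_sim()
  mac_reads <- f$reads[f$reads$space == "mac", ]
  dels <- extract_deletions(mac_reads, f$genomes$mac)
  expect_equal(nrow(dels), 0L)
})

test_that("length histograms tally per class with one-TA lengths", {
  tad <- data.frame(scaffold = "s", del_start = c(0L, 10L, 20L, 30L),
                    del_end = c(28L, 38L, 48L, 60L),
                    length = c(28L, 28L, 28L, 30L),
                    read_count = c(1L, 2L, 1L, 1L),
                    klass = c("cryptic", "cryptic", "alternative_boundary",
                              "cryptic"), stringsAsFactors = FALSE)
  h <- taindel_length_histogram(tad)
  expect_equal(sum(h$count), 4)
  expect_equal(h$count[h$klass == "cryptic" & h$length == 28], 2)
  hr <- taindel_length_histogram(tad, weight = "reads")
  expect_equal(sum(hr$count), 5)
  expect_equal(nrow(taindel_length_histogram(tad[0, ])), 0L)
})

test_that("planted first-peak errors give a 26-30 bp histogram mode", {
  cfg <- sim_config(seed = 63, n_scaffolds = 1, scaffold_len = 40000,
                    n_ies = 30, coverage = 5, n_cryptic = 100,
                    error_length_range = c(26L, 30L))
  g <- build_genomes(cfg)
  pe <- plant_excision_errors(g, cfg)
  tab <- table(pe$deletions$length)
  mode_len <- as.integer(names(tab)[which.max(tab)])
  expect_gte(mode_len, 26L)
  expect_lte(mode_len, 30L)
})
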