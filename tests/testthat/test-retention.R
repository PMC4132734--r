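test_that("single reads classify by end/junction crossing with anchors", {
  a <- ann_rec(start = 1000L, length = 5000L, mac_junction = 800L)
  ## crosses the left IES end with 20 nt on each side
  expect_equal(classify_read(read_rec("s", "mic", 980L, 1020L), a), "IES_plus")
  ## wholly inside a 5 kb IES, touching no end
  expect_equal(classify_read(read_rec("s", "mic", 2000L, 2100L), a),
               "uninformative")
  ## spans the MAC junction TA with 30 nt on each side
  expect_equal(classify_read(read_rec("s", "mac", 770L, 832L), a), "IES_minus")
  ## insufficient anchor on one side
  expect_equal(classify_read(read_rec("s", "mic", 997L, 1100L), a,
                             min_anchor = 5L), "uninformative")
  ## wrong scaffold
  expect_equal(classify_read(read_rec("other", "mic", 980L, 1020L), a),
               "uninformative")
})

test_that("a read crossing both ends of a short IES counts once", {
  a <- ann_rec(start = 100L, length = 26L, mac_junction = 100L)
  r <- read_rec("s", "mic", 80L, 180L)      # covers both ends
  expect_equal(classify_read(r, a), "IES_plus")
  irs <- compute_irs(r, a)
  expect_equal(irs$ies_plus, 1L)
})

test_that("IRS equals IES+ / (IES+ + IES-) with undefined zero-coverage", {
  a <- rbind(ann_rec("i1", start = 100L, length = 30L, mac_junction = 100L),
             ann_rec("i2", scaffold = "s2", start = 500L, length = 30L,
                     mac_junction = 500L))
  plus <- do.call(rbind, lapply(1:7, function(k)
    read_rec("s", "mic", 80L + k, 140L + k)))
  minus <- do.call(rbind, lapply(1:3, function(k)
    read_rec("s", "mac", 80L + k, 140L + k)))
  reads <- rbind(plus, minus)
  reads$qname <- sprintf("r%d", seq_len(nrow(reads)))
  irs <- compute_irs(reads, a)
  expect_equal(irs$ies_plus, c(7L, 0L))
  expect_equal(irs$ies_minus, c(3L, 0L))
  expect_equal(irs$irs, c(0.7, NA_real_))
})

test_that("vectorised scoring matches per-read classification on a sim", {
  f <- small_sim()
  reads <- f$reads[sample(nrow(f$reads), 400), ]
  ann <- f$genomes$annotations
  plus <- integer(nrow(ann)); minus <- integer(nrow(ann))
  for (ri in seq_len(nrow(reads))) for (ai in seq_len(nrow(ann))) {
    lab <- classify_read(reads[ri, ], ann[ai, ])
    if (lab == "IES_plus") plus[ai] <- plus[ai] + 1L
    if (lab == "IES_minus") minus[ai] <- minus[ai] + 1L
  }
  irs <- compute_irs(reads, ann)
  expect_equal(irs$ies_plus, plus)
  expect_equal(irs$ies_minus, minus)
})

test_that("IRS is invariant to read order and to uninformative duplication", {
  f <- small_sim()
  ann <- f$genomes$annotations
  base <- compute_irs(f$reads, ann)
  shuf <- compute_irs(f$reads[sample(nrow(f$reads)), ], ann)
  expect_equal(shuf, base)
  ## duplicating an uninformative interior-only record changes nothing
  uninf <- read_rec(ann$scaffold[1], "mic", ann$start[1] + 6L,
                    ann$start[1] + 10L)
  uninf$qname <- "dup_interior"
  aug <- compute_irs(rbind(f$reads, uninf, uninf), ann)
  expect_equal(aug$irs, base$irs)
})

test_that("IRS recovers a known constant retention fraction", {
  cfg <- sim_config(seed = 51, n_scaffolds = 1, scaffold_len = 15000,
                    n_ies = 20, coverage = 100,
                    retention_model = "constant", retention_value = 0.3)
  g <- build_genomes(cfg)
  irs <- compute_irs(filter_unique_pairs(simulate_dna_reads(g, cfg)),
                     g$annotations)
  n <- irs$ies_plus + irs$ies_minus
  lo <- qbinom(0.005, n, 0.3); hi <- qbinom(0.995, n, 0.3)
  inside <- irs$ies_plus >= lo & irs$ies_plus <= hi
  expect_gte(mean(inside), 0.9)
})

test_that("IRS histograms bin correctly and report undefined records", {
  rec <- data.frame(ies_id = sprintf("i%d", 1:5),
                    ies_plus = c(0L, 0L, 5L, 10L, 0L),
                    ies_minus = c(10L, 8L, 5L, 0L, 0L),
                    irs = c(0, 0, 0.5, 1, NA), sample = NA)
  h <- irs_histogram(rec, bin_width = 0.5)
  ## bins [0, 0.5) and [0.5, 1]: scores 0,0 -> bin 1; 0.5,1 -> bin 2
  expect_equal(h$count, c(2L, 2L))
  expect_equal(attr(h, "n_undefined"), 1L)
  empty <- irs_histogram(rec[0, ], bin_width = 0.25)
  expect_equal(empty$count, rep(0L, 4))
  expect_error(irs_histogram(rec, bin_width = 0.3), "divide 1 evenly")
})
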