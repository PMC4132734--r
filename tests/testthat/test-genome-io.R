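test_that("FASTA round trip preserves names and sequences, uppercasing input", {
  g <- c(alpha = "ACGTACGT", beta = "TTTTAAAA")
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g, path)
  expect_identical(read_fasta(path), g)
  writeLines(c(">x", "acgt"), path)
  expect_identical(read_fasta(path), c(x = "ACGT"))
  writeLines(c(">x", "ACGT", ">x", "GGGG"), path)
  expect_error(read_fasta(path), "duplicate scaffold name.*x")
})

test_that("GFF3 round trip reproduces annotations exactly", {
  f <- small_sim()
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(f$genomes$annotations, path)
  back <- load_annotations(path, f$genomes$mic, f$genomes$mac)
  ord <- order(back$ies_id)
  orig <- f$genomes$annotations[order(f$genomes$annotations$ies_id), ]
  rownames(back) <- rownames(orig) <- NULL
  expect_equal(back[ord, ], orig)
})

test_that("annotation validation catches shifted and misplaced records", {
  f <- small_sim()
  ann <- f$genomes$annotations
  shifted <- ann
  shifted$start[1] <- shifted$start[1] + 1L
  expect_error(validate_annotations(shifted, f$genomes$mic, f$genomes$mac),
               ann$ies_id[1])
  missing_sc <- ann
  missing_sc$scaffold[2] <- "nope"
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(missing_sc, path)
  expect_error(load_annotations(path, f$genomes$mic, f$genomes$mac), "nope")
})

test_that("pair filtering removes multi-mapping pairs and counts orphans", {
  reads <- rbind(read_rec("s", "mac", 0, 100), read_rec("s", "mac", 200, 300),
                 read_rec("s", "mac", 50, 150), read_rec("s", "mac", 250, 350),
                 read_rec("s", "mac", 400, 500))
  reads$pair_id <- c("p1", "p1", "p2", "p2", "p3")
  reads$mate <- c(1L, 2L, 1L, 2L, 1L)
  reads$qname <- paste0(reads$pair_id, "/", reads$mate)
  reads$unique <- c(TRUE, TRUE, TRUE, FALSE, TRUE)
  out <- filter_unique_pairs(reads)
  expect_identical(out$pair_id, c("p1", "p1"))
  expect_equal(attr(out, "n_orphans"), 1L)
  expect_equal(attr(out, "n_nonunique_pairs"), 1L)
  ## idempotent on an all-unique paired stream
  again <- filter_unique_pairs(out)
  expect_equal(out$qname, again$qname)
})

test_that("two-stage sRNA assignment prefers MAC and drops multi-mappers", {
  mac <- data.frame(qname = c("a", "m"), scaffold = "s1",
                    start = c(0L, 10L), end = c(25L, 35L), length = 25L,
                    n_hits = c(1L, 2L), stringsAsFactors = FALSE)
  mic <- data.frame(qname = c("a", "b", "c"), scaffold = "s1",
                    start = c(5L, 50L, 80L), end = c(30L, 77L, 107L),
                    length = c(25L, 27L, 27L),
                    n_hits = c(1L, 1L, 2L), stringsAsFactors = FALSE)
  out <- srna_two_stage_assign(mac, mic)
  ## "a" assigned to MAC even though present in both tables
  expect_equal(out$space[out$qname == "a"], "mac")
  ## "b" absent from MAC, unique in MAC+IES
  expect_equal(out$space[out$qname == "b"], "mic")
  ## multi-mappers dropped in their assigned reference
  expect_false(any(c("m", "c") %in% out$qname))
  expect_equal(attr(out, "normalization_total"), 2L)
  tl <- attr(out, "length_totals")
  expect_equal(unname(tl[c("25", "27")]), c(1L, 1L))
})

test_that("SAM and FASTQ writers emit parseable records", {
  f <- small_sim()
  reads <- head(f$reads, 20)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(reads, f$genomes$mac, sam, space = "mac")
  lines <- readLines(sam)
  expect_true(any(grepl("^@SQ\tSN:scaffold_1", lines)))
  body <- lines[!grepl("^@", lines)]
  expect_equal(length(body), sum(reads$space == "mac"))
  expect_true(all(lengths(strsplit(body, "\t")) == 11L))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fq, mate = 1L)
  fql <- readLines(fq)
  expect_equal(length(fql), 4L * sum(reads$mate == 1L))
  expect_true(all(grepl("^@", fql[seq(1, length(fql), by = 4)])))
})
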