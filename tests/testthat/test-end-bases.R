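test_that("sub-terminal tallies read positions 1-3 inward of the TA", {
  ann <- rbind(ann_rec("a", sequence = paste0("TAG", strrep("A", 25), "TA"),
                       length = 28L),
               ann_rec("b", sequence = paste0("TAG", strrep("A", 25), "TA"),
                       length = 28L))
  prof <- subterminal_frequencies(ann, grouping = rep("g", 2))
  g1 <- prof[prof$position == 1, ]
  expect_equal(g1$freq[g1$base == "G"], 1)
  expect_equal(sum(prof$freq[prof$position == 2]), 1)
})

test_that("forced end tables are recovered from simulated sequences", {
  force_tag <- ies_end_model(strata = list(list(
    max_len = Inf,
    probs = list(c(A = 0.1, C = 0.2, G = 0.3, T = 0.4),
                 c(A = 0.7, C = 0.1, G = 0.1, T = 0.1),
                 c(A = 0.05, C = 0.05, G = 0.8, T = 0.1)))))
  set.seed(81)
  n <- 4000
  seqs <- vapply(rep(40L, n), generate_ies_sequence, character(1),
                 end_model = force_tag)
  ann <- do.call(rbind, lapply(seq_len(n), function(i)
    ann_rec(sprintf("i%d", i), sequence = seqs[i], length = 40L)))
  prof <- subterminal_frequencies(ann, grouping = rep(1L, n),
                                  end_policy = "both_ends_pooled")
  target <- list(c(A = 0.1, C = 0.2, G = 0.3, T = 0.4),
                 c(A = 0.7, C = 0.1, G = 0.1, T = 0.1),
                 c(A = 0.05, C = 0.05, G = 0.8, T = 0.1))
  for (pos in 1:3) {
    sub <- prof[prof$position == pos, ]
    p <- target[[pos]][sub$base]
    se <- sqrt(p * (1 - p) / (2 * n))       # both ends pooled: 2n draws
    expect_true(all(abs(sub$freq - p) <= 4 * se + 1e-9))
  }
})

test_that("palindromic-ended sets give equal pooled and left-only profiles", {
  s <- paste0("TAGCA", strrep("T", 30), "TGCTA")   # revcomp-symmetric ends
  ann <- rbind(ann_rec("a", sequence = s, length = nchar(s) - 2L),
               ann_rec("b", sequence = s, length = nchar(s) - 2L))
  left <- subterminal_frequencies(ann, grouping = rep(1L, 2),
                                  end_policy = "left_end_only")
  both <- subterminal_frequencies(ann, grouping = rep(1L, 2),
                                  end_policy = "both_ends_pooled")
  expect_equal(both$freq, left$freq)
})

test_that("EWMA matches its closed-form recursion", {
  expect_equal(ewma(rep(3.5, 10), span = 5), rep(3.5, 10))
  expect_equal(ewma(c(0, 1), span = 5)[2], 1 / 3)
  expect_equal(ewma(numeric(0), span = 5), numeric(0))
  ## independent recursive oracle on random series
  set.seed(82)
  for (span in c(3, 5, 10, 50)) {
    x <- rnorm(200)
    alpha <- 2 / (span + 1)
    oracle <- Reduce(function(s, xi) alpha * xi + (1 - alpha) * s, x,
                     accumulate = TRUE)
    expect_equal(ewma(x, span), oracle, tolerance = 1e-12)
  }
})

test_that("logo columns carry closed-form relative entropy", {
  ## invariant G column against background q_G = 0.1
  lg <- sequence_logo(rep("G", 100))
  expect_equal(lg$total[1], log2(10), tolerance = 1e-9)
  expect_equal(lg$height[lg$base == "G"], log2(10), tolerance = 1e-9)
  ## invariant TA columns against q_T = q_A = 0.4
  lta <- sequence_logo(rep("TA", 50))
  expect_equal(unique(round(lta$total, 9)), round(log2(2.5), 9))
  ## background-drawn columns carry almost no information
  set.seed(83)
  bg <- random_dna(rep(1L, 10000), c(A = 0.4, C = 0.1, G = 0.1, T = 0.4))
  lbg <- sequence_logo(bg)
  expect_lt(lbg$total[1], 0.02)
  ## zero-probability background with observed counts is an error
  expect_error(sequence_logo(rep("C", 5),
                             background = c(A = 0.5, C = 0, G = 0.1, T = 0.4)),
               "zero background")
})

test_that("two-sample logos detect separated groups and not identical ones", {
  set.seed(84)
  grp <- vapply(1:100, function(i)
    paste(sample(c("A", "C", "G", "T"), 13, replace = TRUE), collapse = ""),
    character(1))
  same <- two_sample_logo(grp, grp)
  expect_false(any(same$significant))
  a <- rep(paste0("G", strrep("A", 12)), 100)
  b <- rep(paste0("T", strrep("A", 12)), 100)
  sep <- two_sample_logo(a, b, alpha = 1e-4)
  hit <- sep[sep$position == 1 & sep$base == "G", ]
  expect_true(hit$significant)
  expect_equal(hit$direction, "enriched")
})

test_that("two-sample logos are antisymmetric under group swap", {
  set.seed(85)
  mk <- function(p1) vapply(1:80, function(i)
    paste(c(sample(c("G", "T"), 1, prob = c(p1, 1 - p1)),
            sample(c("A", "C", "G", "T"), 6, replace = TRUE)), collapse = ""),
    character(1))
  a <- mk(0.8); b <- mk(0.3)
  ab <- two_sample_logo(a, b)
  ba <- two_sample_logo(b, a)
  expect_equal(ab$p_raw, ba$p_raw, tolerance = 1e-12)
  expect_equal(ab$diff, -ba$diff)
  flip <- ifelse(ab$direction == "enriched", "depleted", "enriched")
  disagree <- ab$diff != 0 & flip != ba$direction
  expect_false(any(disagree))
})

test_that("the Welch variant agrees with t.test on indicator variables", {
  set.seed(86)
  a <- c(rep("G", 37), rep("T", 43))
  b <- c(rep("G", 61), rep("T", 19))
  res <- two_sample_logo(a, b)
  ia <- as.integer(a == "G"); ib <- as.integer(b == "G")
  tt <- t.test(ia, ib)
  g <- res[res$position == 1 & res$base == "G", ]
  expect_equal(g$p_raw, tt$p.value, tolerance = 1e-10)
  expect_equal(g$p_bonferroni, min(1, tt$p.value * 4), tolerance = 1e-10)
})

test_that("retention-independent end tables give flat frequency-vs-IRS", {
  set.seed(87)
  n <- 3000
  lens <- sample(26:36, n, replace = TRUE)
  seqs <- iesr:::generate_ies_sequences(lens)
  ann <- data.frame(ies_id = sprintf("i%d", seq_len(n)), scaffold = "s",
                    start = 0L, length = lens, sequence = seqs,
                    mac_scaffold = "s", mac_junction = 0L,
                    stringsAsFactors = FALSE)
  rec <- data.frame(ies_id = ann$ies_id, ies_plus = 1L, ies_minus = 1L,
                    irs = runif(n), sample = NA, stringsAsFactors = FALSE)
  prof <- frequency_vs_irs(ann, rec, length_window = c(26, 36))
  t1 <- prof[prof$position == 1 & prof$base == "T" & prof$in_trend, ]
  fit <- lm(freq ~ bin, data = t1, weights = t1$n)
  ci <- confint(fit)["bin", ]
  expect_gt(ci[2], 0)
  expect_lt(ci[1], 0)
  ## the length confound is removed: mean length constant across bins
  m <- match(ann$ies_id, rec$ies_id)
  bins <- floor(rec$irs[m] / 0.1)
  mean_len <- tapply(ann$length, bins, mean)
  expect_lt(diff(range(mean_len)), 2)
})

test_that("a planted retention-linked end bias yields a monotone trend", {
  set.seed(88)
  n <- 2000
  irs <- runif(n)
  pos1 <- ifelse(runif(n) < 0.2 + 0.6 * irs, "T", "C")
  seqs <- paste0("TA", pos1, "AG", strrep("A", 20), "CTATA")  # 30 = 28 + 2
  ann <- data.frame(ies_id = sprintf("i%d", seq_len(n)), scaffold = "s",
                    start = 0L, length = 28L, sequence = seqs,
                    mac_scaffold = "s", mac_junction = 0L,
                    stringsAsFactors = FALSE)
  rec <- data.frame(ies_id = ann$ies_id, ies_plus = 1L, ies_minus = 1L,
                    irs = irs, sample = NA, stringsAsFactors = FALSE)
  prof <- frequency_vs_irs(ann, rec, length_window = c(26, 36))
  t1 <- prof[prof$position == 1 & prof$base == "T", ]
  expect_gt(cor(t1$bin, t1$freq, method = "spearman"), 0.5)
})
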