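test_that("identical IESs with different flanks pair; identical flanks do not", {
  ies <- paste0("TA", strrep("GAC", 10), "TA")
  L <- nchar(ies) - 2L
  flankA <- strrep("A", 50); flankC <- strrep("C", 50)
  mic <- c(s1 = paste0(flankA, ies, "TA", flankA),
           s2 = paste0(flankC, ies, "TA", flankC))
  ann <- rbind(
    ann_rec("x", scaffold = "s1", start = 50L, length = L, sequence = ies),
    ann_rec("y", scaffold = "s2", start = 50L, length = L, sequence = ies))
  pairs <- find_identical_pairs(ann, mic, flank_window = 20L)
  expect_equal(nrow(pairs), 1L)
  expect_setequal(c(pairs$ies_x, pairs$ies_y), c("x", "y"))
  ## same flanks on both loci -> indistinguishable, excluded and counted
  mic2 <- c(s1 = mic[["s1"]], s2 = mic[["s1"]])
  pairs2 <- find_identical_pairs(ann, mic2, flank_window = 20L)
  expect_equal(nrow(pairs2), 0L)
  expect_equal(attr(pairs2, "n_indistinguishable"), 1L)
})

test_that("planted duplicate IESs are found as identical pairs", {
  cfg <- sim_config(seed = 101, n_scaffolds = 2, scaffold_len = 30000,
                    n_ies = 40, n_identical_pairs = 10)
  g <- build_genomes(cfg)
  pairs <- find_identical_pairs(g$annotations, g$mic, flank_window = 100L)
  expect_gte(nrow(pairs), 10L)
})

test_that("score filters apply to identical pairs", {
  ies <- paste0("TA", strrep("GAC", 10), "TA")
  L <- nchar(ies) - 2L
  mic <- c(s1 = paste0(strrep("A", 50), ies, "TA", strrep("A", 50)),
           s2 = paste0(strrep("C", 50), ies, "TA", strrep("C", 50)))
  ann <- rbind(
    ann_rec("x", scaffold = "s1", start = 50L, length = L, sequence = ies),
    ann_rec("y", scaffold = "s2", start = 50L, length = L, sequence = ies))
  sc <- c(x = 0, y = 0.5)
  p <- find_identical_pairs(ann, mic, scores = sc, flank_window = 20L,
                            exclude_zero = TRUE)
  expect_equal(nrow(p), 0L)
  p2 <- find_identical_pairs(ann, mic, scores = c(x = 0.4, y = 0.5),
                             control_scores = c(x = 1, y = 10),
                             min_control_fraction = 0.1, flank_window = 20L)
  expect_equal(nrow(p2), 0L)   # y fails 0.5 >= 0.1 * 10
  p3 <- find_identical_pairs(ann, mic, scores = c(x = 0.4, y = 0.5),
                             control_scores = c(x = 1, y = 1),
                             min_control_fraction = 0.1, flank_window = 20L)
  expect_equal(nrow(p3), 1L)
  ## scaffold length threshold removes short-scaffold members
  p4 <- find_identical_pairs(ann, mic, flank_window = 20L,
                             min_scaffold_len = nchar(mic[["s1"]]) + 1L)
  expect_equal(nrow(p4), 0L)
})

test_that("correlation matches the closed-form covariance formula", {
  x <- c(0.1, 0.4, 0.2, 0.9, 0.5, 0.3, 0.8, 0.6, 0.05, 0.7)
  y <- c(0.2, 0.5, 0.1, 0.8, 0.6, 0.2, 0.9, 0.5, 0.1, 0.6)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- correlate(x, y)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$n, 10L)
  expect_equal(correlate(x, x)$r, 1)
  expect_lt(correlate(x, x)$p, 0.05)
  expect_equal(correlate(x, -x)$r, -1)
  ## symmetry and Spearman monotone invariance
  expect_equal(correlate(x, y)$r, correlate(y, x)$r)
  expect_equal(correlate(x, y, method = "spearman")$r,
               correlate(exp(x), y, method = "spearman")$r)
  expect_warning(res0 <- correlate(rep(1, 5), y[1:5]), "zero variance")
  expect_true(is.na(res0$r))
  expect_error(correlate(1:2, 2:3), "at least 3")
})

test_that("adjacent pairs respect spacing controls and find correlation
           structure only when present", {
  cfg <- sim_config(seed = 102, n_scaffolds = 2, scaffold_len = 40000,
                    n_ies = 80, coverage = 40)
  g <- build_genomes(cfg)
  irs <- data.frame(ies_id = g$truth$rho$ies_id, ies_plus = 1L,
                    ies_minus = 1L, irs = g$truth$rho$rho, sample = NA,
                    stringsAsFactors = FALSE)
  adj <- adjacent_pairs(g$annotations, irs)
  expect_gt(nrow(adj), 50)
  ## independent rho per IES: adjacent correlation within the permutation null
  r_obs <- correlate(adj$score_x, adj$score_y)$r
  set.seed(103)
  null_r <- replicate(200, {
    perm <- sample(adj$score_y)
    correlate(adj$score_x, perm)$r
  })
  expect_lt(abs(r_obs), quantile(abs(null_r), 0.999))
  ## block-correlated rho produces positive adjacent correlation
  blocks <- cumsum(runif(nrow(g$annotations)) < 0.2)
  rho_block <- runif(max(blocks) + 1L)[blocks + 1L]
  irs2 <- irs; irs2$irs <- pmin(pmax(rho_block + rnorm(nrow(irs), 0, 0.05),
                                     0), 1)
  adj2 <- adjacent_pairs(g$annotations, irs2)
  expect_gt(correlate(adj2$score_x, adj2$score_y)$r, 0.3)
  ## wider gaps weaken the block correlation
  near <- adjacent_pairs(g$annotations, irs2, max_gap = 200)
  if (nrow(near) >= 10)
    expect_gte(correlate(near$score_x, near$score_y)$r,
               correlate(adj2$score_x, adj2$score_y)$r - 0.1)
  ## a single IES per scaffold yields no pairs
  one <- g$annotations[!duplicated(g$annotations$scaffold), ]
  expect_equal(nrow(adjacent_pairs(one, irs)), 0L)
})

test_that("random pairs form the r = 0 baseline", {
  cfg <- sim_config(seed = 104, n_scaffolds = 1, scaffold_len = 30000,
                    n_ies = 60)
  g <- build_genomes(cfg)
  irs <- data.frame(ies_id = g$truth$rho$ies_id, ies_plus = 1L,
                    ies_minus = 1L, irs = g$truth$rho$rho, sample = NA,
                    stringsAsFactors = FALSE)
  rp <- random_pairs(g$annotations, irs, n = 2000, seed = 9)
  expect_true(all(rp$ies_x != rp$ies_y))
  expect_lt(abs(correlate(rp$score_x, rp$score_y)$r), 0.1)
})
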