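toy_matrix <- function() {
  # 2 loci of 2 sites each; site-wise deltas (+1, +2, -0.4, -0.1)
  base <- c(-2, -2, -2, -2)
  structure(rbind(T1 = base + c(1, 2, -0.4, -0.1) / 2,
                  T2 = base - c(1, 2, -0.4, -0.1) / 2),
            class = c("site_lnl_matrix", "matrix", "array"))
}

toy_partition <- function() partition_map(c("locA", "locB"),
                                          c("coding", "igs"), c(1, 3), c(2, 4))

test_that("locus-wise deltas sum site differences with the stated sign", {
  m <- toy_matrix()
  tab <- locuswise_delta(m, "T1", "T2", toy_partition())
  expect_equal(tab$dlnl, c(3.0, -0.5))
  expect_identical(attr(tab, "a"), "T1")
  # self-comparison: all zero, all weak
  tab0 <- locuswise_delta(m, "T1", "T1", toy_partition())
  expect_true(all(tab0$dlnl == 0))
  expect_true(all(tab0$class == "weak"))
  # uncovered columns are aggregated as "_unpartitioned"
  pm1 <- partition_map("locA", "coding", 1, 2)
  tab1 <- locuswise_delta(m, "T1", "T2", pm1)
  expect_identical(tab1$locus, c("locA", "_unpartitioned"))
  expect_equal(sum(tab1$dlnl), attr(tab1, "total_delta"))
  # overlapping ranges are rejected at construction and, defensively, when
  # a hand-built map sneaks past the constructor
  expect_error(partition_map(c("x", "y"), c("coding", "igs"), c(1, 2), c(2, 4)),
               "overlap")
  bad <- structure(data.frame(locus = c("x", "y"), kind = "igs",
                              start = c(1L, 2L), end = c(2L, 4L)),
                   class = c("partition_map", "data.frame"))
  expect_error(locuswise_delta(m, "T1", "T2", bad), "overlap")
  expect_error(locuswise_delta(m, "T1", "TX", toy_partition()), "TX")
})

test_that("support classification uses strict thresholds", {
  tab <- data.frame(locus = letters[1:5], kind = "coding", length = 100,
                    dlnl = c(2.0001, 2.0, -1.5, 0.3, -2.5))
  cl <- classify_support(tab)
  expect_identical(cl$class,
                   c("strong_A", "moderate_A", "moderate_B", "weak", "strong_B"))
  expect_error(classify_support(tab, strong = 1, moderate = 2), "strong")
})

test_that("comparison summaries balance to the total difference", {
  m <- toy_matrix()
  tab <- locuswise_delta(m, "T1", "T2", toy_partition())
  s <- summarize_comparison(tab)
  expect_equal(s$sum_positive, 3.0)
  expect_identical(s$n_positive, 1L)
  expect_equal(s$sum_negative, -0.5)
  expect_identical(s$n_negative, 1L)
  expect_equal(s$net, 2.5)
  expect_equal(s$net, attr(tab, "total_delta"))
  # all-zero table
  z <- locuswise_delta(m, "T2", "T2", toy_partition())
  sz <- summarize_comparison(z)
  expect_equal(sz$sum_positive + sz$sum_negative + sz$net, 0)
  expect_identical(sz$n_positive + sz$n_negative, 0L)
  # TSV export is |delta|-sorted and states the sign convention
  tf <- tempfile(fileext = ".tsv")
  write_dlnl_tsv(tab, tf)
  lines <- readLines(tf)
  expect_match(lines[1], "lnL\\(T1\\) - lnL\\(T2\\)")
  body <- utils::read.delim(tf, comment.char = "#")
  expect_identical(body$locus, c("locA", "locB"))
})

test_that("delta tables are antisymmetric and conserve the total", {
  for (s in 1:3) {
    cfg <- conflict_sim_config(n_loci = 12, n_conflict = 2,
                               length_range = c(60, 200),
                               conflict_length_range = c(150, 300), seed = s)
    sim <- simulate_conflict_dataset(cfg)
    # scored site lnL without refitting keeps this test fast
    topos <- list(T1 = cfg$majority_tree, T2 = cfg$minority_tree)
    m <- rbind(T1 = site_log_likelihoods(sim$alignment, topos$T1, cfg$model),
               T2 = site_log_likelihoods(sim$alignment, topos$T2, cfg$model))
    ab <- locuswise_delta(m, "T1", "T2", sim$partition)
    ba <- locuswise_delta(m, "T2", "T1", sim$partition)
    expect_equal(ab$dlnl, -ba$dlnl, tolerance = 1e-12)
    expect_lt(abs(sum(ab$dlnl) - (sum(m["T1", ]) - sum(m["T2", ]))), 1e-8)
  }
})

test_that("three-topology dissection assigns support by pairwise wins", {
  # locus 1 favours X over both rivals strongly; locus 2 favours Z
  # moderately; locus 3 favours no topology
  mk <- function(dx, dy, dz) c(dx, dy, dz)
  m <- structure(rbind(X = c(3, 0, 0.2), Y = c(0, 0.5, 0), Z = c(0.2, 2, 0.1)),
                 class = c("site_lnl_matrix", "matrix", "array"))
  pm <- partition_map(c("l1", "l2", "l3"), "sim", c(1, 2, 3), c(1, 2, 3))
  dis <- signal_dissection(m, pm)
  expect_named(dis$pairs, c("X_vs_Y", "X_vs_Z", "Y_vs_Z"))
  expect_identical(dis$support$supports, c("X", "Z", "none"))
  expect_identical(dis$support$class, c("strong", "moderate", "weak"))
})

test_that("removal experiments rank candidates consistently", {
  cfg <- suppressWarnings(     # 0 planted loci is intentional here
    conflict_sim_config(majority_tree = preset_topology("T1", 0.01),
                        n_loci = 10, n_conflict = 0,
                        length_range = c(200, 500), seed = 4))
  sim <- suppressWarnings(simulate_conflict_dataset(cfg))
  # candidates: the generating topology and a wrong resolution
  topos <- list(good = preset_topology("T1"), bad = preset_topology("T3"))
  rk <- removal_experiment(sim$alignment, sim$partition, topos,
                           cfg$model, exclude = character(),
                           free = list(rates = FALSE, gamma_shape = FALSE,
                                       p_inv = FALSE))
  expect_identical(rk$topology[1], "good")
  expect_equal(rk$deltaL[1], 0)
  expect_true(all(diff(rk$logLik) <= 0))
  expect_error(removal_experiment(sim$alignment, sim$partition,
                                  topos["good"], cfg$model), "two candidate")
})
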