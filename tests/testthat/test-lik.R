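test_that("two-taxon Jukes-Cantor site likelihoods match the closed form", {
  jc <- substitution_model()
  tr <- ape::read.tree(text = "(a:0.13,b:0.17);")   # path length t = 0.3
  aln <- dna_alignment(c(a = "ACGTACGTAA", b = "ACGTACGTGC"))
  ll <- site_log_likelihoods(aln, tr, jc)
  t <- 0.3
  match_ll <- log(0.25 * (0.25 + 0.75 * exp(-4 * t / 3)))
  mis_ll <- log(0.25 * (0.25 - 0.25 * exp(-4 * t / 3)))
  expect_equal(ll, c(rep(match_ll, 8), rep(mis_ll, 2)), tolerance = 1e-10)
})

test_that("zero branch lengths with identical sequences give ln(pi)", {
  m <- substitution_model(base_freqs = c(0.4, 0.1, 0.2, 0.3), gamma_shape = 1,
                          p_inv = 0.25)
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  aln <- dna_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"))
  ll <- site_log_likelihoods(aln, tr, m)
  expect_equal(ll, log(c(0.4, 0.1, 0.2, 0.3)), tolerance = 1e-12)
})

test_that("pruning matches exhaustive ancestral-state enumeration", {
  for (s in 1:4) {
    tr <- random_tree(5, seed = s)
    mod <- random_model(s + 50)
    aln <- simulate_alignment(tr, mod, 50, seed = s + 200)
    expect_lt(max(abs(site_log_likelihoods(aln, tr, mod) -
                      oracle_site_lnl(aln, tr, mod))), 1e-10)
  }
})

test_that("likelihood is invariant to root placement and taxon order", {
  tr <- random_tree(6, seed = 3)
  mod <- random_model(77)
  aln <- simulate_alignment(tr, mod, 80, seed = 5)
  base <- site_log_likelihoods(aln, tr, mod)
  # pulley principle: rooting anywhere leaves every site lnL unchanged
  for (tip in c("t1", "t4")) {
    rooted <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_lt(max(abs(site_log_likelihoods(aln, rooted, mod) - base)), 1e-10)
  }
  # taxon order of the alignment is irrelevant
  perm <- aln[sample(rownames(aln)), ]
  expect_lt(max(abs(site_log_likelihoods(perm, tr, mod) - base)), 1e-12)
})

test_that("gaps and ambiguities act as partial information", {
  jc <- substitution_model()
  tr <- ape::read.tree(text = "(a:0.1,b:0.1);")
  aln <- dna_alignment(c(a = "A-R", b = "A-A"))
  expect_warning(ll <- site_log_likelihoods(aln, tr, jc), "all-gap")
  expect_equal(ll[2], 0)                      # all-gap column
  expect_true(ll[3] > ll[1])                  # R covers A: less surprise than
  expect_lt(ll[3], 0)                         # a certain match? no - broader
})

test_that("pruning agrees with an independent implementation (phangorn)", {
  skip_if_not_installed("phangorn")
  tr <- random_tree(6, seed = 8)
  mod <- substitution_model(rates = c(1.5, 3, 0.7, 1.2, 4, 1),
                            base_freqs = c(0.3, 0.2, 0.2, 0.3),
                            gamma_shape = 0.7, p_inv = 0.2)
  aln <- simulate_alignment(tr, mod, 300, seed = 2)
  mine <- sum(site_log_likelihoods(aln, tr, mod))
  pd <- phangorn::phyDat(unclass(aln), type = "DNA")
  ph <- phangorn::pml(tr, pd, bf = mod$base_freqs, Q = mod$rates,
                      shape = mod$gamma_shape, k = 4, inv = mod$p_inv)
  expect_equal(mine, ph$logLik, tolerance = 1e-8)
})

test_that("fixed-topology fitting recovers closed-form and simulated truth", {
  # two-taxon JC: fitted distance equals -3/4 log(1 - 4k/(3n))
  k <- 30; n <- 200
  a <- c(rep("A", n - k), rep("C", k))
  b <- rep("A", n)
  fit <- fit_topology(dna_alignment(c(a = paste(a, collapse = ""),
                                      b = paste(b, collapse = ""))),
                      ape::read.tree(text = "(a:0.1,b:0.1);"),
                      substitution_model(), free = list(rates = FALSE),
                      empirical_freqs = FALSE)
  expect_equal(sum(fit$tree$edge.length), -0.75 * log(1 - 4 * k / (3 * n)),
               tolerance = 1e-6)
  # refitting from the optimum is a fixed point
  fit2 <- fit_topology(dna_alignment(c(a = paste(a, collapse = ""),
                                       b = paste(b, collapse = ""))),
                       fit$tree, substitution_model(),
                       free = list(rates = FALSE), empirical_freqs = FALSE)
  expect_lt(abs(fit2$logLik - fit$logLik), 1e-4)
  # local optimality: perturbing branch lengths away lowers the likelihood
  tr <- random_tree(5, seed = 31)
  mod <- substitution_model(gamma_shape = 1)
  aln <- simulate_alignment(tr, mod, 2000, seed = 6)
  f <- fit_topology(aln, tr, mod, free = list(rates = FALSE, p_inv = FALSE,
                                              gamma_shape = FALSE))
  for (fac in c(0.7, 1.4)) {
    pert <- f$tree
    pert$edge.length <- pert$edge.length * fac
    expect_lt(sum(site_log_likelihoods(aln, pert, f$model)), f$logLik)
  }
})

test_that("simulate-then-refit recovers branch lengths and gamma shape", {
  tr <- random_tree(6, seed = 12)
  mod <- substitution_model(rates = c(1.5, 3, 0.7, 1.2, 4, 1),
                            base_freqs = c(0.3, 0.2, 0.2, 0.3),
                            gamma_shape = 0.7)
  aln <- simulate_alignment(tr, mod, 10000, seed = 9)
  fit <- fit_topology(aln, tr, mod,
                      free = list(rates = FALSE, p_inv = FALSE))
  # fitted trees come back in postorder; align edge order before comparing
  ref <- ape::reorder.phylo(tr, "postorder")
  expect_lt(max(abs(fit$tree$edge.length - ref$edge.length) / ref$edge.length),
            0.15)
  expect_lt(abs(fit$model$gamma_shape - 0.7) / 0.7, 0.2)
  expect_true(fit$converged)
})

test_that("the topofit object behaves like a classed model fit", {
  tr <- random_tree(5, seed = 41)
  mod <- substitution_model(gamma_shape = 1)
  aln <- simulate_alignment(tr, mod, 400, seed = 3)
  fit <- fit_topology(aln, tr, mod, free = list(rates = FALSE,
                                                gamma_shape = FALSE,
                                                p_inv = FALSE))
  expect_s3_class(fit, "topofit")
  expect_equal(sum(fit$site_lnl), fit$logLik)
  expect_named(coef(fit)[1:6],
               c("r_AC", "r_AG", "r_AT", "r_CG", "r_CT", "r_GT"))
  expect_identical(attr(logLik(fit), "nobs"), 400L)
  expect_output(print(fit), "log-likelihood")
  expect_output(print(summary(fit)), "tree length")
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2L)
  expect_identical(dim(sims[[1]]), dim(aln))
  # error paths
  expect_error(site_log_likelihoods(aln, ape::rtree(4), mod), "taxa")
  expect_warning(fit_topology(aln, tr, mod, free = list(rates = FALSE),
                              max_passes = 1L), "not converged")
})
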