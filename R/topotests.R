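# RELL resampling of site log-likelihoods and the KH / SH / AU topology
# tests. All randomness is driven by an explicit integer seed and p values
# are bitwise-reproducible given it.

#' RELL replicates of total log-likelihoods
#'
#' Resampling of estimated log-likelihoods: each replicate draws `ncol(m)`
#' site indices with replacement (equal weights) and sums every topology's
#' site log-likelihoods over the draw — the bootstrap that underlies the
#' KH, SH and AU tests, with no refitting.
#'
#' @param m topologies x sites log-likelihood matrix (rows named).
#' @param n number of replicates.
#' @param seed integer seed.
#' @param n_sites sites drawn per replicate (defaults to `ncol(m)`; the AU
#'   test uses scaled values).
#' @return `n` x topologies matrix of resampled total log-likelihoods.
#' @export
rell_replicates <- function(m, n, seed, n_sites = ncol(m)) {
  m <- as_site_lnl_matrix(m)
  stopifnot(n >= 1, n_sites >= 1)
  S <- ncol(m)
  # equal-weight resampling of sites is distributionally identical to
  # weighted multinomial resampling of the unique site-lnL columns, which
  # collapses the cost on pattern-rich matrices
  cols <- asplit(m, 2L)
  first <- !duplicated(cols)
  u <- m[, first, drop = FALSE]
  w <- tabulate(match(cols, cols[first]), sum(first))
  with_seed(seed, {
    out <- matrix(0, n, nrow(m), dimnames = list(NULL, rownames(m)))
    block <- max(1L, min(n, floor(2e7 / ncol(u))))
    done <- 0L
    while (done < n) {
      b <- min(block, n - done)
      counts <- stats::rmultinom(b, n_sites, w)   # npat x b
      out[done + seq_len(b), ] <- t(u %*% counts)
      done <- done + b
    }
    out
  })
}

#' Kishino-Hasegawa test between two topologies
#'
#' Two-sided KH test by RELL: the observed statistic is the total
#' log-likelihood difference `delta = lnL_a - lnL_b`; RELL replicates of the
#' difference are centred at their mean to form the null distribution, and
#' the p value is the fraction of centred replicates at least as extreme in
#' absolute value as the observed difference. Identical rows give p = 1 by
#' convention.
#'
#' @param m topologies x sites matrix.
#' @param a,b topology labels.
#' @param n RELL replicates (the conventional choice is 10,000).
#' @param seed integer seed.
#' @param sided `"two"` (default; topologies not pre-specified as
#'   null/alternative) or `"one"` (probability that `a` falls at least as
#'   far behind `b` as observed — the convention that makes KH comparable
#'   to the AU test).
#' @return p value in `[0, 1]`.
#' @export
kh_test <- function(m, a, b, n = 10000L, seed = 1L, sided = c("two", "one")) {
  sided <- match.arg(sided)
  m <- as_site_lnl_matrix(m)
  if (!all(c(a, b) %in% rownames(m))) stop("labels not in matrix")
  d <- m[a, ] - m[b, ]
  if (all(d == 0)) return(1)
  delta <- sum(d)
  reps <- rell_replicates(m[c(a, b), , drop = FALSE], n, seed)
  dstar <- reps[, 1L] - reps[, 2L]
  dstar <- dstar - mean(dstar)
  if (sided == "two") mean(abs(dstar) >= abs(delta))
  else mean(dstar <= delta)          # P(a falls this far behind b | null)
}

#' Shimodaira-Hasegawa test over a set of topologies
#'
#' For each topology `t` the observed statistic is
#' `max_t' lnL_t' - lnL_t`. The null distribution is formed from RELL
#' replicates centred per topology; in each replicate the statistic is the
#' maximum over topologies of the centred values minus the topology's own
#' centred value. The test is simultaneous over the candidate set and is
#' conservative relative to KH.
#'
#' @param m topologies x sites matrix (>= 2 rows).
#' @param n RELL replicates.
#' @param seed integer seed.
#' @return named numeric vector of p values per topology.
#' @export
sh_test <- function(m, n = 10000L, seed = 1L) {
  m <- as_site_lnl_matrix(m)
  if (nrow(m) < 2L) stop("need at least two topologies")
  totals <- rowSums(m)
  obs <- max(totals) - totals
  reps <- rell_replicates(m, n, seed)
  centred <- sweep(reps, 2L, colMeans(reps))
  repmax <- do.call(pmax, asplit(centred, 2L))
  p <- vapply(seq_len(nrow(m)), function(t)
    mean(repmax - centred[, t] >= obs[t]), 0)
  stats::setNames(p, rownames(m))
}

# weighted least squares fit of qnorm(1 - BP) = d*sqrt(r) + c/sqrt(r);
# returns p_au = 1 - pnorm(d - c)
au_fit <- function(bp, scales, n) {
  eps <- 0.5 / n                       # continuity clamp for BP of 0 or 1
  degenerate <- all(bp <= eps) || all(bp >= 1 - eps)
  bpc <- pmin(pmax(bp, eps), 1 - eps)
  z <- stats::qnorm(1 - bpc)
  w <- n * stats::dnorm(z)^2 / (bpc * (1 - bpc))
  X <- cbind(sqrt(scales), 1 / sqrt(scales))
  fit <- stats::lm.wfit(X, z, w)
  d <- fit$coefficients[1]; cc <- fit$coefficients[2]
  p <- 1 - stats::pnorm(d - cc)
  if (degenerate) p <- if (all(bp <= eps)) 0 else 1
  list(p = unname(p), degenerate = degenerate)
}

#' Approximately-Unbiased test by multiscale RELL bootstrap
#'
#' At each scale factor `r` the RELL bootstrap resamples `round(r * sites)`
#' sites and records each topology's bootstrap proportion BP(r) (how often
#' it attains the maximum total). The signed-distance/curvature model
#' `qnorm(1 - BP) = d * sqrt(r) + c / sqrt(r)` is fitted by weighted least
#' squares over scales, and `p_au = 1 - pnorm(d - c)`. Bootstrap
#' proportions of identically 0 or 1 across scales give a degenerate fit,
#' clamped to 0 or 1 and flagged.
#'
#' @param m topologies x sites matrix (>= 2 rows).
#' @param scales positive scale factors; must include values below and
#'   above 1 (default the conventional 0.5...1.4 grid).
#' @param n RELL replicates per scale.
#' @param seed integer seed.
#' @return data.frame: `topology`, `p_au`, `degenerate`.
#' @export
au_test <- function(m, scales = seq(0.5, 1.4, by = 0.1), n = 10000L,
                    seed = 1L) {
  m <- as_site_lnl_matrix(m)
  if (nrow(m) < 2L) stop("need at least two topologies")
  scales <- as.numeric(scales)
  if (length(scales) < 2L || !any(scales < 1) || !any(scales > 1))
    stop("need at least two scales spanning values below and above 1")
  S <- ncol(m)
  ntopo <- nrow(m)
  bp <- matrix(0, length(scales), ntopo, dimnames = list(NULL, rownames(m)))
  for (si in seq_along(scales)) {
    reps <- rell_replicates(m, n, seed + si - 1L,
                            n_sites = max(1L, round(scales[si] * S)))
    best <- max.col(reps, ties.method = "first")
    bp[si, ] <- tabulate(best, ntopo) / n
  }
  fits <- lapply(seq_len(ntopo), function(t) au_fit(bp[, t], scales, n))
  data.frame(topology = rownames(m),
             p_au = vapply(fits, `[[`, 0, "p"),
             degenerate = vapply(fits, `[[`, TRUE, "degenerate"),
             stringsAsFactors = FALSE)
}

#' Run the full battery of topology tests
#'
#' Produces the standard topology-test table: per topology, the
#' log-likelihood distance behind the best candidate (`deltaL`), and the
#' KH (against the best topology), SH and AU p values, all from the same
#' site log-likelihood matrix with `n` RELL replicates.
#'
#' @param m topologies x sites matrix.
#' @param n RELL replicates.
#' @param seed integer seed (recorded in the result).
#' @param scales AU scale factors.
#' @return data.frame of class `"topology_tests"`: `topology`, `deltaL`,
#'   `p_kh`, `p_sh`, `p_au`; attributes `n` and `seed`.
#' @export
topology_tests <- function(m, n = 10000L, seed = 1L,
                           scales = seq(0.5, 1.4, by = 0.1)) {
  m <- as_site_lnl_matrix(m)
  totals <- rowSums(m)
  best <- rownames(m)[which.max(totals)]
  p_kh <- vapply(rownames(m), function(t)
    if (t == best) 1 else kh_test(m, t, best, n, seed), 0)
  p_sh <- sh_test(m, n, seed)
  au <- au_test(m, scales, n, seed)
  out <- data.frame(topology = rownames(m), deltaL = max(totals) - totals,
                    p_kh = round(p_kh, 4), p_sh = round(p_sh, 4),
                    p_au = round(au$p_au, 4), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n") <- n; attr(out, "seed") <- seed
  class(out) <- c("topology_tests", "data.frame")
  out
}

#' @export
print.topology_tests <- function(x, ...) {
  cat("RELL topology tests (", attr(x, "n"), " replicates, seed ",
      attr(x, "seed"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
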