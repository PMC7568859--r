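# Independent oracles used to compute expected values. These deliberately do
# NOT share code paths with the implementation they check: the matrix
# exponential is a truncated power series, the tree likelihood an exhaustive
# sum over ancestral-state assignments, the gamma category rates numerical
# quadrature, and the longest inverted repeat an exhaustive common-substring
# search.

# exp(Q t) by truncated power series
oracle_expm <- function(Q, t, kmax = 60L) {
  S <- diag(4)
  term <- diag(4)
  A <- Q * t
  for (k in seq_len(kmax)) {
    term <- term %*% A / k
    S <- S + term
  }
  S
}

# per-site log-likelihood by brute-force enumeration of all internal-state
# assignments (ACGT-only alignments)
oracle_site_lnl <- function(aln, tree, model) {
  tr <- ape::reorder.phylo(tree, "postorder")
  E <- tr$edge
  ntip <- ape::Ntip(tr)
  nint <- tr$Nnode
  m <- unclass(aln)[tr$tip.label, , drop = FALSE]
  S <- ncol(m)
  tipstate <- matrix(match(m, c("A", "C", "G", "T")), nrow(m), S)
  stopifnot(!anyNA(tipstate))
  Q <- gtr_matrix(model)
  rates <- discrete_gamma_rates(model$gamma_shape, model$n_cat)
  pi <- model$base_freqs
  root <- E[nrow(E), 1L]
  grid <- as.matrix(expand.grid(rep(list(1:4), nint)))
  K <- length(rates)
  catsum <- numeric(S)
  for (k in seq_len(K)) {
    Ps <- lapply(seq_len(nrow(E)), function(e)
      oracle_expm(Q, tr$edge.length[e] * rates[k]))
    tot <- numeric(S)
    for (g in seq_len(nrow(grid))) {
      st <- grid[g, ]
      w <- rep(pi[st[root - ntip]], S)
      for (e in seq_len(nrow(E))) {
        p <- st[E[e, 1L] - ntip]
        ch <- E[e, 2L]
        w <- w * (if (ch <= ntip) Ps[[e]][p, ][tipstate[ch, ]]
                  else Ps[[e]][p, st[ch - ntip]])
      }
      tot <- tot + w
    }
    catsum <- catsum + tot
  }
  lik <- (1 - model$p_inv) / K * catsum
  if (model$p_inv > 0) {
    const <- apply(tipstate, 2L, function(x) length(unique(x)) == 1L)
    lik <- lik + model$p_inv * ifelse(const, pi[tipstate[1L, ]], 0)
  }
  log(lik)
}

# mean rate of each equal-probability gamma slab by adaptive quadrature
oracle_gamma_rates <- function(shape, n_cat) {
  q <- c(0, stats::qgamma(seq_len(n_cat - 1L) / n_cat, shape, rate = shape), Inf)
  vapply(seq_len(n_cat), function(k)
    n_cat * stats::integrate(function(x) x * stats::dgamma(x, shape, rate = shape),
                             q[k], q[k + 1L], rel.tol = 1e-12)$value,
    0)
}

# longest inverted repeat by exhaustive common-substring search between the
# sequence and its reverse complement (binary search on the length; at each
# candidate length every substring pair is compared via hashing)
oracle_longest_ir <- function(s) {
  rc <- plastosig:::revcomp(s)
  n <- nchar(s)
  pair_at <- function(L) {
    subs_s <- substring(s, 1:(n - L + 1L), L:n)
    subs_r <- substring(rc, 1:(n - L + 1L), L:n)
    hit <- match(subs_s, subs_r)
    ok <- which(!is.na(hit))
    if (!length(ok)) return(NULL)
    for (i in ok) {
      start1 <- i
      start2 <- n - (hit[i] + L - 1L) + 1L  # rc coords -> s coords
      lo <- min(start1, start2); hi <- max(start1, start2)
      if (lo + L - 1L < hi) return(c(length = L, s1 = lo, s2 = hi))
    }
    NULL
  }
  lo <- 1L; hi <- n %/% 2L; best <- NULL
  while (lo <= hi) {
    mid <- (lo + hi) %/% 2L
    p <- pair_at(mid)
    if (!is.null(p)) { best <- p; lo <- mid + 1L } else hi <- mid - 1L
  }
  best
}

# random valid GTR+I+Gamma model
random_model <- function(seed, gamma = TRUE, inv = TRUE) {
  set.seed(seed)
  f <- stats::runif(4, 0.15, 0.35); f <- f / sum(f)
  substitution_model(rates = c(stats::runif(5, 0.3, 4), 1), base_freqs = f,
                     gamma_shape = if (gamma) stats::runif(1, 0.3, 2) else Inf,
                     n_cat = 4L,
                     p_inv = if (inv) stats::runif(1, 0, 0.4) else 0)
}

# random unrooted tree with moderate branch lengths
random_tree <- function(n, seed) {
  set.seed(seed)
  ape::unroot(ape::rtree(n, br = function(k) stats::runif(k, 0.02, 0.4)))
}

# 2-row null site-lnL matrix: i.i.d. symmetric site deltas split over rows
null_matrix <- function(S, seed, sd = 1) {
  set.seed(seed)
  d <- stats::rnorm(S, 0, sd)
  rbind(a = d / 2, b = -d / 2)
}

# random DNA string
rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random sequence with a planted exact inverted repeat of length L; the four
# bases flanking the two copies are pinned to "A" so the planted repeat is
# exactly maximal (no chance reverse-complement extension, which would make
# the circular detector legitimately disagree with the linear oracle)
plant_ir_seq <- function(n, L, seed) {
  set.seed(seed)
  stopifnot(n > 2L * L + 60L)
  bases <- c("A", "C", "G", "T")
  core <- paste(sample(bases, L, replace = TRUE), collapse = "")
  gap1 <- (n - 2L * L) %/% 3L
  gap2 <- (n - 2L * L) %/% 3L
  gap3 <- n - 2L * L - gap1 - gap2
  s <- paste0(paste(sample(bases, gap1, replace = TRUE), collapse = ""),
              core,
              paste(sample(bases, gap2, replace = TRUE), collapse = ""),
              plastosig:::revcomp(core),
              paste(sample(bases, gap3, replace = TRUE), collapse = ""))
  s1 <- gap1 + 1L
  s2 <- gap1 + L + gap2 + 1L
  for (pos in c(s1 - 1L, s1 + L, s2 - 1L, s2 + L)) substr(s, pos, pos) <- "A"
  list(seq = s, s1 = s1, s2 = s2, L = L)
}
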