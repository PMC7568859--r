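#' General time-reversible substitution model with invariant sites and
#' discrete-gamma rate heterogeneity
#'
#' Constructs a GTR+I+Gamma model description as used throughout the
#' likelihood engine. The model is parameterised by six exchangeabilities
#' (order AC, AG, AT, CG, CT, GT; GT is the reference and is rescaled to 1),
#' stationary base frequencies (order A, C, G, T), a gamma shape parameter
#' for among-site rate variation discretised into `n_cat` equal-probability
#' categories, and a proportion of invariant sites.
#'
#' @param rates numeric(6), positive exchangeabilities in the order
#'   AC, AG, AT, CG, CT, GT. Internally divided by the GT rate so the last
#'   entry is 1 (identifiability).
#' @param base_freqs numeric(4), stationary frequencies of A, C, G, T;
#'   must be positive and sum to 1 (renormalised if within 1e-8).
#' @param gamma_shape positive shape (alpha) of the gamma distribution of
#'   site rates. `Inf` means rate homogeneity across the gamma component.
#' @param n_cat integer >= 1, number of discrete gamma categories (the "4"
#'   in GTR+I+Gamma4).
#' @param p_inv proportion of invariant sites in `[0, 1)`.
#' @return an object of class `"subst_model"`: a list with elements
#'   `rates`, `base_freqs`, `gamma_shape`, `n_cat`, `p_inv`.
#' @examples
#' jc <- substitution_model()                    # Jukes-Cantor
#' gtr <- substitution_model(rates = c(1.2, 3.1, 0.8, 1.1, 4.0, 1),
#'                           base_freqs = c(0.31, 0.19, 0.18, 0.32),
#'                           gamma_shape = 0.5, p_inv = 0.3)
#' @export
substitution_model <- function(rates = rep(1, 6), base_freqs = rep(0.25, 4),
                               gamma_shape = Inf, n_cat = 4L, p_inv = 0) {
  rates <- as.numeric(rates)
  base_freqs <- as.numeric(base_freqs)
  if (length(rates) != 6L || any(!is.finite(rates)) || any(rates <= 0))
    stop("'rates' must be 6 positive exchangeabilities (AC, AG, AT, CG, CT, GT)")
  if (length(base_freqs) != 4L || any(base_freqs <= 0))
    stop("'base_freqs' must be 4 positive frequencies (A, C, G, T)")
  s <- sum(base_freqs)
  if (abs(s - 1) > 1e-8)
    stop("'base_freqs' must sum to 1 (got ", format(s), ")")
  base_freqs <- base_freqs / s
  if (!(is.numeric(gamma_shape) && length(gamma_shape) == 1L && gamma_shape > 0))
    stop("'gamma_shape' must be a single positive number (Inf allowed)")
  n_cat <- as.integer(n_cat)
  if (is.na(n_cat) || n_cat < 1L) stop("'n_cat' must be an integer >= 1")
  if (!(is.numeric(p_inv) && length(p_inv) == 1L && p_inv >= 0 && p_inv < 1))
    stop("'p_inv' must lie in [0, 1)")
  structure(
    list(rates = rates / rates[6L], base_freqs = base_freqs,
         gamma_shape = gamma_shape, n_cat = n_cat, p_inv = p_inv),
    class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("GTR+I+Gamma substitution model\n")
  cat("  exchangeabilities (AC AG AT CG CT GT):",
      paste(formatC(x$rates, digits = 4, format = "g"), collapse = " "), "\n")
  cat("  base frequencies  (A C G T):",
      paste(formatC(x$base_freqs, digits = 4, format = "g"), collapse = " "), "\n")
  cat("  gamma shape:", format(x$gamma_shape), " categories:", x$n_cat,
      " p_inv:", format(x$p_inv), "\n")
  invisible(x)
}

#' Instantaneous GTR rate matrix
#'
#' Builds the 4x4 rate matrix Q with off-diagonal entries
#' `q_ij = r_ij * pi_j`, diagonal entries making rows sum to zero, scaled so
#' that the expected substitution rate over the full site-rate mixture
#' (invariant class at rate 0, gamma classes with mean 1) equals one
#' substitution per site per unit branch length. Concretely
#' `-sum_i pi_i q_ii = 1 / (1 - p_inv)`, the convention of mainstream ML
#' software, which keeps branch lengths in expected substitutions/site.
#'
#' @param model a [substitution_model()].
#' @return 4x4 numeric matrix with dimnames A,C,G,T; rows sum to zero.
#' @export
gtr_matrix <- function(model) {
  stopifnot(inherits(model, "subst_model"))
  r <- model$rates
  pi <- model$base_freqs
  Q <- matrix(0, 4, 4, dimnames = list(DNA_STATES, DNA_STATES))
  Q["A", "C"] <- r[1] * pi[2]; Q["C", "A"] <- r[1] * pi[1]
  Q["A", "G"] <- r[2] * pi[3]; Q["G", "A"] <- r[2] * pi[1]
  Q["A", "T"] <- r[3] * pi[4]; Q["T", "A"] <- r[3] * pi[1]
  Q["C", "G"] <- r[4] * pi[3]; Q["G", "C"] <- r[4] * pi[2]
  Q["C", "T"] <- r[5] * pi[4]; Q["T", "C"] <- r[5] * pi[2]
  Q["G", "T"] <- r[6] * pi[4]; Q["T", "G"] <- r[6] * pi[3]
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))          # mean rate before normalisation
  Q / (mu * (1 - model$p_inv))
}

# Eigen-decomposition of Q through the symmetrised matrix
# S = diag(sqrt(pi)) Q diag(1/sqrt(pi)); reversibility makes S symmetric, so
# the decomposition is real and numerically stable.
gtr_eigen <- function(model) {
  Q <- gtr_matrix(model)
  pi <- model$base_freqs
  sq <- sqrt(pi)
  S <- Q * (sq %o% (1 / sq))
  S <- (S + t(S)) / 2               # kill round-off asymmetry
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values,
       right = e$vectors / sq,      # diag(1/sqrt(pi)) %*% U
       left = t(e$vectors * sq))    # t(U) %*% diag(sqrt(pi))
}

# P(t) from a precomputed gtr_eigen(); t >= 0 in substitutions/site
# (already including any per-category rate multiplier).
prob_matrix <- function(eig, t) {
  P <- eig$right %*% (exp(eig$values * t) * eig$left)
  P[P < 0] <- 0                     # clip tiny negative round-off
  P
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a [substitution_model()].
#' @param t branch length (expected substitutions/site), multiplied by
#'   `rate` for rate-scaled branches.
#' @param rate optional rate multiplier (e.g. a gamma category rate).
#' @return 4x4 stochastic matrix with dimnames A,C,G,T.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  stopifnot(is.numeric(t), length(t) == 1L, t >= 0)
  P <- prob_matrix(gtr_eigen(model), t * rate)
  dimnames(P) <- list(DNA_STATES, DNA_STATES)
  P
}

#' Discrete gamma rate categories (mean-category discretisation)
#'
#' Computes `K` positive rates with equal category probabilities from a
#' Gamma(shape = alpha, rate = alpha) distribution: category `k` gets the
#' conditional mean of the distribution over its equal-probability quantile
#' slab. Rates are nondecreasing and average exactly 1.
#'
#' @param shape positive gamma shape alpha; `Inf` returns all-1 rates.
#' @param n_cat integer >= 1, number of categories.
#' @return numeric(n_cat) of category rates, mean 1.
#' @examples
#' discrete_gamma_rates(0.5, 4)
#' @export
discrete_gamma_rates <- function(shape, n_cat = 4L) {
  n_cat <- as.integer(n_cat)
  if (is.na(n_cat) || n_cat < 1L) stop("'n_cat' must be an integer >= 1")
  if (!(is.numeric(shape) && length(shape) == 1L && shape > 0))
    stop("'shape' must be a single positive number")
  if (n_cat == 1L || !is.finite(shape)) return(rep(1, n_cat))
  breaks <- stats::qgamma(seq_len(n_cat - 1L) / n_cat, shape = shape, rate = shape)
  # E[X ; X in (a, b)] for X ~ Gamma(a, a) equals
  # pgamma(b, a + 1, a) - pgamma(a, a + 1, a); divide by slab probability 1/K.
  cum <- c(0, stats::pgamma(breaks, shape = shape + 1, rate = shape), 1)
  r <- n_cat * diff(cum)
  r / mean(r)                       # exact unit mean despite round-off
}

# Mixture rate vector of the gamma component for a model.
gamma_rates <- function(model) discrete_gamma_rates(model$gamma_shape, model$n_cat)
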