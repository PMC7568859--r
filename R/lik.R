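# Likelihood engine: GTR+I+Gamma site log-likelihoods on a fixed topology
# via Felsenstein's pruning algorithm, plus coordinate-wise optimisation of
# branch lengths and model parameters.

# IUPAC nucleotide codes as 4-state indicator columns (A, C, G, T rows).
# Gaps and fully ambiguous characters contribute partial likelihood 1 over
# every state.
iupac_matrix <- function() {
  codes <- list(
    A = "A", C = "C", G = "G", T = "T", U = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
    "-" = c("A", "C", "G", "T"), "?" = c("A", "C", "G", "T"))
  m <- vapply(codes, function(st) as.numeric(DNA_STATES %in% st), numeric(4))
  rownames(m) <- DNA_STATES
  m
}
IUPAC <- iupac_matrix()

# Precompute everything that depends on alignment + topology but not on
# branch lengths or model parameters: postorder edges, site-pattern
# compression, per-tip indicator matrices, invariant-site compatibility.
lik_prep <- function(aln, tree) {
  stopifnot(inherits(aln, "dna_alignment"), inherits(tree, "phylo"))
  if (!setequal(tree$tip.label, rownames(aln)))
    stop("alignment taxa and tree leaves differ: ",
         paste(union(setdiff(tree$tip.label, rownames(aln)),
                     setdiff(rownames(aln), tree$tip.label)), collapse = ", "))
  tree <- ape::reorder.phylo(tree, "postorder")
  m <- unclass(aln)[tree$tip.label, , drop = FALSE]
  bad <- setdiff(unique(as.vector(m)), colnames(IUPAC))
  if (length(bad))
    stop("unknown sequence characters: ", paste(bad, collapse = ", "))
  key <- do.call(paste0, asplit(m, 1L))
  first <- !duplicated(key)
  pat_index <- match(key, key[first])
  pats <- m[, first, drop = FALSE]
  npat <- ncol(pats)
  ntip <- nrow(m)
  tip <- vector("list", ntip)
  compat <- matrix(1, 4, npat)       # states compatible with a constant site
  for (i in seq_len(ntip)) {
    tip[[i]] <- IUPAC[, pats[i, ], drop = FALSE]
    compat <- compat * tip[[i]]
  }
  all_amb <- colSums(tip[[1L]]) == 4
  for (i in seq_len(ntip)[-1L])
    all_amb <- all_amb & colSums(tip[[i]]) == 4
  list(tree = tree, edge = tree$edge, ntip = ntip,
       nnode = ntip + tree$Nnode, npat = npat,
       pat_index = pat_index, weights = tabulate(pat_index, npat),
       tip = tip, compat = compat, all_ambiguous = all_amb)
}

# Per-pattern log-likelihoods for one rate category.
prune_category <- function(prep, lengths, eig, rate, pi) {
  partial <- vector("list", prep$nnode)
  logscale <- numeric(prep$npat)
  E <- prep$edge
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]; ch <- E[e, 2L]
    P <- prob_matrix(eig, lengths[e] * rate)
    pc <- if (ch <= prep$ntip) prep$tip[[ch]] else partial[[ch]]
    cont <- P %*% pc
    mx <- pmax(cont[1L, ], cont[2L, ], cont[3L, ], cont[4L, ])
    cont <- cont / rep(mx, each = 4L)
    logscale <- logscale + log(mx)
    partial[[p]] <- if (is.null(partial[[p]])) cont else partial[[p]] * cont
  }
  root <- E[nrow(E), 1L]
  log(colSums(pi * partial[[root]])) + logscale
}

# Per-pattern site log-likelihoods under the full GTR+I+Gamma mixture.
prune_patterns <- function(prep, lengths, model, eig = gtr_eigen(model),
                           rates = gamma_rates(model)) {
  pi <- model$base_freqs
  K <- length(rates)
  cat_ll <- matrix(0, K, prep$npat)
  for (k in seq_len(K))
    cat_ll[k, ] <- prune_category(prep, lengths, eig, rates[k], pi)
  p_inv <- model$p_inv
  comp <- cat_ll + log((1 - p_inv) / K)
  if (p_inv > 0) {
    inv_lik <- colSums(pi * prep$compat)
    comp <- rbind(comp, ifelse(inv_lik > 0, log(p_inv * inv_lik), -Inf))
  }
  mx <- do.call(pmax, c(asplit(comp, 1L), list(na.rm = FALSE)))
  as.vector(mx + log(colSums(exp(sweep(comp, 2L, mx, `-`)))))
}

prune_total <- function(prep, lengths, model, eig = gtr_eigen(model),
                        rates = gamma_rates(model)) {
  sum(prune_patterns(prep, lengths, model, eig, rates) * prep$weights)
}

#' Site-wise log-likelihoods on a fixed tree
#'
#' Computes the natural-log likelihood of every alignment site on a given
#' tree (with branch lengths) under a GTR+I+Gamma model, using the pruning
#' algorithm with per-pattern log-scaling. Gaps and ambiguity codes enter as
#' partial likelihood 1 over their compatible states; the invariant-site
#' class contributes `p_inv * sum_x pi_x` over states `x` compatible with a
#' constant site.
#'
#' @param aln a [dna_alignment()] whose taxa equal the tree's leaves.
#' @param tree an `ape::phylo` tree with branch lengths (substitutions/site).
#' @param model a [substitution_model()].
#' @return numeric vector of per-site log-likelihoods (`sum()` of it is the
#'   total log-likelihood).
#' @export
site_log_likelihoods <- function(aln, tree, model) {
  stopifnot(inherits(model, "subst_model"))
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths (use fit_topology to estimate them)")
  prep <- lik_prep(aln, tree)
  if (any(prep$all_ambiguous))
    warning(sum(prep$weights[prep$all_ambiguous]),
            " all-gap/ambiguous site(s); their log-likelihood is 0")
  lengths <- prep$tree$edge.length
  if (any(lengths < 0)) stop("negative branch length")
  prune_patterns(prep, lengths, model)[prep$pat_index]
}

# parameter transforms for the model-parameter optimisation step
model_par_pack <- function(model, free) {
  par <- numeric(0)
  if (free$rates) par <- c(par, log(model$rates[1:5]))
  if (free$gamma_shape) par <- c(par, log(model$gamma_shape))
  if (free$p_inv) {
    p <- min(max(model$p_inv, 1e-4), 0.99)
    par <- c(par, stats::qlogis(p))
  }
  par
}

model_par_unpack <- function(par, model, free) {
  i <- 0L
  if (free$rates) { model$rates[1:5] <- exp(par[i + 1:5]); i <- i + 5L }
  if (free$gamma_shape) {
    model$gamma_shape <- min(exp(par[i + 1L]), 1e6); i <- i + 1L
  }
  if (free$p_inv) model$p_inv <- stats::plogis(par[i + 1L]) * 0.999
  model
}

#' Fit a GTR+I+Gamma model on a fixed topology by maximum likelihood
#'
#' The central fitting function of the package: given an alignment and a
#' *fixed* tree topology, it estimates branch lengths and substitution-model
#' parameters by coordinate-wise maximisation of the log-likelihood
#' (Brent-style 1-D optimisation per branch on a log scale, Nelder-Mead for
#' the model parameters, alternated until the improvement per pass drops
#' below `tol`). No topology search is performed — candidate topologies are
#' user inputs, and the engine scores or refits them as supplied.
#'
#' Base frequencies are taken from the empirical counts of the alignment by
#' default (`empirical_freqs = TRUE`), the convention that keeps fits
#' reproducible; exchangeabilities, gamma shape and the invariant proportion
#' are optimised according to `free`.
#'
#' @param aln a [dna_alignment()].
#' @param tree an `ape::phylo` topology over the alignment's taxa. Branch
#'   lengths, if present, are used as starting values; the tree is unrooted
#'   first (the model is time-reversible, so root placement is irrelevant).
#' @param model starting [substitution_model()]. Its `gamma_shape = Inf`
#'   disables the gamma component (and its optimisation) unless `free`
#'   says otherwise.
#' @param free named list of logical flags: `branch_lengths`, `rates`
#'   (exchangeabilities), `gamma_shape`, `p_inv`. Missing entries default to
#'   `TRUE` (except `gamma_shape` when the starting shape is infinite).
#' @param empirical_freqs replace the model's base frequencies by the
#'   empirical frequencies of the alignment before fitting.
#' @param init_branch starting branch length for edges without one.
#' @param tol convergence tolerance in log-likelihood units per pass.
#' @param max_passes maximum optimisation passes; non-convergence returns
#'   the best fit so far with `converged = FALSE` and a warning.
#' @return an object of class `"topofit"`: list with `tree` (fitted branch
#'   lengths), `model`, `logLik`, `site_lnl` (per-site vector), `passes`,
#'   `converged`, `nsites`, `ntaxa`.
#' @seealso [site_log_likelihoods()], [site_lnl_matrix()]
#' @examples
#' set.seed(1)
#' tr <- ape::rtree(5, br = function(n) runif(n, 0.05, 0.2))
#' mod <- substitution_model(gamma_shape = 1, p_inv = 0)
#' aln <- simulate_alignment(tr, mod, 500, seed = 7)
#' fit <- fit_topology(aln, tr, mod, free = list(rates = FALSE, p_inv = FALSE))
#' fit
#' @export
fit_topology <- function(aln, tree, model = substitution_model(gamma_shape = 1),
                         free = list(), empirical_freqs = TRUE,
                         init_branch = 0.05, tol = 1e-4, max_passes = 200L) {
  stopifnot(inherits(model, "subst_model"))
  defaults <- list(branch_lengths = TRUE, rates = TRUE,
                   gamma_shape = is.finite(model$gamma_shape),
                   p_inv = model$p_inv > 0)
  free <- utils::modifyList(defaults, free[intersect(names(free), names(defaults))])
  if (!is.finite(model$gamma_shape)) free$gamma_shape <- FALSE
  if (ape::Ntip(tree) > 3L && ape::is.rooted(tree)) tree <- ape::unroot(tree)
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(init_branch, nrow(tree$edge))
  if (empirical_freqs) {
    counts <- vapply(DNA_STATES, function(s) sum(unclass(aln) == s), 0)
    counts <- pmax(counts, 1)
    model$base_freqs <- counts / sum(counts)
  }
  prep <- lik_prep(aln, tree)
  lengths <- pmin(pmax(prep$tree$edge.length, 1e-8), 100)
  nedge <- nrow(prep$edge)
  # a two-taxon tree has one free path length; hold the extra edge at ~0
  opt_edges <- if (prep$ntip == 2L) 1L else seq_len(nedge)
  if (prep$ntip == 2L && nedge > 1L) lengths[-1L] <- 1e-8

  cur <- prune_total(prep, lengths, model)
  any_model_free <- free$rates || free$gamma_shape || free$p_inv
  passes <- 0L
  converged <- FALSE
  log_lo <- log(1e-8); log_hi <- log(100)
  while (passes < max_passes) {
    passes <- passes + 1L
    before <- cur
    if (free$branch_lengths) {
      eig <- gtr_eigen(model)
      rates <- gamma_rates(model)
      for (e in opt_edges) {
        f <- function(lt) {
          l2 <- lengths; l2[e] <- exp(lt)
          -prune_total(prep, l2, model, eig, rates)
        }
        opt <- stats::optimize(f, c(log_lo, log_hi), tol = 1e-7)
        if (-opt$objective >= cur) {
          lengths[e] <- exp(opt$minimum)
          cur <- -opt$objective
        }
      }
    }
    if (any_model_free) {
      par0 <- model_par_pack(model, free)
      obj <- function(par)
        -prune_total(prep, lengths, model_par_unpack(par, model, free))
      opt <- if (length(par0) == 1L)
        stats::optim(par0, obj, method = "Brent", lower = par0 - 8,
                     upper = par0 + 8)
      else stats::optim(par0, obj, method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-10))
      if (-opt$value >= cur) {
        model <- model_par_unpack(opt$par, model, free)
        cur <- -opt$value
      }
    }
    if (cur - before < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("fit_topology: not converged after ", max_passes,
            " passes; returning best fit so far")
  fitted_tree <- prep$tree
  fitted_tree$edge.length <- lengths
  site_lnl <- prune_patterns(prep, lengths, model)[prep$pat_index]
  structure(list(tree = fitted_tree, model = model, logLik = sum(site_lnl),
                 site_lnl = site_lnl, passes = passes, converged = converged,
                 free = free, nsites = ncol(aln), ntaxa = nrow(aln)),
            class = "topofit")
}

#' @export
print.topofit <- function(x, ...) {
  cat("Fixed-topology ML fit (GTR+I+Gamma)\n")
  cat("  taxa:", x$ntaxa, " sites:", x$nsites,
      " log-likelihood:", formatC(x$logLik, format = "f", digits = 4), "\n")
  cat("  passes:", x$passes,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' @export
summary.topofit <- function(object, ...) {
  out <- list(logLik = object$logLik, ntaxa = object$ntaxa,
              nsites = object$nsites, model = object$model,
              tree_length = sum(object$tree$edge.length),
              branch_lengths = object$tree$edge.length,
              passes = object$passes, converged = object$converged)
  class(out) <- "summary.topofit"
  out
}

#' @export
print.summary.topofit <- function(x, ...) {
  cat("Fixed-topology ML fit\n")
  cat("  log-likelihood:", formatC(x$logLik, format = "f", digits = 4),
      " (", x$ntaxa, "taxa,", x$nsites, "sites )\n")
  cat("  tree length:", formatC(x$tree_length, digits = 5, format = "g"),
      "substitutions/site over", length(x$branch_lengths), "branches\n")
  print(x$model)
  cat("  convergence:", if (x$converged) "yes" else "NO", "after",
      x$passes, "passes\n")
  invisible(x)
}

#' @export
coef.topofit <- function(object, ...) {
  m <- object$model
  c(stats::setNames(m$rates, paste0("r_", c("AC", "AG", "AT", "CG", "CT", "GT"))),
    stats::setNames(m$base_freqs, paste0("pi_", DNA_STATES)),
    gamma_shape = m$gamma_shape, p_inv = m$p_inv)
}

#' @export
logLik.topofit <- function(object, ...) {
  npar <- sum(object$free$branch_lengths * length(object$tree$edge.length),
              object$free$rates * 5, object$free$gamma_shape, object$free$p_inv)
  structure(object$logLik, df = npar, nobs = object$nsites, class = "logLik")
}

#' @export
simulate.topofit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  lapply(seq_len(nsim), function(i)
    simulate_alignment(object$tree, object$model, object$nsites,
                       seed = seed + i - 1L))
}

#' @export
plot.topofit <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  invisible(x)
}
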