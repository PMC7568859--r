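# Locus-wise phylogenetic-signal dissection: per-topology site
# log-likelihoods -> per-locus delta-lnL, support classification, summaries
# and locus-removal experiments.

#' Site log-likelihood matrix for several candidate topologies
#'
#' Fits (or scores) each candidate topology on the same alignment and stacks
#' the per-site log-likelihood vectors into a topologies-by-sites matrix,
#' the common input of the delta-lnL dissection and of the RELL topology
#' tests.
#'
#' @param aln a [dna_alignment()].
#' @param topologies named list of `ape::phylo` candidate topologies.
#' @param model starting [substitution_model()] for each fit.
#' @param free passed to [fit_topology()]; with everything `FALSE` and
#'   branch lengths present, topologies are scored as supplied.
#' @param ... further arguments to [fit_topology()].
#' @return matrix of class `"site_lnl_matrix"` (rows = topologies, columns =
#'   sites), with attribute `"fits"` holding the `topofit` objects.
#' @export
site_lnl_matrix <- function(aln, topologies, model = preset_model(),
                            free = list(), ...) {
  if (is.null(names(topologies)) || anyDuplicated(names(topologies)))
    stop("'topologies' must be a uniquely named list")
  fits <- lapply(topologies, function(tr)
    fit_topology(aln, tr, model, free = free, ...))
  m <- do.call(rbind, lapply(fits, `[[`, "site_lnl"))
  rownames(m) <- names(topologies)
  structure(m, class = c("site_lnl_matrix", "matrix", "array"), fits = fits)
}

as_site_lnl_matrix <- function(m) {
  if (!is.matrix(m) || is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("a site-lnL matrix needs unique topology row names")
  if (!ncol(m)) stop("empty site-lnL matrix")
  m
}

#' Write / read a site-lnL matrix as TSV
#'
#' Columns: `site`, then one column per topology.
#' @param m topologies x sites matrix with row names.
#' @param path file path.
#' @export
write_site_lnl_tsv <- function(m, path) {
  df <- data.frame(site = seq_len(ncol(m)), t(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_lnl_tsv
#' @export
read_site_lnl_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- NULL
  structure(m, class = c("site_lnl_matrix", "matrix", "array"))
}

#' Locus-wise log-likelihood differences between two topologies
#'
#' Sums the site-wise log-likelihood difference `lnL_a - lnL_b` over each
#' locus's columns. Positive values support topology `a` (the sign
#' convention, first label minus second, is recorded in the output). Columns
#' covered by no locus are aggregated as the pseudo-locus `"_unpartitioned"`,
#' so the locus-wise values always sum exactly to the total difference.
#'
#' @param m topologies x sites log-likelihood matrix (rows named).
#' @param a,b topology labels (rows of `m`).
#' @param partition a [partition_map()] on the matrix columns.
#' @param strong,moderate classification thresholds passed to
#'   [classify_support()].
#' @return data.frame of class `"dlnl_table"`: `locus`, `kind`, `length`,
#'   `dlnl`, `class`; attributes `"a"`, `"b"`, `"total_delta"`.
#' @export
locuswise_delta <- function(m, a, b, partition, strong = 2.0, moderate = 1.0) {
  m <- as_site_lnl_matrix(m)
  if (!all(c(a, b) %in% rownames(m)))
    stop("labels not in matrix: ", paste(setdiff(c(a, b), rownames(m)),
                                         collapse = ", "))
  ns <- ncol(m)
  if (any(partition$end > ns)) stop("partition columns outside the matrix")
  d <- m[a, ] - m[b, ]
  covered <- rep(FALSE, ns)
  locus <- partition$locus
  kind <- partition$kind
  len <- partition_lengths(partition)
  dl <- numeric(nrow(partition))
  for (i in seq_len(nrow(partition))) {
    cols <- partition_cols(partition, i)
    if (any(covered[cols])) stop("overlapping partition ranges")
    covered[cols] <- TRUE
    dl[i] <- sum(d[cols])
  }
  if (!all(covered)) {
    locus <- c(locus, "_unpartitioned")
    kind <- c(kind, "unpartitioned")
    len <- c(len, sum(!covered))
    dl <- c(dl, sum(d[!covered]))
  }
  tab <- data.frame(locus = locus, kind = kind, length = len, dlnl = dl,
                    stringsAsFactors = FALSE)
  class(tab) <- c("dlnl_table", "data.frame")
  attr(tab, "a") <- a; attr(tab, "b") <- b
  attr(tab, "total_delta") <- sum(d)
  classify_support(tab, strong = strong, moderate = moderate)
}

#' Classify locus support from delta-lnL values
#'
#' Strict-threshold classification: `|dlnl| > strong` is strong support,
#' `moderate < |dlnl| <= strong` moderate, anything else weak (so a value of
#' exactly 2 with the default thresholds is moderate, not strong). The side
#' (A or B) follows the sign, positive supporting the first topology of the
#' comparison. Zero-length loci are flagged weak.
#'
#' @param table a `dlnl_table` from [locuswise_delta()].
#' @param strong,moderate positive thresholds, `strong > moderate`.
#' @return the table with a `class` column in
#'   `{strong_A, moderate_A, weak, moderate_B, strong_B}`.
#' @export
classify_support <- function(table, strong = 2.0, moderate = 1.0) {
  stopifnot(strong > moderate, moderate > 0)
  a <- abs(table$dlnl)
  side <- ifelse(table$dlnl > 0, "A", "B")
  cls <- ifelse(a > strong, paste0("strong_", side),
                ifelse(a > moderate, paste0("moderate_", side), "weak"))
  table$class <- cls
  attr(table, "thresholds") <- c(strong = strong, moderate = moderate)
  table
}

#' @export
print.dlnl_table <- function(x, n = 10L, ...) {
  cat("Locus-wise delta-lnL:", attr(x, "a"), "-", attr(x, "b"),
      "(positive supports", paste0(attr(x, "a"), ")"), "\n")
  o <- order(-abs(x$dlnl))
  print.data.frame(utils::head(x[o, ], n), row.names = FALSE)
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more loci\n")
  invisible(x)
}

#' Summarise a pairwise delta-lnL comparison
#'
#' The classic per-panel summary: the sum of positive delta-lnL values with
#' the count of loci carrying them, the sum of negatives with its count, and
#' the net difference (which equals the total log-likelihood difference
#' between the two topologies).
#'
#' @param table a `dlnl_table`.
#' @return one-row data.frame: `a`, `b`, `sum_positive`, `n_positive`,
#'   `sum_negative`, `n_negative`, `net`.
#' @export
summarize_comparison <- function(table) {
  stopifnot(nrow(table) > 0)
  pos <- table$dlnl > 0; neg <- table$dlnl < 0
  data.frame(a = attr(table, "a") %||% NA, b = attr(table, "b") %||% NA,
             sum_positive = sum(table$dlnl[pos]), n_positive = sum(pos),
             sum_negative = sum(table$dlnl[neg]), n_negative = sum(neg),
             net = sum(table$dlnl))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Export a delta-lnL table as TSV, sorted by |delta-lnL|
#'
#' @param table a `dlnl_table`.
#' @param path output file; a header line records the sign convention.
#' @export
write_dlnl_tsv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# delta_lnl = lnL(%s) - lnL(%s); positive supports %s",
                     attr(table, "a"), attr(table, "b"), attr(table, "a")), con)
  o <- order(-abs(table$dlnl))
  utils::write.table(as.data.frame(table)[o, ], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' All-pairs delta-lnL dissection of three (or more) topologies
#'
#' Builds the pairwise `dlnl_table` for every ordered pair of topology
#' labels (each unordered pair once), and a per-locus verdict: a locus
#' "supports" a topology when that topology beats every rival in its
#' pairwise deltas by more than the `moderate` threshold, with class taken
#' from the weakest winning margin.
#'
#' @param m topologies x sites matrix.
#' @param partition a [partition_map()].
#' @param strong,moderate thresholds as in [classify_support()].
#' @return list with `pairs` (named list of `dlnl_table`s, names like
#'   `"T1_vs_T2"`) and `support` (data.frame: locus, kind, length,
#'   best topology or `"none"`, class of support).
#' @export
signal_dissection <- function(m, partition, strong = 2.0, moderate = 1.0) {
  m <- as_site_lnl_matrix(m)
  labs <- rownames(m)
  if (length(labs) < 2L) stop("need at least two topologies")
  pairs <- list()
  for (i in seq_along(labs)) for (j in seq_along(labs)) if (i < j)
    pairs[[paste0(labs[i], "_vs_", labs[j])]] <-
      locuswise_delta(m, labs[i], labs[j], partition, strong, moderate)
  base <- pairs[[1]]
  delta_of <- function(x, y) {      # locus-wise lnL_x - lnL_y
    key <- paste0(x, "_vs_", y)
    if (key %in% names(pairs)) pairs[[key]]$dlnl else -pairs[[paste0(y, "_vs_", x)]]$dlnl
  }
  best <- rep("none", nrow(base))
  best_class <- rep("weak", nrow(base))
  for (t in labs) {
    rivals <- setdiff(labs, t)
    margins <- matrix(vapply(rivals, function(r) delta_of(t, r),
                             numeric(nrow(base))), nrow = nrow(base))
    wins <- rowSums(margins > 0) == ncol(margins)
    margin <- do.call(pmin, asplit(margins, 2L))
    cls <- ifelse(margin > strong, "strong",
                  ifelse(margin > moderate, "moderate", "weak"))
    take <- wins & cls != "weak"
    best[take] <- t
    best_class[take] <- cls[take]
  }
  support <- data.frame(locus = base$locus, kind = base$kind,
                        length = base$length, supports = best,
                        class = best_class, stringsAsFactors = FALSE)
  list(pairs = pairs, support = support)
}

#' Locus-removal experiment
#'
#' Removes named loci from a partitioned alignment, refits every candidate
#' topology on the reduced data with [fit_topology()], and ranks candidates
#' by total log-likelihood. This re-scores the supplied resolved candidates
#' rather than re-searching tree space (topology search is out of scope);
#' branch lengths and model parameters are re-optimised on the reduced
#' alignment according to `free`.
#'
#' @param aln a [dna_alignment()].
#' @param partition a [partition_map()].
#' @param topologies named list (>= 2) of candidate `ape::phylo` trees.
#' @param model starting [substitution_model()].
#' @param exclude locus names to remove (validated).
#' @param free,... passed to [fit_topology()].
#' @return data.frame ranked by decreasing log-likelihood: `topology`,
#'   `logLik`, `deltaL` (lnL behind the best); attribute `"fits"`.
#' @export
removal_experiment <- function(aln, partition, topologies,
                               model = preset_model(), exclude = character(),
                               free = list(), ...) {
  if (length(topologies) < 2L) stop("need at least two candidate topologies")
  red <- derive_dataset(aln, partition, "all", exclude = exclude)
  fits <- lapply(topologies, function(tr)
    fit_topology(red$alignment, tr, model, free = free, ...))
  ll <- vapply(fits, `[[`, 0, "logLik")
  o <- order(-ll)
  out <- data.frame(topology = names(topologies)[o], logLik = ll[o],
                    deltaL = max(ll) - ll[o], stringsAsFactors = FALSE)
  attr(out, "fits") <- fits
  out
}
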