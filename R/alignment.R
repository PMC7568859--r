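#' DNA alignment container
#'
#' A thin container for a taxa-by-sites DNA character matrix. Rows are taxa
#' (unique ordered labels), columns are alignment sites. Characters are
#' upper-cased; `?` is normalised to `N`; `-` is the only gap character.
#'
#' @param x a character matrix (rows = taxa) or a named character vector of
#'   equal-length sequence strings.
#' @return an object of class `"dna_alignment"` (a character matrix).
#' @export
dna_alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop("sequences must be named by taxon")
    n <- nchar(x)
    if (length(unique(n)) != 1L) stop("all rows must have equal length")
    x <- do.call(rbind, lapply(x, function(s) strsplit(s, "")[[1]]))
  }
  if (!is.matrix(x) || !is.character(x)) stop("'x' must be a character matrix")
  if (is.null(rownames(x))) stop("alignment rows must be named by taxon")
  if (anyDuplicated(rownames(x))) stop("taxon labels must be unique")
  if (nrow(x) < 2L) stop("an alignment needs at least 2 taxa")
  if (ncol(x) < 1L) stop("an alignment needs at least 1 site")
  x[] <- toupper(x)
  x[x == "?"] <- "N"
  structure(x, class = c("dna_alignment", class(x)))
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("DNA alignment:", nrow(x), "taxa x", ncol(x), "sites\n")
  invisible(x)
}

# subsetting keeps the class (and stays a matrix)
#' @export
`[.dna_alignment` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  class(out) <- c("dna_alignment", "matrix", "array")
  out
}

#' Read a FASTA alignment
#'
#' @param path FASTA file with aligned, equal-length sequences.
#' @return a [dna_alignment()].
#' @export
read_fasta_alignment <- function(path) {
  m <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                     as.matrix = TRUE)
  dna_alignment(unclass(m))
}

#' Write an alignment to FASTA
#'
#' @param aln a [dna_alignment()].
#' @param path output file.
#' @param width characters per sequence line.
#' @export
write_fasta_alignment <- function(aln, path, width = 80L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    s <- paste(aln[i, ], collapse = "")
    chunks <- substring(s, seq(1, nchar(s), width),
                        pmin(seq(1, nchar(s), width) + width - 1L, nchar(s)))
    writeLines(c(paste0(">", rownames(aln)[i]), chunks), con)
  }
  invisible(path)
}

#' Partition map: named, typed column ranges of an alignment
#'
#' Records which alignment columns belong to which locus. Ranges are 1-based
#' inclusive, pairwise disjoint, and may jointly cover only a subset of the
#' columns. A locus masked down to zero length is represented by an empty
#' range (`end == start - 1`).
#'
#' @param locus character, unique locus names.
#' @param kind character, locus type (conventionally one of `coding`,
#'   `intron`, `trna`, `rrna`, `igs`).
#' @param start,end integer column ranges, 1-based inclusive.
#' @return a data.frame of class `"partition_map"` with columns
#'   `locus`, `kind`, `start`, `end`.
#' @export
partition_map <- function(locus, kind, start, end) {
  locus <- as.character(locus); kind <- as.character(kind)
  start <- as.integer(start); end <- as.integer(end)
  if (anyDuplicated(locus)) stop("locus names must be unique")
  if (any(end < start - 1L)) stop("invalid range (end < start - 1)")
  pm <- data.frame(locus = locus, kind = kind, start = start, end = end,
                   stringsAsFactors = FALSE)
  nonempty <- pm[pm$end >= pm$start, , drop = FALSE]
  if (nrow(nonempty) > 1L) {
    o <- order(nonempty$start)
    s <- nonempty$start[o]; e <- nonempty$end[o]
    if (any(s[-1L] <= e[-length(e)]))
      stop("partition ranges overlap")
  }
  structure(pm, class = c("partition_map", "data.frame"))
}

partition_lengths <- function(pm) pmax(pm$end - pm$start + 1L, 0L)

# integer columns of one partition row
partition_cols <- function(pm, i) {
  if (pm$end[i] < pm$start[i]) integer(0) else pm$start[i]:pm$end[i]
}

#' Strip high-gap alignment columns
#'
#' Removes every column whose gap fraction (fraction of `-` among taxa)
#' exceeds `threshold`. `threshold = 0` keeps only entirely gap-free
#' columns. Ambiguity codes (including `N`) count as non-gap. If a
#' [partition_map()] is supplied it is remapped onto the surviving columns
#' (a fully masked locus keeps an empty range).
#'
#' @param aln a [dna_alignment()].
#' @param threshold allowed gap fraction in `[0, 1]`.
#' @param partition optional [partition_map()].
#' @return the masked alignment, or `list(alignment, partition)` when a
#'   partition is supplied.
#' @export
mask_gap_columns <- function(aln, threshold, partition = NULL) {
  stopifnot(inherits(aln, "dna_alignment"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  gapfrac <- colMeans(unclass(aln) == "-")
  keep <- gapfrac <= threshold
  if (!any(keep)) stop("empty alignment after masking")
  out <- aln[, keep, drop = FALSE]
  if (is.null(partition)) return(out)
  surv <- cumsum(keep)                 # new index of old column i (if kept)
  ns <- ne <- integer(nrow(partition))
  for (i in seq_len(nrow(partition))) {
    cols <- partition_cols(partition, i)
    kept <- cols[keep[cols]]
    if (length(kept)) { ns[i] <- surv[kept[1L]]; ne[i] <- surv[kept[length(kept)]] }
    else {
      before <- if (partition$start[i] > 1L) surv[partition$start[i] - 1L] else 0L
      ns[i] <- before + 1L; ne[i] <- before       # empty range
    }
  }
  list(alignment = out,
       partition = partition_map(partition$locus, partition$kind, ns, ne))
}

#' Concatenate per-locus alignments into a supermatrix
#'
#' @param loci named list of [dna_alignment()] objects (names = locus names).
#' @param taxa master taxon set; defaults to the union over loci, in order of
#'   first appearance. Taxa missing from a locus are padded with gaps.
#' @param kinds optional character vector of locus kinds (recycled names of
#'   `loci`); defaults to `"unknown"`.
#' @return `list(alignment, partition)`.
#' @export
concatenate_loci <- function(loci, taxa = NULL, kinds = NULL) {
  if (is.null(names(loci)) || anyDuplicated(names(loci)))
    stop("'loci' must be a uniquely named list")
  if (is.null(taxa)) taxa <- unique(unlist(lapply(loci, rownames)))
  if (is.null(kinds)) kinds <- rep("unknown", length(loci))
  kinds <- rep_len(as.character(kinds), length(loci))
  widths <- vapply(loci, ncol, 0L)
  blocks <- vector("list", length(loci))
  for (i in seq_along(loci)) {
    a <- loci[[i]]
    extra <- setdiff(rownames(a), taxa)
    if (length(extra))
      stop("locus '", names(loci)[i], "' has taxa outside the master set: ",
           paste(extra, collapse = ", "))
    b <- matrix("-", length(taxa), ncol(a), dimnames = list(taxa, NULL))
    b[rownames(a), ] <- unclass(a)
    blocks[[i]] <- b
  }
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  list(alignment = dna_alignment(do.call(cbind, blocks)),
       partition = partition_map(names(loci), kinds, starts, ends))
}

#' Split a concatenated alignment back into per-locus alignments
#'
#' @param aln a [dna_alignment()].
#' @param partition a [partition_map()] on `aln`'s columns.
#' @return named list of [dna_alignment()] objects (empty loci are dropped).
#' @export
split_by_partition <- function(aln, partition) {
  out <- list()
  for (i in seq_len(nrow(partition))) {
    cols <- partition_cols(partition, i)
    if (length(cols)) out[[partition$locus[i]]] <- aln[, cols, drop = FALSE]
  }
  out
}

#' Derive a dataset by locus selection
#'
#' Subsets the columns of a partitioned alignment: all loci, coding loci
#' only, non-coding loci only, and/or everything except named loci. Column
#' order is preserved and the partition remapped.
#'
#' @param aln a [dna_alignment()].
#' @param partition a [partition_map()].
#' @param selector one of `"all"`, `"cds_only"`, `"noncds_only"`.
#' @param exclude character vector of locus names to drop (checked).
#' @return `list(alignment, partition)`.
#' @export
derive_dataset <- function(aln, partition,
                           selector = c("all", "cds_only", "noncds_only"),
                           exclude = character()) {
  selector <- match.arg(selector)
  unknown <- setdiff(exclude, partition$locus)
  if (length(unknown))
    stop("unknown loci in 'exclude': ", paste(unknown, collapse = ", "))
  keep <- switch(selector,
                 all = rep(TRUE, nrow(partition)),
                 cds_only = partition$kind == "coding",
                 noncds_only = partition$kind != "coding")
  keep <- keep & !(partition$locus %in% exclude)
  pm <- partition[keep, , drop = FALSE]
  if (!nrow(pm)) stop("no loci left after selection")
  cols <- unlist(lapply(seq_len(nrow(pm)), function(i) partition_cols(pm, i)))
  if (!length(cols)) stop("selected loci have no columns")
  widths <- partition_lengths(pm)
  ends <- cumsum(widths)
  list(alignment = aln[, cols, drop = FALSE],
       partition = partition_map(pm$locus, pm$kind, ends - widths + 1L, ends))
}

#' Write a partition map as a RAxML-style partition file
#'
#' One line per locus: `DNA, <name> = <start>-<end>`.
#' @param partition a [partition_map()].
#' @param path output file.
#' @export
write_partition_file <- function(partition, path) {
  nonempty <- partition[partition$end >= partition$start, , drop = FALSE]
  writeLines(sprintf("DNA, %s = %d-%d", nonempty$locus, nonempty$start,
                     nonempty$end), path)
  invisible(path)
}

#' Read a RAxML-style partition file
#'
#' @param path partition file written by [write_partition_file()].
#' @param kinds optional named character vector mapping locus name to kind.
#' @return a [partition_map()] (kind `"unknown"` unless given).
#' @export
read_partition_file <- function(path, kinds = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^DNA,\\s*(\\S+)\\s*=\\s*(\\d+)-(\\d+)$", lines))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stop("unparseable partition line: ", lines[bad][1L])
  locus <- vapply(m, `[`, "", 2L)
  kind <- if (is.null(kinds)) rep("unknown", length(locus)) else
    ifelse(locus %in% names(kinds), kinds[locus], "unknown")
  partition_map(locus, kind,
                as.integer(vapply(m, `[`, "", 3L)),
                as.integer(vapply(m, `[`, "", 4L)))
}

#' Write a partition map as TSV
#' @param partition a [partition_map()].
#' @param path output file.
#' @export
write_partition_tsv <- function(partition, path) {
  utils::write.table(as.data.frame(partition), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
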