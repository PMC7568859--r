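# Plastome records, quadripartite structure detection, region statistics,
# gene counts and typed locus extraction.

#' Annotated plastome record
#'
#' A circular DNA sequence with named gene features. Coordinates are 1-based
#' inclusive throughout.
#'
#' @param id accession-like identifier.
#' @param sequence DNA string over A, C, G, T, N (IUPAC codes tolerated).
#' @param features list of features, each a list with elements `gene`
#'   (name), `kind` (`"CDS"`, `"tRNA"` or `"rRNA"`), `strand` (`"+"`/`"-"`)
#'   and `intervals` (two-column start/end matrix, exons in order along the
#'   strand for multi-exon features).
#' @return an object of class `"plastome_record"`.
#' @export
plastome_record <- function(id, sequence, features = list()) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("empty sequence")
  feats <- lapply(features, function(f) {
    iv <- matrix(as.integer(f$intervals), ncol = 2L)
    colnames(iv) <- c("start", "end")
    if (any(iv[, 1] > iv[, 2])) stop("feature ", f$gene, ": start > end")
    if (any(iv < 1L) || any(iv > n))
      stop("feature ", f$gene, " lies outside the sequence [1, ", n, "]")
    if (!f$kind %in% c("CDS", "tRNA", "rRNA"))
      stop("feature ", f$gene, ": unknown kind '", f$kind, "'")
    if (!f$strand %in% c("+", "-")) stop("feature ", f$gene, ": bad strand")
    list(gene = as.character(f$gene), kind = f$kind, strand = f$strand,
         intervals = iv)
  })
  structure(list(id = as.character(id), sequence = sequence, features = feats),
            class = "plastome_record")
}

#' @export
print.plastome_record <- function(x, ...) {
  cat("Plastome record", x$id, "-", nchar(x$sequence), "bp,",
      length(x$features), "features\n")
  invisible(x)
}

# --- circular coordinate helpers (ranges are list(start, length)) ---------

circ_range <- function(start, length) list(start = as.integer(start),
                                           length = as.integer(length))

circ_extract <- function(sequence, range) {
  n <- nchar(sequence)
  s <- range$start; L <- range$length
  if (L == 0L) return("")
  e <- s + L - 1L
  if (e <= n) substr(sequence, s, e)
  else paste0(substr(sequence, s, n), substr(sequence, 1L, e - n))
}

#' Rotate a circular sequence
#'
#' Returns the sequence re-written to start at position `offset + 1` of the
#' original. Rotation changes coordinates but no region length or
#' composition statistic.
#'
#' @param sequence DNA string.
#' @param offset number of leading bases moved to the end.
#' @export
rotate_sequence <- function(sequence, offset) {
  n <- nchar(sequence)
  offset <- ((offset %% n) + n) %% n
  if (offset == 0) return(sequence)
  paste0(substr(sequence, offset + 1L, n), substr(sequence, 1L, offset))
}

#' Rotate a plastome record (sequence and feature coordinates)
#'
#' Used to normalise rotation, conventionally so that the LSC region starts
#' at position 1. Features that would span the new origin raise an error.
#'
#' @param record a [plastome_record()].
#' @param offset bases moved from the front to the back.
#' @param drop_spanning drop (with a message) features that would span the
#'   new origin instead of raising an error.
#' @export
rotate_plastome_record <- function(record, offset, drop_spanning = FALSE) {
  n <- nchar(record$sequence)
  offset <- ((offset %% n) + n) %% n
  if (offset == 0) return(record)
  feats <- lapply(record$features, function(f) {
    iv <- ((f$intervals - offset - 1L) %% n) + 1L
    if (any(iv[, 1] > iv[, 2])) {
      if (drop_spanning) {
        message("dropping feature ", f$gene, ": spans the rotation origin")
        return(NULL)
      }
      stop("feature ", f$gene, " would span the new origin; ",
           "choose a different rotation")
    }
    f$intervals <- iv
    f
  })
  feats <- feats[!vapply(feats, is.null, TRUE)]
  plastome_record(record$id, rotate_sequence(record$sequence, offset), feats)
}

# maximal exact extension of a seed inverted-repeat pair on the doubled
# sequence; (a1..a2) pairs reverse-complementarily with (b1..b2).
# n is the (single-copy) circle length; extension keeps the two copies
# disjoint and the whole span within one circle.
extend_ir_pair <- function(dv, cv, n, a1, a2, b1, b2, max_mismatch = 0L) {
  N2 <- length(dv)
  budget <- max_mismatch
  # rightwards on copy 1 = leftwards on copy 2 (gap between copies shrinks 2/step)
  room <- min(N2 - a2, (b1 - a2 - 1L) %/% 2L)
  if (room > 0L) {
    mism <- dv[(a2 + 1L):(a2 + room)] != cv[(b1 - 1L):(b1 - room)]
    mm <- which(mism)
    take <- if (length(mm) > budget) mm[budget + 1L] - 1L else room
    if (take > 0L) budget <- budget - sum(mism[seq_len(take)])
    a2 <- a2 + take; b1 <- b1 - take
  }
  # leftwards on copy 1 = rightwards on copy 2 (total span grows 2/step)
  room <- min(a1 - 1L, N2 - b2, (n - (b2 - a1 + 1L)) %/% 2L)
  if (room > 0L) {
    mism <- dv[(a1 - 1L):(a1 - room)] != cv[(b2 + 1L):(b2 + room)]
    mm <- which(mism)
    take <- if (length(mm) > budget) mm[budget + 1L] - 1L else room
    a1 <- a1 - take; b2 <- b2 + take
  }
  c(a1 = a1, a2 = a2, b1 = b1, b2 = b2)
}

#' Detect the quadripartite structure of a plastome
#'
#' Finds the longest pair of reverse-complement-identical repeats (the
#' inverted repeat, IR) of at least `min_ir` bases by seed-and-extend search
#' on the doubled (circular) sequence, then names the two single-copy gaps:
#' the longer one is the LSC, the shorter the SSC, and IRa is the repeat
#' copy immediately following the LSC. Exact repeats by default; a mismatch
#' tolerance can be allowed during extension.
#'
#' @param x a [plastome_record()] or a DNA string.
#' @param min_ir minimum IR length in bp (default 1000 — exact long IRs are
#'   the norm in Lauraceae-like plastomes; lower it for toy sequences).
#' @param max_mismatch mismatches tolerated while extending the repeat.
#' @return object of class `"quadripartite"`: list of circular ranges
#'   `lsc`, `ira`, `ssc`, `irb`, each `list(start, length)` in 1-based
#'   coordinates of the input rotation, plus `total`.
#' @export
detect_quadripartite <- function(x, min_ir = 1000L, max_mismatch = 0L) {
  sequence <- if (inherits(x, "plastome_record")) x$sequence else toupper(x)
  n <- nchar(sequence)
  if (n < 4L * min_ir)
    stop("sequence shorter than 4 x min_ir; no quadripartite structure")
  D <- paste0(sequence, sequence)
  dv <- strsplit(D, "")[[1]]
  cv <- unname(COMPLEMENT[dv])
  k <- min(32L, min_ir)
  stride <- max(1L, min_ir - k)
  probe_starts <- unique(c(seq(1L, n, stride), n - k + 1L))
  best <- NULL
  for (i in probe_starts) {
    probe_rc <- revcomp(substr(D, i, i + k - 1L))
    hits <- gregexpr(probe_rc, D, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    for (j in hits) {
      a1 <- i; a2 <- i + k - 1L; b1 <- j; b2 <- j + k - 1L
      if (b1 <= a2) next                      # want copy 2 to the right
      ext <- extend_ir_pair(dv, cv, n, a1, a2, b1, b2, max_mismatch)
      L <- unname(ext["a2"] - ext["a1"] + 1L)
      span <- unname(ext["b2"] - ext["a1"] + 1L)
      if (span > n) next                      # copies must fit one circle
      if (is.null(best) || L > best["L"]) best <- c(ext, L = L)
    }
  }
  if (is.null(best) || best[["L"]] < min_ir)
    stop("no quadripartite structure: no inverted repeat of >= ",
         min_ir, " bp found")
  L <- best[["L"]]
  s1 <- ((best[["a1"]] - 1L) %% n) + 1L
  s2 <- ((best[["b1"]] - 1L) %% n) + 1L
  gap1 <- (best[["b1"]] - best[["a2"]] - 1L)                 # between copies
  gap2 <- n - 2L * L - gap1                                   # around the circle
  if (gap2 < 0L) stop("no quadripartite structure: repeat copies overlap")
  g1_start <- ((best[["a2"]]) %% n) + 1L
  g2_start <- ((best[["b2"]]) %% n) + 1L
  if (gap1 >= gap2) {
    lsc <- circ_range(g1_start, gap1); ssc <- circ_range(g2_start, gap2)
    ira <- circ_range(s2, L); irb <- circ_range(s1, L)
  } else {
    lsc <- circ_range(g2_start, gap2); ssc <- circ_range(g1_start, gap1)
    ira <- circ_range(s1, L); irb <- circ_range(s2, L)
  }
  structure(list(lsc = lsc, ira = ira, ssc = ssc, irb = irb, total = n),
            class = "quadripartite")
}

#' @export
print.quadripartite <- function(x, ...) {
  cat("Quadripartite structure (", x$total, " bp):\n", sep = "")
  for (r in c("lsc", "ira", "ssc", "irb"))
    cat(sprintf("  %-4s start %8d  length %7d\n", toupper(r),
                x[[r]]$start, x[[r]]$length))
  invisible(x)
}

gc_percent <- function(s) {
  v <- strsplit(s, "")[[1]]
  gc <- sum(v %in% c("G", "C"))
  acgt <- sum(v %in% c("A", "C", "G", "T"))
  if (acgt == 0L) stop("region with zero unambiguous bases")
  round(100 * gc / acgt, 1)
}

#' Region lengths and GC content of a plastome
#'
#' Computes the standard per-region summary: total / LSC / SSC / IR lengths
#' and GC percentages (GC over unambiguous bases, reported as percent to one
#' decimal). The exact identity `lsc_bp + ssc_bp + 2 * ir_bp == total_bp`
#' always holds.
#'
#' @param record a [plastome_record()].
#' @param structure a [detect_quadripartite()] result for the record.
#' @return a one-row data.frame of class `"region_stats"` with columns
#'   `total_bp`, `lsc_bp`, `ssc_bp`, `ir_bp`, `total_gc`, `lsc_gc`, `ir_gc`,
#'   `ssc_gc`.
#' @export
region_stats <- function(record, structure) {
  stopifnot(inherits(record, "plastome_record"),
            inherits(structure, "quadripartite"))
  n <- nchar(record$sequence)
  if (structure$total != n) stop("structure does not cover the record")
  ir <- structure$ira$length
  if (structure$lsc$length + structure$ssc$length + 2L * ir != n)
    stop("structure regions do not tile the sequence")
  out <- data.frame(
    total_bp = n,
    lsc_bp = structure$lsc$length,
    ssc_bp = structure$ssc$length,
    ir_bp = ir,
    total_gc = gc_percent(record$sequence),
    lsc_gc = gc_percent(circ_extract(record$sequence, structure$lsc)),
    ir_gc = gc_percent(circ_extract(record$sequence, structure$ira)),
    ssc_gc = gc_percent(circ_extract(record$sequence, structure$ssc)))
  class(out) <- c("region_stats", "data.frame")
  out
}

# strip copy suffixes like "-1", "_2"; case-insensitive canonical form
normalize_gene_name <- function(x) sub("[-_][0-9]+$", "", x)

gene_name_key <- function(x) tolower(normalize_gene_name(x))

# is the feature's midpoint inside a circular range?
in_circ_range <- function(pos, range, n) {
  if (range$length == 0L) return(rep(FALSE, length(pos)))
  off <- ((pos - range$start) %% n)
  off >= 0 & off < range$length
}

#' Gene counts of an annotated plastome
#'
#' Counts gene copies and unique gene names by kind, and the genes
#' duplicated across the two inverted-repeat copies (one copy with its
#' midpoint in IRa and another in IRb).
#'
#' @param record a [plastome_record()].
#' @param structure a [detect_quadripartite()] result.
#' @return one-row data.frame of class `"gene_counts"`: `total_genes`,
#'   `unique_genes`, `unique_cds`, `unique_trna`, `unique_rrna`,
#'   `ir_duplicated`.
#' @export
count_genes <- function(record, structure) {
  stopifnot(inherits(record, "plastome_record"),
            inherits(structure, "quadripartite"))
  n <- nchar(record$sequence)
  if (!length(record$features)) {
    out <- data.frame(total_genes = 0L, unique_genes = 0L, unique_cds = 0L,
                      unique_trna = 0L, unique_rrna = 0L, ir_duplicated = 0L)
    class(out) <- c("gene_counts", "data.frame")
    return(out)
  }
  key <- vapply(record$features, function(f) gene_name_key(f$gene), "")
  kind <- vapply(record$features, `[[`, "", "kind")
  mid <- vapply(record$features, function(f)
    as.numeric(f$intervals[1, 1] + f$intervals[nrow(f$intervals), 2]) / 2, 0)
  in_ira <- in_circ_range(mid, structure$ira, n)
  in_irb <- in_circ_range(mid, structure$irb, n)
  uk <- !duplicated(key)
  dup_ir <- vapply(unique(key), function(k)
    any(in_ira[key == k]) && any(in_irb[key == k]), TRUE)
  out <- data.frame(
    total_genes = length(key),
    unique_genes = sum(uk),
    unique_cds = sum(uk & kind == "CDS"),
    unique_trna = sum(uk & kind == "tRNA"),
    unique_rrna = sum(uk & kind == "rRNA"),
    ir_duplicated = sum(dup_ir))
  class(out) <- c("gene_counts", "data.frame")
  out
}

feature_sequence <- function(sequence, f) {
  segs <- vapply(seq_len(nrow(f$intervals)), function(i)
    substr(sequence, f$intervals[i, 1], f$intervals[i, 2]), "")
  s <- paste(segs, collapse = "")
  if (f$strand == "-") revcomp(s) else s
}

# loci of one record on its unduplicated (or full) genome; returns a
# data.frame name/kind/sequence
record_loci <- function(record, structure, ir_policy, trans_spliced_span) {
  n0 <- nchar(record$sequence)
  feats <- record$features
  if (ir_policy == "drop_one_copy") {
    if (is.null(structure))
      structure <- detect_quadripartite(record)
    # rotate so LSC starts at 1; then IRb occupies the tail and is cut off
    record <- rotate_plastome_record(record, structure$lsc$start - 1L,
                                     drop_spanning = TRUE)
    keep_len <- n0 - structure$irb$length
    feats <- record$features
    inside <- vapply(feats, function(f) all(f$intervals <= keep_len), TRUE)
    if (any(!inside))
      message(record$id, ": dropping ", sum(!inside),
              " feature(s) in/overlapping the removed IR copy")
    feats <- feats[inside]
    genome <- substr(record$sequence, 1L, keep_len)
  } else genome <- record$sequence
  n <- nchar(genome)

  name <- kind <- seqs <- character(0)
  gene_key <- vapply(feats, function(f) gene_name_key(f$gene), "")
  if (ir_policy == "drop_one_copy" && anyDuplicated(gene_key)) {
    d <- unique(gene_key[duplicated(gene_key)])
    conflicting <- d[vapply(d, function(k) {
      ivs <- lapply(feats[gene_key == k], `[[`, "intervals")
      !all(vapply(ivs[-1], identical, TRUE, ivs[[1]]))
    }, TRUE)]
    if (length(conflicting)) {
      orig <- vapply(feats[match(conflicting, gene_key)],
                     function(f) normalize_gene_name(f$gene), "")
      stop("record ", record$id, ": duplicate gene name(s) with conflicting ",
           "coordinates: ", paste(orig, collapse = ", "))
    }
    feats <- feats[!duplicated(gene_key)]
    gene_key <- gene_key[!duplicated(gene_key)]
  }

  seen_copy <- character(0)
  for (f in feats) {
    gname <- normalize_gene_name(f$gene)
    span <- max(f$intervals) - min(f$intervals) + 1L
    if (gene_name_key(gname) == "rps12" || span > trans_spliced_span) {
      message(record$id, ": excluding trans-spliced/dispersed gene ", gname)
      next
    }
    lname <- gname
    if (lname %in% seen_copy) lname <- paste0(gname, "__2")
    seen_copy <- c(seen_copy, lname)
    lkind <- switch(f$kind, CDS = "coding", tRNA = "trna", rRNA = "rrna")
    name <- c(name, lname); kind <- c(kind, lkind)
    seqs <- c(seqs, feature_sequence(genome, f))
    iv <- f$intervals[order(f$intervals[, 1]), , drop = FALSE]
    if (nrow(iv) > 1L) {
      nint <- nrow(iv) - 1L
      for (i in seq_len(nint)) {
        a <- iv[i, 2] + 1L; b <- iv[i + 1L, 1] - 1L
        if (b < a) next
        intr <- substr(genome, a, b)
        if (f$strand == "-") intr <- revcomp(intr)
        num <- if (f$strand == "-") nint - i + 1L else i
        iname <- if (nint == 1L) paste0(lname, "_intron")
                 else paste0(lname, "_intron", num)
        name <- c(name, iname); kind <- c(kind, "intron"); seqs <- c(seqs, intr)
      }
    }
  }

  # intergenic spacers between gene extents (exon-level features merged per
  # gene copy first); circular wrap spacer included
  if (length(feats) >= 2L) {
    ext <- t(vapply(feats, function(f) range(f$intervals), c(1, 1)))
    gn <- vapply(feats, function(f) normalize_gene_name(f$gene), "")
    o <- order(ext[, 1])
    ext <- ext[o, , drop = FALSE]; gn <- gn[o]
    overlap <- FALSE
    for (i in seq_along(gn)) {
      j <- if (i < length(gn)) i + 1L else 1L
      a <- ext[i, 2] + 1L
      b <- if (i < length(gn)) ext[j, 1] - 1L else ext[j, 1] - 1L + n
      if (b < a) { if (b < a - 1L) overlap <- TRUE; next }
      sp <- if (b <= n) substr(genome, a, b) else
        paste0(substr(genome, a, n), substr(genome, 1L, b - n))
      name <- c(name, paste0(gn[i], "-", gn[j]))
      kind <- c(kind, "igs"); seqs <- c(seqs, sp)
    }
    if (overlap)
      message(record$id, ": overlapping gene extents; spacer coverage ",
              "accounting is approximate there")
  }
  dup <- duplicated(name)
  if (any(dup)) name[dup] <- paste0(name[dup], "__", cumsum(dup)[dup] + 1L)
  data.frame(name = name, kind = kind, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Extract typed loci from annotated plastome records
#'
#' Extracts, per record, all coding regions (exons joined), introns (gaps
#' between consecutive exons of a gene), tRNA and rRNA genes, and intergenic
#' spacers (maximal regions between adjacent gene extents, named
#' `"geneA-geneB"` with geneA upstream), then groups the unaligned sequences
#' by locus name across records. With `ir_policy = "drop_one_copy"` each
#' record is first rotated to put the LSC at position 1 and its second IR
#' copy (IRb) is removed, so IR loci enter once. The trans-spliced `rps12`
#' (and any gene whose exons are dispersed beyond `trans_spliced_span`) is
#' excluded and logged.
#'
#' @param records a [plastome_record()] or list of them.
#' @param ir_policy `"drop_one_copy"` (default) or `"keep_both"`.
#' @param structures optional list of [detect_quadripartite()] results
#'   parallel to `records` (detected on the fly when dropping an IR copy).
#' @param min_records drop loci present in fewer records (with a warning).
#' @param trans_spliced_span genomic span (bp) beyond which a multi-exon
#'   gene is treated as trans-spliced and excluded.
#' @return named list of loci; each element is
#'   `list(name, kind, sequences = named character vector by record id)`.
#' @export
extract_loci <- function(records, ir_policy = c("drop_one_copy", "keep_both"),
                         structures = NULL, min_records = 1L,
                         trans_spliced_span = 50000L) {
  ir_policy <- match.arg(ir_policy)
  if (inherits(records, "plastome_record")) records <- list(records)
  per <- lapply(seq_along(records), function(i)
    record_loci(records[[i]],
                if (!is.null(structures)) structures[[i]] else NULL,
                ir_policy, trans_spliced_span))
  ids <- vapply(records, `[[`, "", "id")
  all_names <- unique(unlist(lapply(per, `[[`, "name")))
  loci <- list()
  for (nm in all_names) {
    seqs <- character(0); kind <- NA_character_
    for (i in seq_along(per)) {
      hit <- which(per[[i]]$name == nm)
      if (length(hit)) {
        seqs[ids[i]] <- per[[i]]$sequence[hit[1]]
        kind <- per[[i]]$kind[hit[1]]
      }
    }
    loci[[nm]] <- list(name = nm, kind = kind, sequences = seqs)
  }
  nrec <- vapply(loci, function(l) length(l$sequences), 0L)
  if (any(nrec < min_records)) {
    warning(sum(nrec < min_records), " locus/loci present in fewer than ",
            min_records, " record(s) dropped: ",
            paste(utils::head(names(loci)[nrec < min_records], 10),
                  collapse = ", "))
    loci <- loci[nrec >= min_records]
  }
  loci
}

#' Write extracted loci as per-locus FASTA files
#'
#' @param loci result of [extract_loci()].
#' @param dir output directory (created if needed); files are
#'   `<locus>.fasta`.
#' @export
write_loci_fasta <- function(loci, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (l in loci) {
    path <- file.path(dir, paste0(gsub("[^A-Za-z0-9._-]", "_", l$name), ".fasta"))
    con <- file(path, "w")
    for (i in seq_along(l$sequences))
      writeLines(c(paste0(">", names(l$sequences)[i]), l$sequences[i]), con)
    close(con)
  }
  invisible(dir)
}

#' Table of per-record plastome summary statistics
#'
#' Convenience wrapper producing one row per record with region lengths, GC
#' percentages and gene counts (the classic plastome summary-table shape).
#'
#' @param records a [plastome_record()] or list of them.
#' @param min_ir minimum IR length passed to [detect_quadripartite()].
#' @return data.frame with one row per record.
#' @export
plastome_stats_table <- function(records, min_ir = 1000L) {
  if (inherits(records, "plastome_record")) records <- list(records)
  rows <- lapply(records, function(r) {
    qs <- detect_quadripartite(r, min_ir = min_ir)
    cbind(data.frame(id = r$id), as.data.frame(region_stats(r, qs)),
          as.data.frame(count_genes(r, qs)))
  })
  do.call(rbind, rows)
}
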