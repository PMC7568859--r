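# Minimal single-record GenBank flat-file I/O.
#
# Only what annotated plastome work needs: LOCUS line, gene-bearing features
# (CDS, tRNA, rRNA) with complement()/join() locations and a /gene
# qualifier, and the ORIGIN sequence block. No installed R package parses
# GenBank feature tables offline, hence this hand-rolled reader/writer.

parse_gb_location <- function(loc, feature_label) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  iv <- matrix(0L, length(parts), 2L, dimnames = list(NULL, c("start", "end")))
  for (i in seq_along(parts)) {
    p <- parts[i]
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      se <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^\\d+$", p)) {
      se <- rep(as.integer(p), 2L)
    } else stop("cannot parse location '", p, "' of feature ", feature_label)
    iv[i, ] <- se
  }
  list(intervals = iv, strand = strand)
}

#' Read a single annotated GenBank flat-file record
#'
#' Parses one GenBank record into a [plastome_record()]: the accession (from
#' LOCUS), the full sequence (from ORIGIN) and all CDS/tRNA/rRNA features
#' carrying a `/gene` qualifier, with `complement()`/`join()` locations.
#' Coordinates stay 1-based inclusive (the GenBank convention).
#'
#' @param path path to a GenBank flat file containing one record.
#' @return a [plastome_record()].
#' @export
read_plastome_record <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(locus[1]), "\\s+")[[1]][2] else
    tools::file_path_sans_ext(basename(path))

  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("record has no ORIGIN block: missing sequence")
  oend <- grep("^//", lines)
  oend <- if (length(oend)) oend[oend > ostart[1]][1] else length(lines) + 1L
  seqlines <- lines[(ostart[1] + 1L):(oend - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  if (!nzchar(sequence)) stop("record has an empty ORIGIN block: missing sequence")

  fstart <- grep("^FEATURES", lines)
  features <- list()
  if (length(fstart)) {
    fend <- ostart[1] - 1L
    block <- lines[(fstart[1] + 1L):fend]
    keyline <- grepl("^ {1,10}\\S", block)  # feature keys are indented < 21
    idx <- which(keyline)
    for (k in seq_along(idx)) {
      ln <- block[idx[k]]
      key <- sub("^\\s*(\\S+).*$", "\\1", ln)
      if (!key %in% c("CDS", "tRNA", "rRNA")) next
      last <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
      body <- block[idx[k]:last]
      loc <- sub("^\\s*\\S+\\s*", "", body[1])
      j <- 2L
      while (j <= length(body) && !grepl("^\\s*/", body[j])) {
        loc <- paste0(loc, trimws(body[j])); j <- j + 1L
      }
      gene <- NA_character_
      gm <- regmatches(body, regexec("/gene=\"([^\"]+)\"", body))
      hit <- which(vapply(gm, length, 0L) == 2L)
      if (length(hit)) gene <- gm[[hit[1]]][2]
      if (is.na(gene)) next                  # unnamed features are ignored
      pl <- parse_gb_location(loc, paste0(key, " ", gene))
      features[[length(features) + 1L]] <-
        list(gene = gene, kind = key, strand = pl$strand,
             intervals = pl$intervals)
    }
  }
  plastome_record(id, sequence, features)
}

#' Write a [plastome_record()] as a GenBank flat file
#'
#' @param record a [plastome_record()].
#' @param path output file.
#' @export
write_plastome_record <- function(record, path) {
  n <- nchar(record$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     circular PLN 01-JAN-2026",
                     record$id, n), con)
  writeLines(sprintf("DEFINITION  %s, synthetic or re-exported plastome record.",
                     record$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  for (f in record$features) {
    segs <- sprintf("%d..%d", f$intervals[, 1], f$intervals[, 2])
    loc <- if (length(segs) > 1L)
      paste0("join(", paste(segs, collapse = ","), ")") else segs
    if (f$strand == "-") loc <- paste0("complement(", loc, ")")
    writeLines(sprintf("     %-16s%s", f$kind, loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$gene), con)
  }
  writeLines("ORIGIN", con)
  starts <- seq(1L, n, 60L)
  for (s in starts) {
    chunk <- substr(record$sequence, s, min(s + 59L, n))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(1, nchar(chunk), 10) + 9L, nchar(chunk)))
    writeLines(sprintf("%9d %s", s, tolower(paste(tens, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}
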