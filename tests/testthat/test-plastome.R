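toy_record <- function() {
  # 100 bp, one CDS at 11..40 on the plus strand
  seq100 <- strrep("ACGT", 25)
  plastome_record("TOY1", seq100,
                  list(list(gene = "matK", kind = "CDS", strand = "+",
                            intervals = matrix(c(11L, 40L), 1))))
}

test_that("plastome records validate features and parse from GenBank", {
  r <- toy_record()
  expect_identical(nchar(r$sequence), 100L)
  expect_length(r$features, 1L)
  expect_error(
    plastome_record("bad", "ACGT",
                    list(list(gene = "oops", kind = "CDS", strand = "+",
                              intervals = matrix(c(2L, 9L), 1)))),
    "oops")
  # GenBank round trip of a handcrafted record
  gb <- tempfile(fileext = ".gb")
  write_plastome_record(r, gb)
  r2 <- read_plastome_record(gb)
  expect_identical(r2, r)
  # a record without sequence is a hard error
  writeLines(c("LOCUS       X 10 bp", "FEATURES", "//"), gb)
  expect_error(read_plastome_record(gb), "missing sequence")
})

test_that("quadripartite detection recovers a planted exact repeat", {
  sp <- synth_plastome_record(total_bp = 100000, ir_bp = 20000,
                              ssc_bp = 15000, n_cds = 30, n_trna = 10,
                              n_rrna = 2, ir_cds = 1, ir_trna = 2,
                              ir_rrna = 2, n_ssc_cds = 4, n_one_intron = 4,
                              n_two_intron = 1, seed = 21)
  qs <- detect_quadripartite(sp$record)
  expect_identical(unclass(qs), unclass(sp$structure))
  expect_error(detect_quadripartite(rand_seq(6000, 1), min_ir = 1000),
               "no quadripartite")
  expect_error(detect_quadripartite(rand_seq(500, 2), min_ir = 1000),
               "shorter")
})

test_that("detection agrees with the exhaustive longest-repeat oracle", {
  # random 5-10 kb sequences with planted 200-1000 bp repeats (reduced
  # replicate count to stay within the test budget)
  for (s in 1:10) {
    set.seed(s)
    n <- sample(5000:10000, 1)
    L <- sample(200:1000, 1)
    pl <- plant_ir_seq(n, L, seed = s + 100)
    or <- oracle_longest_ir(pl$seq)
    qs <- detect_quadripartite(pl$seq, min_ir = 150)
    expect_identical(sort(c(qs$ira$start, qs$irb$start)),
                     sort(as.integer(c(or["s1"], or["s2"]))))
    expect_identical(qs$ira$length, as.integer(or["length"]))
    expect_gte(qs$ira$length, L)
  }
})

test_that("region statistics obey the tiling identity and handle degeneracy", {
  manual_structure <- function(l1, l2, l3, l4) {
    structure(list(lsc = plastosig:::circ_range(1, l1),
                   ira = plastosig:::circ_range(l1 + 1, l2),
                   ssc = plastosig:::circ_range(l1 + l2 + 1, l3),
                   irb = plastosig:::circ_range(l1 + l2 + l3 + 1, l4),
                   total = l1 + l2 + l3 + l4),
              class = "quadripartite")
  }
  # all-GC toy: every region at 100.0%
  rec <- plastome_record("GC", strrep("GC", 500))
  st <- manual_structure(400, 150, 300, 150)
  rs <- region_stats(rec, st)
  expect_identical(unlist(rs[c("total_gc", "lsc_gc", "ir_gc", "ssc_gc")]),
                   c(total_gc = 100, lsc_gc = 100, ir_gc = 100, ssc_gc = 100))
  expect_identical(rs$lsc_bp + rs$ssc_bp + 2L * rs$ir_bp, rs$total_bp)
  # region of ambiguous bases only
  recN <- plastome_record("NN", paste0(strrep("A", 400), strrep("N", 150),
                                       strrep("A", 450)))
  expect_error(region_stats(recN, manual_structure(400, 150, 300, 150)),
               "unambiguous")
  # identity + detection-vs-truth across seeded synthetic records
  for (s in c(2, 7)) {
    sp <- synth_plastome_record(total_bp = 60000, ir_bp = 9000, ssc_bp = 8000,
                                n_cds = 20, n_trna = 8, n_rrna = 2,
                                ir_cds = 1, ir_trna = 2, ir_rrna = 2,
                                n_ssc_cds = 3, n_one_intron = 4,
                                n_two_intron = 1, seed = s)
    qs <- detect_quadripartite(sp$record)
    rs <- region_stats(sp$record, qs)
    expect_identical(rs$lsc_bp + rs$ssc_bp + 2L * rs$ir_bp, rs$total_bp)
    expect_identical(unclass(qs), unclass(sp$structure))
  }
})

test_that("rotation changes coordinates but no length or GC statistic", {
  sp <- synth_plastome_record(total_bp = 50000, ir_bp = 8000, ssc_bp = 7000,
                              n_cds = 10, n_trna = 4, n_rrna = 2, ir_cds = 1,
                              ir_trna = 1, ir_rrna = 2, n_ssc_cds = 2,
                              n_one_intron = 2, n_two_intron = 0, seed = 5)
  rec <- sp$record
  base <- region_stats(rec, detect_quadripartite(rec))
  for (off in c(1234, 25000, 49999)) {
    rot <- rotate_sequence(rec$sequence, off)
    qs <- detect_quadripartite(rot)
    rs <- region_stats(plastome_record("rot", rot), qs)
    expect_identical(as.data.frame(rs), as.data.frame(base))
  }
})

test_that("gene counting collapses names and spots IR duplicates", {
  # empty feature list -> all zeros
  empty <- plastome_record("E", rand_seq(200, 3))
  cz <- count_genes(empty, structure(list(
    lsc = plastosig:::circ_range(1, 100), ira = plastosig:::circ_range(101, 30),
    ssc = plastosig:::circ_range(131, 40), irb = plastosig:::circ_range(171, 30),
    total = 200), class = "quadripartite"))
  expect_true(all(as.matrix(cz) == 0))
  # one CDS
  sp <- synth_plastome_record(total_bp = 60000, ir_bp = 9000, ssc_bp = 8000,
                              n_cds = 20, n_trna = 8, n_rrna = 2, ir_cds = 1,
                              ir_trna = 2, ir_rrna = 2, n_ssc_cds = 3,
                              n_one_intron = 4, n_two_intron = 1, seed = 9)
  cg <- count_genes(sp$record, sp$structure)
  expect_identical(cg$unique_genes, 30L)
  expect_identical(cg$unique_cds + cg$unique_trna + cg$unique_rrna,
                   cg$unique_genes)
  expect_identical(cg$ir_duplicated, 5L)
  expect_identical(cg$total_genes, 35L)
  expect_gte(cg$total_genes, cg$unique_genes)
})

test_that("locus extraction produces typed loci with planted coordinates", {
  # two adjacent genes separated by 50 bp -> one igs named geneA-geneB
  s <- rand_seq(400, 8)
  rec <- plastome_record("IGS", s, list(
    list(gene = "geneA", kind = "CDS", strand = "+",
         intervals = matrix(c(1L, 100L), 1)),
    list(gene = "geneB", kind = "CDS", strand = "+",
         intervals = matrix(c(151L, 400L), 1))))
  loci <- extract_loci(rec, ir_policy = "keep_both")
  expect_true("geneA-geneB" %in% names(loci))
  igs <- loci[["geneA-geneB"]]
  expect_identical(igs$kind, "igs")
  expect_identical(nchar(igs$sequences[["IGS"]]), 50L)
  expect_identical(igs$sequences[["IGS"]], substr(s, 101, 150))

  # a two-exon gene -> joined coding locus + one intron locus
  rec2 <- plastome_record("INTR", s, list(
    list(gene = "geneC", kind = "CDS", strand = "+",
         intervals = matrix(c(11L, 100L, 151L, 280L), 2, byrow = TRUE))))
  loci2 <- extract_loci(rec2, ir_policy = "keep_both")
  expect_identical(nchar(loci2$geneC$sequences[["INTR"]]), 90L + 130L)
  expect_identical(loci2$geneC$sequences[["INTR"]],
                   paste0(substr(s, 11, 100), substr(s, 151, 280)))
  expect_identical(nchar(loci2$geneC_intron$sequences[["INTR"]]), 50L)
  expect_identical(loci2$geneC_intron$kind, "intron")

  # minus-strand gene is reverse complemented
  rec3 <- plastome_record("MIN", s, list(
    list(gene = "geneD", kind = "CDS", strand = "-",
         intervals = matrix(c(21L, 80L), 1))))
  loci3 <- extract_loci(rec3, ir_policy = "keep_both")
  expect_identical(loci3$geneD$sequences[["MIN"]],
                   plastosig:::revcomp(substr(s, 21, 80)))
})

test_that("extraction tiles the unduplicated genome and handles edge cases", {
  sp <- synth_plastome_record(total_bp = 60000, ir_bp = 9000, ssc_bp = 8000,
                              n_cds = 20, n_trna = 8, n_rrna = 2, ir_cds = 1,
                              ir_trna = 2, ir_rrna = 2, n_ssc_cds = 3,
                              n_one_intron = 4, n_two_intron = 1, seed = 13)
  loci <- suppressMessages(extract_loci(sp$record))
  total <- sum(nchar(vapply(loci, function(l) l$sequences[[1]], "")))
  expect_identical(total, 60000L - 9000L)
  kinds <- vapply(loci, `[[`, "", "kind")
  expect_setequal(unique(kinds), c("coding", "intron", "trna", "rrna", "igs"))
  expect_identical(sum(kinds == "intron"), 4L + 2L)

  # rps12-like trans-spliced genes are excluded and logged
  s <- rand_seq(1000, 4)
  recr <- plastome_record("RPS", s, list(
    list(gene = "rps12", kind = "CDS", strand = "+",
         intervals = matrix(c(1L, 100L), 1)),
    list(gene = "geneE", kind = "CDS", strand = "+",
         intervals = matrix(c(201L, 400L), 1))))
  expect_message(lr <- extract_loci(recr, ir_policy = "keep_both"), "rps12")
  expect_false("rps12" %in% names(lr))     # no coding locus for it
  expect_true("geneE" %in% names(lr))

  # duplicate gene name with conflicting coordinates names record and gene
  recd <- plastome_record("DUP", s, list(
    list(gene = "geneF", kind = "CDS", strand = "+",
         intervals = matrix(c(1L, 90L), 1)),
    list(gene = "geneF", kind = "CDS", strand = "+",
         intervals = matrix(c(201L, 300L), 1))))
  manual <- structure(list(lsc = plastosig:::circ_range(1, 700),
                           ira = plastosig:::circ_range(701, 100),
                           ssc = plastosig:::circ_range(801, 100),
                           irb = plastosig:::circ_range(901, 100),
                           total = 1000), class = "quadripartite")
  expect_error(suppressMessages(
    plastosig:::record_loci(recd, manual, "drop_one_copy", 50000L)),
    "DUP.*geneF")

  # loci in fewer than min_records are dropped with a warning
  recA <- plastome_record("A1", s, list(
    list(gene = "g1", kind = "CDS", strand = "+",
         intervals = matrix(c(1L, 90L), 1)),
    list(gene = "g2", kind = "CDS", strand = "+",
         intervals = matrix(c(201L, 300L), 1))))
  recB <- plastome_record("B1", s, list(
    list(gene = "g1", kind = "CDS", strand = "+",
         intervals = matrix(c(1L, 90L), 1))))
  expect_warning(
    lab <- extract_loci(list(recA, recB), ir_policy = "keep_both",
                        min_records = 2L),
    "fewer than")
  expect_identical(names(lab), "g1")
  expect_identical(names(lab$g1$sequences), c("A1", "B1"))
})
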