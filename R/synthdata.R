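# Seeded generators: sequence evolution along a tree under GTR+I+Gamma,
# multi-locus datasets with a planted minority of conflicting loci, and
# annotated synthetic plastome records with an exact planted inverted repeat.

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a DNA alignment along a tree
#'
#' Forward simulation under GTR+I+Gamma: root states are drawn from the
#' stationary frequencies; each site is invariant with probability `p_inv`
#' or assigned one of the discrete gamma rate categories (drawn once per
#' site and shared across the whole tree); states then evolve down every
#' branch through `P(t * rate)`.
#'
#' @param tree `ape::phylo` with branch lengths (substitutions/site).
#' @param model a [substitution_model()].
#' @param n_sites number of sites.
#' @param seed integer seed (mandatory for reproducibility).
#' @return a [dna_alignment()] over the tree's tip labels.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "subst_model"),
            n_sites >= 1)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  with_seed(seed, {
    eig <- gtr_eigen(model)
    pi <- model$base_freqs
    grates <- gamma_rates(model)
    ncat <- length(grates)
    rate_of_site <- ifelse(stats::runif(n_sites) < model$p_inv, 0,
                           grates[sample.int(ncat, n_sites, replace = TRUE)])
    tr <- ape::reorder.phylo(tree, "postorder")
    E <- tr$edge
    ntip <- ape::Ntip(tr)
    nnode <- ntip + tr$Nnode
    states <- matrix(0L, nnode, n_sites)
    root <- E[nrow(E), 1L]
    states[root, ] <- sample.int(4L, n_sites, replace = TRUE, prob = pi)
    groups <- split(seq_len(n_sites), rate_of_site)
    for (e in rev(seq_len(nrow(E)))) {          # preorder: parents first
      p <- E[e, 1L]; ch <- E[e, 2L]
      t <- tr$edge.length[e]
      for (g in seq_along(groups)) {
        idx <- groups[[g]]
        r <- rate_of_site[idx[1L]]
        if (r == 0 || t == 0) { states[ch, idx] <- states[p, idx]; next }
        P <- prob_matrix(eig, t * r)
        for (s in 1:4) {
          here <- idx[states[p, idx] == s]
          if (length(here))
            states[ch, here] <- sample.int(4L, length(here), replace = TRUE,
                                           prob = P[s, ])
        }
      }
    }
    m <- matrix(DNA_STATES[states[seq_len(ntip), , drop = FALSE]], ntip, n_sites)
    rownames(m) <- tr$tip.label
    dna_alignment(m)
  })
}

#' Configuration for a planted-conflict multi-locus simulation
#'
#' Describes a multi-locus dataset in which most loci evolve on a majority
#' topology and a small planted minority on an alternative resolution of the
#' same focal split — the regime in which a handful of loci can decide a
#' contentious node. The default preset mimics a rapid-radiation plastome
#' study: three subclades (two taxa each) plus an outgroup joined by short
#' internal branches, 243 loci with log-uniform lengths 100-3000 bp, a
#' nearly unresolved focal edge on the majority resolution (3e-4
#' substitutions/site) against a firmer focal edge (0.005) on the planted
#' minority resolution, plastome-like base composition (about 39% GC) and
#' GTR+I+Gamma4 rate heterogeneity.
#'
#' @param majority_tree,minority_tree `ape::phylo` trees on the same leaf
#'   set differing in the resolution of one internal edge. Defaults are the
#'   preset trees: majority subclades I+II sister with a barely resolved
#'   focal edge (0.001 substitutions/site — the rapid-radiation regime in
#'   which most loci are nearly uninformative about the trichotomy), and
#'   minority II+III with a firmer focal edge (0.005), so the few planted
#'   loci carry concentrated conflicting signal, the regime in which a
#'   handful of outlier loci can decide the concatenated topology.
#' @param n_loci number of loci.
#' @param n_conflict number of planted minority loci (overrides
#'   `conflict_fraction`).
#' @param conflict_fraction fraction of loci planted on the minority tree.
#' @param length_range locus length range (bp); lengths are log-uniform.
#' @param conflict_length_range length range of the planted loci (bp,
#'   log-uniform). Planted loci shorter than ~500 bp carry too little
#'   signal to be detectable even in principle, so the default floor is
#'   500 bp.
#' @param model a [substitution_model()].
#' @param seed integer seed.
#' @return list of class `"conflict_sim_config"`.
#' @export
conflict_sim_config <- function(majority_tree = NULL, minority_tree = NULL,
                                n_loci = 243L, n_conflict = NULL,
                                conflict_fraction = 6 / 243,
                                length_range = c(100L, 3000L),
                                conflict_length_range = c(500L, 3000L),
                                model = NULL, seed = 1L) {
  if (is.null(majority_tree))
    majority_tree <- preset_topology("T1", focal_branch = 3e-4)
  if (is.null(minority_tree))
    minority_tree <- preset_topology("T2", focal_branch = 0.005)
  if (!setequal(majority_tree$tip.label, minority_tree$tip.label))
    stop("majority and minority trees must share their leaf set")
  if (is.null(model)) model <- preset_model()
  if (is.null(n_conflict)) n_conflict <- round(conflict_fraction * n_loci)
  if (n_conflict == 0L)
    warning("configuration plants 0 conflicting loci; proceeding")
  stopifnot(n_loci >= 1L, n_conflict <= n_loci, length_range[1] > 0,
            length_range[2] >= length_range[1],
            conflict_length_range[1] > 0,
            conflict_length_range[2] >= conflict_length_range[1])
  structure(list(majority_tree = majority_tree, minority_tree = minority_tree,
                 n_loci = as.integer(n_loci), n_conflict = as.integer(n_conflict),
                 length_range = as.integer(length_range),
                 conflict_length_range = as.integer(conflict_length_range),
                 model = model, seed = as.integer(seed)),
            class = "conflict_sim_config")
}

#' Preset trees for the three resolutions of a focal trichotomy
#'
#' Three subclades (I, II, III; two taxa each) plus an outgroup. `"T1"`
#' joins subclades I and II, `"T2"` joins II and III, `"T3"` joins I and
#' III. Terminal branches 0.008, subclade stems 0.004, the focal internal
#' branch 0.003 substitutions/site — the short-internal-branch regime of a
#' rapid radiation.
#'
#' @param which `"T1"`, `"T2"` or `"T3"`.
#' @param focal_branch length of the focal internal edge.
#' @return `ape::phylo`.
#' @export
preset_topology <- function(which = c("T1", "T2", "T3"), focal_branch = 0.003) {
  which <- match.arg(which)
  cl <- c(I = "(I_1:0.008,I_2:0.008):0.004",
          II = "(II_1:0.008,II_2:0.008):0.004",
          III = "(III_1:0.008,III_2:0.008):0.004")
  pair <- switch(which, T1 = c("I", "II"), T2 = c("II", "III"),
                 T3 = c("I", "III"))
  rest <- setdiff(names(cl), pair)
  nwk <- sprintf("((%s,%s):%g,%s,OUT:0.02);", cl[pair[1]], cl[pair[2]],
                 focal_branch, cl[rest])
  ape::read.tree(text = nwk)
}

#' Preset plastome-like substitution model
#'
#' GTR+I+Gamma4 with about 39% GC stationary composition, transition bias,
#' gamma shape 0.5 and 30% invariant sites — desk-scale stand-ins for
#' typical plastome estimates.
#' @return a [substitution_model()].
#' @export
preset_model <- function() {
  substitution_model(rates = c(1.2, 2.5, 0.5, 1.0, 3.0, 1.0),
                     base_freqs = c(0.31, 0.19, 0.20, 0.30),
                     gamma_shape = 0.5, n_cat = 4L, p_inv = 0.3)
}

#' Simulate a multi-locus dataset with planted conflicting loci
#'
#' @param cfg a [conflict_sim_config()].
#' @return list with `alignment` (concatenated [dna_alignment()]),
#'   `partition` ([partition_map()]), and `truth` (data.frame: locus,
#'   source `"majority"`/`"minority"`, length).
#' @export
simulate_conflict_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "conflict_sim_config"))
  with_seed(cfg$seed, {
    lr <- log(cfg$length_range)
    len <- as.integer(round(exp(stats::runif(cfg$n_loci, lr[1], lr[2]))))
    planted <- sort(sample.int(cfg$n_loci, cfg$n_conflict))
    if (cfg$n_conflict > 0L) {
      clr <- log(cfg$conflict_length_range)
      len[planted] <- as.integer(round(exp(stats::runif(
        length(planted), clr[1], clr[2]))))
    }
    locus_seed <- sample.int(.Machine$integer.max %/% 2L, cfg$n_loci)
    loci <- vector("list", cfg$n_loci)
    names(loci) <- sprintf("locus%03d", seq_len(cfg$n_loci))
    for (i in seq_len(cfg$n_loci)) {
      tr <- if (i %in% planted) cfg$minority_tree else cfg$majority_tree
      loci[[i]] <- simulate_alignment(tr, cfg$model, len[i], seed = locus_seed[i])
    }
    cat_ <- concatenate_loci(loci, taxa = cfg$majority_tree$tip.label,
                             kinds = rep("sim", cfg$n_loci))
    truth <- data.frame(
      locus = names(loci),
      source = ifelse(seq_len(cfg$n_loci) %in% planted, "minority", "majority"),
      length = len, stringsAsFactors = FALSE)
    list(alignment = cat_$alignment, partition = cat_$partition, truth = truth)
  })
}

random_dna <- function(n, gc = 0.39) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_STATES, n, replace = TRUE, prob = p), collapse = "")
}

# lay n features of given lengths along [from, to] with igs-sized gaps;
# returns list of interval matrices or NULL if they do not fit
lay_genes <- function(from, to, lengths, gap_range) {
  pos <- from
  out <- vector("list", length(lengths))
  for (i in seq_along(lengths)) {
    gap <- if (i == 1L) 0L else sample(gap_range[1]:gap_range[2], 1L)
    start <- pos + gap
    end <- start + lengths[i] - 1L
    if (end > to) return(NULL)
    out[[i]] <- c(start, end)
    pos <- end + 1L
  }
  out
}

#' Generate an annotated synthetic plastome record with known structure
#'
#' Builds a random quadripartite sequence (regions LSC, IRa, SSC, IRb in
#' order, IRb the exact reverse complement of IRa, region-specific GC
#' content) and lays out a non-overlapping gene inventory mirroring a real
#' plastome's: `n_cds`/`n_trna`/`n_rrna` *unique* genes, of which
#' `ir_cds + ir_trna + ir_rrna` live inside the inverted repeat and are
#' therefore present in two copies (one in IRa, its mirror image in IRb) —
#' with the defaults that gives 112 unique genes (78 + 30 + 4) and 13
#' IR-duplicated ones. `n_one_intron`/`n_two_intron` coding genes get 1 or
#' 2 introns. The true structure is returned alongside, so inverted-repeat
#' detection and locus extraction can be tested against a planted answer.
#' Everything about the record is synthetic.
#'
#' @param total_bp total circle length.
#' @param ir_bp inverted-repeat length (each copy).
#' @param ssc_bp small-single-copy length.
#' @param n_cds,n_trna,n_rrna unique genes per kind.
#' @param ir_cds,ir_trna,ir_rrna how many of each kind are IR-duplicated
#'   (defaults 2 + 7 + 4 = 13, the usual plastome pattern where all rRNAs
#'   and several tRNAs sit in the repeat).
#' @param n_ssc_cds how many single-copy CDS go to the SSC (ndh-like).
#' @param n_one_intron,n_two_intron how many single-copy CDS get introns.
#' @param seed integer seed.
#' @return list with `record` ([plastome_record()]) and `structure`
#'   (the true [detect_quadripartite()]-shaped `"quadripartite"` object).
#' @export
synth_plastome_record <- function(total_bp = 152000L, ir_bp = 20000L,
                                  ssc_bp = 18800L, n_cds = 78L, n_trna = 30L,
                                  n_rrna = 4L, ir_cds = 2L, ir_trna = 7L,
                                  ir_rrna = 4L, n_ssc_cds = 8L,
                                  n_one_intron = 16L, n_two_intron = 2L,
                                  seed = 1L) {
  stopifnot(2L * ir_bp < total_bp, ssc_bp + 2L * ir_bp < total_bp,
            ir_cds <= n_cds, ir_trna <= n_trna, ir_rrna <= n_rrna,
            n_ssc_cds <= n_cds - ir_cds,
            n_one_intron + n_two_intron <= n_cds - ir_cds - n_ssc_cds)
  lsc_bp <- total_bp - ssc_bp - 2L * ir_bp
  with_seed(seed, {
    lsc <- random_dna(lsc_bp, gc = 0.379)
    ira <- random_dna(ir_bp, gc = 0.444)
    ssc <- random_dna(ssc_bp, gc = 0.339)
    # pin the bases flanking the repeat copies so the planted IR is exactly
    # maximal (no chance reverse-complement extension across its boundaries)
    substr(lsc, 1L, 1L) <- "A"; substr(lsc, lsc_bp, lsc_bp) <- "A"
    substr(ssc, 1L, 1L) <- "A"; substr(ssc, ssc_bp, ssc_bp) <- "A"
    sequence <- paste0(lsc, ira, ssc, revcomp(ira))

    feats <- list()
    add <- function(gene, kind, strand, iv)
      feats[[length(feats) + 1L]] <<- list(gene = gene, kind = kind,
                                           strand = strand,
                                           intervals = do.call(rbind, iv))
    # --- LSC: single-copy CDS (minus the SSC share) + single-copy tRNA ---
    n_lsc_cds <- n_cds - ir_cds - n_ssc_cds
    n_lsc_trna <- n_trna - ir_trna
    cds_len <- 3L * sample(100:400, n_lsc_cds, replace = TRUE)
    trna_len <- sample(70:90, n_lsc_trna, replace = TRUE)
    kinds <- c(rep("CDS", n_lsc_cds), rep("tRNA", n_lsc_trna))
    lens <- c(cds_len, trna_len)
    ord <- sample(length(lens))
    layout <- lay_genes(1L, lsc_bp, lens[ord], c(60L, 220L))
    if (is.null(layout)) stop("gene inventory does not fit the LSC region")
    intronized <- sample(which(kinds[ord] == "CDS"),
                         n_one_intron + n_two_intron)
    two <- intronized[seq_len(n_two_intron)]
    ncds_seen <- ntrna_seen <- 0L
    for (i in seq_along(ord)) {
      k <- kinds[ord[i]]
      if (k == "CDS") {
        ncds_seen <- ncds_seen + 1L
        gene <- sprintf("scg%03d", ncds_seen)
      } else {
        ntrna_seen <- ntrna_seen + 1L
        gene <- sprintf("trn%02d", ntrna_seen)
      }
      se <- layout[[i]]
      strand <- sample(c("+", "-"), 1L)
      if (k == "CDS" && i %in% intronized) {
        nint <- if (i %in% two) 2L else 1L
        len <- se[2] - se[1] + 1L
        # split the span into exons and introns (pieces >= 80 bp)
        cuts <- sort(sample(seq(80L, len - 80L, by = 4L), 2L * nint))
        bounds <- c(se[1], se[1] + cuts - 1L, se[2])
        iv <- lapply(seq_len(nint + 1L), function(j)
          c(bounds[2L * j - 1L] + (j > 1L), bounds[2L * j]))
        add(gene, "CDS", strand, iv)
      } else add(gene, k, strand, list(se))
    }
    # --- SSC: the remaining single-copy CDS (ndh-like) ---
    ssc_from <- lsc_bp + ir_bp + 1L
    if (n_ssc_cds > 0L) {
      slen <- 3L * sample(150:500, n_ssc_cds, replace = TRUE)
      layout <- lay_genes(ssc_from + 100L, ssc_from + ssc_bp - 100L, slen,
                          c(80L, 250L))
      if (is.null(layout)) stop("CDS inventory does not fit the SSC region")
      for (i in seq_len(n_ssc_cds))
        add(sprintf("scg%03d", n_lsc_cds + i), "CDS",
            sample(c("+", "-"), 1L), layout[i])
    }
    # --- IR: duplicated rRNA + tRNA + CDS, mirrored IRa -> IRb ---
    ira_from <- lsc_bp + 1L
    ir_kinds <- c(rep("rRNA", ir_rrna), rep("tRNA", ir_trna),
                  rep("CDS", ir_cds))
    ir_names <- c(sprintf("rrn%02d", seq_len(ir_rrna)),
                  sprintf("trn%02d", n_lsc_trna + seq_len(ir_trna)),
                  sprintf("irg%02d", seq_len(ir_cds)))
    ir_lens <- ifelse(ir_kinds == "rRNA",
                      sample(1500:2900, length(ir_kinds), replace = TRUE),
                      ifelse(ir_kinds == "tRNA",
                             sample(70:90, length(ir_kinds), replace = TRUE),
                             3L * sample(150:500, length(ir_kinds),
                                         replace = TRUE)))
    layout <- lay_genes(ira_from + 50L, ira_from + ir_bp - 50L, ir_lens,
                        c(60L, 400L))
    if (is.null(layout)) stop("IR gene inventory does not fit the IR region")
    irb_end <- total_bp
    for (i in seq_along(ir_kinds)) {
      se <- layout[[i]]
      add(ir_names[i], ir_kinds[i], "+", list(se))
      # mirror position in IRb: distance from IRa start = distance from IRb end
      add(ir_names[i], ir_kinds[i], "-",
          list(c(irb_end - (se[2] - ira_from), irb_end - (se[1] - ira_from))))
    }
    record <- plastome_record(sprintf("SYNTH%06d", seed), sequence, feats)
    structure_true <- structure(
      list(lsc = circ_range(1L, lsc_bp),
           ira = circ_range(lsc_bp + 1L, ir_bp),
           ssc = circ_range(lsc_bp + ir_bp + 1L, ssc_bp),
           irb = circ_range(lsc_bp + ir_bp + ssc_bp + 1L, ir_bp),
           total = as.integer(total_bp)),
      class = "quadripartite")
    list(record = record, structure = structure_true)
  })
}
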