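# Seeded synthetic germline VH / DH repertoires with a ground-truth ledger.
# Classes are planted at the codon level (codon 103 + Cys104 codon + first
# nucleotide of codon 105), so the anchoring and scanning modules must find
# the heptamer rather than being handed it.  The scaffold upstream of codon
# 103 contains no Cys and no stop codon, and codon-105 candidates exclude
# TGT/TGC, so the planted Cys104 is the 3'-most Cys through codon 105.
# All randomness flows from one seed through a locally restored RNG; the
# draw order (classes, scaffold, codon 103, codon 104, codon 105/footprint,
# DH) is fixed.

CLASS_NAMES <- c("CANONICAL_TAC", "CANONICAL_CAC", "GTG_TYPE", "OTHER")

#' Configuration for the synthetic repertoire generator
#'
#' Defaults emulate a tetrapod-style functional VH repertoire: a class mix
#' whose total GTG fraction (canonical included) is 0.87 and canonical
#' fraction 0.645, Cys104 coded TGT with probability 0.95 where not
#' structurally forced, residue 105 an Ala GCN codon with probability 0.82,
#' and a 7-nt A/G-rich footprint (9 nt for teleost-style sets).  The
#' footprint base weights default to A 0.55, C 0.05, G 0.35, T 0.05, which
#' makes the expected frame-I charged-codon frequency about 0.66 --
#' matching the observed A/G-richness and the >60 percent frame-I charge of
#' real repertoires.
#'
#' @param seed integer RNG seed; same seed + config gives byte-identical
#'   output
#' @param species species label stamped on every gene
#' @param n_families number of VH families ("VH1", "VH2", ...)
#' @param genes_per_family single count or vector of per-family counts
#' @param p_class named probabilities over CANONICAL_TAC, CANONICAL_CAC,
#'   GTG_TYPE, OTHER (must sum to 1)
#' @param p_cys_TGT probability that Cys104 is coded TGT where the class
#'   does not force it (classes containing the GTG core require TGT, so a
#'   GTG-class mass with `p_cys_TGT = 0` is a config error); for OTHER-class
#'   genes this is also the probability of retaining GT at heptamer
#'   positions 5-6
#' @param p_res105_ala probability residue 105 is an Ala GCN codon (forced
#'   off for OTHER genes that retain GT, whose codon 105 must not start
#'   with G)
#' @param footprint_len 7 (tetrapod style) or 9 (teleost style)
#' @param footprint_base_weights named A/C/G/T probabilities for footprint
#'   positions 3..footprint_len (positions 1-2 are the tail of codon 105)
#' @param footprint_charged_codon_p when non-NULL, overrides the base
#'   weights: the footprint is drawn as frame-II codons, each charged with
#'   this probability (charged codons uniform over the 14, non-charged
#'   uniform over the 47 non-stop others); codon 105's tail follows the
#'   draw
#' @param v_len_codons aligned codon count through Cys104 (IMGT position of
#'   the 2nd-CYS; minimum and default 104)
#' @param gap_codons number of codons gapped out of the scaffold (placed at
#'   CDR-region aligned positions); reduces the real codon count upstream
#'   of Cys104
#' @param emit_gapped also emit the IMGT-gapped form of each gene (default
#'   TRUE; with `gap_codons = 0` the gapped form equals the ungapped one)
#' @param dh_count,dh_len_range,dh_charged_codon_p DH generator knobs:
#'   number of DH genes, inclusive length range, probability that each
#'   frame-0 codon is charged
#' @return validated config object of class `crss_sim_config`
#' @export
crss_sim_config <- function(seed = 1L,
                            species = "synthetic_tetrapod",
                            n_families = 4L,
                            genes_per_family = 10L,
                            p_class = c(CANONICAL_TAC = 0.600,
                                        CANONICAL_CAC = 0.045,
                                        GTG_TYPE = 0.224,
                                        OTHER = 0.131),
                            p_cys_TGT = 0.95,
                            p_res105_ala = 0.82,
                            footprint_len = 7L,
                            footprint_base_weights = c(A = 0.55, C = 0.05,
                                                       G = 0.35, T = 0.05),
                            footprint_charged_codon_p = NULL,
                            v_len_codons = 104L,
                            gap_codons = 0L,
                            emit_gapped = TRUE,
                            dh_count = 0L,
                            dh_len_range = c(12L, 30L),
                            dh_charged_codon_p = 0.15) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  n_families <- as.integer(n_families)
  stopifnot(n_families >= 1L)
  if (length(genes_per_family) == 1L)
    genes_per_family <- rep(as.integer(genes_per_family), n_families)
  genes_per_family <- as.integer(genes_per_family)
  if (length(genes_per_family) != n_families || any(genes_per_family < 0L))
    stop("genes_per_family must be one count or one per family, all >= 0")
  if (!setequal(names(p_class), CLASS_NAMES))
    stop("p_class must be named over: ", paste(CLASS_NAMES, collapse = ", "))
  p_class <- p_class[CLASS_NAMES]
  if (any(p_class < 0) || abs(sum(p_class) - 1) > 1e-9)
    stop("p_class must be non-negative and sum to 1")
  gtg_mass <- sum(p_class[c("CANONICAL_TAC", "CANONICAL_CAC", "GTG_TYPE")])
  if (gtg_mass > 0 && p_cys_TGT == 0)
    stop("classes with the GTG core require Cys104 = TGT; ",
         "p_cys_TGT = 0 contradicts p_class")
  footprint_len <- as.integer(footprint_len)
  if (!footprint_len %in% c(7L, 9L))
    stop("footprint_len must be 7 (tetrapod) or 9 (teleost)")
  if (!setequal(names(footprint_base_weights), NT_LETTERS))
    stop("footprint_base_weights must be named over A, C, G, T")
  footprint_base_weights <- footprint_base_weights[NT_LETTERS]
  if (any(footprint_base_weights < 0) ||
      abs(sum(footprint_base_weights) - 1) > 1e-9)
    stop("footprint_base_weights must be non-negative and sum to 1")
  if (!is.null(footprint_charged_codon_p))
    stopifnot(footprint_charged_codon_p >= 0, footprint_charged_codon_p <= 1)
  v_len_codons <- as.integer(v_len_codons)
  if (v_len_codons < 104L) stop("v_len_codons must be >= 104")
  gap_codons <- as.integer(gap_codons)
  if (gap_codons < 0L || gap_codons > 13L)
    stop("gap_codons must be between 0 and 13")
  dh_len_range <- as.integer(dh_len_range)
  stopifnot(length(dh_len_range) == 2L, dh_len_range[1] >= 3L,
            dh_len_range[1] <= dh_len_range[2],
            p_cys_TGT >= 0, p_cys_TGT <= 1,
            p_res105_ala >= 0, p_res105_ala <= 1,
            dh_charged_codon_p >= 0, dh_charged_codon_p <= 1)
  structure(list(seed = as.integer(seed), species = species,
                 n_families = n_families, genes_per_family = genes_per_family,
                 p_class = p_class, p_cys_TGT = p_cys_TGT,
                 p_res105_ala = p_res105_ala, footprint_len = footprint_len,
                 footprint_base_weights = footprint_base_weights,
                 footprint_charged_codon_p = footprint_charged_codon_p,
                 v_len_codons = v_len_codons, gap_codons = gap_codons,
                 emit_gapped = isTRUE(emit_gapped),
                 dh_count = as.integer(dh_count), dh_len_range = dh_len_range,
                 dh_charged_codon_p = dh_charged_codon_p),
            class = "crss_sim_config")
}

# Aligned codon slots (1-based, within CDR1/CDR2 stretches) that gap_codons
# are carved from, in order.
GAP_SLOT_CANDIDATES <- c(32:38, 60:65)

sample_or_empty <- function(x, n, prob = NULL) {
  if (n == 0L) character(0) else sample(x, n, replace = TRUE, prob = prob)
}

# codon-105 candidate sets by first nucleotide: sense codons, not Cys
# (TGT/TGC), not Ala (GCN) -- Ala is drawn separately via p_res105_ala.
codon105_candidates <- function() {
  cods <- setdiff(all_codons(), c(STOP_CODONS, "TGT", "TGC"))
  cods <- cods[!grepl("^GC", cods)]
  split(cods, substr(cods, 1L, 1L))
}

#' Generate a synthetic VH repertoire with a ground-truth ledger
#'
#' Each gene is built codon-by-codon: a random in-frame scaffold through the
#' codon-102 analog (no Cys, no stops, ending in Tyr so the heuristic
#' anchor's aromatic-context rule applies), codons 103-105 planted according
#' to the drawn heptamer class, and a footprint of the configured length.
#' The ledger records, per gene, the drawn class, the true 0-based Cys104
#' codon index, the heptamer, codon-usage flags and the footprint, so every
#' downstream detection result can be checked exactly.
#'
#' @param cfg a `crss_sim_config`
#' @return list with `repertoire` (a `crss_repertoire`, DH genes included
#'   when `dh_count > 0`), `ledger` (per-VH-gene data.frame) and `dh_ledger`
#' @export
generate_repertoire <- function(cfg) {
  stopifnot(inherits(cfg, "crss_sim_config"))
  with_seed(cfg$seed, {
    fam <- paste0("VH", seq_len(cfg$n_families))
    family <- rep(fam, cfg$genes_per_family)
    n <- length(family)
    if (n == 0L) stop("config yields zero genes")
    gene_id <- sprintf("%s-%d*01", family, sequence(cfg$genes_per_family))

    classes <- sample(CLASS_NAMES, n, replace = TRUE, prob = cfg$p_class)
    is_can <- classes %in% c("CANONICAL_TAC", "CANONICAL_CAC")
    is_gtg <- classes == "GTG_TYPE"
    is_oth <- classes == "OTHER"

    # scaffold: k real codons before codon 103 (last one is Tyr = codon 102)
    k <- cfg$v_len_codons - 2L - cfg$gap_codons
    scaf_pool <- setdiff(all_codons(), c(STOP_CODONS, "TGT", "TGC"))
    scaf_m <- matrix(sample(scaf_pool, n * (k - 1L), replace = TRUE),
                     nrow = n)
    y102 <- sample(c("TAC", "TAT"), n, replace = TRUE)
    scaffold <- do.call(paste0, c(as.data.frame(scaf_m, stringsAsFactors = FALSE),
                                  list(y102)))

    # codon 103
    c103 <- character(n)
    c103[classes == "CANONICAL_TAC"] <- "TAC"
    c103[classes == "CANONICAL_CAC"] <- "CAC"
    pool_gtg103 <- setdiff(all_codons(), c(STOP_CODONS, "TAC", "CAC"))
    c103[is_gtg] <- sample_or_empty(pool_gtg103, sum(is_gtg))
    pool_oth103 <- setdiff(all_codons(), STOP_CODONS)
    c103[is_oth] <- sample_or_empty(pool_oth103, sum(is_oth))

    # codon 104: forced TGT for GTG-core classes; TGT w.p. p_cys_TGT else
    # TGC for OTHER (TGT here is exactly GT retention)
    c104 <- rep("TGT", n)
    if (any(is_oth))
      c104[is_oth] <- ifelse(stats::runif(sum(is_oth)) < cfg$p_cys_TGT,
                             "TGT", "TGC")
    oth_gt <- is_oth & c104 == "TGT"
    oth_gc <- is_oth & c104 == "TGC"

    # first nucleotide of codon 105 (heptamer position 7)
    nt1 <- character(n)
    nt1[is_can | is_gtg] <- "G"
    nt1[oth_gt] <- sample_or_empty(c("A", "C", "T"), sum(oth_gt))
    nt1[oth_gc] <- sample_or_empty(NT_LETTERS, sum(oth_gc))

    L <- cfg$footprint_len
    w <- cfg$footprint_base_weights
    if (!is.null(cfg$footprint_charged_codon_p)) {
      # charged-codon mode: footprint = frame-II codons with charged
      # probability p (+ leftover nt from base weights); codon 105's tail
      # is the footprint's first two nucleotides.
      p <- cfg$footprint_charged_codon_p
      ncod <- L %/% 3L
      charged_cods <- codons_for(CHARGED_AA)
      neutral_cods <- setdiff(setdiff(all_codons(), STOP_CODONS), charged_cods)
      pick <- stats::runif(n * ncod) < p
      draw <- character(n * ncod)
      draw[pick] <- sample_or_empty(charged_cods, sum(pick))
      draw[!pick] <- sample_or_empty(neutral_cods, sum(!pick))
      fp_cod <- matrix(draw, nrow = n)
      fp <- do.call(paste0, as.data.frame(fp_cod, stringsAsFactors = FALSE))
      if (L %% 3L)
        fp <- paste0(fp, sample(NT_LETTERS, n, replace = TRUE, prob = w))
      c105 <- paste0(nt1, substr(fp, 1L, 2L))
      # keep codon 105 non-Cys so the planted Cys104 stays 3'-most
      clash <- which(c105 %in% c("TGT", "TGC"))
      if (length(clash)) {
        nt1[clash] <- vapply(clash, function(i)
          sample(if (oth_gt[i]) c("A", "C") else c("A", "C", "G"), 1L), "")
        c105 <- paste0(nt1, substr(fp, 1L, 2L))
      }
    } else {
      # weights mode: codon 105 drawn per p_res105_ala and class
      # constraints; footprint tail (positions 3..L) from base weights.
      is_ala <- stats::runif(n) < cfg$p_res105_ala
      is_ala[oth_gt] <- FALSE          # Ala starts with G; OTHER+GT forbids G
      c105 <- character(n)
      c105[is_ala] <- paste0("GC", sample_or_empty(NT_LETTERS, sum(is_ala)))
      g_nonala <- (!is_ala) & (is_can | is_gtg)
      pool_g <- codon105_candidates()[["G"]]
      c105[g_nonala] <- sample_or_empty(pool_g, sum(g_nonala))
      rest <- (!is_ala) & is_oth
      if (any(rest)) {
        cand <- codon105_candidates()
        c105[rest] <- vapply(nt1[rest], function(f) sample(cand[[f]], 1L), "")
      }
      tail_m <- matrix(sample(NT_LETTERS, n * (L - 2L), replace = TRUE, prob = w),
                       nrow = n)
      fp_tail <- do.call(paste0, as.data.frame(tail_m, stringsAsFactors = FALSE))
      fp <- paste0(substr(c105, 2L, 3L), fp_tail)
    }
    nt1 <- substr(c105, 1L, 1L)        # Ala draws may override the first nt
    res105_is_ala <- grepl("^GC", c105)

    seq_nt <- paste0(scaffold, c103, c104, c105, substr(fp, 3L, L))
    heptamer <- paste0(c103, c104, nt1)
    klass <- ifelse(is_can, "CANONICAL", ifelse(is_gtg, "GTG_TYPE", "OTHER"))
    # structural sanity: planted codons must realize the drawn class
    stopifnot(all(substr(heptamer[is_can | is_gtg], 5L, 7L) == "GTG"),
              all(substr(heptamer[oth_gt], 5L, 6L) == "GT"),
              !any(heptamer[is_oth] %in% c("TACTGTG", "CACTGTG")),
              all(substr(heptamer[is_oth], 5L, 7L) != "GTG"))
    cys_index <- cfg$v_len_codons - 1L - cfg$gap_codons

    gapped <- rep(NA_character_, n)
    if (cfg$emit_gapped) {
      real_cod <- cbind(scaf_m, y102, c103, c104)
      gp <- GAP_SLOT_CANDIDATES[seq_len(cfg$gap_codons)]
      aligned <- matrix("", n, cfg$v_len_codons)
      if (length(gp)) aligned[, gp] <- "..."
      aligned[, setdiff(seq_len(cfg$v_len_codons), gp)] <- real_cod
      gapped <- paste0(
        do.call(paste0, as.data.frame(aligned, stringsAsFactors = FALSE)),
        c105, substr(fp, 3L, L))
    }

    genes <- data.frame(gene_id = gene_id, species = cfg$species,
                        family = family, functional = TRUE,
                        seq_nt = seq_nt, gapped_nt = gapped,
                        source = "synthetic", stringsAsFactors = FALSE)
    ledger <- data.frame(gene_id = gene_id, species = cfg$species,
                         family = family, class = classes, klass = klass,
                         cys104_codon_index = cys_index,
                         heptamer = heptamer, cys104_codon = c104,
                         res105_codon = c105, res105_is_ala = res105_is_ala,
                         gt_retained = substr(heptamer, 5L, 6L) == "GT",
                         footprint = fp, footprint_len = nchar(fp),
                         stringsAsFactors = FALSE)

    dh <- empty_dh()
    dh_ledger <- data.frame(gene_id = character(0), best_fraction = numeric(0),
                            best_offset = integer(0), stringsAsFactors = FALSE)
    if (cfg$dh_count > 0L) {
      built <- build_dh_genes(cfg)
      dh <- built$dh
      dh_ledger <- built$ledger
    }
    list(repertoire = new_repertoire(cfg$species, genes, dh),
         ledger = ledger, dh_ledger = dh_ledger)
  })
}

# Draws DH genes from the current RNG stream (no re-seeding); ledger values
# come from an exhaustive generation-time oracle over the three offsets.
build_dh_genes <- function(cfg) {
  n <- cfg$dh_count
  span <- cfg$dh_len_range[2] - cfg$dh_len_range[1] + 1L
  lens <- cfg$dh_len_range[1] + sample.int(span, n, replace = TRUE) - 1L
  charged_cods <- codons_for(CHARGED_AA)
  neutral_cods <- setdiff(setdiff(all_codons(), STOP_CODONS), charged_cods)
  seqs <- vapply(lens, function(len) {
    ncod <- len %/% 3L
    pick <- stats::runif(ncod) < cfg$dh_charged_codon_p
    cods <- character(ncod)
    cods[pick] <- sample_or_empty(charged_cods, sum(pick))
    cods[!pick] <- sample_or_empty(neutral_cods, sum(!pick))
    rem <- len %% 3L
    paste0(paste(cods, collapse = ""),
           paste(sample_or_empty(NT_LETTERS, rem), collapse = ""))
  }, "")
  ids <- sprintf("IGHD%d*01", seq_len(n))
  oracle <- t(vapply(seqs, function(s) {
    best <- -1; best_off <- NA_integer_
    for (off in 0:2) {
      sub <- substring(s, off + 1L)
      nc <- nchar(sub) %/% 3L
      if (nc == 0L) next
      starts <- 3L * (seq_len(nc) - 1L) + 1L
      aa <- unname(Biostrings::GENETIC_CODE[substring(sub, starts, starts + 2L)])
      frac <- sum(aa %in% c("D", "E", "K", "R", "H")) / nc
      if (frac > best) { best <- frac; best_off <- off }
    }
    c(best, best_off)
  }, numeric(2), USE.NAMES = FALSE))
  list(dh = data.frame(gene_id = ids, species = cfg$species, functional = TRUE,
                       seq_nt = seqs, stringsAsFactors = FALSE),
       ledger = data.frame(gene_id = ids, best_fraction = oracle[, 1],
                           best_offset = as.integer(oracle[, 2]),
                           stringsAsFactors = FALSE))
}

#' Generate a standalone synthetic DH gene set
#'
#' Convenience wrapper that seeds the RNG from `cfg$seed` and builds
#' `cfg$dh_count` DH genes; the ledger carries each gene's best-frame
#' charged fraction computed by an exhaustive generation-time oracle.
#'
#' @param cfg a `crss_sim_config` with `dh_count > 0`
#' @return list with `dh_genes` (data.frame) and `ledger`
#' @export
generate_dh_set <- function(cfg) {
  stopifnot(inherits(cfg, "crss_sim_config"), cfg$dh_count > 0L)
  with_seed(cfg$seed, {
    built <- build_dh_genes(cfg)
    list(dh_genes = built$dh, ledger = built$ledger)
  })
}
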