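# The VH-replacement footprint: every nucleotide 3' of the heptamer.  The
# footprint typically spans 7 nt in tetrapods and 9 nt in teleosts.  It is
# translated in three reading frames whose offsets are fixed by the
# residue counts those lengths must yield (1,2,2 and 2,3,2): frame I is the
# natural continuation of the V frame, so its first two footprint
# nucleotides complete codon 105 and are not scored (offset 2); frame II
# starts at the footprint's first nucleotide (offset 0); frame III at its
# second (offset 1).  Only codons wholly inside the footprint count; stop
# codons ('*') and ambiguous codons ('X') sit in denominators as
# non-charged residues.

FRAME_OFFSETS <- c(I = 2L, II = 0L, III = 1L)

#' Extract the footprint 3' of the heptamer
#'
#' @param gene one VH gene (list/one-row data.frame with `gene_id`, `seq_nt`)
#' @param call the gene's heptamer call (must be complete); only
#'   `cys104_codon_index` and `heptamer` are consulted
#' @return list (Footprint) with `gene_id`, `seq` (possibly ""),
#'   `length_nt`, and `frames = NULL` until [translate_frames()] is applied
#' @export
extract_footprint <- function(gene, call) {
  if (is.na(call$heptamer) || identical(call$klass, "INCOMPLETE"))
    stop("extract_footprint: incomplete heptamer call for ", gene$gene_id)
  c0 <- call$cys104_codon_index
  fp <- substring(gene$seq_nt, 3L * c0 + 5L)  # after codon 105's first nt
  list(gene_id = gene$gene_id, seq = fp, length_nt = nchar(fp), frames = NULL)
}

frame_reading <- function(label, offset, fp_seq) {
  sub <- substring(fp_seq, offset + 1L)
  aa <- translate_codons(split_codons(sub))
  list(label = label, offset = offset,
       peptide = paste(aa, collapse = ""),
       n_residues = length(aa),
       n_charged = sum(aa %in% CHARGED_AA),
       n_positive = sum(aa %in% POSITIVE_AA),
       n_negative = sum(aa %in% NEGATIVE_AA))
}

#' Translate a footprint in the three reading frames
#'
#' Populates `frames` with FrameReading records I (offset 2), II (offset 0)
#' and III (offset 1).  A frame of length L and offset o holds
#' floor((L - o)/3) residues.
#'
#' @param fp a Footprint from [extract_footprint()]
#' @return the Footprint with `frames` populated (a named list I/II/III)
#' @examples
#' fp <- list(gene_id = "g", seq = "GAAAAAG", length_nt = 7L, frames = NULL)
#' translate_frames(fp)$frames$II$peptide  # "EK"
#' @export
translate_frames <- function(fp) {
  fp$frames <- lapply(names(FRAME_OFFSETS), function(lab)
    frame_reading(lab, FRAME_OFFSETS[[lab]], fp$seq))
  names(fp$frames) <- names(FRAME_OFFSETS)
  fp
}

#' Per-gene, per-frame footprint table for a repertoire
#'
#' Extracts and translates the footprint of every gene with a complete
#' heptamer call and returns one row per gene x frame.
#'
#' @param rep a `crss_repertoire`
#' @param calls heptamer calls from [scan_repertoire()]
#' @return data.frame with columns gene_id, species, family, footprint,
#'   length_nt, frame, offset, peptide, n_residues, n_charged, n_positive,
#'   n_negative
#' @export
footprint_table <- function(rep, calls) {
  stopifnot(identical(calls$gene_id, rep$genes$gene_id))
  keep <- which(!is.na(calls$heptamer))
  rows <- lapply(keep, function(i) {
    fp <- translate_frames(extract_footprint(rep$genes[i, ], as.list(calls[i, ])))
    do.call(rbind, lapply(fp$frames, function(fr)
      data.frame(gene_id = fp$gene_id, species = rep$genes$species[i],
                 family = rep$genes$family[i], footprint = fp$seq,
                 length_nt = fp$length_nt, frame = fr$label,
                 offset = fr$offset, peptide = fr$peptide,
                 n_residues = fr$n_residues, n_charged = fr$n_charged,
                 n_positive = fr$n_positive, n_negative = fr$n_negative,
                 stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(gene_id = character(0), species = character(0),
                      family = character(0), footprint = character(0),
                      length_nt = integer(0), frame = character(0),
                      offset = integer(0), peptide = character(0),
                      n_residues = integer(0), n_charged = integer(0),
                      n_positive = integer(0), n_negative = integer(0),
                      stringsAsFactors = FALSE)
  out
}

#' Pool charged-residue counts across genes
#'
#' Residue-level pooling (the default aggregation): numerators and
#' denominators are summed across all genes in each scope, so the result is
#' invariant under gene reordering and under splitting scopes and
#' recombining counts.
#'
#' @param frame_tbl output of [footprint_table()]
#' @param by character vector of grouping columns (default species x frame)
#' @return data.frame with the grouping columns plus n_charged, n_positive,
#'   n_negative, n_total, frequency (NA when n_total is 0) and
#'   positive_over_charged
#' @export
pool_charge <- function(frame_tbl, by = c("species", "frame")) {
  stopifnot(all(by %in% names(frame_tbl)))
  if (nrow(frame_tbl) == 0L) {
    out <- frame_tbl[0, by, drop = FALSE]
    out$n_charged <- out$n_positive <- out$n_negative <- out$n_total <- integer(0)
    out$frequency <- out$positive_over_charged <- numeric(0)
    return(out)
  }
  key <- interaction(frame_tbl[by], drop = TRUE, lex.order = TRUE)
  agg <- function(v) as.integer(rowsum(v, key))
  first <- !duplicated(key)
  ord <- order(key[first])
  out <- frame_tbl[first, by, drop = FALSE][ord, , drop = FALSE]
  out$n_charged <- agg(frame_tbl$n_charged)
  out$n_positive <- agg(frame_tbl$n_positive)
  out$n_negative <- agg(frame_tbl$n_negative)
  out$n_total <- agg(frame_tbl$n_residues)
  out$frequency <- ifelse(out$n_total > 0, out$n_charged / out$n_total, NA_real_)
  out$positive_over_charged <-
    ifelse(out$n_charged > 0, out$n_positive / out$n_charged, NA_real_)
  rownames(out) <- NULL
  out
}

#' Census of charged codons in the standard genetic code
#'
#' Brute-force enumeration of the 64 codons, counting those whose residue
#' lies in `residues`.  The full charged set D/E/K/R/H gives 14 (the 14/64,
#' ~22 percent random baseline); K/R/H gives 10; D/E gives 4.
#'
#' @param residues residue set (default the charged set)
#' @return integer count out of 64
#' @export
charged_codon_census <- function(residues = CHARGED_AA) {
  sum(translate_codons(all_codons()) %in% residues)
}

#' Best-frame charged fraction of a DH gene
#'
#' Translates the DH sequence at offsets 0, 1 and 2 (complete codons only)
#' and returns the maximum charged-residue fraction over the frames; ties
#' resolve to the lowest offset.  This per-gene maximum is deliberately an
#' upper bound on the charge a DH can contribute.
#'
#' @param seq_nt DH nucleotide sequence (length >= 3 for a non-absent value)
#' @return list with `fraction` (NA when no frame holds a complete codon),
#'   `offset`, and `fractions` (per-offset values)
#' @export
dh_best_frame_charged <- function(seq_nt) {
  fr <- vapply(0:2, function(off) {
    aa <- translate_codons(split_codons(substring(seq_nt, off + 1L)))
    if (!length(aa)) NA_real_ else mean(aa %in% CHARGED_AA)
  }, numeric(1))
  names(fr) <- paste0("offset", 0:2)
  if (all(is.na(fr)))
    return(list(fraction = NA_real_, offset = NA_integer_, fractions = fr))
  best <- unname(which.max(fr))        # first max -> lowest offset on ties
  list(fraction = unname(fr[best]), offset = best - 1L, fractions = fr)
}

#' Species-level DH best-frame summary
#'
#' Arithmetic mean, over functional DH genes, of the per-gene best-frame
#' charged fraction.  Reported as an upper bound: the best frame is chosen
#' per gene, so the true average DH charge contribution is lower.
#'
#' @param dh_genes data.frame with columns gene_id, species, functional,
#'   seq_nt
#' @return data.frame with species, n_genes, mean_best_fraction
#' @export
dh_best_frame_summary <- function(dh_genes) {
  dh <- dh_genes[dh_genes$functional, , drop = FALSE]
  if (nrow(dh) == 0L)
    return(data.frame(species = character(0), n_genes = integer(0),
                      mean_best_fraction = numeric(0), stringsAsFactors = FALSE))
  best <- vapply(dh$seq_nt, function(s) dh_best_frame_charged(s)$fraction,
                 numeric(1), USE.NAMES = FALSE)
  sp <- split(best, dh$species)
  data.frame(species = names(sp),
             n_genes = vapply(sp, length, integer(1)),
             mean_best_fraction = vapply(sp, function(v) mean(v, na.rm = TRUE),
                                         numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
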