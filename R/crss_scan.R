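# The candidate 3'cRSS heptamer overlaps codons 103-105: the 6 nt of codons
# 103-104 plus the first nucleotide of codon 105.  The GT of its GTG core is
# supplied by the TGT Cys104 codon, the final G by a G-initial codon 105.
# Classification mirrors the repertoire tables: CANONICAL = TACTGTG or
# CACTGTG (a sub-case of the GTG type, reported separately), GTG_TYPE =
# positions 5-7 equal GTG, OTHER = everything else.  N never matches.

heptamer_call <- function(gene_id, species = NA_character_, family = NA_character_,
                          cys104_codon_index = NA_integer_,
                          heptamer = NA_character_, klass = "INCOMPLETE",
                          gt_retained = NA, cys104_codon = NA_character_,
                          residue105_first_nt = NA_character_,
                          residue105_codon = NA_character_,
                          residue105_is_ala = NA, note = "") {
  list(gene_id = gene_id, species = species, family = family,
       cys104_codon_index = as.integer(cys104_codon_index),
       heptamer = heptamer, klass = klass, gt_retained = gt_retained,
       cys104_codon = cys104_codon, residue105_first_nt = residue105_first_nt,
       residue105_codon = residue105_codon, residue105_is_ala = residue105_is_ala,
       note = note)
}

#' Classify a 7-nt candidate heptamer
#'
#' `CANONICAL` for TACTGTG or CACTGTG; otherwise `GTG_TYPE` when positions
#' 5-7 (1-based) are GTG; otherwise `OTHER`.  Canonical heptamers also
#' satisfy the GTG test, so repertoire tables count them inside the
#' GTG-type column as well.  An N anywhere never matches a motif letter.
#'
#' @param heptamer a single 7-character string over A/C/G/T/N
#' @return one of "CANONICAL", "GTG_TYPE", "OTHER"
#' @examples
#' classify_heptamer("TACTGTG")  # CANONICAL
#' classify_heptamer("AAAAGTG")  # GTG_TYPE
#' classify_heptamer("TACTGTA")  # OTHER
#' @export
classify_heptamer <- function(heptamer) {
  if (!is.character(heptamer) || length(heptamer) != 1L || nchar(heptamer) != 7L)
    stop("heptamer must be a single 7-character string")
  if (grepl("[^ACGTN]", heptamer))
    stop("heptamer contains characters outside A/C/G/T/N: ", heptamer)
  if (heptamer %in% c("TACTGTG", "CACTGTG")) return("CANONICAL")
  if (substr(heptamer, 5L, 7L) == "GTG") return("GTG_TYPE")
  "OTHER"
}

#' Extract and classify the codon-103/105-anchored heptamer
#'
#' With Cys104 at 0-based codon index c, the heptamer is the ungapped
#' sequence slice covering codons 103 and 104 plus the first nucleotide of
#' codon 105.  When the anchor is absent or the slice runs out of sequence
#' the call is `INCOMPLETE` (excluded from all percentage denominators).
#' The call also records codon-usage facts: the Cys104 codon (TGT vs TGC),
#' the full residue-105 codon when available and whether it is an Ala GCN
#' codon, and whether heptamer positions 5-6 retain GT.
#'
#' @param gene one VH gene (list/one-row data.frame with `gene_id`,
#'   `seq_nt`, optionally `species`, `family`)
#' @param anchor an anchor result for that gene (see [anchor_from_gapped()])
#' @return a list (HeptamerCall) with fields gene_id, species, family,
#'   cys104_codon_index, heptamer, klass, gt_retained, cys104_codon,
#'   residue105_first_nt, residue105_codon, residue105_is_ala, note
#' @export
extract_heptamer <- function(gene, anchor) {
  id <- gene$gene_id
  sp <- if (!is.null(gene$species)) gene$species else NA_character_
  fam <- if (!is.null(gene$family)) gene$family else NA_character_
  c0 <- anchor$cys104_codon_index
  if (is.na(c0))
    return(heptamer_call(id, sp, fam, note = paste0("no anchor: ", anchor$note)))
  seq <- gene$seq_nt
  start <- 3L * c0 - 2L               # 1-based first nt of codon 103
  end <- 3L * c0 + 4L                 # 1-based first nt of codon 105
  if (c0 < 1L || end > nchar(seq))
    return(heptamer_call(id, sp, fam, c0,
                         note = "codons 103-105 extend past sequence bounds"))
  hep <- substr(seq, start, end)
  res105 <- if (3L * c0 + 6L <= nchar(seq)) substr(seq, 3L * c0 + 4L, 3L * c0 + 6L)
            else NA_character_
  heptamer_call(
    id, sp, fam, c0,
    heptamer = hep,
    klass = classify_heptamer(hep),
    gt_retained = substr(hep, 5L, 6L) == "GT",
    cys104_codon = substr(hep, 4L, 6L),
    residue105_first_nt = substr(hep, 7L, 7L),
    residue105_codon = res105,
    residue105_is_ala = if (is.na(res105)) NA else grepl("^GC[ACGT]$", res105))
}

#' Scan a whole repertoire for the 3'cRSS heptamer
#'
#' Anchors each gene (via [anchor_repertoire()] unless `anchors` is
#' supplied) and extracts + classifies its heptamer.
#'
#' @param rep a `crss_repertoire`
#' @param anchors optional precomputed anchor data.frame
#' @param prefer_gapped,window_codons passed to [anchor_repertoire()]
#' @return data.frame of heptamer calls, one row per gene, input order
#' @export
scan_repertoire <- function(rep, anchors = NULL, prefer_gapped = TRUE,
                            window_codons = 12L) {
  stopifnot(inherits(rep, "crss_repertoire"))
  if (is.null(anchors)) anchors <- anchor_repertoire(rep, prefer_gapped, window_codons)
  stopifnot(identical(anchors$gene_id, rep$genes$gene_id))
  if (nrow(rep$genes) == 0L) {
    tmpl <- heptamer_call("x")
    out <- as.data.frame(tmpl, stringsAsFactors = FALSE)[0, ]
    return(out)
  }
  rows <- lapply(seq_len(nrow(rep$genes)), function(i) {
    call <- extract_heptamer(rep$genes[i, ], as.list(anchors[i, ]))
    as.data.frame(call, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' GT retention among non-GTG heptamers
#'
#' Among complete heptamers classified OTHER (the GTG test fails), the
#' fraction whose positions 5-6 still read GT -- i.e. Cys104 kept its TGT
#' codon but the following codon does not start with G.
#'
#' @param calls a heptamer-call data.frame from [scan_repertoire()]
#' @return list with `numerator`, `denominator`, `fraction` (NA when the
#'   denominator is zero)
#' @export
gt_retention_stat <- function(calls) {
  other <- calls$klass == "OTHER" & !is.na(calls$heptamer)
  den <- sum(other)
  num <- sum(other & calls$gt_retained)
  list(numerator = num, denominator = den,
       fraction = if (den > 0) num / den else NA_real_)
}

#' Codon-usage tallies at Cys104 and residue 105
#'
#' Over complete heptamer calls: how often the Cys104 codon is TGT (vs TGC
#' or other), and -- over genes whose full codon 105 is available -- how
#' often residue 105 is an Ala GCN codon.
#'
#' @param calls a heptamer-call data.frame
#' @return list with components `cys104_TGT` and `residue105_GCN`, each a
#'   list (numerator, denominator, fraction)
#' @export
codon_usage <- function(calls) {
  complete <- !is.na(calls$heptamer)
  ratio <- function(num, den) list(numerator = num, denominator = den,
                                   fraction = if (den > 0) num / den else NA_real_)
  has105 <- complete & !is.na(calls$residue105_codon)
  list(
    cys104_TGT = ratio(sum(complete & calls$cys104_codon == "TGT"), sum(complete)),
    residue105_GCN = ratio(sum(has105 & calls$residue105_is_ala), sum(has105)))
}
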