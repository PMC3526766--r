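# Locating the 2nd-CYS (Cys104, IMGT unique numbering) in a VH gene.  Under
# IMGT numbering the codon for position 104 occupies aligned nucleotide
# positions 310-312 (1-based) of the gapped V-REGION; in the ungapped
# coding sequence its 0-based codon index is 103 minus one per gapped-out
# codon upstream.  When no gapped form exists, a heuristic exploits the
# conserved (Y/F)-Y-C end of framework region 3.

IMGT_CYS104_NT_START <- 310L  # 1-based aligned nucleotide of codon 104

anchor_result <- function(gene_id, index = NA_integer_,
                          method = c("IMGT_GAPPED", "HEURISTIC"),
                          confident = FALSE, note = "") {
  list(gene_id = gene_id, cys104_codon_index = as.integer(index),
       method = match.arg(method), confident = confident, note = note)
}

#' Anchor Cys104 from an IMGT-gapped V-REGION
#'
#' Maps aligned codon 104 (aligned nucleotides 310-312 of the IMGT-gapped
#' V-REGION) to its codon index in the ungapped sequence by counting
#' non-gap nucleotides upstream.  Returns an absent index with
#' `confident = FALSE` when the gapped form is truncated before position
#' 312, when codon 104 itself contains a gap, or when the upstream
#' non-gap count is not a codon multiple.  If the anchored codon does not
#' translate to Cys the index is still returned but flagged unconfident.
#'
#' @param gene one VH gene: a list or one-row data.frame with fields
#'   `gene_id`, `seq_nt` and `gapped_nt`
#' @return a list with fields `gene_id`, `cys104_codon_index` (0-based codon
#'   index, NA when absent), `method`, `confident`, `note`
#' @export
anchor_from_gapped <- function(gene) {
  id <- gene$gene_id
  gp <- gene$gapped_nt
  if (is.null(gp) || is.na(gp))
    stop("anchor_from_gapped: gene ", id, " has no gapped_nt")
  chars <- strsplit(gp, "", fixed = TRUE)[[1]]
  if (length(chars) < IMGT_CYS104_NT_START + 2L)
    return(anchor_result(id, method = "IMGT_GAPPED",
                         note = "gapped form truncated before aligned position 312"))
  cod104 <- chars[IMGT_CYS104_NT_START:(IMGT_CYS104_NT_START + 2L)]
  if (any(cod104 == "."))
    return(anchor_result(id, method = "IMGT_GAPPED",
                         note = "aligned codon 104 contains gap characters"))
  n_before <- sum(chars[seq_len(IMGT_CYS104_NT_START - 1L)] != ".")
  if (n_before %% 3L != 0L)
    return(anchor_result(id, method = "IMGT_GAPPED",
                         note = "gapping is not codon-aligned upstream of codon 104"))
  idx <- n_before %/% 3L
  seq <- gene$seq_nt
  degapped <- gsub(".", "", gp, fixed = TRUE)
  if (!identical(degapped, seq))
    stop("anchor_from_gapped: gapped/ungapped mismatch for ", id)
  codon <- substr(seq, 3L * idx + 1L, 3L * idx + 3L)
  if (translate_codons(codon) != "C")
    return(anchor_result(id, idx, "IMGT_GAPPED", confident = FALSE,
                         note = sprintf("aligned codon 104 is %s, not a Cys codon", codon)))
  anchor_result(id, idx, "IMGT_GAPPED", confident = TRUE)
}

#' Anchor Cys104 heuristically from an ungapped in-frame sequence
#'
#' Translates the natural frame (first nucleotide) and picks the 3'-most Cys
#' codon within the final `window_codons` complete codons.  The call is
#' confident only when the local context looks like the conserved FR3 end:
#' the residue two positions upstream is aromatic (Y/F/W) or the immediately
#' preceding residue is Tyr.  Codons containing N never match Cys.
#'
#' @param gene one VH gene (list or one-row data.frame with `gene_id`,
#'   `seq_nt`)
#' @param window_codons size of the 3' search window (default 12)
#' @return same shape as [anchor_from_gapped()], `method = "HEURISTIC"`
#' @export
anchor_heuristic <- function(gene, window_codons = 12L) {
  id <- gene$gene_id
  seq <- gene$seq_nt
  n_cod <- nchar(seq) %/% 3L
  if (n_cod == 0L)
    return(anchor_result(id, method = "HEURISTIC",
                         note = "sequence shorter than one codon"))
  aa <- translate_codons(split_codons(seq))
  win <- max(1L, n_cod - as.integer(window_codons) + 1L):n_cod
  cys <- win[aa[win] == "C"]
  if (!length(cys))
    return(anchor_result(id, method = "HEURISTIC",
                         note = sprintf("no Cys codon in final %d codons", window_codons)))
  pos1 <- max(cys)                       # 3'-most, 1-based codon position
  conf <- (pos1 >= 3L && aa[pos1 - 2L] %in% c("Y", "F", "W")) ||
          (pos1 >= 2L && aa[pos1 - 1L] == "Y")
  anchor_result(id, pos1 - 1L, "HEURISTIC", confident = conf,
                note = if (conf) "" else "no aromatic FR3 context upstream of Cys")
}

#' Anchor every gene of a repertoire
#'
#' Uses [anchor_from_gapped()] for genes with a gapped form (when
#' `prefer_gapped`), falling back to [anchor_heuristic()] otherwise.
#'
#' @param rep a `crss_repertoire`
#' @param prefer_gapped use the IMGT-gapped form when available
#' @param window_codons passed to [anchor_heuristic()]
#' @return data.frame with columns gene_id, cys104_codon_index, method,
#'   confident, note (one row per gene, input order)
#' @export
anchor_repertoire <- function(rep, prefer_gapped = TRUE, window_codons = 12L) {
  stopifnot(inherits(rep, "crss_repertoire"))
  if (nrow(rep$genes) == 0L)
    return(data.frame(gene_id = character(0), cys104_codon_index = integer(0),
                      method = character(0), confident = logical(0),
                      note = character(0), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(rep$genes)), function(i) {
    g <- rep$genes[i, ]
    a <- if (prefer_gapped && !is.na(g$gapped_nt)) anchor_from_gapped(g)
         else anchor_heuristic(g, window_codons)
    as.data.frame(a, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
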