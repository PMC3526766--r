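# Reading, validating, filtering and writing germline VH / DH gene sets.
# A repertoire couples a FASTA file (gene_id-only headers) with a sidecar
# annotation TSV carrying the richer metadata (species, family labels such
# as "IGHV1 (J558)", functionality) that FASTA headers cannot hold cleanly.

GENE_COLUMNS <- c("gene_id", "species", "family", "functional",
                  "seq_nt", "gapped_nt", "source")
DH_COLUMNS <- c("gene_id", "species", "functional", "seq_nt")

empty_genes <- function() {
  data.frame(gene_id = character(0), species = character(0),
             family = character(0), functional = logical(0),
             seq_nt = character(0), gapped_nt = character(0),
             source = character(0), stringsAsFactors = FALSE)
}

empty_dh <- function() {
  data.frame(gene_id = character(0), species = character(0),
             functional = logical(0), seq_nt = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a VH repertoire
#'
#' A repertoire holds the functional-candidate germline VH genes of one
#' species, plus (optionally) its germline DH genes.  `genes` must have
#' columns `gene_id`, `species`, `family`, `functional`, `seq_nt`,
#' `gapped_nt` (NA when no IMGT-gapped form is available) and `source`.
#' Sequences must already be normalized (upper-case, T not U); `gapped_nt`,
#' when present, must equal `seq_nt` after removal of "." gap characters.
#'
#' @param species single species label shared by all genes
#' @param genes data.frame of VH genes (see Details)
#' @param dh_genes data.frame of DH genes with columns `gene_id`, `species`,
#'   `functional`, `seq_nt`; may be empty
#' @return an object of class `crss_repertoire`
#' @export
new_repertoire <- function(species, genes = empty_genes(), dh_genes = empty_dh()) {
  stopifnot(is.character(species), length(species) == 1L)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (!all(GENE_COLUMNS %in% names(genes)))
    stop("genes is missing columns: ",
         paste(setdiff(GENE_COLUMNS, names(genes)), collapse = ", "))
  genes <- genes[GENE_COLUMNS]
  rownames(genes) <- NULL
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in repertoire: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (nrow(genes) && !all(genes$species == species))
    stop("all genes must share the repertoire species label '", species, "'")
  if (nrow(genes) && any(!nzchar(genes$seq_nt)))
    stop("empty seq_nt for: ",
         paste(genes$gene_id[!nzchar(genes$seq_nt)], collapse = ", "))
  has_gap <- !is.na(genes$gapped_nt)
  if (any(has_gap)) {
    degapped <- gsub(".", "", genes$gapped_nt[has_gap], fixed = TRUE)
    bad <- degapped != genes$seq_nt[has_gap]
    if (any(bad))
      stop("gapped_nt does not match seq_nt after gap removal for: ",
           paste(genes$gene_id[has_gap][bad], collapse = ", "))
  }
  dh_genes <- as.data.frame(dh_genes, stringsAsFactors = FALSE)
  if (!all(DH_COLUMNS %in% names(dh_genes)))
    stop("dh_genes is missing columns: ",
         paste(setdiff(DH_COLUMNS, names(dh_genes)), collapse = ", "))
  dh_genes <- dh_genes[DH_COLUMNS]
  rownames(dh_genes) <- NULL
  structure(list(species = species, genes = genes, dh_genes = dh_genes),
            class = "crss_repertoire")
}

#' @export
print.crss_repertoire <- function(x, ...) {
  cat("<crss_repertoire> species:", x$species, "\n")
  cat("  VH genes:", nrow(x$genes),
      sprintf("(%d functional, %d with IMGT-gapped form)",
              sum(x$genes$functional), sum(!is.na(x$genes$gapped_nt))), "\n")
  cat("  DH genes:", nrow(x$dh_genes), "\n")
  if (nrow(x$genes))
    cat("  families:", paste(unique(x$genes$family), collapse = ", "), "\n")
  invisible(x)
}

read_fasta_named <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(as.character(set), ids)
}

parse_bool <- function(x, what) {
  v <- tolower(trimws(x))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out))
    stop("unparseable ", what, " values: ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Read a VH (and optionally DH) repertoire from FASTA + annotation TSV
#'
#' FASTA headers carry only the gene_id; all metadata lives in a
#' tab-separated annotation table with header columns `gene_id`, `species`,
#' `family`, `functional` (true/false) and optional `source`.  Sequences are
#' normalized on read (upper-case, U to T, "-" to "."); characters outside
#' A/C/G/T/N/"." are rejected.  Every FASTA record must have an annotation
#' row; orphan records are reported by ID.  An IMGT-gapped companion FASTA
#' (same IDs, "." gaps) may be supplied for a subset of the genes.
#'
#' @param fasta_path path to the ungapped nucleotide FASTA
#' @param annotations_path path to the annotation TSV
#' @param gapped_fasta_path optional path to an IMGT-gapped FASTA
#' @param dh_fasta_path,dh_annotations_path optional DH gene FASTA and TSV
#'   (TSV columns: gene_id, species, functional)
#' @return a `crss_repertoire`
#' @seealso [write_repertoire()], [filter_functional_allele01()]
#' @export
read_repertoire <- function(fasta_path, annotations_path,
                            gapped_fasta_path = NULL,
                            dh_fasta_path = NULL, dh_annotations_path = NULL) {
  seqs <- read_fasta_named(fasta_path)
  ann <- utils::read.delim(annotations_path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  need <- c("gene_id", "species", "family", "functional")
  if (!all(need %in% names(ann)))
    stop("annotation table lacks columns: ",
         paste(setdiff(need, names(ann)), collapse = ", "))
  if (!"source" %in% names(ann)) ann$source <- ""
  orphans <- setdiff(names(seqs), ann$gene_id)
  if (length(orphans))
    stop("FASTA records without annotation: ", paste(orphans, collapse = ", "))
  missing_seq <- setdiff(ann$gene_id, names(seqs))
  if (length(missing_seq))
    warning("annotation rows without FASTA record (dropped): ",
            paste(missing_seq, collapse = ", "))
  ann <- ann[match(names(seqs), ann$gene_id), , drop = FALSE]

  gapped <- rep(NA_character_, length(seqs))
  if (!is.null(gapped_fasta_path)) {
    g <- read_fasta_named(gapped_fasta_path)
    unknown <- setdiff(names(g), names(seqs))
    if (length(unknown))
      stop("gapped FASTA records absent from ungapped set: ",
           paste(unknown, collapse = ", "))
    gapped[match(names(g), names(seqs))] <- normalize_nt(unname(g), names(g))
  }

  species <- unique(ann$species)
  if (length(species) == 0L) species <- "unspecified"
  if (length(species) != 1L)
    stop("annotation table mixes species (", paste(species, collapse = ", "),
         "); build one repertoire per species")

  genes <- data.frame(
    gene_id = names(seqs),
    species = ann$species,
    family = ann$family,
    functional = parse_bool(ann$functional, "functional"),
    seq_nt = normalize_nt(unname(seqs), names(seqs)),
    gapped_nt = gapped,
    source = ann$source,
    stringsAsFactors = FALSE)

  dh <- empty_dh()
  if (!is.null(dh_fasta_path)) {
    if (is.null(dh_annotations_path))
      stop("dh_fasta_path given without dh_annotations_path")
    dseqs <- read_fasta_named(dh_fasta_path)
    dann <- utils::read.delim(dh_annotations_path, stringsAsFactors = FALSE,
                              colClasses = "character", check.names = FALSE)
    dorph <- setdiff(names(dseqs), dann$gene_id)
    if (length(dorph))
      stop("DH FASTA records without annotation: ", paste(dorph, collapse = ", "))
    dann <- dann[match(names(dseqs), dann$gene_id), , drop = FALSE]
    dh <- data.frame(gene_id = names(dseqs), species = dann$species,
                     functional = parse_bool(dann$functional, "DH functional"),
                     seq_nt = normalize_nt(unname(dseqs), names(dseqs)),
                     stringsAsFactors = FALSE)
  }
  new_repertoire(species, genes, dh)
}

#' Allele suffix of an IMGT-style gene name
#'
#' The substring after the last "*"; `NA` when the name carries no "*".
#' @param gene_id character vector
#' @return character vector of suffixes (e.g. "01") or NA
#' @export
allele_suffix <- function(gene_id) {
  ifelse(grepl("*", gene_id, fixed = TRUE), sub(".*\\*", "", gene_id),
         NA_character_)
}

#' Keep functional genes and collapse alleles to *01
#'
#' Retains genes that are annotated functional and whose name either carries
#' no allele suffix or carries the "*01" suffix; when a gene has several
#' alleles only the 01 allele enters the analysis.  Input order is
#' preserved; the operation is idempotent.
#'
#' @param rep a `crss_repertoire`
#' @return a new `crss_repertoire`
#' @export
filter_functional_allele01 <- function(rep) {
  stopifnot(inherits(rep, "crss_repertoire"))
  suf <- allele_suffix(rep$genes$gene_id)
  keep <- rep$genes$functional & (is.na(suf) | suf == "01")
  dh_keep <- rep$dh_genes$functional
  new_repertoire(rep$species, rep$genes[keep, , drop = FALSE],
                 rep$dh_genes[dh_keep, , drop = FALSE])
}

write_fasta <- function(seqs, ids, path) {
  set <- Biostrings::BStringSet(stats::setNames(seqs, ids))
  Biostrings::writeXStringSet(set, path, width = 60L)
}

#' Write a repertoire to FASTA + annotation TSV
#'
#' Inverse of [read_repertoire()]: writing then reading reproduces the
#' repertoire field-for-field.  When any gene carries an IMGT-gapped form it
#' is written to a sibling file `<stem>_gapped.<ext>`; DH genes, when
#' present, go to `<stem>_dh.<ext>` plus `<annotations stem>_dh.<ext>`.
#'
#' @param rep a `crss_repertoire`
#' @param fasta_path,annotations_path output paths
#' @return invisibly, a named list of the files written
#' @export
write_repertoire <- function(rep, fasta_path, annotations_path) {
  stopifnot(inherits(rep, "crss_repertoire"))
  sibling <- function(path, tag) {
    ext <- tools::file_ext(path)
    stem <- tools::file_path_sans_ext(path)
    paste0(stem, "_", tag, if (nzchar(ext)) paste0(".", ext))
  }
  write_fasta(rep$genes$seq_nt, rep$genes$gene_id, fasta_path)
  ann <- rep$genes[c("gene_id", "species", "family", "functional", "source")]
  ann$functional <- ifelse(ann$functional, "true", "false")
  utils::write.table(ann, annotations_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- list(fasta = fasta_path, annotations = annotations_path)
  has_gap <- !is.na(rep$genes$gapped_nt)
  if (any(has_gap)) {
    gp <- sibling(fasta_path, "gapped")
    write_fasta(rep$genes$gapped_nt[has_gap], rep$genes$gene_id[has_gap], gp)
    files$gapped_fasta <- gp
  }
  if (nrow(rep$dh_genes)) {
    df <- sibling(fasta_path, "dh")
    da <- sibling(annotations_path, "dh")
    write_fasta(rep$dh_genes$seq_nt, rep$dh_genes$gene_id, df)
    dann <- rep$dh_genes[c("gene_id", "species", "functional")]
    dann$functional <- ifelse(dann$functional, "true", "false")
    utils::write.table(dann, da, sep = "\t", quote = FALSE, row.names = FALSE)
    files$dh_fasta <- df
    files$dh_annotations <- da
  }
  invisible(files)
}
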