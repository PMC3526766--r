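# End-to-end orchestration: read/filter -> anchor -> extract -> classify ->
# summarize, the footprint charge summary, and the simulate entry point.
# Table rendering follows the repertoire-table convention: one decimal
# place, round-half-up, zero cells as "-", GTG-type column counting
# canonical heptamers as well.

#' Family-level heptamer-class summary
#'
#' One row per (species, family) over complete heptamer calls, plus a
#' `Total` row per species.  Within each row `n_gtg + n_other = N` and
#' `n_canonical <= n_gtg` (the canonical column is a sub-case of the
#' GTG-type column).
#'
#' @param calls heptamer-call data.frame from [scan_repertoire()]
#' @return data.frame with species, family, N, n_canonical, n_gtg, n_other
#'   and rendered canonical/gtg/other cells
#' @export
summarize_families <- function(calls) {
  complete <- calls[!is.na(calls$heptamer), , drop = FALSE]
  row_for <- function(species, family, sub) {
    n_can <- sum(sub$klass == "CANONICAL")
    n_gtg <- sum(sub$klass %in% c("CANONICAL", "GTG_TYPE"))
    n_oth <- sum(sub$klass == "OTHER")
    data.frame(species = species, family = family, N = nrow(sub),
               n_canonical = n_can, n_gtg = n_gtg, n_other = n_oth,
               canonical = fmt_pct_cell(n_can, nrow(sub)),
               gtg = fmt_pct_cell(n_gtg, nrow(sub)),
               other = fmt_pct_cell(n_oth, nrow(sub)),
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (sp in unique(complete$species)) {
    sub_sp <- complete[complete$species == sp, , drop = FALSE]
    for (fam in unique(sub_sp$family))
      out[[length(out) + 1L]] <-
        row_for(sp, fam, sub_sp[sub_sp$family == fam, , drop = FALSE])
    out[[length(out) + 1L]] <- row_for(sp, "Total", sub_sp)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE))) %||%
    data.frame(species = character(0), family = character(0), N = integer(0),
               n_canonical = integer(0), n_gtg = integer(0),
               n_other = integer(0), canonical = character(0),
               gtg = character(0), other = character(0),
               stringsAsFactors = FALSE)
}

#' Run the heptamer scan pipeline on a repertoire
#'
#' Chains filtering (functional, allele *01), anchoring, heptamer
#' extraction and classification, and the family summary.  Every input gene
#' lands in exactly one of the filtered / incomplete / summarized tallies.
#'
#' @param rep a `crss_repertoire`
#' @param prefer_gapped anchor from the IMGT-gapped form when available
#' @param window_codons heuristic anchor window
#' @return object of class `crss_scan_result`: list with `calls`,
#'   `family_summary`, `gt_retention`, `codon_usage` and a `counts` log
#' @export
run_scan <- function(rep, prefer_gapped = TRUE, window_codons = 12L) {
  stopifnot(inherits(rep, "crss_repertoire"))
  n_input <- nrow(rep$genes)
  repf <- filter_functional_allele01(rep)
  calls <- scan_repertoire(repf, prefer_gapped = prefer_gapped,
                           window_codons = window_codons)
  n_incomplete <- sum(is.na(calls$heptamer))
  counts <- c(n_input = n_input,
              n_filtered_out = n_input - nrow(repf$genes),
              n_scanned = nrow(repf$genes),
              n_incomplete = n_incomplete,
              n_summarized = nrow(repf$genes) - n_incomplete)
  structure(list(repertoire = repf, calls = calls,
                 family_summary = summarize_families(calls),
                 gt_retention = gt_retention_stat(calls),
                 codon_usage = codon_usage(calls),
                 counts = counts),
            class = "crss_scan_result")
}

#' @export
print.crss_scan_result <- function(x, ...) {
  cat("<crss_scan_result>\n")
  cat(sprintf("  genes: %d in, %d filtered out, %d scanned (%d incomplete)\n",
              x$counts["n_input"], x$counts["n_filtered_out"],
              x$counts["n_scanned"], x$counts["n_incomplete"]))
  print(x$family_summary[c("species", "family", "canonical", "gtg", "other")],
        row.names = FALSE)
  gr <- x$gt_retention
  if (gr$denominator > 0)
    cat(sprintf("  GT retained among non-GTG heptamers: %d/%d\n",
                gr$numerator, gr$denominator))
  invisible(x)
}

#' Footprint charge summary for a repertoire
#'
#' Per species x reading frame, the pooled charged-residue frequency (or
#' the per-gene mean when `aggregation = "mean"`), the positive/charged
#' split, the DH best-frame column when DH genes are present, and the
#' constant 14/64 random baseline.
#'
#' @param rep a `crss_repertoire`
#' @param scan optional precomputed [run_scan()] result for `rep`
#' @param aggregation "pooled" (residue-level, default) or "mean"
#'   (per-gene frequencies averaged)
#' @return object of class `crss_footprint_result`: list with
#'   `frame_summary`, `dh_summary` (NULL when no DH genes), `baseline`
#'   (list n, N, pct) and the per-gene `footprints` table
#' @export
run_footprint <- function(rep, scan = NULL, aggregation = c("pooled", "mean")) {
  aggregation <- match.arg(aggregation)
  if (is.null(scan)) scan <- run_scan(rep)
  tbl <- footprint_table(scan$repertoire, scan$calls)
  if (aggregation == "pooled") {
    fs <- pool_charge(tbl, by = c("species", "frame"))
  } else {
    with_res <- tbl[tbl$n_residues > 0, , drop = FALSE]
    with_res$gene_freq <- with_res$n_charged / with_res$n_residues
    key <- interaction(with_res[c("species", "frame")], drop = TRUE,
                       lex.order = TRUE)
    first <- !duplicated(key)
    ord <- order(key[first])
    fs <- with_res[first, c("species", "frame"), drop = FALSE][ord, , drop = FALSE]
    fs$n_genes <- as.integer(rowsum(rep(1L, nrow(with_res)), key))
    fs$frequency <- as.numeric(rowsum(with_res$gene_freq, key)) / fs$n_genes
    rownames(fs) <- NULL
  }
  dh <- NULL
  if (nrow(rep$dh_genes) > 0L) {
    dh <- dh_best_frame_summary(rep$dh_genes)
  } else {
    warning("no DH genes in repertoire; DH column omitted")
  }
  structure(list(frame_summary = fs, dh_summary = dh,
                 baseline = list(n = charged_codon_census(), N = 64L,
                                 pct = 100 * charged_codon_census() / 64),
                 aggregation = aggregation, footprints = tbl),
            class = "crss_footprint_result")
}

#' @export
print.crss_footprint_result <- function(x, ...) {
  cat("<crss_footprint_result> aggregation:", x$aggregation, "\n")
  print(x$frame_summary, row.names = FALSE)
  cat(sprintf("  random baseline: %d/%d = %.3f%%\n",
              x$baseline$n, x$baseline$N, x$baseline$pct))
  if (!is.null(x$dh_summary) && nrow(x$dh_summary)) {
    cat("  DH best-frame (upper bound):\n")
    print(x$dh_summary, row.names = FALSE)
  }
  invisible(x)
}

#' Simulate a repertoire and write it to disk
#'
#' Generates a synthetic repertoire from `cfg`, writes the FASTA +
#' annotation TSV dialect that [read_repertoire()] consumes (gapped and DH
#' siblings included when present) and the ground-truth ledgers as TSV.
#'
#' @param cfg a `crss_sim_config`
#' @param out_dir output directory (created if needed)
#' @param stem file-name stem (default "synthetic")
#' @return invisibly, a list with the generated object and the file paths
#' @export
run_simulate <- function(cfg, out_dir, stem = "synthetic") {
  gen <- generate_repertoire(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(out_dir, paste0(stem, ".fasta"))
  ann <- file.path(out_dir, paste0(stem, "_annotations.tsv"))
  files <- write_repertoire(gen$repertoire, fasta, ann)
  ledger_path <- file.path(out_dir, paste0(stem, "_ledger.tsv"))
  utils::write.table(gen$ledger, ledger_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files$ledger <- ledger_path
  if (nrow(gen$dh_ledger)) {
    dhl <- file.path(out_dir, paste0(stem, "_dh_ledger.tsv"))
    utils::write.table(gen$dh_ledger, dhl, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files$dh_ledger <- dhl
  }
  invisible(list(generated = gen, files = files))
}
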