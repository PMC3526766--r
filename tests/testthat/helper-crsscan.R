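# Fixtures are built in code: toy genes with a known Cys104 placement, and
# small FASTA/TSV files written to tempdirs.

# A gene with the IMGT gap-free layout: n_filler filler codons (indices
# 0..n_filler-1), a Tyr at index n_filler, codon103 at n_filler+1 and the
# Cys codon at index n_filler+2.  The default n_filler = 101 puts the Cys
# at 0-based codon index 103, i.e. aligned nucleotides 310-312.
make_toy_seq <- function(codon103 = "TAC", codon104 = "TGT",
                         codon105 = "GCA", tail = "AGAGA",
                         filler = "GCT", n_filler = 101L) {
  paste0(strrep(filler, n_filler), "TAC", codon103, codon104, codon105, tail)
}

toy_gene <- function(seq, id = "g1", species = "toy", family = "VH1",
                     functional = TRUE, gapped = NA_character_,
                     source = "test") {
  list(gene_id = id, species = species, family = family,
       functional = functional, seq_nt = seq, gapped_nt = gapped,
       source = source)
}

toy_repertoire <- function(seqs, ids = paste0("g", seq_along(seqs)),
                           species = "toy", family = "VH1",
                           functional = TRUE, gapped = NA_character_) {
  genes <- data.frame(gene_id = ids, species = species, family = family,
                      functional = functional, seq_nt = seqs,
                      gapped_nt = gapped, source = "test",
                      stringsAsFactors = FALSE)
  new_repertoire(species, genes)
}

write_toy_fasta <- function(seqs, path) {
  lines <- unlist(mapply(function(id, s) c(paste0(">", id), s),
                         names(seqs), seqs, SIMPLIFY = FALSE))
  writeLines(lines, path)
  path
}

write_toy_annotations <- function(ids, path, species = "toy",
                                  family = "VH1", functional = "true") {
  df <- data.frame(gene_id = ids, species = species, family = family,
                   functional = functional, source = "test",
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
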