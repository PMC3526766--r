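# Shared low-level helpers: alphabets, codon arithmetic, translation,
# percentage rendering.  Coordinate convention used throughout the package:
# nucleotide intervals are 0-based half-open; codon index c (0-based) covers
# nucleotides [3c, 3c+3).  IMGT codon numbers are 1-based, so the 2nd-CYS at
# IMGT codon 104 has 0-based codon index 103 in a gap-free V-REGION.

NT_LETTERS <- c("A", "C", "G", "T")

#' Charged amino-acid alphabet
#'
#' Residue sets used for footprint charge scoring: charged = D, E, K, R, H
#' (His counted as charged and positive); positive = K, R, H; negative = D, E.
#'
#' @format Character vectors of one-letter amino-acid codes.
#' @name charge-sets
#' @keywords internal
NULL

CHARGED_AA  <- c("D", "E", "K", "R", "H")
POSITIVE_AA <- c("K", "R", "H")
NEGATIVE_AA <- c("D", "E")
STOP_CODONS <- c("TAA", "TAG", "TGA")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate the 64 codons
#' @return Character vector of all 64 DNA codons, alphabetical order.
#' @keywords internal
all_codons <- function() {
  nt <- NT_LETTERS
  paste0(rep(nt, each = 16L), rep(rep(nt, each = 4L), 4L), rep(nt, 16L))
}

#' Codons encoding a residue set under the standard genetic code
#' @param residues character vector of one-letter amino-acid codes
#' @keywords internal
codons_for <- function(residues) {
  cods <- all_codons()
  cods[unname(Biostrings::GENETIC_CODE[cods]) %in% residues]
}

#' Translate a vector of codons under the standard genetic code
#'
#' Codons containing N (or anything outside ACGT) translate to "X"; stop
#' codons translate to "*".
#' @param codons character vector of 3-nt strings
#' @return character vector of single residues
#' @keywords internal
translate_codons <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Split a nucleotide string into complete codons
#' @keywords internal
split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  starts <- 3L * (seq_len(n) - 1L) + 1L
  substring(seq, starts, starts + 2L)
}

#' Normalize a nucleotide string
#'
#' Upper-cases, converts U to T and "-" gaps to the IMGT "." gap, and rejects
#' any character outside A, C, G, T, N, ".".
#'
#' @param x character vector of sequences
#' @param id optional identifiers used in error messages
#' @return normalized character vector
#' @export
normalize_nt <- function(x, id = NULL) {
  x <- chartr("uU-", "TT.", x)
  x <- toupper(x)
  bad <- grepl("[^ACGTN.]", x)
  if (any(bad)) {
    who <- if (is.null(id)) which(bad) else id[bad]
    stop("invalid nucleotide characters in: ", paste(who, collapse = ", "),
         " (allowed: A C G T N and gap '.')", call. = FALSE)
  }
  x
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; repertoire tables use round-half-up,
#' e.g. 86.95 renders as 87.0 not 86.9.
#' @param x numeric
#' @param digits decimal places
#' @export
round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Render a count as "percent (n/N)"
#'
#' Formats the cell style used in repertoire frequency tables: one decimal
#' place, round-half-up, with a trailing ".0" dropped (so 9/10 is
#' "90 (9/10)" and 93/107 is "86.9 (93/107)").  Zero counts render as the
#' `zero` placeholder.
#'
#' @param n numerator (count)
#' @param N denominator (total)
#' @param zero string used when n or N is zero (default "-")
#' @return a single character string
#' @examples
#' fmt_pct_cell(93, 107)  # "86.9 (93/107)"
#' fmt_pct_cell(16, 17)   # "94.1 (16/17)"
#' fmt_pct_cell(0, 5)     # "-"
#' @export
fmt_pct_cell <- function(n, N, zero = "-") {
  stopifnot(length(n) == 1L, length(N) == 1L, n >= 0, N >= n)
  if (N == 0L || n == 0L) return(zero)
  p <- round_half_up(100 * n / N, 1L)
  p_str <- if (p == trunc(p)) format(trunc(p)) else formatC(p, format = "f", digits = 1L)
  sprintf("%s (%d/%d)", p_str, as.integer(n), as.integer(N))
}

# Run code with a local, restored RNG state seeded from `seed`.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}
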