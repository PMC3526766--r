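# Cross-species clade grouping.  Group membership is a declarative
# (species, family) -> group mapping supplied as a YAML config -- the
# published grouping is a printed table, so it is consumed as data, not
# re-inferred.  A deterministic neighbor-joining guide tree on a
# framework-region alignment is available for exploratory use; it plays no
# role in the frequency computation.

#' Build a group scheme from a named list
#'
#' @param groups named list: group label -> character vector of
#'   "species:family" strings (the family label may itself contain ":"-free
#'   spaces and parentheses, e.g. "mouse:IGHV1 (J558)")
#' @return object of class `group_scheme`: a data.frame mapping plus the
#'   ordered group labels
#' @export
group_scheme <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) == 0L)
    return(structure(list(mapping = data.frame(species = character(0),
                                               family = character(0),
                                               group = character(0),
                                               stringsAsFactors = FALSE),
                          groups = character(0)), class = "group_scheme"))
  stopifnot(!is.null(names(groups)), all(nzchar(names(groups))))
  rows <- lapply(names(groups), function(g) {
    entries <- as.character(groups[[g]])
    bad <- !grepl(":", entries, fixed = TRUE)
    if (any(bad))
      stop("group ", g, ": entries must be 'species:family', got: ",
           paste(entries[bad], collapse = ", "))
    data.frame(species = trimws(sub(":.*$", "", entries)),
               family = trimws(sub("^[^:]*:", "", entries)),
               group = g, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, c(rows, list(make.row.names = FALSE))) %||%
    data.frame(species = character(0), family = character(0),
               group = character(0), stringsAsFactors = FALSE)
  dup <- duplicated(map[c("species", "family")])
  if (any(dup)) {
    offender <- map[dup, ]
    stop("(species, family) assigned to more than one group: ",
         paste(sprintf("%s:%s", offender$species, offender$family), collapse = ", "))
  }
  structure(list(mapping = map, groups = names(groups)), class = "group_scheme")
}

#' Load a group scheme from a YAML config
#'
#' The config maps each group label to a list of "species:family" strings:
#' ```
#' groups:
#'   A: ["mouse:IGHV1 (J558)", "rat:IGHV1"]
#'   B: ["mouse:IGHV2 (Q52)"]
#' ```
#' A top-level `groups:` key is optional (a bare mapping is accepted).
#'
#' @param config_path path to the YAML file
#' @return a `group_scheme`
#' @export
load_group_scheme <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  if (!is.null(cfg$groups)) cfg <- cfg$groups
  if (is.null(cfg)) cfg <- stats::setNames(list(), character(0))
  group_scheme(cfg)
}

#' @export
print.group_scheme <- function(x, ...) {
  cat("<group_scheme>", length(x$groups), "groups,",
      nrow(x$mapping), "(species, family) pairs\n")
  invisible(x)
}

#' Attach clade-group labels to heptamer calls
#'
#' @param calls heptamer-call data.frame carrying species and family
#' @param scheme a `group_scheme`
#' @return `calls` with a `group` column (NA for unmapped pairs)
#' @export
assign_groups <- function(calls, scheme) {
  stopifnot(inherits(scheme, "group_scheme"))
  idx <- match(paste(calls$species, calls$family, sep = "\r"),
               paste(scheme$mapping$species, scheme$mapping$family, sep = "\r"))
  calls$group <- scheme$mapping$group[idx]
  calls
}

#' Per-group heptamer-class frequencies
#'
#' Tabulates complete heptamer calls by clade group: canonical count
#' (TACTGTG/CACTGTG), GTG-type count (canonical included, as in the
#' two-column table convention) and the rendered "pct (n/N)" cells.
#' Unassigned genes are summarized on a separate `unassigned` row; groups
#' with no genes are dropped with a warning.
#'
#' @param calls heptamer-call data.frame with species and family columns
#' @param scheme a `group_scheme`
#' @return data.frame with group, N, n_canonical, n_gtg, n_other and the
#'   rendered canonical/gtg/other cells
#' @export
group_frequencies <- function(calls, scheme) {
  calls <- assign_groups(calls, scheme)
  complete <- calls[!is.na(calls$heptamer), , drop = FALSE]
  complete$group[is.na(complete$group)] <- "unassigned"
  levels_wanted <- c(scheme$groups, "unassigned")
  tab <- lapply(levels_wanted, function(g) {
    sub <- complete[complete$group == g, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    n_can <- sum(sub$klass == "CANONICAL")
    n_gtg <- sum(sub$klass %in% c("CANONICAL", "GTG_TYPE"))
    n_oth <- sum(sub$klass == "OTHER")
    data.frame(group = g, N = nrow(sub), n_canonical = n_can, n_gtg = n_gtg,
               n_other = n_oth,
               canonical = fmt_pct_cell(n_can, nrow(sub)),
               gtg = fmt_pct_cell(n_gtg, nrow(sub)),
               other = fmt_pct_cell(n_oth, nrow(sub)),
               stringsAsFactors = FALSE)
  })
  empty <- setdiff(scheme$groups,
                   c(unlist(lapply(tab, function(d) d$group)), "unassigned"))
  if (length(empty))
    warning("groups with no genes omitted: ", paste(empty, collapse = ", "))
  do.call(rbind, c(tab, list(make.row.names = FALSE))) %||%
    data.frame(group = character(0), N = integer(0), n_canonical = integer(0),
               n_gtg = integer(0), n_other = integer(0),
               canonical = character(0), gtg = character(0),
               other = character(0), stringsAsFactors = FALSE)
}

#' Pairwise p-distance matrix of an alignment
#'
#' Proportion of mismatching sites per pair, with sites containing a gap
#' (".", "-") or N in either sequence excluded pairwise.  Distances are
#' symmetric, zero on the diagonal and in [0, 1]; a pair with no valid
#' sites is an error.
#'
#' @param aln named character vector of equal-length aligned sequences
#' @return symmetric numeric matrix with the sequence names as dimnames
#' @export
p_distance_matrix <- function(aln) {
  stopifnot(is.character(aln), length(aln) >= 2L, !is.null(names(aln)))
  if (length(unique(nchar(aln))) != 1L)
    stop("aligned sequences must all have the same length")
  m <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  valid <- m %in% NT_LETTERS
  dim(valid) <- dim(m)
  n <- length(aln)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- valid[i, ] & valid[j, ]
    if (!any(ok))
      stop("no valid sites shared by ", names(aln)[i], " and ", names(aln)[j])
    d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Deterministic wrapper around classical neighbor joining: taxa are
#' ordered lexicographically before agglomeration (tie-break), and any
#' numerically negative branch length is clamped to zero.  On an additive
#' distance matrix NJ reconstructs the generating tree metric exactly.
#'
#' @param d symmetric distance matrix with dimnames, >= 3 taxa
#' @return an `ape::phylo` tree
#' @export
nj_from_distances <- function(d) {
  stopifnot(is.matrix(d), nrow(d) >= 3L, !is.null(rownames(d)))
  ord <- order(rownames(d))
  tree <- ape::nj(stats::as.dist(d[ord, ord, drop = FALSE]))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Neighbor-joining guide tree from an aligned FASTA
#'
#' Reads an equal-length nucleotide alignment, optionally restricts it to
#' framework-region column ranges, computes pairwise p-distances and runs
#' deterministic neighbor joining.  The tree is exploratory only -- clade
#' groups always come from the declarative scheme.
#'
#' @param aligned_fasta path to the aligned FASTA (gaps "." or "-")
#' @param regions optional list of `c(start, end)` 1-based column ranges
#'   (e.g. FR1-FR3) concatenated before distance computation
#' @return list with `tree` (phylo) and `newick` (string, 6-decimal branch
#'   lengths)
#' @export
nj_guide_tree <- function(aligned_fasta, regions = NULL) {
  aln <- read_fasta_named(aligned_fasta)
  aln <- normalize_nt(aln, names(aln))
  if (length(aln) < 3L) stop("need at least 3 aligned sequences")
  if (length(unique(nchar(aln))) != 1L)
    stop("aligned sequences must all have the same length")
  if (!is.null(regions)) {
    width <- nchar(aln[[1]])
    pieces <- lapply(regions, function(r) {
      stopifnot(length(r) == 2L, r[1] >= 1L, r[2] <= width, r[1] <= r[2])
      substr(aln, r[1], r[2])
    })
    aln <- stats::setNames(do.call(paste0, pieces), names(aln))
  }
  tree <- nj_from_distances(p_distance_matrix(aln))
  list(tree = tree, newick = ape::write.tree(tree, digits = 6))
}
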