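scheme_yaml <- function(dir, text) {
  path <- file.path(dir, "scheme.yaml")
  writeLines(text, path)
  path
}

test_that("group scheme loads from YAML and rejects duplicate assignment", {
  dir <- withr::local_tempdir()
  path <- scheme_yaml(dir, c(
    "groups:",
    "  A:",
    "    - 'mouse:IGHV1 (J558)'",
    "    - 'rat:IGHV1'",
    "  B:",
    "    - 'mouse:IGHV2 (Q52)'"))
  sch <- load_group_scheme(path)
  expect_identical(sch$groups, c("A", "B"))
  expect_identical(nrow(sch$mapping), 3L)
  expect_identical(
    sch$mapping$group[sch$mapping$family == "IGHV1 (J558)"], "A")

  expect_error(group_scheme(list(A = "mouse:IGHV1", B = "mouse:IGHV1")),
               "more than one group")
  expect_error(group_scheme(list(A = "no-colon-here")), "species:family")

  empty <- group_scheme(stats::setNames(list(), character(0)))
  expect_identical(nrow(empty$mapping), 0L)
})

test_that("group frequencies reproduce the generator ledger and render cells", {
  gen <- generate_repertoire(crss_sim_config(seed = 9, n_families = 3,
                                             genes_per_family = 20))
  calls <- scan_repertoire(gen$repertoire)
  sch <- group_scheme(list(
    G1 = c("synthetic_tetrapod:VH1", "synthetic_tetrapod:VH2"),
    G2 = "synthetic_tetrapod:VH3"))
  freq <- group_frequencies(calls, sch)
  led <- gen$ledger
  for (g in c("G1", "G2")) {
    fams <- sch$mapping$family[sch$mapping$group == g]
    sub <- led[led$family %in% fams, ]
    row <- freq[freq$group == g, ]
    expect_identical(row$N, nrow(sub))
    expect_identical(row$n_canonical, sum(sub$klass == "CANONICAL"))
    expect_identical(row$n_gtg,
                     sum(sub$klass %in% c("CANONICAL", "GTG_TYPE")))
  }
  # cross-module conservation: group totals = sum of family totals
  fam_sum <- summarize_families(calls)
  expect_identical(sum(freq$N),
                   fam_sum$N[fam_sum$family == "Total"])

  # unmapped families go to an explicit unassigned row
  sch2 <- group_scheme(list(G1 = "synthetic_tetrapod:VH1"))
  freq2 <- group_frequencies(calls, sch2)
  expect_true("unassigned" %in% freq2$group)
  expect_identical(sum(freq2$N), 60L)

  # a group with no genes is omitted with a warning
  sch3 <- group_scheme(list(G1 = "synthetic_tetrapod:VH1",
                            GX = "nosuch:VH9"))
  expect_warning(group_frequencies(calls, sch3), "GX")
})

test_that("a 16-of-17 group renders as '94.1 (16/17)'", {
  calls <- data.frame(
    gene_id = sprintf("g%d", 1:17), species = "sp", family = "VH10",
    heptamer = c(rep("TACTGTG", 16), "TACTGTA"),
    klass = c(rep("CANONICAL", 16), "OTHER"),
    stringsAsFactors = FALSE)
  freq <- group_frequencies(calls, group_scheme(list(F = "sp:VH10")))
  expect_identical(freq$canonical, "94.1 (16/17)")
  expect_identical(freq$gtg, "94.1 (16/17)")
})

test_that("p-distance is symmetric, bounded, and excludes gap/N sites pairwise", {
  aln <- c(a = "ACGTACGT", b = "ACGTACGA", c = "AC.TACNT")
  d <- p_distance_matrix(aln)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d["a", "b"], 1 / 8)
  expect_equal(d["a", "c"], 0)        # 6 valid sites, all matching
  expect_error(p_distance_matrix(c(a = "ACGT", b = "ACG")), "same length")
})

test_that("NJ reconstructs hand-built additive matrices exactly", {
  # tree ((A:1,B:2):3,(C:4,D:5))
  d4 <- matrix(c(0, 3, 8, 9,
                 3, 0, 9, 10,
                 8, 9, 0, 9,
                 9, 10, 9, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- nj_from_distances(d4)
  expect_equal(as.matrix(stats::cophenetic(tree))[LETTERS[1:4], LETTERS[1:4]],
               d4, tolerance = 1e-10)
  expected <- ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5));")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tree),
                                         ape::unroot(expected))), 0)
})

test_that("NJ on a 5-taxon additive matrix is exact too", {
  # tree ((A:1,B:2):1.5,(C:3,(D:2,E:4):1):0.5)
  lab <- LETTERS[1:5]
  d5 <- matrix(0, 5, 5, dimnames = list(lab, lab))
  d5["A", "B"] <- 3; d5["A", "C"] <- 6; d5["A", "D"] <- 6; d5["A", "E"] <- 8
  d5["B", "C"] <- 7; d5["B", "D"] <- 7; d5["B", "E"] <- 9
  d5["C", "D"] <- 6; d5["C", "E"] <- 8; d5["D", "E"] <- 6
  d5 <- d5 + t(d5)
  tree <- nj_from_distances(d5)
  expect_equal(as.matrix(stats::cophenetic(tree))[lab, lab], d5,
               tolerance = 1e-10)
})

test_that("degenerate alignments give star trees and pair identical neighbors", {
  dir <- withr::local_tempdir()
  fa <- write_toy_fasta(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"),
                        file.path(dir, "same.fasta"))
  gt <- nj_guide_tree(fa)
  expect_true(all(gt$tree$edge.length == 0))
  expect_identical(sort(gt$tree$tip.label), c("a", "b", "c"))
  expect_match(gt$newick, "^\\(")

  fa2 <- write_toy_fasta(c(a = "ACGTACGT", b = "ACGTACGT",
                           c = "TGCATGCA", d = "TGCAACCA"),
                         file.path(dir, "pair.fasta"))
  gt2 <- nj_guide_tree(fa2)
  cop <- as.matrix(stats::cophenetic(gt2$tree))
  expect_equal(cop["a", "b"], 0)
  expect_lt(cop["a", "b"], cop["a", "c"])

  expect_error(nj_guide_tree(fa2, regions = list(c(1, 100))), "")
  fa3 <- write_toy_fasta(c(a = "ACGT", b = "ACGA"), file.path(dir, "two.fasta"))
  expect_error(nj_guide_tree(fa3), "at least 3")
})

test_that("region ranges restrict the alignment columns used", {
  dir <- withr::local_tempdir()
  # differences only in columns 5-8; restricting to 1-4 zeroes distances
  fa <- write_toy_fasta(c(a = "ACGTAAAA", b = "ACGTCCCC", c = "ACGTGGGG"),
                        file.path(dir, "reg.fasta"))
  gt <- nj_guide_tree(fa, regions = list(c(1, 4)))
  expect_true(all(gt$tree$edge.length == 0))
})
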