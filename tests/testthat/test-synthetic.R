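test_that("same seed and config give byte-identical output", {
  cfg <- crss_sim_config(seed = 42, n_families = 2, genes_per_family = 10,
                         dh_count = 5)
  a <- generate_repertoire(cfg)
  b <- generate_repertoire(cfg)
  expect_identical(a$repertoire$genes, b$repertoire$genes)
  expect_identical(a$ledger, b$ledger)
  expect_identical(a$repertoire$dh_genes, b$repertoire$dh_genes)
  c <- generate_repertoire(crss_sim_config(seed = 43, n_families = 2,
                                           genes_per_family = 10))
  expect_false(identical(a$repertoire$genes$seq_nt,
                         c$repertoire$genes$seq_nt))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  invisible(generate_repertoire(crss_sim_config(seed = 99, n_families = 1,
                                                genes_per_family = 2)))
  expect_identical(runif(1), before)
})

test_that("degenerate class distribution plants only canonical TACTGTG", {
  gen <- generate_repertoire(crss_sim_config(
    seed = 3, n_families = 1, genes_per_family = 30,
    p_class = c(CANONICAL_TAC = 1, CANONICAL_CAC = 0, GTG_TYPE = 0, OTHER = 0)))
  expect_true(all(gen$ledger$heptamer == "TACTGTG"))
  calls <- scan_repertoire(gen$repertoire)
  expect_true(all(calls$klass == "CANONICAL"))
})

test_that("GTG-core structural constraints hold on every generated gene", {
  gen <- generate_repertoire(crss_sim_config(seed = 17, n_families = 3,
                                             genes_per_family = 100))
  led <- gen$ledger
  gtg <- led$klass %in% c("CANONICAL", "GTG_TYPE")
  expect_true(all(led$cys104_codon[gtg] == "TGT"))
  expect_true(all(substr(led$heptamer[gtg], 7, 7) == "G"))
  oth <- led$klass == "OTHER"
  expect_true(all(substr(led$heptamer[oth], 5, 7) != "GTG"))
  expect_true(all(led$cys104_codon %in% c("TGT", "TGC")))
  # footprint length is as configured and equals the recorded footprint
  expect_true(all(led$footprint_len == 7L))
  expect_true(all(nchar(led$footprint) == 7L))
})

test_that("config validation rejects inconsistent settings", {
  expect_error(crss_sim_config(p_class = c(CANONICAL_TAC = 0.5,
                                           CANONICAL_CAC = 0.2,
                                           GTG_TYPE = 0.2, OTHER = 0.2)),
               "sum to 1")
  expect_error(crss_sim_config(p_cys_TGT = 0), "TGT")
  expect_silent(crss_sim_config(
    p_cys_TGT = 0,
    p_class = c(CANONICAL_TAC = 0, CANONICAL_CAC = 0, GTG_TYPE = 0, OTHER = 1)))
  expect_error(crss_sim_config(footprint_len = 8), "7")
  expect_error(crss_sim_config(v_len_codons = 90), "104")
  expect_error(crss_sim_config(footprint_base_weights = c(A = 1, C = 0, G = 0)),
               "named over")
})

test_that("footprint tail composition matches the base weights within 3 sigma", {
  w <- c(A = 0.55, C = 0.05, G = 0.35, T = 0.05)
  gen <- generate_repertoire(crss_sim_config(
    seed = 23, n_families = 1, genes_per_family = 2200,
    footprint_base_weights = w))
  tails <- substr(gen$ledger$footprint, 3, 7)   # weight-governed positions
  counts <- table(factor(strsplit(paste(tails, collapse = ""), "")[[1]],
                         levels = names(w)))
  n <- sum(counts)
  for (b in names(w)) {
    se <- sqrt(w[[b]] * (1 - w[[b]]) / n)
    expect_lt(abs(counts[[b]] / n - w[[b]]), 3 * se)
  }
})

test_that("ledger class counts equal what the pipeline re-derives", {
  gen <- generate_repertoire(crss_sim_config(seed = 57, n_families = 4,
                                             genes_per_family = 50))
  res <- run_scan(gen$repertoire)
  expect_identical(res$calls$heptamer, gen$ledger$heptamer)
  expect_identical(res$calls$klass, gen$ledger$klass)
  expect_identical(res$calls$residue105_codon, gen$ledger$res105_codon)
  expect_identical(res$calls$residue105_is_ala, gen$ledger$res105_is_ala)
  # footprints re-derive too
  tbl <- footprint_table(res$repertoire, res$calls)
  fpI <- tbl$footprint[tbl$frame == "I"]
  expect_identical(fpI, gen$ledger$footprint)
})

test_that("gapped emission round-trips through files and anchors correctly", {
  cfg <- crss_sim_config(seed = 77, n_families = 2, genes_per_family = 10,
                         gap_codons = 3)
  out <- run_simulate(cfg, withr::local_tempdir())
  files <- out$files
  expect_true(file.exists(files$gapped_fasta))
  back <- read_repertoire(files$fasta, files$annotations,
                          gapped_fasta_path = files$gapped_fasta)
  anchors <- anchor_repertoire(back)
  expect_true(all(anchors$cys104_codon_index == 100L))  # 103 - 3 gap codons
  res <- run_scan(back)
  led <- utils::read.delim(files$ledger, stringsAsFactors = FALSE)
  expect_identical(res$calls$klass, led$klass)
})
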