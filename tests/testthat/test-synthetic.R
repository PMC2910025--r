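small_cfg <- function(...) {
  defaults <- list(n_kinases = 21, n_inhibitors = 8,
                   n_ligand_descriptors = 25,
                   seq_length_range = c(120, 150),
                   length_tails = c(110, 180), core_length = 100)
  overrides <- list(...)
  do.call(synth_config, utils::modifyList(defaults, overrides))
}

test_that("configuration invariants are enforced", {
  expect_error(synth_config(n_groups = 0), "n_groups")
  expect_error(synth_config(pkd_floor = 6), "pkd_floor")
  expect_error(synth_config(active_fraction_target = 1.2), "active_fraction")
  expect_error(synth_config(motif_length = 300,
                            seq_length_range = c(240, 300)), "motif_too_long")
  expect_error(synth_config(core_length = 500), "core_length")
})

test_that("group assignment is pigeonhole-exact when groups equal kinases", {
  cfg <- synth_config(n_kinases = 7, n_groups = 7,
                      seq_length_range = c(120, 140),
                      length_tails = c(110, 160), core_length = 100)
  seqs <- generate_sequences(cfg)
  expect_equal(nrow(seqs), 7)
  expect_equal(length(unique(seqs$group)), 7)
  expect_equal(as.integer(table(seqs$group)), rep(1L, 7))
})

test_that("the default panel covers 317 kinases in 7 named groups", {
  seqs <- generate_sequences(synth_config(seed = 1))
  expect_equal(nrow(seqs), 317)
  expect_setequal(unique(seqs$group),
                  c("AGC", "CAMK", "CK1", "CMGC", "STE", "TK", "TKL"))
  lens <- nchar(seqs$sequence)
  expect_true(all(lens >= 194 & lens <= 606))
  expect_gt(mean(lens >= 240 & lens <= 300), 0.8)
})

test_that("sequences use the 20-letter alphabet and embed the group motif", {
  cfg <- small_cfg(seed = 5)
  seqs <- generate_sequences(cfg)
  expect_false(any(grepl("[^ACDEFGHIKLMNPQRSTVWY]", seqs$sequence)))
  truth <- attr(seqs, "truth")
  for (i in seq_len(nrow(seqs))) {
    g <- truth$group_index[i]
    motif <- truth$motifs[g]
    s <- truth$motif_start[i]
    expect_equal(substr(seqs$sequence[i], s, s + nchar(motif) - 1), motif)
  }
})

test_that("the emitted alignment is consistent with the sequences", {
  seqs <- generate_sequences(small_cfg(seed = 6))
  expect_equal(length(unique(nchar(seqs$aligned))), 1)
  expect_equal(gsub("-", "", seqs$aligned), seqs$sequence)
})

test_that("generation is deterministic: same seed, byte-identical output", {
  cfg <- small_cfg(seed = 11)
  p1 <- simulate_kinome_panel(cfg)
  p2 <- simulate_kinome_panel(cfg)
  expect_identical(p1$sequences, p2$sequences)
  expect_identical(p1$ligand_table, p2$ligand_table)
  expect_identical(p1$activity, p2$activity)
  d1 <- file.path(tempdir(), "panel_a"); d2 <- file.path(tempdir(), "panel_b")
  write_panel(p1, d1); write_panel(p2, d2)
  for (f in c("kinases.fasta", "kinases_aligned.fasta")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  p3 <- simulate_kinome_panel(small_cfg(seed = 12))
  expect_false(identical(p1$ligand_table, p3$ligand_table))
  expect_equal(dim(p1$ligand_table), dim(p3$ligand_table))
})

test_that("ligand tables have the configured shape, down to one column", {
  tbl <- generate_ligand_table(synth_config(seed = 2))
  expect_equal(dim(tbl), c(38, 151))  # compound id + 150 descriptors
  one <- generate_ligand_table(small_cfg(n_ligand_descriptors = 1, seed = 3))
  expect_equal(ncol(one), 2)
})

test_that("censoring is exact: inactive if and only if pK_d equals the floor", {
  panel <- simulate_kinome_panel(small_cfg(seed = 13))
  act <- panel$activity
  expect_equal(act$inactive, act$pkd == 4)
  expect_true(all(act$pkd[!act$inactive] >= 5))
  expect_true(all(act$pkd[!act$inactive] <= 10.62))
  expect_true(all(act$pkd %in% c(4, act$pkd[act$pkd >= 5])))
})

test_that("the default matrix has 12,046 cells near the target active rate", {
  panel <- simulate_kinome_panel(synth_config(seed = 4))
  expect_equal(nrow(panel$activity), 12046)
  expect_lt(abs(mean(!panel$activity$inactive) - 0.248), 0.03)
})

test_that("without noise or cross effect the surface is exactly additive", {
  cfg <- small_cfg(noise_sd = 0, interaction_weight = 0, seed = 14)
  panel <- simulate_kinome_panel(cfg)
  unc <- panel$truth$pkd_uncensored
  centred <- sweep(sweep(unc, 1, rowMeans(unc)), 2, colMeans(unc)) + mean(unc)
  expect_lt(max(abs(centred)), 1e-10)
})

test_that("dimension mismatches between stages are rejected", {
  cfg_a <- small_cfg(seed = 15)
  cfg_b <- small_cfg(n_inhibitors = 5, seed = 15)
  seqs <- generate_sequences(cfg_a)
  lig <- generate_ligand_table(cfg_b)
  expect_error(generate_activity_matrix(seqs, lig, cfg_a), "dimensions")
})

test_that("panel files round-trip through FASTA and TSV", {
  panel <- simulate_kinome_panel(small_cfg(seed = 16))
  dir <- file.path(tempdir(), "panel_rt")
  paths <- write_panel(panel, dir)
  expect_true(all(file.exists(paths)))
  fasta <- Biostrings::readAAStringSet(file.path(dir, "kinases.fasta"))
  expect_equal(as.character(fasta),
               stats::setNames(panel$sequences$sequence,
                               panel$sequences$kinase))
  lig <- load_ligand_table(file.path(dir, "ligand_descriptors.tsv"))
  expect_equal(dim(lig), dim(panel$ligand_table))
})
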