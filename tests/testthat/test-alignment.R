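toy_alignment <- function(seqs, ids = paste0("s", seq_along(seqs))) {
  tibble::tibble(id = ids, seq = seqs)
}

test_that("identical ungapped sequences map to all-invariant columns", {
  aln <- toy_alignment(rep("MKTAYIAKQR", 3))
  cols <- map_alignment(aln)
  expect_equal(nrow(cols), 10)
  expect_equal(cols$position, 1:10)
  expect_true(all(cols$n_gaps == 0))
  expect_true(all(vapply(cols$residues, function(r) length(unique(r)) == 1,
                         logical(1))))
})

test_that("gaps are excluded from residue multisets and counted", {
  aln <- toy_alignment(c("MKT", "M-T", "MAT"))
  cols <- map_alignment(aln, ref_id = "s1")
  expect_equal(cols$n_gaps, c(0, 1, 0))
  expect_equal(cols$n_species, c(3, 2, 3))
  expect_setequal(cols$residues[[2]], c("K", "A"))
})

test_that("reference numbering skips reference gap columns", {
  # ref has an internal gap: alignment column 3 is not a reference position
  aln <- toy_alignment(c("MK-TA", "MKCTA", "MKCTA"), c("ref", "a", "b"))
  cols <- map_alignment(aln, ref_id = "ref")
  expect_equal(nrow(cols), 4)
  expect_equal(cols$ref_aa, c("M", "K", "T", "A"))
  expect_equal(cols$alignment_column, c(1, 2, 4, 5))
})

test_that("malformed alignments are rejected", {
  expect_error(map_alignment(toy_alignment(c("MKT", "MK"))), "ragged")
  expect_error(map_alignment(toy_alignment(c("MKT", "MKT")), ref_id = "zz"),
               "zz")
  expect_error(map_alignment(toy_alignment(c("MKT", "MJT"))), "J")
})

test_that("alignment FASTA round-trips through Biostrings", {
  aln <- gen_alignment(L = 30, n_species = 5, invariant_fraction = 0.5,
                       seed = 7)$alignment
  path <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, path)
  back <- read_alignment(path)
  expect_equal(back, aln)
})

test_that("conservation profile flags invariant and conserved positions", {
  aln <- toy_alignment(rep(strrep("ACDEFGHIKLMNPQRSTVWY", 1), 4))
  prof <- conservation_profile(map_alignment(aln))
  expect_equal(sum(prof$invariant), 20)
  expect_equal(sum(prof$conserved), 20)
  expect_true(all(prof$gv == 0))
})

test_that("profile round-trips the generator's ground truth", {
  sim <- gen_alignment(L = 120, n_species = 12, invariant_fraction = 0.65,
                       seed = 42)
  prof <- conservation_profile(map_alignment(sim$alignment))
  expect_equal(sum(prof$invariant), round(120 * 0.65))
  expect_equal(prof$invariant, sim$truth$invariant)
  expect_identical(lapply(prof$residues, function(r) sort(unique(r))),
                   sim$truth$residues)
  # invariant count equals a brute-force count of single-residue columns
  brute <- sum(vapply(sim$truth$residues, length, integer(1)) == 1)
  expect_equal(sum(prof$invariant), brute)
  # invariant implies gv == 0, and conserved is gv < threshold
  expect_true(all(prof$gv[prof$invariant] == 0))
  expect_equal(prof$conserved, prof$gv < 61.3)
})

test_that("columns with fewer than two residues are unscorable, not zero", {
  aln <- toy_alignment(c("MKT", "M--", "M--"))
  prof <- conservation_profile(map_alignment(aln))
  expect_false(prof$scorable[2])
  expect_true(is.na(prof$gv[2]))
  expect_false(prof$conserved[2])
})

test_that("GV/frequency correlation recovers a negative coupling", {
  sim <- gen_alignment(L = 300, n_species = 12, invariant_fraction = 0.5,
                       seed = 3)
  prof <- conservation_profile(map_alignment(sim$alignment))
  fam <- gen_family_counts(prof, coupling = 0.05, base_mean = 5,
                           dispersion = 2, seed = 4)
  res <- conservation_frequency_corr(prof, fam)
  expect_equal(res$method, c("pearson", "spearman"))
  expect_lt(res$estimate[res$method == "spearman"], -0.2)
  expect_equal(res$n[1], 300)
})

test_that("constant inputs make the correlation error out", {
  sim <- gen_alignment(L = 50, n_species = 6, invariant_fraction = 0.4,
                       seed = 9)
  prof <- conservation_profile(map_alignment(sim$alignment))
  expect_error(conservation_frequency_corr(prof, rep(0, nrow(prof))),
               "constant")
  all_inv <- gen_alignment(L = 50, n_species = 6, invariant_fraction = 1,
                           seed = 10)
  prof2 <- conservation_profile(map_alignment(all_inv$alignment))
  expect_error(conservation_frequency_corr(prof2, rpois(50, 2)), "constant")
})

test_that("positions absent from a family-count table are zero-filled", {
  sim <- gen_alignment(L = 40, n_species = 6, invariant_fraction = 0.5,
                       seed = 5)
  prof <- conservation_profile(map_alignment(sim$alignment))
  fam_tbl <- tibble::tibble(position = c(3L, 10L), families = c(4L, 1L))
  res <- conservation_frequency_corr(prof, fam_tbl)
  full <- rep(0, 40)
  full[c(3, 10)] <- c(4, 1)
  res2 <- conservation_frequency_corr(prof, full)
  expect_equal(res$estimate, res2$estimate)
  expect_equal(res$n[1], 40)
})
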