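test_that("conservation fractions, interchange tolerance, strict >99% boundary", {
  # 100 records; site 1 all Leu, site 2 has one Val (interchange),
  # site 3 has one Ser (breaks the strict boundary), site 4 gapped once
  n <- 100
  s1 <- rep("L", n)
  s2 <- c(rep("L", n - 1), "V")
  s3 <- c(rep("L", n - 1), "S")
  s4 <- c(rep("L", n - 1), "-")
  seqs <- setNames(vapply(seq_len(n), function(r)
    paste0(s1[r], s2[r], s3[r], s4[r]), ""),
    c("ref", sprintf("h%03d", seq_len(n - 1))))
  prof <- hydrophobic_conservation(alignment(seqs), "ref")
  st <- prof$sites
  expect_equal(st$fraction[1], 1)
  expect_true(st$conserved[1])
  expect_equal(st$fraction[2], 1)          # hydrophobic interchange
  expect_true(st$conserved[2])
  expect_equal(st$fraction[3], 99 / 100)   # exactly 99%
  expect_false(st$conserved[3])            # strict > 0.99
  expect_false(st$eligible[4])             # gap anywhere disqualifies
  expect_false(st$conserved[4])
  expect_error(hydrophobic_conservation(alignment(seqs), "nope"),
               "not in alignment")
})

test_that("non-hydrophobic reference residues are never flagged", {
  aln <- alignment(c(ref = "SLAG", h1 = "SLAG", h2 = "SLAG"))
  st <- hydrophobic_conservation(aln, "ref")$sites
  expect_false(st$conserved[1])  # Ser reference
  expect_true(st$conserved[2])   # Leu reference, fully conserved
  expect_true(st$conserved[3])   # Ala
  expect_false(st$conserved[4])  # Gly is not in the hydrophobic set
})

test_that("flags are invariant under record reordering and hydrophobic permutation", {
  m <- make_msa(n_records = 10, length = 30, region = c(10, 20),
                conserved_sites = data.frame(site = c(12, 15), target = 1),
                seed = 21)
  aln <- m$alignment
  base <- hydrophobic_conservation(aln, "ref")$sites$conserved
  # reorder records (reference stays present)
  perm <- alignment(setNames(aln$seqs[c(3, 1, 2, 4:10)],
                             aln$ids[c(3, 1, 2, 4:10)]))
  expect_equal(hydrophobic_conservation(perm, "ref")$sites$conserved, base)
  # permute hydrophobic letters at a conserved site in the homologues
  mat <- alignment_matrix(aln)
  hset <- hydrophobic_residues()
  swap <- setNames(hset[c(2:length(hset), 1)], hset)
  mat[-1, 12] <- swap[mat[-1, 12]]
  perm2 <- alignment(setNames(apply(mat, 1, paste, collapse = ""), aln$ids))
  expect_equal(hydrophobic_conservation(perm2, "ref")$sites$conserved, base)
})

test_that("adding a reference copy never lowers conservation fractions", {
  m <- make_msa(n_records = 8, length = 25, region = c(8, 18),
                conserved_sites = data.frame(site = 10, target = 1),
                seed = 5)
  aln <- m$alignment
  prof1 <- hydrophobic_conservation(aln, "ref")$sites
  aug <- alignment(setNames(c(aln$seqs, aln$seqs[1]), c(aln$ids, "ref2")))
  prof2 <- hydrophobic_conservation(aug, "ref")$sites
  el <- prof1$eligible & prof2$eligible &
    prof1$reference_residue %in% hydrophobic_residues()
  expect_true(all(prof2$fraction[el] >= prof1$fraction[el] - 1e-12))
})

test_that("site-to-reference mapping skips reference gaps and round-trips", {
  aln <- alignment(c(ref = "ML-AV-W", h1 = "MLKAVSW", h2 = "MLAAVTW"))
  prof <- hydrophobic_conservation(aln, "ref")
  st <- prof$sites
  expect_equal(st$reference_position, c(1, 2, NA, 3, 4, NA, 5))
  flags <- map_sites_to_reference(prof)
  expect_length(flags, 5)  # ungapped reference length
  # round-trip: flags at reference positions equal site flags
  keep <- !is.na(st$reference_position)
  expect_equal(flags[st$reference_position[keep]], st$conserved[keep])
  # gap-free reference: identity mapping
  aln2 <- alignment(c(ref = "MLAV", h1 = "MLAV", h2 = "MLAV"))
  p2 <- hydrophobic_conservation(aln2, "ref")
  expect_equal(p2$sites$reference_position, 1:4)
})
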