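test_that("isolated and fully buried atoms hit the closed-form limits", {
  iso <- make_sasa_fixture("isolated_pair")
  s <- shrake_rupley(iso)
  expect_equal(s, rep(4 * pi * 3.1^2, 2), tolerance = 1e-9)  # full spheres
  buried <- make_sasa_fixture("buried_atom")
  expect_lt(shrake_rupley(buried)[1], 1)
  # coincident centers error
  bad <- data.frame(element = "C", x = c(0, 0), y = 0, z = 0)
  expect_error(shrake_rupley(bad), "coincident")
})

test_that("two-sphere burial matches the analytic cap across a distance grid", {
  R <- 1.7 + 1.4
  full <- 4 * pi * R^2
  for (d in seq(2.0, 6.2, by = 0.6)) {
    atoms <- data.frame(element = "C", x = c(0, d), y = 0, z = 0)
    s <- shrake_rupley(atoms, n_points = 5000)
    # analytic: cap height h = R - d/2 (overlap of equal expanded spheres)
    h <- max(R - d / 2, 0)
    analytic <- full - 2 * pi * R * h
    expect_equal(s[1], analytic, tolerance = 0.02 * full)
  }
})

test_that("two-carbon reference reproduces 27.27 A^2 and its limits", {
  expect_equal(two_carbon_reference(), 27.27, tolerance = 1e-3)
  expect_equal(two_carbon_reference(probe = 0), 0)
  # numeric Shrake-Rupley agrees within 1% at n_points = 10000
  pp <- make_sasa_fixture("packed_pair")
  s <- shrake_rupley(pp, n_points = 10000)
  buried <- 4 * pi * 3.1^2 - s[1]
  expect_lt(abs(buried - two_carbon_reference()) / two_carbon_reference(),
            0.01)
})

test_that("side-chain contacts: burial threshold, symmetry, degenerate cases", {
  fix <- packed_fixture()
  nc <- sidechain_contacts(fix)
  expect_s3_class(nc, "native_contacts")
  expect_equal(nrow(nc$pairs), 1)  # only the (1, 3) hydrophobic pair
  row <- nc$pairs[1, ]
  expect_true(row$in_contact)
  # oracle: direct recomputation of the directional burial of residue 1
  at <- fix$atoms
  sc1 <- which(at$residue_index == 1 & at$atom == "CB")
  occ_all <- seq_len(nrow(at))
  occ_no3 <- which(at$residue_index != 3)
  pts <- golden_spiral_points(960)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- rep(1.7, nrow(at))
  s_full <- foldinit:::.sasa_core(xyz, rad, sc1, occ_all, 1.4, pts)
  s_no3 <- foldinit:::.sasa_core(xyz, rad, sc1, occ_no3, 1.4, pts)
  expect_equal(row$dsasa_i, s_no3 - s_full, tolerance = 1e-9)
  expect_gte(row$dsasa_i, 27)

  # far-apart pair: no contact; threshold 0 makes any burial a contact
  far <- protein_structure("A", c("L", "G", "L"),
                           rbind(c(0, 0, 0), c(20, 0, 0), c(40, 0, 0)),
                           atoms = data.frame(
                             residue_index = c(1L, 2L, 3L),
                             atom = "CB", element = "C",
                             x = c(0, 20, 40), y = 0, z = 0))
  expect_false(any(sidechain_contacts(far)$pairs$in_contact))
  nc0 <- sidechain_contacts(fix, threshold = 0)
  expect_true(all(nc0$pairs$in_contact))

  # residue without side-chain heavy atoms is never in contact
  noside <- protein_structure("A", c("A", "G", "L"),
                              rbind(c(0, 0, 0), c(30, 30, 30), c(3.4, 0, 0)),
                              atoms = data.frame(
                                residue_index = c(1L, 2L, 3L),
                                atom = c("CA", "CA", "CB"), element = "C",
                                x = c(0, 30, 3.4), y = 0, z = 0))
  expect_equal(nrow(sidechain_contacts(noside)$pairs), 0)
})

test_that("conserved contact profile counts pairs with both partners conserved", {
  pairs <- data.frame(res_i = c(1, 1, 2, 4), res_j = c(3, 5, 5, 5),
                      in_contact = c(TRUE, TRUE, TRUE, FALSE))
  flags <- c(TRUE, FALSE, TRUE, TRUE, TRUE)
  prof <- conserved_contact_profile(pairs, flags)
  # contacts (1,3) and (1,5) conserved-conserved; (2,5) blocked by residue 2;
  # (4,5) not a contact
  expect_equal(prof, c(2L, 0L, 1L, 0L, 1L))
  expect_equal(conserved_contact_profile(pairs, rep(FALSE, 5)), rep(0L, 5))
  # all conserved: counts equal plain contact degrees
  expect_equal(conserved_contact_profile(pairs, rep(TRUE, 5)),
               c(2L, 1L, 1L, 0L, 2L))
})

test_that("Gaussian smoothing conserves mass and resolves separated deltas", {
  counts <- rep(0, 40); counts[10] <- 4; counts[30] <- 2
  sm <- smooth_profile(counts, bandwidth = 2)
  expect_equal(sum(sm$smoothed), sum(counts), tolerance = 1e-6)
  expect_setequal(sm$peaks, c(10, 30))
  # delta at the edge still conserves mass (renormalized kernel)
  edge <- rep(0, 15); edge[1] <- 3
  sme <- smooth_profile(edge, bandwidth = 2)
  expect_equal(sum(sme$smoothed), 3, tolerance = 1e-6)
  # constant input: no interior peak
  smc <- smooth_profile(rep(2, 20), bandwidth = 2)
  expect_length(setdiff(smc$peaks, c(1, 20)), 0)
  # convolution oracle for an interior delta
  half <- ceiling(8)
  kern <- dnorm(-half:half, sd = 2); kern <- kern / sum(kern)
  expect_equal(sm$smoothed[10 + (-3:3)] / 4, kern[half + 1 + (-3:3)],
               tolerance = 1e-6)
})
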