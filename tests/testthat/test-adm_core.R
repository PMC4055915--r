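test_that("ADM lookup matches a brute-force oracle; homopolymer is banded", {
  stats <- small_stats()
  seqr <- test_sequence_50()
  adm <- build_adm(seqr, stats)
  aa <- strsplit(seqr, "")[[1]]
  # brute-force lookup oracle on a sample of pairs
  set.seed(2)
  for (k in 1:40) {
    i <- sample(1:49, 1); j <- sample((i + 1):50, 1)
    lk <- lookup_stats(stats, aa[i], aa[j], range_of_separation(j - i))
    expect_equal(adm$expected[i, j], lk$mean)
    expect_equal(adm$expected[j, i], adm$expected[i, j])  # symmetric query
  }
  # homopolymer: expected distance constant within each separation range
  hadm <- build_adm(strrep("A", 40), stats)
  for (m in 1:3) {
    ks <- which(range_of_separation(1:39) == m)
    vals <- unlist(lapply(ks, function(k)
      sapply(1:(40 - k), function(i) hadm$expected[i, i + k])))
    expect_equal(length(unique(round(vals[!is.na(vals)], 10))), 1)
  }
  expect_error(build_adm(strrep("A", 19), stats), "at least 20")
  expect_error(build_adm(paste0(strrep("X", 15), strrep("A", 10)), stats),
               "50%")
})

test_that("region density and eta match exhaustive pair enumeration", {
  stats <- small_stats()
  adm <- build_adm(test_sequence_50(), stats)
  # exhaustive oracle for all intervals of a 40-residue prefix
  count_oracle <- function(a, b) {
    cnt <- 0L
    for (i in a:(b - 1)) for (j in (i + 1):b)
      cnt <- cnt + as.integer(isTRUE(adm$contact[i, j]))
    cnt
  }
  for (a in seq(1, 31, by = 3)) for (b in seq(a + 4, 40, by = 5)) {
    npairs <- (b - a + 1) * (b - a) / 2
    expect_equal(region_density(adm, a, b), count_oracle(a, b) / npairs)
  }
  # eta laws
  expect_equal(region_eta(adm, 1, adm$n), 0)
  expect_error(region_density(adm, 5, 9, min_len = 10), "shorter")
})

test_that("extract_regions recovers planted two-block structure", {
  fam <- make_two_domain_family(100, 40, n_structures = 5, seed = 42)
  adm <- build_adm(fam$probe_sequence, fam$stats)
  reg <- extract_regions(adm)
  expect_equal(nrow(reg), 2)
  reg <- reg[order(reg$start), ]
  expect_lte(abs(reg$start[1] - 1), 5)
  expect_lte(abs(reg$end[1] - 40), 5)
  expect_lte(abs(reg$start[2] - 41), 5)
  expect_lte(abs(reg$end[2] - 100), 5)
  expect_setequal(reg$rank, c("primary", "auxiliary"))
  expect_true(all(reg$eta > 0.03))
  expect_equal(reg$dominance, c("N", "C"))

  # symmetric boundary gives two near-equal regions
  fam2 <- make_two_domain_family(80, 40, n_structures = 5, seed = 7)
  reg2 <- extract_regions(build_adm(fam2$probe_sequence, fam2$stats))
  reg2 <- reg2[order(reg2$start), ]
  expect_equal(nrow(reg2), 2)
  expect_lte(abs((reg2$end[1] - reg2$start[1]) - (reg2$end[2] - reg2$start[2])), 2)
})

test_that("uniform/sub-threshold maps yield no regions; reported regions do not overlap", {
  stats <- small_stats()
  # a cutoff below any expected distance: no contacts anywhere
  adm0 <- build_adm(test_sequence_50(), stats, contact_cutoff = 0.1)
  expect_equal(nrow(extract_regions(adm0)), 0)
  # property over random families: no overlaps among reported regions
  for (s in 1:5) {
    fam <- make_two_domain_family(60, 20 + 4 * s, n_structures = 4, seed = s)
    reg <- extract_regions(build_adm(fam$probe_sequence, fam$stats))
    if (nrow(reg) < 2) next
    reg <- reg[order(reg$start), ]
    expect_true(all(reg$start[-1] > reg$end[-nrow(reg)]))
    expect_true(all(reg$eta > 0.03))
    expect_false(any(reg$start == 1 & reg$end == 60))
  }
})

test_that("adm_similarity laws: symmetry, bounds, identity, complement", {
  set.seed(5)
  for (k in 1:10) {
    n <- sample(20:40, 1)
    a <- sample(c(TRUE, FALSE, NA), n, replace = TRUE, prob = c(.4, .5, .1))
    b <- sample(c(TRUE, FALSE, NA), n, replace = TRUE, prob = c(.4, .5, .1))
    if (!any(!is.na(a) & !is.na(b))) next
    s_ab <- adm_similarity(a, b)
    expect_equal(s_ab, adm_similarity(b, a))
    expect_gte(s_ab, 0); expect_lte(s_ab, 100)
    expect_equal(adm_similarity(a, a), 100)
    # 100 iff agreement at every mutual site
    mutual <- !is.na(a) & !is.na(b)
    expect_equal(s_ab == 100, all(a[mutual] == b[mutual]))
  }
  comp <- c(TRUE, FALSE, TRUE); expect_equal(adm_similarity(comp, !comp), 0)
  expect_error(adm_similarity(c(NA, TRUE), c(FALSE, NA)), "no mutually")
})

test_that("regions map into alignment sites respecting gaps", {
  # record with gaps: ungapped positions 1..8 over 10 sites
  asg <- regions_to_assignment("MK-VLAT-GG",
                               data.frame(start = 3, end = 5))
  expect_equal(asg, c(FALSE, FALSE, NA, TRUE, TRUE, TRUE, FALSE, NA,
                      FALSE, FALSE))
  # empty regions: all FALSE outside gaps
  asg0 <- regions_to_assignment("MK-V", data.frame(start = integer(0),
                                                   end = integer(0)))
  expect_equal(asg0, c(FALSE, FALSE, NA, FALSE))
})

test_that("site inclusion profile counts only non-gapped records", {
  a1 <- c(TRUE, TRUE, FALSE, NA)
  a2 <- c(TRUE, FALSE, FALSE, TRUE)
  a3 <- c(NA, TRUE, FALSE, TRUE)
  prof <- site_inclusion_profile(list(a1, a2, a3))
  expect_equal(prof, c(1, 2 / 3, 0, 1))
  # single record: 0/1 indicator
  expect_equal(site_inclusion_profile(list(a2)), as.numeric(a2))
  # identical assignments: flat 1 inside region
  expect_equal(site_inclusion_profile(list(a2, a2))[c(1, 4)], c(1, 1))
})

test_that("similarity-identity curve matches direct recomputation", {
  m <- make_msa(n_records = 12, length = 50, region = c(15, 35),
                conserved_sites = data.frame(site = 20, target = 1),
                seed = 9)
  aln <- m$alignment
  curve <- similarity_identity_curve(aln, m$assignments, "ref")
  expect_true(all(diff(curve$identity_limit) > 0))
  # direct recomputation oracle
  others <- setdiff(aln$ids, "ref")
  ident <- sapply(others, function(id)
    pairwise_identity(aln$seqs[aln$ids == "ref"], aln$seqs[aln$ids == id]))
  sims <- sapply(others, function(id)
    adm_similarity(m$assignments[["ref"]], m$assignments[[id]]))
  for (r in seq_len(nrow(curve))) {
    sel <- ident >= curve$identity_limit[r]
    expect_equal(curve$mean_similarity[r], mean(sims[sel]))
    expect_equal(curve$n[r], sum(sel))
  }
  # all homologues identical to reference: flat 100
  aln2 <- alignment(c(r = "MKVLATWWIVLFADEGHKKL", h1 = "MKVLATWWIVLFADEGHKKL",
                      h2 = "MKVLATWWIVLFADEGHKKL"))
  asg <- rep(list(c(rep(TRUE, 8), rep(FALSE, 12))), 3)
  names(asg) <- aln2$ids
  c2 <- similarity_identity_curve(aln2, asg, "r")
  expect_true(all(c2$mean_similarity == 100))
})

test_that("NJ recovers a 4-taxon additive topology; degenerate cases", {
  # additive tree: (A:1,B:2) -1- (C:1.5,D:2.5)
  d <- matrix(c(0, 3, 3.5, 4.5,
                3, 0, 4.5, 5.5,
                3.5, 4.5, 0, 4,
                4.5, 5.5, 4, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  sim <- 100 * (1 - d / 10)
  tree <- nj_tree(sim)
  expect_s3_class(tree, "phylo")
  # NJ on additive distances reproduces the path metric exactly
  co <- ape::cophenetic.phylo(tree)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(co, d / 10, tolerance = 1e-9)
  nwk <- ape::write.tree(tree)
  expect_match(nwk, "^\\(")
  expect_error(nj_tree(sim[1:2, 1:2]), "at least 3")
  # duplicate rows: zero-length branch pair
  sim3 <- matrix(100, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tr3 <- nj_tree(sim3)
  expect_true(all(abs(tr3$edge.length) < 1e-12))
})
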