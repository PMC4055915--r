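# Average Distance Map construction, compact-region (folding segment)
# extraction with eta scores, and family-level ADM-similarity analyses.

#' Build an Average Distance Map
#'
#' Fills the upper triangle (j - i >= 1) with the statistical mean CA-CA
#' distance for the key (aa_i, aa_j, M(j - i)) and thresholds it: a pair
#' whose expected distance is at most `contact_cutoff` is a predicted
#' contact. Dense diagonal blocks of this predicted contact map mark
#' segments expected to collapse early in folding.
#'
#' @param sequence One-letter amino-acid string (length >= 20, at most
#'   50 % `"X"`).
#' @param stats A `distance_stats` object (see [build_statistics()]).
#' @param contact_cutoff Contact threshold on the expected distance, in
#'   Angstrom (default 13).
#' @return Object of class `adm` with fields `sequence`, `expected`
#'   (N x N symmetric matrix, NA on/near the diagonal), `contact`
#'   (logical matrix) and `contact_cutoff`.
#' @export
build_adm <- function(sequence, stats, contact_cutoff = 13) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  if (n < 20) stop("sequence must have at least 20 residues")
  if (mean(aa == "X") > 0.5) stop("more than 50% unknown (X) residues")
  expected <- matrix(NA_real_, n, n)
  pr <- which(upper.tri(expected), arr.ind = TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  known <- aa[i] != "X" & aa[j] != "X"
  lk <- lookup_stats(stats, aa[i[known]], aa[j[known]],
                     range_of_separation(j[known] - i[known]))
  expected[cbind(i[known], j[known])] <- lk$mean
  expected[lower.tri(expected)] <- t(expected)[lower.tri(expected)]
  contact <- !is.na(expected) & expected <= contact_cutoff
  contact[cbind(seq_len(n), seq_len(n))] <- NA
  # integral image of the upper-triangular contact indicator, for O(1)
  # region pair counts
  up <- matrix(0, n, n)
  up[pr] <- as.numeric(contact[pr])
  cum <- apply(apply(up, 2, cumsum), 1, cumsum)  # cum[j, i] after t
  cum <- t(cum)
  structure(list(sequence = paste(aa, collapse = ""), aa = aa, n = n,
                 expected = expected, contact = contact,
                 contact_cutoff = contact_cutoff, .cum = cum),
            class = "adm")
}

#' @export
print.adm <- function(x, ...) {
  cat(sprintf("<adm> %d residues, cutoff %.1f A, %.1f%% predicted contacts\n",
              x$n, x$contact_cutoff,
              100 * mean(x$contact[upper.tri(x$contact)], na.rm = TRUE)))
  invisible(x)
}

# number of predicted contacts among pairs a <= i < j <= b (O(1) via the
# integral image)
.region_contacts <- function(adm, a, b) {
  cum <- adm$.cum
  tot <- cum[b, b]
  if (a > 1) tot <- tot - cum[a - 1, b] - cum[b, a - 1] + cum[a - 1, a - 1]
  # subtracting row/col blocks of the upper-tri image: contacts with i < a
  # are rows < a; cum[a-1, b] = sum rows 1..a-1, cols 1..b which is exactly
  # pairs (i < a, j <= b); pairs with j < a are inside that too.
  tot
}

#' Predicted-contact density and eta of a region
#'
#' `region_density` is the fraction of residue pairs inside `[a, b]` that
#' are predicted contacts; `region_eta` subtracts the whole-map density,
#' so eta > 0 marks a region denser than the sequence average.
#'
#' @param adm An [build_adm()] map.
#' @param a,b 1-based inclusive region bounds, `a < b`.
#' @param min_len Minimum admissible region length (default 10).
#' @return A single numeric value.
#' @export
region_density <- function(adm, a, b, min_len = 2) {
  stopifnot(a >= 1, b <= adm$n, a < b)
  if (b - a + 1 < min_len) stop("region shorter than minimum length ", min_len)
  npairs <- (b - a + 1) * (b - a) / 2
  .region_contacts(adm, a, b) / npairs
}

#' @rdname region_density
#' @export
region_eta <- function(adm, a, b, min_len = 2) {
  region_density(adm, a, b, min_len = min_len) -
    region_density(adm, 1, adm$n, min_len = 2)
}

# Recursive diagonal boundary scan. For the interval [a, b], every split
# point p is scored by eta(a, p) + eta(p + 1, b) and the best split
# (smallest p on ties) is examined. The interval is split -- and its two
# children recorded as candidates and recursed into -- only when the
# predicted-contact density *between* the two parts falls below the
# whole-map density: the parts then interact less than background, which
# is the signature of genuine substructure. Inside a homogeneous compact
# block every split leaves cross-density at block level, so recursion
# stops and the block is reported whole instead of fragmenting.
.scan_intervals <- function(adm, a, b, eta_threshold, min_len, acc) {
  len <- b - a + 1
  if (len < 2 * min_len) return(acc)
  ps <- seq(a + min_len - 1, b - min_len)
  if (!length(ps)) return(acc)
  g <- region_density(adm, 1, adm$n)
  cnt_l <- vapply(ps, function(p) .region_contacts(adm, a, p), 0)
  cnt_r <- vapply(ps, function(p) .region_contacts(adm, p + 1, b), 0)
  np_l <- (ps - a + 1) * (ps - a) / 2
  np_r <- (b - ps) * (b - ps - 1) / 2
  score <- (cnt_l / np_l - g) + (cnt_r / np_r - g)
  k <- which.max(score)  # which.max takes the first (smallest p) on ties
  p <- ps[k]
  cross <- (.region_contacts(adm, a, b) - cnt_l[k] - cnt_r[k]) /
    ((p - a + 1) * (b - p))
  if (cross >= g) return(acc)  # homogeneous: no substructure
  for (child in list(c(a, p), c(p + 1, b))) {
    eta <- region_eta(adm, child[1], child[2])
    acc[[length(acc) + 1L]] <- c(child, eta)
    acc <- .scan_intervals(adm, child[1], child[2], eta_threshold,
                           min_len, acc)
  }
  acc
}

# greedy non-overlap resolution: keep higher eta first
.resolve_overlaps <- function(cand) {
  cand <- cand[order(-cand$eta, cand$start, cand$end), ]
  kept <- cand[0, ]
  for (r in seq_len(nrow(cand))) {
    s <- cand$start[r]; e <- cand$end[r]
    if (!nrow(kept) || all(e < kept$start | s > kept$end))
      kept <- rbind(kept, cand[r, ])
  }
  kept
}

#' Extract compact regions (predicted folding segments) from an ADM
#'
#' Candidate intervals are generated by a recursive boundary scan along the
#' diagonal; candidates covering the whole sequence are discarded,
#' overlapping candidates are resolved in favour of the higher eta, and a
#' kept region covering at least 70 % of the sequence triggers a second
#' scan restricted to its interior whose sub-regions are reported
#' alongside it. The region with the maximal eta is labelled `primary`,
#' the rest `auxiliary`; `dominance` is `N` or `C` by the terminal half
#' containing the region midpoint.
#'
#' @param adm An [build_adm()] map.
#' @param eta_threshold Minimum eta for a reported region (default 0.03).
#' @param min_len Minimum region length in residues (default 10).
#' @param numbering_offset Integer added to internal positions to obtain
#'   source (e.g. PDB) numbering in the `start_src`/`end_src` columns.
#' @return Data frame with columns `start`, `end`, `start_src`, `end_src`,
#'   `eta`, `rank`, `dominance`, sorted by eta descending; zero rows if no
#'   region clears the threshold.
#' @export
extract_regions <- function(adm, eta_threshold = 0.03, min_len = 10,
                            numbering_offset = 0) {
  n <- adm$n
  raw <- .scan_intervals(adm, 1, n, eta_threshold, min_len, list())
  empty <- data.frame(start = integer(0), end = integer(0),
                      start_src = integer(0), end_src = integer(0),
                      eta = numeric(0), rank = character(0),
                      dominance = character(0))
  as_df <- function(lst) {
    if (!length(lst)) return(empty[, 1:3][0, ])
    m <- do.call(rbind, lst)
    df <- data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
                     eta = m[, 3])
    unique(df)
  }
  cand <- as_df(raw)
  cand <- cand[!(cand$start == 1 & cand$end == n), , drop = FALSE]
  cand <- cand[cand$eta > eta_threshold &
                 (cand$end - cand$start + 1) >= min_len, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  kept <- .resolve_overlaps(cand)
  # 70-100 % coverage: re-search inside any dominating region
  extra <- empty[, c("start", "end", "eta")][0, ]
  for (r in seq_len(nrow(kept))) {
    if ((kept$end[r] - kept$start[r] + 1) / n >= 0.7) {
      sub_raw <- .scan_intervals(adm, kept$start[r], kept$end[r],
                                 eta_threshold, min_len, list())
      sub <- as_df(sub_raw)
      sub <- sub[!(sub$start == kept$start[r] & sub$end == kept$end[r]), ,
                 drop = FALSE]
      sub <- sub[sub$eta > eta_threshold &
                   (sub$end - sub$start + 1) >= min_len, , drop = FALSE]
      if (nrow(sub)) extra <- rbind(extra, .resolve_overlaps(sub))
    }
  }
  out <- unique(rbind(kept[, c("start", "end", "eta")], extra))
  out <- out[order(-out$eta, out$start), , drop = FALSE]
  out$start_src <- out$start + as.integer(numbering_offset)
  out$end_src <- out$end + as.integer(numbering_offset)
  out$rank <- c("primary", rep("auxiliary", nrow(out) - 1L))
  mid <- (out$start + out$end) / 2
  out$dominance <- ifelse(mid <= n / 2, "N", "C")
  rownames(out) <- NULL
  out[, c("start", "end", "start_src", "end_src", "eta", "rank", "dominance")]
}

#' Map per-sequence regions into alignment-site coordinates
#'
#' @param aligned_seq Aligned sequence string of the record (with gaps).
#' @param regions Data frame with `start`, `end` in the record's own
#'   (ungapped, 1-based) coordinates; zero rows allowed.
#' @return Logical vector over alignment sites: `TRUE` inside a region,
#'   `FALSE` outside, `NA` at the record's gap sites.
#' @export
regions_to_assignment <- function(aligned_seq, regions) {
  chars <- strsplit(aligned_seq, "")[[1]]
  isgap <- chars == "-"
  pos <- cumsum(!isgap)
  member <- rep(FALSE, length(chars))
  if (nrow(regions))
    for (r in seq_len(nrow(regions)))
      member <- member | (pos >= regions$start[r] & pos <= regions$end[r])
  member[isgap] <- NA
  member
}

#' ADM similarity between two region assignments
#'
#' Sites gapped in either record are removed; among the remaining,
#' mutually non-gapped sites, the fraction agreeing on region membership
#' (both inside or both outside a predicted compact region) is returned as
#' a percentage.
#'
#' @param assign_a,assign_b Logical site vectors from
#'   [regions_to_assignment()] (NA = gap), equal length.
#' @return Similarity percentage in `[0, 100]`.
#' @export
adm_similarity <- function(assign_a, assign_b) {
  stopifnot(length(assign_a) == length(assign_b))
  mutual <- !is.na(assign_a) & !is.na(assign_b)
  if (!any(mutual)) stop("no mutually non-gapped sites; similarity undefined")
  100 * sum(assign_a[mutual] == assign_b[mutual]) / sum(mutual)
}

#' Per-site region inclusion profile of a family
#'
#' @param assignments List of per-record assignment vectors (one per
#'   alignment record, equal lengths).
#' @return Numeric vector per alignment site: among records non-gapped at
#'   the site, the fraction whose predicted region covers it (NA where all
#'   records are gapped).
#' @export
site_inclusion_profile <- function(assignments) {
  m <- do.call(rbind, assignments)
  colMeans(m, na.rm = TRUE)
}

#' Pairwise sequence identity over mutually non-gapped sites
#'
#' @param seq_a,seq_b Aligned sequence strings of equal length.
#' @return Identity percentage in `[0, 100]`.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  a <- strsplit(seq_a, "")[[1]]; b <- strsplit(seq_b, "")[[1]]
  stopifnot(length(a) == length(b))
  mutual <- a != "-" & b != "-"
  if (!any(mutual)) stop("no mutually non-gapped sites; identity undefined")
  100 * sum(a[mutual] == b[mutual]) / sum(mutual)
}

#' Average ADM similarity as a function of a sequence-identity lower limit
#'
#' For each lower limit on the grid, the ADM similarity between the
#' reference record and every homologue whose identity to the reference is
#' at least the limit is averaged. Empty bins are omitted.
#'
#' @param aln An [alignment()].
#' @param assignments Named list of assignment vectors, one per record.
#' @param reference_id Identifier of the reference record.
#' @param limits Identity lower limits in percent (default `seq(30, 100, 5)`).
#' @return Data frame with columns `identity_limit`, `mean_similarity`, `n`.
#' @export
similarity_identity_curve <- function(aln, assignments, reference_id,
                                      limits = seq(30, 100, by = 5)) {
  ridx <- match(reference_id, aln$ids)
  if (is.na(ridx)) stop("reference '", reference_id, "' not in alignment")
  others <- setdiff(seq_along(aln$ids), ridx)
  ident <- vapply(others, function(i)
    pairwise_identity(aln$seqs[ridx], aln$seqs[i]), 0)
  sim <- vapply(others, function(i)
    adm_similarity(assignments[[aln$ids[ridx]]], assignments[[aln$ids[i]]]), 0)
  rows <- lapply(limits, function(L) {
    sel <- ident >= L
    if (!any(sel)) return(NULL)
    data.frame(identity_limit = L, mean_similarity = mean(sim[sel]),
               n = sum(sel))
  })
  do.call(rbind, rows)
}

#' Pairwise ADM similarity matrix of a family
#'
#' @param assignments Named list of assignment vectors.
#' @return Symmetric matrix of similarities in percent (100 on diagonal).
#' @export
similarity_matrix <- function(assignments) {
  ids <- names(assignments)
  k <- length(ids)
  m <- matrix(100, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    m[i, j] <- m[j, i] <- adm_similarity(assignments[[i]], assignments[[j]])
  }
  m
}

#' Neighbor-joining tree from an ADM similarity matrix
#'
#' Similarities s (percent) are converted to distances d = 1 - s/100 and
#' passed to standard neighbor joining.
#'
#' @param sim Square symmetric similarity matrix in `[0, 100]` with
#'   identifiers as dimnames; at least 3 taxa.
#' @return An `ape::phylo` tree (unrooted). Serialize with
#'   [ape::write.tree()] for Newick.
#' @export
nj_tree <- function(sim) {
  sim <- as.matrix(sim)
  if (nrow(sim) < 3) stop("neighbor joining needs at least 3 taxa")
  if (any(abs(sim - t(sim)) > 1e-8)) stop("similarity matrix must be symmetric")
  d <- 1 - sim / 100
  ape::nj(stats::as.dist(d))
}
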