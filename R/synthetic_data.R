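# Synthetic-data generators: compact CA chains for statistics building,
# two-domain families with planted block structure, alignments with
# controlled hydrophobic conservation, and heavy-atom SASA fixtures.
# Every generator is a pure function of its seed and returns its ground
# truth alongside the data.

# evaluate `code` under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.random_unit <- function() {
  repeat {
    v <- runif(3, -1, 1)
    s <- sum(v^2)
    if (s > 1e-6 && s <= 1) return(v / sqrt(s))
  }
}

#' Radius of gyration of a coordinate set
#'
#' @param coords `n x 3` matrix.
#' @return Rg in the coordinate units.
#' @export
radius_of_gyration <- function(coords) {
  c0 <- colMeans(coords)
  sqrt(mean(rowSums((coords - matrix(c0, nrow(coords), 3, byrow = TRUE))^2)))
}

# grow one self-avoiding confined chain; NULL on failure
.grow_chain <- function(n, bond, min_dist, r_conf) {
  x <- matrix(NA_real_, n, 3)
  x[1, ] <- c(0, 0, 0)
  k <- 2L
  steps <- 0L
  while (k <= n) {
    steps <- steps + 1L
    if (steps > 200L * n) return(matrix(NA_real_, n, 3))
    placed <- FALSE
    for (try in 1:200) {
      cand <- x[k - 1, ] + bond * .random_unit()
      if (sqrt(sum(cand^2)) > r_conf) next
      if (k > 2) {
        d2 <- rowSums((x[1:(k - 2), , drop = FALSE] -
                         matrix(cand, k - 2, 3, byrow = TRUE))^2)
        if (min(d2) < min_dist^2) next
      }
      x[k, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed) {
      # backtrack a few beads and regrow
      k <- max(2L, k - 6L)
      next
    }
    k <- k + 1L
  }
  x
}

#' Generate a compact self-avoiding C-alpha chain
#'
#' Beads are grown with fixed virtual bonds inside a confining sphere
#' sized so the radius of gyration lands near the globular scaling
#' `2.2 n^(1/3)` Angstrom; non-bonded beads keep at least `min_dist`
#' apart. The sequence is random and hydrophobic-rich. Deterministic for
#' a given seed.
#'
#' @param n Number of residues (>= 20).
#' @param seed Integer seed.
#' @param target_rg Target radius of gyration (default `2.2 * n^(1/3)`).
#' @param bond_length Virtual bond length, Angstrom (default 3.8).
#' @param min_dist Self-avoidance distance, Angstrom (default 3.0).
#' @param alphabet Letters to sample the sequence from, with weights
#'   favouring the hydrophobic set by default.
#' @param max_restarts Reseeded growth attempts before erroring
#'   (default 20).
#' @return A [protein_structure()] (CA only) with attribute `target_rg`.
#' @export
make_compact_chain <- function(n, seed, target_rg = 2.2 * n^(1/3),
                               bond_length = 3.8, min_dist = 3.0,
                               alphabet = NULL, max_restarts = 20) {
  stopifnot(n >= 20)
  .with_seed(seed, {
    # confinement radius calibrated so a confined SAW's Rg tracks the
    # target (sphere-filling walks have Rg ~ 0.72 R)
    r_conf <- target_rg / 0.72
    x <- NULL
    for (attempt in seq_len(max_restarts)) {
      x <- .grow_chain(n, bond_length, min_dist, r_conf)
      if (!anyNA(x)) break
      x <- NULL
    }
    if (is.null(x))
      stop("failed to grow a compact chain after ", max_restarts, " restarts")
    if (is.null(alphabet)) {
      aa <- ifelse(runif(n) < 0.6,
                   sample(HYDROPHOBIC_SET, n, replace = TRUE),
                   sample(setdiff(AA_ALPHABET, HYDROPHOBIC_SET), n,
                          replace = TRUE))
    } else {
      aa <- sample(alphabet, n, replace = TRUE)
    }
    out <- protein_structure("A", aa, x)
    attr(out, "target_rg") <- target_rg
    out
  })
}

# random 3x3 rotation matrix (from the current RNG)
.random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    s <- sqrt(sum(q^2))
    if (s > 1e-8) { q <- q / s; break }
  }
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a two-domain family with planted block structure
#'
#' Each structure consists of two compact blobs, one per sequence block,
#' separated in space so intra-block CA distances are systematically
#' shorter than inter-block distances. Disjoint block alphabets make the
#' derived distance statistics encode the block structure, so an ADM
#' built for a probe sequence over those alphabets shows two dense
#' diagonal blocks with the planted boundary.
#'
#' @param n Chain length of every family member.
#' @param boundary Last residue of the first block
#'   (`0.2 n <= boundary <= 0.8 n`).
#' @param n_structures Number of structures generated (default 6).
#' @param seed Integer seed.
#' @param gap Surface-to-surface spacing between the blobs, Angstrom
#'   (default 15; keep it above the ADM contact cutoff).
#' @return List: `structures`, `stats` (their [build_statistics()]),
#'   `probe_sequence` (an n-mer over the block alphabets matching the
#'   boundary), `boundary`, `alphabet_a`, `alphabet_b`.
#' @export
make_two_domain_family <- function(n, boundary, n_structures = 6, seed = 1,
                                   gap = 15) {
  stopifnot(boundary >= 0.2 * n, boundary <= 0.8 * n)
  alpha_a <- c("L", "V", "I", "F", "A", "M")
  alpha_b <- c("D", "E", "K", "R", "S", "T", "N", "Q")
  .with_seed(seed, {
    seeds <- sample.int(1e6, n_structures * 2 + 1)
    structures <- vector("list", n_structures)
    for (s in seq_len(n_structures)) {
      na <- boundary; nb <- n - boundary
      blob_a <- make_compact_chain(max(na, 20), seeds[2 * s - 1],
                                   alphabet = alpha_a)
      blob_b <- make_compact_chain(max(nb, 20), seeds[2 * s],
                                   alphabet = alpha_b)
      xa <- blob_a$ca[seq_len(na), , drop = FALSE]
      xb <- blob_b$ca[seq_len(nb), , drop = FALSE]
      xa <- xa %*% .random_rotation()
      xb <- xb %*% .random_rotation()
      # centre blobs and separate along x
      xa <- sweep(xa, 2, colMeans(xa))
      xb <- sweep(xb, 2, colMeans(xb))
      ra <- max(sqrt(rowSums(xa^2))); rb <- max(sqrt(rowSums(xb^2)))
      xb[, 1] <- xb[, 1] + ra + rb + gap
      structures[[s]] <- protein_structure(
        "A",
        c(blob_a$aa[seq_len(na)], blob_b$aa[seq_len(nb)]),
        rbind(xa, xb))
    }
    probe <- paste(c(sample(alpha_a, boundary, replace = TRUE),
                     sample(alpha_b, n - boundary, replace = TRUE)),
                   collapse = "")
    list(structures = structures, stats = build_statistics(structures),
         probe_sequence = probe, boundary = boundary,
         alphabet_a = alpha_a, alphabet_b = alpha_b)
  })
}

#' Generate an alignment with planted conservation and regions
#'
#' The reference record is ungapped; planted conserved sites carry an
#' exact number of hydrophobic records (hydrophobic interchange applied),
#' so a conservation target of 1.0 is recovered exactly and targets below
#' the threshold are not. Gaps are inserted at the stated rate, never in
#' the reference record, never at planted conserved sites and never
#' within `jitter` sites of the planted region. Per-record region
#' boundaries are jittered by at most `jitter` sites.
#'
#' @param n_records Number of records including the reference
#'   (default 20).
#' @param length Alignment length in sites (default 60).
#' @param region Planted region of the reference, `c(start, end)` in
#'   alignment sites.
#' @param conserved_sites Data frame with columns `site` and `target`
#'   (fraction of hydrophobic records planted, e.g. 1.0 or 0.95), or an
#'   integer vector (targets default to 1.0).
#' @param identity Probability a non-planted site keeps the reference
#'   letter in a homologue (default 0.7).
#' @param gap_rate Per-site gap probability in non-reference records
#'   (default 0.05, must be <= 0.1).
#' @param jitter Maximum region-boundary shift per record, sites
#'   (default 1).
#' @param seed Integer seed.
#' @return List: `alignment`, `reference_id`, `conserved_sites` (data
#'   frame with realized fractions), `assignments` (named list of
#'   membership vectors over sites, NA at gaps), `regions` (data frame of
#'   per-record jittered bounds in site coordinates).
#' @export
make_msa <- function(n_records = 20, length = 60, region = c(21, 40),
                     conserved_sites = data.frame(site = c(25, 30, 35),
                                                  target = 1.0),
                     identity = 0.7, gap_rate = 0.05, jitter = 1,
                     seed = 1) {
  stopifnot(gap_rate <= 0.1, n_records >= 2)
  if (!is.data.frame(conserved_sites))
    conserved_sites <- data.frame(site = conserved_sites, target = 1.0)
  L <- length
  .with_seed(seed, {
    nonhyd <- setdiff(AA_ALPHABET, HYDROPHOBIC_SET)
    ref <- sample(AA_ALPHABET, L, replace = TRUE)
    ref[conserved_sites$site] <- sample(HYDROPHOBIC_SET,
                                        nrow(conserved_sites), replace = TRUE)
    ids <- c("ref", sprintf("hom%02d", seq_len(n_records - 1)))
    mat <- matrix("", n_records, L)
    mat[1, ] <- ref
    for (r in 2:n_records) {
      keep <- runif(L) < identity
      row <- ifelse(keep, ref, sample(AA_ALPHABET, L, replace = TRUE))
      mat[r, ] <- row
    }
    # plant exact hydrophobic counts at the conserved sites
    for (k in seq_len(nrow(conserved_sites))) {
      s <- conserved_sites$site[k]
      t <- conserved_sites$target[k]
      n_non <- if (t >= 1) 0L else max(1L, round((1 - t) * n_records))
      hyd_rows <- setdiff(seq_len(n_records), 1L)
      non_rows <- if (n_non > 0) sample(hyd_rows, n_non) else integer(0)
      for (r in 2:n_records) {
        mat[r, s] <- if (r %in% non_rows) sample(nonhyd, 1)
        else sample(HYDROPHOBIC_SET, 1)  # hydrophobic interchange
      }
    }
    # non-planted sites carry an implicit conservation target below the
    # threshold: where the reference is hydrophobic and every homologue
    # happened to stay hydrophobic, one random homologue is knocked out so
    # only planted sites can clear the >99 % rule
    for (s in setdiff(which(ref %in% HYDROPHOBIC_SET), conserved_sites$site)) {
      if (all(mat[, s] %in% HYDROPHOBIC_SET))
        mat[sample(2:n_records, 1), s] <- sample(nonhyd, 1)
    }
    # gaps: non-reference records only, away from planted sites and region
    protected <- unique(c(conserved_sites$site,
                          max(1, region[1] - jitter):min(L, region[2] + jitter)))
    for (r in 2:n_records) {
      gsites <- which(runif(L) < gap_rate)
      gsites <- setdiff(gsites, protected)
      if (length(gsites)) mat[r, gsites] <- "-"
    }
    seqs <- setNames(apply(mat, 1, paste, collapse = ""), ids)
    aln <- alignment(seqs)
    regions <- data.frame(id = ids, start = NA_integer_, end = NA_integer_)
    assignments <- vector("list", n_records)
    names(assignments) <- ids
    for (r in seq_len(n_records)) {
      js <- if (r == 1) 0L else sample(-jitter:jitter, 1)
      je <- if (r == 1) 0L else sample(-jitter:jitter, 1)
      st <- max(1, region[1] + js); en <- min(L, region[2] + je)
      regions$start[r] <- st; regions$end[r] <- en
      memb <- seq_len(L) >= st & seq_len(L) <= en
      memb[mat[r, ] == "-"] <- NA
      assignments[[r]] <- memb
    }
    realized <- vapply(conserved_sites$site, function(s)
      mean(mat[, s] %in% HYDROPHOBIC_SET), 0)
    conserved_sites$realized <- realized
    list(alignment = aln, reference_id = "ref",
         conserved_sites = conserved_sites, assignments = assignments,
         regions = regions)
  })
}

#' Heavy-atom toy structures with analytically known burial
#'
#' * `isolated_pair`: two carbon "side chains" 10 Angstrom apart (zero
#'   burial).
#' * `packed_pair`: two carbons at vdW contact distance 3.4 Angstrom (cap
#'   burial, the 27.27 A^2 reference).
#' * `buried_atom`: one carbon enclosed by a shell of carbons (SASA ~ 0).
#'
#' @param kind One of `"isolated_pair"`, `"packed_pair"`, `"buried_atom"`.
#' @return A [protein_structure()] with heavy atoms.
#' @export
make_sasa_fixture <- function(kind = c("isolated_pair", "packed_pair",
                                       "buried_atom")) {
  kind <- match.arg(kind)
  if (kind %in% c("isolated_pair", "packed_pair")) {
    d <- if (kind == "isolated_pair") 10 else 3.4
    ca <- rbind(c(0, 0, 0), c(d, 0, 0))
    atoms <- data.frame(residue_index = 1:2, atom = c("CA", "CA"),
                        element = "C", x = c(0, d), y = 0, z = 0)
    return(protein_structure("A", c("A", "A"), ca, atoms = atoms))
  }
  shell <- golden_spiral_points(42) * 3.2
  xyz <- rbind(c(0, 0, 0), shell)
  atoms <- data.frame(residue_index = 1L,
                      atom = c("CA", rep("CB", nrow(shell))), element = "C",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  protein_structure("A", "A", matrix(0, 1, 3), atoms = atoms)
}
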