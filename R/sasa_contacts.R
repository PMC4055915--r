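# Shrake-Rupley solvent-accessible surface area, the 27 A^2 side-chain
# burial contact definition, and conserved-hydrophobic-contact profiling.

# van der Waals radii (Angstrom); the carbon value is fixed by the
# two-carbon reference burial of 27.27 A^2 at probe 1.4.
DEFAULT_VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Quasi-uniform points on the unit sphere (golden-spiral lattice)
#'
#' @param n Number of points (>= 1).
#' @return `n x 3` matrix of unit vectors. Deterministic.
#' @export
golden_spiral_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(x = cos(theta) * sin(phi), y = sin(theta) * sin(phi), z = cos(phi))
}

.vdw_of <- function(element, radii) {
  el <- toupper(trimws(element))
  r <- radii[el]
  if (any(is.na(r)))
    stop("no van der Waals radius for element(s): ",
         paste(unique(el[is.na(r)]), collapse = ", "))
  unname(r)
}

# core: SASA of the atoms in `which` against occluders in `occluders`
# (indices into the atom table)
.sasa_core <- function(xyz, rad, which, occluders, probe, pts) {
  n_pts <- nrow(pts)
  out <- numeric(length(which))
  for (q in seq_along(which)) {
    i <- which[q]
    R <- rad[i] + probe
    occ <- occluders[occluders != i]
    if (length(occ)) {
      d2 <- rowSums((xyz[occ, , drop = FALSE] -
                       matrix(xyz[i, ], length(occ), 3, byrow = TRUE))^2)
      reach <- (rad[occ] + probe + R)^2
      occ <- occ[d2 < reach]
    }
    if (!length(occ)) {
      out[q] <- 4 * pi * R^2
      next
    }
    sp <- pts * R + matrix(xyz[i, ], n_pts, 3, byrow = TRUE)
    acc <- rep(TRUE, n_pts)
    for (o in occ) {
      r2 <- (rad[o] + probe)^2
      d2 <- (sp[, 1] - xyz[o, 1])^2 + (sp[, 2] - xyz[o, 2])^2 +
        (sp[, 3] - xyz[o, 3])^2
      acc <- acc & d2 >= r2
      if (!any(acc)) break
    }
    out[q] <- 4 * pi * R^2 * sum(acc) / n_pts
  }
  out
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Each atom's sphere (radius vdW + probe) is sampled with a deterministic
#' golden-spiral point set; a point is accessible when outside every other
#' atom's expanded sphere. SASA is the accessible fraction times the full
#' sphere area.
#'
#' @param atoms Data frame with columns `element`, `x`, `y`, `z` (heavy
#'   atoms only), or a [protein_structure()] carrying heavy atoms.
#' @param probe Probe radius, Angstrom (default 1.4).
#' @param n_points Sphere sampling density (default 960, minimum 100).
#' @param radii Named vdW radius table (default C/N/O/S convention).
#' @return Numeric vector of per-atom SASA in A^2.
#' @export
shrake_rupley <- function(atoms, probe = 1.4, n_points = 960,
                          radii = DEFAULT_VDW) {
  if (inherits(atoms, "protein_structure")) atoms <- atoms$atoms
  stopifnot(n_points >= 100)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(xyz) > 1) {
    d <- as.matrix(stats::dist(xyz))
    diag(d) <- Inf
    if (min(d) < 1e-6) stop("coincident atom centers")
  }
  rad <- .vdw_of(atoms$element, radii)
  pts <- golden_spiral_points(n_points)
  .sasa_core(xyz, rad, seq_len(nrow(xyz)), seq_len(nrow(xyz)), probe, pts)
}

#' Analytic two-carbon burial reference
#'
#' Buried area on one carbon when a second carbon sits at vdW-contact
#' distance (2 vdW): the spherical cap `2 pi R h` with `R = vdw + probe`
#' and `h = probe`. Defaults reproduce the 27.27 A^2 contact threshold.
#'
#' @param probe Probe radius, Angstrom (default 1.4).
#' @param vdw_c Carbon vdW radius, Angstrom (default 1.7).
#' @return Buried area in A^2.
#' @export
two_carbon_reference <- function(probe = 1.4, vdw_c = 1.7) {
  R <- vdw_c + probe
  d <- 2 * vdw_c
  h <- R - d / 2
  2 * pi * R * h
}

#' Hydrophobic side-chain contacts by SASA burial
#'
#' For every pair of hydrophobic residues (at least `min_separation`
#' apart), the directional burial `dSASA_i` is the SASA of residue i's
#' side-chain heavy atoms with residue j's atoms removed minus that in the
#' full structure; the pair is in contact when either direction reaches
#' `threshold`. Glycine has no side-chain heavy atoms and is never in
#' contact.
#'
#' @param structure A [protein_structure()] with heavy atoms.
#' @param threshold Burial threshold in A^2 (default 27).
#' @param hydrophobic Residue letters considered (default the package
#'   hydrophobic set).
#' @param min_separation Minimum `|i - j|` (default 2).
#' @param probe,n_points,radii Passed to the SASA engine.
#' @return Object of class `native_contacts`: data frame `pairs`
#'   (`res_i`, `res_j`, `dsasa_i`, `dsasa_j`, `in_contact`) plus fields
#'   `threshold` and `n` (residue count).
#' @export
sidechain_contacts <- function(structure, threshold = 27,
                               hydrophobic = HYDROPHOBIC_SET,
                               min_separation = 2,
                               probe = 1.4, n_points = 960,
                               radii = DEFAULT_VDW) {
  at <- structure$atoms
  if (is.null(at)) stop("structure has no heavy atoms")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- .vdw_of(at$element, radii)
  pts <- golden_spiral_points(n_points)
  n <- length(structure$aa)
  sc_idx <- lapply(seq_len(n), function(i)
    which(at$residue_index == i & !(at$atom %in% BACKBONE_ATOMS)))
  res_idx <- lapply(seq_len(n), function(i) which(at$residue_index == i))
  hyd <- which(structure$aa %in% hydrophobic)
  # full-structure side-chain SASA per residue
  all_idx <- seq_len(nrow(at))
  sc_sasa_full <- vapply(seq_len(n), function(i) {
    if (!length(sc_idx[[i]])) return(0)
    sum(.sasa_core(xyz, rad, sc_idx[[i]], all_idx, probe, pts))
  }, 0)
  rows <- list()
  for (ii in seq_along(hyd)) {
    i <- hyd[ii]
    if (ii == length(hyd)) break
    for (j in hyd[(ii + 1):length(hyd)]) {
      if (j - i < min_separation) next
      if (!length(sc_idx[[i]]) || !length(sc_idx[[j]])) next
      # quick reach test between residues
      di <- xyz[res_idx[[i]], , drop = FALSE]
      dj <- xyz[res_idx[[j]], , drop = FALSE]
      mind2 <- min(outer(rowSums(di^2), rowSums(dj^2), "+") -
                     2 * di %*% t(dj))
      maxreach <- (max(rad) * 2 + 2 * probe + max(rad) + probe)^2
      if (mind2 > maxreach) next
      occ_no_j <- setdiff(all_idx, res_idx[[j]])
      occ_no_i <- setdiff(all_idx, res_idx[[i]])
      ds_i <- sum(.sasa_core(xyz, rad, sc_idx[[i]], occ_no_j, probe, pts)) -
        sc_sasa_full[i]
      ds_j <- sum(.sasa_core(xyz, rad, sc_idx[[j]], occ_no_i, probe, pts)) -
        sc_sasa_full[j]
      rows[[length(rows) + 1L]] <- data.frame(
        res_i = i, res_j = j, dsasa_i = ds_i, dsasa_j = ds_j,
        in_contact = max(ds_i, ds_j) >= threshold)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows)
  else data.frame(res_i = integer(0), res_j = integer(0),
                  dsasa_i = numeric(0), dsasa_j = numeric(0),
                  in_contact = logical(0))
  structure(list(pairs = pairs, threshold = threshold, n = n),
            class = "native_contacts")
}

#' @export
print.native_contacts <- function(x, ...) {
  cat(sprintf("<native_contacts> %d residues, %d pairs evaluated, %d in contact (>= %.0f A^2)\n",
              x$n, nrow(x$pairs), sum(x$pairs$in_contact), x$threshold))
  invisible(x)
}

#' Per-residue conserved hydrophobic contact counts
#'
#' Counts, for each residue, the native contacts whose both partners are
#' conserved hydrophobic residues.
#'
#' @param contacts A [sidechain_contacts()] result (or a data frame with
#'   `res_i`, `res_j`, `in_contact`).
#' @param conserved_flags Logical vector per residue (from
#'   [map_sites_to_reference()]).
#' @return Integer vector of per-residue counts.
#' @export
conserved_contact_profile <- function(contacts, conserved_flags) {
  pairs <- if (inherits(contacts, "native_contacts")) contacts$pairs
  else contacts
  n <- length(conserved_flags)
  counts <- integer(n)
  sel <- pairs$in_contact & conserved_flags[pairs$res_i] &
    conserved_flags[pairs$res_j]
  for (k in which(sel)) {
    counts[pairs$res_i[k]] <- counts[pairs$res_i[k]] + 1L
    counts[pairs$res_j[k]] <- counts[pairs$res_j[k]] + 1L
  }
  counts
}

#' Gaussian smoothing of a per-residue profile
#'
#' Discrete Gaussian convolution with reflecting (mirrored) boundaries:
#' kernel mass falling off either chain end is folded back inside, so the
#' total mass is conserved exactly and a constant profile stays constant.
#' Peaks are strict local maxima of the smoothed curve.
#'
#' @param counts Numeric per-residue vector.
#' @param bandwidth Kernel standard deviation in residues (default 2).
#' @return List: `smoothed` (same length as `counts`), `peaks` (indices).
#' @export
smooth_profile <- function(counts, bandwidth = 2) {
  n <- length(counts)
  half <- min(ceiling(4 * bandwidth), n - 1)
  kern <- dnorm(-half:half, sd = bandwidth)
  kern <- kern / sum(kern)
  reflect <- function(i) {  # symmetric reflection into 1..n
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  sm <- numeric(n)
  for (j in which(counts != 0)) {
    idx <- reflect(j + (-half:half))
    for (t in seq_along(idx))
      sm[idx[t]] <- sm[idx[t]] + counts[j] * kern[t]
  }
  peaks <- integer(0)
  eps <- 1e-9 * max(abs(sm), 1)  # guard against summation-order ripple
  for (i in seq_len(n)) {
    nb <- setdiff(max(1, i - 1):min(n, i + 1), i)
    if (length(nb) && all(sm[i] > sm[nb] + eps)) peaks <- c(peaks, i)
  }
  list(smoothed = sm, peaks = peaks)
}
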