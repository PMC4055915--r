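# F-value analysis: Metropolis Monte-Carlo sampling of a C-alpha bead
# chain under the Gaussian distance potential; contact frequencies g(i,j),
# range-wise normalization Q(i,j), per-residue F profile and peaks.

#' Gaussian pair energy
#'
#' The pair potential is derived by equating the Boltzmann weight of a
#' pair distance with the Gaussian density of the distance statistics:
#' `E(r) = kT * (r - rbar)^2 / (2 sigma^2) + const`. The conformation-
#' independent constant `-kT * log(Z / (sqrt(2 pi) sigma))` cancels in any
#' Metropolis energy difference; set `include_constant = TRUE` (with
#' `Z = 1`) to evaluate the full expression.
#'
#' @param r Observed pair distance(s), Angstrom.
#' @param rbar Statistical mean distance, Angstrom.
#' @param sigma Statistical standard deviation, Angstrom (> 0).
#' @param kT Temperature factor (default 1).
#' @param include_constant Add the per-pair constant term (default FALSE).
#' @return Energy value(s); minimum at `r = rbar`.
#' @export
pair_energy <- function(r, rbar, sigma, kT = 1, include_constant = FALSE) {
  if (any(sigma <= 0)) stop("sigma must be positive (floor it upstream)")
  e <- kT * (r - rbar)^2 / (2 * sigma^2)
  if (include_constant) e <- e + kT * log(sqrt(2 * pi) * sigma)
  e
}

#' Build the pair potential for a sequence from distance statistics
#'
#' For every pair with `|i - j| >= 2` the statistics key
#' `(aa_i, aa_j, M(|i - j|))` supplies the mean and SD; standard
#' deviations below `sigma_floor` are raised to it so one-sample keys do
#' not produce infinite forces. `"X"` residues fall back to the range-mean
#' statistics.
#'
#' @param sequence One-letter amino-acid string.
#' @param stats A `distance_stats` object.
#' @param sigma_floor Minimum allowed SD, Angstrom (default 0.1).
#' @return Object of class `pair_potential`: list with `n`, matrices
#'   `rbar` and `sigma` (NA for `|i - j| < 2`).
#' @export
potential_from_stats <- function(sequence, stats, sigma_floor = 0.1) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  if (n < 10) stop("chain shorter than 10 residues")
  rbar <- sig <- matrix(NA_real_, n, n)
  pr <- which(upper.tri(rbar), arr.ind = TRUE)
  pr <- pr[pr[, 2] - pr[, 1] >= 2, , drop = FALSE]
  i <- pr[, 1]; j <- pr[, 2]
  M <- range_of_separation(j - i)
  aai <- aa[i]; aaj <- aa[j]
  # X residues: use the per-range fallback via a placeholder letter
  unknown <- aai == "X" | aaj == "X"
  mu <- sg <- numeric(length(i))
  if (any(!unknown)) {
    lk <- lookup_stats(stats, aai[!unknown], aaj[!unknown], M[!unknown])
    mu[!unknown] <- lk$mean; sg[!unknown] <- lk$sd
  }
  if (any(unknown)) {
    observed <- which(!is.na(stats$range_mean))
    Mc <- vapply(M[unknown], function(m)
      observed[which.min(abs(observed - m))], 0L)
    mu[unknown] <- stats$range_mean[Mc]
    sg[unknown] <- stats$range_sd[Mc]
  }
  sg <- pmax(sg, sigma_floor)
  rbar[cbind(i, j)] <- mu; rbar[cbind(j, i)] <- mu
  sig[cbind(i, j)] <- sg; sig[cbind(j, i)] <- sg
  structure(list(n = n, sequence = paste(aa, collapse = ""),
                 rbar = rbar, sigma = sig, sigma_floor = sigma_floor),
            class = "pair_potential")
}

# NA entries never reach C++ (pairs |i-j| < 2 are skipped there), but
# replace them with harmless values so no NaN can propagate.
.potential_matrices <- function(pot) {
  rbar <- pot$rbar; sig <- pot$sigma
  rbar[is.na(rbar)] <- 1
  sig[is.na(sig)] <- 1
  list(rbar = rbar, sigma = sig)
}

#' Build chain coordinates from internal angles
#'
#' Places beads with fixed virtual bond length from bond angles (at
#' vertices 2..n-1) and dihedral angles (about bonds 2..n-2).
#'
#' @param theta Bond angles in degrees, length `n - 2`.
#' @param phi Dihedral angles in degrees, length `n - 3` (may be length 0).
#' @param bond_length Virtual bond length, Angstrom (default 3.8).
#' @return `n x 3` coordinate matrix.
#' @export
chain_from_angles <- function(theta, phi, bond_length = 3.8) {
  n <- length(theta) + 2L
  stopifnot(length(phi) == max(n - 3L, 0L))
  th <- theta * pi / 180
  ph <- phi * pi / 180
  x <- matrix(0, n, 3)
  x[2, ] <- c(bond_length, 0, 0)
  if (n >= 3)
    x[3, ] <- x[2, ] + bond_length *
      c(-cos(th[1]), sin(th[1]), 0)
  if (n >= 4) for (k in 4:n) {
    # standard internal-to-Cartesian placement (NeRF)
    a <- x[k - 3, ]; b <- x[k - 2, ]; c0 <- x[k - 1, ]
    t <- th[k - 2]; p <- ph[k - 3]
    bc <- c0 - b
    bc <- bc / sqrt(sum(bc^2))
    ab <- b - a
    nv <- c(ab[2] * bc[3] - ab[3] * bc[2],
            ab[3] * bc[1] - ab[1] * bc[3],
            ab[1] * bc[2] - ab[2] * bc[1])
    nv <- nv / sqrt(sum(nv^2))
    mv <- c(nv[2] * bc[3] - nv[3] * bc[2],
            nv[3] * bc[1] - nv[1] * bc[3],
            nv[1] * bc[2] - nv[2] * bc[1])
    d2 <- bond_length * c(-cos(t), cos(p) * sin(t), sin(p) * sin(t))
    x[k, ] <- c0 + d2[1] * bc + d2[2] * mv + d2[3] * nv
  }
  colnames(x) <- c("x", "y", "z")
  x
}

#' Random initial conformation
#'
#' Bond and dihedral angles of the initial chain are drawn uniformly
#' (bond angles 60-160 degrees, dihedrals -180..180) and converted to
#' Cartesian coordinates. Uses the current R RNG state.
#'
#' @param n Number of residues.
#' @param bond_length Virtual bond length, Angstrom (default 3.8).
#' @return `n x 3` coordinate matrix.
#' @export
random_chain <- function(n, bond_length = 3.8) {
  chain_from_angles(runif(n - 2, 60, 160), runif(max(n - 3, 0), -180, 180),
                    bond_length = bond_length)
}

#' One or more Metropolis sweeps
#'
#' A sweep perturbs every joint i = 1..N-1 in order: the downstream
#' segment is rotated by a bend and a torsion angle, each drawn uniformly
#' from `[-max_angle, +max_angle]` degrees, and the move is accepted with
#' probability `min(1, exp(-dU / kT))`. Bond lengths are exactly
#' preserved. Uses the current R RNG state.
#'
#' @param coords `n x 3` coordinate matrix.
#' @param potential A [potential_from_stats()] object.
#' @param kT Temperature (default 1).
#' @param n_sweeps Number of sweeps (default 1).
#' @param max_angle Perturbation amplitude in degrees (default 10).
#' @return List: `coords`, `accepted`, `trials`, `acceptance`,
#'   `acc_per_sweep`.
#' @export
mc_sweep <- function(coords, potential, kT = 1, n_sweeps = 1,
                     max_angle = 10) {
  pm <- .potential_matrices(potential)
  res <- mc_run_cpp(coords, pm$rbar, pm$sigma, kT, as.integer(n_sweeps),
                    burn_in_sweeps = 0L, contact_cutoff = 8,
                    max_angle_deg = max_angle, collect = FALSE)
  list(coords = res$coords, accepted = res$accepted, trials = res$trials,
       acceptance = res$acceptance, acc_per_sweep = res$acc_per_sweep)
}

#' Total chain energy under the pair potential (kT = 1 units)
#'
#' @param coords `n x 3` coordinate matrix.
#' @param potential A [potential_from_stats()] object.
#' @return Dimensionless energy (sum over pairs `|i - j| >= 2`).
#' @export
chain_energy <- function(coords, potential) {
  pm <- .potential_matrices(potential)
  chain_energy_cpp(coords, pm$rbar, pm$sigma)
}

#' Calibrate kT to a target acceptance ratio
#'
#' Bisection on log kT: each iteration runs `pilot_runs` pilot chains from
#' random initial conformations and measures the mean acceptance ratio
#' over the last quarter of their sweeps (the late window tracks the
#' equilibrated acceptance that production sampling realizes); iteration
#' stops when the measured ratio is within `tol` of `target`. Uses the
#' current R RNG state.
#'
#' @param potential A [potential_from_stats()] object.
#' @param target Target acceptance ratio in (0, 1) (default 0.5).
#' @param pilot_runs Pilot chains averaged per bisection step (default 20).
#' @param pilot_sweeps Sweeps per pilot run (default 400); acceptance is
#'   measured over the last quarter.
#' @param max_iter Maximum bisection steps (default 20).
#' @param tol Acceptance tolerance for early stop (default 0.01).
#' @param max_angle Move amplitude, degrees (default 10).
#' @param bond_length Virtual bond length (default 3.8).
#' @param kT_bracket Initial log-spaced bracket (default `c(1e-4, 1e4)`).
#' @return Calibrated kT with attributes `acceptance` (last pilot
#'   measurement) and `iterations`.
#' @export
calibrate_kT <- function(potential, target = 0.5, pilot_runs = 20,
                         pilot_sweeps = 400, max_iter = 20, tol = 0.01,
                         max_angle = 10, bond_length = 3.8,
                         kT_bracket = c(1e-4, 1e4)) {
  stopifnot(target > 0, target < 1)
  pm <- .potential_matrices(potential)
  measure <- function(kT) {
    mean(vapply(seq_len(pilot_runs), function(dummy) {
      x0 <- random_chain(potential$n, bond_length)
      res <- mc_run_cpp(x0, pm$rbar, pm$sigma, kT, as.integer(pilot_sweeps),
                        burn_in_sweeps = as.integer(3 * pilot_sweeps / 4),
                        contact_cutoff = 8, max_angle_deg = max_angle,
                        collect = FALSE)
      res$acceptance_post
    }, 0))
  }
  lo <- log(kT_bracket[1]); hi <- log(kT_bracket[2])
  kT <- exp((lo + hi) / 2)
  acc <- NA_real_
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    kT <- exp((lo + hi) / 2)
    acc <- measure(kT)
    if (abs(acc - target) <= tol) break
    if (acc < target) lo <- log(kT) else hi <- log(kT)
  }
  if (abs(acc - target) > 5 * tol) {
    # bisection collapsed toward a bracket endpoint without reaching the
    # target: the target acceptance is unreachable inside kT_bracket
    stop(sprintf(paste0("failed to bracket target acceptance %.2f within ",
                        "kT in [%.2g, %.2g]; last acceptance %.3f at ",
                        "kT=%.3g after %d pilot steps"),
                 target, kT_bracket[1], kT_bracket[2], acc, kT, it))
  }
  structure(kT, acceptance = acc, iterations = it)
}

#' Run the F-value Monte-Carlo simulation
#'
#' Per run: a random initial conformation is drawn, kT is calibrated to
#' the target acceptance ratio, `n_steps` sweeps are performed, the first
#' `burn_in` fraction is discarded and the contact indicator
#' (`CA-CA distance <= contact_cutoff`, `|i - j| >= 2`) is accumulated
#' every remaining sweep. Contact frequencies are averaged over runs.
#' Fully reproducible for a given `seed`.
#'
#' @param sequence One-letter amino-acid string (>= 10 residues), or NULL
#'   if `potential` is given.
#' @param stats A `distance_stats` object (ignored if `potential` given).
#' @param n_steps Sweeps per run (default 60000).
#' @param n_runs Number of independent runs (default 100).
#' @param seed Integer seed.
#' @param potential Optional precomputed [potential_from_stats()] object.
#' @param contact_cutoff Simulation-time contact radius, Angstrom
#'   (default 8).
#' @param burn_in Fraction of sweeps discarded (default 0.1).
#' @param target_acceptance Calibration target (default 0.5).
#' @param max_angle Move amplitude, degrees (default 10).
#' @param bond_length Virtual bond length, Angstrom (default 3.8).
#' @param calibrate Calibrate kT per run (default TRUE); if FALSE, `kT`
#'   is used as given.
#' @param kT Temperature when `calibrate = FALSE` (default 1).
#' @param pilot_runs,pilot_sweeps Calibration pilot sizes (see
#'   [calibrate_kT()]).
#' @return Object of class `contact_freq`: list with `g` (symmetric
#'   frequency matrix in `[0, 1]`), `n_samples`, per-run `kT`,
#'   `acceptance` (production, post burn-in) and the call parameters.
#' @export
run_simulation <- function(sequence = NULL, stats = NULL, n_steps = 60000,
                           n_runs = 100, seed = 1, potential = NULL,
                           contact_cutoff = 8, burn_in = 0.1,
                           target_acceptance = 0.5, max_angle = 10,
                           bond_length = 3.8, calibrate = TRUE, kT = 1,
                           pilot_runs = 20, pilot_sweeps = 400) {
  if (is.null(potential)) potential <- potential_from_stats(sequence, stats)
  n <- potential$n
  if (n < 10) stop("chain shorter than 10 residues")
  pm <- .potential_matrices(potential)
  set.seed(as.integer(seed))
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  g_sum <- matrix(0, n, n)
  samples <- 0
  kts <- accs <- numeric(n_runs)
  burn_sweeps <- as.integer(floor(n_steps * burn_in))
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    kt_r <- if (calibrate) {
      as.numeric(calibrate_kT(potential, target = target_acceptance,
                              pilot_runs = pilot_runs,
                              pilot_sweeps = pilot_sweeps,
                              max_angle = max_angle,
                              bond_length = bond_length))
    } else kT
    x0 <- random_chain(n, bond_length)
    res <- mc_run_cpp(x0, pm$rbar, pm$sigma, kt_r, as.integer(n_steps),
                      burn_in_sweeps = burn_sweeps,
                      contact_cutoff = contact_cutoff,
                      max_angle_deg = max_angle, collect = TRUE)
    g_sum <- g_sum + res$g_counts
    samples <- samples + res$n_samples
    kts[r] <- kt_r
    accs[r] <- res$acceptance_post
  }
  g <- g_sum / samples
  g[abs(row(g) - col(g)) < 2] <- NA
  structure(list(g = g, n_samples = samples, kT = kts, acceptance = accs,
                 contact_cutoff = contact_cutoff, n_steps = n_steps,
                 n_runs = n_runs, seed = seed,
                 sequence = potential$sequence),
            class = "contact_freq")
}

#' @export
print.contact_freq <- function(x, ...) {
  cat(sprintf(
    "<contact_freq> %d residues, %d samples, mean acceptance %.3f\n",
    nrow(x$g), x$n_samples, mean(x$acceptance)))
  invisible(x)
}

# pairs |i-j| >= 2 grouped by separation range M
.range_pairs <- function(n) {
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pr <- pr[pr[, 2] - pr[, 1] >= 2, , drop = FALSE]
  list(i = pr[, 1], j = pr[, 2],
       M = range_of_separation(pr[, 2] - pr[, 1]))
}

#' Range-wise normalization of contact frequencies
#'
#' Within each separation range M, contact frequencies are centred on the
#' range mean and divided by the range's population standard deviation
#' D_M, so that Q sums to zero over the pairs of each range. A range with
#' zero variance yields Q = 0 for all of its pairs.
#'
#' @param g Symmetric contact-frequency matrix (or a `contact_freq`
#'   object).
#' @return Symmetric matrix Q (NA for `|i - j| < 2`).
#' @export
normalize_contacts <- function(g) {
  if (inherits(g, "contact_freq")) g <- g$g
  n <- nrow(g)
  rp <- .range_pairs(n)
  v <- g[cbind(rp$i, rp$j)]
  Q <- matrix(NA_real_, n, n)
  for (m in unique(rp$M)) {
    sel <- rp$M == m
    x <- v[sel]
    mu <- mean(x)
    dm <- sqrt(mean((x - mu)^2))  # population SD
    q <- if (dm == 0) rep(0, length(x)) else (x - mu) / dm
    Q[cbind(rp$i[sel], rp$j[sel])] <- q
    Q[cbind(rp$j[sel], rp$i[sel])] <- q
  }
  Q
}

#' F profile and peak detection
#'
#' `F_i = sum_j Q(i, j)`; peaks are strict local maxima of F over a
#' `+/- window` neighbourhood, discarding peaks within
#' `terminal_exclusion` residues of either end (terminal F values are
#' inflated by the ends' flexibility in the simulation).
#'
#' @param Q Normalized contact matrix from [normalize_contacts()].
#' @param terminal_exclusion Residues excluded at each end (default 5).
#' @param window Half-width of the peak neighbourhood (default 2).
#' @return Object of class `f_profile`: list with `F` (per-residue
#'   values), `peaks` (residue indices), `terminal_exclusion`, `window`.
#' @export
f_profile <- function(Q, terminal_exclusion = 5, window = 2) {
  n <- nrow(Q)
  f <- rowSums(Q, na.rm = TRUE)
  peaks <- integer(0)
  eps <- 1e-9 * max(abs(f), 1)  # guard against summation-order ripple
  for (i in seq_len(n)) {
    if (i <= terminal_exclusion || i > n - terminal_exclusion) next
    nb <- setdiff(max(1, i - window):min(n, i + window), i)
    if (all(f[i] > f[nb] + eps)) peaks <- c(peaks, i)
  }
  structure(list(F = f, peaks = peaks,
                 terminal_exclusion = terminal_exclusion, window = window),
            class = "f_profile")
}

#' @export
print.f_profile <- function(x, ...) {
  cat(sprintf("<f_profile> %d residues, peaks at: %s\n", length(x$F),
              if (length(x$peaks)) paste(x$peaks, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Match two peak lists within a residue tolerance
#'
#' Greedy nearest matching: the globally closest admissible pair is
#' matched first, each peak used at most once.
#'
#' @param peaks_a,peaks_b Integer vectors of peak positions.
#' @param tolerance Maximum allowed |distance| (default 3).
#' @return List with `matched` (data frame `a`, `b`, `distance`),
#'   `unmatched_a`, `unmatched_b`.
#' @export
match_peaks <- function(peaks_a, peaks_b, tolerance = 3) {
  matched <- data.frame(a = integer(0), b = integer(0), distance = integer(0))
  ua <- peaks_a; ub <- peaks_b
  repeat {
    if (!length(ua) || !length(ub)) break
    d <- abs(outer(ua, ub, "-"))
    if (min(d) > tolerance) break
    idx <- which(d == min(d), arr.ind = TRUE)[1, ]
    matched <- rbind(matched,
                     data.frame(a = ua[idx[1]], b = ub[idx[2]],
                                distance = abs(ua[idx[1]] - ub[idx[2]])))
    ua <- ua[-idx[1]]; ub <- ub[-idx[2]]
  }
  list(matched = matched, unmatched_a = ua, unmatched_b = ub)
}
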