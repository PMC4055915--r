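# Inter-residue average distance statistics: mean and SD of the CA-CA
# distance per (residue-type pair, separation range M).

#' Separation range M of a sequence separation k
#'
#' Separations are binned as k = 1-8 (M = 1), 9-20 (M = 2), 21-30 (M = 3)
#' and width-10 bins thereafter (M >= 3 spans 10(M-1)+1 ... 10M).
#'
#' @param k Positive integer vector of sequence separations `|i - j|`.
#' @return Integer vector of range indices M.
#' @export
range_of_separation <- function(k) {
  k <- as.integer(k)
  if (any(is.na(k)) || any(k <= 0L)) stop("separation k must be positive")
  ifelse(k <= 8L, 1L, ifelse(k <= 20L, 2L, (k - 1L) %/% 10L + 1L))
}

#' Build inter-residue average distance statistics
#'
#' For every residue pair i < j in every chain, the CA-CA Euclidean
#' distance contributes to the key (aa_i, aa_j, M(j - i)). Mean and
#' population standard deviation are accumulated per key; the key is
#' symmetric in the two residue types. `"X"` residues are skipped (they
#' still occupy sequence positions, so separations stay faithful).
#'
#' @param structures List of [protein_structure()] objects.
#' @return Object of class `distance_stats` holding arrays `mean`, `sd`
#'   and `n` of dimension 20 x 20 x M_max, plus per-range fallback means.
#' @export
build_statistics <- function(structures) {
  if (inherits(structures, "protein_structure")) structures <- list(structures)
  if (!length(structures)) stop("need at least one structure")
  acc <- list()  # per structure: data frame of (a, b, M, d)
  for (s in structures) {
    n <- length(s$aa)
    if (n < 2) next
    idx <- match(s$aa, AA_ALPHABET)  # NA for X
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- pr[, 1]; j <- pr[, 2]
    ok <- !is.na(idx[i]) & !is.na(idx[j])
    i <- i[ok]; j <- j[ok]
    d <- sqrt(rowSums((s$ca[i, , drop = FALSE] - s$ca[j, , drop = FALSE])^2))
    acc[[length(acc) + 1L]] <- data.frame(
      a = pmin(idx[i], idx[j]), b = pmax(idx[i], idx[j]),
      M = range_of_separation(j - i), d = d)
  }
  if (!length(acc)) stop("no usable residue pairs in input structures")
  all <- do.call(rbind, acc)
  m_max <- max(all$M)
  dims <- c(20L, 20L, m_max)
  key <- (all$M - 1L) * 400L + (all$b - 1L) * 20L + all$a  # linear index
  n_arr <- array(0L, dims)
  mean_arr <- array(NA_real_, dims)
  sd_arr <- array(NA_real_, dims)
  # two-pass per key (numerically exact, no cancellation)
  tab_n <- tapply(all$d, key, length)
  tab_mean <- tapply(all$d, key, mean)
  tab_sd <- tapply(all$d, key, function(v) sqrt(mean((v - mean(v))^2)))
  kk <- as.integer(names(tab_n))
  # mirror (a, b) -> (b, a) within each range slab
  a_idx <- (kk - 1L) %% 20L + 1L
  b_idx <- ((kk - 1L) %/% 20L) %% 20L + 1L
  m_idx <- (kk - 1L) %/% 400L + 1L
  kk2 <- (m_idx - 1L) * 400L + (a_idx - 1L) * 20L + b_idx
  for (pair in list(kk, kk2)) {
    n_arr[pair] <- as.integer(tab_n)
    mean_arr[pair] <- tab_mean
    sd_arr[pair] <- tab_sd  # population SD
  }
  # fallbacks: mean/SD over every observed distance of the range (each
  # pair distance counted once)
  rng_n <- vapply(seq_len(m_max), function(m) sum(all$M == m), 0)
  rng_mean <- vapply(seq_len(m_max), function(m) {
    if (!any(all$M == m)) return(NA_real_)
    mean(all$d[all$M == m])
  }, 0)
  rng_sd <- vapply(seq_len(m_max), function(m) {
    if (!any(all$M == m)) return(NA_real_)
    v <- all$d[all$M == m]
    sqrt(mean((v - mean(v))^2))
  }, 0)
  dn <- list(AA_ALPHABET, AA_ALPHABET, NULL)
  dimnames(mean_arr) <- dimnames(sd_arr) <- dimnames(n_arr) <- dn
  structure(list(mean = mean_arr, sd = sd_arr, n = n_arr,
                 M_max = m_max, range_mean = rng_mean, range_sd = rng_sd,
                 range_n = rng_n),
            class = "distance_stats")
}

#' @export
print.distance_stats <- function(x, ...) {
  cat(sprintf("<distance_stats> %d ranges, %d / %d keys observed, %d pairs\n",
              x$M_max, sum(x$n > 0) %/% 2 + sum(sapply(seq_len(x$M_max),
                function(m) sum(diag(x$n[, , m]) > 0))) %/% 2,
              210L * x$M_max, as.integer(sum(x$n) / 2)))
  invisible(x)
}

#' Look up mean and SD for residue-type pairs
#'
#' Vectorized lookup with the documented fallback chain: an unobserved
#' (pair, M) key backs off to the all-pair mean of the same M; an
#' unobserved range backs off to the nearest observed M.
#'
#' @param stats A `distance_stats` object.
#' @param aa_a,aa_b One-letter codes (vectors, recycled).
#' @param M Separation range indices (vector).
#' @return Data frame with columns `mean`, `sd`, `n` (`n` = 0 marks a
#'   fallback value).
#' @export
lookup_stats <- function(stats, aa_a, aa_b, M) {
  k <- max(length(aa_a), length(aa_b), length(M))
  aa_a <- rep_len(aa_a, k); aa_b <- rep_len(aa_b, k); M <- rep_len(as.integer(M), k)
  ia <- match(aa_a, AA_ALPHABET); ib <- match(aa_b, AA_ALPHABET)
  if (any(is.na(ia)) || any(is.na(ib)))
    stop("unknown residue letter in lookup (X has no statistics)")
  observed <- which(!is.na(stats$range_mean))
  if (!length(observed)) stop("statistics table is empty")
  # clamp range to nearest observed M
  Mc <- vapply(M, function(m) observed[which.min(abs(observed - m))], 0L)
  lin <- (Mc - 1L) * 400L + (ib - 1L) * 20L + ia
  n <- stats$n[lin]
  mu <- stats$mean[lin]
  sg <- stats$sd[lin]
  miss <- n == 0L
  mu[miss] <- stats$range_mean[Mc[miss]]
  sg[miss] <- stats$range_sd[Mc[miss]]
  data.frame(mean = mu, sd = sg, n = as.integer(n))
}

#' Save / load a distance statistics table
#'
#' Plain TSV with columns `aa_a`, `aa_b`, `M`, `mean`, `sd`, `n` and a
#' `#`-prefixed header; round-trips to full double precision.
#'
#' @param stats A `distance_stats` object.
#' @param path File path.
#' @return [load_statistics()] returns the `distance_stats` object.
#' @export
save_statistics <- function(stats, path) {
  rows <- list()
  for (m in seq_len(stats$M_max)) {
    nm <- stats$n[, , m]
    idx <- which(nm > 0 & upper.tri(nm, diag = TRUE), arr.ind = TRUE)
    if (!nrow(idx)) next
    rows[[length(rows) + 1L]] <- data.frame(
      aa_a = AA_ALPHABET[idx[, 1]], aa_b = AA_ALPHABET[idx[, 2]], M = m,
      mean = stats$mean[, , m][idx], sd = stats$sd[, , m][idx],
      n = nm[idx])
  }
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# foldinit distance statistics v1",
               "# columns: aa_a aa_b M mean sd n"), con)
  writeLines(paste(df$aa_a, df$aa_b, df$M,
                   sprintf("%.17g", df$mean), sprintf("%.17g", df$sd),
                   df$n, sep = "\t"), con)
  invisible(path)
}

#' @rdname save_statistics
#' @export
load_statistics <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "# foldinit distance statistics"))
    stop("not a foldinit statistics file: ", path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 6L)
  if (length(bad))
    stop("malformed statistics row at line ",
         which(!startsWith(lines, "#") & nzchar(lines))[bad[1]])
  df <- data.frame(
    aa_a = vapply(parts, `[`, "", 1), aa_b = vapply(parts, `[`, "", 2),
    M = as.integer(vapply(parts, `[`, "", 3)),
    mean = as.numeric(vapply(parts, `[`, "", 4)),
    sd = as.numeric(vapply(parts, `[`, "", 5)),
    n = as.integer(vapply(parts, `[`, "", 6)))
  if (any(is.na(df$M)) || any(is.na(df$mean)) || any(is.na(df$n)))
    stop("malformed numeric field in statistics file ", path)
  m_max <- max(df$M)
  dims <- c(20L, 20L, m_max)
  mean_arr <- array(NA_real_, dims); sd_arr <- array(NA_real_, dims)
  n_arr <- array(0L, dims)
  ia <- match(df$aa_a, AA_ALPHABET); ib <- match(df$aa_b, AA_ALPHABET)
  for (r in seq_len(nrow(df))) {
    for (lin in unique(c((df$M[r] - 1L) * 400L + (ib[r] - 1L) * 20L + ia[r],
                         (df$M[r] - 1L) * 400L + (ia[r] - 1L) * 20L + ib[r]))) {
      mean_arr[lin] <- df$mean[r]; sd_arr[lin] <- df$sd[r]
      n_arr[lin] <- df$n[r]
    }
  }
  rng_mean <- rng_sd <- rep(NA_real_, m_max)
  rng_n <- numeric(m_max)
  for (m in seq_len(m_max)) {
    sel <- df$M == m
    if (!any(sel)) next
    w <- df$n[sel]
    rng_n[m] <- sum(w)
    rng_mean[m] <- sum(w * df$mean[sel]) / sum(w)
    # pooled second moment from per-key mean and population SD
    m2 <- sum(w * (df$sd[sel]^2 + df$mean[sel]^2)) / sum(w)
    rng_sd[m] <- sqrt(max(m2 - rng_mean[m]^2, 0))
  }
  dn <- list(AA_ALPHABET, AA_ALPHABET, NULL)
  dimnames(mean_arr) <- dimnames(sd_arr) <- dimnames(n_arr) <- dn
  structure(list(mean = mean_arr, sd = sd_arr, n = n_arr, M_max = m_max,
                 range_mean = rng_mean, range_sd = rng_sd, range_n = rng_n),
            class = "distance_stats")
}
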