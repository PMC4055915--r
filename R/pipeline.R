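# Pipeline orchestration: Phi-value comparison by secondary structure and
# the end-to-end report runner.

#' Average experimental Phi values per secondary-structure segment
#'
#' Computes the arithmetic mean Phi over the residues of each annotated
#' segment and calls the experimental folding segment: the alpha helix
#' with the higher mean Phi, plus every beta strand whose mean Phi
#' exceeds that of the lower-mean helix. Segments without any Phi value
#' are reported as missing and never called.
#'
#' @param phi Data frame with columns `residue` (number) and `phi`.
#' @param segments Data frame with columns `label`, `type`
#'   (`"helix"`/`"strand"`), `start`, `end` (residue numbers,
#'   non-overlapping).
#' @return Object of class `phi_comparison`: `segments` data frame with
#'   added `mean_phi`, `n_phi`, `in_folding_segment`.
#' @export
average_phi_by_ss <- function(phi, segments) {
  stopifnot(all(c("residue", "phi") %in% names(phi)),
            all(c("label", "type", "start", "end") %in% names(segments)))
  if (nrow(segments) > 1) {
    o <- order(segments$start)
    s <- segments[o, ]
    if (any(s$start[-1] <= s$end[-nrow(s)]))
      stop("secondary-structure segments overlap")
  }
  seg <- segments
  seg$mean_phi <- NA_real_
  seg$n_phi <- 0L
  for (r in seq_len(nrow(seg))) {
    v <- phi$phi[phi$residue >= seg$start[r] & phi$residue <= seg$end[r]]
    v <- v[!is.na(v)]
    seg$n_phi[r] <- length(v)
    if (length(v)) seg$mean_phi[r] <- mean(v)
  }
  seg$in_folding_segment <- FALSE
  helices <- which(seg$type == "helix" & !is.na(seg$mean_phi))
  if (length(helices) >= 2) {
    lower <- helices[which.min(seg$mean_phi[helices])]
    higher <- helices[which.max(seg$mean_phi[helices])]
    seg$in_folding_segment[higher] <- TRUE
    strands <- which(seg$type == "strand" & !is.na(seg$mean_phi))
    seg$in_folding_segment[strands] <-
      seg$mean_phi[strands] > seg$mean_phi[lower]
  }
  structure(list(segments = seg), class = "phi_comparison")
}

#' @export
print.phi_comparison <- function(x, ...) {
  s <- x$segments
  for (r in seq_len(nrow(s)))
    cat(sprintf("%-6s %-6s %3d-%3d  mean phi %s%s\n", s$label[r], s$type[r],
                s$start[r], s$end[r],
                ifelse(is.na(s$mean_phi[r]), "(missing)",
                       sprintf("%.3f", s$mean_phi[r])),
                ifelse(s$in_folding_segment[r], "  [folding segment]", "")))
  invisible(x)
}

#' Consistency of predicted regions with high-Phi segments
#'
#' A prediction is consistent when the midpoint of every called folding
#' segment lies inside some predicted compact region.
#'
#' @param regions [extract_regions()] output (source numbering columns
#'   used).
#' @param phi_comparison An [average_phi_by_ss()] result.
#' @return Logical scalar (NA if nothing was called).
#' @export
regions_consistent_with_phi <- function(regions, phi_comparison) {
  called <- phi_comparison$segments[phi_comparison$segments$in_folding_segment, ]
  if (!nrow(called)) return(NA)
  mids <- (called$start + called$end) / 2
  all(vapply(mids, function(m)
    any(m >= regions$start_src & m <= regions$end_src), TRUE))
}

.write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: distance statistics (built from structures or
#' loaded from a table), ADM construction and region extraction for the
#' query sequence, the F-value Monte-Carlo simulation, and optionally
#' SASA native contacts (if a structure with heavy atoms is supplied),
#' conservation plus conserved-contact profiling and peak matching (if an
#' alignment is supplied), family ADM-similarity analyses, and the
#' Phi-value comparison (if Phi data are supplied). All artifacts are
#' written as TSV under `out_dir`.
#'
#' @param config List with elements: one of `stats_path` /
#'   `structures` (list of [protein_structure()]); `sequence` (query,
#'   one-letter string); optional `structure` (heavy-atom
#'   [protein_structure()] of the query), `alignment` (an [alignment()]),
#'   `reference_id`, `phi` (data frame residue/phi), `segments`
#'   (secondary structure data frame); `seed`; optional parameter
#'   overrides `contact_cutoff`, `eta_threshold`, `min_len`, `n_steps`,
#'   `n_runs`, `mc_contact_cutoff`, `sasa_threshold`, `bandwidth`.
#' @param out_dir Output directory (created if needed).
#' @return Invisible list of the in-memory results (`stats`, `adm`,
#'   `regions`, `contact_freq`, `f_profile`, and the optional stages).
#' @export
run_all <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  getpar <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  seed <- getpar("seed", 1L)
  res <- list()

  stats <- if (!is.null(config[["stats_path"]])) load_statistics(config[["stats_path"]])
  else if (!is.null(config[["structures"]])) build_statistics(config[["structures"]])
  else stop("config needs 'stats_path' or 'structures'")
  res$stats <- stats
  save_statistics(stats, p("statistics.tsv"))

  sequence <- config[["sequence"]]
  if (is.null(sequence)) stop("config needs 'sequence'")
  adm <- build_adm(sequence, stats,
                   contact_cutoff = getpar("contact_cutoff", 13))
  regions <- extract_regions(adm,
                             eta_threshold = getpar("eta_threshold", 0.03),
                             min_len = getpar("min_len", 10))
  res$adm <- adm
  res$regions <- regions
  .write_tsv(regions, p("regions.tsv"),
             comment = sprintf("compact regions, cutoff %.1f A, seed %d",
                               adm$contact_cutoff, seed))

  cf <- run_simulation(sequence, stats,
                       n_steps = getpar("n_steps", 60000),
                       n_runs = getpar("n_runs", 100), seed = seed,
                       contact_cutoff = getpar("mc_contact_cutoff", 8),
                       calibrate = getpar("calibrate", TRUE),
                       kT = getpar("kT", 1),
                       pilot_runs = getpar("pilot_runs", 20),
                       pilot_sweeps = getpar("pilot_sweeps", 400))
  Q <- normalize_contacts(cf)
  fp <- f_profile(Q)
  res$contact_freq <- cf
  res$f_profile <- fp
  .write_tsv(data.frame(residue = seq_along(fp$F), F = fp$F,
                        is_peak = seq_along(fp$F) %in% fp$peaks),
             p("f_profile.tsv"),
             comment = sprintf("F profile, %d runs x %d sweeps, seed %d",
                               cf$n_runs, cf$n_steps, seed))

  if (!is.null(config[["structure"]])) {
    nseq <- structure_sequence(config[["structure"]])
    if (nchar(nseq) != nchar(sequence))
      stop(sprintf("sequence (%d residues) and structure (%d residues) disagree",
                   nchar(sequence), nchar(nseq)))
    contacts <- sidechain_contacts(config[["structure"]],
                                   threshold = getpar("sasa_threshold", 27))
    res$contacts <- contacts
    .write_tsv(contacts$pairs, p("contacts.tsv"),
               comment = sprintf("hydrophobic side-chain contacts, %.0f A^2",
                                 contacts$threshold))
  }

  if (!is.null(config[["alignment"]])) {
    aln <- config[["alignment"]]
    refid <- getpar("reference_id", aln$ids[1])
    prof <- hydrophobic_conservation(aln, refid)
    res$conservation <- prof
    .write_tsv(prof$sites, p("conservation.tsv"),
               comment = paste("hydrophobic conservation vs", refid))
    if (!is.null(res$contacts)) {
      flags <- map_sites_to_reference(prof)
      counts <- conserved_contact_profile(res$contacts, flags)
      sm <- smooth_profile(counts, bandwidth = getpar("bandwidth", 2))
      res$conserved_profile <- list(counts = counts, smoothed = sm)
      .write_tsv(data.frame(residue = seq_along(counts), count = counts,
                            smoothed = sm$smoothed,
                            is_peak = seq_along(counts) %in% sm$peaks),
                 p("conserved_contacts.tsv"),
                 comment = "conserved hydrophobic contact profile")
      res$peak_match <- match_peaks(fp$peaks, sm$peaks, tolerance = 3)
    }
    # family ADM analysis
    assignments <- lapply(seq_along(aln$ids), function(i) {
      s <- gsub("-", "", aln$seqs[i])
      if (nchar(s) < 20) return(NULL)
      a <- build_adm(s, stats, contact_cutoff = getpar("contact_cutoff", 13))
      r <- extract_regions(a, eta_threshold = getpar("eta_threshold", 0.03),
                           min_len = getpar("min_len", 10))
      regions_to_assignment(aln$seqs[i], r)
    })
    names(assignments) <- aln$ids
    keep <- !vapply(assignments, is.null, TRUE)
    assignments <- assignments[keep]
    if (sum(keep) >= 2) {
      sim <- similarity_matrix(assignments)
      res$similarity <- sim
      .write_tsv(as.data.frame(sim), p("similarity.tsv"),
                 comment = "pairwise ADM similarity (%)")
      incl <- site_inclusion_profile(assignments)
      .write_tsv(data.frame(site = seq_along(incl), inclusion = incl),
                 p("inclusion.tsv"), comment = "per-site region inclusion")
      res$inclusion <- incl
      if (refid %in% names(assignments)) {
        curve <- similarity_identity_curve(aln, assignments, refid)
        res$identity_curve <- curve
        if (!is.null(curve))
          .write_tsv(curve, p("similarity_identity.tsv"),
                     comment = "similarity vs identity lower limit")
      }
      if (sum(keep) >= 3) {
        tree <- nj_tree(sim)
        ape::write.tree(tree, p("family.nwk"))
        res$tree <- tree
      }
    }
  }

  if (!is.null(config[["phi"]]) && !is.null(config[["segments"]])) {
    cmp <- average_phi_by_ss(config[["phi"]], config[["segments"]])
    res$phi_comparison <- cmp
    res$phi_consistent <- regions_consistent_with_phi(regions, cmp)
    .write_tsv(cmp$segments, p("phi_by_ss.tsv"),
               comment = paste("mean phi per secondary structure;",
                               "consistent:", res$phi_consistent))
  }
  invisible(res)
}
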