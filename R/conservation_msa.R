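# Evolutionarily conserved hydrophobic residues from a multiple alignment:
# the >99 % rule with hydrophobic-interchange tolerance.

#' Hydrophobic conservation profile of an alignment
#'
#' A site is *eligible* when no record has a gap there. At eligible sites
#' the hydrophobic-conservation fraction is the share of records whose
#' residue belongs to the hydrophobic set {A, M, W, L, F, V, I, Y}
#' (mutation to another member of the set still counts as conserved). A
#' site is flagged as a conserved hydrophobic residue when it is eligible,
#' the reference residue is hydrophobic, and the fraction is strictly
#' greater than 0.99.
#'
#' @param aln An [alignment()].
#' @param reference_id Identifier of the reference record (must be
#'   present).
#' @param threshold Strict lower bound on the fraction (default 0.99).
#' @return Object of class `conservation_profile`: data frame `sites`
#'   with per-alignment-site columns `site`, `reference_residue`,
#'   `reference_position` (ungapped residue number in the reference, NA
#'   at reference gaps), `eligible`, `fraction`, `conserved`; plus field
#'   `reference_id`.
#' @export
hydrophobic_conservation <- function(aln, reference_id, threshold = 0.99) {
  ridx <- match(reference_id, aln$ids)
  if (is.na(ridx)) stop("reference '", reference_id, "' not in alignment")
  m <- alignment_matrix(aln)
  eligible <- colSums(m == "-") == 0L
  frac <- colMeans(matrix(m %in% HYDROPHOBIC_SET, nrow(m), ncol(m)))
  refres <- m[ridx, ]
  refpos <- ifelse(refres == "-", NA_integer_, cumsum(refres != "-"))
  conserved <- eligible & refres %in% HYDROPHOBIC_SET & frac > threshold
  sites <- data.frame(site = seq_len(aln$length),
                      reference_residue = refres,
                      reference_position = refpos,
                      eligible = eligible,
                      fraction = ifelse(eligible, frac, NA_real_),
                      conserved = conserved)
  structure(list(sites = sites, reference_id = reference_id,
                 threshold = threshold),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf(
    "<conservation_profile> %d sites, %d eligible, %d conserved hydrophobic\n",
    nrow(x$sites), sum(x$sites$eligible), sum(x$sites$conserved)))
  invisible(x)
}

#' Project conserved-site flags onto the ungapped reference sequence
#'
#' @param profile A [hydrophobic_conservation()] result.
#' @return Logical vector indexed by reference residue number (sites
#'   gapped in the reference are dropped).
#' @export
map_sites_to_reference <- function(profile) {
  s <- profile$sites
  keep <- !is.na(s$reference_position)
  flags <- logical(sum(keep))
  flags[s$reference_position[keep]] <- s$conserved[keep]
  flags
}
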