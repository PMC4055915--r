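# Structure and sequence I/O: fixed-column PDB, FASTA, aligned FASTA.

AA_THREE_TO_ONE <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
  GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
  MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
  SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y")

AA_ONE_TO_THREE <- setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)

#' Construct a protein structure object
#'
#' A light container for one chain: per-residue one-letter codes, original
#' (PDB) residue numbers, C-alpha coordinates and, optionally, all heavy
#' atoms. Internal residue positions are 1-based and contiguous; the source
#' numbering is kept so regions can be reported in PDB numbers.
#'
#' @param chain_id Single-character chain identifier.
#' @param aa Character vector of one-letter residue codes (non-standard
#'   residues as `"X"`).
#' @param ca Numeric matrix, one row per residue, columns x/y/z in Angstrom.
#' @param residue_number Integer vector of source-file residue numbers
#'   (default `seq_along(aa)`).
#' @param atoms Optional data frame of heavy atoms with columns
#'   `residue_index` (1-based internal position), `atom` (PDB atom name),
#'   `element`, `x`, `y`, `z`.
#' @return An object of class `protein_structure`.
#' @export
protein_structure <- function(chain_id, aa, ca,
                              residue_number = seq_along(aa),
                              atoms = NULL) {
  ca <- as.matrix(ca)
  stopifnot(is.character(aa), nrow(ca) == length(aa), ncol(ca) == 3,
            length(residue_number) == length(aa))
  if (!all(aa %in% c(AA_ALPHABET, "X")))
    stop("amino-acid codes must be the 20 standard letters or 'X'")
  dimnames(ca) <- list(NULL, c("x", "y", "z"))
  structure(list(chain_id = chain_id, aa = aa, ca = ca,
                 residue_number = as.integer(residue_number),
                 atoms = atoms),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure> chain %s, %d residues%s\n",
              x$chain_id, length(x$aa),
              if (is.null(x$atoms)) " (CA only)"
              else sprintf(", %d heavy atoms", nrow(x$atoms))))
  invisible(x)
}

#' Sequence of a protein structure
#'
#' @param structure A [protein_structure()].
#' @return Single one-letter string.
#' @export
structure_sequence <- function(structure) {
  paste(structure$aa, collapse = "")
}

#' Read one chain from a PDB file
#'
#' Parses fixed-column `ATOM` records (no `HETATM`) of the first model.
#' Alternate locations are resolved to the highest occupancy. Residues
#' without a resolved C-alpha are skipped with a warning. Non-standard
#' residue names map to `"X"`.
#'
#' @param path Path to a PDB-format text file.
#' @param chain Chain identifier to extract (default: first chain seen).
#' @return A [protein_structure()] with all heavy atoms attached.
#' @export
read_pdb <- function(path, chain = NULL) {
  lines <- readLines(path, warn = FALSE)
  # first model only
  i_end <- grep("^ENDMDL", lines)
  if (length(i_end)) lines <- lines[seq_len(i_end[1] - 1L)]
  atom <- lines[startsWith(lines, "ATOM  ")]
  if (!length(atom)) stop("no ATOM records in ", path)
  fld <- function(a, b) trimws(substring(atom, a, b))
  chains <- substring(atom, 22, 22)
  if (is.null(chain)) chain <- chains[1]
  keep <- chains == chain
  if (!any(keep)) stop("chain '", chain, "' not found in ", path)
  atom <- atom[keep]
  df <- data.frame(
    name = fld(13, 16), altloc = substring(atom, 17, 17),
    resname = fld(18, 20), resseq = fld(23, 26), icode = fld(27, 27),
    x = as.numeric(fld(31, 38)), y = as.numeric(fld(39, 46)),
    z = as.numeric(fld(47, 54)),
    occ = suppressWarnings(as.numeric(fld(55, 60))),
    element = fld(77, 78), stringsAsFactors = FALSE)
  df$occ[is.na(df$occ)] <- 1
  if (!nzchar(df$element[1]))  # old files without element column
    df$element <- substring(gsub("[0-9]", "", df$name), 1, 1)
  df$reskey <- paste(df$resseq, df$icode, sep = "|")
  key_order <- unique(df$reskey)  # original chain order
  # altLoc: keep highest occupancy per (residue, atom name)
  df <- df[order(-df$occ), ]
  df <- df[!duplicated(paste(df$reskey, df$name)), ]
  df <- df[order(match(df$reskey, key_order)), ]

  reskeys <- key_order
  has_ca <- vapply(reskeys, function(k)
    any(df$name[df$reskey == k] == "CA"), logical(1))
  if (any(!has_ca))
    warning(sum(!has_ca), " residue(s) without CA skipped in ", path)
  reskeys <- reskeys[has_ca]
  df <- df[df$reskey %in% reskeys, ]

  resname <- vapply(reskeys, function(k) df$resname[df$reskey == k][1], "")
  aa <- unname(AA_THREE_TO_ONE[resname])
  aa[is.na(aa)] <- "X"
  ca_rows <- df[df$name == "CA", ]
  ca <- as.matrix(ca_rows[match(reskeys, ca_rows$reskey), c("x", "y", "z")])
  resno <- as.integer(sub("\\|.*$", "", reskeys))
  atoms <- data.frame(residue_index = match(df$reskey, reskeys),
                      atom = df$name, element = df$element,
                      x = df$x, y = df$y, z = df$z,
                      stringsAsFactors = FALSE)
  protein_structure(chain, aa, ca, residue_number = resno, atoms = atoms)
}

#' Write a protein structure as a PDB file
#'
#' Emits fixed-column `ATOM` records. If the structure carries heavy atoms
#' they are all written; otherwise one CA record per residue.
#'
#' @param structure A [protein_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  res3 <- function(a) ifelse(a == "X", "UNK", AA_ONE_TO_THREE[a])
  lines <- character(0)
  serial <- 0L
  emit <- function(name, elem, resi, xyz) {
    serial <<- serial + 1L
    aa <- structure$aa[resi]
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
            res3(aa), structure$chain_id,
            structure$residue_number[resi],
            xyz[1], xyz[2], xyz[3], 1, 0, elem)
  }
  if (is.null(structure$atoms)) {
    for (i in seq_along(structure$aa))
      lines <- c(lines, emit("CA", "C", i, structure$ca[i, ]))
  } else {
    at <- structure$atoms
    for (k in seq_len(nrow(at)))
      lines <- c(lines, emit(at$atom[k], at$element[k], at$residue_index[k],
                             c(at$x[k], at$y[k], at$z[k])))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path Path to FASTA text. Sequences are uppercased.
#' @return Named character vector (identifier -> sequence).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path)
  hdr <- grep("^>", lines)
  if (!length(hdr) || hdr[1] != 1) stop("not FASTA format: ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  to <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1L > to[i]) stop("empty sequence for '", ids[i], "'")
    toupper(paste(lines[(hdr[i] + 1L):to[i]], collapse = ""))
  }, "")
  setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a multiple sequence alignment object
#'
#' @param seqs Named character vector of aligned sequences (gap `"-"`),
#'   all of identical length; at least 2 records.
#' @return Object of class `alignment` with fields `ids`, `seqs`, `length`.
#' @export
alignment <- function(seqs) {
  if (length(seqs) < 2) stop("an alignment needs at least 2 records")
  len <- unique(nchar(seqs))
  if (length(len) != 1)
    stop("ragged alignment: sequence lengths ", paste(nchar(seqs), collapse = ", "))
  structure(list(ids = names(seqs), seqs = unname(toupper(seqs)),
                 length = len),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d records x %d sites\n", length(x$ids), x$length))
  invisible(x)
}

#' Alignment as a character matrix
#'
#' @param aln An [alignment()].
#' @return Character matrix, records x sites, rownames = identifiers.
#' @export
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- aln$ids
  m
}

#' Read / write an aligned FASTA file
#'
#' @param path Path to aligned FASTA text.
#' @return [read_alignment()]: an [alignment()].
#' @export
read_alignment <- function(path) alignment(read_fasta(path))

#' @param aln An [alignment()].
#' @rdname read_alignment
#' @export
write_alignment <- function(aln, path) {
  write_fasta(setNames(aln$seqs, aln$ids), path)
}
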