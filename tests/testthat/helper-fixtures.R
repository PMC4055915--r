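# Shared fixtures, built in code. Expensive objects are cached per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small synthetic statistics set: six compact 60-mers
small_stats <- function() {
  cached("small_stats", {
    build_statistics(lapply(1:6, function(s) make_compact_chain(60, s)))
  })
}

# deterministic 50-mer test sequence over a mixed alphabet
test_sequence_50 <- function() {
  cached("seq50", {
    set.seed(11)
    paste(sample(c(hydrophobic_residues(), "S", "T", "E", "K", "G", "D"),
                 50, replace = TRUE), collapse = "")
  })
}

# one fixed-column PDB ATOM line
pdb_line <- function(serial, name, altloc, resname, chain, resseq, xyz,
                     occ = 1, element = "C", icode = " ") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          altloc, resname, chain, resseq, icode,
          xyz[1], xyz[2], xyz[3], occ, 0, element)
}

# 3-residue toy PDB (ALA-GLY-LEU), CA only
toy_pdb <- function(path) {
  writeLines(c(
    pdb_line(1, "CA", " ", "ALA", "A", 1, c(0, 0, 0)),
    pdb_line(2, "CA", " ", "GLY", "A", 2, c(3.8, 0, 0)),
    pdb_line(3, "CA", " ", "LEU", "A", 3, c(7.6, 0, 0)),
    "END"), path)
  path
}

# packed three-residue heavy-atom fixture: two "leucine-like" residues
# (CA + CB) whose CB atoms sit at carbon contact distance (3.4 A); each
# CA sits on the far side of its own CB so it does not shadow the
# CB-CB contact interface
packed_fixture <- function() {
  ca <- rbind(c(-1.5, 0, 0), c(30, 30, 30), c(4.9, 0, 0))
  atoms <- data.frame(
    residue_index = c(1L, 1L, 2L, 3L, 3L),
    atom = c("CA", "CB", "CA", "CA", "CB"),
    element = "C",
    x = c(-1.5, 0, 30, 4.9, 3.4),
    y = c(0, 0, 30, 0, 0),
    z = c(0, 0, 30, 0, 0))
  protein_structure("A", c("L", "G", "L"), ca, atoms = atoms)
}
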