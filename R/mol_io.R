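#' Construct a molecule graph
#'
#' A light-weight molecular graph: atoms carry an element symbol and optional
#' Cartesian coordinates (Angstrom); bonds carry the two 1-based atom
#' indices, a bond order in \{1, 2, 3\} and an aromatic flag. This is the
#' structure consumed by all descriptor calculations.
#'
#' @param name text identifier of the molecule (MOL title line)
#' @param atoms data frame with columns `element` (character) and,
#'   optionally, `x`, `y`, `z` (numeric, Angstrom)
#' @param bonds data frame with columns `i`, `j` (1-based atom indices),
#'   `order` (integer in 1..3) and `aromatic` (logical)
#' @return an object of class `molecule_graph`
#' @export
molecule_graph <- function(name, atoms, bonds) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  if (nrow(atoms) < 1) stop("a molecule must have at least one atom")
  if (!"element" %in% names(atoms)) stop("`atoms` needs an `element` column")
  if (nrow(bonds) > 0) {
    for (col in c("i", "j", "order", "aromatic")) {
      if (!col %in% names(bonds)) stop("`bonds` needs a `", col, "` column")
    }
    idx <- c(bonds$i, bonds$j)
    if (any(idx < 1 | idx > nrow(atoms))) {
      stop("bond endpoint out of range (", nrow(atoms), " atoms)")
    }
    if (any(bonds$i == bonds$j)) stop("self-bond (i == j) is not allowed")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bond between the same atom pair")
    if (any(!bonds$order %in% 1:3)) stop("bond order must be 1, 2 or 3")
  } else {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0),
                        aromatic = logical(0))
  }
  structure(list(name = name, atoms = atoms, bonds = bonds),
            class = "molecule_graph")
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat("<molecule_graph> '", x$name, "': ", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

has_coordinates <- function(mol) {
  all(c("x", "y", "z") %in% names(mol$atoms)) &&
    !anyNA(mol$atoms[c("x", "y", "z")])
}

# Parse one V2000 connection-table block given as a character vector of
# lines. `where` labels error messages ("file 'x'" / "record 3").
parse_molblock <- function(lines, where) {
  if (length(lines) < 4) {
    stop("truncated MOL block in ", where, ": fewer than 4 header lines")
  }
  counts <- lines[4]
  if (grepl("V3000", counts, fixed = TRUE)) {
    stop("V3000 connection tables are not supported (", where,
         "); please supply a V2000 MOL file")
  }
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 0 || nbonds < 0) {
    stop("malformed counts line (line 4) in ", where, ": '", counts, "'")
  }
  if (natoms < 1) {
    stop("counts line in ", where, " declares ", natoms, " atoms; need >= 1")
  }
  atom_lines <- lines[4 + seq_len(natoms)]
  bond_lines <- lines[4 + natoms + seq_len(nbonds)]
  if (anyNA(atom_lines) || anyNA(bond_lines)) {
    stop("truncated connection table in ", where, ": counts line declares ",
         natoms, " atoms and ", nbonds, " bonds but the block is shorter")
  }
  num_field <- function(txt, lab, ln) {
    v <- suppressWarnings(as.numeric(txt))
    if (anyNA(v)) {
      stop("cannot parse ", lab, " on line ", ln[which(is.na(v))[1]],
           " of ", where)
    }
    v
  }
  x <- num_field(substr(atom_lines, 1, 10), "x coordinate", 4 + seq_len(natoms))
  y <- num_field(substr(atom_lines, 11, 20), "y coordinate", 4 + seq_len(natoms))
  z <- num_field(substr(atom_lines, 21, 30), "z coordinate", 4 + seq_len(natoms))
  element <- trimws(substr(atom_lines, 32, 34))
  if (any(!nzchar(element))) {
    stop("missing element symbol in atom block of ", where)
  }
  atoms <- data.frame(element = element, x = x, y = y, z = z,
                      stringsAsFactors = FALSE)
  if (nbonds > 0) {
    bi <- as.integer(num_field(substr(bond_lines, 1, 3), "bond atom 1",
                               4 + natoms + seq_len(nbonds)))
    bj <- as.integer(num_field(substr(bond_lines, 4, 6), "bond atom 2",
                               4 + natoms + seq_len(nbonds)))
    bt <- as.integer(num_field(substr(bond_lines, 7, 9), "bond type",
                               4 + natoms + seq_len(nbonds)))
    if (any(!bt %in% c(1L, 2L, 3L, 4L))) {
      stop("unsupported bond type in ", where,
           " (only 1, 2, 3 and aromatic 4 are handled)")
    }
    aromatic <- bt == 4L
    order <- ifelse(aromatic, 1L, bt)
    bonds <- data.frame(i = bi, j = bj, order = order, aromatic = aromatic)
  } else {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0),
                        aromatic = logical(0))
  }
  molecule_graph(name = trimws(lines[1]), atoms = atoms, bonds = bonds)
}

split_sdf_records <- function(lines) {
  delim <- which(trimws(lines) == "$$$$")
  starts <- c(1L, delim + 1L)
  ends <- c(delim - 1L, length(lines))
  recs <- Map(function(s, e) if (s <= e) lines[s:e] else character(0),
              starts, ends)
  # drop empty trailing chunks (file ending in "$$$$" plus blank lines)
  recs[vapply(recs, function(r) any(nzchar(trimws(r))), logical(1))]
}

#' Read a single molecule from a MOL (or single-record SDF) file
#'
#' Parses a V2000 connection table: title line, counts line, atom block
#' (coordinates + element symbol) and bond block (indices, order, aromatic
#' flag 4). V3000 files are rejected with an explicit error, as is any block
#' whose atom/bond blocks are shorter than the counts line declares.
#'
#' @param path path to a MOL or SDF file
#' @return a [molecule_graph]
#' @examples
#' mol_file <- tempfile(fileext = ".mol")
#' writeLines(c("water", "", "",
#'   "  3  2  0  0  0  0  0  0  0  0999 V2000",
#'   "    0.0000    0.0000    0.0000 O   0  0",
#'   "    0.9572    0.0000    0.0000 H   0  0",
#'   "   -0.2400    0.9266    0.0000 H   0  0",
#'   "  1  2  1  0", "  1  3  1  0", "M  END"), mol_file)
#' read_mol(mol_file)
#' @export
read_mol <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- split_sdf_records(lines)
  if (length(recs) == 0) stop("empty MOL file: ", path)
  parse_molblock(recs[[1]], paste0("file '", path, "'"))
}

#' Read all molecules from an SDF file
#'
#' Records are delimited by `$$$$`; each record's connection table is parsed
#' as in [read_mol()] and named from its title line. Record order is
#' preserved.
#'
#' @param path path to an SDF file
#' @return a list of [molecule_graph] objects, one per record
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- split_sdf_records(lines)
  if (length(recs) == 0) stop("empty SDF file (no records): ", path)
  lapply(seq_along(recs), function(k) {
    parse_molblock(recs[[k]], paste0("record ", k, " of '", path, "'"))
  })
}
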