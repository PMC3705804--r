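#' Element constant tables
#'
#' Atomic masses (IUPAC 2021 standard atomic weights, u) and van der Waals
#' radii (Bondi set, Angstrom) for the elements commonly found in drug-like
#' molecules, loaded from the plain-text tables packaged with the module.
#' Pinning these constants keeps descriptor values reproducible across
#' installations.
#'
#' @return a named numeric vector keyed by element symbol
#' @export
atomic_masses <- function() {
  path <- system.file("extdata", "atomic_masses.csv", package = "qsardpp",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$mass, df$element)
}

#' @rdname atomic_masses
#' @export
vdw_radii <- function() {
  path <- system.file("extdata", "vdw_radii.csv", package = "qsardpp",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$radius, df$element)
}

# default valences used when materializing implicit hydrogens; multi-valent
# elements list all allowed states (smallest state >= used valence wins)
default_valences <- list(
  H = 1, C = 4, N = 3, O = 2, F = 1, Cl = 1, Br = 1, I = 1,
  S = c(2, 4, 6), P = c(3, 5), B = 3, Si = 4
)

# per-atom valence consumed by explicit bonds; aromatic bonds count 1.5
used_valence <- function(mol) {
  n <- nrow(mol$atoms)
  used <- numeric(n)
  if (nrow(mol$bonds) > 0) {
    w <- ifelse(mol$bonds$aromatic, 1.5, mol$bonds$order)
    for (b in seq_len(nrow(mol$bonds))) {
      used[mol$bonds$i[b]] <- used[mol$bonds$i[b]] + w[b]
      used[mol$bonds$j[b]] <- used[mol$bonds$j[b]] + w[b]
    }
  }
  used
}

# implicit hydrogen count per heavy atom by standard valence rules; atoms of
# elements without a valence rule get no implicit hydrogens
implicit_hydrogens <- function(mol) {
  used <- ceiling(used_valence(mol) - 1e-9)
  vapply(seq_len(nrow(mol$atoms)), function(a) {
    el <- mol$atoms$element[a]
    val <- default_valences[[el]]
    if (is.null(val)) return(0)
    target <- val[val >= used[a]][1]
    if (is.na(target)) return(0)
    as.numeric(target - used[a])
  }, numeric(1))
}

#' Element counts of a molecule
#'
#' Counts atoms per element, materializing implicit hydrogens by standard
#' valence rules (C 4, N 3, O 2, S 2/4/6, P 3/5, halogens 1) so that
#' mass-fraction descriptors are meaningful on hydrogen-suppressed
#' connection tables.
#'
#' @param mol a [molecule_graph]
#' @param implicit_h add implicit hydrogens before counting (default TRUE)
#' @return named numeric vector of atom counts per element symbol
#' @export
element_counts <- function(mol, implicit_h = TRUE) {
  counts <- table(mol$atoms$element)
  counts <- stats::setNames(as.numeric(counts), names(counts))
  if (implicit_h) {
    nh <- sum(implicit_hydrogens(mol))
    if (nh > 0) {
      counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0) + nh
    }
  }
  counts
}

#' Elemental-analysis mass fraction
#'
#' `mass_fraction()` returns the percent-by-mass contribution of one element
#' to the molecular mass (implicit hydrogens included); `o_composition()` is
#' the oxygen special case used in the descriptor registry ("O Composition").
#'
#' @param mol a [molecule_graph]
#' @param element element symbol to report, e.g. `"O"`
#' @param masses named mass table as returned by [atomic_masses()]
#' @return mass percentage in `[0, 100]`
#' @examples
#' # ethanol, hydrogen-suppressed: C-C-O
#' eth <- molecule_graph("ethanol",
#'   atoms = data.frame(element = c("C", "C", "O")),
#'   bonds = data.frame(i = c(1, 2), j = c(2, 3), order = 1, aromatic = FALSE))
#' o_composition(eth)  # ~34.73
#' @export
mass_fraction <- function(mol, element, masses = atomic_masses()) {
  counts <- element_counts(mol)
  unknown <- setdiff(names(counts), names(masses))
  if (length(unknown)) {
    stop("element(s) missing from the mass table: ",
         paste(unknown, collapse = ", "))
  }
  total <- sum(counts * masses[names(counts)])
  part <- if (element %in% names(counts)) {
    counts[[element]] * masses[[element]]
  } else 0
  100 * part / total
}

#' @rdname mass_fraction
#' @export
o_composition <- function(mol, masses = atomic_masses()) {
  mass_fraction(mol, "O", masses)
}

#' Ring bond count
#'
#' Number of bonds that belong to at least one cycle of the molecular graph
#' (equivalently, bonds that are not bridges). Disconnected graphs are
#' accepted.
#'
#' @param mol a [molecule_graph]
#' @return nonnegative integer
#' @export
ring_bond_count <- function(mol) {
  sum(ring_bond_membership(mol))
}

#' Aliphatic ring count
#'
#' Number of rings in the smallest set of smallest rings ([sssr()]) whose
#' bonds are not all aromatic. Aromatic flags are taken from the input when
#' present (MOL bond type 4); otherwise six-membered rings with strictly
#' alternating single/double bonds are perceived as aromatic.
#'
#' @param mol a [molecule_graph]
#' @return nonnegative integer
#' @export
aliphatic_ring_count <- function(mol) {
  mol <- perceive_aromaticity(mol)
  rings <- sssr(mol)
  if (length(rings) == 0) return(0L)
  sum(vapply(rings, function(r) !all(mol$bonds$aromatic[r]), logical(1)))
}

#' Projection-area settings
#'
#' Controls the numerical evaluation of the minimal/maximal projection
#' areas: the van der Waals radii used for the atomic disks, the number of
#' projection directions sampled on the sphere, and the edge length of the
#' area-integration grid cell.
#'
#' Directions come from a deterministic spiral lattice whose first entries
#' are the two poles and the equator, so axis-aligned extremal views of a
#' molecule laid out along the z axis are sampled exactly; the lattice has
#' the prefix property (the first n directions are a subset of the first
#' 2n), so raising `n_orientations` can only tighten the min/max bracket.
#'
#' @param radii named van der Waals radius table (Angstrom)
#' @param n_orientations number of sampled projection directions (>= 1)
#' @param grid_resolution integration cell edge (Angstrom, > 0)
#' @return a `projection_settings` list
#' @export
projection_settings <- function(radii = vdw_radii(), n_orientations = 200L,
                                grid_resolution = 0.05) {
  stopifnot(all(radii > 0), n_orientations >= 1, grid_resolution > 0)
  structure(list(radii = radii, n_orientations = as.integer(n_orientations),
                 grid_resolution = grid_resolution),
            class = "projection_settings")
}

# Deterministic direction lattice with the prefix property: the first n
# directions are always a subset of the first 2n, so enlarging
# n_orientations can only tighten the (min, max) bracket. The two poles and
# the equator lead; the tail is a golden-angle spiral whose latitude follows
# the base-2 van der Corput sequence (dense on the sphere, never repeating).
projection_directions <- function(n) {
  van_der_corput <- function(k) {
    v <- 0; base <- 0.5
    while (k > 0) {
      v <- v + base * (k %% 2)
      k <- k %/% 2
      base <- base / 2
    }
    v
  }
  dirs <- matrix(0, n, 3)
  fixed <- list(c(0, 0, 1), c(0, 0, -1))
  for (k in seq_len(n)) {
    if (k <= length(fixed)) {
      dirs[k, ] <- fixed[[k]]
    } else {
      z <- 1 - 2 * van_der_corput(k - length(fixed))
      rho <- sqrt(max(0, 1 - z^2))
      phi <- (k - length(fixed)) * pi * (3 - sqrt(5))
      dirs[k, ] <- c(rho * cos(phi), rho * sin(phi), z)
    }
  }
  dirs
}

# union-of-disks area by counting grid-cell centres covered by any disk
union_disk_area <- function(px, py, r, h) {
  xmin <- min(px - r); xmax <- max(px + r)
  ymin <- min(py - r); ymax <- max(py + r)
  nx <- max(1L, ceiling((xmax - xmin) / h))
  ny <- max(1L, ceiling((ymax - ymin) / h))
  covered <- matrix(FALSE, ny, nx)
  xc <- xmin + (seq_len(nx) - 0.5) * h
  yc <- ymin + (seq_len(ny) - 0.5) * h
  for (a in seq_along(px)) {
    ix <- which(abs(xc - px[a]) <= r[a])
    iy <- which(abs(yc - py[a]) <= r[a])
    if (!length(ix) || !length(iy)) next
    dx2 <- (xc[ix] - px[a])^2
    dy2 <- (yc[iy] - py[a])^2
    inside <- outer(dy2, dx2, `+`) <= r[a]^2
    covered[iy, ix] <- covered[iy, ix] | inside
  }
  sum(covered) * h^2
}

#' Minimal and maximal projection areas
#'
#' For each sampled direction the atoms are projected as van der Waals
#' disks onto the orthogonal plane and the area of the union of disks is
#' integrated on a regular grid; the minimum and maximum over directions
#' are returned. Requires 3D coordinates on every atom. Hydrogens present
#' in the file contribute; implicit hydrogens (which have no coordinates)
#' do not.
#'
#' @param mol a [molecule_graph] with coordinates
#' @param settings a [projection_settings] object
#' @return named numeric vector `c(min = ..., max = ...)` in square Angstrom
#' @export
projection_areas <- function(mol, settings = projection_settings()) {
  if (!has_coordinates(mol)) {
    stop("projection areas need 3D coordinates on every atom; ",
         "supply a 3D structure (e.g. an optimized conformer)")
  }
  unknown <- setdiff(unique(mol$atoms$element), names(settings$radii))
  if (length(unknown)) {
    stop("element(s) missing from the radius table: ",
         paste(unknown, collapse = ", "))
  }
  coords <- as.matrix(mol$atoms[, c("x", "y", "z")])
  r <- settings$radii[mol$atoms$element]
  dirs <- projection_directions(settings$n_orientations)
  areas <- apply(dirs, 1, function(d) {
    # orthonormal basis of the plane orthogonal to d
    ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- ref - sum(ref * d) * d
    u <- u / sqrt(sum(u^2))
    v <- c(d[2] * u[3] - d[3] * u[2],
           d[3] * u[1] - d[1] * u[3],
           d[1] * u[2] - d[2] * u[1])
    union_disk_area(coords %*% u, coords %*% v, r, settings$grid_resolution)
  })
  c(min = min(areas), max = max(areas))
}

descriptor_registry <- function() {
  c("OComposition", "RingBondCount", "AliphaticRingCount",
    "MinimalProjectionArea", "MaximalProjectionArea", "BasicpKa")
}

#' Compute a descriptor table for a batch of molecules
#'
#' Evaluates the requested descriptors for every molecule and assembles a
#' [feature_table] (one row per molecule, one column per descriptor).
#' `BasicpKa` is not computed from structure: basic pKa prediction requires
#' an empirical model outside the scope of this package, so it is copied by
#' sample id from a user-supplied table (`sample_id,BasicpKa` CSV loaded
#' with [read_feature_csv()]).
#'
#' @param mols list of [molecule_graph] objects; molecule names become
#'   sample ids (falling back to `mol_<k>` when absent)
#' @param which character vector of descriptor names from the registry:
#'   `OComposition`, `RingBondCount`, `AliphaticRingCount`,
#'   `MinimalProjectionArea`, `MaximalProjectionArea`, `BasicpKa`
#' @param pka_table optional [feature_table] with a `BasicpKa` column,
#'   required when `BasicpKa` is requested
#' @param settings [projection_settings] for the geometry descriptors
#' @return a [feature_table] without activity column
#' @export
compute_descriptor_table <- function(mols, which = setdiff(descriptor_registry(), "BasicpKa"),
                                     pka_table = NULL,
                                     settings = projection_settings()) {
  unknown <- setdiff(which, descriptor_registry())
  if (length(unknown)) {
    stop("unknown descriptor(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(descriptor_registry(), collapse = ", "))
  }
  if ("BasicpKa" %in% which && is.null(pka_table)) {
    stop("descriptor BasicpKa requires `pka_table` (it is an input column, ",
         "not computed from structure)")
  }
  ids <- vapply(seq_along(mols), function(k) {
    nm <- mols[[k]]$name
    if (is.null(nm) || !nzchar(nm)) paste0("mol_", k) else nm
  }, character(1))
  vals <- matrix(NA_real_, length(mols), length(which),
                 dimnames = list(NULL, which))
  needs_proj <- any(c("MinimalProjectionArea", "MaximalProjectionArea") %in% which)
  for (k in seq_along(mols)) {
    mol <- mols[[k]]
    proj <- if (needs_proj) projection_areas(mol, settings) else NULL
    for (d in which) {
      vals[k, d] <- switch(d,
        OComposition = o_composition(mol),
        RingBondCount = ring_bond_count(mol),
        AliphaticRingCount = aliphatic_ring_count(mol),
        MinimalProjectionArea = proj[["min"]],
        MaximalProjectionArea = proj[["max"]],
        BasicpKa = {
          if (!"BasicpKa" %in% feature_names(pka_table)) {
            stop("`pka_table` has no BasicpKa column")
          }
          if (!ids[k] %in% pka_table$sample_ids) {
            stop("no BasicpKa entry for sample '", ids[k], "'")
          }
          pka_table$values[match(ids[k], pka_table$sample_ids), "BasicpKa"]
        })
    }
  }
  feature_table(vals, ids)
}
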