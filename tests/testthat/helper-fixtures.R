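# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; no binary fixtures.

# ---- MOL/SDF text builders -------------------------------------------------

mol_block <- function(name, atoms, bonds) {
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    nrow(atoms), nrow(bonds))
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        atoms$x, atoms$y, atoms$z, atoms$element)
  bond_lines <- if (nrow(bonds) > 0) {
    sprintf("%3d%3d%3d  0", bonds$i, bonds$j, bonds$type)
  } else character(0)
  c(name, "  tests", "", counts, atom_lines, bond_lines, "M  END")
}

water_atoms <- data.frame(element = c("O", "H", "H"),
                          x = c(0, 0.9572, -0.24),
                          y = c(0, 0, 0.9266), z = 0)
water_bonds <- data.frame(i = c(1, 1), j = c(2, 3), type = 1L)

# benzene with aromatic bond flags (type 4), flat hexagon, 1.39 A sides
benzene_atoms <- local({
  ang <- 2 * pi * (0:5) / 6
  data.frame(element = "C", x = 1.39 * cos(ang), y = 1.39 * sin(ang), z = 0)
})
benzene_bonds <- data.frame(i = 1:6, j = c(2:6, 1), type = 4L)

write_mol_file <- function(lines, ext = ".mol") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# ---- molecule-graph builders (no file round trip) --------------------------

chain_molecule <- function(elements) {
  n <- length(elements)
  molecule_graph(paste0("chain", n),
    atoms = data.frame(element = elements),
    bonds = if (n > 1) {
      data.frame(i = 1:(n - 1), j = 2:n, order = 1L, aromatic = FALSE)
    } else data.frame(i = integer(0), j = integer(0), order = integer(0),
                      aromatic = logical(0)))
}

ring_molecule <- function(elements, orders = 1L, aromatic = FALSE) {
  n <- length(elements)
  molecule_graph(paste0("ring", n),
    atoms = data.frame(element = elements),
    bonds = data.frame(i = 1:n, j = c(2:n, 1),
                       order = rep_len(orders, n),
                       aromatic = rep_len(aromatic, n)))
}

# fused bicyclic C10: ring 1-2-3-4-5-6, ring 6-7-8-9-10-1 sharing bond (1,6)
naphthalene_graph <- function(orders = 1L, aromatic = TRUE) {
  bonds <- data.frame(
    i = c(1, 2, 3, 4, 5, 6, 6, 7, 8, 9, 10),
    j = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10, 1))
  bonds$order <- rep_len(orders, nrow(bonds))
  bonds$aromatic <- rep_len(aromatic, nrow(bonds))
  molecule_graph("naphthalene", data.frame(element = rep("C", 10)), bonds)
}

# random connected molecule graph: spanning tree plus extra edges
random_molecule <- function(n_atoms, n_extra, seed) {
  set.seed(seed)
  bonds <- data.frame(i = integer(0), j = integer(0))
  if (n_atoms > 1) {
    bonds <- data.frame(i = vapply(2:n_atoms, function(v) sample.int(v - 1, 1),
                                   integer(1)),
                        j = 2:n_atoms)
  }
  pairs <- which(upper.tri(matrix(TRUE, n_atoms, n_atoms)), arr.ind = TRUE)
  have <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
  avail <- pairs[!paste(pairs[, 1], pairs[, 2]) %in% have, , drop = FALSE]
  if (n_extra > 0 && nrow(avail) > 0) {
    pick <- avail[sample.int(nrow(avail), min(n_extra, nrow(avail))), ,
                  drop = FALSE]
    bonds <- rbind(bonds, data.frame(i = pick[, 1], j = pick[, 2]))
  }
  bonds$order <- 1L
  bonds$aromatic <- FALSE
  molecule_graph(paste0("rand", seed),
                 data.frame(element = rep("C", n_atoms)), bonds)
}

# ---- independent oracles ---------------------------------------------------

# brute-force double sum over the joint table (nats)
mi_brute_force <- function(x, y) {
  n <- length(x)
  s <- 0
  for (vx in unique(x)) {
    for (vy in unique(y)) {
      pxy <- sum(x == vx & y == vy) / n
      if (pxy > 0) {
        s <- s + pxy * log(pxy / ((sum(x == vx) / n) * (sum(y == vy) / n)))
      }
    }
  }
  s
}

# closed-form area of the union of two disks at centre distance d
union_two_disks <- function(r1, r2, d) {
  if (d >= r1 + r2) return(pi * (r1^2 + r2^2))
  if (d <= abs(r1 - r2)) return(pi * max(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  lens <- a1 + a2 -
    0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  pi * (r1^2 + r2^2) - lens
}

# independent quadratic-programming oracle for the eps-SVR dual: interior
# point solve of the 2n-variable (alpha, alpha*) box QP with kernlab::ipop,
# reported as the dual objective W(beta) = y'beta - eps*sum|beta| - beta'K beta/2
qp_oracle <- function(K, y, C, eps) {
  n <- length(y)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-10, 2 * n)
  cc <- c(eps - y, eps + y)
  A <- matrix(c(rep(1, n), rep(-1, n)), 1)
  sol <- kernlab::ipop(c = cc, H = H, A = A, b = 0,
                       l = rep(0, 2 * n), u = rep(C, 2 * n), r = 0,
                       sigf = 9, maxiter = 200)
  x <- kernlab::primal(sol)
  beta <- x[1:n] - x[n + 1:n]
  list(beta = beta, objective = svr_dual_objective(K, y, eps, beta))
}

svr_dual_objective <- function(K, y, eps, beta) {
  sum(y * beta) - eps * sum(abs(beta)) - 0.5 * drop(beta %*% K %*% beta)
}

# feature table around an explicit matrix with default ids
quick_table <- function(values, activity = NULL) {
  feature_table(values, paste0("s", seq_len(nrow(values))), activity)
}
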