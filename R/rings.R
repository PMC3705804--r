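# Ring perception on molecule graphs: cycle-membership of bonds, a smallest
# set of smallest rings (SSSR, sized by circuit rank), and an aromaticity
# heuristic for files without aromatic bond flags.

adjacency_list <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    adj[[i]] <- rbind(adj[[i]], c(j, b))
    adj[[j]] <- rbind(adj[[j]], c(i, b))
  }
  adj
}

# shortest path between two atoms by BFS, optionally forbidding one bond;
# returns the sequence of bond indices, or NULL if disconnected
bfs_path <- function(adj, from, to, forbidden_bond = 0L) {
  n <- length(adj)
  prev_atom <- integer(n); prev_bond <- integer(n)
  seen <- logical(n); seen[from] <- TRUE
  queue <- from
  while (length(queue) > 0) {
    a <- queue[1]; queue <- queue[-1]
    nb <- adj[[a]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      b <- nb[r, 2]
      if (b == forbidden_bond) next
      v <- nb[r, 1]
      if (!seen[v]) {
        seen[v] <- TRUE
        prev_atom[v] <- a; prev_bond[v] <- b
        if (v == to) {
          path <- integer(0); cur <- to
          while (cur != from) {
            path <- c(prev_bond[cur], path)
            cur <- prev_atom[cur]
          }
          return(path)
        }
        queue <- c(queue, v)
      }
    }
  }
  NULL
}

n_components <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- adjacency_list(mol)
  seen <- logical(n); comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue) > 0) {
      a <- queue[1]; queue <- queue[-1]
      nb <- adj[[a]]
      if (is.null(nb)) next
      for (v in nb[, 1]) if (!seen[v]) { seen[v] <- TRUE; queue <- c(queue, v) }
    }
  }
  comps
}

# logical vector over bonds: TRUE iff the bond lies on at least one cycle
# (equivalently, it is not a bridge)
ring_bond_membership <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0) return(logical(0))
  adj <- adjacency_list(mol)
  vapply(seq_len(nb), function(b) {
    !is.null(bfs_path(adj, mol$bonds$i[b], mol$bonds$j[b], forbidden_bond = b))
  }, logical(1))
}

#' Smallest set of smallest rings
#'
#' Extracts a minimal cycle basis of the molecular graph: for every bond
#' that lies on a cycle the smallest ring through it is found by
#' breadth-first search, candidate rings are sorted by size, and rings are
#' accepted greedily while linearly independent over GF(2) on their bond
#' incidence vectors. The number of rings equals the circuit rank
#' `bonds - atoms + components`, which makes the ring count well defined
#' even where the smallest-ring set itself is ambiguous.
#'
#' @param mol a [molecule_graph]
#' @return a list of integer vectors, each the bond indices of one ring
#' @export
sssr <- function(mol) {
  rank <- nrow(mol$bonds) - nrow(mol$atoms) + n_components(mol)
  if (rank <= 0) return(list())
  adj <- adjacency_list(mol)
  in_ring <- ring_bond_membership(mol)
  cand <- list()
  for (b in which(in_ring)) {
    path <- bfs_path(adj, mol$bonds$i[b], mol$bonds$j[b], forbidden_bond = b)
    ring <- sort(c(path, b))
    cand[[length(cand) + 1L]] <- ring
  }
  cand <- unique(cand)
  sizes <- lengths(cand)
  keys <- vapply(cand, function(r) paste(sprintf("%06d", r), collapse = ""),
                 character(1))
  cand <- cand[order(sizes, keys)]
  # greedy GF(2) independence via incremental Gaussian elimination
  basis <- list()  # reduced bond-set vectors (as sorted integer sets)
  chosen <- list()
  xor_set <- function(a, b) sort(c(setdiff(a, b), setdiff(b, a)))
  for (ring in cand) {
    v <- ring
    for (bv in basis) {
      if (length(v) && bv[1] %in% v) v <- xor_set(v, bv)
    }
    if (length(v) > 0) {
      basis[[length(basis) + 1L]] <- v
      basis <- basis[order(vapply(basis, function(v) as.numeric(v[1]),
                                  numeric(1)))]
      chosen[[length(chosen) + 1L]] <- ring
      if (length(chosen) == rank) break
    }
  }
  chosen
}

# returns the mol with bond aromatic flags resolved: flags from the file are
# kept; if the file carried none, 6-membered rings of strictly alternating
# single/double bonds are flagged aromatic (benzenoid heuristic)
perceive_aromaticity <- function(mol) {
  if (nrow(mol$bonds) == 0 || any(mol$bonds$aromatic)) return(mol)
  rings <- sssr(mol)
  for (ring in rings) {
    if (length(ring) != 6) next
    orders <- sort(mol$bonds$order[ring])
    if (!identical(orders, rep(c(1L, 2L), each = 3))) next
    if (alternates_around_ring(mol, ring)) {
      mol$bonds$aromatic[ring] <- TRUE
    }
  }
  mol
}

# walk the ring cycle and check single/double orders strictly alternate
alternates_around_ring <- function(mol, ring) {
  bonds <- mol$bonds[ring, ]
  start <- bonds$i[1]
  seq_orders <- integer(0)
  cur_atom <- start; used <- logical(nrow(bonds))
  for (step in seq_len(nrow(bonds))) {
    nxt <- which(!used & (bonds$i == cur_atom | bonds$j == cur_atom))[1]
    if (is.na(nxt)) return(FALSE)  # not a simple cycle
    used[nxt] <- TRUE
    seq_orders <- c(seq_orders, bonds$order[nxt])
    cur_atom <- if (bonds$i[nxt] == cur_atom) bonds$j[nxt] else bonds$i[nxt]
  }
  if (cur_atom != start) return(FALSE)
  all(abs(diff(c(seq_orders, seq_orders[1]))) == 1)
}
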