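# Shared fixtures and independent oracles.

phys <- list(
  eps0 = 8.8541878128e-12,
  hbar = 1.054571817e-34,
  e = 1.602176634e-19,
  m_e = 9.1093837015e-31
)

# One wwPDB v3.3 ATOM/HETATM record.
pdb_line <- function(serial, name, resn, chain, resno, x, y, z,
                     alt = " ", occ = 1, elem = "C", record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, paste0(" ", name), alt, resn, chain, resno,
          x, y, z, occ, 0, elem)
}

# Minimal 3-residue PDB with N/CA atoms, a HETATM and a water, coordinates
# chosen by hand.
write_minimal_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    pdb_line(1, "N",  "ALA", "A", 1, 0.100, 0.200, 0.300, elem = "N"),
    pdb_line(2, "CA", "ALA", "A", 1, 1.000, 2.000, 3.000),
    pdb_line(3, "CA", "GLY", "A", 2, 4.500, 2.000, 3.000),
    pdb_line(4, "CA", "SER", "A", 3, 4.500, 5.750, 3.000),
    pdb_line(5, "O",  "HOH", "A", 9, 9.000, 9.000, 9.000, elem = "O",
             record = "HETATM"),
    "END"), path)
  path
}

# Same skeleton with one residue in two alternate locations (A: occ 0.60,
# B: occ 0.40).
write_altloc_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    pdb_line(1, "CA", "ALA", "A", 1, 1.000, 2.000, 3.000),
    pdb_line(2, "CA", "GLY", "A", 2, 4.500, 2.000, 3.000, alt = "A", occ = 0.60),
    pdb_line(3, "CA", "GLY", "A", 2, 4.600, 2.100, 3.100, alt = "B", occ = 0.40),
    pdb_line(4, "CA", "SER", "A", 3, 4.500, 5.750, 3.000),
    "END"), path)
  path
}

# Two-chain fixture.
write_two_chain_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_line(3, "CA", "LEU", "B", 1, 0, 10, 0),
    pdb_line(4, "CA", "LYS", "B", 2, 3.8, 10, 0),
    "END"), path)
  path
}

# Independent breadth-first-search connectivity oracle.
bfs_connected <- function(n, edges, s, t) {
  adj <- vector("list", n)
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- rep(FALSE, n); seen[s] <- TRUE; queue <- s
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  seen[t]
}

# Independent two-terminal impedance oracle: effective impedance between
# node sets via the pseudoinverse route, Z = u' (L + J/n)^{-1} u with
# u = e_in - e_out, after shorting each contact set. Works for real and
# complex admittances; no supernode/grounding elimination shared with the
# implementation.
oracle_two_terminal <- function(n, edges_ij, y, input, output) {
  grp <- seq_len(n)
  grp[input] <- n + 1L
  grp[output] <- n + 2L
  ids <- match(grp, unique(grp))
  K <- max(ids)
  L <- matrix(if (is.complex(y)) 0 + 0i else 0, K, K)
  for (k in seq_len(nrow(edges_ij))) {
    a <- ids[edges_ij[k, 1]]; b <- ids[edges_ij[k, 2]]
    if (a == b) next
    L[a, a] <- L[a, a] + y[k]; L[b, b] <- L[b, b] + y[k]
    L[a, b] <- L[a, b] - y[k]; L[b, a] <- L[b, a] - y[k]
  }
  u <- rep(if (is.complex(y)) 0 + 0i else 0, K)
  u[ids[input[1]]] <- 1
  u[ids[output[1]]] <- -1
  # any nonzero rank-one shift along the ones vector regularizes L without
  # changing u' L^+ u (u is orthogonal to ones); scale it to the admittances
  alpha <- mean(Mod(y))
  sol <- solve(L + matrix(alpha / K, K, K), u)
  drop(u %*% sol)
}

# Random compact chain in a box, reproducible.
random_chain <- function(n, box = 30, seed = 42) {
  xyz <- inpa:::with_seed(seed, matrix(stats::runif(3 * n, 0, box), ncol = 3))
  calpha_chain("A", seq_len(n), "ALA", xyz[, 1], xyz[, 2], xyz[, 3])
}

# Small synthetic membrane-spanning helix bundle: n_helix parallel ideal
# helices spanning the same z range, packed on a circle.
make_helix_bundle <- function(n_helix = 3, n_res = 14, spacing = 6) {
  parts <- lapply(seq_len(n_helix), function(k) {
    h <- make_helix(n_res)
    ang <- 2 * pi * (k - 1) / n_helix
    h$x <- h$x + spacing * cos(ang)
    h$y <- h$y + spacing * sin(ang)
    h$chain <- LETTERS[k]
    h
  })
  df <- do.call(rbind, lapply(parts, as.data.frame))
  inpa:::validate_calpha_chain(df)
}
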