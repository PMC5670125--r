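# Shared fixtures and independent oracles, all built in code.

# a hand-written 2-model PDB of a 3-residue peptide (CA trace plus backbone)
write_tiny_pdb <- function(path, drop_atom_model2 = FALSE) {
  m1 <- c(
    "MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.100   1.300   0.000  1.00  0.00           C",
    "ATOM      4  CA  GLY A   2       3.500   1.500   0.500  1.00  0.00           C",
    "ATOM      5  CA  SER A   3       5.100   2.700   1.100  1.00  0.00           C",
    "ENDMDL")
  m2 <- sub("0.000   0.000   0.000", "0.100   0.000   0.000", m1)
  m2[1] <- "MODEL        2"
  if (drop_atom_model2) m2 <- m2[-3L]
  writeLines(c(m1, m2, "END"), path)
  path
}

# frame constructor for hand-built toys
make_frame <- function(names, resnames, resnos, chains, coords,
                       elements = substr(names, 1, 1)) {
  atoms <- data.frame(serial = seq_along(names), name = names,
                      element = elements, resname = resnames,
                      resno = resnos, chain = chains,
                      stringsAsFactors = FALSE)
  trajectory(atoms, as.vector(t(coords)))
}

# brute-force RMSD oracle: dense rotation grid (Euler angles) after centroid
# alignment, refined by grid halving around the running best
grid_search_rmsd <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P)); Q <- sweep(Q, 2, colMeans(Q))
  rot <- function(a, b, c) {
    Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rz2
  }
  eval_r <- function(a, b, c) sqrt(mean(rowSums((P %*% rot(a, b, c) - Q)^2)))
  best <- c(0, 0, 0); best_v <- eval_r(0, 0, 0)
  step <- 20 * pi / 180
  grid <- expand.grid(a = seq(0, 2 * pi, by = step),
                      b = seq(0, pi, by = step),
                      c = seq(0, 2 * pi, by = step))
  for (i in seq_len(nrow(grid))) {
    v <- eval_r(grid$a[i], grid$b[i], grid$c[i])
    if (v < best_v) { best_v <- v; best <- as.numeric(grid[i, ]) }
  }
  while (step > 1e-5) {
    step <- step / 2
    cand <- expand.grid(a = best[1] + step * (-2:2),
                        b = best[2] + step * (-2:2),
                        c = best[3] + step * (-2:2))
    for (i in seq_len(nrow(cand))) {
      v <- eval_r(cand$a[i], cand$b[i], cand$c[i])
      if (v < best_v) { best_v <- v; best <- as.numeric(cand[i, ]) }
    }
  }
  best_v
}

# naive DF oracle: explicit double loop over residue pairs, two-pass variance
naive_df <- function(traj) {
  ca <- select_calpha(traj)
  nf <- n_frames(traj)
  n <- length(ca)
  coords <- lapply(seq_len(nf), function(f)
    matrix(traj$xyz[f, ], ncol = 3, byrow = TRUE)[ca, , drop = FALSE])
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- vapply(coords, function(x) sqrt(sum((x[i, ] - x[j, ])^2)), 0)
    m <- sum(d) / nf
    out[i, j] <- out[j, i] <- sum((d - m)^2) / nf
  }
  out
}

tetramer_blocks <- function(n_chains = 4, n_res = 30)
  split(seq_len(n_chains * n_res), rep(seq_len(n_chains), each = n_res))
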