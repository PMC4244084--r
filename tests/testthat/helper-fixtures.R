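# Fixture builders and independent oracles shared across the test files.

# Bead model: one single-atom residue per bead, chains given as
# list(id = , role = , n = ) specs. Residue numbering starts at 1.
make_bead_model <- function(chains) {
  rows <- lapply(chains, function(ch) {
    rn <- if (is.null(ch$resnames)) rep("GLY", ch$n) else
      rep_len(ch$resnames, ch$n)
    data.frame(chain = ch$id, resno = seq_len(ch$n), resname = rn,
               name = "CA", element = "C", stringsAsFactors = FALSE)
  })
  roles <- setNames(vapply(chains, `[[`, "", "role"),
                    vapply(chains, `[[`, "", "id"))
  oligotraj:::new_system_model(do.call(rbind, rows), roles)
}

# random multi-atom-residue fixture for oracle-equivalence checks
random_contact_fixture <- function(n_res = 50, box_edge = 30, seed = 1,
                                   n_chains = 2) {
  set.seed(seed)
  atoms_per_res <- sample(1:4, n_res, replace = TRUE)
  chain_of_res <- sort(sample(seq_len(n_chains), n_res, replace = TRUE))
  rows <- do.call(rbind, lapply(seq_len(n_res), function(r)
    data.frame(chain = LETTERS[chain_of_res[r]], resno = r,
               resname = "GLY", name = "CA", element = "C",
               stringsAsFactors = FALSE)[rep(1, atoms_per_res[r]), ]))
  roles <- setNames(rep("peptide", n_chains),
                    LETTERS[seq_len(n_chains)])
  model <- oligotraj:::new_system_model(rows, roles)
  # coordinates beyond the box on purpose: wrapping must not matter
  xyz <- matrix(runif(model$natoms * 3, -box_edge, 2 * box_edge),
                ncol = 3)
  list(model = model, frame = frame(0, xyz, rep(box_edge, 3)))
}

# Kabsch oracle: brute-force minimization of RMSD over rotations
# (Euler-angle grid followed by Nelder-Mead refinement from the best cells).
euler_rotation <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                             0, 0, 1), 3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                             sin(t), 0, cos(t)), 3, 3)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

rmsd_rotation_search <- function(ref, mob) {
  A <- scale(ref, scale = FALSE)
  B <- scale(mob, scale = FALSE)
  obj <- function(p) {
    R <- euler_rotation(p[1], p[2], p[3])
    sqrt(mean(rowSums((B %*% R - A)^2)))
  }
  gr <- seq(0, 2 * pi, length.out = 9)[-9]
  gb <- seq(0, pi, length.out = 5)
  grid <- expand.grid(a = gr, b = gb, c = gr)
  vals <- apply(grid, 1, obj)
  best <- order(vals)[1:5]
  refined <- vapply(best, function(i) {
    stats::optim(as.numeric(grid[i, ]), obj,
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 2000))$value
  }, numeric(1))
  min(refined)
}

# slow reference implementation of the survival correlation
survival_oracle <- function(b, dt, origins_stride = 1) {
  nf <- nrow(b)
  max_lag <- (nf - 1) %/% 2
  vapply(0:max_lag, function(L) {
    orig <- seq(1, nf - L, by = origins_stride)
    mean(vapply(orig, function(t)
      sum(apply(b[t:(t + L), , drop = FALSE] == 1, 2, all)),
      numeric(1)))
  }, numeric(1))
}

# minimal fixed-width PDB writer (with optional hydrogens) for load_system
write_tiny_pdb <- function(path, atoms) {
  # atoms: data.frame(chain, resno, resname, name, element, x, y, z)
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, a$name, a$resname, a$chain, a$resno, a$x, a$y, a$z,
            a$element)
  }, character(1))
  writeLines(c(lines, "END"), path)
}

expect_same_pairs <- function(pairs_a, pairs_b) {
  key <- function(p) if (nrow(p) == 0) character(0) else
    paste(p[, 1], p[, 2], sep = "-")
  expect_setequal(key(pairs_a), key(pairs_b))
}
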