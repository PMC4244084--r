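rand_points <- function(n, seed) {
  set.seed(seed)
  matrix(rnorm(3 * n, 0, 3), n, 3)
}

test_that("kabsch recovers rigid transforms exactly", {
  P <- rand_points(8, 1)
  sp <- kabsch(P, P)
  expect_equal(sp$rmsd, 0, tolerance = 1e-12)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)
  for (seed in 2:6) {
    set.seed(seed)
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    moved <- sweep(P %*% R, 2, c(5, -3, 11), "+")
    sp <- kabsch(P, moved)
    expect_lt(sp$rmsd, 1e-9)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
    expect_equal(apply_superposition(sp, moved), P, tolerance = 1e-9)
  }
  expect_error(kabsch(P, P[1:5, ]), "dimensions")
  expect_warning(kabsch(cbind(1:5, 0, 0), cbind(c(1, 3, 2, 5, 4), 0, 0)),
                 "degenerate")
})

test_that("kabsch rmsd is symmetric and matches the rotation-search oracle", {
  for (seed in 1:6) {
    n <- sample(3:5, 1)
    A <- rand_points(n, seed * 11)
    B <- A + matrix(rnorm(3 * n, 0, 0.8), n, 3)
    expect_equal(kabsch(A, B)$rmsd, kabsch(B, A)$rmsd, tolerance = 1e-9)
    expect_equal(kabsch(A, B)$rmsd, rmsd_rotation_search(A, B),
                 tolerance = 1e-3)
  }
  # 4-point fixture with one point displaced by 1 A
  A <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(0, 0, 4))
  B <- A
  B[2, 1] <- B[2, 1] + 1
  expect_equal(kabsch(A, B)$rmsd, rmsd_rotation_search(A, B),
               tolerance = 1e-3)
})

test_that("rmsd series is zero along rigid motions and ramps linearly", {
  m <- make_bead_model(list(list(id = "A", role = "inhibitor", n = 6),
                            list(id = "B", role = "peptide", n = 2)))
  ref <- rand_points(8, 40)
  nf <- 6
  coords <- array(0, c(8, 3, nf))
  set.seed(41)
  for (f in seq_len(nf)) {
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    coords[, , f] <- sweep(ref %*% R, 2, rnorm(3, 0, 10), "+")
  }
  tr <- trajectory(m, 0:5, coords, rep(200, 3))
  sel <- select_atoms(m, role = "inhibitor")
  rs <- rmsd_series(tr, reference = ref[sel, ], selection = sel)
  expect_true(all(rs$rmsd < 1e-9))
  # interpolation toward a displaced structure: monotone ramp to the
  # oracle value of the endpoint
  target <- ref
  target[1, ] <- target[1, ] + c(3, 1, -2)
  for (f in seq_len(nf))
    coords[, , f] <- ref + (f - 1) / (nf - 1) * (target - ref)
  tr2 <- trajectory(m, 0:5, coords, rep(200, 3))
  rs2 <- rmsd_series(tr2, reference = ref[sel, ], selection = sel)
  expect_true(all(diff(rs2$rmsd) > 0))
  expect_equal(rs2$rmsd[nf],
               rmsd_rotation_search(ref[sel, ], target[sel, ]),
               tolerance = 1e-3)
  expect_error(rmsd_series(tr2, selection = integer(0)), "selection")
})

test_that("rmsf matches a constructed oscillation and rigid invariance", {
  # four single-bead residues; the two outer beads (on the x axis)
  # oscillate along x in opposite phase: no net translation or rotation,
  # so the alignment stays at identity and RMSF equals the amplitude; the
  # two inner beads sit off-axis to keep the configuration non-degenerate
  m <- make_bead_model(list(list(id = "A", role = "peptide", n = 4)))
  base <- rbind(c(-3, 0, 0), c(-1, 0.8, 0), c(1, 0, 0.8), c(3, 0, 0))
  a <- 0.5
  nf <- 8
  coords <- array(0, c(4, 3, nf))
  for (f in seq_len(nf)) {
    d <- if (f %% 2 == 0) a else -a
    fr <- base
    fr[4, 1] <- fr[4, 1] + d
    fr[1, 1] <- fr[1, 1] - d
    coords[, , f] <- fr
  }
  tr <- trajectory(m, seq_len(nf), coords, rep(100, 3))
  rf <- rmsf_per_residue(tr, selection = 1:4)
  expect_equal(rf$rmsf[c(1, 4)], c(a, a), tolerance = 1e-9)
  expect_equal(rf$rmsf[c(2, 3)], c(0, 0), tolerance = 1e-9)
  # static trajectory: all zeros
  coords0 <- array(rep(base, nf), c(4, 3, nf))
  tr0 <- trajectory(m, seq_len(nf), coords0, rep(100, 3))
  expect_true(all(rmsf_per_residue(tr0, 1:4)$rmsf < 1e-12))
  expect_error(rmsf_per_residue(trajectory(m, 1, coords[, , 1,
                                                        drop = FALSE],
                                           rep(100, 3)), 1:4),
               "2 frames")
  # invariance under a global rigid motion added to every frame
  set.seed(50)
  coords2 <- coords
  for (f in seq_len(nf)) {
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    coords2[, , f] <- sweep(coords[, , f] %*% R, 2, rnorm(3, 0, 5), "+")
  }
  tr2 <- trajectory(m, seq_len(nf), coords2, rep(100, 3))
  rf2 <- rmsf_per_residue(tr2, 1:4)
  expect_equal(rf2$rmsf, rf$rmsf, tolerance = 1e-6)
})
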