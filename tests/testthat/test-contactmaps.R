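# A deterministic docking fixture: 10-residue peptide, 8-residue inhibitor,
# one bead per residue. Peptide residues 1-6 sit 3 A from inhibitor
# residues 1-6 (six contacts > 5: the peptide is complexed); residues 7-10
# never touch.
docked_fixture <- function(bound = TRUE) {
  m <- make_bead_model(list(
    list(id = "P01", role = "peptide", n = 10),
    list(id = "X", role = "inhibitor", n = 8,
         resnames = c("ARG", "ASP", "LEU", "SER", "GLY", "TYR", "ARG",
                      "LYS"))))
  xyz <- matrix(0, 18, 3)
  xyz[1:10, 2] <- (0:9) * 20               # peptide beads
  xyz[11:18, 2] <- (0:7) * 20              # inhibitor beads
  xyz[11:18, 1] <- if (bound) 3 else 500   # 3 A gap for residues 1-6
  xyz[17:18, 1] <- 500                     # inhibitor residues 7-8 far
  if (!bound) xyz[11:18, 1] <- 500
  fr <- frame(0, xyz, rep(2000, 3))
  tr <- replicate_frame(fr, m, n_frames = 3, dt = 0.1, jitter = 0,
                        seed = 1)
  list(model = m, traj = tr)
}

test_that("inhibitor-peptide map recovers a planted docking pattern", {
  fx <- docked_fixture(bound = TRUE)
  map <- inhibitor_peptide_map(fx$traj)
  expect_equal(map$n_obs, 3)               # one complexed peptide, 3 frames
  expect_equal(dim(map$P), c(8, 10))
  for (i in 1:6) expect_equal(map$P[i, i], 1)
  expect_equal(sum(map$P), 6)              # nothing else touches
  expect_true(all(map$P >= 0 & map$P <= 1))
  # no binding events -> empty-result signal
  expect_null(inhibitor_peptide_map(docked_fixture(bound = FALSE)$traj))
})

test_that("per-residue profile dominates its map row cells", {
  fx <- docked_fixture(bound = TRUE)
  map <- inhibitor_peptide_map(fx$traj)
  prof <- per_residue_profile(map)
  expect_equal(prof$probability, c(rep(1, 6), rep(0, 4)))
  # any-contact probability >= each pairwise cell of that residue
  for (j in 1:10)
    expect_gte(prof$probability[j], max(map$P[, j]))
})

test_that("per-type profile averages residues of a type, flags absent ones", {
  fx <- docked_fixture(bound = TRUE)
  map <- inhibitor_peptide_map(fx$traj)
  ty <- per_type_profile(map, side = "inhibitor")
  # one Arg always in contact (residue 1), one never (residue 7) -> 0.5
  expect_equal(ty$probability[ty$type == "R"], 0.5)
  expect_equal(ty$n_residues[ty$type == "R"], 2L)
  # Lys (residue 8) never in contact
  expect_equal(ty$probability[ty$type == "K"], 0)
  # a type absent from the inhibitor sequence is flagged, not zero
  expect_false(ty$present[ty$type == "W"])
  expect_true(is.na(ty$probability[ty$type == "W"]))
  ok <- !is.na(ty$probability)
  expect_true(all(ty$probability[ok] >= 0 & ty$probability[ok] <= 1))
})

test_that("tertiary map masks the sequential band and sees a hairpin", {
  m <- make_bead_model(list(list(id = "P01", role = "peptide", n = 10)))
  # fully extended chain: no non-sequential contacts at all
  ext <- cbind(0, (0:9) * 3.8, 0)
  tre <- replicate_frame(frame(0, ext, rep(500, 3)), m, n_frames = 2,
                         dt = 1, jitter = 0, seed = 1)
  me <- tertiary_map(tre, population = "free")
  expect_true(all(me$P[!me$mask] == 0))
  expect_true(all(is.na(me$P[me$mask])))
  # hairpin: residue k pairs with residue 11-k across a 4 A gap
  hp <- ext
  hp[6:10, 1] <- 4
  hp[6:10, 2] <- (10 - (6:10)) * 3.8
  trh <- replicate_frame(frame(0, hp, rep(500, 3)), m, n_frames = 2,
                         dt = 1, jitter = 0, seed = 1)
  mh <- tertiary_map(trh, population = "free")
  for (k in 1:4) expect_equal(mh$P[k, 11 - k], 1)
  expect_equal(mh$P, t(mh$P))
  expect_true(all(is.na(mh$P[abs(outer(1:10, 1:10, "-")) < 3])))
})

test_that("quaternary map sees the planted antiparallel dimer block", {
  m <- make_bead_model(list(list(id = "P01", role = "peptide", n = 10),
                            list(id = "P02", role = "peptide", n = 10)))
  xyz <- matrix(0, 20, 3)
  xyz[1:10, 2] <- (0:9) * 3.8
  xyz[11:20, 1] <- 3
  xyz[11:20, 2] <- (15 - (1:10) - 1) * 3.8   # antiparallel, C-term halves
  tr <- replicate_frame(frame(0, xyz, rep(500, 3)), m, n_frames = 2,
                        dt = 1, jitter = 0, seed = 1)
  qm <- quaternary_map(tr, population = "free")
  expect_false(is.null(qm))
  expect_equal(qm$P, t(qm$P))
  expect_true(all(qm$P >= 0 & qm$P <= 1))
  # C-terminal block elevated, N-terminal block empty
  expect_gt(mean(qm$P[6:10, 6:10]), 0.1)
  expect_equal(sum(qm$P[1:4, 1:4]), 0)
  # isolated monomers: no qualifying pair
  far <- xyz
  far[11:20, 1] <- 300
  trf <- replicate_frame(frame(0, far, rep(500, 3)), m, n_frames = 2,
                         dt = 1, jitter = 0, seed = 1)
  expect_null(quaternary_map(trf, population = "free"))
})

test_that("quaternary populations honor the one-member-bound rule", {
  sc <- oligomer_scene_builder(sizes = c(2, 1, 1), bound = c(TRUE, FALSE,
                                                             FALSE),
                               seed = 12)
  tr <- replicate_frame(sc$frame, sc$model, n_frames = 3, dt = 0.1,
                        jitter = 0, seed = 2)
  qc <- quaternary_map(tr, population = "complexed")
  expect_false(is.null(qc))
  expect_true(all(qc$P >= 0 & qc$P <= 1, na.rm = TRUE))
  expect_equal(qc$P, t(qc$P))
  # the only interacting pair has a bound member, so the free population
  # is empty
  expect_null(quaternary_map(tr, population = "free"))
})

test_that("map probabilities stay in bounds on stochastic generator data", {
  sc <- kinetic_scenario(n_peptides = 4, k_on = 0.3, k_off = 0.2,
                         n_frames = 150, dt = 0.5, seed = 33)
  g <- markov_binding_generator(sc)
  ens <- contact_ensemble(g$trajectory)
  map <- inhibitor_peptide_map(ens)
  expect_false(is.null(map))
  expect_true(all(map$P >= 0 & map$P <= 1))
  expect_equal(map$n_obs, sum(g$truth$bound))
  tm <- tertiary_map(ens, population = "complexed")
  if (!is.null(tm))
    expect_true(all(tm$P[!tm$mask] >= 0 & tm$P[!tm$mask] <= 1))
})
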