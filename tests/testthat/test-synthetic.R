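test_that("absorbing limits of the Markov generator are exact", {
  sc <- kinetic_scenario(n_peptides = 3, k_on = 0.5, k_off = 0,
                         n_frames = 100, dt = 0.5, seed = 1,
                         initially_bound = TRUE)
  g <- markov_binding_generator(sc)
  expect_true(all(g$truth$bound))
  expect_true(all(bound_series(g$trajectory)$b == 1))
  sc0 <- kinetic_scenario(n_peptides = 3, k_on = 0, k_off = 0.5,
                          n_frames = 100, dt = 0.5, seed = 2,
                          initially_bound = FALSE)
  g0 <- markov_binding_generator(sc0)
  expect_false(any(g0$truth$bound))
  expect_true(all(bound_series(g0$trajectory)$b == 0))
})

test_that("analysis agrees with generator ground truth on every frame", {
  sc <- kinetic_scenario(n_peptides = 8, k_on = 0.15, k_off = 0.15,
                         n_frames = 400, dt = 0.25, seed = 14)
  g <- markov_binding_generator(sc)
  bs <- bound_series(g$trajectory)
  expect_equal(unname(bs$b), unname(g$truth$bound * 1L))
  # peptides never oligomerize in this generator
  states <- aggregation_states(g$trajectory)
  expect_true(all(vapply(states, function(s)
    all(lengths(s$oligomers) == 1), logical(1))))
})

test_that("identical scenario and seed give byte-identical trajectories", {
  sc <- kinetic_scenario(n_peptides = 3, n_frames = 40, dt = 0.5,
                         seed = 77)
  g1 <- markov_binding_generator(sc)
  g2 <- markov_binding_generator(sc)
  f1 <- tempfile(); f2 <- tempfile()
  write_trajectory(g1$trajectory, f1)
  write_trajectory(g2$trajectory, f2)
  expect_identical(readLines(f1), readLines(f2))
  g3 <- markov_binding_generator(
    kinetic_scenario(n_peptides = 3, n_frames = 40, dt = 0.5, seed = 78))
  expect_false(identical(g1$trajectory$coords, g3$trajectory$coords))
})

test_that("occupancy converges to the stationary bound probability", {
  k_on <- 0.05; k_off <- 0.1
  p0 <- k_on / (k_on + k_off)
  occ <- vapply(1:5, function(s) {
    g <- markov_binding_generator(
      kinetic_scenario(n_peptides = 10, k_on = k_on, k_off = k_off,
                       n_frames = 4000, dt = 0.25, seed = 300 + s))
    mean(g$truth$bound)
  }, numeric(1))
  se <- sd(occ) / sqrt(length(occ))
  expect_lt(abs(mean(occ) - p0), 3 * se + 0.01)
})

test_that("scene builder compositions are classified exactly as built", {
  # the snapshot-style composition: bound trimer + bound dimer + 5 monomers
  sc <- oligomer_scene_builder(sizes = c(3, 2, 1, 1, 1, 1, 1),
                               bound = c(TRUE, TRUE, rep(FALSE, 5)),
                               seed = 41)
  st <- aggregation_state(residue_contacts(sc$frame, sc$model), sc$model)
  expect_setequal(vapply(st$oligomers, paste, "", collapse = ","),
                  vapply(sc$truth$partition, paste, "", collapse = ","))
  expect_equal(sum(st$complexed & lengths(st$oligomers) %in% 2:5), 2)
  expect_equal(sum(!st$complexed & lengths(st$oligomers) == 1), 5)
  # boundary of the size classes: pentamer small, hexamer large
  s5 <- oligomer_scene_builder(sizes = c(5), bound = FALSE,
                               inhibitor = FALSE, seed = 42)
  st5 <- aggregation_state(residue_contacts(s5$frame, s5$model), s5$model)
  expect_equal(lengths(st5$oligomers), 5)
  s6 <- oligomer_scene_builder(sizes = c(6, 1), bound = c(FALSE, FALSE),
                               inhibitor = FALSE, seed = 43)
  tr6 <- replicate_frame(s6$frame, s6$model, n_frames = 2, dt = 1,
                         jitter = 0, seed = 1)
  sp6 <- species_counts(tr6, bin_ns = 50)
  expect_equal(sp6$free_large[1], 1)
  expect_equal(sp6$free_monomer[1], 1)
  expect_error(oligomer_scene_builder(sizes = c(2), bound = TRUE,
                                      inhibitor = FALSE), "inhibitor")
})

test_that("brownian toy: ideal gas stays monomeric, sticky chains clump", {
  # zero attraction: no oligomers emerge
  b0 <- brownian_toy_sim(n_peptides = 6, peptide_length = 8,
                         box_edge = 60, eps_pp = 0, inhibitor = FALSE,
                         n_steps = 3000, save_every = 300, seed = 5)
  st <- aggregation_states(b0$trajectory)
  frac_oligo <- mean(vapply(st, function(s)
    sum(lengths(s$oligomers) > 1) > 0, logical(1)))
  expect_lt(frac_oligo, 0.35)
  # strong attraction in a small box: large clusters emerge
  sizes_end <- vapply(0:2, function(s) {
    b1 <- brownian_toy_sim(n_peptides = 6, peptide_length = 8,
                           box_edge = 38, eps_pp = 5, inhibitor = FALSE,
                           n_steps = 16000, save_every = 1000,
                           seed = 60 + s)
    st1 <- aggregation_states(b1$trajectory)
    max(lengths(st1[[length(st1)]]$oligomers))
  }, numeric(1))
  expect_gt(mean(sizes_end), 2.5)
  # unstable step is reported, not silently produced
  expect_error(brownian_toy_sim(n_peptides = 2, peptide_length = 4,
                                box_edge = 40, eps_pp = 50,
                                inhibitor = FALSE, dt = 0.5,
                                n_steps = 200, save_every = 100,
                                seed = 1),
               "unstable")
})

test_that("generator templates respect the placement constraints", {
  sc <- kinetic_scenario(n_peptides = 6, k_on = 0.1, k_off = 0.1,
                         n_frames = 50, dt = 0.5, seed = 91)
  g <- markov_binding_generator(sc)
  tr <- g$trajectory
  inh_sel <- select_atoms(tr$model, role = "inhibitor")
  for (f in c(1, 25, 50)) {
    cnt <- residue_contacts(get_frame(tr, f), tr$model)$chain_counts
    inh_cnt <- colSums(cnt[c("X", "Y"), chains_by_role(tr$model, "peptide")])
    bound <- g$truth$bound[f, ]
    expect_true(all(inh_cnt[bound] > 5))
    expect_true(all(inh_cnt[!bound] == 0))
  }
  expect_error(kinetic_scenario(box_edge = 40), "box too small")
})
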