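test_that("contact cutoff is inclusive and minimum-image aware", {
  m <- make_bead_model(list(list(id = "A", role = "peptide", n = 1),
                            list(id = "B", role = "peptide", n = 1)))
  box <- rep(124, 3)
  rec <- function(d) residue_contacts(
    frame(0, rbind(c(10, 10, 10), c(10 + d, 10, 10)), box), m)
  expect_equal(nrow(rec(4.9)$pairs), 1)
  expect_equal(nrow(rec(5.0)$pairs), 1)   # boundary counts as contact
  expect_equal(nrow(rec(5.1)$pairs), 0)
  # atoms at x = 1 and x = 123 in a 124 A box: image distance 2 A
  wrap <- residue_contacts(frame(0, rbind(c(1, 5, 5), c(123, 5, 5)), box),
                           m)
  expect_equal(nrow(wrap$pairs), 1)
  nowrap <- residue_contacts(frame(0, rbind(c(1, 5, 5), c(123, 5, 5)),
                                   box), m,
                             contact_config(minimum_image = FALSE))
  expect_equal(nrow(nowrap$pairs), 0)
})

test_that("small boxes trigger an image-ambiguity warning, not an error", {
  m <- make_bead_model(list(list(id = "A", role = "peptide", n = 1),
                            list(id = "B", role = "peptide", n = 1)))
  expect_warning(
    residue_contacts(frame(0, rbind(c(0, 0, 0), c(3, 0, 0)), rep(8, 3)),
                     m),
    "minimum-image")
})

test_that("neighbor-search kernel matches the brute-force oracle", {
  for (seed in 1:20) {
    fx <- random_contact_fixture(n_res = 50, box_edge = 22, seed = seed)
    oracle <- residue_contacts_brute(fx$frame, fx$model)
    for (method in c("auto", "cells", "brute")) {
      got <- residue_contacts(fx$frame, fx$model,
                              contact_config(method = method))
      expect_same_pairs(got$pairs, oracle)
    }
  }
})

test_that("contacts are invariant under lattice translations", {
  for (seed in 1:5) {
    fx <- random_contact_fixture(n_res = 40, box_edge = 25, seed = seed)
    ref <- residue_contacts(fx$frame, fx$model)
    shift <- matrix(rep(25 * c(2, -1, 3), each = fx$model$natoms), ncol = 3)
    fr2 <- frame(0, fx$frame$xyz + shift, fx$frame$box)
    got <- residue_contacts(fr2, fx$model)
    expect_identical(ref$pairs, got$pairs)
    expect_identical(ref$chain_counts, got$chain_counts)
  }
})

test_that("chain-pair counts are exact, symmetric and additive", {
  # chain A and B with exactly 7 crafted cross-chain contacts
  m <- make_bead_model(list(list(id = "A", role = "peptide", n = 10),
                            list(id = "B", role = "peptide", n = 10),
                            list(id = "C", role = "peptide", n = 2)))
  xyz <- matrix(0, 22, 3)
  xyz[1:10, 2] <- (0:9) * 20          # chain A spread out along y
  xyz[11:20, 2] <- (0:9) * 20         # chain B opposite
  xyz[11:20, 1] <- 200                # far by default
  xyz[11:17, 1] <- 3                  # first 7 B residues near their A twin
  xyz[21:22, ] <- 400                 # chain C far away
  fr <- frame(0, xyz, rep(1000, 3))
  rec <- residue_contacts(fr, m)
  expect_equal(chain_pair_contact_count(rec, "A", "B"), 7)
  expect_equal(chain_pair_contact_count(rec, "B", "A"), 7)
  expect_equal(chain_pair_contact_count(rec, "A", "C"), 0)
  expect_equal(chain_pair_contact_count(rec, "A", c("B", "C")),
               chain_pair_contact_count(rec, "A", "B") +
                 chain_pair_contact_count(rec, "A", "C"))
  expect_error(chain_pair_contact_count(rec, c("A", "B"), "B"),
               "disjoint")
  # oracle agreement on the crafted geometry
  expect_same_pairs(rec$pairs, residue_contacts_brute(fr, m))
})

test_that("atom-pair counting is available behind the count switch", {
  m <- make_bead_model(list(list(id = "A", role = "peptide", n = 1),
                            list(id = "B", role = "peptide", n = 1)))
  # single residue pair, one atom each -> residue count 1, atom count 1
  fr <- frame(0, rbind(c(0, 0, 0), c(3, 0, 0)), rep(100, 3))
  rec <- residue_contacts(fr, m)
  expect_equal(chain_pair_contact_count(rec, "A", "B", count = "atom"), 1)
})

test_that("contact-count distributions are normalized and recover modes", {
  m <- synthetic_system_model(n_peptides = 2, inhibitor = FALSE)
  # synthetic counts array: pair always at 8 contacts
  nf <- 50
  counts <- array(0L, c(2, 2, nf), dimnames = list(c("A", "B"),
                                                   c("A", "B"), NULL))
  counts[1, 2, ] <- counts[2, 1, ] <- 8L
  d <- contact_count_distribution(counts, "peptide-peptide", model = m)
  expect_equal(d$count, 8)
  expect_equal(d$probability, 1)
  # two-population ensemble: counts 6-10 and 20-30
  set.seed(1)
  lo <- sample(6:10, nf, replace = TRUE)
  hi <- sample(20:30, nf, replace = TRUE)
  counts[1, 2, ] <- counts[2, 1, ] <- ifelse(seq_len(nf) %% 2 == 0, lo, hi)
  d2 <- contact_count_distribution(counts, "peptide-peptide", model = m)
  expect_equal(sum(d2$probability), 1, tolerance = 1e-12)
  expect_true(any(d2$count <= 10) && any(d2$count >= 20))
  expect_false(any(d2$count > 10 & d2$count < 20))
  # pairs at or below the threshold never enter
  counts[1, 2, ] <- counts[2, 1, ] <- 5L
  expect_null(contact_count_distribution(counts, "peptide-peptide",
                                         model = m))
})
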