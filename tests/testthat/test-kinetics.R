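make_bs <- function(b, dt = 0.5) {
  b <- as.matrix(b)
  structure(list(times = (seq_len(nrow(b)) - 1) * dt, dt = dt, b = b,
                 peptides = colnames(b)), class = "bound_series")
}

test_that("short-excursion bridging follows the strict < t0 rule", {
  expect_equal(bridge_excursions(c(1, 0, 1), t0 = 1, dt = 0.5),
               c(1, 1, 1))                      # 0.5 ns gap < 1 ns
  expect_equal(bridge_excursions(c(1, 0, 0, 1), t0 = 1, dt = 0.5),
               c(1, 0, 0, 1))                   # 1.0 ns gap, not < t0
  expect_equal(bridge_excursions(rep(1, 6), t0 = 1, dt = 0.5), rep(1, 6))
  # leading/trailing zero runs are never bridged
  expect_equal(bridge_excursions(c(0, 1, 0, 1, 0), t0 = 1, dt = 0.5),
               c(0, 1, 1, 1, 0))
  # t0 = 0 is the strict continuous-occupancy limit
  expect_equal(bridge_excursions(c(1, 0, 1), t0 = 0, dt = 0.5),
               c(1, 0, 1))
})

test_that("survival correlation has the documented limits and semantics", {
  # single peptide bound at every frame
  sv <- survival_correlation(make_bs(matrix(1, 20, 1)),
                             kinetics_config(t0 = 0))
  expect_true(all(sv$S == 1))
  # no peptide ever bound
  sv0 <- survival_correlation(make_bs(matrix(0, 20, 2)),
                              kinetics_config(t0 = 0))
  expect_true(all(sv0$S == 0))
  expect_null(mean_residence_time(sv0))
  # S(0) equals the average number of simultaneously bound peptides
  set.seed(2)
  b <- matrix(rbinom(200, 1, 0.4), 50, 4)
  sv2 <- survival_correlation(make_bs(b), kinetics_config(t0 = 0))
  expect_equal(attr(sv2, "S0"), mean(rowSums(b)))
  # S is non-increasing and bounded by N
  expect_true(all(diff(sv2$S) <= 1e-12))
  expect_true(all(sv2$S >= 0 & sv2$S <= 4))
  expect_error(survival_correlation(make_bs(b),
                                    kinetics_config(max_lag = 100)),
               "max lag")
})

test_that("fast survival path matches the direct-definition oracle", {
  set.seed(31)
  for (i in 1:5) {
    b <- matrix(rbinom(40 * 3, 1, 0.5), 40, 3)
    bs <- make_bs(b, dt = 0.2)
    sv <- survival_correlation(bs, kinetics_config(t0 = 0))
    expect_equal(sv$S, survival_oracle(b, 0.2), tolerance = 1e-12)
    # strided origins agree with the strided oracle
    sv2 <- survival_correlation(bs, kinetics_config(t0 = 0,
                                                    origin_stride = 3))
    expect_equal(sv2$S, survival_oracle(b, 0.2, origins_stride = 3),
                 tolerance = 1e-12)
  }
})

test_that("bridging can only increase the survival curve", {
  set.seed(17)
  b <- matrix(rbinom(300, 1, 0.6), 100, 3)
  bs <- make_bs(b, dt = 0.5)
  s_strict <- survival_correlation(bs, kinetics_config(t0 = 0))
  s_b1 <- survival_correlation(bs, kinetics_config(t0 = 1))
  s_b2 <- survival_correlation(bs, kinetics_config(t0 = 2))
  expect_true(all(s_b1$S >= s_strict$S - 1e-12))
  expect_true(all(s_b2$S >= s_b1$S - 1e-12))
})

test_that("residence-time estimators invert an exact exponential", {
  tau <- 10
  lag <- seq(0, 60, by = 0.2)
  curve <- structure(
    data.frame(lag_ns = lag, S = exp(-lag / tau),
               S_norm = exp(-lag / tau), n_origins = rep(100,
                                                         length(lag))),
    class = c("survival_curve", "data.frame"), N = 1, S0 = 1, dt = 0.2)
  expect_equal(as.numeric(mean_residence_time(curve, "exp_fit")), tau,
               tolerance = 0.01)
  ti <- mean_residence_time(curve, "integral")
  expect_equal(as.numeric(ti), tau, tolerance = 0.01)
  expect_false(attr(ti, "lower_bound"))
  # constant S: the integral is a censored lower bound
  flat <- structure(
    data.frame(lag_ns = lag, S = rep(2, length(lag)),
               S_norm = rep(1, length(lag)),
               n_origins = rep(100, length(lag))),
    class = c("survival_curve", "data.frame"), N = 2, S0 = 2, dt = 0.2)
  tf <- mean_residence_time(flat, "integral")
  expect_true(attr(tf, "lower_bound"))
  expect_equal(as.numeric(tf), max(lag))
})

test_that("bound series from the generator match ground truth exactly", {
  sc <- kinetic_scenario(n_peptides = 5, k_on = 0.1, k_off = 0.1,
                         n_frames = 500, dt = 0.2, seed = 13)
  g <- markov_binding_generator(sc)
  bs <- bound_series(g$trajectory)
  expect_equal(unname(bs$b), unname(g$truth$bound * 1L))
  # threshold semantics: a count of exactly 5 is unbound
  cmat <- matrix(5L, nrow = 1, ncol = 10)
  rownames(cmat) <- "P01"
  bs5 <- bound_series(cmat, times = seq(0, 0.9, 0.1))
  expect_true(all(bs5$b == 0))
})

test_that("survival analysis recovers the generator residence time", {
  k_off <- 0.2
  taus <- vapply(1:2, function(s) {
    sc <- kinetic_scenario(k_on = 0.02, k_off = k_off, dt = 0.1,
                           n_frames = 8000, seed = 100 + s)
    g <- markov_binding_generator(sc)
    sv <- survival_correlation(bound_series(g$trajectory),
                               kinetics_config(t0 = 1, max_lag = 25))
    as.numeric(mean_residence_time(sv, "exp_fit"))
  }, numeric(1))
  expect_equal(mean(taus), 1 / k_off, tolerance = 0.15)
})
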