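test_that("pairwise Förster rates follow the sixth-power law", {
  ph <- mono_photo(tau = 1, r0 = 5)
  expect_equal(pairwise_rate(5, ph), 1)
  expect_equal(pairwise_rate(10, ph), 1 / 64)
  ph3 <- mono_photo(tau = 3, r0 = 5)
  expect_equal(pairwise_rate(4, ph3), (5 / 4)^6 / 3, tolerance = 1e-12)
  r <- seq(1, 12, by = 0.5)
  expect_true(all(diff(pairwise_rate(r, ph)) < 0))
  expect_error(pairwise_rate(0, ph), "positive")
})

test_that("donor total rates sum in-plane and cross-leaflet contributions", {
  ph <- mono_photo(tau = 1, r0 = 5)
  don <- tibble::tibble(x = 50, y = 50, leaflet = 0L)
  # no acceptors
  f0 <- manual_field(don, tibble::tibble(x = numeric(), y = numeric(),
                                         leaflet = integer()))
  expect_equal(donor_total_rate(f0, ph), 0)
  # one acceptor at exactly R0 in-plane
  f1 <- manual_field(don, tibble::tibble(x = 55, y = 50, leaflet = 0L))
  expect_equal(donor_total_rate(f1, ph), 1, tolerance = 1e-12)
  # acceptors at R0 and 2 R0
  f2 <- manual_field(don, tibble::tibble(x = c(55, 60), y = 50,
                                         leaflet = c(0L, 0L)))
  expect_equal(donor_total_rate(f2, ph), 1 + 1 / 64, tolerance = 1e-12)
  # cross-leaflet distance is sqrt(rho^2 + h^2)
  f3 <- manual_field(don, tibble::tibble(x = 53, y = 50, leaflet = 1L), h = 4)
  expect_equal(donor_total_rate(f3, ph), (25 / (9 + 16))^3, tolerance = 1e-12)
  # minimum image: acceptor across the periodic boundary
  f4 <- manual_field(don, tibble::tibble(x = 99, y = 50, leaflet = 0L),
                     box_side = 100)
  expect_equal(donor_total_rate(f4, ph), (25 / 49^2)^3, tolerance = 1e-12)
})

test_that("transfer-time sampling is exponential with mean 1/Omega", {
  expect_equal(sample_transfer_time(2, gamma = exp(-1)), 0.5)
  expect_lt(sample_transfer_time(2, gamma = 1 - 1e-12), 1e-11)
  expect_equal(sample_transfer_time(0, gamma = 0.5), Inf)
  set.seed(1)
  draws <- sample_transfer_time(rep(0.4, 1e5))
  expect_lt(abs(mean(draws) - 2.5), 3 * 2.5 / sqrt(1e5))
  expect_error(sample_transfer_time(1, gamma = 0), "gamma")
  expect_error(sample_transfer_time(-1), "omega")
})

test_that("simulated survival satisfies its invariants and is reproducible", {
  ph <- photophysics()
  g1 <- simulate_survival(ph, r_d = 8, ar = 0.37, k_d_donor = 10,
                          n_events = 5000, seed = 21)
  expect_equal(g1$g[1], 1)
  expect_monotone_nonincreasing(g1$g)
  expect_true(all(g1$g > 0 | g1$g == 0))
  g2 <- simulate_survival(ph, r_d = 8, ar = 0.37, k_d_donor = 10,
                          n_events = 5000, seed = 21)
  expect_identical(g1$g, g2$g)
})

test_that("histogram survival matches its exact per-scene expectation", {
  ph <- photophysics()
  n <- 5e4
  g <- simulate_survival(ph, r_d = 8, ar = 0.4, k_d_donor = 10,
                         n_events = n, bins = 100, seed = 31,
                         keep_rates = TRUE)
  omega <- attr(g, "omega")
  oracle <- rowMeans(vapply(omega,
                            function(w) colMeans(exp(-outer(w, g$time))),
                            numeric(nrow(g))))
  bound <- 4 * sqrt(pmax(oracle * (1 - oracle), 0) / n) + 1e-12
  expect_true(all(abs(g$g - oracle) <= bound))
})

test_that("expectation estimator agrees with the event histogram", {
  ph <- photophysics()
  gh <- simulate_survival(ph, r_d = 8, ar = 0.4, k_d_donor = 10,
                          n_events = 3e4, bins = 100, seed = 44)
  ge <- simulate_survival(ph, r_d = 8, ar = 0.4, k_d_donor = 10,
                          n_events = 3e4, bins = 100, seed = 44,
                          method = "expectation")
  bound <- 4 * sqrt(pmax(ge$g * (1 - ge$g), 0) / 3e4) + 1e-12
  expect_true(all(abs(gh$g - ge$g) <= bound))
})

test_that("domain-blind probes (K_D = 1) give domain-independent decays", {
  ph <- photophysics()
  n <- 3e4
  g_dom <- simulate_survival(ph, r_d = 8, ar = 0.4, k_d_donor = 1,
                             n_events = n, bins = 100, seed = 51)
  g_hom <- simulate_survival(ph, ar = 0, k_d_donor = 1,
                             n_events = n, bins = 100, seed = 52)
  bound <- 4 * sqrt(2 * pmax(g_hom$g * (1 - g_hom$g), 0) / n) + 1e-12
  expect_true(all(abs(g_dom$g - g_hom$g) <= bound))
})

test_that("probe redistribution shifts FRET in the expected directions", {
  # donors into domains with acceptors excluded separates the pair and slows
  # the decay; co-enrichment of both species speeds it up
  ph <- photophysics()
  d0 <- compose_decay(NULL, ph, poisson = FALSE)
  ee <- vapply(list(hom = c(1, 1), sep = c(20, 0.05), both = c(20, 20)),
               function(k) {
    g <- simulate_survival(ph, r_d = 8, ar = 0.4, k_d_donor = k[1],
                           k_d_acceptor = k[2], n_events = 5000, seed = 61,
                           method = "expectation")
    fret_efficiency(compose_decay(g, ph, poisson = FALSE), d0)
  }, numeric(1))
  expect_lt(ee[["sep"]], ee[["hom"]])
  expect_gt(ee[["both"]], ee[["hom"]])
})

test_that("decay composition, scaling and noise behave as specified", {
  ph <- mono_photo(tau = 3, r0 = 5)
  d <- compose_decay(NULL, ph, total_counts = 1e6, poisson = FALSE,
                     window = 30, bins = 300)
  shape <- exp(-d$time / 3)
  expect_equal(d$counts / d$counts[1], shape / shape[1], tolerance = 1e-12)
  expect_equal(sum(d$counts), 1e6)

  # deterministic without noise, Poisson counts within 5 sigma with it
  d2 <- compose_decay(NULL, ph, total_counts = 1e6, poisson = FALSE,
                      window = 30, bins = 300)
  expect_identical(d$counts, d2$counts)
  dn <- compose_decay(NULL, ph, total_counts = 1e6, poisson = TRUE,
                      seed = 5, window = 30, bins = 300)
  expect_true(all(abs(dn$counts - d$counts) <= 5 * sqrt(d$counts) + 5))

  # a delta-function IRF leaves the decay unchanged; mismatched grids fail
  irf <- tibble::tibble(time = d$time,
                        counts = c(1, rep(0, nrow(d) - 1)))
  dc <- compose_decay(NULL, ph, irf = irf, total_counts = 1e6,
                      poisson = FALSE, window = 30, bins = 300)
  expect_equal(dc$counts, d$counts, tolerance = 1e-9)
  bad_irf <- tibble::tibble(time = 1:10, counts = rep(1, 10))
  expect_error(compose_decay(NULL, ph, irf = bad_irf, window = 30,
                             bins = 300), "IRF")
})

test_that("FRET efficiency is the amplitude-normalized area deficit", {
  ph <- mono_photo(tau = 3, r0 = 5)
  d0 <- compose_decay(NULL, ph, poisson = FALSE, window = 90, bins = 2048)
  expect_equal(fret_efficiency(d0, d0), 0)
  expect_equal(relative_efficiency(fret_efficiency(d0, d0) + 0.4, 0.4), 1)

  # uniform extra rate 1/3 on tau = 3 halves the mean lifetime: E = 0.5
  da <- d0
  da$counts <- exp(-da$time * (1 / 3 + 1 / 3))
  expect_equal(fret_efficiency(da, d0), 0.5, tolerance = 0.01)
  expect_error(relative_efficiency(0.5, 0), "positive")
})
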