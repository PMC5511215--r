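test_that("reduced chi-squared and its scale factor behave as designed", {
  ph <- mono_photo(tau = 3)
  d <- compose_decay(NULL, ph, total_counts = 1e5, poisson = FALSE,
                     window = 30, bins = 200)
  same <- chi_squared(d, d)
  expect_equal(same$chi2_red, 0)
  expect_equal(same$scale, 1)
  # intensity scaling is absorbed analytically
  d2 <- d
  d2$counts <- d$counts * 2
  expect_equal(chi_squared(d2, d)$chi2_red, 0, tolerance = 1e-12)
  expect_equal(chi_squared(d2, d)$scale, 0.5, tolerance = 1e-12)
  # Poisson data around the model gives chi2_red near 1
  dn <- compose_decay(NULL, ph, total_counts = 1e6, poisson = TRUE,
                      seed = 3, window = 12, bins = 400)
  m <- compose_decay(NULL, ph, total_counts = 1e6, poisson = FALSE,
                     window = 12, bins = 400)
  expect_lt(abs(chi_squared(m, dn)$chi2_red - 1), 4 * sqrt(2 / 400))
  zero <- d
  zero$counts <- rep(0, nrow(d))
  expect_error(chi_squared(d, zero), "zero")
})

test_that("homogeneous data produce a flat, degenerate surface", {
  ph <- photophysics()
  surv <- simulate_survival(ph, ar = 0, n_events = 3e4, seed = 5)
  data <- compose_decay(surv, ph, total_counts = 1e6, poisson = TRUE,
                        seed = 6)
  fit <- grid_fit(data, ph, r_d_grid = c(4, 8, 12), ar_grid = c(0, 0.2, 0.4),
                  k_d_grid = c(1, 5, 20), n_events = 500, n_donors = 100,
                  seed = 7)
  expect_true(fit$degenerate)
  expect_true(all(profile_uncertainty(fit, 0.05)$unbounded))
})

test_that("grid fits are deterministic and report ordered local minima", {
  ph <- photophysics()
  surv <- simulate_survival(ph, r_d = 8, ar = 0.37, k_d_donor = 10,
                            n_events = 3e4, seed = 15)
  data <- compose_decay(surv, ph, total_counts = 1e6, poisson = TRUE,
                        seed = 16)
  grids <- list(r_d_grid = c(4, 8, 12, 16), ar_grid = c(0.2, 0.35, 0.5),
                k_d_grid = c(5, 10, 20))
  f1 <- grid_fit(data, ph, r_d_grid = grids$r_d_grid,
                 ar_grid = grids$ar_grid, k_d_grid = grids$k_d_grid,
                 n_events = 500, n_donors = 100, seed = 17)
  f2 <- grid_fit(data, ph, r_d_grid = grids$r_d_grid,
                 ar_grid = grids$ar_grid, k_d_grid = grids$k_d_grid,
                 n_events = 500, n_donors = 100, seed = 17)
  expect_identical(f1$surface, f2$surface)
  expect_identical(f1$minima, f2$minima)
  expect_gte(nrow(f1$minima), 1)
  expect_true(!is.unsorted(f1$minima$chi2_red))
  # reported minima form the near-degenerate set around the best one
  expect_true(all(f1$minima$chi2_red <= min(f1$minima$chi2_red) + f1$delta))
  # the best minimum sits on the chi-squared valley through the truth:
  # its area fraction tracks the generated 0.37 coverage
  expect_lte(abs(glance(f1)$ar - 0.37), 0.15)
})

test_that("profile intervals collapse at zero threshold and contain the estimate", {
  ph <- photophysics()
  surv <- simulate_survival(ph, r_d = 8, ar = 0.37, k_d_donor = 10,
                            n_events = 3e4, seed = 25)
  data <- compose_decay(surv, ph, total_counts = 1e6, poisson = TRUE,
                        seed = 26)
  fit <- grid_fit(data, ph, r_d_grid = c(4, 8, 12), ar_grid = c(0.2, 0.35, 0.5),
                  k_d_grid = c(5, 10), n_events = 500, n_donors = 100,
                  seed = 27, refine = FALSE)
  iv0 <- profile_uncertainty(fit, 0)
  expect_equal(iv0$low, iv0$estimate)
  expect_equal(iv0$high, iv0$estimate)
  iv <- profile_uncertainty(fit, 0.05)
  expect_true(all(iv$low <= iv$estimate & iv$estimate <= iv$high))
})

test_that("tidy, glance and surface export expose the fit", {
  ph <- photophysics()
  surv <- simulate_survival(ph, r_d = 8, ar = 0.37, k_d_donor = 10,
                            n_events = 2e4, seed = 35)
  data <- compose_decay(surv, ph, total_counts = 1e6, poisson = TRUE,
                        seed = 36)
  fit <- grid_fit(data, ph, r_d_grid = c(6, 8, 10), ar_grid = c(0.3, 0.4),
                  k_d_grid = c(10), n_events = 500, n_donors = 100,
                  seed = 37, refine = FALSE)
  expect_identical(tidy(fit), fit$minima)
  gl <- glance(fit)
  expect_equal(gl$n_nodes, 6L)
  expect_s3_class(autoplot(fit), "ggplot")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_surface_tsv(fit, path)
  surf <- utils::read.delim(path)
  expect_equal(nrow(surf), 6L)
})
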