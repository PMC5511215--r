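test_that("domain placement hits the requested count and area fraction", {
  lay <- place_domains(200, r_d = 8, ar = 0.37, seed = 42)
  expect_equal(lay$n_domains, 74)  # round(0.37 * 200^2 / (pi * 64))
  expect_equal(lay$ar_achieved, 74 * pi * 64 / 200^2, tolerance = 1e-12)
  expect_lte(abs(lay$ar_achieved - 0.37), pi * 64 / 200^2)

  empty <- place_domains(200, r_d = 8, ar = 0, seed = 42)
  expect_equal(empty$n_domains, 0)
  expect_equal(empty$ar_achieved, 0)
})

test_that("domains never overlap under the minimum-image convention", {
  for (ar in c(0.2, 0.45, 0.6)) {
    lay <- place_domains(160, r_d = 8, ar = ar, seed = 7)
    cen <- as.matrix(lay$centers)
    n <- nrow(cen)
    dx <- abs(outer(cen[, 1], cen[, 1], "-"))
    dy <- abs(outer(cen[, 2], cen[, 2], "-"))
    dx <- pmin(dx, lay$box_side - dx)
    dy <- pmin(dy, lay$box_side - dy)
    d <- sqrt(dx^2 + dy^2)
    diag(d) <- Inf
    expect_gte(min(d), 2 * lay$r_d - 1e-9)
  }
})

test_that("invalid placement inputs are rejected", {
  expect_error(place_domains(15, r_d = 2, ar = 0.3), "box_side")
  expect_error(place_domains(200, r_d = 1, ar = 0.3), "r_d")
  expect_error(place_domains(200, r_d = 8, ar = 0.7), "ar")
  # starved packing effort must fail loudly, not under-fill
  expect_error(
    place_domains(100, r_d = 8, ar = 0.6, seed = 1, max_fail = 5,
                  relax_sweeps = 1, max_rounds = 1),
    "packing unreachable"
  )
})

test_that("same seed reproduces layouts and probe fields bit-identically", {
  a <- place_domains(150, r_d = 6, ar = 0.4, seed = 11)
  b <- place_domains(150, r_d = 6, ar = 0.4, seed = 11)
  expect_identical(a$centers, b$centers)

  pa <- place_probes(a, 500, 500, k_d_donor = 5, seed = 3)
  pb <- place_probes(b, 500, 500, k_d_donor = 5, seed = 3)
  expect_identical(as.data.frame(pa), as.data.frame(pb))
})

test_that("partition probability follows the area-weighted law", {
  expect_equal(partition_probability(1, 0.37), 0.37)
  expect_equal(partition_probability(10, 0.37), 3.7 / (3.7 + 0.63),
               tolerance = 1e-12)
  expect_equal(partition_probability(20, 0.45), 9 / 9.55, tolerance = 1e-12)
  # monotone in K_D
  k <- c(0, 0.5, 1, 2, 5, 20, 100)
  expect_true(all(diff(partition_probability(k, 0.3)) > 0))
  expect_error(partition_probability(-1, 0.3), "k_d")
  expect_error(partition_probability(2, 1), "ar")
})

test_that("probe inside-fractions converge to the partition law", {
  lay <- place_domains(150, r_d = 8, ar = 0.45, seed = 5)
  n <- 1e5
  for (k in c(1, 20)) {
    pf <- place_probes(lay, n, 10, k_d_donor = k, k_d_acceptor = 1, seed = 8)
    don <- pf[pf$species == "donor", ]
    p <- partition_probability(k, lay$ar_achieved)
    expect_lt(abs(mean(don$inside) - p), 4 * sqrt(p * (1 - p) / n))
    # flags agree with a geometric point-in-domain test
    inside_geo <- mcfret:::cpp_in_domains(don$x, don$y,
                                          as.matrix(lay$centers),
                                          lay$box_side, lay$r_d)
    expect_true(all(don$inside == inside_geo))
    # leaflets split evenly
    expect_lt(abs(mean(don$leaflet) - 0.5), 4 * sqrt(0.25 / n))
  }
  # extreme partitioning drives every probe inside
  pf <- place_probes(lay, 2000, 10, k_d_donor = 1e6, seed = 9)
  expect_true(all(pf$inside[pf$species == "donor"]))
})

test_that("scenes round-trip through JSON", {
  lay <- place_domains(120, r_d = 6, ar = 0.3, seed = 2)
  pf <- place_probes(lay, 40, 60, k_d_donor = 3, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_scene_json(pf, path)
  back <- read_scene_json(path)
  expect_equal(as.data.frame(back), as.data.frame(pf))
  expect_equal(attr(back, "layout")$centers, lay$centers)
  expect_equal(attr(back, "h"), attr(pf, "h"))
})
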