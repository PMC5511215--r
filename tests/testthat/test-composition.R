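test_that("ternary nanodomain lipid counts match the published arithmetic", {
  comp <- bilayer_composition(65, 10, 25)
  counts <- domain_lipid_counts(comp, r_d = 9, ar = 0.45)
  n_sites <- pi * 81 / 0.72
  expect_equal(attr(counts, "n_sites"), n_sites, tolerance = 1e-12)
  get <- function(sp, col) counts[[col]][counts$species == sp]
  expect_equal(get("dopc", "count"), n_sites * 0.65, tolerance = 1e-12)
  expect_equal(get("chol", "count"), n_sites * 0.25 / 0.45, tolerance = 1e-12)
  expect_equal(get("sm", "count"), n_sites * 0.10 / 0.45, tolerance = 1e-12)
  expect_equal(get("dopc", "molecules"), 230)
  expect_equal(get("chol", "molecules"), 196)
  expect_equal(get("sm", "molecules"), 79)
  ratios <- domain_ratios(counts)
  expect_equal(ratios$dopc_sm, 0.65 * 0.45 / 0.10, tolerance = 1e-12)  # 2.925
  expect_equal(ratios$chol_sm, 2.5, tolerance = 1e-12)
})

test_that("binary counts use the means of the two fitted minima", {
  comp <- bilayer_composition(90, 10, 0)
  counts <- domain_lipid_counts(comp, r_d = 10, ar = 0.46)
  get <- function(sp) counts$molecules[counts$species == sp]
  expect_equal(get("dopc"), 393)
  expect_equal(get("sm"), 95)
  expect_equal(domain_ratios(counts)$dopc_sm, 0.9 * 0.46 / 0.1,
               tolerance = 1e-12)  # 4.14
  expect_true(is.na(domain_ratios(counts)$chol_sm))
})

test_that("degenerate compositions are handled explicitly", {
  comp0 <- bilayer_composition(100, 0, 0)
  counts <- domain_lipid_counts(comp0, r_d = 9, ar = 0.45)
  expect_equal(counts$molecules[counts$species == "sm"], 0)
  expect_warning(r <- domain_ratios(counts), "undefined")
  expect_true(is.na(r$dopc_sm))
  # confined species need domains to live in
  expect_error(domain_lipid_counts(bilayer_composition(90, 10), 9, 0),
               "ar = 0")
  expect_error(bilayer_composition(-1, 2))
})

test_that("confined fractions exceeding the domain area are flagged", {
  comp <- bilayer_composition(65, 10, 25)  # confined sum 0.35
  expect_warning(
    counts <- domain_lipid_counts(comp, r_d = 9, ar = 0.2),
    "inconsistent"
  )
  expect_false(attr(counts, "consistent"))
  expect_true(attr(domain_lipid_counts(comp, 9, 0.45), "consistent"))
})

test_that("count identities hold across random parameter draws", {
  set.seed(9)
  for (i in 1:25) {
    fr <- runif(3)
    comp <- bilayer_composition(fr[1], fr[2], fr[3])
    x <- comp$fraction
    ar <- runif(1, sum(x[2:3]), 0.99)  # keep the confined set feasible
    a <- runif(1, 0.4, 1.1)
    r_d <- runif(1, 4, 20)
    counts <- domain_lipid_counts(comp, r_d, ar, a)
    ratios <- domain_ratios(counts)
    # Chol:SM depends only on the global fractions when both are confined
    expect_equal(ratios$chol_sm, x[3] / x[2], tolerance = 1e-9)
    # counts scale as R_D^2 and 1/a
    c2 <- domain_lipid_counts(comp, 2 * r_d, ar, a)
    expect_equal(c2$count, 4 * counts$count, tolerance = 1e-9)
    c3 <- domain_lipid_counts(comp, r_d, ar, 2 * a)
    expect_equal(c3$count, counts$count / 2, tolerance = 1e-9)
  }
})
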