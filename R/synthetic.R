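#' Catalogue of synthetic GUV scenario presets
#'
#' Ground-truth scenarios emulating the studied lipid mixtures: homogeneous
#' binary and ternary bilayers and the nanodomain-containing compositions
#' with the radius, area fraction and partition coefficients recovered for
#' each donor/acceptor pair. Every generated fixture records its truth, so
#' the forward-simulate/fit round trip can be closed in tests.
#'
#' @return A tibble with one row per preset: `label`, composition
#'   (`dopc`, `sm`, `chol`, mol%), truth (`r_d` nm, `ar`, `k_d`; `NA`/0 for
#'   homogeneous bilayers) and the probe pair the scenario mimics.
#' @examples
#' scenario_presets()
#' @export
scenario_presets <- function() {
  tibble::tribble(
    ~label,                ~dopc, ~sm, ~chol, ~r_d, ~ar,  ~k_d, ~pair,
    "binary_homogeneous",     92,   8,     0,   NA,    0,     1, "g-GM1/r-GM1",
    "binary_gm1_37",          90,  10,     0,    8, 0.37,    10, "g-GM1/r-GM1",
    "binary_gm1_55",          90,  10,     0,   12, 0.55,    10, "g-GM1/r-GM1",
    "ternary_homogeneous",    75,   0,    25,   NA,    0,     1, "g-GM1/r-GM1",
    "ternary_gm1",            65,  10,    25,    9, 0.45,    20, "g-GM1/r-GM1",
    "ternary_peg",            63,  12,    25,    8, 0.55,     5, "CF-PEG-DSPE/Rh-PEG-DSPE"
  )
}

get_preset <- function(preset) {
  cat <- scenario_presets()
  if (is.character(preset)) {
    row <- cat[cat$label == preset, ]
    if (nrow(row) != 1) abort(sprintf("unknown preset '%s'.", preset))
    row
  } else {
    stopifnot(is.data.frame(preset), nrow(preset) == 1)
    preset
  }
}

#' Generate a synthetic TCSPC decay fixture
#'
#' Runs the forward model for a scenario preset and writes a donor-only
#' decay, a donor+acceptor decay and a machine-readable truth file. The
#' donor-only decay is the intrinsic multi-exponential model with Poisson
#' noise; the donor+acceptor decay composes the Monte Carlo survival
#' function. Byte-identical files are produced for identical seeds.
#'
#' @param preset A preset label from [scenario_presets()] or a one-row tibble
#'   with the same columns.
#' @param dir Output directory (created if missing).
#' @param photo A [photophysics()] object; defaults emulate a 1:200
#'   acceptor-to-lipid loading.
#' @param total_counts Photons per decay.
#' @param n_events,reuse Monte Carlo effort.
#' @param window,bins Time axis (ns, bin count).
#' @param seed Integer seed.
#' @return Invisibly, a list with the file paths (`donor`, `da`, `truth`)
#'   and the in-memory decays.
#' @export
generate_decay_fixture <- function(preset, dir = tempfile("fixture"),
                                   photo = photophysics(),
                                   total_counts = 1e6, n_events = 3e5,
                                   reuse = 100, window = 100, bins = 512,
                                   seed = 1) {
  row <- get_preset(preset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ar <- row$ar
  r_d <- if (is.na(row$r_d)) 8 else row$r_d
  surv <- simulate_survival(photo, r_d = r_d, ar = ar, k_d_donor = row$k_d,
                            k_d_acceptor = row$k_d, n_events = n_events,
                            reuse = reuse, window = window, bins = bins,
                            seed = seed)
  da <- compose_decay(surv, photo, total_counts = total_counts,
                      poisson = TRUE, seed = seed + 1)
  donor <- compose_decay(NULL, photo, total_counts = total_counts,
                         poisson = TRUE, seed = seed + 2, window = window,
                         bins = bins)
  paths <- list(
    donor = file.path(dir, paste0(row$label, "_donor.tsv")),
    da = file.path(dir, paste0(row$label, "_da.tsv")),
    truth = file.path(dir, paste0(row$label, "_truth.json"))
  )
  write_decay(donor, paths$donor,
              meta = list(scenario = row$label, role = "donor_only",
                          seed = seed))
  write_decay(da, paths$da,
              meta = list(scenario = row$label, role = "donor_acceptor",
                          seed = seed))
  truth <- c(as.list(row),
             list(c_a = photo$c_a, r0 = photo$r0,
                  amplitudes = photo$amplitudes, lifetimes = photo$lifetimes,
                  total_counts = total_counts, n_events = n_events,
                  reuse = reuse, window = window, bins = bins, seed = seed))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(donor_decay = donor, da_decay = da, truth = truth)))
}

#' Generate a synthetic z-scan FCS fixture
#'
#' Writes one autocorrelation TSV per z position (dwell times following the
#' z-scan diffusion law, particle numbers growing with the beam
#' cross-section away from the waist, Gaussian noise on G) plus a truth
#' JSON. By default 20 positions spaced 150 nm cover roughly +/- 1.5 um
#' around the waist.
#'
#' @param d Diffusion coefficient truth (um^2/s).
#' @param w0 Beam waist (nm).
#' @param dir Output directory.
#' @param n_z,step Number of z steps and their spacing (nm).
#' @param n0 Mean particle number at the waist.
#' @param noise Relative Gaussian noise on the autocorrelation values.
#' @param wavelength,ref_index Beam parameters for the diffusion law.
#' @param seed Integer seed.
#' @return Invisibly, a list with `files`, the per-z `series` tibble
#'   (columns `z`, `tau`, `n_particles`) and the `truth` list.
#' @export
generate_fcs_fixture <- function(d = 5, w0 = 250, dir = tempfile("fcs"),
                                 n_z = 20, step = 150, n0 = 8,
                                 noise = 0.05, wavelength = 470,
                                 ref_index = 1.33, seed = 1) {
  if (n_z < 5) abort("at least 5 z positions are required.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  z <- (seq_len(n_z) - (n_z + 1) / 2) * step
  series <- zscan_series_model(z, d, w0, n0, wavelength, ref_index)
  lag <- exp(seq(log(1e-5), log(1), length.out = 64))  # s
  files <- character(n_z)
  with_seed(seed, {
    for (i in seq_len(n_z)) {
      g <- acf_2d(lag, series$n_particles[i], series$tau[i] * 1e-3)
      if (noise > 0) g <- g * (1 + stats::rnorm(length(g), 0, noise))
      files[i] <- file.path(dir, sprintf("acf_z%+05d.tsv", as.integer(z[i])))
      write_fcs(tibble::tibble(lag = lag, g = g), files[i],
                meta = list(z_nm = z[i], duration_s = 60))
    }
  })
  truth <- list(d = d, w0 = w0, n0 = n0, n_z = n_z, step = step,
                noise = noise, wavelength = wavelength,
                ref_index = ref_index, seed = seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(files = files, series = series, truth = truth,
                 truth_path = file.path(dir, "truth.json")))
}

# Noiseless dwell-time series under the z-scan diffusion law; tau in ms.
zscan_series_model <- function(z, d, w0, n0 = 8, wavelength = 470,
                               ref_index = 1.33) {
  beam <- 1 + (wavelength * z / (pi * w0^2 * ref_index))^2
  tibble::tibble(
    z = z,
    tau = (w0^2 / (4 * d) * 1e-3) * beam,
    n_particles = n0 * beam
  )
}

#' Synthetic dwell-time series with noise
#'
#' Convenience generator for recovery experiments at the fitted-parameter
#' level: the diffusion-law dwell times with multiplicative Gaussian noise.
#'
#' @inheritParams generate_fcs_fixture
#' @param tau_noise Relative Gaussian noise applied to the dwell times.
#' @return A tibble (`z`, `tau`, `n_particles`) ready for
#'   [zscan_diffusion_fit()].
#' @export
generate_zscan_series <- function(d = 5, w0 = 250, n_z = 20, step = 150,
                                  n0 = 8, tau_noise = 0, wavelength = 470,
                                  ref_index = 1.33, seed = NULL) {
  z <- (seq_len(n_z) - (n_z + 1) / 2) * step
  series <- zscan_series_model(z, d, w0, n0, wavelength, ref_index)
  if (tau_noise > 0) {
    series$tau <- with_seed(seed,
      series$tau * (1 + stats::rnorm(n_z, 0, tau_noise)))
  }
  series
}
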