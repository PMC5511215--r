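# Shared fixtures built in code.

# Mono-exponential donor, convenient for closed-form checks.
mono_photo <- function(tau = 3, r0 = 5, c_a = 0.002) {
  photophysics(r0 = r0, amplitudes = 1, lifetimes = tau, c_a = c_a)
}

# Probe field with hand-placed positions (bypasses random placement) so that
# pair distances are exact.
manual_field <- function(donors, acceptors, box_side = 100, h = 4) {
  layout <- place_domains(box_side, r_d = 2, ar = 0, seed = 1)
  field <- dplyr::bind_rows(
    dplyr::mutate(donors, species = "donor"),
    dplyr::mutate(acceptors, species = "acceptor")
  )
  field$inside <- FALSE
  structure(field, layout = layout, h = h,
            class = c("probe_field", class(field)))
}

expect_monotone_nonincreasing <- function(x, tol = 0) {
  expect_true(all(diff(x) <= tol))
}
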