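#' Place circular nanodomains in a periodic bilayer patch
#'
#' Packs non-overlapping hard disks of radius `r_d` into a periodic square box
#' until the target area fraction `ar` is reached. Packing uses random
#' sequential adsorption followed by small-displacement Metropolis relaxation
#' sweeps, which reaches area fractions up to ~0.6 (plain sequential insertion
#' jams near 0.547). The number of domains is `round(ar * box_side^2 /
#' (pi * r_d^2))`, i.e. the domain number density is `ar / (pi * r_d^2)`.
#'
#' @param box_side Side of the periodic box (nm). Must be at least
#'   `10 * r_d` to keep finite-size effects in check.
#' @param r_d Nanodomain radius (nm), within the 2-50 nm range accessible to
#'   the FRET experiment.
#' @param ar Target fractional bilayer area occupied by nanodomains, in
#'   `[0, 0.6]`.
#' @param seed Optional integer seed; the same seed reproduces the layout
#'   bit-identically.
#' @param max_fail,relax_sweeps,max_rounds Packing effort controls: insertion
#'   attempts tolerated before a relaxation round, displacement sweeps per
#'   round, and the number of rounds before packing is declared unreachable.
#'
#' @return A `domain_layout` object: box side, radius, target and achieved
#'   area fraction, and a tibble of domain centers. `tidy()` returns the
#'   centers.
#' @examples
#' lay <- place_domains(200, r_d = 8, ar = 0.37, seed = 1)
#' lay$n_domains
#' lay$ar_achieved
#' @export
place_domains <- function(box_side, r_d, ar, seed = NULL,
                          max_fail = 5000L, relax_sweeps = 40L,
                          max_rounds = 50L) {
  check_number(r_d, "r_d", lower = 2, upper = 50)
  check_number(ar, "ar", lower = 0, upper = 0.6)
  check_number(box_side, "box_side", lower = 10 * r_d)
  n <- as.integer(round(ar * box_side^2 / (pi * r_d^2)))
  centers <- if (n > 0L) {
    with_seed(seed, cpp_place_domains(box_side, r_d, n, as.integer(max_fail),
                                      as.integer(relax_sweeps),
                                      as.integer(max_rounds)))
  } else {
    matrix(numeric(0), ncol = 2)
  }
  structure(
    list(
      box_side = box_side,
      r_d = r_d,
      ar_target = ar,
      ar_achieved = n * pi * r_d^2 / box_side^2,
      n_domains = n,
      centers = tibble::tibble(x = centers[, 1], y = centers[, 2])
    ),
    class = "domain_layout"
  )
}

#' @export
print.domain_layout <- function(x, ...) {
  cat(sprintf(
    "<domain_layout> %d domains, R_D = %g nm, box = %g nm, Ar = %.4f (target %.4f)\n",
    x$n_domains, x$r_d, x$box_side, x$ar_achieved, x$ar_target
  ))
  invisible(x)
}

#' @export
tidy.domain_layout <- function(x, ...) x$centers

#' @rdname place_domains
#' @param object,x A `domain_layout`.
#' @param ... Ignored.
#' @export
autoplot.domain_layout <- function(object, ...) {
  circ <- tidyr::crossing(object$centers |>
                            dplyr::mutate(id = dplyr::row_number()),
                          theta = seq(0, 2 * pi, length.out = 64)) |>
    dplyr::mutate(
      px = .data$x + object$r_d * cos(.data$theta),
      py = .data$y + object$r_d * sin(.data$theta)
    )
  ggplot2::ggplot(circ, ggplot2::aes(.data$px, .data$py, group = .data$id)) +
    ggplot2::geom_polygon(fill = "grey70", colour = "grey30") +
    ggplot2::coord_fixed(xlim = c(0, object$box_side),
                         ylim = c(0, object$box_side)) +
    ggplot2::labs(x = "x (nm)", y = "y (nm)",
                  title = sprintf("R_D = %g nm, Ar = %.2f", object$r_d,
                                  object$ar_achieved))
}

#' Probability that a probe sits inside the nanodomains
#'
#' Area-weighted partitioning: a probe with partition coefficient `k_d`
#' (surface concentration inside over outside) occupies the domain union,
#' which covers an area fraction `ar`, with probability
#' `k_d * ar / (k_d * ar + 1 - ar)`. `k_d = 1` means no preference and the
#' probability reduces to `ar`.
#'
#' @param k_d Partition (distribution) coefficient, `>= 0`.
#' @param ar Domain area fraction, in `[0, 1)`.
#' @return Probability in `[0, 1]`.
#' @examples
#' partition_probability(10, 0.37)
#' @export
partition_probability <- function(k_d, ar) {
  if (any(k_d < 0)) abort("`k_d` must be non-negative.")
  if (any(ar < 0 | ar >= 1)) abort("`ar` must be in [0, 1).")
  k_d * ar / (k_d * ar + 1 - ar)
}

#' Distribute donor and acceptor probes over a nanodomain layout
#'
#' Each probe is assigned to the domain union with probability
#' [partition_probability()] evaluated at the layout's achieved area fraction,
#' then placed uniformly within the union (inside) or its complement
#' (outside). Leaflets are assigned by a fair binomial split; fluorophore
#' planes of the two leaflets are separated by `h`.
#'
#' @param layout A [place_domains()] layout.
#' @param n_donors,n_acceptors Probe counts (> 0).
#' @param k_d_donor,k_d_acceptor Partition coefficients of the two species.
#' @param h Distance between the two fluorophore planes (nm).
#' @param seed Optional integer seed.
#' @return A `probe_field`: a tibble with columns `species`, `x`, `y`,
#'   `leaflet` (0/1) and `inside`, carrying the layout and `h` as attributes.
#' @examples
#' lay <- place_domains(120, r_d = 8, ar = 0.3, seed = 1)
#' pf <- place_probes(lay, 100, 200, k_d_donor = 10, k_d_acceptor = 10,
#'                    seed = 2)
#' mean(pf$inside[pf$species == "donor"])
#' @export
place_probes <- function(layout, n_donors, n_acceptors, k_d_donor = 1,
                         k_d_acceptor = k_d_donor, h = 4, seed = NULL) {
  stopifnot(inherits(layout, "domain_layout"))
  check_number(n_donors, "n_donors", lower = 1)
  check_number(n_acceptors, "n_acceptors", lower = 1)
  with_seed(seed, {
    field <- purrr::map2(
      c(donor = n_donors, acceptor = n_acceptors),
      c(k_d_donor, k_d_acceptor),
      function(n, k) {
        p_in <- partition_probability(k, layout$ar_achieved)
        pts <- cpp_place_probes(as.matrix(layout$centers), layout$box_side,
                                layout$r_d, as.integer(n), p_in, 100000L)
        tibble::tibble(
          x = pts[, 1], y = pts[, 2],
          leaflet = rbinom(n, 1L, 0.5),
          inside = pts[, 3] > 0
        )
      }
    ) |>
      dplyr::bind_rows(.id = "species")
    structure(field, layout = layout, h = h, class = c("probe_field",
                                                       class(field)))
  })
}

#' Serialize a layout and probe field to JSON
#'
#' Writes box geometry, domain centers and probe positions/flags to a JSON
#' document so a simulated scene can be archived and re-read exactly.
#'
#' @param field A [place_probes()] probe field.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scene_json <- function(field, path) {
  layout <- attr(field, "layout")
  doc <- list(
    box_side = layout$box_side,
    r_d = layout$r_d,
    ar_target = layout$ar_target,
    ar_achieved = layout$ar_achieved,
    h = attr(field, "h"),
    centers = as.data.frame(layout$centers),
    probes = as.data.frame(field)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scene written by [write_scene_json()]
#' @param path JSON file path.
#' @return A `probe_field` with its layout attribute restored.
#' @export
read_scene_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  centers <- tibble::as_tibble(doc$centers)
  if (nrow(centers) == 0) centers <- tibble::tibble(x = numeric(), y = numeric())
  layout <- structure(
    list(box_side = doc$box_side, r_d = doc$r_d, ar_target = doc$ar_target,
         ar_achieved = doc$ar_achieved, n_domains = nrow(centers),
         centers = centers),
    class = "domain_layout"
  )
  field <- tibble::as_tibble(doc$probes)
  structure(field, layout = layout, h = doc$h,
            class = c("probe_field", class(field)))
}
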