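#' Bilayer lipid composition
#'
#' Mole fractions of the bilayer components together with the partitioning
#' assumption used for nanodomain accounting: confined species (by default
#' sphingomyelin and cholesterol) localize exclusively within the
#' nanodomains, homogeneous species (by default DOPC) distribute equally
#' between the domains and the remaining bilayer.
#'
#' @param dopc,sm,chol Mole fractions (or mole percentages; they are
#'   normalized to sum to 1).
#' @param confined Character vector of species confined to the nanodomains.
#' @return A `bilayer_composition` tibble with columns `species`, `fraction`,
#'   `confined`.
#' @examples
#' bilayer_composition(65, 10, 25)
#' @export
bilayer_composition <- function(dopc, sm, chol = 0,
                                confined = c("sm", "chol")) {
  fr <- c(dopc = dopc, sm = sm, chol = chol)
  if (any(fr < 0)) abort("mole fractions must be non-negative.")
  tot <- sum(fr)
  if (tot <= 0) abort("composition is empty.")
  fr <- fr / tot
  bad <- setdiff(confined, names(fr))
  if (length(bad)) abort(paste0("unknown confined species: ",
                                paste(bad, collapse = ", ")))
  out <- tibble::tibble(species = names(fr), fraction = unname(fr),
                        confined = names(fr) %in% confined)
  structure(out, class = c("bilayer_composition", class(out)))
}

#' Lipid molecules per nanodomain
#'
#' Counts lipids within one nanodomain (single leaflet) from the fitted
#' domain radius and area fraction. The domain holds `N_sites = pi R_D^2 / a`
#' lipids at an area per lipid `a`. A homogeneously distributed species
#' contributes `N_sites * x_i`; a species confined exclusively to the domains
#' concentrates all of its bilayer amount into the domain area and
#' contributes `N_sites * x_i / Ar`.
#'
#' @param comp A [bilayer_composition()].
#' @param r_d Domain radius (nm).
#' @param ar Domain area fraction, in (0, 1).
#' @param area_per_lipid Area per lipid `a` (nm^2); default 0.72 (DOPC-like).
#' @return A tibble with one row per species: exact (`count`) and rounded
#'   (`molecules`) counts plus the local in-domain mole fraction. The result
#'   carries a `consistent` attribute: `FALSE` (with a warning) when the
#'   confined fractions exceed the domain area fraction, which would imply
#'   local fractions above 1.
#' @examples
#' bilayer_composition(65, 10, 25) |>
#'   domain_lipid_counts(r_d = 9, ar = 0.45)
#' @export
domain_lipid_counts <- function(comp, r_d, ar, area_per_lipid = 0.72) {
  stopifnot(inherits(comp, "bilayer_composition"))
  check_number(r_d, "r_d", lower = 1e-6)
  check_number(area_per_lipid, "area_per_lipid", lower = 1e-6)
  check_number(ar, "ar", lower = 0, upper = 1)
  if (ar == 0 && any(comp$fraction[comp$confined] > 0))
    abort("confined species cannot be accounted for with `ar = 0`.")
  if (ar == 1) abort("`ar` must be below 1.")
  n_sites <- pi * r_d^2 / area_per_lipid
  out <- comp |>
    dplyr::mutate(
      enrichment = ifelse(.data$confined, 1 / ar, 1),
      count = n_sites * .data$fraction * .data$enrichment,
      molecules = round(.data$count),
      local_fraction = .data$fraction * .data$enrichment
    )
  confined_sum <- sum(comp$fraction[comp$confined])
  consistent <- confined_sum <= ar + 1e-12
  if (!consistent)
    warn(sprintf(paste0("confined fractions (%.3f) exceed the domain area ",
                        "fraction (%.3f): implied local fractions are above 1; ",
                        "parameter set flagged inconsistent."),
                 confined_sum, ar))
  structure(out, n_sites = n_sites, r_d = r_d, ar = ar,
            area_per_lipid = area_per_lipid, consistent = consistent,
            class = c("domain_counts", class(out)))
}

#' Molar ratios within a nanodomain
#'
#' DOPC:SM and Chol:SM molar ratios from the exact (unrounded) per-domain
#' counts. When SM and Chol are both confined, Chol:SM reduces to the ratio
#' of their bilayer mole fractions and is independent of `Ar` and of the area
#' per lipid.
#'
#' @param counts A [domain_lipid_counts()] result.
#' @return A one-row tibble with `dopc_sm` and (when cholesterol is present)
#'   `chol_sm`; ratios with a zero denominator are `NA` with a warning.
#' @export
domain_ratios <- function(counts) {
  stopifnot(inherits(counts, "domain_counts"))
  get <- function(sp) {
    v <- counts$count[counts$species == sp]
    if (length(v) == 0) 0 else v
  }
  sm <- get("sm")
  if (sm == 0) {
    warn("SM count is zero; ratios are undefined.")
    return(tibble::tibble(dopc_sm = NA_real_, chol_sm = NA_real_))
  }
  tibble::tibble(
    dopc_sm = get("dopc") / sm,
    chol_sm = if (get("chol") > 0) get("chol") / sm else NA_real_
  )
}
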