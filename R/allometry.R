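#' Brain tissue densities
#'
#' Neural-tissue densities used to convert brain mass to brain volume:
#' 1.04 g/cm3 for cetaceans and 1.036 g/cm3 for terrestrial artiodactyls
#' (the value measured in humans).
#'
#' @param group `"cetacean"` or `"terrestrial"`.
#' @return Density in g/cm3.
#' @export
brain_density <- function(group = c("cetacean", "terrestrial")) {
  group <- match.arg(group)
  c(cetacean = 1.04, terrestrial = 1.036)[[group]]
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop("`", name, "` must be strictly positive and finite", call. = FALSE)
  }
  invisible(x)
}

#' Brain volume from brain mass
#'
#' @param mass_g Brain mass in grams (> 0); vectorized.
#' @param density Neural tissue density in g/cm3 (see [brain_density()]).
#' @return Brain volume in cm3.
#' @examples
#' brain_volume_from_mass(2948, brain_density("cetacean"))  # 2834.6 cm3
#' @export
brain_volume_from_mass <- function(mass_g, density = brain_density("cetacean")) {
  check_positive(mass_g, "mass_g")
  check_positive(density, "density")
  mass_g / density
}

#' Percent of the endocranial cavity not occupied by brain
#'
#' `100 * (endocranial - brain volume) / endocranial`. The remainder is
#' adnexa (meninges, nerves, vasculature including the rete mirabile) plus
#' cerebrospinal fluid. A negative result (brain volume exceeding the cavity)
#' signals inconsistent inputs and is flagged with a warning rather than an
#' error.
#'
#' @param endocranial_cm3 Measured endocranial volume in cm3 (> 0).
#' @param brain_volume_cm3 Brain volume in cm3 (> 0).
#' @return Percent in \[0, 100\] for consistent inputs.
#' @export
percent_not_occupied <- function(endocranial_cm3, brain_volume_cm3) {
  check_positive(endocranial_cm3, "endocranial_cm3")
  check_positive(brain_volume_cm3, "brain_volume_cm3")
  pct <- 100 * (endocranial_cm3 - brain_volume_cm3) / endocranial_cm3
  if (any(pct < 0)) {
    warning("brain volume exceeds endocranial volume for some records ",
            "(negative percent); check inputs", call. = FALSE)
  }
  pct
}

#' Endocranial volume reconstructed from brain plus adnexa mass
#'
#' `(brain + adnexa) / density`: the volume one would infer for the cranial
#' cavity if only tissue masses were recorded. Because the cerebrospinal
#' fluid contributes no mass here, this reconstruction systematically
#' underestimates the measured endocranial volume.
#'
#' @param brain_g Brain mass in g (> 0).
#' @param adnexa_g Adnexa mass in g (>= 0).
#' @param density Neural tissue density in g/cm3.
#' @return Reconstructed endocranial volume in cm3.
#' @examples
#' reconstructed_endocranial_volume(2948, 1238, 1.04)  # 4025 cm3
#' @export
reconstructed_endocranial_volume <- function(brain_g, adnexa_g = 0,
                                             density = brain_density("cetacean")) {
  check_positive(brain_g, "brain_g")
  if (any(adnexa_g < 0)) stop("`adnexa_g` must be >= 0", call. = FALSE)
  check_positive(density, "density")
  (brain_g + adnexa_g) / density
}

#' A named power-law registry entry
#'
#' Represents `log_b(y) = slope * log_b(x) + intercept` with declared input
#' and output units, as stored in the coefficient registry.
#'
#' @param slope,intercept Coefficients on the log scale.
#' @param base Logarithm base (10 throughout this package).
#' @param x_unit,y_unit Units of the input and output on the natural scale.
#' @param note Free-text provenance note.
#' @return A one-row tibble usable wherever a fitted `allometric_fit` is.
#' @export
power_law <- function(slope, intercept, base = 10, x_unit = "", y_unit = "",
                      note = "") {
  stopifnot(is.numeric(slope), is.numeric(intercept), base > 1)
  tibble::tibble(slope = slope, intercept = intercept, base = base,
                 x_unit = x_unit, y_unit = y_unit, note = note)
}

law_coefs <- function(fit) {
  if (inherits(fit, "allometric_fit")) {
    list(slope = fit$slope, intercept = fit$intercept, base = fit$log_base)
  } else if (is.data.frame(fit) && all(c("slope", "intercept") %in% names(fit))) {
    if (nrow(fit) != 1) stop("registry entry must be a single row", call. = FALSE)
    list(slope = fit$slope, intercept = fit$intercept,
         base = if ("base" %in% names(fit)) fit$base else 10)
  } else {
    stop("`fit` must be an allometric_fit or a power_law registry row",
         call. = FALSE)
  }
}

eval_power_law <- function(x, fit) {
  cf <- law_coefs(fit)
  cf$base^(cf$slope * log(x, base = cf$base) + cf$intercept)
}

#' Default coefficient registry
#'
#' Named power laws used by the estimation pipeline, all on log10 scale:
#'
#' * `brain_mass_from_endocranial_volume`: log10(brain g) =
#'   0.933 log10(endocranial cm3) + 0.088, calibrated by PGLS on species
#'   means of extant placental mammals measured for both quantities.
#' * `body_mass_from_ocw`: log10(body kg) = 3.135 log10(OCW mm) - 3.575,
#'   calibrated by PGLS on adult species means of extant cetaceans.
#'
#' Per-taxon length-to-mass laws and any prior-literature OCW law used for
#' back-calculating OCW from published body masses are not shipped: they must
#' be added by the user (see [power_law()]), since their coefficients come
#' from external sources.
#'
#' @return A tibble with columns `name`, `slope`, `intercept`, `base`,
#'   `x_unit`, `y_unit`, `note`.
#' @export
default_registry <- function() {
  dplyr::bind_rows(
    dplyr::mutate(power_law(0.933, 0.088, 10, "cm3", "g",
                            "printed PGLS calibration, lambda ~ 0"),
                  name = "brain_mass_from_endocranial_volume"),
    dplyr::mutate(power_law(3.135, -3.575, 10, "mm", "kg",
                            "printed PGLS calibration, lambda 0.942"),
                  name = "body_mass_from_ocw")
  )[, c("name", "slope", "intercept", "base", "x_unit", "y_unit", "note")]
}

#' Look up a registry entry by name
#'
#' @param registry A registry tibble (see [default_registry()]).
#' @param name Entry name.
#' @return The single matching row.
#' @export
registry_entry <- function(registry, name) {
  hit <- registry[registry$name == name, , drop = FALSE]
  if (nrow(hit) == 0) {
    stop("no registry entry named \"", name, "\"", call. = FALSE)
  }
  hit
}

#' Predict brain mass from endocranial volume
#'
#' Evaluates the brain-mass allometry `10^(slope * log10(v) + intercept)`.
#' An optional fractional deduction of the endocranial volume (e.g.
#' `rete_fraction = 0.2` for the fixed 20% rete correction used by earlier
#' studies) is available for comparison purposes and is OFF by default: this
#' package's calibration already absorbs adnexa and cerebrospinal fluid into
#' the regression.
#'
#' @param endocranial_cm3 Endocranial volume in cm3 (> 0); vectorized.
#' @param fit An `allometric_fit` or registry row on log10 scale.
#' @param rete_fraction Fraction of endocranial volume deducted before
#'   prediction (default 0).
#' @return Predicted brain mass in g.
#' @export
predict_brain_mass <- function(endocranial_cm3,
                               fit = registry_entry(default_registry(),
                                                    "brain_mass_from_endocranial_volume"),
                               rete_fraction = 0) {
  check_positive(endocranial_cm3, "endocranial_cm3")
  stopifnot(rete_fraction >= 0, rete_fraction < 1)
  eval_power_law(endocranial_cm3 * (1 - rete_fraction), fit)
}

#' Predict body mass from occipital condyle width
#'
#' Evaluates the OCW body-mass allometry (kg from mm); strictly increasing
#' in OCW.
#'
#' @param ocw_mm Occipital condyle width in mm (> 0); vectorized.
#' @param fit An `allometric_fit` or registry row on log10 scale.
#' @return Predicted body mass in kg.
#' @examples
#' predict_body_mass_from_ocw(88.7)  # ~340 kg
#' @export
predict_body_mass_from_ocw <- function(ocw_mm,
                                       fit = registry_entry(default_registry(),
                                                            "body_mass_from_ocw")) {
  check_positive(ocw_mm, "ocw_mm")
  eval_power_law(ocw_mm, fit)
}

#' Back-calculate OCW from body mass
#'
#' Exact inverse of the OCW power law:
#' `10^((log10(m) - intercept) / slope)`. Used to recover occipital condyle
#' widths from published body masses when the original measurements are
#' unavailable.
#'
#' @param body_mass_kg Body mass in kg (> 0); vectorized.
#' @param fit The forward law (slope must be nonzero).
#' @return OCW in mm.
#' @export
back_calculate_ocw <- function(body_mass_kg,
                               fit = registry_entry(default_registry(),
                                                    "body_mass_from_ocw")) {
  check_positive(body_mass_kg, "body_mass_kg")
  cf <- law_coefs(fit)
  if (cf$slope == 0) stop("cannot invert a zero-slope law", call. = FALSE)
  cf$base^((log(body_mass_kg, base = cf$base) - cf$intercept) / cf$slope)
}

#' Body mass from body length via a taxon-specific power law
#'
#' Looks the taxon up in the registry (entry name
#' `paste0("length_mass_", taxon)`) and evaluates the law. There is no
#' fallback: a missing entry is an error naming the taxon, so silent use of
#' an inappropriate law is impossible.
#'
#' @param length Body length (> 0) in the unit declared by the entry.
#' @param taxon Taxon (species or genus) name keying the registry entry.
#' @param registry Registry tibble containing `length_mass_<taxon>` entries.
#' @return Body mass in the unit declared by the entry (kg by convention).
#' @export
body_mass_from_length <- function(length, taxon, registry) {
  check_positive(length, "length")
  name <- paste0("length_mass_", normalize_taxon_names(taxon))
  hit <- registry[registry$name == name, , drop = FALSE]
  if (nrow(hit) == 0) {
    stop("no length-mass law registered for taxon \"", taxon, "\"",
         call. = FALSE)
  }
  eval_power_law(length, hit)
}

#' Cavity accounting for measured specimens
#'
#' Derives, per specimen, brain volume, the percent of the endocranial cavity
#' not occupied by brain and (where adnexa mass is available) the endocranial
#' volume reconstructed from brain plus adnexa mass alone — quantifying how
#' much of the cavity is cerebrospinal fluid and adnexa, and by how much a
#' mass-only reconstruction underestimates the measured cavity.
#'
#' @param records Data frame with columns `taxon`, `group` (`"cetacean"` /
#'   `"terrestrial"`), `brain_mass_g`, `endocranial_volume_cm3` and
#'   optionally `adnexa_mass_g`.
#' @return The input as a tibble with added columns `density_g_cm3`,
#'   `brain_volume_cm3`, `percent_not_occupied`,
#'   `reconstructed_endocranial_cm3` (NA without adnexa),
#'   `percent_filled_measured` and `percent_filled_reconstructed`.
#' @examples
#' cavity_accounting(extant_brain_measurements())
#' @export
cavity_accounting <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("taxon", "group", "brain_mass_g",
                  "endocranial_volume_cm3") %in% names(records)))
  records <- dplyr::as_tibble(records)
  if (!"adnexa_mass_g" %in% names(records)) records$adnexa_mass_g <- NA_real_
  records |>
    dplyr::mutate(
      density_g_cm3 = ifelse(.data$group == "cetacean",
                             brain_density("cetacean"),
                             brain_density("terrestrial")),
      brain_volume_cm3 = .data$brain_mass_g / .data$density_g_cm3,
      percent_not_occupied = 100 * (.data$endocranial_volume_cm3 -
                                      .data$brain_volume_cm3) /
        .data$endocranial_volume_cm3,
      reconstructed_endocranial_cm3 = ifelse(
        is.na(.data$adnexa_mass_g), NA_real_,
        (.data$brain_mass_g + .data$adnexa_mass_g) / .data$density_g_cm3),
      percent_filled_measured = 100 * .data$brain_volume_cm3 /
        .data$endocranial_volume_cm3,
      percent_filled_reconstructed = 100 * .data$brain_volume_cm3 /
        .data$reconstructed_endocranial_cm3
    )
}
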