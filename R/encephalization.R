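#' Encephalization-quotient scalings
#'
#' The two reference allometries used to compute EQ. Both express expected
#' brain mass (g) from body mass (g) as
#' `10^(exponent * log10(body_g) - constant)`:
#'
#' * `EQ_0.56`: exponent 0.56, constant 0.44 — the scaling observed in extant
#'   terrestrial artiodactyls, the closest terrestrial relatives of
#'   cetaceans.
#' * `EQ_0.75`: exponent 0.75, constant 1.26 — the scaling across all
#'   mammals.
#'
#' @param label `"EQ_0.56"` or `"EQ_0.75"`.
#' @return A list with `exponent`, `constant`, `label`.
#' @export
eq_scaling <- function(label = c("EQ_0.56", "EQ_0.75")) {
  label <- match.arg(label)
  switch(label,
         EQ_0.56 = list(exponent = 0.56, constant = 0.44, label = "EQ_0.56"),
         EQ_0.75 = list(exponent = 0.75, constant = 1.26, label = "EQ_0.75"))
}

#' Both shipped EQ scalings
#' @return A named list of the `EQ_0.56` and `EQ_0.75` scalings.
#' @export
eq_scalings <- function() {
  list(EQ_0.56 = eq_scaling("EQ_0.56"), EQ_0.75 = eq_scaling("EQ_0.75"))
}

#' Expected brain mass under a reference allometry
#'
#' @param body_mass_g Body mass in grams (> 0); vectorized.
#' @param scaling An EQ scaling (see [eq_scaling()]).
#' @return Expected brain mass in grams.
#' @examples
#' expected_brain_mass(1e5, eq_scaling("EQ_0.75"))  # ~309 g for a 100 kg mammal
#' @export
expected_brain_mass <- function(body_mass_g, scaling = eq_scaling("EQ_0.56")) {
  check_positive(body_mass_g, "body_mass_g")
  10^(scaling$exponent * log10(body_mass_g) - scaling$constant)
}

#' Encephalization quotient
#'
#' EQ is the ratio of observed brain mass to the brain mass expected for an
#' animal of the same body mass under the reference allometry: EQ = 1 means
#' exactly as large as expected. Body mass is supplied in kilograms (the
#' unit the estimation pipeline works in) and converted to grams internally,
#' the unit in which the scaling constants are expressed.
#'
#' @param brain_g Observed (or estimated) brain mass in g (> 0); vectorized.
#' @param body_mass_kg Body mass in kg (> 0).
#' @param scaling An EQ scaling (see [eq_scaling()]).
#' @return The dimensionless EQ.
#' @export
compute_eq <- function(brain_g, body_mass_kg, scaling = eq_scaling("EQ_0.56")) {
  check_positive(brain_g, "brain_g")
  check_positive(body_mass_kg, "body_mass_kg")
  brain_g / expected_brain_mass(body_mass_kg * 1000, scaling)
}

#' Body mass at which the two EQ scalings cross
#'
#' For a fixed brain mass, EQ_0.56 exceeds EQ_0.75 above the body mass where
#' the two expected-brain-mass curves intersect:
#' `10^((c2 - c1) / (e2 - e1))` grams with (e1, c1) = (0.56, 0.44) and
#' (e2, c2) = (0.75, 1.26).
#'
#' @return Crossover body mass in grams.
#' @export
eq_crossover_mass <- function() {
  s1 <- eq_scaling("EQ_0.56")
  s2 <- eq_scaling("EQ_0.75")
  10^((s2$constant - s1$constant) / (s2$exponent - s1$exponent))
}

#' Build per-specimen fossil estimates
#'
#' The assembly step of the estimation pipeline: for each fossil record,
#' estimate brain mass from endocranial volume and body mass from occipital
#' condyle width (or take a supplied override body mass, e.g. for fossil
#' delphinoids whose published masses are retained), then compute both EQs.
#' Records with neither OCW nor an override body mass are skipped, with the
#' reason recorded in the `skipped` attribute.
#'
#' @param records Data frame of fossil records: `taxon`, optional
#'   `specimen_id`, `age_ma`, `endocranial_volume_cm3`, `ocw_mm`, optional
#'   `override_body_mass_kg`, optional `family`.
#' @param brain_fit,body_fit Power laws (fits or registry rows) for brain
#'   mass from endocranial volume and body mass from OCW; defaults are the
#'   shipped calibrations.
#' @param scalings List of EQ scalings to evaluate (default both).
#' @param rete_fraction Optional fractional endocranial-volume deduction
#'   passed to [predict_brain_mass()] (default 0; see that help page).
#' @return A tibble of class `fossil_estimates`: one row per usable record
#'   with `brain_mass_g`, `body_mass_kg`, one `EQ_*` and one `log10_EQ_*`
#'   column per scaling, and provenance flags `body_mass_source`
#'   (`"ocw"`/`"override"`) and `rete_fraction`.
#' @examples
#' build_fossil_estimates(eocene_archaeocetes())
#' @export
build_fossil_estimates <- function(records,
                                   brain_fit = registry_entry(default_registry(),
                                                              "brain_mass_from_endocranial_volume"),
                                   body_fit = registry_entry(default_registry(),
                                                             "body_mass_from_ocw"),
                                   scalings = eq_scalings(),
                                   rete_fraction = 0) {
  stopifnot(is.data.frame(records))
  records <- dplyr::as_tibble(records)
  if (nrow(records) == 0) {
    out <- tibble::tibble(taxon = character())
    class(out) <- c("fossil_estimates", class(out))
    attr(out, "skipped") <- tibble::tibble(taxon = character(),
                                           reason = character())
    return(out)
  }
  for (col in c("specimen_id", "family")) {
    if (!col %in% names(records)) records[[col]] <- NA_character_
  }
  for (col in c("age_ma", "ocw_mm", "endocranial_volume_cm3",
                "override_body_mass_kg")) {
    if (!col %in% names(records)) records[[col]] <- NA_real_
  }
  usable <- !is.na(records$endocranial_volume_cm3) &
    (!is.na(records$ocw_mm) | !is.na(records$override_body_mass_kg))
  skipped <- tibble::tibble(
    taxon = records$taxon[!usable],
    reason = ifelse(is.na(records$endocranial_volume_cm3[!usable]),
                    "missing endocranial volume",
                    "missing both OCW and override body mass")
  )
  if (nrow(skipped) > 0) {
    message(nrow(skipped), " record(s) skipped; see attr(., \"skipped\")")
  }
  rec <- records[usable, , drop = FALSE]
  out <- rec |>
    dplyr::mutate(
      brain_mass_g = predict_brain_mass(.data$endocranial_volume_cm3,
                                        brain_fit,
                                        rete_fraction = rete_fraction),
      body_mass_source = ifelse(is.na(.data$override_body_mass_kg),
                                "ocw", "override"),
      body_mass_kg = ifelse(is.na(.data$override_body_mass_kg),
                            predict_body_mass_from_ocw(
                              dplyr::coalesce(.data$ocw_mm, 1), body_fit),
                            .data$override_body_mass_kg),
      rete_fraction = rete_fraction
    )
  for (s in scalings) {
    out[[s$label]] <- compute_eq(out$brain_mass_g, out$body_mass_kg, s)
    out[[paste0("log10_", s$label)]] <- log10(out[[s$label]])
  }
  class(out) <- c("fossil_estimates", class(out))
  attr(out, "skipped") <- skipped
  out
}
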