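#' Reference brain, endocranial-volume and adnexa measurements
#'
#' Direct measurements on extant specimens: four domestic goats, two domestic
#' pigs, one beluga (brain segmented from a CT scan) and two bowhead whales.
#' Brain masses include pia and arachnoid; adnexa mass (dura, rete mirabile,
#' vasculature) was weighed for one pig, the beluga and one bowhead.
#' Endocranial volumes were measured by filling the cavity with beads/seeds,
#' or from the CT scan for the beluga. These records anchor the
#' cavity-accounting arithmetic (see [cavity_accounting()]).
#'
#' @return A tibble with columns `taxon`, `specimen_id`, `group`,
#'   `maturity`, `brain_mass_g`, `endocranial_volume_cm3`, `adnexa_mass_g`.
#' @export
extant_brain_measurements <- function() {
  tibble::tribble(
    ~taxon, ~specimen_id, ~group, ~brain_mass_g, ~endocranial_volume_cm3,
    ~adnexa_mass_g,
    "Capra_hircus", "Goat A", "terrestrial", 113.3, 145, NA,
    "Capra_hircus", "Goat C", "terrestrial", 121.5, 149, NA,
    "Capra_hircus", "Goat D", "terrestrial", 102.1, 130, NA,
    "Capra_hircus", "Goat E", "terrestrial", 99.3, 132, NA,
    "Sus_scrofa", "PGL 417", "terrestrial", 128.5, 186, NA,
    "Sus_scrofa", "PGL 419", "terrestrial", 140, 176, 13.4,
    "Delphinapterus_leucas", "NSB-DWM 2019LDL10", "cetacean", 2074, 2528, 165,
    "Balaena_mysticetus", "NSB-DWM 2008B11", "cetacean", 2948, 8400, 1238,
    "Balaena_mysticetus", "NSB-DWM 2009B9", "cetacean", 2980, 8900, NA
  ) |>
    dplyr::mutate(maturity = "adult", .after = "group")
}

#' Eocene archaeocete specimen records
#'
#' Occipital condyle widths, endocranial volumes and geological ages for the
#' seven Eocene archaeocete specimens analysed by the estimation pipeline:
#' four basilosaurids (Dorudon atrox, Saghacetus osiris, two specimens of
#' Zygorhiza kochii), one protocetid (Rodhocetus kasrani) and two
#' remingtonocetids (Dalanistes ahmedi, Remingtonocetus harudiensis).
#' Measurements are compiled from the primary descriptive literature (Uhen;
#' Dart; Kellogg; Gingerich; Bajpai et al.; Marino et al.), as recorded in
#' the `source` column.
#'
#' @return A tibble with columns `taxon`, `specimen_id`, `family`, `group`,
#'   `age_ma`, `endocranial_volume_cm3`, `ocw_mm`, `source`.
#' @export
eocene_archaeocetes <- function() {
  tibble::tribble(
    ~taxon, ~specimen_id, ~family, ~age_ma, ~endocranial_volume_cm3, ~ocw_mm,
    ~source,
    "Dorudon_atrox", "UM 101222", "Basilosauridae", 39, 1173, 126,
    "Uhen 2004",
    "Saghacetus_osiris", "BMNH 10228", "Basilosauridae", 39, 480, 91.8,
    "Dart 1923; Kellogg 1936",
    "Zygorhiza_kochii", "USNM 16639", "Basilosauridae", 37, 917, 112,
    "Marino et al. 2000; Kellogg 1936",
    "Zygorhiza_kochii", "FMNH PM-459", "Basilosauridae", 34, 1189, 120,
    "Gingerich 2015, 2016",
    "Rodhocetus_kasrani", "GSP-UM 3012", "Protocetidae", 47, 290, 88.7,
    "Gingerich 1998; Uhen pers. comm. 2020",
    "Dalanistes_ahmedi", "GSP-UM 3106", "Remingtonocetidae", 45, 400, 104.8,
    "Gingerich 1998; Uhen pers. comm. 2020",
    "Remingtonocetus_harudiensis", "IITR-SB 2770", "Remingtonocetidae", 42,
    253, 87, "Bajpai et al. 2011"
  ) |>
    dplyr::mutate(group = "cetacean", .after = "family")
}
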