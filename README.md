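# paleobrain

Brain size relative to body size — encephalization — is the standard currency
for comparing cognitive capacity across living and fossil mammals. For fossil
cetaceans both inputs must be estimated from bone: brain mass from the volume
of the cranial cavity, and body mass from a skeletal proxy. Both steps are
error-prone. The cranial cavity also holds cerebrospinal fluid and "adnexa"
(meninges, nerves, and vasculature including the rete mirabile, which is
enormous in baleen whales), so endocranial volume systematically overstates
brain size; and body-mass proxies calibrated on the wrong reference group
propagate bias into every downstream quotient.

`paleobrain` implements that estimation pipeline end to end for
paleobiologists working on cetacean brain evolution:

* **Allometric calibration by PGLS with ML Pagel's lambda.** Log–log
  regressions of brain mass (g) on endocranial volume (cm³), and of body mass
  (kg) on occipital condyle width (OCW, mm), are fit by generalized least
  squares with error covariance `σ²V(λ)`, where `V` is the Brownian-motion
  covariance implied by a phylogeny and Pagel's λ ∈ [0, 1] scales its
  off-diagonal entries. λ is estimated by maximizing the profile likelihood
  (σ² profiled analytically; 101-point grid scan plus local refinement).
  The GLS engine is closed form: `β̂ = (XᵀV⁻¹X)⁻¹XᵀV⁻¹y`.
* **Shipped printed calibrations.** The package ships the two published
  power laws — `log10(brain g) = 0.933·log10(endocranial cm³) + 0.088` and
  `log10(body kg) = 3.135·log10(OCW mm) − 3.575` — so fossil estimates are
  reproducible without the original calibration compilations; refitting from
  user-supplied tables and Newick trees is one config switch away.
* **Cavity accounting.** Conversions between brain mass, brain volume
  (density 1.04 g/cm³ for cetaceans, 1.036 g/cm³ for terrestrial
  artiodactyls), adnexa mass and endocranial volume, quantifying what
  fraction of the cavity the brain actually fills.
* **Encephalization quotients.** EQ = observed / expected brain mass under
  two reference scalings: `EQ_0.56` (terrestrial artiodactyls,
  `10^(0.56·log10(body g) − 0.44)`) and `EQ_0.75` (all mammals,
  `10^(0.75·log10(body g) − 1.26)`).
* **Epoch comparison.** Species-mean `log10 EQ` compared across geological
  time bins by one-way ANOVA followed by Tukey's HSD, with the
  studentized-range CDF evaluated by Gauss–Legendre double integration
  (Tukey–Kramer standard errors for unequal bin sizes).
* **Seeded synthetic data.** Pure-birth trees, Brownian traits with
  λ-structured residuals, and specimen tables with maturity flags and
  lognormal measurement noise, so every stage is testable without downloads.

Everything is data-frame-first and pipe-friendly: tibbles in, tibbles out,
`tidy()`/`glance()` on fitted objects, ggplot2 plot functions.

## Worked example

Estimate brain mass, body mass and both EQs for the seven bundled Eocene
archaeocete specimens, then compare epochs:

```r
library(paleobrain)
library(dplyr)

est <- build_fossil_estimates(eocene_archaeocetes())
est |> select(taxon, specimen_id, brain_mass_g, body_mass_kg, EQ_0.56)
#> # A tibble: 7 × 5
#>   taxon                       specimen_id  brain_mass_g body_mass_kg EQ_0.56
#> 1 Dorudon_atrox               UM 101222            895.        1022.   1.06
#> 2 Saghacetus_osiris           BMNH 10228           389.         379.   0.80
#> 3 Zygorhiza_kochii            USNM 16639           711.         707.   1.04
#> 4 Zygorhiza_kochii            FMNH PM-459          906.         877.   1.17
#> 5 Rodhocetus_kasrani          GSP-UM 3012          243.         340.   0.53
#> 6 Dalanistes_ahmedi           GSP-UM 3106          328.         574.   0.54
#> 7 Remingtonocetus_harudiensis IITR-SB 2770         214.         320.   0.49

compare_epochs(est)
#> <epoch_comparison of log10_EQ_0.56 >
#>   bins: late Eocene basilosaurids (n=3), middle Eocene archaeocetes (n=3)
#>   ANOVA: F(1, 4) = 37.005, p = 0.003691
#> # A tibble: 1 × 6
#>   group1                    group2           estimate std.error statistic adj.p.value
#> 1 late Eocene basilosaurids middle Eocene a…   -0.276    0.0321      8.60     0.00369
```

The body masses come from each specimen's occipital condyle width through the
OCW power law (e.g. 88.7 mm → 340 kg for *Rodhocetus*), the brain masses from
endocranial volume through the brain-mass law, and the EQs from their ratio
against the reference scaling. The comparison shows middle Eocene
archaeocetes (semi-aquatic remingtonocetids and protocetids) had
significantly lower relative brain size than the fully aquatic late Eocene
basilosaurids; species means are the analysis units, so the two *Zygorhiza*
specimens contribute one value.

Cavity accounting on the measured extant specimens shows why endocranial
volume must not be equated with brain volume — a bowhead whale's brain fills
only a third of its cranial cavity:

```r
cavity_accounting(extant_brain_measurements()) |>
  filter(specimen_id == "NSB-DWM 2008B11") |>
  select(brain_volume_cm3, percent_not_occupied, reconstructed_endocranial_cm3)
#> # A tibble: 1 × 3
#>   brain_volume_cm3 percent_not_occupied reconstructed_endocranial_cm3
#> 1            2835.                 66.3                          4025
```

The 2,948 g brain converts to 2,835 cm³, leaving 66.3% of the 8,400 cm³
cavity to adnexa and cerebrospinal fluid; reconstructing the cavity from
brain + adnexa mass alone (4,025 cm³) would underestimate it by more than
half, because cerebrospinal fluid carries volume but no recorded mass.

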