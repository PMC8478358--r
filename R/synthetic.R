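#' Simulation settings for the synthetic-data generator
#'
#' Collects every knob of the generator in one validated list. Defaults
#' emulate the structure of the extant-cetacean compilation the OCW
#' calibration rests on: 35 species sampled as ~112 specimens of which about
#' two thirds are adults, an allometric slope near 3.1 on log10 scale,
#' strong phylogenetic signal, and modest multiplicative measurement noise.
#'
#' @param n_tips Number of species (tree tips), >= 2.
#' @param birth Speciation rate of the pure-birth tree (per unit time, > 0).
#' @param slope,intercept True log10-scale allometric relation.
#' @param sigma2 Residual variance of the response on log10 scale (>= 0).
#' @param lambda Pagel's lambda of the residuals, in \[0, 1\].
#' @param replicates Mean number of specimens per species (>= 1).
#' @param cv Coefficient of variation of specimen-level lognormal noise
#'   (>= 0).
#' @param subadult_fraction Probability a specimen is a subadult.
#' @param subadult_shrink Multiplicative factor (< 1) applied to subadult
#'   trait values, so adult filtering is consequential.
#' @param x_mean,x_sd Mean and Brownian-scale of the log10 predictor at the
#'   root / per unit branch length.
#' @param seed Mandatory integer seed; no unseeded randomness anywhere.
#' @return A validated list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_tips = 35, birth = 0.1, slope = 3.135,
                            intercept = -3.575, sigma2 = 0.04, lambda = 0.9,
                            replicates = 3.2, cv = 0.1,
                            subadult_fraction = 0.34, subadult_shrink = 0.8,
                            x_mean = 2, x_sd = 0.15, seed) {
  if (missing(seed) || !is.numeric(seed)) {
    stop("`seed` is mandatory", call. = FALSE)
  }
  stopifnot(n_tips >= 2, birth > 0, sigma2 >= 0, lambda >= 0, lambda <= 1,
            replicates >= 1, cv >= 0, subadult_fraction >= 0,
            subadult_fraction <= 1, subadult_shrink > 0, subadult_shrink <= 1,
            x_sd >= 0)
  structure(as.list(environment()), class = "simulation_spec")
}

#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Starts from two lineages at the root; while fewer than `n_tips` lineages
#' exist, waits an exponential time with rate `birth * k` (k = current
#' lineage count) and splits a uniformly chosen lineage; after reaching
#' `n_tips` a final exponential stretch with rate `birth * n_tips` is added
#' so that expected tree depth is \eqn{\sum_{k=2}^{n} 1/(k\,\mathrm{birth})}.
#' All tips end at the same depth (ultrametric). Deterministic given the
#' seed.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth Speciation rate (> 0).
#' @param seed Integer seed.
#' @return A `phylo` tree with tips labelled `t1 ... tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth = 0.1, seed) {
  stopifnot(n_tips >= 2, birth > 0)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  withr::with_seed(seed, {
    n_nodes <- 2L * n_tips - 1L
    root <- n_tips + 1L
    depth <- numeric(n_nodes)        # creation depth of each node (root = 0)
    parent <- integer(0)
    child <- integer(0)
    # live lineages identified by the node each hangs from
    live <- c(root, root)
    t_now <- 0
    next_node <- root + 1L
    while (length(live) < n_tips) {
      k <- length(live)
      t_now <- t_now + stats::rexp(1, rate = birth * k)
      i <- sample.int(k, 1)
      parent <- c(parent, live[i])
      child <- c(child, next_node)
      depth[next_node] <- t_now
      live[i] <- next_node
      live <- c(live, next_node)
      next_node <- next_node + 1L
    }
    t_now <- t_now + stats::rexp(1, rate = birth * n_tips)
    tip_ids <- seq_len(n_tips)
    parent <- c(parent, live)
    child <- c(child, tip_ids)
    depth[tip_ids] <- t_now
    tree <- list(edge = cbind(parent, child),
                 edge.length = depth[child] - depth[parent],
                 Nnode = n_tips - 1L,
                 tip.label = paste0("t", tip_ids))
    class(tree) <- "phylo"
    ape::reorder.phylo(tree, "cladewise")
  })
}

#' Simulate phylogenetically structured log-log trait data
#'
#' The predictor's log10 values evolve by Brownian motion on the tree
#' (root value `x_mean`, rate `x_sd^2` per unit branch length); the response
#' is `slope * x + intercept` plus residuals drawn multivariate normal with
#' covariance `sigma2 * V(lambda)` — exactly the model PGLS with Pagel's
#' lambda assumes. Values are returned on the natural scale (`10^`), one row
#' per species.
#'
#' @param tree A `phylo` tree.
#' @param slope,intercept,sigma2,lambda,x_mean,x_sd See [simulation_spec()].
#' @param seed Integer seed.
#' @return A trait table tibble (`taxon`, `x`, `y`, natural scale) ready for
#'   [fit_pgls()].
#' @export
simulate_allometric_traits <- function(tree, slope = 3.135,
                                       intercept = -3.575, sigma2 = 0.04,
                                       lambda = 0.9, x_mean = 2, x_sd = 0.15,
                                       seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  tree <- validate_phylo(tree)
  n <- ape::Ntip(tree)
  V1 <- phylo_covariance(tree, lambda = 1)
  # scale V to unit mean depth so x_sd/sigma2 are comparable across trees
  Vx <- V1 / mean(diag(V1))
  Vl <- phylo_covariance(tree, lambda = lambda) / mean(diag(V1))
  withr::with_seed(seed, {
    logx <- x_mean + drop(crossprod(chol(Vx + diag(1e-10, n)),
                                    stats::rnorm(n))) * x_sd
    resid <- if (sigma2 == 0) rep(0, n) else
      drop(crossprod(chol(Vl + diag(1e-10, n)), stats::rnorm(n))) *
      sqrt(sigma2)
    logy <- slope * logx + intercept + resid
  })
  tibble::tibble(taxon = rownames(Vx), x = 10^logx, y = 10^logy)
}

#' Simulate a specimen-level table with maturity structure
#'
#' Builds species-level true OCW/body-mass pairs from
#' [simulate_allometric_traits()] and expands each species into specimen
#' records: specimen values are the species values perturbed by lognormal
#' noise at coefficient of variation `cv`; each specimen is a subadult with
#' probability `subadult_fraction`, and subadult measurements are shrunk by
#' `subadult_shrink` so that adult-only filtering changes the answer.
#' Also emits `n_fossils` fossil-style records (OCW + endocranial volume +
#' age, no body mass) drawn from the same allometries.
#'
#' @param tree A `phylo` tree (one tip per species).
#' @param spec A [simulation_spec()].
#' @param n_fossils Number of fossil-style records to append (default 0).
#' @return A tibble of specimen records with the columns
#'   [read_specimen_table()] understands; fossil rows carry
#'   `endocranial_volume_cm3` and `age_ma` instead of `body_mass_kg`.
#' @export
simulate_specimen_table <- function(tree, spec, n_fossils = 0) {
  stopifnot(inherits(spec, "simulation_spec"))
  species <- simulate_allometric_traits(
    tree, slope = spec$slope, intercept = spec$intercept,
    sigma2 = spec$sigma2, lambda = spec$lambda, x_mean = spec$x_mean,
    x_sd = spec$x_sd, seed = spec$seed
  )
  sdlog <- sqrt(log(1 + spec$cv^2))
  withr::with_seed(spec$seed + 1L, {
    # 1 + Poisson keeps the mean at `replicates` while guaranteeing every
    # species at least one specimen (and exactly one when replicates = 1)
    n_rep <- 1L + stats::rpois(nrow(species), spec$replicates - 1)
    rows <- species[rep(seq_len(nrow(species)), n_rep), ]
    m <- nrow(rows)
    noise_x <- stats::rlnorm(m, -sdlog^2 / 2, sdlog)
    noise_y <- stats::rlnorm(m, -sdlog^2 / 2, sdlog)
    subadult <- stats::runif(m) < spec$subadult_fraction
    shrink <- ifelse(subadult, spec$subadult_shrink, 1)
    out <- tibble::tibble(
      taxon = rows$taxon,
      specimen_id = paste0(rows$taxon, "_s",
                           unlist(lapply(n_rep, seq_len))),
      group = "cetacean",
      maturity = ifelse(subadult, "subadult", "adult"),
      ocw_mm = rows$x * noise_x * shrink,
      body_mass_kg = rows$y * noise_y * shrink^3
    )
    if (n_fossils > 0) {
      fx <- 10^stats::runif(n_fossils, log10(min(species$x)),
                            log10(max(species$x)))
      fossil <- tibble::tibble(
        taxon = paste0("fossil_", seq_len(n_fossils)),
        specimen_id = paste0("F", seq_len(n_fossils)),
        group = "cetacean",
        maturity = "adult",
        ocw_mm = fx,
        endocranial_volume_cm3 = 10^(0.9 * log10(
          eval_power_law(fx, power_law(spec$slope, spec$intercept))) + 1),
        age_ma = stats::runif(n_fossils, 23, 48)
      )
      out <- dplyr::bind_rows(out, fossil)
    }
  })
  out
}
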