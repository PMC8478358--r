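#' Aggregate specimen records into species means
#'
#' Computes one row per species for the requested traits, averaging on the
#' natural measurement scale (so a species mean brain mass is a mean of
#' masses, not of log masses; set `geometric = TRUE` for means of logs).
#' Records missing any requested trait are dropped and counted in the
#' `dropped` attribute of the result.
#'
#' @param records A data frame of specimen records with at least `taxon`,
#'   `maturity` and the requested trait columns.
#' @param traits Character vector of trait column names to average.
#' @param adults_only If `TRUE` (default) only records with
#'   `maturity == "adult"` are used; `"subadult"` and `"unknown"` are both
#'   excluded.
#' @param geometric If `TRUE`, means are computed on the log10 scale and
#'   back-transformed (geometric means).
#' @return A tibble with one row per species: `taxon`, the trait means, and
#'   `n_specimens`. Attribute `dropped` is a tibble counting excluded records
#'   by reason (`not_adult`, `incomplete`).
#' @export
aggregate_species_means <- function(records, traits, adults_only = TRUE,
                                    geometric = FALSE) {
  stopifnot(is.data.frame(records), all(c("taxon") %in% names(records)))
  missing_cols <- setdiff(traits, names(records))
  if (length(missing_cols) > 0) {
    stop("trait column(s) absent: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- dplyr::as_tibble(records)
  records$taxon <- normalize_taxon_names(records$taxon)
  n0 <- nrow(records)
  if (adults_only) {
    if (!"maturity" %in% names(records)) {
      stop("`maturity` column required when adults_only = TRUE", call. = FALSE)
    }
    eligible <- records[!is.na(records$maturity) &
                          records$maturity == "adult", , drop = FALSE]
  } else {
    eligible <- records
  }
  n_not_adult <- n0 - nrow(eligible)
  complete <- stats::complete.cases(eligible[, traits, drop = FALSE])
  n_incomplete <- sum(!complete)
  eligible <- eligible[complete, , drop = FALSE]
  lost <- setdiff(unique(records$taxon), unique(eligible$taxon))
  if (length(lost) > 0) {
    warning("species with no eligible complete record omitted: ",
            paste(lost, collapse = ", "), call. = FALSE)
  }
  avg <- if (geometric) function(v) 10^mean(log10(v)) else mean
  out <- eligible |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(traits), avg),
                     n_specimens = dplyr::n(), .groups = "drop")
  attr(out, "dropped") <- tibble::tibble(
    reason = c("not_adult", "incomplete"),
    n = c(n_not_adult, n_incomplete)
  )
  out
}

# Cholesky-based GLS solve; falls back to an eigenvalue pseudo-inverse when V
# is numerically singular (with a warning). Returns coefficients, their
# covariance scale (X'V^-1 X)^-1, GLS residual/total sums of squares and
# log|V|.
gls_core <- function(X, y, V) {
  n <- nrow(X)
  ok <- TRUE
  L <- tryCatch(chol(V), error = function(e) {ok <<- FALSE; NULL})
  if (ok) {
    # whiten: solve L' u = . so that u'u = .' V^-1 .
    Xw <- backsolve(L, X, transpose = TRUE)
    yw <- backsolve(L, y, transpose = TRUE)
    logdetV <- 2 * sum(log(diag(L)))
  } else {
    warning("covariance matrix numerically singular; using pseudo-inverse",
            call. = FALSE)
    ei <- eigen(V, symmetric = TRUE)
    keep <- ei$values > max(ei$values) * 1e-12
    B <- ei$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(ei$values[keep]), sum(keep))
    Xw <- t(B) %*% X
    yw <- t(B) %*% y
    logdetV <- sum(log(ei$values[keep]))
  }
  XtX <- crossprod(Xw)
  if (rcond(XtX) < 1e-14) stop("rank-deficient design matrix", call. = FALSE)
  XtXi <- solve(XtX)
  b <- drop(XtXi %*% crossprod(Xw, yw))
  r <- yw - Xw %*% b
  rss <- drop(crossprod(r))
  # total SS about the GLS-estimated mean (intercept-only GLS fit)
  onew <- if (ok) backsolve(L, rep(1, n), transpose = TRUE) else t(B) %*% rep(1, n)
  mu <- drop(crossprod(onew, yw) / crossprod(onew))
  tss <- drop(crossprod(yw - onew * mu))
  list(b = b, XtXi = XtXi, rss = rss, tss = tss, logdetV = logdetV, n = n)
}

# ML log-likelihood of the GLS fit with sigma^2 profiled out analytically.
gls_loglik <- function(core) {
  n <- core$n
  s2 <- core$rss / n
  -n / 2 * log(2 * pi) - n / 2 * log(s2) - core$logdetV / 2 - n / 2
}

new_allometric_fit <- function(core, lambda, method, response, predictor,
                               boundary = FALSE) {
  n <- core$n
  p <- length(core$b)
  s2 <- core$rss / (n - p)
  se <- sqrt(diag(core$XtXi) * s2)
  r2 <- 1 - core$rss / core$tss
  structure(list(
    slope = unname(core$b[2]),
    intercept = unname(core$b[1]),
    lambda = lambda,
    slope_se = unname(se[2]),
    intercept_se = unname(se[1]),
    r2 = r2,
    adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p),
    n_species = n,
    log_likelihood = gls_loglik(core),
    sigma2 = core$rss / n,
    method = method,
    response = response,
    predictor = predictor,
    log_base = 10,
    boundary_lambda = boundary
  ), class = "allometric_fit")
}

check_trait_table <- function(data, log10_transform) {
  stopifnot(is.data.frame(data))
  need <- c("taxon", "x", "y")
  if (!all(need %in% names(data))) {
    stop("trait table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) < 3) stop("need >= 3 species for a fit", call. = FALSE)
  if (anyDuplicated(normalize_taxon_names(data$taxon))) {
    stop("trait table must have one row per taxon (aggregate first)",
         call. = FALSE)
  }
  if (log10_transform && (any(data$x <= 0) || any(data$y <= 0))) {
    stop("x and y must be strictly positive before log transform",
         call. = FALSE)
  }
  data
}

#' Generalized least squares fit of a log-log allometry at fixed covariance
#'
#' Closed-form GLS, \eqn{\hat\beta = (X'V^{-1}X)^{-1} X'V^{-1} y}, of
#' `log10(y)` on `log10(x)` (or of raw values with `log10_transform = FALSE`)
#' under a given phylogenetic covariance matrix. Standard errors come from
#' \eqn{(X'V^{-1}X)^{-1}\hat\sigma^2}; the reported log-likelihood is the ML
#' multivariate-normal likelihood with \eqn{\sigma^2} profiled out; R-squared
#' is computed from GLS residual and total sums of squares about the GLS mean.
#'
#' @param data A trait table: columns `taxon`, `x` (predictor), `y`
#'   (response), one row per species.
#' @param V Covariance matrix with taxon dimnames covering `data$taxon`
#'   (see [phylo_covariance()]).
#' @param log10_transform Fit on log10 scale (default; all reported
#'   coefficients are base-10).
#' @param lambda Value recorded in the returned fit (bookkeeping only; `V`
#'   must already be transformed).
#' @param response,predictor Names recorded in the fit.
#' @return An `allometric_fit` object; see [tidy.allometric_fit()].
#' @export
fit_gls <- function(data, V, log10_transform = TRUE, lambda = NA_real_,
                    response = "y", predictor = "x") {
  data <- check_trait_table(data, log10_transform)
  taxa <- normalize_taxon_names(data$taxon)
  if (is.null(rownames(V)) || !setequal(taxa, rownames(V)) ||
      length(taxa) != nrow(V)) {
    stop("taxa in trait table and covariance matrix do not match",
         call. = FALSE)
  }
  V <- V[taxa, taxa, drop = FALSE]
  x <- if (log10_transform) log10(data$x) else data$x
  y <- if (log10_transform) log10(data$y) else data$y
  core <- gls_core(cbind(`(Intercept)` = 1, x = x), y, V)
  new_allometric_fit(core, lambda, "GLS", response, predictor)
}

#' PGLS with maximum-likelihood Pagel's lambda
#'
#' Fits the log-log allometry by generalized least squares with the
#' phylogenetic covariance under Pagel's lambda, choosing lambda to maximize
#' the profile log-likelihood over \[0, 1\] (sigma-squared is profiled out
#' analytically). The search is a 101-point grid pre-scan followed by local
#' refinement with [stats::optimize()] to a tolerance of 1e-6 on lambda.
#' Boundary optima (0 or 1) are legal and flagged via `boundary_lambda`; a
#' lambda within the search tolerance of a boundary is reported as exactly 0
#' or 1.
#'
#' @inheritParams fit_gls
#' @param tree A rooted `phylo` tree covering (at least) the taxa in `data`;
#'   it is pruned to the trait table automatically.
#' @param lambda `"ML"` (default) to estimate, or a fixed value in \[0, 1\].
#' @param grid_n Number of grid points in the pre-scan.
#' @param tol Convergence tolerance on lambda.
#' @return An `allometric_fit` with `lambda` set to the ML estimate.
#' @examples
#' tr <- simulate_yule_tree(20, birth = 1, seed = 1)
#' td <- simulate_allometric_traits(tr, slope = 0.93, intercept = 0.09,
#'                                  sigma2 = 0.01, lambda = 1, seed = 2)
#' fit_pgls(td, tr)
#' @export
fit_pgls <- function(data, tree, lambda = "ML", log10_transform = TRUE,
                     grid_n = 101, tol = 1e-6,
                     response = "y", predictor = "x") {
  data <- check_trait_table(data, log10_transform)
  taxa <- normalize_taxon_names(data$taxon)
  tree <- prune_to_taxa(tree, taxa)
  V1 <- phylo_covariance(tree, lambda = 1, taxa = taxa)
  x <- if (log10_transform) log10(data$x) else data$x
  y <- if (log10_transform) log10(data$y) else data$y
  X <- cbind(`(Intercept)` = 1, x = x)
  d <- diag(V1)
  V_at <- function(lam) {
    V <- V1 * lam
    diag(V) <- d
    V
  }
  ll_at <- function(lam) {
    core <- tryCatch(gls_core(X, y, V_at(lam)), error = function(e) NULL)
    if (is.null(core)) -Inf else gls_loglik(core)
  }
  if (identical(lambda, "ML")) {
    if (length(taxa) < 4) {
      stop("need >= 4 taxa to estimate lambda by ML", call. = FALSE)
    }
    grid <- seq(0, 1, length.out = grid_n)
    ll <- vapply(grid, ll_at, numeric(1))
    if (all(!is.finite(ll))) {
      stop("profile likelihood non-finite at every grid point; ",
           "check tree/covariance conditioning", call. = FALSE)
    }
    i <- which.max(ll)
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(grid_n, i + 1)]
    opt <- stats::optimize(ll_at, lower = lo, upper = hi, maximum = TRUE,
                           tol = tol)
    lam_hat <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
    if (lam_hat < tol) lam_hat <- 0
    if (lam_hat > 1 - tol) lam_hat <- 1
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      stop("`lambda` must be \"ML\" or a value in [0, 1]", call. = FALSE)
    }
    lam_hat <- lambda
  }
  core <- gls_core(X, y, V_at(lam_hat))
  fit <- new_allometric_fit(core, lam_hat, "PGLS", response, predictor,
                            boundary = lam_hat %in% c(0, 1))
  if (fit$boundary_lambda && identical(lambda, "ML")) {
    message("ML lambda at boundary: ", lam_hat)
  }
  fit
}

#' Profile log-likelihood of Pagel's lambda
#'
#' Evaluates the sigma-squared-profiled GLS log-likelihood over a grid of
#' lambda values; useful for diagnostics and for verifying that the ML
#' estimate is a global argmax.
#'
#' @inheritParams fit_pgls
#' @param lambdas Numeric vector of lambda values in \[0, 1\].
#' @return A tibble with columns `lambda` and `log_likelihood`.
#' @export
lambda_profile <- function(data, tree, lambdas = seq(0, 1, by = 0.01),
                           log10_transform = TRUE) {
  data <- check_trait_table(data, log10_transform)
  taxa <- normalize_taxon_names(data$taxon)
  tree <- prune_to_taxa(tree, taxa)
  V1 <- phylo_covariance(tree, lambda = 1, taxa = taxa)
  x <- if (log10_transform) log10(data$x) else data$x
  y <- if (log10_transform) log10(data$y) else data$y
  X <- cbind(1, x)
  d <- diag(V1)
  ll <- vapply(lambdas, function(lam) {
    V <- V1 * lam
    diag(V) <- d
    gls_loglik(gls_core(X, y, V))
  }, numeric(1))
  tibble::tibble(lambda = lambdas, log_likelihood = ll)
}

#' Ordinary least squares on log10-transformed data
#'
#' The simple-regression route used where no phylogeny applies (for example
#' fitting genus-level body length to body mass power laws). Both variables
#' are log10-transformed; coefficients therefore describe
#' \eqn{\log_{10} y = b \log_{10} x + a}.
#'
#' @param data Data frame with positive columns `x` and `y` (>= 3 rows).
#' @inheritParams fit_gls
#' @return An `allometric_fit` with `method = "OLS"` and `lambda = NA`.
#' @export
fit_ols_loglog <- function(data, response = "y", predictor = "x") {
  stopifnot(is.data.frame(data), all(c("x", "y") %in% names(data)))
  if (nrow(data) < 3) stop("need >= 3 pairs", call. = FALSE)
  if (any(data$x <= 0) || any(data$y <= 0)) {
    stop("x and y must be strictly positive", call. = FALSE)
  }
  x <- log10(data$x)
  y <- log10(data$y)
  core <- gls_core(cbind(`(Intercept)` = 1, x = x), y, diag(length(x)))
  new_allometric_fit(core, NA_real_, "OLS", response, predictor)
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf("<allometric_fit: %s>\n", x$method))
  cat(sprintf("  log10(%s) = %.4f * log10(%s) %+.4f\n",
              x$response, x$slope, x$predictor, x$intercept))
  if (!is.na(x$lambda)) {
    cat(sprintf("  lambda = %.4g%s\n", x$lambda,
                if (isTRUE(x$boundary_lambda)) " (boundary)" else ""))
  }
  cat(sprintf("  n = %d species, adj. R2 = %.4f, logLik = %.3f\n",
              x$n_species, x$adj_r2, x$log_likelihood))
  invisible(x)
}

#' Tidy an allometric fit
#'
#' @param x An `allometric_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.allometric_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se)
  )
}

#' One-row summary of an allometric fit
#'
#' @param x An `allometric_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `lambda`, `r.squared`,
#'   `adj.r.squared`, `n.species`, `log.likelihood`.
#' @export
glance.allometric_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, lambda = x$lambda, r.squared = x$r2,
    adj.r.squared = x$adj_r2, n.species = x$n_species,
    log.likelihood = x$log_likelihood
  )
}

#' @export
coef.allometric_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}
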