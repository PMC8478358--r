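# Coerce the (data, value, group) tidy interface or a plain list of numeric
# vectors into a named list of groups.
as_group_list <- function(data, value, group) {
  if (is.list(data) && !is.data.frame(data)) {
    groups <- lapply(data, as.numeric)
    if (is.null(names(groups))) {
      names(groups) <- paste0("group", seq_along(groups))
    }
    return(groups)
  }
  stopifnot(is.data.frame(data))
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  keep <- !is.na(v) & !is.na(g)
  split(as.numeric(v[keep]), as.character(g[keep]))
}

#' One-way analysis of variance from sums of squares
#'
#' Standard between/within decomposition. The p-value comes from the upper
#' tail of the F distribution (via [stats::pf()], i.e. the regularized
#' incomplete beta function). Zero within-group variance with non-zero
#' between-group variance (exact separation) yields infinite F, reported with
#' `p.value = 0` and `exact.separation = TRUE`.
#'
#' @param data A data frame, or a list of numeric vectors (one per group).
#' @param value,group Columns of `data` holding values and group labels
#'   (tidy-eval; ignored for list input).
#' @return A one-row tibble: `statistic` (F), `p.value`, `df.between`,
#'   `df.within`, `n`, `k`, `exact.separation`.
#' @export
one_way_anova <- function(data, value, group) {
  groups <- as_group_list(data, {{ value }}, {{ group }})
  k <- length(groups)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  n_i <- lengths(groups)
  if (any(n_i < 1)) stop("every group needs >= 1 value", call. = FALSE)
  n <- sum(n_i)
  if (n - k < 1) {
    stop("no within-group degrees of freedom (need >= 1 group with >= 2 values)",
         call. = FALSE)
  }
  all_v <- unlist(groups, use.names = FALSE)
  grand <- mean(all_v)
  m_i <- vapply(groups, mean, numeric(1))
  ss_between <- sum(n_i * (m_i - grand)^2)
  ss_within <- sum(vapply(seq_len(k),
                          function(i) sum((groups[[i]] - m_i[i])^2),
                          numeric(1)))
  df_b <- k - 1
  df_w <- n - k
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  sep <- ms_w == 0 && ms_b > 0
  f <- if (ms_w == 0) {
    if (ms_b == 0) 0 else Inf
  } else {
    ms_b / ms_w
  }
  p <- if (is.infinite(f)) 0 else stats::pf(f, df_b, df_w, lower.tail = FALSE)
  if (sep) {
    warning("zero within-group variance (exact separation); p reported as 0",
            call. = FALSE)
  }
  tibble::tibble(statistic = f, p.value = p, df.between = df_b,
                 df.within = df_w, n = n, k = k, exact.separation = sep)
}

#' Studentized-range distribution function by numerical integration
#'
#' Evaluates \eqn{P(Q \le q)} for the studentized range of `k` groups with
#' `df` within-group degrees of freedom by Gauss-Legendre quadrature of the
#' classical double integral: the inner integral
#' \eqn{k \int \phi(z) [\Phi(z) - \Phi(z - w)]^{k-1} dz} gives the range CDF
#' at a known scale, and the outer integral averages it over the distribution
#' of the estimated standard deviation (a scaled chi variate). Accuracy with
#' the default node counts is well inside 1e-6 absolute; `df = Inf` skips the
#' outer integral.
#'
#' @param q Quantile (>= 0); vectorized.
#' @param k Number of groups (>= 2).
#' @param df Within-group degrees of freedom (>= 1, or `Inf`).
#' @param inner_nodes,outer_nodes Gauss-Legendre node counts.
#' @return \eqn{P(Q \le q)}.
#' @export
studentized_range_cdf <- function(q, k, df, inner_nodes = 128,
                                  outer_nodes = 96) {
  stopifnot(k >= 2, df >= 1)
  gl_z <- pracma::gaussLegendre(inner_nodes, -8.5, 8.5)
  # CDF of the range of k iid standard normals at width w
  range_cdf <- function(w) {
    if (w <= 0) return(0)
    vals <- k * stats::dnorm(gl_z$x) *
      (stats::pnorm(gl_z$x) - stats::pnorm(gl_z$x - w))^(k - 1)
    min(1, sum(gl_z$w * vals))
  }
  one <- function(qi) {
    if (qi <= 0) return(0)
    if (!is.finite(qi)) return(1)
    if (is.infinite(df)) return(range_cdf(qi))
    lo <- sqrt(stats::qchisq(1e-12, df) / df)
    hi <- sqrt(stats::qchisq(1 - 1e-12, df) / df)
    gl_u <- pracma::gaussLegendre(outer_nodes, lo, hi)
    # density of u = sqrt(chi^2_df / df), evaluated in log space
    log_f <- (df / 2) * log(df) - lgamma(df / 2) - (df / 2 - 1) * log(2) +
      (df - 1) * log(gl_u$x) - df * gl_u$x^2 / 2
    pk <- vapply(qi * gl_u$x, range_cdf, numeric(1))
    min(1, sum(gl_u$w * exp(log_f) * pk))
  }
  vapply(q, one, numeric(1))
}

#' Tukey's honest significant difference test
#'
#' All pairwise group comparisons after a one-way ANOVA, with standard errors
#' by the Tukey-Kramer rule for unequal group sizes
#' (\eqn{\sqrt{MS_w/2\,(1/n_i + 1/n_j)}}) and adjusted p-values from the
#' studentized-range distribution evaluated by
#' [studentized_range_cdf()].
#'
#' @inheritParams one_way_anova
#' @return A tibble with one row per pair: `group1`, `group2`, `estimate`
#'   (mean difference, group2 - group1), `std.error`, `statistic` (q),
#'   `adj.p.value`.
#' @export
tukey_hsd <- function(data, value, group) {
  groups <- as_group_list(data, {{ value }}, {{ group }})
  k <- length(groups)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  n_i <- lengths(groups)
  n <- sum(n_i)
  df_w <- n - k
  if (df_w < 1) stop("no within-group degrees of freedom", call. = FALSE)
  m_i <- vapply(groups, mean, numeric(1))
  ms_w <- sum(vapply(seq_len(k),
                     function(i) sum((groups[[i]] - m_i[i])^2),
                     numeric(1))) / df_w
  pairs <- utils::combn(k, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(col) {
    i <- pairs[1, col]; j <- pairs[2, col]
    se <- unname(sqrt(ms_w / 2 * (1 / n_i[i] + 1 / n_i[j])))
    diff <- unname(m_i[j] - m_i[i])
    qstat <- if (se == 0) {
      if (diff == 0) 0 else Inf
    } else {
      abs(diff) / se
    }
    tibble::tibble(
      group1 = names(groups)[i], group2 = names(groups)[j],
      estimate = diff, std.error = se, statistic = qstat,
      adj.p.value = 1 - studentized_range_cdf(qstat, k, df_w)
    )
  })
}

#' Default geological time bins for the epoch comparison
#'
#' Three bins: middle Eocene archaeocetes (remingtonocetids and protocetids,
#' matched by family), late Eocene basilosaurids (matched by family), and
#' Oligocene odontocetes (matched by age, 23.03-33.9 Ma). Family matches take
#' priority over age matches.
#'
#' @return A tibble with columns `bin`, `family`, `age_min`, `age_max`
#'   (several rows may share a bin).
#' @export
epoch_bins <- function() {
  tibble::tribble(
    ~bin, ~family, ~age_min, ~age_max,
    "middle Eocene archaeocetes", "Remingtonocetidae", NA, NA,
    "middle Eocene archaeocetes", "Protocetidae", NA, NA,
    "late Eocene basilosaurids", "Basilosauridae", NA, NA,
    "Oligocene odontocetes", NA, 23.03, 33.9
  )
}

#' Assign fossil estimates to time bins and reduce to species-level values
#'
#' Each estimate is matched to a bin by family first, then (for rows whose
#' family matches no bin) by `age_ma` falling inside `[age_min, age_max]`.
#' Estimates matching no bin are excluded with a warning. Within a bin, the
#' analysis unit is the species: the value is the mean across a species'
#' specimens of the requested column (species mean log10 EQ by default).
#'
#' @param estimates A `fossil_estimates` tibble (or any data frame with
#'   `taxon`, `family`, `age_ma` and the value column).
#' @param bins A bin specification tibble (see [epoch_bins()]).
#' @param value Name of the column to analyse (default
#'   `"log10_EQ_0.56"`).
#' @return A tibble: `bin`, `taxon`, `n_specimens`, `value`.
#' @export
assign_time_bins <- function(estimates, bins = epoch_bins(),
                             value = "log10_EQ_0.56") {
  stopifnot(is.data.frame(estimates), value %in% names(estimates) ||
              nrow(estimates) == 0)
  if (nrow(estimates) == 0) {
    return(tibble::tibble(bin = character(), taxon = character(),
                          n_specimens = integer(), value = numeric()))
  }
  if (!"family" %in% names(estimates)) estimates$family <- NA_character_
  if (!"age_ma" %in% names(estimates)) estimates$age_ma <- NA_real_
  match_bin <- function(family, age) {
    if (!is.na(family)) {
      hit <- bins$bin[!is.na(bins$family) & bins$family == family]
      if (length(hit) > 0) return(hit[1])
    }
    if (!is.na(age)) {
      hit <- bins$bin[!is.na(bins$age_min) & !is.na(bins$age_max) &
                        bins$age_min <= age & age <= bins$age_max]
      if (length(hit) > 0) return(hit[1])
    }
    NA_character_
  }
  estimates$bin <- purrr::map2_chr(estimates$family, estimates$age_ma,
                                   match_bin)
  unmatched <- estimates$taxon[is.na(estimates$bin)]
  if (length(unmatched) > 0) {
    warning("estimate(s) matching no bin excluded: ",
            paste(unique(unmatched), collapse = ", "), call. = FALSE)
  }
  estimates |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$bin, .data$taxon) |>
    dplyr::summarise(n_specimens = dplyr::n(),
                     value = mean(.data[[value]]), .groups = "drop")
}

#' Compare mean log10 EQ across time bins
#'
#' Assigns estimates to bins, reduces to species means, then runs one-way
#' ANOVA followed by Tukey's HSD.
#'
#' @inheritParams assign_time_bins
#' @param alpha Significance level recorded with the result.
#' @return An object of class `epoch_comparison`: a list with `groups` (the
#'   species-level values per bin), `anova` (one-row tibble), `tukey`
#'   (pairwise tibble), `value`, `alpha`. `tidy()` returns the Tukey table,
#'   `glance()` the ANOVA row.
#' @export
compare_epochs <- function(estimates, bins = epoch_bins(),
                           value = "log10_EQ_0.56", alpha = 0.05) {
  species <- assign_time_bins(estimates, bins, value)
  if (dplyr::n_distinct(species$bin) < 2) {
    stop("need species in >= 2 bins to compare", call. = FALSE)
  }
  structure(list(
    groups = species,
    anova = one_way_anova(species, .data$value, .data$bin),
    tukey = tukey_hsd(species, .data$value, .data$bin),
    value = value,
    alpha = alpha
  ), class = "epoch_comparison")
}

#' @export
print.epoch_comparison <- function(x, ...) {
  cat("<epoch_comparison of", x$value, ">\n")
  sizes <- table(x$groups$bin)
  cat("  bins:", paste(sprintf("%s (n=%d)", names(sizes), sizes),
                       collapse = ", "), "\n")
  cat(sprintf("  ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$anova$df.between, x$anova$df.within,
              x$anova$statistic, x$anova$p.value))
  print(x$tukey)
  invisible(x)
}

#' @rdname compare_epochs
#' @param x An `epoch_comparison`.
#' @param ... Unused.
#' @export
tidy.epoch_comparison <- function(x, ...) x$tukey

#' @rdname compare_epochs
#' @export
glance.epoch_comparison <- function(x, ...) x$anova
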