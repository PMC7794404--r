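#' Distance from a point to the nearest marked raster cell
#'
#' Minimum distance from a point to the centre of any cell with value 1 in a
#' binary mask; 0 when the point's own cell is marked. Planar (km) on
#' projected grids, great-circle on lon/lat grids.
#'
#' @param point length-2 numeric (x, y) or (lon, lat).
#' @param mask binary `meltpot_raster`.
#' @return distance in km.
#' @export
nearest_distance <- function(point, mask) {
  nearest_distances(matrix(point, ncol = 2L), mask)[1L]
}

#' Build the per-population predictor table
#'
#' Joins the Simpson admixture index with the distances from each
#' population to the nearest glacial refugium and to the nearest stability
#' area — the design matrix of the attribution models.
#'
#' @param populations data frame with `population` (or `id`) and coordinate
#'   columns `x`, `y` (planar km) or `lon`, `lat`.
#' @param pop_q population-mean admixture from [population_mean_q()].
#' @param refugia,stability binary `meltpot_raster` masks.
#' @return data frame: `population`, `simpson`, `dist_refugium`,
#'   `dist_stability`.
#' @export
build_predictor_table <- function(populations, pop_q, refugia, stability) {
  id_col <- if ("population" %in% names(populations)) "population" else "id"
  xy <- if (all(c("x", "y") %in% names(populations)))
    as.matrix(populations[c("x", "y")]) else as.matrix(populations[c("lon", "lat")])
  qc <- setdiff(names(pop_q), "population")
  i <- match(as.character(populations[[id_col]]),
             as.character(pop_q$population))
  if (anyNA(i))
    stop("populations without admixture rows: ",
         paste(populations[[id_col]][is.na(i)], collapse = ", "))
  simpson <- apply(as.matrix(pop_q[i, qc, drop = FALSE]), 1L, simpson_index)
  data.frame(
    population = as.character(populations[[id_col]]),
    simpson = unname(simpson),
    dist_refugium = nearest_distances(xy, refugia),
    dist_stability = nearest_distances(xy, stability)
  )
}

## vectorised nearest_distance over many points
nearest_distances <- function(xy, mask) {
  cells <- cell_centres(mask)
  v <- mask$values[cbind(cells$row, cells$col)]
  on <- !is.na(v) & v == 1
  if (!any(on)) stop("mask has no marked cell; cannot compute a distance")
  D <- point_distances(xy, cells[on, c("x", "y")], mask$crs)
  d <- apply(D, 1L, min)
  rc <- cell_of(mask, xy)
  inside <- !is.na(rc$row) & mask$values[cbind(rc$row, rc$col)] == 1
  inside[is.na(inside)] <- FALSE
  d[inside] <- 0
  d
}

#' Gaussian GLM (ordinary least squares) fit
#'
#' Fits a Gaussian-family, identity-link model of a diversity response on
#' the supplied predictors by ordinary least squares, and reports
#' coefficient t-tests and the Gaussian AIC
#' \eqn{n \log(2\pi\,RSS/n) + n + 2(k + 2)} (counting the intercept, the
#' `k` slopes and the variance parameter).
#'
#' @param formula model formula.
#' @param data data frame holding response and predictors.
#' @return object of class `meltpot_ols`: the underlying [stats::lm()] fit
#'   plus `coefficients` table, `rss`, `df_residual`, `aic`, `formula_tag`.
#' @export
fit_gaussian_glm <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) {
    fit0 <- stats::lm(formula, data)
    aliased <- names(which(is.na(stats::coef(fit0))))
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  n <- nrow(X)
  if (n <= ncol(X)) stop("need more observations than coefficients")
  fit <- stats::lm(formula, data)
  sm <- summary(fit)$coefficients
  rss <- sum(stats::residuals(fit)^2)
  k <- length(stats::coef(fit)) - 1L
  structure(
    list(
      lm = fit,
      coefficients = data.frame(
        term = rownames(sm), estimate = sm[, 1L], std_error = sm[, 2L],
        t = sm[, 3L], p = sm[, 4L], row.names = NULL),
      rss = rss,
      df_residual = fit$df.residual,
      aic = n * log(2 * pi * rss / n) + n + 2 * (k + 2),
      formula_tag = paste(deparse(formula), collapse = "")
    ),
    class = "meltpot_ols"
  )
}

#' @export
print.meltpot_ols <- function(x, ...) {
  cat("<meltpot_ols>", x$formula_tag, sprintf(" AIC = %.3f\n", x$aic))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Sequential (Type I) ANOVA of an OLS fit
#'
#' Sequential sums of squares in formula order, each term tested against
#' the full model's residual mean square:
#' \eqn{F = (SS_{term}/df_{term}) / (RSS/df_{resid})}.
#'
#' @param fit a `meltpot_ols` from [fit_gaussian_glm()].
#' @return data frame: `term`, `df`, `df_resid`, `F`, `p`.
#' @export
anova_sequential <- function(fit) {
  a <- stats::anova(fit$lm)
  terms <- rownames(a)
  keep <- terms != "Residuals"
  data.frame(
    term = terms[keep],
    df = a$Df[keep],
    df_resid = fit$df_residual,
    F = a$`F value`[keep],
    p = a$`Pr(>F)`[keep],
    row.names = NULL
  )
}

model_set_formulas <- function(response, include_interactions = FALSE) {
  rhs <- c(
    "dist_stability + dist_refugium + simpson",
    "dist_stability + simpson",
    "dist_refugium + simpson",
    "dist_stability",
    "dist_refugium",
    "simpson"
  )
  if (include_interactions)
    rhs <- c(rhs,
             "dist_stability + dist_refugium + simpson + dist_stability:simpson + dist_refugium:simpson",
             "(dist_stability + dist_refugium + simpson)^2")
  lapply(rhs, function(r) stats::as.formula(paste(response, "~", r)))
}

#' Fit and rank the attribution model set
#'
#' For each diversity response (rarefied allelic richness `Ar` and expected
#' heterozygosity `He`) fits the fixed set of Gaussian GLMs — the full
#' three-predictor model, the two Simpson-containing two-predictor models,
#' and the three single-predictor models (plus two-way-interaction models
#' when `include_interactions = TRUE`) — and ranks them by AIC, reporting
#' coefficient tables and sequential ANOVA for every model.
#'
#' @param diversity data frame with `population` and the response columns.
#' @param predictors predictor table from [build_predictor_table()].
#' @param responses response column names (default `c("Ar", "He")`).
#' @param include_interactions also fit interaction models (default `FALSE`).
#' @return object of class `meltpot_model_comparison`: per response a list
#'   of fits (each with `ols`, `anova`), an `aic` table ranked best-first,
#'   and `best` (the AIC-best fit's index in `fits`).
#' @export
run_model_set <- function(diversity, predictors, responses = c("Ar", "He"),
                          include_interactions = FALSE) {
  i <- match(as.character(predictors$population),
             as.character(diversity$population))
  if (anyNA(i))
    stop("predictor populations without diversity rows: ",
         paste(predictors$population[is.na(i)], collapse = ", "))
  data <- cbind(predictors,
                diversity[i, setdiff(names(diversity), "population"),
                          drop = FALSE])
  if (nrow(data) < 8)
    stop("model set needs at least 8 populations; got ", nrow(data))
  out <- list()
  for (resp in responses) {
    forms <- model_set_formulas(resp, include_interactions)
    fits <- lapply(forms, function(f) {
      ols <- fit_gaussian_glm(f, data)
      list(ols = ols, anova = anova_sequential(ols))
    })
    aic <- data.frame(
      model = vapply(fits, function(f) f$ols$formula_tag, character(1)),
      aic = vapply(fits, function(f) f$ols$aic, numeric(1))
    )
    ranking <- order(aic$aic)
    out[[resp]] <- list(fits = fits, aic = aic[ranking, ],
                        best = ranking[1L])
  }
  structure(list(responses = out, n = nrow(data),
                 data = data), class = "meltpot_model_comparison")
}

#' @export
print.meltpot_model_comparison <- function(x, ...) {
  for (resp in names(x$responses)) {
    r <- x$responses[[resp]]
    cat(sprintf("Response %s (n = %d): AIC ranking\n", resp, x$n))
    print(r$aic, row.names = FALSE, digits = 6)
    best <- r$fits[[r$best]]
    cat("Best model coefficients:\n")
    print(best$ols$coefficients, digits = 4)
    cat("\n")
  }
  invisible(x)
}

#' Restrict a table to selected populations
#'
#' Row filter by population id, preserving input order — used to reproduce
#' a geographic restriction of the analysis (e.g. dropping populations for
#' which no refugium could be mapped).
#'
#' @param table data frame with a `population` column.
#' @param include_ids character or integer vector of population ids to keep.
#' @return the filtered table.
#' @export
subset_populations <- function(table, include_ids) {
  keep <- as.character(table$population) %in% as.character(include_ids)
  if (!any(keep)) stop("no population matches the requested ids")
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Driver-recovery verdict of a model comparison
#'
#' Pre-specified rule for deciding which driver a fitted model comparison
#' supports, used by the synthetic-world recovery experiments. For a given
#' response it reports: whether the AIC-best model contains the Simpson
#' term / a distance term; the p-value of the Simpson term inside the
#' AIC-best model containing it; the smallest distance-term p-value inside
#' the AIC-best model containing a distance term; and the marginal
#' coefficient p-values of all three predictors in the full model.
#'
#' @param mc a `meltpot_model_comparison`.
#' @param response which response to assess (default `"He"`).
#' @return list of flags and p-values (see Details).
#' @export
recovery_flags <- function(mc, response = "He") {
  r <- mc$responses[[response]]
  if (is.null(r)) stop("no such response in the comparison: ", response)
  best <- r$fits[[r$best]]
  terms_best <- best$ols$coefficients$term
  full <- r$fits[[1L]]$ols$coefficients   # full model is always first
  dist_terms <- c("dist_refugium", "dist_stability")
  coef_p <- function(tab, term) {
    i <- match(term, tab$term)
    if (is.na(i)) NA_real_ else tab$p[i]
  }
  best_simpson_p <- coef_p(best$ols$coefficients, "simpson")
  best_dist_p <- suppressWarnings(
    min(stats::na.omit(vapply(dist_terms,
                              function(t) coef_p(best$ols$coefficients, t),
                              numeric(1)))))
  if (!is.finite(best_dist_p)) best_dist_p <- NA_real_
  best_dist_est <- NA_real_
  in_best <- intersect(dist_terms, terms_best)
  if (length(in_best)) {
    i <- match(in_best, best$ols$coefficients$term)
    j <- i[which.min(best$ols$coefficients$p[i])]
    best_dist_est <- best$ols$coefficients$estimate[j]
  }
  list(
    best_model = best$ols$formula_tag,
    best_contains_simpson = "simpson" %in% terms_best,
    best_contains_distance = length(in_best) > 0,
    simpson_p_best = best_simpson_p,
    distance_p_best = best_dist_p,
    distance_estimate_best = best_dist_est,
    simpson_p_full = coef_p(full, "simpson"),
    dist_refugium_p_full = coef_p(full, "dist_refugium"),
    dist_stability_p_full = coef_p(full, "dist_stability")
  )
}
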