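#' Occurrence sets
#'
#' Occurrence records are data frames with coordinate columns `lon`, `lat`
#' plus optional `source` and `uncertainty` (positional uncertainty in
#' arcseconds). A `crs` attribute (`"lonlat"` or `"planar"`) controls
#' distance computations; synthetic planar worlds store km in the coordinate
#' columns.
#'
#' @param lon,lat coordinates.
#' @param source optional character tag per record.
#' @param uncertainty optional positional uncertainty (arcseconds).
#' @param crs `"lonlat"` (default) or `"planar"`.
#' @return data frame of occurrences with a `crs` attribute.
#' @export
occurrence_set <- function(lon, lat, source = NA_character_,
                           uncertainty = NA_real_, crs = "lonlat") {
  n <- length(lon)
  out <- data.frame(lon = as.numeric(lon), lat = as.numeric(lat),
                    source = rep_len(source, n),
                    uncertainty = rep_len(as.numeric(uncertainty), n))
  attr(out, "crs") <- crs
  out
}

occ_crs <- function(x) {
  crs <- attr(x, "crs")
  if (is.null(crs)) "lonlat" else crs
}

#' Clean raw occurrence records
#'
#' Removes exact coordinate duplicates (first record kept) and records whose
#' positional uncertainty is at or above `max_uncertainty_arcsec`. Records
#' with unknown uncertainty are kept.
#'
#' @param occ an [occurrence_set()].
#' @param max_uncertainty_arcsec removal threshold in arcseconds (default 30).
#' @return the cleaned occurrence set.
#' @export
clean_occurrences <- function(occ, max_uncertainty_arcsec = 30) {
  keep <- is.na(occ$uncertainty) | occ$uncertainty < max_uncertainty_arcsec
  out <- occ[keep, , drop = FALSE]
  out <- out[!duplicated(out[c("lon", "lat")]), , drop = FALSE]
  if (nrow(out) == 0) stop("no occurrence records survive cleaning")
  attr(out, "crs") <- occ_crs(occ)
  rownames(out) <- NULL
  out
}

#' Spatially thin occurrence records
#'
#' Produces `n_datasets` alternative thinned datasets in which no two
#' retained records lie closer than `d_min` km. Thinning is greedy: while
#' any pair conflicts, the record involved in the most conflicts is removed,
#' ties broken at random (a different random stream per replicate). The
#' records removed by each replicate are returned as its validation set.
#'
#' @param occ an [occurrence_set()].
#' @param d_min minimum nearest-neighbour distance in km.
#' @param n_datasets number of alternative thinned datasets (default 5).
#' @param seed integer seed.
#' @return list of length `n_datasets`; each element has `retained` and
#'   `excluded` occurrence sets.
#' @export
thin_occurrences <- function(occ, d_min, n_datasets = 5, seed = 1) {
  if (d_min <= 0) stop("d_min must be positive")
  n <- nrow(occ)
  D <- point_distances(occ[c("lon", "lat")], occ[c("lon", "lat")],
                       occ_crs(occ))
  conflict <- D < d_min
  diag(conflict) <- FALSE
  set.seed(seed)
  reps <- lapply(seq_len(n_datasets), function(r) {
    cf <- conflict
    alive <- rep(TRUE, n)
    while (TRUE) {
      deg <- rowSums(cf[, alive, drop = FALSE]) * alive
      if (!any(deg > 0)) break
      worst <- which(deg == max(deg))
      drop <- if (length(worst) > 1) sample(worst, 1L) else worst
      alive[drop] <- FALSE
      cf[drop, ] <- FALSE
      cf[, drop] <- FALSE
    }
    if (sum(alive) < 2)
      warning("thinning replicate ", r, " retained fewer than 2 records")
    ret <- occ[alive, , drop = FALSE]
    exc <- occ[!alive, , drop = FALSE]
    attr(ret, "crs") <- occ_crs(occ); attr(exc, "crs") <- occ_crs(occ)
    rownames(ret) <- NULL; rownames(exc) <- NULL
    list(retained = ret, excluded = exc)
  })
  reps
}

#' Prune collinear variables by variance inflation factor
#'
#' Iteratively regresses each variable on all others, computes
#' \eqn{VIF_j = 1 / (1 - R^2_j)}, and removes the variable with the largest
#' VIF while any VIF is at or above `threshold`. Perfectly collinear
#' variables get infinite VIF and are removed first.
#'
#' @param X numeric design matrix or data frame (columns = variables).
#' @param threshold VIF retention threshold (default 5: keep `VIF < 5`).
#' @return character vector of retained variable names, in input order.
#' @export
vif_select <- function(X, threshold = 5) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (ncol(X) < 2) stop("VIF selection needs at least 2 variables")
  if (nrow(X) <= ncol(X)) stop("VIF selection needs more rows than variables")
  keep <- colnames(X)
  repeat {
    if (length(keep) == 1L) break
    vifs <- vapply(keep, function(v) {
      fit <- stats::lm.fit(cbind(1, X[, setdiff(keep, v), drop = FALSE]),
                           X[, v])
      rss <- sum(fit$residuals^2)
      tss <- sum((X[, v] - mean(X[, v]))^2)
      if (tss == 0) return(Inf)
      r2 <- 1 - rss / tss
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    if (max(vifs) < threshold) break
    keep <- setdiff(keep, keep[which.max(vifs)])
  }
  colnames(X)[colnames(X) %in% keep]
}

#' Target-group background points
#'
#' Uses the occurrence records of a broader sampled taxon group, restricted
#' to a region mask and de-duplicated to one record per raster cell, as
#' background points that carry the same spatial sampling bias as the
#' presences.
#'
#' @param target_group an [occurrence_set()] of target-group records.
#' @param region_mask a binary `meltpot_raster` (1 = inside the region).
#' @return occurrence set of background points, one per occupied cell.
#' @export
target_group_background <- function(target_group, region_mask) {
  if (nrow(target_group) == 0) stop("target group is empty")
  rc <- cell_of(region_mask, target_group[c("lon", "lat")])
  inside <- !is.na(rc$row) &
    region_mask$values[cbind(rc$row, rc$col)] == 1
  inside[is.na(inside)] <- FALSE
  out <- target_group[inside, , drop = FALSE]
  if (nrow(out) == 0) stop("no target-group records fall inside the region mask")
  cellkey <- paste(rc$row[inside], rc$col[inside])
  out <- out[!duplicated(cellkey), , drop = FALSE]
  attr(out, "crs") <- occ_crs(target_group)
  rownames(out) <- NULL
  out
}

#' Area under the ROC curve
#'
#' Rank-statistic AUC: the probability that a randomly drawn presence score
#' exceeds a randomly drawn background score, ties counting one half.
#'
#' @param scores_presence,scores_background numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores_presence, scores_background) {
  n1 <- length(scores_presence); n0 <- length(scores_background)
  if (n1 == 0 || n0 == 0) stop("both score groups must be non-empty")
  r <- rank(c(scores_presence, scores_background), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold maximising the true skill statistic
#'
#' Scans the unique observed scores as candidate thresholds; a score is
#' predicted present when it is at or above the threshold. Returns the
#' smallest threshold attaining the maximum of
#' TSS = sensitivity + specificity - 1.
#'
#' @param scores_presence,scores_background numeric score vectors.
#' @return list with `threshold` and `tss`.
#' @export
max_tss_threshold <- function(scores_presence, scores_background) {
  if (!length(scores_presence) || !length(scores_background))
    stop("both score groups must be non-empty")
  cand <- sort(unique(c(scores_presence, scores_background)))
  tss <- vapply(cand, function(t) {
    sens <- mean(scores_presence >= t)
    spec <- mean(scores_background < t)
    sens + spec - 1
  }, numeric(1))
  best <- max(tss)
  list(threshold = cand[which(tss >= best - 1e-12)[1L]], tss = best)
}

#' Binomial GLM learner
#'
#' The built-in baseline learner: a binomial-family linear classifier with
#' logit link, optionally with quadratic terms, fitted by iteratively
#' reweighted least squares via [stats::glm()]. Conforms to the learner
#' contract used by [fit_ensemble()]: a `fit(X, y)` function returning a
#' fitted object and a `predict(fit, X)` function returning probabilities.
#'
#' @param quadratic add squared terms for every variable (default `FALSE`).
#' @return a learner object (list with `name`, `fit`, `predict`).
#' @export
glm_learner <- function(quadratic = FALSE) {
  expand <- function(X) {
    X <- as.matrix(X)
    if (quadratic) {
      X2 <- X^2
      colnames(X2) <- paste0(colnames(X), "_sq")
      X <- cbind(X, X2)
    }
    X
  }
  list(
    name = if (quadratic) "glm_quadratic" else "glm_linear",
    fit = function(X, y) {
      d <- data.frame(expand(X))
      d$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = d, family = stats::binomial()))
    },
    predict = function(fit, X) {
      unname(stats::predict(fit, newdata = data.frame(expand(X)),
                            type = "response"))
    }
  )
}

#' Spline GAM learner
#'
#' Generalised additive model learner with thin-plate smooths per variable
#' (binomial family, logit link), fitted with \pkg{mgcv}.
#'
#' @param k basis dimension per smooth (default 4).
#' @return a learner object.
#' @export
gam_learner <- function(k = 4) {
  list(
    name = "gam",
    fit = function(X, y) {
      d <- data.frame(as.matrix(X))
      d$.y <- y
      ks <- pmin(k, vapply(d[setdiff(names(d), ".y")],
                           function(v) length(unique(v)), integer(1)) - 1L)
      terms <- ifelse(ks >= 3,
                      sprintf("s(%s, k = %d)", setdiff(names(d), ".y"), ks),
                      setdiff(names(d), ".y"))
      f <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
      suppressWarnings(mgcv::gam(f, data = d, family = stats::binomial()))
    },
    predict = function(fit, X) {
      unname(as.numeric(stats::predict(fit, newdata = data.frame(as.matrix(X)),
                                       type = "response")))
    }
  )
}

values_at <- function(stack, vars, pts) {
  X <- sapply(vars, function(v) extract_values(stack$layers[[v]],
                                               pts[c("lon", "lat")]))
  matrix(X, nrow = nrow(pts), dimnames = list(NULL, vars))
}

#' Fit an AUC-weighted ensemble distribution model
#'
#' Fits every learner on every thinned calibration dataset (presences versus
#' target-group background), validates each fitted model on the presences
#' that its thinning replicate excluded against a fresh random-cell
#' background sample disjoint from the training background, and keeps models
#' whose validation AUC exceeds `auc_cutoff`. The ensemble prediction is the
#' AUC-weighted mean of the included models' probabilities; the maxTSS
#' binarisation threshold is computed on the ensemble's validation
#' predictions.
#'
#' @param thinned list of thinned replicates from [thin_occurrences()].
#' @param background occurrence set of background points.
#' @param env a `meltpot_stack` of calibration layers.
#' @param vars variable (layer) names to use, e.g. from [vif_select()].
#' @param learners list of learner objects (default: linear GLM, quadratic
#'   GLM, GAM).
#' @param auc_cutoff inclusion threshold on validation AUC (default 0.7).
#' @param n_validation_bg validation background points per replicate
#'   (default 200).
#' @param seed integer seed for the validation background draw.
#' @return object of class `meltpot_ensemble` with elements `models`
#'   (fitted learners with replicate id, AUC, inclusion flag, weight),
#'   `vars`, `threshold` (maxTSS), `tss`, and `auc_cutoff`.
#' @export
fit_ensemble <- function(thinned, background, env, vars,
                         learners = list(glm_learner(), glm_learner(TRUE),
                                         gam_learner()),
                         auc_cutoff = 0.7, n_validation_bg = 200, seed = 1) {
  if (!length(learners)) stop("at least one learner is required")
  if (!length(thinned)) stop("at least one thinned dataset is required")
  Xbg <- values_at(env, vars, background)
  ok_bg <- stats::complete.cases(Xbg)
  Xbg <- Xbg[ok_bg, , drop = FALSE]
  ref <- env$layers[[vars[1L]]]
  bg_cells <- cell_of(ref, background[ok_bg, c("lon", "lat")])
  bg_key <- paste(bg_cells$row, bg_cells$col)
  centres <- cell_centres(ref)
  free <- !(paste(centres$row, centres$col) %in% bg_key)
  set.seed(seed)
  models <- list()
  val_pred_p <- list(); val_pred_b <- list()
  for (r in seq_along(thinned)) {
    pres <- thinned[[r]]$retained
    excl <- thinned[[r]]$excluded
    Xp <- values_at(env, vars, pres)
    ok_p <- stats::complete.cases(Xp)
    Xtrain <- rbind(Xp[ok_p, , drop = FALSE], Xbg)
    ytrain <- c(rep(1L, sum(ok_p)), rep(0L, nrow(Xbg)))
    if (nrow(excl) == 0) {
      warning("thinning replicate ", r, " excluded no presences; ",
              "validating on its training presences")
      excl <- pres
    }
    Xv_p <- values_at(env, vars, excl)
    Xv_p <- Xv_p[stats::complete.cases(Xv_p), , drop = FALSE]
    pickable <- which(free)
    vb <- centres[sample(pickable, min(n_validation_bg, length(pickable))), ]
    Xv_b <- sapply(vars, function(v)
      env$layers[[v]]$values[cbind(vb$row, vb$col)])
    Xv_b <- matrix(Xv_b, nrow = nrow(vb), dimnames = list(NULL, vars))
    Xv_b <- Xv_b[stats::complete.cases(Xv_b), , drop = FALSE]
    for (l in learners) {
      fit <- l$fit(Xtrain, ytrain)
      sp <- l$predict(fit, Xv_p)
      sb <- l$predict(fit, Xv_b)
      models[[length(models) + 1L]] <- list(
        learner = l, fit = fit, replicate = r,
        auc = roc_auc(sp, sb),
        val_presence = sp, val_background = sb
      )
    }
  }
  aucs <- vapply(models, `[[`, numeric(1), "auc")
  include <- aucs > auc_cutoff
  if (!any(include))
    stop("no model exceeds the AUC cutoff ", auc_cutoff, "; AUCs: ",
         paste(sprintf("%.3f", aucs), collapse = ", "))
  w <- ifelse(include, aucs, 0)
  w <- w / sum(w)
  for (i in seq_along(models)) {
    models[[i]]$included <- include[i]
    models[[i]]$weight <- w[i]
  }
  ## ensemble validation scores: AUC-weighted within each replicate
  ## (validation point sets differ across replicates)
  val_p <- c(); val_b <- c()
  for (r in seq_along(thinned)) {
    idx <- which(include & vapply(models, `[[`, numeric(1), "replicate") == r)
    if (!length(idx)) next
    wr <- aucs[idx] / sum(aucs[idx])
    val_p <- c(val_p, Reduce(`+`, Map(function(i, wi)
      wi * models[[i]]$val_presence, idx, wr)))
    val_b <- c(val_b, Reduce(`+`, Map(function(i, wi)
      wi * models[[i]]$val_background, idx, wr)))
  }
  thr <- max_tss_threshold(val_p, val_b)
  structure(
    list(models = models, vars = vars, threshold = thr$threshold,
         tss = thr$tss, auc_cutoff = auc_cutoff,
         aucs = aucs, weights = w),
    class = "meltpot_ensemble"
  )
}

#' @export
print.meltpot_ensemble <- function(x, ...) {
  cat(sprintf(
    "<meltpot_ensemble> %d models (%d included, AUC > %.2f)\n",
    length(x$models), sum(vapply(x$models, `[[`, logical(1), "included")),
    x$auc_cutoff))
  cat(sprintf("  AUC: %s\n", paste(sprintf("%.3f", x$aucs), collapse = " ")))
  cat(sprintf("  maxTSS threshold %.3f (TSS %.3f)\n", x$threshold, x$tss))
  invisible(x)
}

#' Project an ensemble onto an environmental scenario
#'
#' Per-cell AUC-weighted ensemble probability on any scenario stack that
#' supplies every calibration variable; nodata cells stay `NA`.
#'
#' @param model a `meltpot_ensemble`.
#' @param env_scenario a `meltpot_stack`.
#' @return suitability `meltpot_raster` with values in `[0, 1]`.
#' @export
project_suitability <- function(model, env_scenario) {
  sd_ <- stack_design(env_scenario, model$vars)
  ok <- stats::complete.cases(sd_$X)
  pred <- rep(NA_real_, nrow(sd_$X))
  if (any(ok)) {
    Xok <- sd_$X[ok, , drop = FALSE]
    acc <- 0
    for (m in model$models) {
      if (!m$included) next
      acc <- acc + m$weight * m$learner$predict(m$fit, Xok)
    }
    pred[ok] <- pmin(1, pmax(0, acc))
  }
  ref <- env_scenario$layers[[model$vars[1L]]]
  out <- ref$values
  out[cbind(sd_$cells$row, sd_$cells$col)] <- pred
  raster_grid(out, xll = ref$xll, yll = ref$yll, cellsize = ref$cellsize,
              crs = ref$crs, nodata = ref$nodata)
}

#' Threshold a suitability map
#'
#' @param suitability a `meltpot_raster` with values in `[0, 1]`.
#' @param threshold cell = 1 when suitability >= threshold.
#' @return binary `meltpot_raster` (NA cells propagate).
#' @export
binarize <- function(suitability, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  v <- suitability$values
  v[v == suitability$nodata] <- NA_real_
  out <- ifelse(is.na(v), NA_real_, as.numeric(v >= threshold))
  raster_grid(out, xll = suitability$xll, yll = suitability$yll,
              cellsize = suitability$cellsize, crs = suitability$crs,
              nodata = suitability$nodata)
}

#' Consensus of binary maps across palaeoclimate models
#'
#' A cell is a putative glacial refugium when at least `min_agree` of the
#' per-GCM binary suitability maps classify it as suitable.
#'
#' @param binary_maps list of binary `meltpot_raster` maps on one geometry.
#' @param min_agree agreement count required (default 2).
#' @return consensus `meltpot_raster` (0/1) with an `agreement` attribute
#'   holding the per-cell agreement count matrix.
#' @export
gcm_consensus <- function(binary_maps, min_agree = 2) {
  if (!length(binary_maps)) stop("no binary maps supplied")
  ref <- binary_maps[[1L]]
  for (b in binary_maps)
    if (!same_geometry(ref, b)) stop("binary maps differ in geometry")
  agree <- Reduce(`+`, lapply(binary_maps, function(b) {
    v <- b$values
    v[is.na(v) | v == b$nodata] <- 0
    v
  }))
  out <- raster_grid((agree >= min_agree) * 1, xll = ref$xll, yll = ref$yll,
                     cellsize = ref$cellsize, crs = ref$crs,
                     nodata = ref$nodata)
  attr(out, "agreement") <- agree
  out
}

#' Ancestral-area polygons
#'
#' @param coords two-column matrix of ring vertices (closed or open; the
#'   ring is closed automatically).
#' @param lineage lineage tag.
#' @param hpd highest-posterior-density level of the contour (fraction).
#' @return object of class `ancestral_area`.
#' @export
ancestral_area <- function(coords, lineage = "lineage", hpd = 0.7) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2 || nrow(coords) < 3)
    stop("a polygon ring needs at least 3 vertices of 2 coordinates")
  if (any(coords[1L, ] != coords[nrow(coords), ]))
    coords <- rbind(coords, coords[1L, ])
  structure(list(coords = coords, lineage = lineage, hpd = hpd),
            class = "ancestral_area")
}

points_in_polygons <- function(xy, polygons) {
  if (inherits(polygons, "ancestral_area")) polygons <- list(polygons)
  inside <- rep(FALSE, nrow(xy))
  for (p in polygons)
    inside <- inside | mgcv::in.out(p$coords, as.matrix(xy))
  inside
}

#' Long-term stability areas
#'
#' A cell is stable when it is a consensus glacial refugium, its centre lies
#' inside an ancestral-area polygon, and (when `include_current = TRUE`,
#' the default) it is also suitable under the current climate — i.e. every
#' available time window supports species presence there. With
#' `include_current = FALSE` only the refugium/ancestral overlap is
#' required.
#'
#' @param current binary current-suitability `meltpot_raster`.
#' @param refugia consensus refugia map from [gcm_consensus()].
#' @param ancestral an [ancestral_area()] or a list of them.
#' @param include_current require current suitability too (default `TRUE`).
#' @return binary stability `meltpot_raster`.
#' @export
stability_areas <- function(current, refugia, ancestral,
                            include_current = TRUE) {
  if (!same_geometry(current, refugia))
    stop("current and refugia maps differ in geometry")
  cells <- cell_centres(refugia)
  inside <- points_in_polygons(cells[c("x", "y")], ancestral)
  m <- matrix(0, nrow(refugia$values), ncol(refugia$values))
  m[cbind(cells$row, cells$col)] <- as.numeric(inside)
  if (!any(m == 1))
    warning("no cell centre falls inside the ancestral polygon(s)")
  ref_v <- refugia$values; ref_v[is.na(ref_v)] <- 0
  cur_v <- current$values; cur_v[is.na(cur_v)] <- 0
  stable <- (ref_v == 1) & (m == 1)
  if (include_current) stable <- stable & (cur_v == 1)
  raster_grid(stable * 1, xll = refugia$xll, yll = refugia$yll,
              cellsize = refugia$cellsize, crs = refugia$crs,
              nodata = refugia$nodata)
}
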