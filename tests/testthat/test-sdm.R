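planar_occ <- function(x, y, ...) occurrence_set(x, y, ..., crs = "planar")

test_that("occurrence cleaning removes duplicates and imprecise records", {
  occ <- occurrence_set(lon = c(10, 10, 11, 12), lat = c(45, 45, 45, 45),
                        uncertainty = c(5, 5, 45, NA))
  out <- clean_occurrences(occ)
  expect_equal(nrow(out), 2)               # duplicate collapsed, 45" removed
  expect_false(11 %in% out$lon)
  clean <- occurrence_set(c(1, 2), c(3, 4), uncertainty = c(1, 2))
  expect_equal(nrow(clean_occurrences(clean)), 2)
  expect_error(clean_occurrences(occurrence_set(5, 5, uncertainty = 60)),
               "survive")
})

test_that("thinning enforces the minimum nearest-neighbour distance", {
  # all pairs far apart: identity, nothing excluded
  far <- planar_occ(c(0, 100, 200), c(0, 0, 0))
  thin <- thin_occurrences(far, d_min = 5, n_datasets = 2, seed = 1)
  expect_equal(nrow(thin[[1]]$retained), 3)
  expect_equal(nrow(thin[[1]]$excluded), 0)
  # two points 3 km apart: exactly one survives (with the <2-left warning)
  close2 <- planar_occ(c(0, 3), c(0, 0))
  expect_warning(thin_occurrences(close2, d_min = 5, n_datasets = 1, seed = 1),
                 "fewer than 2")
  thin2 <- suppressWarnings(thin_occurrences(close2, d_min = 5, seed = 1))[[1]]
  expect_equal(nrow(thin2$retained), 1)
  expect_equal(nrow(thin2$excluded), 1)
  # three collinear points 4 km apart: the endpoints form the maximal set
  col3 <- planar_occ(c(0, 4, 8), c(0, 0, 0))
  thin3 <- thin_occurrences(col3, d_min = 5, seed = 1)[[1]]
  expect_equal(sort(thin3$retained$lon), c(0, 8))
  expect_error(thin_occurrences(col3, d_min = 0), "positive")
})

test_that("no thinned dataset contains a pair closer than d_min (full scan)", {
  set.seed(14)
  for (rep in 1:5) {
    occ <- planar_occ(runif(40, 0, 100), runif(40, 0, 100))
    for (t in thin_occurrences(occ, d_min = 15, n_datasets = 3, seed = rep)) {
      r <- t$retained
      if (nrow(r) < 2) next
      D <- meltpot:::point_distances(r[c("lon", "lat")], r[c("lon", "lat")],
                                     "planar")
      diag(D) <- Inf
      expect_gte(min(D), 15)
    }
  }
})

test_that("great-circle distances are used for lon/lat thinning", {
  # ~111 km apart along a meridian: kept at d_min 100, thinned at 120
  occ <- occurrence_set(c(10, 10), c(45, 46))
  expect_equal(nrow(thin_occurrences(occ, d_min = 100, seed = 1)[[1]]$retained), 2)
  thin <- suppressWarnings(thin_occurrences(occ, d_min = 120, seed = 1))
  expect_equal(nrow(thin[[1]]$retained), 1)
})

test_that("VIF pruning keeps orthogonal variables and drops collinear ones", {
  set.seed(2)
  n <- 200
  a <- rnorm(n); b <- rnorm(n)
  expect_equal(vif_select(cbind(a = a, b = b)), c("a", "b"))
  # exact duplicate: one of the pair goes
  kept <- vif_select(cbind(a = a, a2 = a, b = b))
  expect_length(kept, 2)
  expect_true("b" %in% kept)
  # correlation 0.9 -> VIF 5.26 >= 5: one removed
  r <- 0.9
  c2 <- r * a + sqrt(1 - r^2) * rnorm(n)
  rho <- cor(a, c2)
  expect_length(vif_select(cbind(a = a, c2 = c2), threshold = 5),
                if (1 / (1 - rho^2) >= 5) 1 else 2)
  expect_error(vif_select(cbind(a = a)), "at least 2")
})

test_that("target-group background is mask-restricted and one per cell", {
  mask <- raster_grid(matrix(c(1, 1, 0, 0), 2, 2), cellsize = 10,
                      crs = "planar")
  tg <- planar_occ(c(2, 3, 8, 15, 15), c(12, 13, 17, 5, 18))
  bg <- target_group_background(tg, mask)
  # points in the right column (x >= 10) are outside the mask
  expect_true(all(bg$lon < 10))
  # cell deduplication: pigeonhole bound
  expect_lte(nrow(bg), sum(mask$values == 1))
  expect_error(target_group_background(planar_occ(15, 5), mask), "inside")
  expect_error(target_group_background(tg[0, ], mask), "empty")
})

test_that("rank AUC matches its definition and the pair-counting oracle", {
  expect_equal(roc_auc(c(5, 6), c(1, 2)), 1)
  expect_equal(roc_auc(c(3, 3), c(3, 3)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  set.seed(8)
  for (i in 1:20) {
    sp <- round(runif(sample(1:12, 1)), 2)
    sb <- round(runif(sample(1:12, 1)), 2)
    expect_equal(roc_auc(sp, sb), auc_pair_oracle(sp, sb), tolerance = 1e-12)
  }
  expect_error(roc_auc(numeric(0), 1), "non-empty")
})

test_that("maxTSS threshold equals an exhaustive fine-grid scan", {
  r <- max_tss_threshold(c(0.9, 0.8), c(0.2, 0.1))
  expect_equal(r$threshold, 0.8)
  expect_equal(r$tss, 1)
  expect_equal(max_tss_threshold(c(0.5, 0.5), c(0.5, 0.5))$tss, 0)
  expect_equal(max_tss_threshold(0.9, c(0.1, 0.3))$tss, 1)
  set.seed(30)
  for (i in 1:15) {
    sp <- runif(8); sb <- runif(10)
    got <- max_tss_threshold(sp, sb)
    grid <- seq(0, 1, by = 1e-3)
    tss_at <- vapply(grid, function(t)
      mean(sp >= t) + mean(sb < t) - 1, numeric(1))
    expect_equal(got$tss, max(tss_at), tolerance = 1e-9)
  }
})

test_that("ensemble weighting follows validation AUC with the inclusion cutoff", {
  # learner stubs with controlled skill: the 'oracle' learner scores by the
  # true layer; the 'coin' learner returns a constant
  oracle_learner <- list(name = "oracle",
                         fit = function(X, y) NULL,
                         predict = function(fit, X) plogis(3 * X[, "bio1"]))
  coin_learner <- list(name = "coin",
                       fit = function(X, y) NULL,
                       predict = function(fit, X) rep(0.5, nrow(X)))
  w <- generate_world(small_world_config(seed = 41))
  occ <- clean_occurrences(w$occurrences)
  thinned <- thin_occurrences(occ, d_min = 15, n_datasets = 2, seed = 2)
  region <- raster_grid(matrix(1, 20, 20), cellsize = 10, crs = "planar")
  bg <- target_group_background(w$target_group, region)
  # single strong learner: weight 1, ensemble equals that model
  e1 <- fit_ensemble(thinned, bg, w$env_current, vars = c("bio1", "bio2"),
                     learners = list(oracle_learner), seed = 3)
  expect_equal(sum(vapply(e1$models, `[[`, numeric(1), "weight")), 1)
  expect_true(all(e1$aucs > 0.7))
  # uninformative learner is excluded from the weights
  e2 <- fit_ensemble(thinned, bg, w$env_current,
                     vars = c("bio1", "bio2"),
                     learners = list(oracle_learner, coin_learner), seed = 3)
  coin_idx <- vapply(e2$models, function(m) m$learner$name == "coin",
                     logical(1))
  expect_true(all(!vapply(e2$models[coin_idx], `[[`, logical(1), "included")))
  expect_true(all(vapply(e2$models[coin_idx], `[[`, numeric(1), "weight") == 0))
  # nothing above the cutoff is an error listing the AUCs
  expect_error(fit_ensemble(thinned, bg, w$env_current,
                            vars = c("bio1", "bio2"),
                            learners = list(coin_learner), seed = 3),
               "AUC cutoff")
})

test_that("projection reproduces calibration suitability and stays in [0, 1]", {
  w <- generate_world(small_world_config(seed = 43))
  occ <- clean_occurrences(w$occurrences)
  thinned <- thin_occurrences(occ, d_min = 15, n_datasets = 2, seed = 5)
  region <- raster_grid(matrix(1, 20, 20), cellsize = 10, crs = "planar")
  bg <- target_group_background(w$target_group, region)
  ens <- fit_ensemble(thinned, bg, w$env_current, vars = c("bio1", "bio2"),
                      learners = list(glm_learner()), seed = 7)
  cal <- project_suitability(ens, w$env_current)
  cal2 <- project_suitability(ens, w$env_current)
  expect_identical(cal$values, cal2$values)     # identity scenario
  expect_true(all(cal$values >= 0 & cal$values <= 1, na.rm = TRUE))
  # constant layers give a constant map
  const <- env_stack(list(
    bio1 = raster_grid(matrix(0.3, 20, 20), cellsize = 10, crs = "planar"),
    bio2 = raster_grid(matrix(-1, 20, 20), cellsize = 10, crs = "planar")))
  cm <- project_suitability(ens, const)
  expect_equal(length(unique(as.vector(cm$values))), 1)
  # random scenarios stay bounded
  set.seed(50)
  for (i in 1:5) {
    rnd <- env_stack(list(
      bio1 = raster_grid(matrix(rnorm(400, sd = 3), 20, 20), cellsize = 10,
                         crs = "planar"),
      bio2 = raster_grid(matrix(rnorm(400, sd = 3), 20, 20), cellsize = 10,
                         crs = "planar")))
    v <- project_suitability(ens, rnd)$values
    expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
  }
  # a missing layer is a named error
  expect_error(project_suitability(ens, env_stack(list(
    bio1 = raster_grid(matrix(0, 20, 20), cellsize = 10, crs = "planar")))),
    "bio2")
})

test_that("binarisation is a clean threshold rule and idempotent", {
  r <- raster_grid(matrix(c(0.2, 0.5, 0.8, NA), 2, 2), cellsize = 1)
  b <- binarize(r, 0.5)
  expect_equal(as.vector(b$values), c(0, 1, 1, NA))
  expect_equal(as.vector(binarize(r, 0)$values), c(1, 1, 1, NA))
  b2 <- binarize(binarize(r, 0.5), 0.5)
  expect_equal(b2$values, b$values)
  expect_error(binarize(r, 1.5), "\\[0, 1\\]")
})

test_that("GCM consensus applies the at-least-two rule and AND/OR limits", {
  m <- function(...) raster_grid(matrix(c(...), 1, 3), cellsize = 1)
  maps <- list(m(1, 1, 0), m(1, 0, 0), m(0, 0, 0))
  cons <- gcm_consensus(maps, min_agree = 2)
  expect_equal(as.vector(cons$values), c(1, 0, 0))
  expect_equal(as.vector(attr(cons, "agreement")), c(2, 1, 0))
  expect_equal(as.vector(gcm_consensus(maps, min_agree = 1)$values),
               as.numeric(as.vector(Reduce(`|`, lapply(maps, `[[`, "values")))))
  expect_equal(as.vector(gcm_consensus(maps, min_agree = 3)$values),
               as.numeric(as.vector(Reduce(`&`, lapply(maps, `[[`, "values")))))
  zero <- list(m(0, 0, 0), m(0, 0, 0))
  expect_true(all(gcm_consensus(zero)$values == 0))
  bad <- raster_grid(matrix(1, 2, 2), cellsize = 1)
  expect_error(gcm_consensus(list(maps[[1]], bad)), "geometry")
})

test_that("stability areas are the refugia/ancestral/current triple overlap", {
  refugia <- raster_grid(matrix(c(1, 1, 0, 0), 2, 2), cellsize = 10,
                         crs = "planar")
  current <- raster_grid(matrix(c(1, 0, 1, 1), 2, 2), cellsize = 10,
                         crs = "planar")
  poly <- ancestral_area(rbind(c(-1, -1), c(21, -1), c(21, 21), c(-1, 21)))
  st <- stability_areas(current, refugia, poly)
  # only the cell that is refugial AND current AND inside the polygon
  expect_equal(as.vector(st$values), c(1, 0, 0, 0))
  st2 <- stability_areas(current, refugia, poly, include_current = FALSE)
  expect_equal(as.vector(st2$values), c(1, 1, 0, 0))
  # stability is a subset of refugia
  expect_true(all(st$values <= refugia$values))
  # polygon that misses the grid: empty map with a warning
  off <- ancestral_area(rbind(c(100, 100), c(110, 100), c(110, 110)))
  expect_warning(st3 <- stability_areas(current, refugia, off), "ancestral")
  expect_true(all(st3$values == 0))
})
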