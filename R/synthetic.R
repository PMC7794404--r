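#' Configuration of a synthetic study system
#'
#' Builds and validates the configuration for [generate_world()]. The
#' defaults describe the reference study conditions used throughout the
#' test suite: a 400 x 400 km planar landscape (40 x 40 cells of 10 km),
#' five correlated bioclim-like layers, three divergent lineages meeting
#' along a west-east admixture cline, 50 sampled populations genotyped at
#' eight microsatellite loci, and three palaeoclimate (GCM) variants.
#'
#' `driver_mode` states which mechanism generates spatial structure in
#' diversity: `"admixture"` (heterozygosity rises with the Simpson index of
#' true admixture), `"stability"` (allele pools erode with distance from
#' the glacial refugia), `"both"`, or `"none"`.
#'
#' @param grid_rows,grid_cols grid size in cells.
#' @param cell_size cell edge in km.
#' @param n_layers number of environmental layers.
#' @param collinearity_spec list of `list(layer, parent, correlation)`
#'   entries inducing multicollinearity between layers.
#' @param lineage_specs per lineage: `centre` (row, col), `niche`
#'   (coefficient per layer on the logit of suitability), `dispersal_scale`
#'   (km; radius of the ancestral-area polygon).
#' @param cline_axis `"col"` (west-east) or `"row"` (north-south).
#' @param cline_midpoints km positions of the lineage boundaries along the
#'   axis (`NULL`: evenly spaced).
#' @param cline_width logistic cline width in km.
#' @param n_populations,inds_per_population,n_loci,pool_alleles_per_locus
#'   sampling design counts.
#' @param driver_mode `"admixture"`, `"stability"`, `"both"` or `"none"`.
#' @param beta_admixture,beta_stability dimensionless effect sizes in
#'   `[0, 1]`: the admixture mixing weight and the maximal allele-pool
#'   erosion weight.
#' @param erosion_scale distance (km) at which pool erosion saturates.
#' @param noise_sd residual noise on diversity (frequency-tempering sd).
#' @param n_gcm number of palaeoclimate variants (default 3).
#' @param gcm_perturbation_sd sd of the per-GCM layer perturbation.
#' @param n_occurrences,n_target_group occurrence counts for the focal
#'   species and the target group.
#' @param mt_per_population,seq_length mtDNA sample size and alignment
#'   length per population.
#' @param missing_rate genotype dropout probability.
#' @param q_concentration Dirichlet concentration of the emitted Q-matrix
#'   around the true admixture proportions.
#' @param dic_k_max,dic_replicates shape of the emitted DIC table.
#' @param refugia_quantile suitability quantile above which a cell is
#'   truth-refugial (default 0.75).
#' @param seed integer seed; the same config and seed give a bit-identical
#'   world.
#' @return validated list of class `world_config`.
#' @export
world_config <- function(grid_rows = 40, grid_cols = 40, cell_size = 10,
                         n_layers = 5,
                         collinearity_spec = list(
                           list(layer = 3, parent = 1, correlation = 0.85),
                           list(layer = 4, parent = 2, correlation = 0.9)),
                         lineage_specs = NULL,
                         cline_axis = c("col", "row"),
                         cline_midpoints = NULL,
                         cline_width = 30,
                         n_populations = 50, inds_per_population = 10,
                         n_loci = 8, pool_alleles_per_locus = 8,
                         driver_mode = c("admixture", "stability", "both",
                                         "none"),
                         beta_admixture = 0.8, beta_stability = 0.6,
                         erosion_scale = 300, noise_sd = 0.02,
                         n_gcm = 3, gcm_perturbation_sd = 0.15,
                         n_occurrences = 400, n_target_group = 1200,
                         mt_per_population = 5, seq_length = 300,
                         missing_rate = 0.03, q_concentration = 50,
                         dic_k_max = 8, dic_replicates = 10,
                         refugia_quantile = 0.75, seed = 1) {
  cline_axis <- match.arg(cline_axis)
  driver_mode <- match.arg(driver_mode)
  if (is.null(lineage_specs)) {
    centre_at <- function(fr, fc) c(max(1, round(fr * grid_rows)),
                                    max(1, round(fc * grid_cols)))
    lineage_specs <- list(
      list(centre = centre_at(0.8, 0.2),
           niche = c(3, rep(0, n_layers - 1)), dispersal_scale = 60),
      list(centre = centre_at(0.5, 0.5),
           niche = c(3, rep(0, n_layers - 1)), dispersal_scale = 60),
      list(centre = centre_at(0.2, 0.82),
           niche = c(3, rep(0, n_layers - 1)), dispersal_scale = 60)
    )
  }
  cfg <- list(grid_rows = grid_rows, grid_cols = grid_cols,
              cell_size = cell_size, n_layers = n_layers,
              collinearity_spec = collinearity_spec,
              lineage_specs = lineage_specs, cline_axis = cline_axis,
              cline_midpoints = cline_midpoints, cline_width = cline_width,
              n_populations = n_populations,
              inds_per_population = inds_per_population, n_loci = n_loci,
              pool_alleles_per_locus = pool_alleles_per_locus,
              driver_mode = driver_mode, beta_admixture = beta_admixture,
              beta_stability = beta_stability, erosion_scale = erosion_scale,
              noise_sd = noise_sd, n_gcm = n_gcm,
              gcm_perturbation_sd = gcm_perturbation_sd,
              n_occurrences = n_occurrences,
              n_target_group = n_target_group,
              mt_per_population = mt_per_population, seq_length = seq_length,
              missing_rate = missing_rate, q_concentration = q_concentration,
              dic_k_max = dic_k_max, dic_replicates = dic_replicates,
              refugia_quantile = refugia_quantile, seed = seed)
  validate_world_config(cfg)
  structure(cfg, class = "world_config")
}

validate_world_config <- function(cfg) {
  pos_count <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stop("invalid configuration: ", field, " must be a count >= 1")
  }
  for (f in c("grid_rows", "grid_cols", "n_layers", "n_populations",
              "inds_per_population", "n_loci", "pool_alleles_per_locus",
              "n_gcm", "mt_per_population", "seq_length", "dic_k_max",
              "dic_replicates")) pos_count(f)
  if (cfg$cline_width <= 0)
    stop("invalid configuration: cline_width must be positive")
  if (cfg$cell_size <= 0)
    stop("invalid configuration: cell_size must be positive")
  if (cfg$erosion_scale <= 0)
    stop("invalid configuration: erosion_scale must be positive")
  for (cs in cfg$collinearity_spec) {
    if (cs$correlation < 0 || cs$correlation > 1)
      stop("invalid configuration: collinearity_spec correlations must lie in [0, 1]")
    if (cs$layer > cfg$n_layers || cs$parent > cfg$n_layers)
      stop("invalid configuration: collinearity_spec references layer beyond n_layers")
  }
  for (ls in cfg$lineage_specs) {
    if (length(ls$niche) != cfg$n_layers)
      stop("invalid configuration: lineage_specs niche length must equal n_layers")
    if (any(ls$centre < 1) || ls$centre[1] > cfg$grid_rows ||
        ls$centre[2] > cfg$grid_cols)
      stop("invalid configuration: lineage_specs centre outside the grid")
  }
  if (cfg$n_populations > cfg$grid_rows * cfg$grid_cols)
    stop("invalid configuration: n_populations exceeds the number of grid cells")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("invalid configuration: missing_rate must lie in [0, 1)")
  invisible(cfg)
}

#' Two-lineage logistic admixture cline
#'
#' \eqn{q_1 = 1 / (1 + e^{-(x - m)/w})}, \eqn{q_2 = 1 - q_1}: the
#' proportion of the lineage found beyond the cline midpoint rises
#' sigmoidally with position.
#'
#' @param position_km position along the cline axis (km).
#' @param midpoint cline midpoint (km).
#' @param width cline width (km, > 0).
#' @return numeric pair `(q1, q2)` summing to 1.
#' @export
admixture_cline <- function(position_km, midpoint, width) {
  if (width <= 0) stop("cline width must be positive")
  q1 <- stats::plogis((position_km - midpoint) / width)
  c(q1, 1 - q1)
}

#' Multi-lineage admixture profile along an axis
#'
#' Generalises [admixture_cline()] to K lineages ordered along the axis by
#' stacking K - 1 logistic boundaries: with
#' \eqn{F_j = \sigma((x - m_j)/w)}, lineage 1 gets \eqn{1 - F_1}, lineage K
#' gets \eqn{F_{K-1}}, and intermediate lineages get \eqn{F_{j-1} - F_j}
#' (clamped at 0 and renormalised when boundaries are close).
#'
#' @param position_km position along the axis (km).
#' @param midpoints increasing boundary midpoints (km), length K - 1.
#' @param width shared logistic width (km).
#' @return proportion vector of length K.
#' @export
admixture_profile <- function(position_km, midpoints, width) {
  if (width <= 0) stop("cline width must be positive")
  if (is.unsorted(midpoints)) stop("cline midpoints must be increasing")
  Fj <- stats::plogis((position_km - midpoints) / width)
  q <- c(1 - Fj[1L], if (length(Fj) > 1) -diff(Fj) else NULL,
         Fj[length(Fj)])
  q[q < 0] <- 0
  q / sum(q)
}

#' Mixture allele frequencies with pool erosion
#'
#' Admixed population allele frequencies:
#' \eqn{p = (1 - w) \sum_l q_l \, \pi_l + w \, \delta_{a^*}} where
#' \eqn{\pi_l} are lineage allele pools, \eqn{q} the admixture proportions
#' and \eqn{a^*} the most frequent allele of the plain mixture. The erosion
#' weight `w` collapses the pool toward a point mass, modelling diversity
#' loss away from refugia; `w = 0` gives the plain convex mixture, whose
#' gene diversity is at least the admixture-weighted mean of the pool gene
#' diversities.
#'
#' @param pools list of per-lineage frequency vectors on one allele space.
#' @param q admixture proportions (sums to 1).
#' @param erosion_weight erosion weight in `[0, 1]`.
#' @return frequency vector summing to 1.
#' @export
mixture_allele_frequencies <- function(pools, q, erosion_weight = 0) {
  lens <- vapply(pools, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("allele pools differ in length: ", paste(lens, collapse = ", "))
  if (length(q) != length(pools))
    stop("q must have one proportion per pool")
  if (abs(sum(q) - 1) > 1e-8) stop("q must sum to 1")
  if (erosion_weight < 0 || erosion_weight > 1)
    stop("erosion_weight must lie in [0, 1]")
  mix <- Reduce(`+`, Map(`*`, pools, as.list(q)))
  delta <- numeric(length(mix))
  delta[which.max(mix)] <- 1
  (1 - erosion_weight) * mix + erosion_weight * delta
}

#' Sample occurrence points from a suitability surface
#'
#' Cells are drawn with probability proportional to their suitability and
#' each point is jittered uniformly within its cell.
#'
#' @param suitability `meltpot_raster` with values in `[0, 1]`.
#' @param n number of points.
#' @param seed integer seed.
#' @return an [occurrence_set()] in the raster's crs.
#' @export
sample_occurrences <- function(suitability, n, seed = 1) {
  cells <- cell_centres(suitability)
  p <- suitability$values[cbind(cells$row, cells$col)]
  p[is.na(p) | p == suitability$nodata] <- 0
  if (n == 0)
    return(occurrence_set(numeric(0), numeric(0), crs = suitability$crs))
  if (all(p <= 0)) stop("cannot sample occurrences: suitability is all zero")
  set.seed(seed)
  idx <- sample.int(nrow(cells), n, replace = TRUE, prob = p)
  half <- suitability$cellsize / 2
  occurrence_set(
    lon = cells$x[idx] + stats::runif(n, -half, half),
    lat = cells$y[idx] + stats::runif(n, -half, half),
    source = "synthetic",
    crs = suitability$crs
  )
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s == 0) {            # degenerate: all mass on the largest alpha
    g[which.max(alpha)] <- 1
    s <- 1
  }
  g / s
}

## smooth random field on the grid: linear gradient + Gaussian bumps,
## standardised to mean 0 / sd 1
smooth_field <- function(nr, nc, cell, gradient = c(0, 0), n_bumps = 4) {
  rowc <- matrix(rep(seq_len(nr), nc), nr, nc)
  colc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  f <- gradient[1] * (rowc - (nr + 1) / 2) / nr +
    gradient[2] * (colc - (nc + 1) / 2) / nc
  for (b in seq_len(n_bumps)) {
    cr <- stats::runif(1, 1, nr); cc <- stats::runif(1, 1, nc)
    s <- stats::runif(1, 0.12, 0.3) * max(nr, nc)
    a <- stats::rnorm(1, 0, 0.5)
    f <- f + a * exp(-(((rowc - cr)^2 + (colc - cc)^2)) / (2 * s^2))
  }
  (f - mean(f)) / stats::sd(f)
}

#' Generate a complete synthetic study system
#'
#' Produces, from a [world_config()], everything the analysis pipeline
#' consumes: current and palaeoclimate (per-GCM) layer stacks, sampled
#' populations with diploid microsatellite genotypes and aligned mtDNA
#' sequences, an individual Q-matrix and DIC-versus-K table emulating
#' external Bayesian clustering output, ancestral-area polygons, species
#' and target-group occurrences, and a truth record (driver mode, realised
#' effect sizes, refugia/stability masks, per-population true admixture and
#' distances).
#'
#' Diversity is wired to the configured driver: lineage allele pools are
#' disjoint blocks sharing one frequency multiset per locus (so pure
#' populations of any lineage have equal expected diversity), admixture
#' inflates heterozygosity through the convexity of the mixture, and pool
#' erosion with distance from the refugia mask deflates it.
#'
#' @param config a [world_config()].
#' @return list of class `synthetic_world`; see Details.
#' @export
generate_world <- function(config) {
  validate_world_config(config)
  cfg <- config
  set.seed(cfg$seed)
  nr <- cfg$grid_rows; nc <- cfg$grid_cols; cs <- cfg$cell_size
  K <- length(cfg$lineage_specs)

  ## --- environmental layers (layer1 row-gradient, layer2 col-gradient) ---
  base <- vector("list", cfg$n_layers)
  for (j in seq_len(cfg$n_layers)) {
    grad <- if (j == 1) c(1.2, 0) else if (j == 2) c(0, 1.2) else c(0, 0)
    base[[j]] <- smooth_field(nr, nc, cs, gradient = grad)
  }
  for (csp in cfg$collinearity_spec) {
    r <- csp$correlation
    child <- r * base[[csp$parent]] + sqrt(1 - r^2) * base[[csp$layer]]
    base[[csp$layer]] <- (child - mean(child)) / stats::sd(child)
  }
  mk_raster <- function(m) raster_grid(m, cellsize = cs, crs = "planar")
  env_current <- env_stack(stats::setNames(lapply(base, mk_raster),
                                           paste0("bio", seq_len(cfg$n_layers))))

  ## LGM base = cooled layers; per-GCM smooth perturbations on top
  lgm_base <- base
  lgm_base[[1]] <- base[[1]] - 1.0
  for (j in seq_len(cfg$n_layers)[-1]) lgm_base[[j]] <- base[[j]] - 0.3
  env_gcm <- lapply(seq_len(cfg$n_gcm), function(g) {
    layers <- lapply(lgm_base, function(m)
      m + cfg$gcm_perturbation_sd * smooth_field(nr, nc, cs))
    env_stack(stats::setNames(lapply(layers, mk_raster),
                              paste0("bio", seq_len(cfg$n_layers))))
  })

  ## --- true suitability and masks ---
  lin_logit <- function(layers) {
    lapply(cfg$lineage_specs, function(ls)
      Reduce(`+`, Map(`*`, layers, as.list(ls$niche))))
  }
  suit_from <- function(layers) {
    s <- lapply(lin_logit(layers), stats::plogis)
    Reduce(pmax, s)
  }
  suit_current <- suit_from(base)
  suit_lgm <- suit_from(lgm_base)
  refugia_mask <- mk_raster((suit_lgm >=
                               stats::quantile(suit_lgm, cfg$refugia_quantile)) * 1)
  current_mask <- mk_raster((suit_current >=
                               stats::quantile(suit_current, cfg$refugia_quantile)) * 1)
  suit_current_r <- mk_raster(suit_current)
  suit_lgm_r <- mk_raster(suit_lgm)

  ## ancestral polygons: circle of radius dispersal_scale per lineage
  ancestral <- lapply(seq_len(K), function(l) {
    ls <- cfg$lineage_specs[[l]]
    cx <- (ls$centre[2] - 0.5) * cs
    cy <- (nr - ls$centre[1] + 0.5) * cs
    ang <- seq(0, 2 * pi, length.out = 25L)
    ancestral_area(cbind(cx + ls$dispersal_scale * cos(ang),
                         cy + ls$dispersal_scale * sin(ang)),
                   lineage = paste0("L", l), hpd = 0.7)
  })

  ## stability truth: refugia AND current AND inside an ancestral polygon,
  ## relaxed stepwise if the triple overlap is empty on this landscape
  cells <- cell_centres(refugia_mask)
  inside <- points_in_polygons(cells[c("x", "y")], ancestral)
  in_m <- matrix(0, nr, nc); in_m[cbind(cells$row, cells$col)] <- inside
  stab <- refugia_mask$values * current_mask$values * in_m
  if (!any(stab == 1)) stab <- refugia_mask$values * in_m
  if (!any(stab == 1)) {
    d2poly <- point_distances(cells[c("x", "y")],
                              t(vapply(ancestral, function(a)
                                colMeans(a$coords[-nrow(a$coords), ]),
                                numeric(2))), "planar")
    on <- which(refugia_mask$values[cbind(cells$row, cells$col)] == 1)
    pick <- on[which.min(apply(d2poly[on, , drop = FALSE], 1L, min))]
    stab <- matrix(0, nr, nc)
    stab[cells$row[pick], cells$col[pick]] <- 1
  }
  stability_mask <- mk_raster(stab)

  ## --- populations on distinct cells ---
  pick <- sample.int(nr * nc, cfg$n_populations)
  prow <- ((pick - 1L) %% nr) + 1L
  pcol <- ((pick - 1L) %/% nr) + 1L
  px <- (pcol - 0.5) * cs
  py <- (nr - prow + 0.5) * cs
  ## equirectangular lon/lat companion coordinates (origin 42N, 12E)
  lat0 <- 42; lon0 <- 12
  populations <- data.frame(
    id = sprintf("P%02d", seq_len(cfg$n_populations)),
    row = prow, col = pcol, x = px, y = py,
    lon = lon0 + px / (111.32 * cos(lat0 * pi / 180)),
    lat = lat0 + py / 111.32
  )

  ## --- true admixture along the cline ---
  axis_pos <- if (cfg$cline_axis == "col") px else py
  extent <- if (cfg$cline_axis == "col") nc * cs else nr * cs
  midpoints <- cfg$cline_midpoints
  if (is.null(midpoints))
    midpoints <- extent * seq_len(K - 1) / K
  q_true <- t(vapply(axis_pos, function(x)
    admixture_profile(x, midpoints, cfg$cline_width), numeric(K)))

  ## --- distances to truth masks (vectorised over populations) ---
  mask_dist <- function(mask) {
    on <- which(mask$values[cbind(cells$row, cells$col)] == 1)
    D <- point_distances(cbind(px, py), cells[on, c("x", "y")], "planar")
    d <- apply(D, 1L, min)
    d[mask$values[cbind(prow, pcol)] == 1] <- 0
    d
  }
  d_ref <- mask_dist(refugia_mask)
  d_stab <- mask_dist(stability_mask)

  ## --- realised effect sizes ---
  lambda <- if (cfg$driver_mode %in% c("admixture", "both"))
    min(1, max(0, cfg$beta_admixture)) else 0
  w_max <- if (cfg$driver_mode %in% c("stability", "both"))
    min(1, max(0, cfg$beta_stability)) else 0

  ## --- lineage allele pools: one frequency multiset per locus, assigned
  ##     to each lineage's disjoint allele block under a random permutation
  ##     (equal pool diversity across lineages by construction) ---
  A <- cfg$pool_alleles_per_locus
  pools <- lapply(seq_len(cfg$n_loci), function(l) {
    freqs <- rdirichlet1(rep(1.5, A))
    lapply(seq_len(K), function(k) {
      v <- numeric(K * A)
      v[(k - 1) * A + seq_len(A)] <- freqs[sample.int(A)]
      v
    })
  })

  ## --- genotypes (preallocated columns) ---
  inds <- cfg$inds_per_population
  n_rec <- cfg$n_populations * cfg$n_loci * inds
  g_pop <- character(n_rec); g_ind <- character(n_rec)
  g_loc <- character(n_rec)
  g_a <- integer(n_rec); g_b <- integer(n_rec)
  locus_names <- sprintf("loc%02d", seq_len(cfg$n_loci))
  at <- 0L
  for (i in seq_len(cfg$n_populations)) {
    qi <- q_true[i, ]
    q_eff <- lambda * qi
    q_eff[which.max(qi)] <- q_eff[which.max(qi)] + (1 - lambda)
    w_i <- min(1, d_ref[i] / cfg$erosion_scale) * w_max
    ind_names <- sprintf("%s_I%02d", populations$id[i], seq_len(inds))
    for (l in seq_len(cfg$n_loci)) {
      p <- mixture_allele_frequencies(pools[[l]], q_eff, w_i)
      if (cfg$noise_sd > 0) {
        p <- p^(1 + stats::rnorm(1, 0, 4 * cfg$noise_sd))
        p <- p / sum(p)
      }
      alle <- sample.int(length(p), 2L * inds, replace = TRUE, prob = p)
      aa <- 100L + 2L * alle[seq_len(inds)]
      bb <- 100L + 2L * alle[inds + seq_len(inds)]
      miss <- stats::runif(inds) < cfg$missing_rate
      aa[miss] <- NA_integer_; bb[miss] <- NA_integer_
      idx <- at + seq_len(inds)
      g_pop[idx] <- populations$id[i]
      g_ind[idx] <- ind_names
      g_loc[idx] <- locus_names[l]
      g_a[idx] <- aa; g_b[idx] <- bb
      at <- at + inds
    }
  }
  genotypes <- genotype_table(data.frame(
    population = g_pop, individual = g_ind, locus = g_loc,
    allele_a = g_a, allele_b = g_b))

  ## --- mtDNA sequences: divergent lineage haplotype pools ---
  bases <- c("A", "C", "G", "T")
  Lb <- cfg$seq_length
  anc <- sample(bases, Lb, replace = TRUE)
  lineage_anc <- lapply(seq_len(K), function(k) {
    s <- anc
    mut <- sample.int(Lb, max(1L, round(0.05 * Lb * (k - 1) / max(1, K - 1))))
    if (k > 1) s[mut] <- vapply(s[mut], function(b)
      sample(setdiff(bases, b), 1L), character(1))
    s
  })
  n_hap <- 6L
  hap_pools <- lapply(lineage_anc, function(a) {
    haps <- lapply(seq_len(n_hap), function(h) {
      s <- a
      mut <- sample.int(Lb, stats::rpois(1, 0.005 * Lb) + (h > 1))
      if (length(mut)) s[mut] <- vapply(s[mut], function(b)
        sample(setdiff(bases, b), 1L), character(1))
      paste(s, collapse = "")
    })
    list(haps = unlist(haps), freq = rdirichlet1(rep(1.2, n_hap)))
  })
  sequences <- stats::setNames(lapply(seq_len(cfg$n_populations), function(i) {
    lin <- sample.int(K, cfg$mt_per_population, replace = TRUE,
                      prob = q_true[i, ])
    vapply(lin, function(k)
      sample(hap_pools[[k]]$haps, 1L, prob = hap_pools[[k]]$freq),
      character(1))
  }), populations$id)

  ## --- Q-matrix with Dirichlet noise around the truth ---
  ind_pop <- rep(seq_len(cfg$n_populations), each = inds)
  alpha <- q_true[ind_pop, , drop = FALSE] * cfg$q_concentration + 1e-6
  G <- matrix(stats::rgamma(length(alpha), shape = alpha, rate = 1),
              nrow = nrow(alpha))
  rs <- rowSums(G)
  zero <- rs == 0
  if (any(zero)) {
    G[cbind(which(zero), max.col(alpha[zero, , drop = FALSE]))] <- 1
    rs[zero] <- 1
  }
  Q <- G / rs
  qdf <- data.frame(
    population = populations$id[ind_pop],
    individual = sprintf("%s_I%02d", populations$id[ind_pop],
                         sequence(rep(inds, cfg$n_populations)))
  )
  qdf[paste0("cluster", seq_len(K))] <- Q
  qmat <- q_matrix(qdf)

  ## --- DIC table: decreasing curve with plateau at the true K ---
  ks <- 2:cfg$dic_k_max
  dic_mean <- ifelse(ks < K, 5000 + 400 * (K - ks), 5000 - 2 * (ks - K))
  dic_table <- data.frame(
    K = rep(ks, each = cfg$dic_replicates),
    replicate = rep(seq_len(cfg$dic_replicates), length(ks)),
    DIC = rep(dic_mean, each = cfg$dic_replicates) +
      stats::rnorm(length(ks) * cfg$dic_replicates, 0, 20)
  )

  ## --- occurrences (with a little dirt to exercise cleaning) ---
  occ_seed <- sample.int(.Machine$integer.max, 3L)
  occ <- sample_occurrences(suit_current_r, cfg$n_occurrences,
                            seed = occ_seed[1L])
  set.seed(occ_seed[2L])
  occ$uncertainty <- stats::rexp(nrow(occ), rate = 1 / 10)
  dup <- sample.int(nrow(occ), max(1L, round(0.03 * nrow(occ))))
  occ <- rbind(occ, occ[dup, , drop = FALSE])
  attr(occ, "crs") <- "planar"
  rownames(occ) <- NULL
  uniform <- mk_raster(matrix(1, nr, nc))
  target_group <- sample_occurrences(uniform, cfg$n_target_group,
                                     seed = occ_seed[3L])

  structure(list(
    config = cfg,
    env_current = env_current,
    env_gcm = env_gcm,
    populations = populations,
    genotypes = genotypes,
    sequences = sequences,
    q_matrix = qmat,
    dic_table = dic_table,
    ancestral_areas = ancestral,
    occurrences = occ,
    target_group = target_group,
    truth = list(
      driver_mode = cfg$driver_mode,
      beta_admixture = lambda,
      beta_stability = w_max,
      refugia_mask = refugia_mask,
      stability_mask = stability_mask,
      current_mask = current_mask,
      suitability_current = suit_current_r,
      suitability_lgm = suit_lgm_r,
      q_true = q_true,
      dist_refugium = d_ref,
      dist_stability = d_stab
    )
  ), class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %dx%d grid, %d lineages, %d populations, driver %s\n",
    x$config$grid_rows, x$config$grid_cols, length(x$config$lineage_specs),
    x$config$n_populations, x$truth$driver_mode))
  invisible(x)
}
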