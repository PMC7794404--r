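#' Read a GenePop genotype file
#'
#' Parses the classic GenePop layout: a title line, one locus name per line
#' (or one comma-separated line), then population blocks opened by lines
#' reading `POP`. Individual lines are `name , g1 g2 ...` with each
#' genotype a 4-digit (2-digit alleles) or 6-digit (3-digit alleles) code;
#' `0000` / `000000` is a missing genotype. Mixing the two dialects in one
#' file is rejected.
#'
#' @param path file path.
#' @return a [genotype_table()]. Individual names of the form
#'   `population|individual` (as written by [write_genepop()]) carry the
#'   population id explicitly; otherwise each block is labelled by its
#'   first individual name, the conventional usage.
#' @export
read_genepop <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("GenePop file too short: ", path)
  i <- 2L
  loci <- character()
  while (i <= length(lines) && !grepl("^\\s*pop\\s*$", lines[i],
                                      ignore.case = TRUE)) {
    loci <- c(loci, trimws(strsplit(lines[i], ",")[[1L]]))
    i <- i + 1L
  }
  loci <- loci[nzchar(loci)]
  if (i > length(lines)) stop("no POP line found in ", path)
  digits <- NA_integer_
  recs <- list()
  pop_idx <- 0L
  pop_label <- NULL
  while (i <= length(lines)) {
    line <- lines[i]
    if (grepl("^\\s*pop\\s*$", line, ignore.case = TRUE)) {
      pop_idx <- pop_idx + 1L
      pop_label <- NULL
      i <- i + 1L
      next
    }
    if (!nzchar(trimws(line))) { i <- i + 1L; next }
    parts <- strsplit(line, ",")[[1L]]
    if (length(parts) < 2)
      stop("malformed GenePop line ", i, ": missing comma separator")
    ind <- trimws(parts[1L])
    genos <- strsplit(trimws(parts[2L]), "\\s+")[[1L]]
    if (length(genos) != length(loci))
      stop("malformed GenePop line ", i, ": ", length(genos),
           " genotypes for ", length(loci), " loci")
    w <- unique(nchar(genos))
    if (length(w) != 1L || !(w %in% c(4L, 6L)))
      stop("GenePop dialect error at line ", i,
           ": genotype codes must be uniformly 4 or 6 digits")
    if (is.na(digits)) digits <- w / 2L
    else if (digits != w / 2L)
      stop("GenePop dialect error at line ", i,
           ": file mixes 2- and 3-digit allele codes")
    if (grepl("|", ind, fixed = TRUE)) {
      pp <- strsplit(ind, "|", fixed = TRUE)[[1L]]
      if (is.null(pop_label)) pop_label <- pp[1L]
      ind <- pp[2L]
    }
    if (is.null(pop_label)) pop_label <- ind
    a <- as.integer(substr(genos, 1L, digits))
    b <- as.integer(substr(genos, digits + 1L, 2L * digits))
    miss <- a == 0L & b == 0L
    a[miss] <- NA_integer_; b[miss] <- NA_integer_
    if (any(xor(a == 0L, b == 0L), na.rm = TRUE))
      stop("malformed GenePop line ", i, ": half-missing genotype code")
    recs[[length(recs) + 1L]] <- data.frame(
      population = pop_label, individual = ind, locus = loci,
      allele_a = a, allele_b = b)
    i <- i + 1L
  }
  genotype_table(do.call(rbind, recs))
}

#' Write a GenePop genotype file
#'
#' @param gt a [genotype_table()].
#' @param path output path.
#' @param digits allele code width, 2 or 3 (default 3).
#' @param title first line of the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gt, path, digits = 3,
                          title = "meltpot genotype export") {
  if (!digits %in% c(2, 3)) stop("digits must be 2 or 3")
  loci <- unique(as.character(gt$locus))
  if (any(c(gt$allele_a, gt$allele_b) >= 10^digits, na.rm = TRUE))
    stop("allele codes exceed ", digits, " digits")
  fmt <- function(a, b) {
    a[is.na(a)] <- 0L; b[is.na(b)] <- 0L
    sprintf(paste0("%0", digits, "d%0", digits, "d"), a, b)
  }
  out <- title
  out <- c(out, loci)
  for (p in unique(as.character(gt$population))) {
    out <- c(out, "POP")
    sub <- gt[gt$population == p, ]
    for (ind in unique(as.character(sub$individual))) {
      g <- sub[sub$individual == ind, ]
      g <- g[match(loci, g$locus), ]
      out <- c(out, paste0(p, "|", ind, " , ",
                           paste(fmt(g$allele_a, g$allele_b),
                                 collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read aligned population sequences from FASTA
#'
#' Sequence records are grouped by population either from the header
#' convention `>population|individual` or from a sidecar mapping.
#'
#' @param path FASTA file of aligned sequences.
#' @param mapping optional data frame with columns `name` (FASTA header)
#'   and `population`; overrides the header convention.
#' @return named list: per population a character vector of upper-case
#'   sequences, all the same length.
#' @export
read_fasta_populations <- function(path, mapping = NULL) {
  dna <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                       as.matrix = FALSE)
  seqs <- toupper(vapply(dna, paste, character(1), collapse = ""))
  lens <- unique(nchar(seqs))
  if (length(lens) != 1L)
    stop("alignment error: sequences have unequal lengths (",
         paste(lens, collapse = ", "), ")")
  nm <- names(seqs)
  pop <- if (!is.null(mapping)) {
    i <- match(nm, mapping$name)
    if (anyNA(i)) stop("mapping is missing records: ",
                       paste(nm[is.na(i)], collapse = ", "))
    as.character(mapping$population[i])
  } else {
    sub("\\|.*$", "", nm)
  }
  split(unname(seqs), pop)
}

#' Write aligned population sequences to FASTA
#'
#' Headers follow the `>population|individual` convention read back by
#' [read_fasta_populations()].
#'
#' @param sequences named list of per-population sequence vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_populations <- function(sequences, path) {
  out <- character()
  for (p in names(sequences)) {
    s <- sequences[[p]]
    for (i in seq_along(s))
      out <- c(out, sprintf(">%s|%s_%03d", p, p, i), s[i])
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a Q-matrix CSV
#'
#' @param path CSV with a `population` column, optional `individual`
#'   column, and one numeric column per cluster.
#' @return a [q_matrix()].
#' @export
read_qmatrix <- function(path) {
  q_matrix(utils::read.csv(path, check.names = FALSE))
}

#' Read a DIC table CSV (columns `K`, `replicate`, `DIC`)
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_dic_table <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("K", "DIC") %in% names(d)))
    stop("DIC table needs columns K and DIC: ", path)
  d
}

#' Read occurrence records from CSV
#'
#' @param path CSV with columns `lon`, `lat` and optional `source`,
#'   `uncertainty`.
#' @param crs coordinate system tag (default `"lonlat"`).
#' @return an [occurrence_set()].
#' @export
read_occurrences <- function(path, crs = "lonlat") {
  d <- utils::read.csv(path)
  if (!all(c("lon", "lat") %in% names(d)))
    stop("occurrence CSV needs lon and lat columns: ", path)
  occurrence_set(d$lon, d$lat,
                 source = if ("source" %in% names(d)) d$source else NA,
                 uncertainty = if ("uncertainty" %in% names(d))
                   d$uncertainty else NA,
                 crs = crs)
}

#' Write occurrence records to CSV
#'
#' @param occ an [occurrence_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}

#' Write ancestral-area polygons to GeoJSON
#'
#' One `Polygon` feature per area with `lineage` and `hpd` properties.
#'
#' @param areas list of [ancestral_area()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geojson_polygons <- function(areas, path) {
  features <- lapply(areas, function(a) {
    ring <- lapply(seq_len(nrow(a$coords)), function(i)
      as.numeric(a$coords[i, ]))
    list(type = "Feature",
         properties = list(lineage = a$lineage, hpd = a$hpd),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ancestral-area polygons from GeoJSON
#'
#' Understands `Polygon` features (outer ring only).
#'
#' @param path GeoJSON path.
#' @return list of [ancestral_area()] objects.
#' @export
read_geojson_polygons <- function(path) {
  g <- jsonlite::read_json(path)
  if (is.null(g$features)) stop("not a GeoJSON FeatureCollection: ", path)
  lapply(g$features, function(f) {
    ring <- f$geometry$coordinates[[1L]]
    coords <- do.call(rbind, lapply(ring, function(p)
      c(as.numeric(p[[1L]]), as.numeric(p[[2L]]))))
    ancestral_area(coords,
                   lineage = f$properties$lineage %||% "lineage",
                   hpd = f$properties$hpd %||% NA_real_)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline run configuration from YAML
#'
#' Missing stage parameters fall back to the package defaults (minimum
#' sample size 4, VIF threshold 5, AUC cutoff 0.7, GCM agreement 2).
#'
#' @param path YAML file.
#' @return configuration list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_run_config()
  utils::modifyList(defaults, cfg)
}

#' Default pipeline configuration
#'
#' @return list of stage parameters with the standard defaults.
#' @export
default_run_config <- function() {
  list(
    schema = "meltpot-run/1",
    seed = 1,
    world = list(),               # world_config() overrides
    min_n = 4,
    max_flagged = 14,
    thin_d_min = 12,
    thin_datasets = 5,
    vif_threshold = 5,
    auc_cutoff = 0.7,
    n_validation_bg = 200,
    min_agree = 2,
    top_m = 10,
    dic_epsilon = 0.05,
    include_interactions = FALSE,
    subset_ids = NULL
  )
}

#' Write all artifacts of a synthetic world to a directory
#'
#' Emits the world in the interchange formats of the pipeline: FASTA
#' sequences, GenePop genotypes, CSV tables (populations, Q-matrix, DIC,
#' occurrences, target group), ESRI ASCII grids (environmental layers and
#' truth masks), GeoJSON ancestral areas, and a YAML truth record.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  write_fasta_populations(world$sequences, fp("sequences.fasta"))
  write_genepop(world$genotypes, fp("genotypes.gen"))
  utils::write.csv(world$populations, fp("populations.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(world$q_matrix), fp("q_matrix.csv"),
                   row.names = FALSE)
  utils::write.csv(world$dic_table, fp("dic_table.csv"), row.names = FALSE)
  write_occurrences(world$occurrences, fp("occurrences.csv"))
  write_occurrences(world$target_group, fp("target_group.csv"))
  for (nm in names(world$env_current$layers))
    write_ascii_grid(world$env_current$layers[[nm]],
                     fp(sprintf("env_current_%s.asc", nm)))
  for (g in seq_along(world$env_gcm))
    for (nm in names(world$env_gcm[[g]]$layers))
      write_ascii_grid(world$env_gcm[[g]]$layers[[nm]],
                       fp(sprintf("env_gcm%d_%s.asc", g, nm)))
  write_ascii_grid(world$truth$refugia_mask, fp("truth_refugia.asc"))
  write_ascii_grid(world$truth$stability_mask, fp("truth_stability.asc"))
  write_geojson_polygons(world$ancestral_areas, fp("ancestral_areas.geojson"))
  truth <- list(
    driver_mode = world$truth$driver_mode,
    beta_admixture = world$truth$beta_admixture,
    beta_stability = world$truth$beta_stability,
    dist_refugium = as.numeric(world$truth$dist_refugium),
    dist_stability = as.numeric(world$truth$dist_stability),
    q_true = apply(world$truth$q_true, 1L, function(r)
      as.numeric(r), simplify = FALSE)
  )
  yaml::write_yaml(truth, fp("truth.yaml"))
  invisible(dir)
}
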