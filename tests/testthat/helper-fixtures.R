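# Shared fixtures built in code.

# small genotype table: explicit allele pairs per (pop, ind, locus)
gt_from <- function(...) {
  rows <- list(...)
  genotype_table(do.call(rbind, lapply(rows, function(r)
    data.frame(population = r[[1]], individual = r[[2]], locus = r[[3]],
               allele_a = r[[4]], allele_b = r[[5]]))))
}

# genotype table for one population/locus from an explicit genotype list
# (list of c(a, b) pairs; NA pairs allowed)
one_locus_gt <- function(pairs, pop = "p1", locus = "L1") {
  genotype_table(data.frame(
    population = pop,
    individual = sprintf("i%02d", seq_along(pairs)),
    locus = locus,
    allele_a = vapply(pairs, `[`, numeric(1), 1),
    allele_b = vapply(pairs, `[`, numeric(1), 2)
  ))
}

# random genotype table, optionally with missing records
random_gt <- function(n_pop = 2, n_ind = 6, n_loci = 3, n_alleles = 4,
                      missing_rate = 0, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(pop = sprintf("p%d", seq_len(n_pop)),
                      ind = sprintf("i%02d", seq_len(n_ind)),
                      locus = sprintf("L%d", seq_len(n_loci)),
                      stringsAsFactors = FALSE)
  a <- sample.int(n_alleles, nrow(grid), replace = TRUE)
  b <- sample.int(n_alleles, nrow(grid), replace = TRUE)
  miss <- runif(nrow(grid)) < missing_rate
  a[miss] <- NA; b[miss] <- NA
  genotype_table(data.frame(
    population = grid$pop,
    individual = paste(grid$pop, grid$ind, sep = "_"),
    locus = grid$locus, allele_a = a, allele_b = b))
}

# tiny world for fast pipeline-level tests
small_world_config <- function(...) {
  world_config(grid_rows = 20, grid_cols = 20, n_populations = 15,
               inds_per_population = 8, n_loci = 4,
               n_occurrences = 150, n_target_group = 400,
               mt_per_population = 4, seq_length = 120, ...)
}

# exhaustive-subsample oracle for rarefaction allelic richness: mean number
# of distinct alleles over all size-g subsets of the gene-copy pool
ar_enumeration_oracle <- function(copy_counts, g) {
  pool <- rep(seq_along(copy_counts), copy_counts)
  subs <- utils::combn(length(pool), g)
  mean(apply(subs, 2, function(i) length(unique(pool[i]))))
}

# brute-force AUC over all presence/background pairs
auc_pair_oracle <- function(sp, sb) {
  wins <- outer(sp, sb, function(a, b) (a > b) + 0.5 * (a == b))
  mean(wins)
}

# population-mean He from a genotype table, as used by recovery replicates
pop_he <- function(gt, pops) {
  vapply(split(gt, gt$population)[pops], expected_heterozygosity, numeric(1))
}

# one driver-recovery replicate: simulate, summarise, attribute
recovery_replicate <- function(mode, seed) {
  w <- generate_world(world_config(driver_mode = mode, seed = seed))
  gt <- filter_populations(w$genotypes)$genotypes
  pops <- w$populations
  names(pops)[names(pops) == "id"] <- "population"
  pops <- pops[pops$population %in% unique(gt$population), , drop = FALSE]
  div <- data.frame(population = pops$population,
                    He = unname(pop_he(gt, pops$population)))
  pq <- population_mean_q(w$q_matrix)
  pred <- build_predictor_table(pops, pq, w$truth$refugia_mask,
                                w$truth$stability_mask)
  recovery_flags(run_model_set(div, pred, responses = "He"), "He")
}
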