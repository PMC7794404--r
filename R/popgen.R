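#' Diploid microsatellite genotype tables
#'
#' The genotype container is a plain data frame with columns `population`,
#' `individual`, `locus`, `allele_a`, `allele_b`. Alleles are positive
#' integers (repeat-number or fragment-size codes); a failed amplification is
#' recorded as `NA` in both allele columns, never in only one.
#'
#' @param df data frame with the five columns above.
#' @return validated data frame of class `c("genotype_table", "data.frame")`.
#' @export
genotype_table <- function(df) {
  need <- c("population", "individual", "locus", "allele_a", "allele_b")
  if (!all(need %in% names(df)))
    stop("genotype table needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  half <- xor(is.na(df$allele_a), is.na(df$allele_b))
  if (any(half))
    stop("alleles must be missing both-or-neither (", sum(half),
         " half-missing records)")
  ok <- !is.na(df$allele_a)
  if (any(df$allele_a[ok] <= 0 | df$allele_b[ok] <= 0))
    stop("alleles must be positive integers")
  key <- paste(df$population, df$individual, df$locus, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (population, individual, locus) records")
  class(df) <- c("genotype_table", "data.frame")
  df
}

## allele count vector for one population x locus slice (non-missing only)
allele_counts <- function(a, b) {
  keep <- !is.na(a)
  v <- c(a[keep], b[keep])
  u <- unique(v)
  stats::setNames(tabulate(match(v, u), nbins = length(u)), u)
}

#' Haplotype diversity
#'
#' Unbiased gene (haplotype) diversity
#' \eqn{h = \frac{n}{n-1}\left(1 - \sum_i (c_i/n)^2\right)} for haplotype
#' counts \eqn{c_i}, i.e. the probability that two sequences drawn without
#' replacement carry different haplotypes.
#'
#' @param counts positive integer vector of haplotype counts.
#' @return `h` in `[0, 1]`.
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity is undefined for n < 2")
  n / (n - 1) * (1 - sum((counts / n)^2))
}

#' Nucleotide diversity
#'
#' Mean per-site difference between all sequence pairs of an aligned sample.
#' Sites holding `N` or a gap in either member of a pair are excluded for
#' that pair (pairwise deletion); each pair's difference count is divided by
#' its own number of comparable sites and the per-pair ratios are averaged.
#'
#' @param sequences character vector of aligned sequences (A/C/G/T/N/-),
#'   all the same length.
#' @return per-site nucleotide diversity (>= 0).
#' @export
nucleotide_diversity <- function(sequences) {
  n <- length(sequences)
  if (n < 2) stop("nucleotide diversity is undefined for n < 2")
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences are not aligned (unequal lengths)")
  if (L < 1) stop("zero-length alignment")
  m <- t(vapply(toupper(sequences),
                function(s) strsplit(s, "", fixed = TRUE)[[1L]],
                character(L), USE.NAMES = FALSE))
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  ratios <- c()
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      comp <- valid[i, ] & valid[j, ]
      if (!any(comp)) {
        warning("sequence pair (", i, ",", j,
                ") shares no comparable sites; pair excluded")
        next
      }
      ratios <- c(ratios, sum(m[i, comp] != m[j, comp]) / sum(comp))
    }
  }
  if (!length(ratios)) stop("no comparable sequence pairs")
  mean(ratios)
}

#' Expected heterozygosity (unbiased)
#'
#' Per locus, Nei's unbiased expected heterozygosity
#' \eqn{H_e = \frac{2n}{2n-1}(1 - \sum_a p_a^2)} with \eqn{n} the number of
#' non-missing genotypes; the population value is the mean over loci. Set
#' `unbiased = FALSE` for the plain \eqn{1 - \sum p^2} form.
#'
#' @param gt genotype records for one population (see [genotype_table()]).
#' @param unbiased apply the small-sample correction (default `TRUE`).
#' @param per_locus return the per-locus vector rather than the mean.
#' @return mean expected heterozygosity, or a named per-locus vector.
#' @export
expected_heterozygosity <- function(gt, unbiased = TRUE, per_locus = FALSE) {
  by_locus <- split(gt[c("allele_a", "allele_b")], gt$locus)
  he <- vapply(by_locus, function(d) {
    cnt <- allele_counts(d$allele_a, d$allele_b)
    n <- sum(cnt) / 2
    if (n == 0) return(NA_real_)
    p <- as.numeric(cnt) / sum(cnt)
    h <- 1 - sum(p^2)
    if (unbiased && n > 0.5) h <- 2 * n / (2 * n - 1) * h
    h
  }, numeric(1))
  he <- he[!is.na(he)]
  if (!length(he)) stop("no scorable locus in this population")
  if (per_locus) he else mean(he)
}

#' Observed heterozygosity
#'
#' Fraction of non-missing genotypes with two different alleles, per locus,
#' averaged over loci.
#'
#' @inheritParams expected_heterozygosity
#' @return mean observed heterozygosity, or a named per-locus vector.
#' @export
observed_heterozygosity <- function(gt, per_locus = FALSE) {
  by_locus <- split(gt[c("allele_a", "allele_b")], gt$locus)
  ho <- vapply(by_locus, function(d) {
    keep <- !is.na(d$allele_a)
    if (!any(keep)) return(NA_real_)
    mean(d$allele_a[keep] != d$allele_b[keep])
  }, numeric(1))
  ho <- ho[!is.na(ho)]
  if (!length(ho)) stop("no scorable locus in this population")
  if (per_locus) ho else mean(ho)
}

## expected allele count in a subsample of g of N gene copies (hypergeometric)
rarefied_allele_count <- function(copy_counts, g) {
  N <- sum(copy_counts)
  if (g < 1 || g > N) stop("rarefaction size g must satisfy 1 <= g <= N")
  ## P(allele absent from subsample) = C(N - Na, g) / C(N, g); zero when
  ## N - Na < g
  p_absent <- exp(lchoose(N - copy_counts, g) - lchoose(N, g))
  p_absent[N - copy_counts < g] <- 0
  sum(1 - p_absent)
}

#' Rarefaction allelic richness
#'
#' Expected number of distinct alleles in a standardised subsample of `g`
#' gene copies, by the hypergeometric rarefaction formula
#' \eqn{A_r = \sum_a \left[1 - \binom{N-N_a}{g} / \binom{N}{g}\right]}.
#' Per-locus values are averaged per population. When `g` is `NULL` it
#' defaults to the smallest number of gene copies (2 x non-missing
#' genotypes) found in any population x locus cell, so every population is
#' rarefied to a common, attainable size.
#'
#' @param gt a [genotype_table()] (one or many populations).
#' @param g rarefaction size in gene copies, or `NULL` for the default.
#' @return data frame with `population`, `Ar`, and the `g` used.
#' @export
allelic_richness <- function(gt, g = NULL) {
  cell <- interaction(gt$population, gt$locus, drop = TRUE)
  copies <- tapply(!is.na(gt$allele_a), cell, sum) * 2
  if (is.null(g)) g <- min(copies)
  if (g < 1) stop("rarefaction size g must be >= 1")
  if (g > min(copies))
    stop("rarefaction size g = ", g, " exceeds the smallest cell (",
         min(copies), " gene copies)")
  pops <- unique(gt$population)
  ar <- vapply(pops, function(p) {
    sub <- gt[gt$population == p, ]
    per_locus <- vapply(split(sub[c("allele_a", "allele_b")], sub$locus),
                        function(d) {
                          cnt <- allele_counts(d$allele_a, d$allele_b)
                          if (!length(cnt)) return(NA_real_)
                          rarefied_allele_count(as.numeric(cnt), g)
                        }, numeric(1))
    mean(per_locus, na.rm = TRUE)
  }, numeric(1))
  data.frame(population = pops, Ar = unname(ar), g = g)
}

## log conditional probability of a genotype configuration given its allele
## counts under Hardy-Weinberg (Levene 1949):
##   P = n! / prod(n_ij!) * 2^H * prod(a_i!) / (2n)!
log_hwe_prob <- function(a, b) {
  g1 <- pmin(a, b); g2 <- pmax(a, b)
  geno <- table(paste(g1, g2))
  alle <- table(c(a, b))
  n <- length(a)
  H <- sum(g1 != g2)
  lfactorial(n) - sum(lfactorial(geno)) + H * log(2) +
    sum(lfactorial(alle)) - lfactorial(2 * n)
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test for one locus in one population: the test statistic
#' is the multinomial probability of the observed genotype configuration
#' given the allele counts; the p-value is the fraction of random re-pairings
#' of the allele pool whose configuration is no more probable than the
#' observed one, with the add-one correction `(k + 1) / (n_perm + 1)`.
#'
#' @param gt genotype records for one population and one locus.
#' @param n_perm number of random pairings (default 2000).
#' @param seed integer seed for the permutation stream.
#' @return the Monte-Carlo p-value.
#' @export
hwe_test <- function(gt, n_perm = 2000, seed = 1) {
  keep <- !is.na(gt$allele_a)
  a <- gt$allele_a[keep]; b <- gt$allele_b[keep]
  if (length(a) < 3) stop("HWE test needs at least 3 genotypes")
  pool <- c(a, b)
  if (length(unique(pool)) < 2) {
    warning("monomorphic locus: HWE p-value set to 1")
    return(1)
  }
  obs <- log_hwe_prob(a, b)
  set.seed(seed)
  n <- length(a)
  k <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample(pool)
    if (log_hwe_prob(perm[seq_len(n)], perm[n + seq_len(n)]) <= obs + 1e-9)
      k <- k + 1L
  }
  (k + 1) / (n_perm + 1)
}

#' Bonferroni adjustment
#'
#' \eqn{p'_i = \min(1, m \, p_i)} with `m` the number of tests.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "bonferroni")
}

#' Drop under-sampled populations
#'
#' Removes every population with fewer than `min_n` non-missing genotypes at
#' one or more loci, the sample-size hygiene rule applied before computing
#' comparative diversity statistics.
#'
#' @param gt a [genotype_table()].
#' @param min_n minimum non-missing genotypes required at every locus
#'   (default 4).
#' @return list with `genotypes` (retained records) and `report` (data frame
#'   of dropped populations with the offending locus and its count).
#' @export
filter_populations <- function(gt, min_n = 4) {
  cell <- tapply(!is.na(gt$allele_a),
                 list(gt$population, gt$locus), sum, default = 0L)
  bad <- which(cell < min_n, arr.ind = TRUE)
  report <- data.frame(
    population = rownames(cell)[bad[, 1L]],
    locus = colnames(cell)[bad[, 2L]],
    n = cell[bad]
  )
  report <- report[order(report$population, report$locus), , drop = FALSE]
  drop_pops <- unique(report$population)
  keep <- !(gt$population %in% drop_pops)
  if (!any(keep)) stop("all populations dropped by the n < ", min_n, " rule")
  list(genotypes = gt[keep, , drop = FALSE], report = report)
}

#' Drop loci flagged for null alleles
#'
#' Removes every locus flagged positive for null alleles in at least
#' `max_flagged` populations. Flags come from an external null-allele
#' screen; this function only applies the removal rule.
#'
#' @param gt a [genotype_table()].
#' @param flags data frame with columns `locus`, `population`, `flagged`
#'   (logical).
#' @param max_flagged number of flagged populations at which a locus is
#'   removed (default 14).
#' @return list with `genotypes` and `report` (dropped loci with their flag
#'   counts).
#' @export
filter_loci <- function(gt, flags, max_flagged = 14) {
  if (nrow(flags) == 0) {
    return(list(genotypes = gt,
                report = data.frame(locus = character(), n_flagged = integer())))
  }
  unknown <- setdiff(unique(flags$locus), unique(gt$locus))
  if (length(unknown))
    stop("flags reference unknown locus: ", paste(unknown, collapse = ", "))
  counts <- tapply(flags$flagged, flags$locus, sum, default = 0L)
  drop <- names(counts)[counts >= max_flagged]
  report <- data.frame(locus = drop,
                       n_flagged = as.integer(counts[drop]))
  list(genotypes = gt[!(gt$locus %in% drop), , drop = FALSE], report = report)
}

#' Per-population diversity table
#'
#' Combines the mitochondrial statistics (`n_mt`, haplotype diversity `h`,
#' nucleotide diversity `pi`) and the microsatellite statistics (`n_nuc`,
#' `Ho`, `He`, rarefied `Ar`) into one table, one row per population.
#' Sequences differing only at `N`/gap positions are collapsed into one
#' haplotype.
#'
#' @param sequences named list: per population a character vector of aligned
#'   sequences (may be `NULL` for populations without mtDNA data).
#' @param gt a [genotype_table()] (may be `NULL`).
#' @param g rarefaction size passed to [allelic_richness()].
#' @return data frame with columns `population`, `n_mt`, `h`, `pi`, `n_nuc`,
#'   `Ho`, `He`, `Ar`.
#' @export
diversity_table <- function(sequences = NULL, gt = NULL, g = NULL) {
  pops <- union(names(sequences),
                if (!is.null(gt)) unique(as.character(gt$population)))
  out <- data.frame(population = pops, n_mt = NA_integer_, h = NA_real_,
                    pi = NA_real_, n_nuc = NA_integer_, Ho = NA_real_,
                    He = NA_real_, Ar = NA_real_)
  for (p in names(sequences)) {
    s <- sequences[[p]]
    i <- match(p, out$population)
    out$n_mt[i] <- length(s)
    if (length(s) >= 2) {
      out$h[i] <- haplotype_diversity(haplotype_counts(s))
      out$pi[i] <- nucleotide_diversity(s)
    }
  }
  if (!is.null(gt) && nrow(gt)) {
    ar <- allelic_richness(gt, g = g)
    for (p in unique(as.character(gt$population))) {
      sub <- gt[gt$population == p, ]
      i <- match(p, out$population)
      out$n_nuc[i] <- length(unique(sub$individual))
      out$Ho[i] <- observed_heterozygosity(sub)
      out$He[i] <- expected_heterozygosity(sub)
      out$Ar[i] <- ar$Ar[match(p, ar$population)]
    }
  }
  out
}

#' Haplotype counts of an aligned sample
#'
#' Two sequences are the same haplotype when they agree at every site where
#' both carry a plain base (differences confined to `N`/gap positions do not
#' separate haplotypes). Grouping is by single-linkage over that
#' compatibility relation.
#'
#' @param sequences character vector of aligned sequences.
#' @return integer vector of haplotype counts (unnamed).
#' @export
haplotype_counts <- function(sequences) {
  n <- length(sequences)
  if (n == 0) return(integer())
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences are not aligned (unequal lengths)")
  m <- t(vapply(toupper(sequences),
                function(s) strsplit(s, "", fixed = TRUE)[[1L]],
                character(L), USE.NAMES = FALSE))
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  grp <- seq_len(n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      comp <- valid[i, ] & valid[j, ]
      if (!any(m[i, comp] != m[j, comp])) {
        old <- grp[j]; new <- grp[i]
        grp[grp == old] <- new
      }
    }
  }
  as.integer(unname(table(grp)))
}
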