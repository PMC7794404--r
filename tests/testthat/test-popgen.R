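test_that("haplotype diversity matches the unbiased estimator on known configurations", {
  # worked configurations whose sample size forces the printed value
  expect_equal(haplotype_diversity(c(2, 1)), 0.667, tolerance = 5e-4)
  expect_equal(haplotype_diversity(c(4, 1)), 0.400, tolerance = 1e-9)
  expect_equal(haplotype_diversity(c(3, 2)), 0.600, tolerance = 1e-9)
  expect_equal(haplotype_diversity(c(2, 1, 1, 1)), 0.900, tolerance = 1e-9)
  expect_equal(haplotype_diversity(5), 0)
  expect_equal(haplotype_diversity(c(1, 1, 1, 1)), 1)
  expect_error(haplotype_diversity(1), "n < 2")
})

test_that("haplotype diversity equals n/(n-1) * (1 - sum p^2) for random configurations", {
  set.seed(42)
  for (i in 1:50) {
    counts <- rpois(sample(2:6, 1), 3) + 1
    n <- sum(counts)
    expect_equal(haplotype_diversity(counts),
                 n / (n - 1) * (1 - sum((counts / n)^2)))
  }
})

test_that("nucleotide diversity handles clean pairs and pairwise deletion", {
  expect_equal(nucleotide_diversity(c("ACGT", "ACGT", "ACGT")), 0)
  s <- c(paste(rep("A", 100), collapse = ""),
         paste(c(rep("A", 99), "C"), collapse = ""))
  expect_equal(nucleotide_diversity(s), 0.01)
  # three 10-bp sequences, pairwise differences (1, 2, 1)
  s3 <- c("AAAAAAAAAA", "CAAAAAAAAA", "CTAAAAAAAA")
  expect_equal(nucleotide_diversity(s3), (4 / 3) / 10, tolerance = 1e-12)
  # N / gap sites drop out of the pair that carries them
  s4 <- c("ANGT", "ACGT")  # comparable sites: 3, no differences
  expect_equal(nucleotide_diversity(s4), 0)
  s5 <- c("A-GT", "ACGA")  # comparable: 3, one difference
  expect_equal(nucleotide_diversity(s5), 1 / 3)
  expect_error(nucleotide_diversity("ACGT"), "n < 2")
})

test_that("nucleotide diversity agrees with the ape pairwise-deletion oracle", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(2:5, 1); L <- sample(8:20, 1)
    m <- matrix(sample(c("a", "c", "g", "t", "n"), n * L, replace = TRUE,
                       prob = c(0.23, 0.23, 0.23, 0.23, 0.08)), n, L)
    seqs <- apply(m, 1, paste, collapse = "")
    d <- ape::dist.dna(ape::as.DNAbin(m), model = "raw",
                       pairwise.deletion = TRUE)
    if (anyNA(d)) next   # a pair without comparable sites: oracle undefined
    expect_equal(nucleotide_diversity(seqs), mean(d), tolerance = 1e-12)
  }
})

test_that("expected heterozygosity applies Nei's small-sample correction per locus", {
  # 5 genotypes, allele counts {5, 5} of 10 copies
  gt <- one_locus_gt(list(c(1, 2), c(1, 2), c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(expected_heterozygosity(gt), (10 / 9) * 0.5, tolerance = 1e-12)
  # allele counts {9, 1}
  gt2 <- one_locus_gt(list(c(1, 1), c(1, 1), c(1, 1), c(1, 1), c(1, 2)))
  expect_equal(expected_heterozygosity(gt2), (10 / 9) * 0.18, tolerance = 1e-12)
  expect_equal(expected_heterozygosity(gt2, unbiased = FALSE), 0.18,
               tolerance = 1e-12)
  mono <- one_locus_gt(list(c(3, 3), c(3, 3), c(3, 3)))
  expect_equal(expected_heterozygosity(mono), 0)
})

test_that("expected heterozygosity is invariant to allele relabelling and record order", {
  gt <- random_gt(n_pop = 1, n_ind = 8, n_loci = 3, seed = 5)
  he <- expected_heterozygosity(gt)
  relab <- gt
  relab$allele_a <- 100 - gt$allele_a
  relab$allele_b <- 100 - gt$allele_b
  expect_equal(expected_heterozygosity(genotype_table(relab)), he)
  shuf <- gt[sample(nrow(gt)), ]
  expect_equal(expected_heterozygosity(genotype_table(shuf)), he)
})

test_that("observed heterozygosity averages per-locus heterozygote fractions", {
  hom <- one_locus_gt(list(c(1, 1), c(2, 2), c(3, 3)))
  expect_equal(observed_heterozygosity(hom), 0)
  het <- one_locus_gt(list(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(observed_heterozygosity(het), 1)
  # 3 of 10 heterozygous at locus 1, 1 of 10 at locus 2 -> mean 0.2
  pairs1 <- c(replicate(3, c(1, 2), simplify = FALSE),
              replicate(7, c(1, 1), simplify = FALSE))
  pairs2 <- c(replicate(1, c(1, 2), simplify = FALSE),
              replicate(9, c(2, 2), simplify = FALSE))
  gt <- rbind(one_locus_gt(pairs1, locus = "L1"),
              one_locus_gt(pairs2, locus = "L2"))
  expect_equal(observed_heterozygosity(genotype_table(gt)), 0.2)
})

test_that("rarefaction allelic richness matches closed form and edge contracts", {
  # N = 6 copies, counts {4, 2}, g = 4
  gt <- one_locus_gt(list(c(1, 1), c(1, 1), c(2, 2)))
  expect_equal(allelic_richness(gt, g = 4)$Ar, (1 - 0) + (1 - 1 / 15),
               tolerance = 1e-12)
  expect_equal(allelic_richness(gt, g = 6)$Ar, 2)   # full size: observed count
  expect_equal(allelic_richness(gt, g = 1)$Ar, 1)   # one copy shows one allele
  expect_error(allelic_richness(gt, g = 0), "g must")
  expect_error(allelic_richness(gt, g = 7), "exceeds")
})

test_that("rarefaction equals exhaustive subset enumeration and is monotone in g", {
  set.seed(3)
  for (rep in 1:12) {
    n_alleles <- sample(2:4, 1)
    counts <- as.numeric(rmultinom(1, sample(4:8, 1), rep(1, n_alleles)))
    counts <- counts[counts > 0]
    if (length(counts) < 1) next
    N <- sum(counts)
    prev <- 0
    for (g in 1:N) {
      ar <- meltpot:::rarefied_allele_count(counts, g)
      expect_equal(ar, ar_enumeration_oracle(counts, g), tolerance = 1e-10)
      expect_gte(ar + 1e-12, prev)
      prev <- ar
    }
  }
})

test_that("HWE Monte-Carlo test matches full enumeration on a tiny case", {
  gt <- one_locus_gt(list(c(1, 1), c(1, 2), c(2, 2)))
  # enumeration oracle: every permutation of the pool {1,1,1,2,2,2},
  # paired consecutively, weighted equally
  pool <- c(1, 1, 1, 2, 2, 2)
  obs <- meltpot:::log_hwe_prob(gt$allele_a, gt$allele_b)
  perm_all <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_all(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  lps <- vapply(perm_all(pool), function(p)
    meltpot:::log_hwe_prob(p[1:3], p[4:6]), numeric(1))
  exact_p <- mean(lps <= obs + 1e-9)
  mc_p <- hwe_test(gt, n_perm = 4000, seed = 9)
  expect_lt(abs(mc_p - exact_p), 0.02)
})

test_that("HWE test accepts Hardy-Weinberg proportions and flags monomorphism", {
  mono <- one_locus_gt(list(c(1, 1), c(1, 1), c(1, 1)))
  expect_warning(p <- hwe_test(mono), "monomorphic")
  expect_equal(p, 1)
  # 16 genotypes at exact HW proportions with p = q = 0.5: 4 AA, 8 AB, 4 BB
  pairs <- c(replicate(4, c(1, 1), simplify = FALSE),
             replicate(8, c(1, 2), simplify = FALSE),
             replicate(4, c(2, 2), simplify = FALSE))
  expect_gt(hwe_test(one_locus_gt(pairs), n_perm = 1000, seed = 2), 0.5)
})

test_that("Bonferroni adjustment clamps at 1 and rejects bad input", {
  expect_equal(bonferroni_adjust(c(0.01, 0.04)), c(0.02, 0.08))
  expect_equal(bonferroni_adjust(0.3), 0.3)
  expect_equal(bonferroni_adjust(c(0.9, 0.9, 0.9)), c(1, 1, 1))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("population filter drops any population under-sampled at one locus", {
  big <- lapply(1:10, function(i) c(1, 2))
  small <- lapply(1:3, function(i) c(1, 2))
  gt <- rbind(one_locus_gt(big, pop = "keep", locus = "L1"),
              one_locus_gt(big, pop = "keep", locus = "L2"),
              one_locus_gt(big, pop = "drop", locus = "L1"),
              one_locus_gt(small, pop = "drop", locus = "L2"))
  res <- filter_populations(genotype_table(gt), min_n = 4)
  expect_setequal(unique(res$genotypes$population), "keep")
  expect_equal(res$report$population, "drop")
  expect_equal(res$report$locus, "L2")
  # identity cases
  ok <- genotype_table(gt[gt$population == "keep", ])
  expect_equal(nrow(filter_populations(ok, min_n = 4)$genotypes), nrow(ok))
  expect_equal(nrow(filter_populations(ok, min_n = 0)$genotypes), nrow(ok))
  expect_error(filter_populations(ok, min_n = 99), "all populations dropped")
})

test_that("locus filter applies the null-allele flag-count rule", {
  gt <- random_gt(n_pop = 15, n_ind = 4, n_loci = 2, seed = 8)
  flags <- data.frame(locus = "L1", population = sprintf("p%d", 1:14),
                      flagged = TRUE)
  res <- filter_loci(gt, flags, max_flagged = 14)
  expect_false("L1" %in% res$genotypes$locus)
  expect_equal(res$report$locus, "L1")
  expect_equal(res$report$n_flagged, 14L)
  # no flags and over-large thresholds are identities
  none <- filter_loci(gt, flags[0, ], max_flagged = 14)
  expect_equal(nrow(none$genotypes), nrow(gt))
  lax <- filter_loci(gt, flags, max_flagged = 99)
  expect_equal(nrow(lax$genotypes), nrow(gt))
})

test_that("haplotype grouping tolerates N and gap positions", {
  expect_equal(sort(haplotype_counts(c("ACGT", "ACGT", "AGGT"))), c(1, 2))
  # middle sequence is compatible with the first: one haplotype of 2
  expect_equal(sort(haplotype_counts(c("ACGT", "ACNT", "AGGT"))), c(1, 2))
  # gap-only difference merges the pair into one haplotype of count 2
  expect_equal(haplotype_counts(c("AC-T", "ACGT")), 2)
})

test_that("diversity table combines mtDNA and microsatellite statistics", {
  gt <- random_gt(n_pop = 2, n_ind = 6, n_loci = 3, seed = 11)
  seqs <- list(p1 = c("ACGTACGT", "ACGTACGT", "ACCTACGT"),
               p2 = c("ACGTACGT", "TCGTACGA"))
  div <- diversity_table(seqs, gt)
  expect_setequal(div$population, c("p1", "p2"))
  expect_equal(div$n_mt, c(3, 2))
  expect_equal(div$h[1], haplotype_diversity(c(2, 1)))
  expect_equal(div$pi[2], 2 / 8)
  expect_true(all(div$He >= 0 & div$He <= 1))
  expect_true(all(div$Ar >= 1))
})
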