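#' Individual admixture matrices
#'
#' A Q-matrix holds one row per individual with its population label and the
#' estimated membership proportion in each of K genetic clusters; rows sum
#' to 1. These matrices are produced by external spatial Bayesian clustering
#' and consumed here as data frames with a `population` column followed by
#' numeric cluster columns.
#'
#' @param df data frame: `population`, then K numeric cluster columns (an
#'   optional `individual` column is retained).
#' @param tol row-sum tolerance (default 1e-6).
#' @return validated data frame of class `c("q_matrix", "data.frame")`.
#' @export
q_matrix <- function(df, tol = 1e-6) {
  if (!"population" %in% names(df)) stop("q_matrix needs a population column")
  qc <- q_cols(df)
  if (length(qc) < 2) stop("q_matrix needs at least two cluster columns")
  Q <- as.matrix(df[qc])
  if (any(Q < -tol | Q > 1 + tol)) stop("admixture proportions must lie in [0, 1]")
  bad <- abs(rowSums(Q) - 1) > tol
  if (any(bad))
    stop(sum(bad), " Q-matrix row(s) do not sum to 1 within ", tol)
  df <- as.data.frame(df)
  class(df) <- c("q_matrix", "data.frame")
  df
}

q_cols <- function(df) {
  setdiff(names(df)[vapply(df, is.numeric, logical(1))],
          c("population", "individual"))
}

#' Population-average admixture proportions
#'
#' Arithmetic mean of the individual cluster proportions within each
#' population, renormalised to sum exactly to 1.
#'
#' @param q a [q_matrix()].
#' @return data frame: `population`, one column per cluster.
#' @export
population_mean_q <- function(q) {
  qc <- q_cols(q)
  pops <- unique(as.character(q$population))
  rows <- lapply(pops, function(p) {
    sub <- as.matrix(q[q$population == p, qc, drop = FALSE])
    if (nrow(sub) == 0) {
      warning("population ", p, " has no individuals; excluded")
      return(NULL)
    }
    m <- colMeans(sub)
    m / sum(m)
  })
  keep <- !vapply(rows, is.null, logical(1))
  out <- data.frame(population = pops[keep])
  out[qc] <- do.call(rbind, rows[keep])
  out
}

#' Average the lowest-DIC clustering replicates
#'
#' Element-wise mean of the Q-matrices of the `top_m` replicate runs with
#' the lowest deviance information criterion. Replicates are assumed
#' label-aligned (cluster columns refer to the same cluster in every run);
#' a misalignment heuristic warns when some run's columns correlate better
#' with a permutation of the first run's columns than with the identity.
#'
#' @param q_runs list of [q_matrix()] objects sharing individuals and K.
#' @param dic numeric vector, one DIC per run.
#' @param top_m number of lowest-DIC runs to average (default 10).
#' @return a [q_matrix()] with the averaged proportions.
#' @export
average_replicates <- function(q_runs, dic, top_m = 10) {
  if (length(q_runs) != length(dic))
    stop("q_runs and dic must have the same length")
  if (length(q_runs) < top_m) {
    warning("only ", length(q_runs), " runs available; averaging all of them")
    top_m <- length(q_runs)
  }
  pick <- order(dic)[seq_len(top_m)]
  qc <- q_cols(q_runs[[pick[1L]]])
  ref <- as.matrix(q_runs[[pick[1L]]][qc])
  acc <- matrix(0, nrow(ref), length(qc))
  for (i in pick) {
    cur <- as.matrix(q_runs[[i]][qc])
    if (!all(dim(cur) == dim(ref)))
      stop("replicate Q-matrices differ in shape")
    if (alignment_score(ref, cur) < best_permuted_score(ref, cur) - 1e-8)
      warning("run ", i, " looks label-switched relative to the first run; ",
              "averaging anyway (align replicates upstream)")
    acc <- acc + cur
  }
  out <- q_runs[[pick[1L]]]
  out[qc] <- acc / top_m
  q_matrix(as.data.frame(out))
}

alignment_score <- function(ref, cur) {
  mean(vapply(seq_len(ncol(ref)), function(k) {
    s1 <- stats::sd(ref[, k]); s2 <- stats::sd(cur[, k])
    if (is.na(s1) || is.na(s2) || s1 == 0 || s2 == 0) return(1)
    stats::cor(ref[, k], cur[, k])
  }, numeric(1)))
}

best_permuted_score <- function(ref, cur) {
  perms <- permutations_of(ncol(ref))
  max(vapply(perms, function(p) alignment_score(ref, cur[, p, drop = FALSE]),
             numeric(1)))
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (rest in permutations_of(k - 1L)) {
      tail <- seq_len(k)[-i][rest]
      out[[length(out) + 1L]] <- c(i, tail)
    }
  }
  out
}

#' Simpson diversity index of admixture
#'
#' \eqn{D = 1 - \sum_k q_k^2} over a population's mean cluster proportions:
#' 0 for a pure population, approaching \eqn{1 - 1/K} under even admixture.
#' This is the probability that two gene pools drawn with replacement from
#' the population's cluster profile belong to different clusters, and it is
#' the admixture predictor used in the attribution models.
#'
#' @param q numeric vector of proportions summing to 1.
#' @return Simpson index in `[0, 1 - 1/K]`.
#' @export
simpson_index <- function(q) {
  if (any(q < 0)) stop("proportions must be non-negative")
  if (abs(sum(q) - 1) > 1e-6) stop("proportions must sum to 1")
  1 - sum(q^2)
}

#' Select the number of clusters at the DIC plateau
#'
#' Averages DIC over replicates per K and returns the smallest K at which
#' the improvement to K + 1 falls below `epsilon` times the total range of
#' the mean-DIC curve — a reproducible operationalisation of reading the
#' plateau off the DIC-versus-K plot.
#'
#' @param dic data frame with columns `K`, `replicate`, `DIC`.
#' @param epsilon plateau sensitivity as a fraction of the DIC range
#'   (default 0.05).
#' @return the selected K (integer).
#' @export
select_k_plateau <- function(dic, epsilon = 0.05) {
  if (!all(c("K", "DIC") %in% names(dic)))
    stop("dic table needs columns K and DIC")
  means <- tapply(dic$DIC, dic$K, mean)
  ks <- as.integer(names(means))
  if (length(ks) < 3) stop("plateau selection needs at least 3 distinct K")
  o <- order(ks)
  ks <- ks[o]; means <- as.numeric(means)[o]
  rng <- max(means) - min(means)
  if (rng == 0) return(ks[1L])
  if (any(diff(means) > epsilon * rng))
    warning("mean DIC rises substantially with K; curve is not monotone")
  improvement <- -diff(means)  # drop from K to K + 1
  hit <- which(improvement < epsilon * rng)
  if (!length(hit)) {
    warning("no DIC plateau found; returning the largest K")
    return(ks[length(ks)])
  }
  ks[hit[1L]]
}
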