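## Individual-based finite-population simulations with demography.
##
## Each patch holds an integer count per diploid genotype.  One generation:
## every individual migrates to an adjacent patch with probability m
## (interior patches split migrants evenly between the two neighbours,
## boundary patches send m/2 to their single neighbour, mirroring the
## deterministic kernel); each patch then produces a Poisson number of
## offspring with mean N * F * Wbar, truncated at the carrying capacity K
## (density regulation by uniform culling); offspring are formed by random
## union of two gametes drawn from the patch's fitness-weighted gamete
## output pool (parents sampled proportional to fitness, gametes from the
## drive-aware meiosis of each parental genotype).

#' Demography parameters for the stochastic model
#'
#' @param K Carrying capacity per patch (individuals).
#' @param F Fertility: expected offspring per individual at low density for
#'   a population of maximal fitness.  Values slightly above 1 mean a
#'   population can only just replace itself once the payload has fixed.
#' @param m Per-individual migration probability per generation.
#' @param replicates Number of replicate simulations for summaries.
#' @param seed Integer seed.
#' @return An object of class \code{"demography_params"}.
#' @examples
#' demography_params(K = 2000, F = 1.2, m = 0.05, replicates = 20, seed = 1)
#' @export
demography_params <- function(K = 10000, F = 1.2, m = 0, replicates = 50,
                              seed = 1L) {
  stopifnot(K >= 1, F > 0)
  check_prob(m, "m")
  stopifnot(replicates >= 1)
  structure(list(K = as.integer(K), F = F, m = m,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "demography_params")
}

## Genotype bookkeeping shared by the stochastic routines: unordered gamete
## pairs, their fitness, gamete output distributions, and carrier flags.
genotype_tables <- function(model) {
  G <- model$arch$G
  pairs <- which(upper.tri(matrix(0, G, G), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  a <- pairs[, 1]; b <- pairs[, 2]
  ng <- length(a)
  pair_id <- matrix(0L, G, G)
  pair_id[cbind(a, b)] <- seq_len(ng)
  pair_id[cbind(b, a)] <- seq_len(ng)
  w <- model$W[cbind(a, b)]
  Tg <- model$Tm[(b - 1) * G + a, , drop = FALSE]  # gamete output per genotype
  bC <- model$arch$bits[, model$arch$n_daisy + 1] == 1
  hasC <- bC[a] | bC[b]
  if (model$arch$n_daisy >= 1) {
    bB <- model$arch$bits[, model$arch$n_daisy] == 1
    hasB <- bB[a] | bB[b]
  } else hasB <- rep(FALSE, ng)
  list(a = a, b = b, n = ng, pair_id = pair_id, w = w, Tg = Tg,
       hasC = hasC, hasB = hasB)
}

#' Initial genotype counts for a stochastic release
#'
#' Fills every patch with \code{K} wildtype homozygotes and replaces a
#' fraction \code{f0} of the release patch with fully engineered
#' homozygotes.
#'
#' @param model A [daisy_quorum_model()].
#' @param demo A [demography_params()].
#' @param M Number of patches.
#' @param f0 Release frequency in the release patch.
#' @param release_patch Release patch index (default centre).
#' @return Genotype-by-patch count matrix.
#' @export
initial_counts <- function(model, demo, M, f0 = 0.05,
                           release_patch = (M + 1) %/% 2) {
  gt <- genotype_tables(model)
  counts <- matrix(0L, gt$n, M)
  wt <- gt$pair_id[1, 1]
  full <- gt$pair_id[model$arch$G, model$arch$G]
  counts[wt, ] <- demo$K
  nrel <- round(f0 * demo$K)
  counts[wt, release_patch] <- demo$K - nrel
  counts[full, release_patch] <- nrel
  counts
}

migrate_counts <- function(counts, m) {
  M <- ncol(counts)
  if (M == 1 || m == 0) return(counts)
  out <- matrix(0L, nrow(counts), M)
  for (j in seq_len(M)) {
    cj <- counts[, j]
    tot <- sum(cj)
    if (tot == 0) next
    p <- if (j == 1) c(1 - m / 2, 0, m / 2)
         else if (j == M) c(1 - m / 2, m / 2, 0)
         else c(1 - m, m / 2, m / 2)
    for (g in which(cj > 0)) {
      mv <- stats::rmultinom(1, cj[g], p)
      out[g, j] <- out[g, j] + mv[1]
      if (j > 1) out[g, j - 1] <- out[g, j - 1] + mv[2]
      if (j < M) out[g, j + 1] <- out[g, j + 1] + mv[3]
    }
  }
  out
}

reproduce_patch <- function(cj, gt, demo, G) {
  N <- sum(cj)
  if (N == 0) return(cj)
  wbar <- sum(cj * gt$w) / N
  n_off <- stats::rpois(1, N * demo$F * wbar)
  n_off <- min(n_off, demo$K)
  out <- integer(length(cj))
  if (n_off == 0) return(out)
  # fitness-weighted gamete output pool of the patch
  q <- as.vector(crossprod(gt$Tg, cj * gt$w))
  q <- q / sum(q)
  g1 <- sample.int(G, n_off, replace = TRUE, prob = q)
  g2 <- sample.int(G, n_off, replace = TRUE, prob = q)
  ids <- gt$pair_id[cbind(g1, g2)]
  tab <- tabulate(ids, nbins = length(cj))
  out + tab
}

#' One stochastic generation
#'
#' Migration followed by reproduction with selection, drive and density
#' regulation in every patch.  Extinct patches stay empty until recolonised
#' by migrants.
#'
#' @param model A [daisy_quorum_model()].
#' @param counts Genotype-by-patch count matrix.
#' @param demo A [demography_params()].
#' @param gt Genotype tables from \code{genotype_tables(model)} (computed
#'   if missing).
#' @return Updated count matrix.
#' @export
sample_generation <- function(model, counts, demo, gt = genotype_tables(model)) {
  counts <- migrate_counts(counts, demo$m)
  G <- model$arch$G
  for (j in seq_len(ncol(counts)))
    counts[, j] <- reproduce_patch(counts[, j], gt, demo, G)
  counts
}

#' Run one stochastic replicate
#'
#' @param model A [daisy_quorum_model()].
#' @param demo A [demography_params()].
#' @param M Number of patches.
#' @param f0 Release frequency in the release patch.
#' @param generations Horizon.
#' @param release_patch Release patch (default centre).
#' @return A data frame with one row per generation and patch:
#'   population size \code{N}, payload carriers \code{n_C}, driver
#'   carriers \code{n_B}.
#' @export
run_stochastic <- function(model, demo, M = 1, f0 = 0.05, generations = 100,
                           release_patch = (M + 1) %/% 2) {
  gt <- genotype_tables(model)
  counts <- initial_counts(model, demo, M, f0, release_patch)
  rows <- vector("list", generations + 1)
  snap <- function(t) data.frame(generation = t, patch = seq_len(M),
                                 N = colSums(counts),
                                 n_C = colSums(counts[gt$hasC, , drop = FALSE]),
                                 n_B = colSums(counts[gt$hasB, , drop = FALSE]))
  rows[[1]] <- snap(0)
  for (t in seq_len(generations)) {
    counts <- sample_generation(model, counts, demo, gt)
    rows[[t + 1]] <- snap(t)
  }
  do.call(rbind, rows)
}

#' Replicate summaries of the stochastic model
#'
#' Runs \code{demo$replicates} stochastic replicates from a single seeded
#' random stream and summarises, per generation and patch, the median and
#' first/third quartiles of the population size and of the numbers of
#' payload (C) and driver (B) carriers.
#'
#' @inheritParams run_stochastic
#' @return A data frame with columns \code{generation}, \code{patch},
#'   and for each of \code{N}, \code{n_C}, \code{n_B} the median and
#'   quartile columns.
#' @examples
#' \donttest{
#' m <- daisy_quorum_model(drive_params(2, 0.9, 0.02), valley_params(0.9, 0.1))
#' demo <- demography_params(K = 500, F = 1.2, replicates = 4, seed = 1)
#' s <- run_replicates(m, demo, M = 1, f0 = 0.2, generations = 20)
#' }
#' @export
run_replicates <- function(model, demo, M = 1, f0 = 0.05, generations = 100,
                           release_patch = (M + 1) %/% 2) {
  stopifnot(demo$replicates >= 2)
  set.seed(demo$seed)
  reps <- lapply(seq_len(demo$replicates), function(i) {
    cbind(replicate = i,
          run_stochastic(model, demo, M, f0, generations, release_patch))
  })
  all <- do.call(rbind, reps)
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  agg <- function(col) {
    a <- stats::aggregate(all[[col]],
                          by = list(generation = all$generation, patch = all$patch),
                          FUN = qs)
    out <- data.frame(a$generation, a$patch, a$x)
    names(out) <- c("generation", "patch",
                    paste0(col, c("_q1", "_median", "_q3")))
    out
  }
  out <- agg("N")
  for (col in c("n_C", "n_B")) out <- merge(out, agg(col),
                                            by = c("generation", "patch"))
  out[order(out$generation, out$patch), ]
}
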