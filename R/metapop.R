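## Linear stepping-stone metapopulation of deterministic patches.

#' Stepping-stone metapopulation configuration
#'
#' @param M Number of patches (default 101).
#' @param m Per-generation migration fraction exchanged with each pair of
#'   adjacent patches.
#' @param release_patch Index of the release patch (default the centre).
#' @param release A [release_spec()] or release frequency \code{f0} of the
#'   fully engineered gamete (default 0.05).
#' @return An object of class \code{"metapop_config"}.
#' @examples
#' metapop_config(m = 0.025)
#' @export
metapop_config <- function(M = 101, m = 0.01, release_patch = (M + 1) %/% 2,
                           release = 0.05) {
  stopifnot(M >= 1, M == round(M))
  check_prob(m, "m")
  stopifnot(release_patch >= 1, release_patch <= M)
  if (is.numeric(release)) release <- release_spec(release)
  structure(list(M = as.integer(M), m = m,
                 release_patch = as.integer(release_patch), release = release),
            class = "metapop_config")
}

#' Initial metapopulation state
#'
#' @param model A [daisy_quorum_model()].
#' @param cfg A [metapop_config()].
#' @return A gamete-by-patch frequency matrix.
#' @export
initial_metapopulation <- function(model, cfg) {
  X <- matrix(0, model$arch$G, cfg$M)
  X[1, ] <- 1
  X[, cfg$release_patch] <- release_state(model, cfg$release)
  rownames(X) <- model$arch$labels
  X
}

## Nearest-neighbour migration; interior patches exchange m/2 with each
## neighbour, boundary patches keep 1 - m/2 and exchange m/2 with their
## single neighbour, so the kernel is doubly stochastic.
migrate_stepping_stone <- function(X, m) {
  M <- ncol(X)
  if (M == 1 || m == 0) return(X)
  Xl <- X[, c(1, seq_len(M - 1)), drop = FALSE]
  Xr <- X[, c(2:M, M), drop = FALSE]
  Y <- (1 - m) * X + (m / 2) * (Xl + Xr)
  Y[, 1] <- (1 - m / 2) * X[, 1] + (m / 2) * X[, 2]
  Y[, M] <- (1 - m / 2) * X[, M] + (m / 2) * X[, M - 1]
  Y
}

#' One generation of the stepping-stone metapopulation
#'
#' Migration (interior patches exchange \code{m/2} with each neighbour,
#' boundary patches only with the interior) followed by one generation of
#' local selection, drive and recombination within each patch.
#'
#' @param model A [daisy_quorum_model()].
#' @param X Gamete-by-patch frequency matrix.
#' @param cfg A [metapop_config()] (supplies \code{m}).
#' @return Updated frequency matrix.
#' @export
step_metapopulation <- function(model, X, cfg) {
  next_generation(model, migrate_stepping_stone(X, cfg$m))
}

#' Run the spatial spread of a central release
#'
#' @param model A [daisy_quorum_model()].
#' @param cfg A [metapop_config()].
#' @param generations Horizon (default 1000).
#' @param record_every Record the payload allele frequency field every this
#'   many generations (default 50; the final generation is always
#'   recorded).
#' @return A list with \code{payload}, the patches-by-time matrix of
#'   engineered C-allele frequencies, \code{final} (its last column),
#'   \code{times}, and the final full state \code{X}.
#' @examples
#' \donttest{
#' m <- daisy_quorum_model(drive_params(2, 0.9, 0.02), valley_params(0.9, 0.1))
#' sp <- run_spread(m, metapop_config(M = 31, m = 0.025), generations = 200)
#' sum(sp$final > 0.5)
#' }
#' @export
run_spread <- function(model, cfg, generations = 1000, record_every = 50) {
  X <- initial_metapopulation(model, cfg)
  bC <- model$arch$bits[, model$arch$n_daisy + 1] == 1
  rec_t <- unique(c(seq(record_every, generations, by = record_every), generations))
  payload <- matrix(0, cfg$M, length(rec_t))
  j <- 1
  for (t in seq_len(generations)) {
    X <- step_metapopulation(model, X, cfg)
    if (j <= length(rec_t) && t == rec_t[j]) {
      payload[, j] <- colSums(X[bC, , drop = FALSE])
      j <- j + 1
    }
  }
  list(payload = payload, final = payload[, length(rec_t)], times = rec_t, X = X)
}

#' Sweep the migration rate
#'
#' Runs [run_spread()] for each migration rate and collects the final
#' payload-frequency field, reproducing the confinement / expansion /
#' swamping phase behaviour of the stepping-stone model.
#'
#' @param model A [daisy_quorum_model()].
#' @param m_grid Sorted vector of migration rates.
#' @param cfg Template [metapop_config()] (its \code{m} is replaced).
#' @param generations Horizon per run (default 1000).
#' @return A long-format data frame with columns \code{m}, \code{patch}
#'   and \code{payload_frequency}.
#' @export
migration_sweep <- function(model, m_grid, cfg = metapop_config(),
                            generations = 1000) {
  stopifnot(!is.unsorted(m_grid))
  rows <- lapply(m_grid, function(m) {
    cfg$m <- m
    fin <- run_spread(model, cfg, generations,
                      record_every = generations)$final
    data.frame(m = m, patch = seq_along(fin), payload_frequency = fin)
  })
  do.call(rbind, rows)
}

#' Empirical gene-swamping threshold on the migration rate
#'
#' Finds the smallest migration rate at which the payload fails to
#' establish anywhere (no patch above \code{established} at the horizon),
#' by bisection between a migration rate where establishment succeeds and
#' one where it fails.
#'
#' @param model A [daisy_quorum_model()].
#' @param cfg Template [metapop_config()].
#' @param lower,upper Bracketing migration rates (establishment must
#'   succeed at \code{lower} and fail at \code{upper}).
#' @param generations Horizon per run (default 1000).
#' @param tol Bisection tolerance on \code{m} (default 1e-3).
#' @param established Payload frequency counted as establishment
#'   (default 0.5).
#' @return The smallest migration rate (within \code{tol}) at which
#'   establishment fails.
#' @export
swamping_threshold <- function(model, cfg = metapop_config(),
                               lower = 0.01, upper = 0.15,
                               generations = 1000, tol = 1e-3,
                               established = 0.5) {
  establishes <- function(m) {
    cfg$m <- m
    fin <- run_spread(model, cfg, generations,
                      record_every = generations)$final
    any(fin > established)
  }
  if (!establishes(lower))
    stop("establishment already fails at 'lower'", call. = FALSE)
  if (establishes(upper))
    stop("establishment still succeeds at 'upper'", call. = FALSE)
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (establishes(mid)) lo <- mid else hi <- mid
  }
  hi
}
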