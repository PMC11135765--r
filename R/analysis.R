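## Equilibrium, separatrix and invasion analysis for the cargo subsystem,
## and release-threshold bisection for the full system.

## --- symmetric valley fixed points -----------------------------------------
## The cargo subsystem started from a CD release keeps X_cD = X_Cd, so
## symmetric states are parameterised by (x, y) = (X_CD, X_cD = X_Cd) with
## X_cd = 1 - x - 2y.

valley_map_xy <- function(model, z) {
  x <- c(1 - z[1] - 2 * z[2], z[2], z[2], z[1])
  xp <- tryCatch(next_generation(model, x), error = function(e) NULL)
  if (is.null(xp)) return(c(NA_real_, NA_real_))
  c(xp[4], xp[2])
}

newton_valley <- function(model, z0, iters = 80, tol = 1e-13) {
  z <- z0; h <- 1e-7
  for (i in seq_len(iters)) {
    if (any(!is.finite(z)) || z[1] < -0.2 || z[1] > 1.2 || z[2] < -0.2 || z[2] > 0.7)
      return(NULL)
    Fz <- valley_map_xy(model, z) - z
    if (any(!is.finite(Fz))) return(NULL)
    if (max(abs(Fz)) < tol) break
    J <- matrix(0, 2, 2)
    for (k in 1:2) {
      zp <- z; zp[k] <- zp[k] + h
      J[, k] <- (valley_map_xy(model, zp) - Fz - z) / h
    }
    J <- J - diag(2)
    step <- tryCatch(solve(J, Fz), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    z <- z - step
  }
  res <- valley_map_xy(model, z) - z
  if (all(is.finite(res)) && max(abs(res)) < 1e-10) z else NULL
}

## All interior symmetric fixed points (x, y interior, cd interior)
internal_symmetric_equilibria <- function(model, starts = NULL, merge_tol = 1e-6,
                                          include_grid = TRUE) {
  if (include_grid) {
    grid_x <- seq(0.05, 0.95, length.out = 10)
    grid_y <- c(0.002, 0.01, 0.04, 0.1, 0.2, 0.3)
    starts <- rbind(starts,
                    as.matrix(expand.grid(x = grid_x, y = grid_y)))
  }
  sols <- list()
  for (k in seq_len(nrow(starts))) {
    z0 <- as.numeric(starts[k, ])
    if (z0[1] + 2 * z0[2] >= 0.999) next
    z <- newton_valley(model, z0)
    if (is.null(z)) next
    cd <- 1 - z[1] - 2 * z[2]
    if (z[1] < 1e-8 || cd < 1e-8 || z[2] < 1e-8) next
    if (!any(vapply(sols, function(s) max(abs(s - z)) < merge_tol, logical(1))))
      sols[[length(sols) + 1]] <- z
  }
  sols
}

## Jacobian of the full 4-gamete map in the 3 free coordinates (x4 implicit)
valley_jacobian <- function(model, x) {
  h <- 1e-6
  f <- function(v3) {
    next_generation(model, c(v3, 1 - sum(v3)))[1:3]
  }
  v <- x[1:3]
  J <- matrix(0, 3, 3)
  for (k in 1:3) {
    e <- numeric(3); e[k] <- h
    J[, k] <- (f(v + e) - f(v - e)) / (2 * h)
  }
  J
}

classify_equilibrium <- function(model, x, tol = 1e-4) {
  lam <- max(Mod(eigen(valley_jacobian(model, x), only.values = TRUE)$values))
  if (lam < 1 - tol) return(list(class = "stable", lambda = lam))
  if (lam > 1 + tol) return(list(class = "unstable", lambda = lam))
  # marginal leading eigenvalue (e.g. construct fixation, where rare single
  # haplotypes are neutral at linear order): probe with a small interior
  # perturbation and compare the distance travelled
  eps <- 0.01
  y <- (1 - eps) * x + eps * rep(0.25, 4)
  d0 <- max(abs(y - x))
  for (t in 1:500) y <- next_generation(model, y)
  d <- max(abs(y - x))
  cls <- if (d < 0.9 * d0) "stable" else if (d > 3 * d0) "unstable" else "marginal"
  list(class = cls, lambda = lam)
}

#' Equilibria of the cargo (fitness-valley) subsystem
#'
#' Finds the boundary equilibria (loss, \code{X_cd = 1}, and fixation,
#' \code{X_CD = 1}) and any interior symmetric equilibria
#' (\code{X_cD = X_Cd}) of the two-locus valley recursions without drive,
#' from a grid of starting points refined by Newton iteration, and
#' classifies their local stability from the numerically differentiated
#' Jacobian (with a nonlinear probe when the leading eigenvalue is
#' marginal, as at construct fixation where rare single-engineered
#' haplotypes are selectively neutral at linear order).
#'
#' @param valley A [valley_params()] object.
#' @param drive_force Optional constant drive force applied at the cargo
#'   loci (default 0).
#' @return A data frame with one row per equilibrium: the four gamete
#'   frequencies, the engineered-allele frequency \code{p_C}, the
#'   stability \code{class}, and the leading Jacobian eigenvalue modulus
#'   \code{lambda}.
#' @examples
#' find_equilibria(valley_params(s_t = 0.9, s_p = 0.2))
#' @export
find_equilibria <- function(valley, drive_force = 0) {
  model <- valley_model(valley, drive_force)
  states <- list(c(1, 0, 0, 0), c(0, 0, 0, 1))
  for (z in internal_symmetric_equilibria(model))
    states[[length(states) + 1]] <- c(1 - z[1] - 2 * z[2], z[2], z[2], z[1])
  rows <- lapply(states, function(x) {
    cl <- classify_equilibrium(model, x)
    data.frame(X_cd = x[1], X_cD = x[2], X_Cd = x[3], X_CD = x[4],
               p_C = x[3] + x[4], class = cl$class, lambda = cl$lambda)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## --- separatrix and thresholds ---------------------------------------------

#' Introduction threshold of the valley construct along the CD release ray
#'
#' Bisects the introduction frequency \code{f} of \code{CD} gametes (with
#' the remainder wildtype) for the smallest \code{f} whose trajectory
#' reaches the high-frequency basin of the construct, i.e. the point where
#' the release ray crosses the separatrix.  A constant drive force can be
#' applied at the cargo loci, which moves the separatrix towards lower
#' thresholds.
#'
#' @param valley A [valley_params()] object.
#' @param drive_force Constant transmission-bias conversion probability at
#'   heterozygous cargo loci (default 0).
#' @param tol Bisection tolerance on \code{f} (default 1e-4).
#' @param generations Horizon used to decide the basin (default 500); the
#'   criterion is evaluated at the horizon, so trajectories that rise and
#'   collapse again are not mistaken for crossings.
#' @param success_freq Engineered-allele frequency at locus C counted as
#'   having reached the high basin (default 0.99).
#' @return The threshold frequency, or \code{NA} (with a warning) if no
#'   introduction frequency below 1 reaches the high basin.
#' @examples
#' \donttest{
#' separatrix_threshold(valley_params(s_t = 0.9, s_p = 0.2))
#' }
#' @export
separatrix_threshold <- function(valley, drive_force = 0, tol = 1e-4,
                                 generations = 500, success_freq = 0.99) {
  model <- valley_model(valley, drive_force)
  succ <- function(f) {
    x <- c(1 - f, 0, 0, f)
    for (t in seq_len(generations)) x <- next_generation(model, x)
    x[[3]] + x[[4]] > success_freq
  }
  if (!succ(1 - 1e-9)) {
    warning("no introduction frequency below 1 reaches the high basin")
    return(NA_real_)
  }
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (succ(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Toxin load giving a 50\% introduction threshold
#'
#' Closed-form toxin load \code{s_t} at which the interior unstable
#' equilibrium of the valley construct (dominant payload) sits exactly at
#' allele frequency 1/2:
#' \deqn{s_t = s_p \sqrt{\frac{r}{2 (1 - s_p) (2 r (1 - s_p) - s_p)}}.}
#'
#' @param s_p Payload cost.
#' @param r Recombination fraction between the cargo loci.
#' @return The midpoint toxin load.
#' @examples
#' midpoint_toxin_load(0.2, 0.5)
#' @export
midpoint_toxin_load <- function(s_p, r = 0.5) {
  check_prob(s_p, "s_p")
  check_prob(r, "r", max = 0.5)
  den <- 2 * (1 - s_p) * (2 * r * (1 - s_p) - s_p)
  if (den <= 0) stop("no midpoint toxin load exists: 2 r (1 - s_p) <= s_p",
                     call. = FALSE)
  s_p * sqrt(r / den)
}

## --- invasion analysis ------------------------------------------------------

#' Invasion eigenvalues of the rare cargo under a fixed drive force
#'
#' Linearised growth rates of the cargo around the wildtype state when the
#' cargo loci experience a constant drive force \code{delta_c} (dominant
#' payload).  The two routes of invasion are a single engineered allele
#' (C or D alone, which pays the toxin load),
#' \deqn{\lambda_1 = (1 + \delta_c)(1 - s_p)(1 - s_t),}
#' and the intact CD haplotype, whose spread is slowed by recombination,
#' \deqn{\lambda_2 = (1 - s_p)\,[\,1 + \delta_c^2 - r (1 - \delta_c)^2\,].}
#' The cargo can spread when rare iff \eqn{\lambda_L = \max(\lambda_1,
#' \lambda_2) > 1}.
#'
#' @param delta_c Drive force in \code{[0, 1]}.
#' @param valley A [valley_params()] object (dominant payload).
#' @return A list with \code{lambda1}, \code{lambda2}, \code{lambdaL},
#'   the current drive force \code{delta_c}, and the critical force
#'   \code{delta_c_star} from [critical_drive_force()].
#' @examples
#' invasion_eigenvalues(0.95, valley_params(s_t = 0.9, s_p = 0.2))
#' @export
invasion_eigenvalues <- function(delta_c, valley) {
  check_prob(delta_c, "delta_c")
  s_p <- valley$s_p; s_t <- valley$s_t; r <- valley$r
  l1 <- (1 + delta_c) * (1 - s_p) * (1 - s_t)
  l2 <- (1 - s_p) * (1 + delta_c^2 - r * (1 - delta_c)^2)
  list(lambda1 = l1, lambda2 = l2, lambdaL = max(l1, l2),
       delta_c = delta_c, delta_c_star = critical_drive_force(valley))
}

#' Critical drive force for invasion of the cargo
#'
#' The smallest constant drive force for which the rare cargo grows
#' (\eqn{\lambda_L = 1}): the minimum over the single-allele route,
#' \eqn{1/((1-s_p)(1-s_t)) - 1}, and the haplotype route, the positive root
#' of \eqn{(1-s_p)[1 + \delta_c^2 - r(1-\delta_c)^2] = 1} (at \code{r = 1/2}
#' this root is \eqn{\sqrt{2/(1-s_p)} - 1}).  Values above 1 mean the cargo
#' can never invade (a dominant payload with \code{s_p > 1/2} at
#' \code{s_t = 0}, for example).
#'
#' @param valley A [valley_params()] object (dominant payload).
#' @return The critical drive force (possibly > 1).
#' @examples
#' critical_drive_force(valley_params(s_t = 0, s_p = 0.5))  # exactly 1
#' @export
critical_drive_force <- function(valley) {
  s_p <- valley$s_p; s_t <- valley$s_t; r <- valley$r
  d1 <- if (s_p < 1 && s_t < 1) 1 / ((1 - s_p) * (1 - s_t)) - 1 else Inf
  q <- if (s_p < 1) 1 / (1 - s_p) else Inf
  # (1 - r) dc^2 + 2 r dc - r - (q - 1) = 0
  d2 <- if (is.finite(q)) {
    if (r < 0.5) {
      a <- 1 - r
      (-2 * r + sqrt(4 * r^2 + 4 * a * (r + q - 1))) / (2 * a)
    } else {
      sqrt(2 * q) - 1
    }
  } else Inf
  min(d1, d2)
}

## --- release threshold for the full system ----------------------------------

#' Minimal release frequency for fixation of the cargo
#'
#' Bisects the release frequency \code{f0} of the fully engineered gamete
#' for the smallest \code{f0} from which the engineered allele at cargo
#' locus C exceeds \code{success_freq} within the horizon.
#'
#' @param model A [daisy_quorum_model()].
#' @param generations Horizon (default 500).
#' @param tol Bisection tolerance on \code{f0} (default 1e-3).
#' @param success_freq Fixation criterion on the C-allele frequency
#'   (default 0.99; deterministic recursions never reach exactly 1).
#' @param gamete Released gamete (default the fully engineered one).
#' @return The threshold release frequency, or \code{NA} (with a warning)
#'   if no release below 1 fixes the cargo.
#' @examples
#' \donttest{
#' m <- daisy_quorum_model(drive_params(2, 0.95, 0.1), valley_params(0.9, 0.2))
#' release_threshold(m)
#' }
#' @export
release_threshold <- function(model, generations = 500, tol = 1e-3,
                              success_freq = 0.99, gamete = "full") {
  iC <- model$arch$n_daisy + 1
  bC <- model$arch$bits[, iC] == 1
  succ <- function(f0) {
    x <- release_state(model, release_spec(f0, gamete))
    for (t in seq_len(generations)) x <- next_generation(model, x)
    sum(x[bC]) > success_freq
  }
  if (!succ(1 - 1e-9)) {
    warning("no release frequency below 1 fixes the cargo")
    return(NA_real_)
  }
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (succ(mid)) hi <- mid else lo <- mid
  }
  hi
}

## --- disappearance of the interior equilibria (variant payloads) ------------

#' Payload cost at which the interior valley equilibria vanish
#'
#' For non-dominant payload schemes the interior stable and unstable
#' equilibria of the valley subsystem approach each other as the payload
#' grows and annihilate (become complex) at a critical payload, beyond
#' which only the wildtype state is stable.  Scans \code{s_p} upward on a
#' fixed grid and reports the smallest value with no interior symmetric
#' equilibrium, using the equilibria found at the previous step as warm
#' starts.
#'
#' @param payload_mode \code{"multiplicative"} or \code{"recessive"} (any
#'   mode accepted by [valley_params()]).
#' @param s_t Toxin load.
#' @param r Recombination fraction between cargo loci.
#' @param step Scan resolution in \code{s_p} (default 0.001).
#' @param s_p_max Upper end of the scan (default 0.99).
#' @return The smallest scanned \code{s_p} with no interior equilibrium
#'   (\code{NA} if equilibria persist throughout the scan).
#' @examples
#' \donttest{
#' payload_vanishing_point("multiplicative", s_t = 0.1)
#' }
#' @export
payload_vanishing_point <- function(payload_mode, s_t, r = 0.5,
                                    step = 0.001, s_p_max = 0.99) {
  prev <- NULL
  for (s_p in seq(step, s_p_max, by = step)) {
    model <- valley_model(valley_params(s_t = s_t, s_p = s_p, r = r,
                                        payload_mode = payload_mode))
    sols <- NULL
    if (!is.null(prev)) {
      # warm start: track the equilibria continuously in s_p
      warm <- do.call(rbind, prev)
      sols <- internal_symmetric_equilibria(model, starts = warm,
                                            include_grid = FALSE)
    }
    if (is.null(sols) || length(sols) == 0)
      sols <- internal_symmetric_equilibria(model)  # full grid confirms absence
    if (length(sols) == 0) return(s_p)
    prev <- sols
  }
  NA_real_
}
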