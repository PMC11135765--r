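## Discretized reaction-diffusion dynamics on a one-dimensional landscape.
##
## Space is a chain of cells; per diffusion substep a cell sends a fraction
## D * dt / d^2 of its population across each edge, with d the distance
## between the adjacent cell centres (truncated for very short edges so
## probabilities stay valid).  Each generation is split into 1/dt substeps;
## the local selection/drive dynamics are applied in each substep as the
## fractional interpolation x <- (1 - dt) x + dt f(x), with f the
## one-generation update, interleaved with diffusion.

#' Build a one-dimensional landscape
#'
#' A homogeneous landscape has cells every \code{dx} along a domain of
#' length \code{L}.  A heterogeneous landscape is built from a set of cell
#' boundaries (either supplied or drawn uniformly at random over the
#' domain); cells are the segments between consecutive boundaries and the
#' per-edge hop probability falls with the squared distance between cell
#' centres, so wide gaps act as dispersal barriers.
#'
#' @param L Domain length (default 200).
#' @param dx Cell spacing of a homogeneous landscape (default 0.25).
#' @param D Diffusion coefficient (default 0.2, spatial units squared per
#'   time unit).
#' @param dt Time substep as a fraction of a generation (default 0.1, i.e.
#'   ten substeps per generation).
#' @param boundaries Either \code{NULL} (homogeneous), an integer number of
#'   random boundaries to draw, or a numeric vector of boundary positions.
#' @param seed Optional seed used when drawing random boundaries.
#' @param max_hop Cap on the per-edge hop probability (default 0.45), which
#'   keeps probabilities valid on very short edges.
#' @return An object of class \code{"dq_landscape"} with cell positions
#'   \code{pos} and per-edge hop probabilities \code{mu}.
#' @examples
#' build_landscape()
#' build_landscape(boundaries = 400, seed = 1)
#' @export
build_landscape <- function(L = 200, dx = 0.25, D = 0.2, dt = 0.1,
                            boundaries = NULL, seed = NULL, max_hop = 0.45) {
  stopifnot(L > 0, dx > 0, D > 0, dt > 0, dt <= 1)
  if (is.null(boundaries)) {
    pos <- seq(dx / 2, L - dx / 2, by = dx)
    mu0 <- D * dt / dx^2
    if (mu0 > 0.5)
      stop(sprintf("stability condition violated: D*dt/dx^2 = %.3g > 1/2", mu0),
           call. = FALSE)
    mu <- rep(mu0, length(pos) - 1)
  } else {
    if (length(boundaries) == 1 && boundaries == round(boundaries) && boundaries > 1) {
      if (!is.null(seed)) {
        old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
        set.seed(seed)
        on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      }
      boundaries <- sort(stats::runif(boundaries, 0, L))
    }
    edges <- sort(unique(c(0, boundaries, L)))
    pos <- (edges[-1] + edges[-length(edges)]) / 2
    d <- diff(pos)
    mu <- pmin(D * dt / d^2, max_hop)
  }
  structure(list(pos = pos, mu = mu, N = length(pos), L = L, D = D, dt = dt),
            class = "dq_landscape")
}

#' @export
print.dq_landscape <- function(x, ...) {
  cat(sprintf("1-D landscape: %d cells over [0, %g], D = %g, dt = %g\n",
              x$N, x$L, x$D, x$dt))
  invisible(x)
}

diffuse_field <- function(X, mu) {
  N <- ncol(X)
  if (N == 1) return(X)
  right <- sweep(X[, -N, drop = FALSE], 2, mu, "*")
  left <- sweep(X[, -1, drop = FALSE], 2, mu, "*")
  Y <- X
  Y[, -N] <- Y[, -N] - right + left
  Y[, -1] <- Y[, -1] - left + right
  Y
}

#' Run reaction-diffusion dynamics
#'
#' Releases a gamete at frequency 1 in a central region and alternates
#' diffusion substeps with partial-generation local dynamics.  The payload
#' (C) allele-frequency field is recorded at regular intervals together
#' with the left and right positions where it crosses 0.5 (linearly
#' interpolated).
#'
#' @param model A [daisy_quorum_model()].
#' @param landscape A [build_landscape()] object.
#' @param Tgen Total time in generations.
#' @param release_halfwidth Half-width of the central release region
#'   (default 40 spatial units).
#' @param release_gamete Released gamete (default \code{"full"}; use
#'   \code{"CD"} for the drive-free valley construct).
#' @param record_every Recording interval in generations (default 10).
#' @return An object of class \code{"dq_field"}: list with \code{times},
#'   the payload field \code{payload} (cells by recordings), front
#'   positions \code{front_left} / \code{front_right}, the landscape, and
#'   the final state.
#' @examples
#' \donttest{
#' m <- daisy_quorum_model(drive_params(2, 0.9, 0.02), valley_params(0.9, 0.35))
#' land <- build_landscape(L = 60, dx = 0.5)
#' fld <- run_reaction_diffusion(m, land, Tgen = 20, release_halfwidth = 15)
#' }
#' @export
run_reaction_diffusion <- function(model, landscape, Tgen,
                                   release_halfwidth = 40,
                                   release_gamete = "full",
                                   record_every = 10) {
  N <- landscape$N; dt <- landscape$dt
  X <- matrix(0, model$arch$G, N)
  X[1, ] <- 1
  ctr <- landscape$L / 2
  sel <- abs(landscape$pos - ctr) <= release_halfwidth
  idx <- gamete_index(model$arch, release_gamete)
  X[, sel] <- 0; X[idx, sel] <- 1
  bC <- model$arch$bits[, model$arch$n_daisy + 1] == 1
  nsub <- round(Tgen / dt)
  rec_sub <- max(1, round(record_every / dt))
  nrec <- floor(nsub / rec_sub)
  payload <- matrix(NA_real_, N, nrec)
  times <- numeric(nrec)
  fl <- numeric(nrec); fr <- numeric(nrec)
  k_rec <- 0
  for (k in seq_len(nsub)) {
    X <- diffuse_field(X, landscape$mu)
    X <- (1 - dt) * X + dt * next_generation(model, X)
    if (k %% rec_sub == 0) {
      k_rec <- k_rec + 1
      pc <- colSums(X[bC, , drop = FALSE])
      payload[, k_rec] <- pc
      times[k_rec] <- k * dt
      fl[k_rec] <- front_cross(landscape$pos, pc, side = "left")
      fr[k_rec] <- front_cross(landscape$pos, pc, side = "right")
    }
  }
  structure(list(times = times, payload = payload,
                 front_left = fl, front_right = fr,
                 landscape = landscape, X = X),
            class = "dq_field")
}

## position where the payload frequency crosses 0.5, linearly interpolated
front_cross <- function(pos, pc, side = c("left", "right"), level = 0.5) {
  side <- match.arg(side)
  above <- pc >= level
  if (!any(above)) return(NA_real_)
  if (side == "left") {
    i <- min(which(above))
    if (i == 1) return(pos[1])
    j <- i - 1
  } else {
    i <- max(which(above))
    if (i == length(pos)) return(pos[length(pos)])
    j <- i + 1
  }
  # interpolate between the below-level neighbour j and the crossing cell i
  pos[j] + (pos[i] - pos[j]) * (level - pc[j]) / (pc[i] - pc[j])
}

#' Asymptotic wave speed from a reaction-diffusion field
#'
#' Fits the front position against time over the final fraction of the
#' record by least squares and reports the signed outward speed: positive
#' means the occupied region is expanding, negative that it is
#' contracting.  The left front is tracked by default (mirroring applies
#' by symmetry on homogeneous landscapes).
#'
#' @param field A \code{"dq_field"} from [run_reaction_diffusion()].
#' @param window Final fraction of recorded times used for the fit
#'   (default 0.25).
#' @param side Which front to track (default \code{"left"}).
#' @return A list of class \code{"dq_wavefront"}: \code{speed} (signed,
#'   spatial units per time unit; \code{NA} with \code{flagged = TRUE} if
#'   the front is absent from the fit window), the fitted window, and the
#'   front time series.
#' @export
asymptotic_wave_speed <- function(field, window = 0.25,
                                  side = c("left", "right")) {
  side <- match.arg(side)
  f <- if (side == "left") field$front_left else field$front_right
  t <- field$times
  ok <- !is.na(f)
  flagged <- FALSE; speed <- NA_real_
  if (sum(ok) >= 3) {
    t1 <- max(t); t0 <- t1 - window * (t1 - min(t))
    w <- ok & t >= t0
    if (sum(w) >= 3 && stats::sd(t[w]) > 0) {
      slope <- stats::coef(stats::lm(f[w] ~ t[w]))[[2]]
      # outward motion of the left front is towards smaller positions
      speed <- if (side == "left") -slope else slope
    } else flagged <- TRUE
  } else flagged <- TRUE
  structure(list(speed = speed, flagged = flagged, side = side,
                 window = window, times = t, front = f),
            class = "dq_wavefront")
}

#' @export
print.dq_wavefront <- function(x, ...) {
  if (x$flagged) cat("Wave front: absent or unusable in the fit window\n")
  else cat(sprintf("Asymptotic %s-front speed: %+.4g spatial units per time unit\n",
                   x$side, x$speed))
  invisible(x)
}

#' Asymptotic wave speed across landscape patchiness
#'
#' Runs the reaction-diffusion dynamics on homogeneous landscapes with
#' increasing cell spacing (from near-continuous to clumped stepping-stone
#' spacing) for each payload value and tabulates the asymptotic speed.
#'
#' @param model_for Function taking \code{s_p} and returning a
#'   [daisy_quorum_model()] (so the sweep can vary the payload).
#' @param step_sizes Vector of cell spacings.
#' @param s_p_values Vector of payload costs.
#' @param L,Tgen,release_halfwidth,D,dt Simulation geometry passed through
#'   to [build_landscape()] and [run_reaction_diffusion()].
#' @return Data frame with columns \code{step_size}, \code{s_p},
#'   \code{speed}.
#' @export
patchiness_sweep <- function(model_for, step_sizes, s_p_values,
                             L = 200, Tgen = 400, release_halfwidth = 40,
                             D = 0.2, dt = 0.1) {
  rows <- list()
  for (s_p in s_p_values) {
    model <- model_for(s_p)
    for (dx in step_sizes) {
      land <- build_landscape(L = L, dx = dx, D = D, dt = dt)
      fld <- run_reaction_diffusion(model, land, Tgen,
                                    release_halfwidth = release_halfwidth)
      ws <- asymptotic_wave_speed(fld)
      rows[[length(rows) + 1]] <-
        data.frame(step_size = dx, s_p = s_p, speed = ws$speed)
    }
  }
  do.call(rbind, rows)
}
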