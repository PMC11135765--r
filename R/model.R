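#' Build a daisy quorum drive model
#'
#' Precomputes the one-generation recursion operator for the full multilocus
#' system: the fitness of every diploid genotype and the gamete output
#' distribution of every genotype under homing conversion and recombination.
#' The life cycle is census at gametes, random union, diploid selection,
#' then meiosis with germline conversion and recombination; the next
#' generation's gamete frequencies are
#' \deqn{X'_g \propto \sum_{g_1, g_2} X_{g_1} X_{g_2} W(g_1, g_2) P(g \mid g_1, g_2),}
#' normalised by the mean fitness (the sum of the numerators).
#'
#' @param drive A [drive_params()] object, or \code{NULL} for the two-locus
#'   valley subsystem on its own.
#' @param valley A [valley_params()] object.
#' @param cross_rec Recombination fraction between the last driver locus and
#'   cargo locus C (0.5 by default: different chromosomes).
#' @param cargo_force Constant transmission-bias ("drive force")
#'   probability applied at heterozygous cargo loci irrespective of driver
#'   genotype; used for separatrix analysis under a fixed drive force.
#'   Leave 0 for the mechanistic model.
#' @return An object of class \code{"dq_model"}.
#' @examples
#' m <- daisy_quorum_model(drive_params(2, 0.95, 0.1), valley_params(0.9, 0.2))
#' m
#' @export
daisy_quorum_model <- function(drive, valley, cross_rec = 0.5, cargo_force = 0) {
  stopifnot(is.null(drive) || inherits(drive, "drive_params"),
            inherits(valley, "valley_params"))
  check_prob(cargo_force, "cargo_force")
  arch <- genome_architecture(drive, valley, cross_rec)
  s_d <- if (is.null(drive)) 0 else drive$s_d
  delta <- if (is.null(drive)) 0 else drive$delta
  W <- fitness_matrix(arch, s_d, valley)
  Tm <- transition_matrix(arch, delta, cargo_force)
  G <- arch$G
  structure(list(drive = drive, valley = valley, arch = arch,
                 delta = delta, cargo_force = cargo_force,
                 W = W, Tm = Tm,
                 i1 = rep(seq_len(G), times = G), i2 = rep(seq_len(G), each = G),
                 Wv = as.vector(W)),
            class = "dq_model")
}

#' Valley-only model with a fixed drive force
#'
#' Convenience constructor for the two-locus cargo subsystem, optionally
#' experiencing a constant transmission bias \code{drive_force} at
#' heterozygous cargo loci (the effective drive currently supplied by the
#' daisy chain).
#'
#' @param valley A [valley_params()] object.
#' @param drive_force Constant conversion probability at heterozygous cargo
#'   loci, in \code{[0, 1]}.
#' @return A \code{"dq_model"} over the 4 cargo gametes.
#' @examples
#' valley_model(valley_params(0.9, 0.2))
#' @export
valley_model <- function(valley, drive_force = 0) {
  daisy_quorum_model(NULL, valley, cargo_force = drive_force)
}

#' @export
print.dq_model <- function(x, ...) {
  cat(sprintf("Daisy quorum drive model: loci %s (%d gametes)\n",
              paste(x$arch$loci, collapse = "-"), x$arch$G))
  if (!is.null(x$drive)) print(x$drive)
  print(x$valley)
  if (x$cargo_force > 0)
    cat(sprintf("Constant cargo drive force: %g\n", x$cargo_force))
  invisible(x)
}

#' One generation of the multilocus recursion
#'
#' Applies diploid selection followed by meiosis with drive and
#' recombination to a gamete-frequency state (or to each column of a matrix
#' of states, e.g. one column per patch).
#'
#' @param model A [daisy_quorum_model()].
#' @param x Numeric vector of gamete frequencies (length \code{model$arch$G},
#'   summing to 1), or a matrix with one state per column.
#' @return Updated state of the same shape.
#' @examples
#' m <- valley_model(valley_params(0.9, 0.2))
#' next_generation(m, c(0.5, 0.05, 0.05, 0.4))
#' @export
next_generation <- function(model, x) {
  if (is.matrix(x)) {
    P <- x[model$i1, , drop = FALSE] * x[model$i2, , drop = FALSE] * model$Wv
    num <- crossprod(model$Tm, P)
    wbar <- colSums(num)
    if (any(wbar <= 0)) stop("degenerate state: mean fitness is zero", call. = FALSE)
    return(sweep(num, 2, wbar, "/"))
  }
  num <- crossprod(model$Tm, as.vector(outer(x, x) * model$W))
  wbar <- sum(num)
  if (wbar <= 0) stop("degenerate state: mean fitness is zero", call. = FALSE)
  out <- as.vector(num / wbar)
  names(out) <- model$arch$labels
  out
}

#' Initial gamete-frequency state for a release
#'
#' @param model A [daisy_quorum_model()].
#' @param release A [release_spec()], or a single number taken as the
#'   release frequency of the fully engineered gamete.
#' @return Named frequency vector.
#' @export
release_state <- function(model, release) {
  if (is.numeric(release)) release <- release_spec(release)
  x <- numeric(model$arch$G)
  idx <- gamete_index(model$arch, release$gamete)
  x[idx] <- release$f0
  x[1] <- x[1] + 1 - release$f0
  names(x) <- model$arch$labels
  x
}

#' Simulate a single well-mixed population
#'
#' Iterates the one-generation recursion from a release state and records
#' the full gamete-frequency trajectory.
#'
#' @param model A [daisy_quorum_model()].
#' @param release A [release_spec()] or a release frequency \code{f0} of the
#'   fully engineered gamete.
#' @param generations Number of generations to iterate (>= 1).
#' @return An object of class \code{"dq_trajectory"}: a matrix with one row
#'   per generation (row 1 = initial state) and one column per gamete, with
#'   helper accessors [allele_trajectory()] and
#'   \code{as.data.frame()}.
#' @examples
#' m <- daisy_quorum_model(drive_params(2, 0.95, 0.1), valley_params(0.9, 0.2))
#' tr <- simulate_population(m, 0.1, 50)
#' tail(allele_trajectory(tr), 3)
#' @export
simulate_population <- function(model, release, generations) {
  stopifnot(generations >= 1)
  x <- release_state(model, release)
  out <- matrix(0, generations + 1, model$arch$G,
                dimnames = list(NULL, model$arch$labels))
  out[1, ] <- x
  for (t in seq_len(generations)) {
    x <- next_generation(model, x)
    out[t + 1, ] <- x
  }
  structure(out, class = c("dq_trajectory", "matrix"), model = model)
}

#' Allele-frequency marginals of a trajectory or state
#'
#' @param x A \code{"dq_trajectory"} (from [simulate_population()]) or a
#'   gamete-frequency vector.
#' @param model Required when \code{x} is a plain vector.
#' @return For a trajectory, a data frame with columns \code{generation} and
#'   one column per locus; for a vector, a named vector of engineered-allele
#'   frequencies per locus.
#' @export
allele_trajectory <- function(x, model = attr(x, "model")) {
  bits <- model$arch$bits
  if (inherits(x, "dq_trajectory")) {
    af <- unclass(x) %*% bits
    data.frame(generation = 0:(nrow(x) - 1), af, check.names = FALSE)
  } else {
    drop(x %*% bits)
  }
}

#' @export
as.data.frame.dq_trajectory <- function(x, ...) {
  model <- attr(x, "model")
  m <- unclass(x)
  data.frame(generation = rep(0:(nrow(m) - 1), times = ncol(m)),
             gamete_label = rep(colnames(m), each = nrow(m)),
             frequency = as.vector(m))
}

#' Effective drive force acting on the cargo
#'
#' The drive force currently experienced by the cargo is the conversion
#' probability \code{delta} times the frequency of individuals carrying the
#' last driver allele (B) among individuals heterozygous at cargo locus C,
#' with genotypes formed by random union of the current gamete pool.
#' Returns 0 (by convention) when no C-heterozygotes exist.
#'
#' @param model A [daisy_quorum_model()] with at least one driver locus.
#' @param x Gamete-frequency state.
#' @return The effective drive force \code{delta_c(t)} in \code{[0, delta]}.
#' @export
effective_drive_force <- function(model, x) {
  arch <- model$arch
  stopifnot(arch$n_daisy >= 1)
  bC <- arch$bits[, arch$n_daisy + 1]
  bB <- arch$bits[, arch$n_daisy]
  pg <- outer(x, x)
  het <- outer(bC == 1, bC == 0) | outer(bC == 0, bC == 1)
  hasB <- outer(bB == 1, bB == 1) | outer(bB == 1, bB == 0) | outer(bB == 0, bB == 1)
  denom <- sum(pg[het])
  if (denom <= 0) return(0)
  model$delta * sum(pg[het & hasB]) / denom
}
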