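#' Daisy-chain drive parameters
#'
#' Parameters of the self-exhausting homing-drive component: a chain of
#' \code{n_daisy} driver loci in which each locus carries a guide RNA
#' targeting the wildtype allele at the next locus, the last driver targets
#' both cargo loci, and the first locus is not driven by anything.  Every
#' engineered daisy allele carries a fitness cost \code{s_d} (the drive
#' load), so the whole chain is eliminated by selection once it has done its
#' work.
#'
#' @param n_daisy Integer number of driver loci (>= 1).  The reference
#'   four-locus design has \code{n_daisy = 2} (loci A and B).
#' @param delta Homing conversion probability per targeted heterozygous
#'   locus, in \code{[0, 1]}: the probability that a wildtype allele at a
#'   targeted locus is cut and repaired off the engineered homologue in the
#'   germline.
#' @param s_d Drive load: multiplicative fitness cost per daisy allele
#'   carried, in \code{[0, 1]}.
#' @param R Recombination fraction between adjacent daisy loci, in
#'   \code{[0, 0.5]}.  Defaults to free recombination.
#'
#' @return An object of class \code{"drive_params"}.
#' @seealso [valley_params()], [daisy_quorum_model()]
#' @examples
#' drive_params(n_daisy = 2, delta = 0.95, s_d = 0.1)
#' @export
drive_params <- function(n_daisy = 2, delta = 0.95, s_d = 0.1, R = 0.5) {
  stopifnot(length(n_daisy) == 1, n_daisy >= 1, n_daisy == round(n_daisy))
  check_prob(delta, "delta")
  check_prob(s_d, "s_d")
  check_prob(R, "R", max = 0.5)
  structure(list(n_daisy = as.integer(n_daisy), delta = delta, s_d = s_d, R = R),
            class = "drive_params")
}

#' Fitness-valley (cargo) parameters
#'
#' Parameters of the two-locus toxin-antidote construct that forms the
#' high-threshold cargo.  Each engineered cargo allele (C or D) expresses a
#' toxin unless the engineered allele at the partner locus supplies the
#' antidote; individuals carrying engineered alleles at exactly one of the
#' two loci therefore pay the toxin load \code{s_t}.  Both alleles also carry
#' the payload, the population-modifying element, costing \code{s_p}.
#'
#' Payload expression (\code{payload_mode}):
#' \describe{
#'   \item{dominant}{fitness factor \code{1 - s_p} if at least one engineered
#'     cargo allele is carried (the default, and the only mode under which
#'     fixation of the construct is locally stable).}
#'   \item{multiplicative}{factor \code{(1 - s_p)^(k/4)} with \code{k} the
#'     number of engineered cargo alleles carried (0-4), so the fully
#'     engineered genotype again has fitness \code{1 - s_p}.}
#'   \item{recessive}{factor \code{(1 - s_p)^(h/2)} with \code{h} the number
#'     of cargo loci homozygous for the engineered allele.}
#' }
#'
#' Valley construction (\code{valley_mode}):
#' \describe{
#'   \item{toxin_antidote}{the reference two-locus two-toxin design described
#'     above.}
#'   \item{haploinsufficient_swap}{the valley is created by swapping two
#'     haploinsufficient genes between the loci: an individual needs two
#'     copies of (c or D) and two copies of (d or C); a deficient genotype
#'     pays \code{s_t}.  The payload is dominant.}
#'   \item{dhole_champer}{toxin-antidote as in the reference design but the
#'     payload is carried multiplicatively by allele C only, the fitness
#'     regime used in earlier two-locus fitness-valley studies.}
#'   \item{cargo_only}{no valley at all: a single payload locus C with no
#'     toxin (locus D is inert), the classic daisy-chain cargo used as a
#'     comparison case.}
#' }
#'
#' @param s_t Toxin load in \code{[0, 1]}.
#' @param s_p Payload cost in \code{[0, 1]}.
#' @param r Recombination fraction between the cargo loci C and D, in
#'   \code{[0, 0.5]}.
#' @param payload_mode One of \code{"dominant"}, \code{"multiplicative"},
#'   \code{"recessive"}.
#' @param valley_mode One of \code{"toxin_antidote"},
#'   \code{"haploinsufficient_swap"}, \code{"dhole_champer"},
#'   \code{"cargo_only"}.
#'
#' @return An object of class \code{"valley_params"}.
#' @examples
#' valley_params(s_t = 0.9, s_p = 0.2)
#' valley_params(s_t = 0.1, s_p = 0.15, payload_mode = "multiplicative")
#' @export
valley_params <- function(s_t = 0.9, s_p = 0.1, r = 0.5,
                          payload_mode = c("dominant", "multiplicative", "recessive"),
                          valley_mode = c("toxin_antidote", "haploinsufficient_swap",
                                          "dhole_champer", "cargo_only")) {
  check_prob(s_t, "s_t")
  check_prob(s_p, "s_p")
  check_prob(r, "r", max = 0.5)
  payload_mode <- match.arg(payload_mode)
  valley_mode <- match.arg(valley_mode)
  structure(list(s_t = s_t, s_p = s_p, r = r,
                 payload_mode = payload_mode, valley_mode = valley_mode),
            class = "valley_params")
}

#' Release specification
#'
#' A release introduces the fully engineered gamete (all loci engineered) at
#' frequency \code{f0} immediately before reproduction, with the remaining
#' frequency on the all-wildtype gamete.  Alternative release haplotypes
#' (e.g. the cargo-only haplotype \code{"CD"} without the drivers) can be
#' named by their gamete label.
#'
#' @param f0 Initial frequency of the released gamete, in \code{[0, 1]}.
#' @param gamete Label of the released gamete, or \code{"full"} for the
#'   all-engineered haplotype.
#' @return An object of class \code{"release_spec"}.
#' @examples
#' release_spec(0.1)
#' release_spec(0.4, gamete = "CD")
#' @export
release_spec <- function(f0, gamete = "full") {
  check_prob(f0, "f0")
  structure(list(f0 = f0, gamete = gamete), class = "release_spec")
}

check_prob <- function(x, name, min = 0, max = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max)
    stop(sprintf("'%s' must be a single number in [%g, %g]", name, min, max),
         call. = FALSE)
  invisible(x)
}

#' @export
print.drive_params <- function(x, ...) {
  cat(sprintf("Daisy-chain drive: %d driver locus/loci, delta = %g, s_d = %g, R = %g\n",
              x$n_daisy, x$delta, x$s_d, x$R))
  invisible(x)
}

#' @export
print.valley_params <- function(x, ...) {
  cat(sprintf("Fitness valley (%s, %s payload): s_t = %g, s_p = %g, r = %g\n",
              x$valley_mode, x$payload_mode, x$s_t, x$s_p, x$r))
  invisible(x)
}
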