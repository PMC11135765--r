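## Genome architecture and gamete enumeration.
##
## The genome has n_daisy driver loci followed by the two cargo loci C and D.
## A gamete is a bit vector over the loci (1 = engineered allele); gametes
## are enumerated in binary order with locus 1 as the most significant bit,
## so index 1 is the all-wildtype gamete and index 2^(n+2) the fully
## engineered one.  This order is stable and documented.

#' Genome architecture of a daisy quorum construct
#'
#' Describes the locus order (driver loci, then cargo loci C and D) and the
#' recombination fractions between adjacent loci: \code{R} between driver
#' loci, \code{cross_rec} between the last driver locus and C (0.5 by
#' default, i.e. different chromosomes), and \code{r} between C and D.
#'
#' @param drive A [drive_params()] object, or \code{NULL} for the cargo-only
#'   (two-locus valley) subsystem.
#' @param valley A [valley_params()] object (supplies \code{r}).
#' @param cross_rec Recombination fraction between the last driver locus and
#'   cargo locus C.
#' @return An object of class \code{"genome_architecture"} with locus names,
#'   adjacent recombination fractions, and the gamete bit matrix.
#' @examples
#' genome_architecture(drive_params(2, 0.95, 0.1), valley_params(0.9, 0.2))
#' @export
genome_architecture <- function(drive, valley, cross_rec = 0.5) {
  n <- if (is.null(drive)) 0L else drive$n_daisy
  check_prob(cross_rec, "cross_rec", max = 0.5)
  daisy_names <- if (n == 0) character(0)
                 else if (n == 1) "B"
                 else c(if (n > 2) paste0("A", seq_len(n - 1)) else "A", "B")
  loci <- c(daisy_names, "C", "D")
  L <- n + 2L
  cfrac <- c(if (n > 1) rep(drive$R, n - 1), if (n >= 1) cross_rec, valley$r)
  G <- 2L^L
  bits <- matrix(0L, G, L)
  for (k in seq_len(L)) bits[, k] <- as.integer(bitwAnd(0:(G - 1), bitwShiftL(1L, L - k)) > 0)
  colnames(bits) <- loci
  labels <- apply(bits, 1, function(b) paste0(ifelse(b == 1, loci, tolower(loci)), collapse = ""))
  structure(list(n_daisy = n, loci = loci, L = L, G = G, cfrac = cfrac,
                 bits = bits, labels = labels),
            class = "genome_architecture")
}

#' @export
print.genome_architecture <- function(x, ...) {
  cat(sprintf("Genome: %s (%d gametes); adjacent recombination: %s\n",
              paste(x$loci, collapse = "-"), x$G,
              paste(format(x$cfrac), collapse = ", ")))
  invisible(x)
}

## Resolve a gamete given as a label ("AbCd"), a bit vector, or "full"
gamete_index <- function(arch, gamete) {
  if (is.character(gamete)) {
    if (identical(gamete, "full")) return(arch$G)
    if (identical(gamete, "wildtype")) return(1L)
    # labels may omit absent loci, e.g. "CD" for the valley haplotype
    b <- integer(arch$L)
    for (k in seq_len(arch$L)) {
      if (grepl(arch$loci[k], gamete, fixed = TRUE)) b[k] <- 1L
    }
    full <- match(gamete, arch$labels)
    if (!is.na(full)) return(full)
    return(bits_to_index(b))
  }
  if (is.numeric(gamete) && length(gamete) == arch$L) return(bits_to_index(as.integer(gamete)))
  stop("cannot interpret gamete specification", call. = FALSE)
}

bits_to_index <- function(b) {
  L <- length(b)
  1L + sum(b * 2L^((L - 1):0))
}
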