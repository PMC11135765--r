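## Drive-aware meiosis.
##
## Conversion (homing) happens in the germline of the diploid, judged on the
## birth genotype: for every driver locus i at which the individual carries
## at least one engineered allele, the targeted locus (the next driver locus,
## or both cargo loci for the last driver) is converted wildtype ->
## engineered with probability delta, provided the target is heterozygous
## (a homozygous wildtype target has no engineered template for homologous
## repair; resistance alleles from end-joining are not modelled).
## Conversion events at distinct targets are independent.  Recombination
## follows conversion.  Judging conversion on the birth genotype is
## equivalent to a sequential cascade down the chain, because conversion
## only acts on heterozygous targets, where the driver allele of the next
## step is already present.

## Mendelian gamete distribution for diploid (b1, b2) with adjacent
## recombination fractions cfrac; forward recursion over loci keeping the
## probability of each gamete prefix on each parental chromosome.
mendel_dist <- function(b1, b2, cfrac) {
  L <- length(b1)
  # p1[g], p2[g]: probability of emitting prefix of gamete g while currently
  # copying from chromosome 1 resp. 2; grown locus by locus
  p1 <- if (b1[1] == 0) c(0.5, 0) else c(0, 0.5)
  p2 <- if (b2[1] == 0) c(0.5, 0) else c(0, 0.5)
  if (L > 1) for (k in 2:L) {
    cc <- cfrac[k - 1]
    stay1 <- p1 * (1 - cc) + p2 * cc
    stay2 <- p2 * (1 - cc) + p1 * cc
    n <- length(stay1)
    p1 <- numeric(2 * n); p2 <- numeric(2 * n)
    idx0 <- seq_len(n) * 2 - 1  # prefix extended by allele 0
    if (b1[k] == 0) p1[idx0] <- stay1 else p1[idx0 + 1] <- stay1
    if (b2[k] == 0) p2[idx0] <- stay2 else p2[idx0 + 1] <- stay2
  }
  # index construction yields binary order with locus 1 as the most
  # significant bit, matching the gamete enumeration
  p1 + p2
}

## Distribution over output gametes for one diploid, with conversion.
convert_and_segregate <- function(b1, b2, arch, delta, cargo_force = 0) {
  n <- arch$n_daisy
  targets <- integer(0); probs <- numeric(0)
  if (n >= 1) for (i in seq_len(n)) {
    if (b1[i] == 1 || b2[i] == 1) {
      tg <- if (i < n) i + 1L else c(n + 1L, n + 2L)
      for (t in tg) {
        if (b1[t] != b2[t]) { targets <- c(targets, t); probs <- c(probs, delta) }
      }
    }
  }
  if (cargo_force > 0) {
    for (t in (n + 1L):(n + 2L)) {
      if (b1[t] != b2[t] && !(t %in% targets)) {
        targets <- c(targets, t); probs <- c(probs, cargo_force)
      }
    }
  }
  nt <- length(targets)
  if (nt == 0) return(mendel_dist(b1, b2, arch$cfrac))
  out <- numeric(arch$G)
  for (s in 0:(2^nt - 1)) {
    sel <- as.logical(bitwAnd(s, 2^(seq_len(nt) - 1)))
    p <- prod(ifelse(sel, probs, 1 - probs))
    if (p == 0) next
    g1 <- b1; g2 <- b2
    g1[targets[sel]] <- 1L; g2[targets[sel]] <- 1L
    out <- out + p * mendel_dist(g1, g2, arch$cfrac)
  }
  out
}

#' Gamete output distribution of a diploid genotype
#'
#' Probability distribution over gametes produced by the diploid formed by
#' two gametes, under germline homing conversion (probability \code{delta}
#' per driven heterozygous target) followed by meiosis with recombination.
#' At \code{delta = 0} this reduces to Mendelian segregation with the
#' architecture's recombination fractions.
#'
#' @param g1,g2 Gametes (labels, bit vectors, \code{"full"} or
#'   \code{"wildtype"}).
#' @param model A [daisy_quorum_model()] object (its architecture and
#'   \code{delta} are used).
#' @return Named numeric vector of gamete probabilities (sums to 1).
#' @examples
#' m <- daisy_quorum_model(drive_params(2, 0.95, 0.1), valley_params(0.9, 0.2))
#' gamete_distribution("aBcd", "Abcd", m)
#' @export
gamete_distribution <- function(g1, g2, model) {
  arch <- model$arch
  i <- gamete_index(arch, g1); j <- gamete_index(arch, g2)
  d <- convert_and_segregate(arch$bits[i, ], arch$bits[j, ], arch,
                             model$delta, model$cargo_force)
  names(d) <- arch$labels
  d
}

## Full transition matrix: rows indexed by ordered genotype pairs
## (a + (b-1)*G), columns by output gamete.
transition_matrix <- function(arch, delta, cargo_force = 0) {
  G <- arch$G
  Tm <- matrix(0, G * G, G)
  for (a in seq_len(G)) for (b in a:G) {
    d <- convert_and_segregate(arch$bits[a, ], arch$bits[b, ], arch,
                               delta, cargo_force)
    Tm[(b - 1) * G + a, ] <- d
    Tm[(a - 1) * G + b, ] <- d
  }
  Tm
}
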