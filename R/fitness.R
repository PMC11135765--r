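## Genotype fitness: valley scheme at the cargo loci times the drive-load
## multiplier (1 - s_d)^j, with j the number of daisy alleles carried.

valley_fitness <- function(nC, nD, valley) {
  s_t <- valley$s_t; s_p <- valley$s_p
  hasC <- nC > 0; hasD <- nD > 0
  switch(valley$valley_mode,
    toxin_antidote = {
      wt <- if (xor(hasC, hasD)) 1 - s_t else 1
      wp <- switch(valley$payload_mode,
        dominant       = if (hasC || hasD) 1 - s_p else 1,
        multiplicative = (1 - s_p)^((nC + nD) / 4),
        recessive      = (1 - s_p)^(((nC == 2) + (nD == 2)) / 2))
      wt * wp
    },
    haploinsufficient_swap = {
      # functional copies: locus-C function from c or D, locus-D function from d or C
      x <- (2 - nC) + nD
      y <- (2 - nD) + nC
      wt <- if (x < 2 || y < 2) 1 - s_t else 1
      wp <- if (hasC || hasD) 1 - s_p else 1
      wt * wp
    },
    dhole_champer = {
      wt <- if (xor(hasC, hasD)) 1 - s_t else 1
      wt * (1 - s_p)^(nC / 2)
    },
    cargo_only = {
      switch(valley$payload_mode,
        dominant       = if (hasC) 1 - s_p else 1,
        multiplicative = (1 - s_p)^(nC / 2),
        recessive      = if (nC == 2) 1 - s_p else 1)
    },
    stop("unknown valley_mode: ", valley$valley_mode, call. = FALSE))
}

#' Fitness of a diploid genotype
#'
#' Relative fitness of the diploid formed by two gametes: the cargo-locus
#' valley fitness (toxin load expressed when engineered alleles are present
#' at exactly one cargo locus; payload expressed according to the payload
#' mode) multiplied by the drive-load factor \code{(1 - s_d)^j}, where
#' \code{j} is the total number of daisy-chain alleles carried.
#'
#' @param g1,g2 Gametes, as labels (e.g. \code{"ABCd"}), bit vectors, or
#'   \code{"full"} / \code{"wildtype"}.
#' @param drive A [drive_params()] object (or \code{NULL} for the valley
#'   subsystem alone).
#' @param valley A [valley_params()] object.
#' @return A single relative fitness in \code{[0, 1]}.
#' @examples
#' dr <- drive_params(2, 0.95, s_d = 0.1)
#' va <- valley_params(s_t = 0.9, s_p = 0.2)
#' genotype_fitness("abcd", "abcd", dr, va)  # wildtype: 1
#' genotype_fitness("abcd", "abcD", dr, va)  # unprotected toxin
#' genotype_fitness("ABCD", "ABCD", dr, va)  # full construct
#' @export
genotype_fitness <- function(g1, g2, drive, valley) {
  arch <- genome_architecture(drive, valley)
  i <- gamete_index(arch, g1); j <- gamete_index(arch, g2)
  pair_fitness(arch$bits[i, ], arch$bits[j, ], arch$n_daisy,
               if (is.null(drive)) 0 else drive$s_d, valley)
}

pair_fitness <- function(b1, b2, n_daisy, s_d, valley) {
  b1 <- unname(b1); b2 <- unname(b2)
  j <- if (n_daisy > 0) sum(b1[seq_len(n_daisy)]) + sum(b2[seq_len(n_daisy)]) else 0
  nC <- b1[n_daisy + 1] + b2[n_daisy + 1]
  nD <- b1[n_daisy + 2] + b2[n_daisy + 2]
  valley_fitness(nC, nD, valley) * (1 - s_d)^j
}

fitness_matrix <- function(arch, s_d, valley) {
  G <- arch$G
  W <- matrix(0, G, G)
  for (a in seq_len(G)) for (b in a:G) {
    W[a, b] <- W[b, a] <- pair_fitness(arch$bits[a, ], arch$bits[b, ],
                                       arch$n_daisy, s_d, valley)
  }
  dimnames(W) <- list(arch$labels, arch$labels)
  W
}
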