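## Hand-coded one-generation recursions for the two 2-locus subsystems,
## written term by term from the published mating tables, independent of the
## package's generic engine.  States are c(ab, aB, Ab, AB) for the daisy
## subsystem and c(cd, cD, Cd, CD) for the valley subsystem.

eq1_daisy_oracle <- function(x, s_d, delta, R) {
  ab <- x[1]; aB <- x[2]; Ab <- x[3]; AB <- x[4]
  q <- 1 - s_d
  num <- c(
    ab^2 +
      aB * Ab * q^2 * (1 - delta) * R +
      ab * aB * q +
      ab * Ab * q +
      ab * AB * q^2 * (1 - delta) * (1 - R),
    aB^2 * q^2 +
      aB * Ab * q^2 * (1 - R * (1 - delta)) +
      aB * AB * q^3 +
      ab * aB * q +
      ab * AB * q^2 * (R + delta * (1 - R)),
    Ab^2 * q^2 +
      aB * Ab * q^2 * (1 - delta) * (1 - R) +
      Ab * AB * q^3 * (1 - delta) +
      ab * Ab * q +
      ab * AB * q^2 * (1 - delta) * R,
    AB^2 * q^4 +
      ab * AB * q^2 * (1 - R * (1 - delta)) +
      Ab * AB * q^3 * (1 + delta) +
      aB * Ab * q^2 * (R + delta * (1 - R)) +
      aB * AB * q^3
  )
  num / sum(num)
}

eq2_valley_oracle <- function(x, s_t, s_p, r) {
  cd <- x[1]; cD <- x[2]; Cd <- x[3]; CD <- x[4]
  W_cd_cd <- 1
  W_tox <- (1 - s_t) * (1 - s_p)
  W_pay <- 1 - s_p
  dis <- cd * CD * W_pay - cD * Cd * W_pay
  num <- c(
    cd^2 * W_cd_cd + cd * cD * W_tox + cd * Cd * W_tox + cd * CD * W_pay - r * dis,
    cD^2 * W_tox + cd * cD * W_tox + cD * CD * W_pay + cD * Cd * W_pay + r * dis,
    Cd^2 * W_tox + cd * Cd * W_tox + Cd * CD * W_pay + cD * Cd * W_pay + r * dis,
    CD^2 * W_pay + cD * CD * W_pay + Cd * CD * W_pay + cd * CD * W_pay - r * dis
  )
  num / sum(num)
}

## Map a 4-state daisy-subsystem vector onto the 16-gamete state of the
## n_daisy = 2 model (cargo loci fixed wildtype) and back.
daisy_embed <- function(x) {
  X <- numeric(16)
  X[c(1, 5, 9, 13)] <- x  # abcd, aBcd, Abcd, ABcd
  X
}
daisy_extract <- function(X) X[c(1, 5, 9, 13)]

random_simplex <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}
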