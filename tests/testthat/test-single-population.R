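fig3_model <- function(n = 2) {
  daisy_quorum_model(drive_params(n, delta = 0.95, s_d = 0.1, R = 0.5),
                     valley_params(s_t = 0.9, s_p = 0.2, r = 0.5))
}

test_that("a sufficient release fixes the cargo while the drive exhausts", {
  m <- fig3_model()
  af <- allele_trajectory(simulate_population(m, 0.1, 300))
  last <- af[nrow(af), ]
  expect_gt(last$C, 0.99)
  expect_gt(last$D, 0.99)
  expect_lt(last$A, 1e-4)
  expect_lt(last$B, 1e-4)
})

test_that("an insufficient release loses the construct", {
  m <- fig3_model()
  af <- allele_trajectory(simulate_population(m, 0.03, 300))
  expect_lt(af$C[nrow(af)], 0.01)
})

test_that("daisy alleles are always eliminated, win or lose", {
  m <- daisy_quorum_model(drive_params(2, 0.9, s_d = 0.02),
                          valley_params(0.9, 0.1))
  # from a moderate release the chain exhausts within ~1500 generations;
  # from a massive release B transiently almost fixes (the load is then
  # carried by everyone and selection against it nearly stalls), and the
  # return of wildtype alleles takes correspondingly longer
  for (case in list(c(0.05, 1500), c(0.5, 4000))) {
    af <- allele_trajectory(simulate_population(m, case[1], case[2]))
    expect_lt(af$A[nrow(af)], 1e-3)
    expect_lt(af$B[nrow(af)], 1e-3)
  }
})

test_that("trajectories expose tidy gamete and allele tables", {
  m <- fig3_model()
  tr <- simulate_population(m, 0.1, 10)
  df <- as.data.frame(tr)
  expect_named(df, c("generation", "gamete_label", "frequency"))
  expect_equal(nrow(df), 11 * 16)
  af <- allele_trajectory(tr)
  expect_named(af, c("generation", "A", "B", "C", "D"))
  expect_equal(af$generation, 0:10)
})

test_that("effective drive force follows the driver frequency among cargo heterozygotes", {
  m <- fig3_model()
  # right after a full release every Cc heterozygote carries B
  expect_equal(effective_drive_force(m, release_state(m, 0.1)), 0.95)
  # no driver alleles anywhere
  x <- numeric(16); x[1] <- 0.7
  x[gamete_index(m$arch, "abCD")] <- 0.3
  expect_equal(effective_drive_force(m, x), 0)
  # no cargo heterozygotes at all: returns 0 by convention
  expect_equal(effective_drive_force(m, c(1, numeric(15))), 0)
  # half of the Cc heterozygotes carry B
  x <- numeric(16)
  x[gamete_index(m$arch, "abCd")] <- 0.2
  x[gamete_index(m$arch, "abcd")] <- 0.4
  x[gamete_index(m$arch, "aBcd")] <- 0.4
  expect_equal(effective_drive_force(m, x), 0.95 / 2)
})

test_that("invasion eigenvalues match their closed forms and the linearised recursion", {
  # neutral boundary
  inv <- invasion_eigenvalues(0, valley_params(s_t = 0, s_p = 0))
  expect_equal(inv$lambda1, 1)
  # lambda_L agrees with the dominant eigenvalue of the numerically
  # linearised valley recursion under a constant drive force
  for (case in list(c(0.5, 0.7, 0.1, 0.5), c(0.3, 0.2, 0.3, 0.3),
                    c(0.95, 0.9, 0.2, 0.5))) {
    dc <- case[1]
    va <- valley_params(s_t = case[2], s_p = case[3], r = case[4])
    inv <- invasion_eigenvalues(dc, va)
    model <- valley_model(va, drive_force = dc)
    J <- daisyquorum:::valley_jacobian(model, c(1, 0, 0, 0))
    # restrict to the invading directions (cD, Cd, CD)
    lam_num <- max(Mod(eigen(J[2:3, 2:3], only.values = TRUE)$values))
    lam_num <- max(lam_num, Re(eigen(J, only.values = TRUE)$values))
    expect_equal(inv$lambdaL, lam_num, tolerance = 1e-6)
  }
})

test_that("lambda_L increases with the drive force", {
  va <- valley_params(s_t = 0.9, s_p = 0.2)
  lams <- vapply(seq(0, 1, by = 0.1),
                 function(dc) invasion_eigenvalues(dc, va)$lambdaL, numeric(1))
  expect_true(all(diff(lams) > 0))
})

test_that("the critical drive force hits its closed-form landmarks", {
  # a dominant payload halving fitness can never invade: delta_c* = 1 exactly
  expect_identical(critical_drive_force(valley_params(s_t = 0, s_p = 0.5)), 1)
  # s_t = 0, s_p = 0.2: the single-allele route gives 1/(1 - 0.2) - 1 = 0.25
  # and is the minimiser (the haplotype route root is larger)
  va <- valley_params(s_t = 0, s_p = 0.2)
  expect_equal(critical_drive_force(va), 0.25)
  expect_lt((1 - 0.2) * (1 + 0.25)^2 / 2, 1)
  # at the critical force the leading eigenvalue is exactly 1
  va2 <- valley_params(s_t = 0.9, s_p = 0.2)
  dc <- critical_drive_force(va2)
  expect_equal(invasion_eigenvalues(dc, va2)$lambdaL, 1, tolerance = 1e-12)
})

test_that("midpoint toxin load places the unstable equilibrium at one half", {
  st <- midpoint_toxin_load(0.2, 0.5)
  eq <- find_equilibria(valley_params(s_t = st, s_p = 0.2))
  internal <- eq[eq$X_cd > 1e-6 & eq$X_CD > 1e-6 & eq$X_cd < 1, ]
  expect_equal(internal$p_C, 0.5, tolerance = 1e-6)
  # monotone increasing in s_p on the valid domain, vanishing as s_p -> 0
  sps <- seq(0.02, 0.3, by = 0.02)
  sts <- vapply(sps, midpoint_toxin_load, numeric(1), r = 0.5)
  expect_true(all(diff(sts) > 0))
  expect_lt(midpoint_toxin_load(1e-4, 0.5), 1e-3)
  # outside the domain the denominator closes
  expect_error(midpoint_toxin_load(0.5, 0.25), "midpoint")
})

test_that("equilibria of the dominant-payload valley match the known structure", {
  eq <- find_equilibria(valley_params(s_t = 0.9, s_p = 0.2))
  expect_equal(nrow(eq), 3)
  expect_equal(eq$class[eq$X_cd == 1], "stable")
  expect_equal(eq$class[eq$X_CD == 1], "stable")
  internal <- eq[eq$X_cd < 1 & eq$X_CD < 1, ]
  expect_equal(internal$class, "unstable")
  expect_equal(internal$p_C, 0.3627, tolerance = 1e-3)
  expect_equal(internal$X_cD, internal$X_Cd)
})

test_that("multiplicative payload above its critical value leaves only the wildtype stable", {
  eq <- find_equilibria(valley_params(s_t = 0.1, s_p = 0.15,
                                      payload_mode = "multiplicative"))
  expect_equal(nrow(eq), 2)  # no interior equilibrium survives
  expect_equal(eq$class[eq$X_cd == 1], "stable")
  expect_equal(eq$class[eq$X_CD == 1], "unstable")
})

test_that("without selection every linkage-equilibrium state is a marginal fixed point", {
  eq <- find_equilibria(valley_params(s_t = 0, s_p = 0))
  expect_true(all(eq$class == "marginal"))
  # the interior members found indeed have zero linkage disequilibrium
  internal <- eq[eq$X_cd < 1 & eq$X_CD < 1, ]
  D <- internal$X_cd * internal$X_CD - internal$X_cD * internal$X_Cd
  expect_equal(D, rep(0, nrow(internal)), tolerance = 1e-8)
})

test_that("separatrix threshold matches the valley basin and responds to drive force", {
  va <- valley_params(s_t = 0.9, s_p = 0.2)
  thr <- separatrix_threshold(va, tol = 1e-3)
  expect_gt(thr, 0.36)
  expect_lt(thr, 0.45)
  # the release-threshold bisection of the drive-free model reduces to it
  thr2 <- release_threshold(valley_model(va), tol = 1e-3)
  expect_equal(thr, thr2, tolerance = 2e-3)
  # a strong constant drive force removes the threshold almost entirely
  thr_driven <- separatrix_threshold(va, drive_force = 0.99, tol = 1e-3)
  expect_lt(thr_driven, 0.01)
  # bisection is stable under tolerance refinement
  expect_equal(separatrix_threshold(va, tol = 2e-4), thr, tolerance = 2e-3)
})

test_that("a payload too strong to ever spread is flagged as having no basin", {
  # multiplicative payload above its critical value: only the wildtype
  # state is stable, so no introduction frequency reaches a high basin
  va <- valley_params(s_t = 0.1, s_p = 0.3, payload_mode = "multiplicative")
  expect_warning(out <- separatrix_threshold(va, generations = 200),
                 "no introduction frequency")
  expect_true(is.na(out))
})

test_that("release thresholds bracket the printed single-population contrasts", {
  thr2 <- release_threshold(fig3_model(2))
  expect_gt(thr2, 0.03)
  expect_lte(thr2, 0.1)
})

test_that("longer daisy chains push the last driver allele higher", {
  maxB <- vapply(1:3, function(n) {
    m <- daisy_quorum_model(drive_params(n, delta = 1, s_d = 0.05, R = 0.5),
                            valley_params(s_t = 0, s_p = 0))
    af <- allele_trajectory(simulate_population(m, 0.01, 250))
    max(af$B)
  }, numeric(1))
  expect_true(all(diff(maxB) > 0))
})

test_that("valley crossing is payload-limited but insensitive to the toxin load", {
  final_C <- function(s_t, s_p) {
    m <- daisy_quorum_model(drive_params(2, 0.95, 0.1),
                            valley_params(s_t, s_p))
    af <- allele_trajectory(simulate_population(m, 0.05, 100))
    af$C[nrow(af)]
  }
  for (s_t in c(0.5, 0.9)) {
    fin <- vapply(c(0.05, 0.1, 0.2, 0.35), final_C, numeric(1), s_t = s_t)
    expect_true(all(diff(fin) < 1e-9))  # non-increasing in s_p
    expect_gt(fin[1], 0.9)              # mild payloads cross and fix
    expect_lt(fin[4], 0.01)             # heavy payloads fail
  }
  # establishment pattern is the same at either toxin load
  expect_equal(final_C(0.5, 0.1) > 0.5, final_C(0.9, 0.1) > 0.5)
})
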