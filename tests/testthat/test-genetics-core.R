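test_that("genotype fitness reproduces the valley fitness table with drive load", {
  dr <- drive_params(2, 0.95, s_d = 0.1)
  va <- valley_params(s_t = 0.9, s_p = 0.1)
  # wildtype and single-toxin entries
  expect_equal(genotype_fitness("abcd", "abcd", dr, va), 1)
  expect_equal(genotype_fitness("abcd", "abcD", dr, va), 0.1 * 0.9)
  expect_equal(genotype_fitness("abcd", "abCd", dr, va), 0.1 * 0.9)
  # both engineered alleles present: toxin suppressed, payload only
  expect_equal(genotype_fitness("abcd", "abCD", dr, va), 0.9)
  expect_equal(genotype_fitness("abCd", "abcD", dr, va), 0.9)
  # full construct: payload times drive load for 4 daisy alleles
  va2 <- valley_params(s_t = 0.9, s_p = 0.2)
  expect_equal(genotype_fitness("ABCD", "ABCD", dr, va2), 0.9^4 * 0.8)
  # drive load exponent counts daisy alleles across both haplotypes
  expect_equal(genotype_fitness("ABcd", "Abcd", dr, va), 0.9^3)
})

test_that("fitness is symmetric in the two gametes for every scheme", {
  dr <- drive_params(1, 0.9, s_d = 0.07)
  for (vm in c("toxin_antidote", "haploinsufficient_swap", "dhole_champer",
               "cargo_only")) {
    for (pm in c("dominant", "multiplicative", "recessive")) {
      va <- valley_params(s_t = 0.6, s_p = 0.3, payload_mode = pm,
                          valley_mode = vm)
      m <- daisy_quorum_model(dr, va)
      expect_equal(m$W, t(m$W), info = paste(vm, pm))
      expect_true(all(m$W >= 0 & m$W <= 1))
    }
  }
})

test_that("variant payload schemes keep the fully engineered genotype at 1 - s_p", {
  for (pm in c("dominant", "multiplicative", "recessive")) {
    va <- valley_params(s_t = 0.4, s_p = 0.25, payload_mode = pm)
    expect_equal(genotype_fitness("CD", "CD", NULL, va), 0.75, info = pm)
  }
  # multiplicative: a double heterozygote expresses less payload than the
  # homozygote, and escapes the toxin
  va <- valley_params(s_t = 0.4, s_p = 0.25, payload_mode = "multiplicative")
  expect_gt(genotype_fitness("Cd", "cD", NULL, va),
            genotype_fitness("CD", "CD", NULL, va))
  # recessive: double heterozygote expresses no payload at all
  va <- valley_params(s_t = 0.4, s_p = 0.25, payload_mode = "recessive")
  expect_equal(genotype_fitness("Cd", "cD", NULL, va), 1)
})

test_that("haploinsufficient swap penalises unbalanced genotypes only", {
  va <- valley_params(s_t = 0.5, s_p = 0.2,
                      valley_mode = "haploinsufficient_swap")
  expect_equal(genotype_fitness("cd", "cd", NULL, va), 1)
  expect_equal(genotype_fitness("CD", "CD", NULL, va), 0.8)      # balanced swap
  expect_equal(genotype_fitness("CD", "cd", NULL, va), 0.8)      # balanced
  expect_equal(genotype_fitness("Cd", "cd", NULL, va), 0.5 * 0.8) # deficient
  expect_equal(genotype_fitness("Cd", "Cd", NULL, va), 0.5 * 0.8) # deficient
})

test_that("invalid parameters and modes are rejected", {
  expect_error(drive_params(0, 0.9, 0.1), "n_daisy")
  expect_error(drive_params(2, 1.2, 0.1), "delta")
  expect_error(valley_params(s_t = -0.1, s_p = 0.2), "s_t")
  expect_error(valley_params(0.9, 0.2, payload_mode = "epistatic"))
  expect_error(valley_params(0.9, 0.2, valley_mode = "nonsense"))
})

test_that("gamete distributions reproduce the daisy conversion coefficients", {
  m <- daisy_quorum_model(drive_params(2, delta = 0.95, s_d = 0.1, R = 0.3),
                          valley_params(0.9, 0.2))
  d <- gamete_distribution("aBcd", "Abcd", m)
  delta <- 0.95; R <- 0.3
  expect_equal(d[["ABcd"]], (R + delta * (1 - R)) / 2)
  expect_equal(d[["abcd"]], (1 - delta) * R / 2)
  expect_equal(d[["aBcd"]], (1 - R * (1 - delta)) / 2)
  expect_equal(d[["Abcd"]], (1 - delta) * (1 - R) / 2)
  expect_equal(sum(d), 1)
})

test_that("cargo conversion acts only with a driver present and independently at C and D", {
  m <- daisy_quorum_model(drive_params(2, delta = 0.8, s_d = 0, R = 0.5),
                          valley_params(0.9, 0.2, r = 0.2))
  # no driver anywhere: pure Mendelian recombination between C and D
  d <- gamete_distribution("abCd", "abcD", m)
  expect_equal(d[["abCD"]], 0.2 / 2)
  expect_equal(d[["abcd"]], 0.2 / 2)
  # driver B present, both cargo loci heterozygous: independent conversions
  d <- gamete_distribution("aBCD", "abcd", m)
  # P(gamete carries C) = delta + (1 - delta)/2 marginally
  pc <- sum(d[grepl("C", names(d), fixed = TRUE)])
  expect_equal(pc, 0.8 + 0.2 / 2)
  pd <- sum(d[grepl("D", names(d), fixed = TRUE)])
  expect_equal(pd, 0.8 + 0.2 / 2)
  # a homozygous wildtype target has no template: no conversion at D
  d <- gamete_distribution("aBCd", "abcd", m)
  expect_equal(sum(d[grepl("D", names(d), fixed = TRUE)]), 0)
})

test_that("delta = 0 with free recombination is uniform over heterozygous resolutions", {
  m <- daisy_quorum_model(drive_params(2, delta = 0, s_d = 0, R = 0.5),
                          valley_params(0, 0, r = 0.5))
  d <- gamete_distribution("ABCD", "abcd", m)
  expect_equal(unname(d), rep(1 / 16, 16))
  d <- gamete_distribution("ABcd", "abcd", m)  # 2 heterozygous loci
  expect_equal(sort(unique(round(d, 12))), c(0, 0.25))
})

test_that("every genotype's gamete distribution sums to one", {
  set.seed(7)
  for (rep in 1:5) {
    m <- daisy_quorum_model(
      drive_params(sample(1:3, 1), runif(1), runif(1, 0, 0.5), runif(1, 0, 0.5)),
      valley_params(runif(1), runif(1, 0, 0.8), runif(1, 0, 0.5)))
    expect_equal(rowSums(m$Tm), rep(1, nrow(m$Tm)), tolerance = 1e-12)
  }
})

test_that("the recursion conserves frequencies and fixes the wildtype state", {
  m <- daisy_quorum_model(drive_params(2, 0.95, 0.1), valley_params(0.9, 0.2))
  wt <- c(1, numeric(15))
  expect_equal(unname(next_generation(m, wt)), wt)
  set.seed(11)
  x <- random_simplex(16)
  for (t in 1:50) {
    x <- next_generation(m, x)
    expect_lt(abs(sum(x) - 1), 1e-12)
    expect_true(all(x >= 0))
  }
})

test_that("an all-lethal population raises a degenerate-state error", {
  m <- daisy_quorum_model(NULL, valley_params(s_t = 1, s_p = 1))
  # only single-toxin genotypes present: every genotype is lethal
  expect_error(next_generation(m, c(0, 0.5, 0.5, 0)), "degenerate")
})

test_that("the generic engine reproduces the hand-coded daisy recursion", {
  set.seed(101)
  for (rep in 1:40) {
    s_d <- runif(1, 0, 0.4); delta <- runif(1); R <- runif(1, 0, 0.5)
    m <- daisy_quorum_model(drive_params(2, delta, s_d, R),
                            valley_params(runif(1), runif(1, 0, 0.8)))
    x <- random_simplex(4)
    got <- unname(daisy_extract(next_generation(m, daisy_embed(x))))
    expect_equal(got, eq1_daisy_oracle(x, s_d, delta, R), tolerance = 1e-12)
  }
})

test_that("the generic engine reproduces the hand-coded valley recursion", {
  set.seed(202)
  for (rep in 1:40) {
    s_t <- runif(1); s_p <- runif(1, 0, 0.8); r <- runif(1, 0, 0.5)
    m <- valley_model(valley_params(s_t, s_p, r))
    x <- random_simplex(4)
    expect_equal(unname(next_generation(m, x)),
                 eq2_valley_oracle(x, s_t, s_p, r), tolerance = 1e-12)
  }
})

test_that("neutral parameters leave allele frequencies constant", {
  m <- daisy_quorum_model(drive_params(2, delta = 0, s_d = 0),
                          valley_params(s_t = 0, s_p = 0))
  set.seed(5)
  x <- random_simplex(16)
  af0 <- allele_trajectory(x, m)
  for (t in 1:20) x <- next_generation(m, x)
  expect_equal(allele_trajectory(x, m), af0, tolerance = 1e-12)
})

test_that("a symmetric valley start stays symmetric", {
  m <- valley_model(valley_params(0.7, 0.15))
  x <- c(0.5, 0.15, 0.15, 0.2)
  for (t in 1:100) {
    x <- next_generation(m, x)
    expect_equal(x[["cD"]], x[["Cd"]], tolerance = 1e-14)
  }
})
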