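test_that("founder dosages follow the hexaploid binomial model", {
  # boundary frequency: everything fixed at dosage 6
  Z1 <- simulate_founders(5, 10, p = rep(1, 10), seed = 1)
  expect_true(all(Z1 == 6))
  # p = 0.5: mean dosage approaches 3 (Binomial(6, 0.5))
  Z2 <- simulate_founders(2000, 50, p = rep(0.5, 50), seed = 2)
  expect_equal(mean(Z2), 3, tolerance = 0.01)
  expect_true(all(Z2 >= 0 & Z2 <= 6))
  # pool sizes and labels preserved (two pools of 19 and 20)
  Z3 <- simulate_founders(39, 5, pools = c(A = 19, B = 20), seed = 3)
  expect_equal(as.vector(table(attr(Z3, "pool"))[c("A", "B")]), c(19L, 20L))
  expect_equal(rownames(Z3)[1], "A1")
})

test_that("polysomic meiosis: offspring dosages match the hypergeometric law", {
  fnd <- matrix(c(6, 6, 0, 0, 3, 3), nrow = 3, ncol = 2, byrow = TRUE,
                dimnames = list(c("Phi", "Plo", "Pmid"), c("L1", "L2")))
  attr(fnd, "pool") <- c(Phi = "A", Plo = "A", Pmid = "A")
  # fixed-allele parents
  off <- simulate_partial_diallel(fnd, data.frame(parent1 = "Phi",
                                                  parent2 = "Phi", n = 20),
                                  seed = 1)
  expect_true(all(off$dosage == 6))
  off0 <- simulate_partial_diallel(fnd, data.frame(parent1 = "Plo",
                                                   parent2 = "Plo", n = 20),
                                   seed = 2)
  expect_true(all(off0$dosage == 0))
  # gamete mean is half the parental dosage (hypergeometric mean 3z/6)
  offm <- simulate_partial_diallel(fnd, data.frame(parent1 = "Pmid",
                                                   parent2 = "Pmid",
                                                   n = 4000), seed = 3)
  expect_equal(mean(offm$dosage), 3, tolerance = 0.03)
  # pedigree records both parents
  expect_equal(offm$pedigree$parent1[4], "Pmid")
  expect_error(simulate_partial_diallel(
    fnd, data.frame(parent1 = "nope", parent2 = "Phi", n = 1)), "unknown")
})

test_that("genetic effects reproduce the factor-analytic covariance", {
  pop <- small_population(U = 400, seed = 7)
  dos <- pop$cross$dosage
  # loadings (1, 2) with unit specific variances: variance ratio 5/2
  reps <- 40
  v1 <- v2 <- cor12 <- numeric(reps)
  for (r in seq_len(reps)) {
    eff <- simulate_genetic_effects(dos, Lambda = matrix(c(1, 2), 2, 1),
                                    Psi = c(1, 1), sigma2_na = c(0, 0),
                                    varrho = 0, seed = 100 + r)
    v1[r] <- var(eff$a[, 1]); v2[r] <- var(eff$a[, 2])
  }
  expect_equal(mean(v2) / mean(v1), 5 / 2, tolerance = 0.15)
  # rank-1 common factor with no specific variance: correlation 1
  eff1 <- simulate_genetic_effects(dos, Lambda = matrix(1, 3, 1),
                                   Psi = rep(0, 3), sigma2_na = rep(0, 3),
                                   varrho = 0, seed = 5)
  expect_equal(cor(eff1$a[, 1], eff1$a[, 2]), 1, tolerance = 1e-10)
  # varrho = 0: non-additive values uncorrelated across environments
  nas <- sapply(1:30, function(r) {
    e <- simulate_genetic_effects(dos, Lambda = matrix(0, 2, 1),
                                  Psi = c(0, 0), sigma2_na = c(1, 1),
                                  varrho = 0, seed = 200 + r)
    cor(e$na[, 1], e$na[, 2])
  })
  expect_lt(abs(mean(nas)), 0.06)
})

test_that("spatial residuals carry the configured AR1 autocorrelations", {
  cfg0 <- demo_config(rho_r = 0, rho_c = 0, sigma2_rg = 0, sigma2_cg = 0,
                      sigma2_b = 0, missing_rate = 0)
  lay <- augmented_layout(12, 10, 6, 5, checks = "CK1",
                          parent_reps = c(P1 = 8),
                          tests = paste0("T", 1:108), seed = 1)
  lag1 <- function(cfg, m, seed) {
    ph <- simulate_phenotypes(lay, m, list(a = matrix(0, 1, cfg$M,
                                                      dimnames = list("x")),
                                           na = matrix(0, 1, cfg$M,
                                                       dimnames = list("x"))),
                              c(CK1 = 0), cfg, seed = seed)
    E <- matrix(ph$spatial[order(ph$col, ph$row)], 12, 10)
    cor(as.vector(E[-12, ]), as.vector(E[-1, ]))
  }
  r0 <- mean(sapply(1:30, function(s) lag1(cfg0, 1, s)))
  expect_lt(abs(r0), 0.05)
  cfg6 <- demo_config(rho_r = 0.6, rho_c = 0, sigma2_rg = 0, sigma2_cg = 0,
                      sigma2_b = 0, missing_rate = 0)
  r6 <- mean(sapply(1:30, function(s) lag1(cfg6, 1, s)))
  expect_equal(r6, 0.6, tolerance = 0.07)
})

test_that("phenotypes decompose exactly into their stored components", {
  sim <- simulate_met(demo_config(seed = 17))
  with(sim$plots, expect_lt(
    max(abs(y - (mu + fixed_trt + a + na + rg_eff + cg_eff + b_eff +
                   spatial))), 1e-10))
  # all-zero configuration gives identically zero phenotypes
  cfg0 <- demo_config(Lambda = matrix(0, 3, 2), Psi = rep(0, 3),
                      sigma2_na = rep(0, 3), sigma2_e = rep(0, 3),
                      sigma2_rg = 0, sigma2_cg = 0, sigma2_b = 0,
                      env_means = rep(0, 3), sigma2_check = 0,
                      missing_rate = 0)
  sim0 <- simulate_met(cfg0)
  expect_lt(max(abs(sim0$plots$y)), 1e-12)
})

test_that("the simulated dataset is reproducible and well-formed", {
  cfg <- demo_config(seed = 23)
  s1 <- simulate_met(cfg)
  s2 <- simulate_met(cfg)
  expect_identical(s1$plots$y, s2$plots$y)
  expect_identical(s1$dosage, s2$dosage)
  # missing plots removed at roughly the configured rate
  expect_lt(abs(mean(s1$plots_full$missing) - cfg$missing_rate), 0.03)
  # pool labels: checks form their own pool
  expect_setequal(unique(s1$plots$pool), c("A", "B", "C"))
  # CSV round trip
  dir <- file.path(tempdir(), "met_io")
  write_met(s1, dir)
  pl <- read_plots(file.path(dir, "plots.csv"))
  expect_equal(nrow(pl), nrow(s1$plots))
  dos <- read_dosage(file.path(dir, "dosage.csv"))
  expect_equal(dim(dos), c(length(s1$genotyped), cfg$U))
  ped <- read_pedigree(file.path(dir, "pedigree.csv"))
  expect_equal(nrow(ped), nrow(s1$pedigree))
  unlink(dir, recursive = TRUE)
})
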