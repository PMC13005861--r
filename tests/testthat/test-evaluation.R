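test_that("fold assignment partitions units evenly and reproducibly", {
  plan <- cv_plan("cv1", folds = 5, reps = 2, seed = 21)
  units <- paste0("g", 1:100)
  f1 <- make_folds(units, plan, rep = 1)
  expect_equal(as.vector(table(f1)), rep(20L, 5))
  expect_equal(sort(names(f1)), sort(units))
  # every unit tested exactly once per repetition
  expect_equal(sum(table(f1)), 100)
  expect_identical(f1, make_folds(units, plan, rep = 1))
  expect_false(identical(f1, make_folds(units, plan, rep = 2)))
  expect_error(make_folds(paste0("g", 1:3), plan), "fewer")

  # CV2: stratified by environment, about 20% of each environment per fold
  cells <- expand.grid(geno = paste0("g", 1:100), env = paste0("E", 1:4))
  ids <- paste(cells$env, cells$geno, sep = ":")
  f2 <- make_folds(ids, plan, rep = 1, strata = as.character(cells$env))
  tab <- table(cells$env, f2)
  expect_true(all(tab == 20))
})

test_that("theoretical accuracy and MSPE follow their closed forms", {
  expect_equal(theoretical_accuracy(0, 1), 1)
  expect_equal(theoretical_accuracy(1 * (1 + 5 * 0.2), 1, F = 0.2), 0)
  expect_equal(theoretical_accuracy(0.36, 1, F = 0), 0.8)
  expect_warning(theoretical_accuracy(2, 1), "clipped")
  expect_error(theoretical_accuracy(0.1, 0), "positive")

  expect_equal(mspe(c(1, 2), c(0, 0)), 2.5)
  expect_equal(mspe(c(a = 1, b = 2), c(b = 2, a = 1)), 0)
  y <- rnorm(20); a <- rnorm(20)
  cc <- 0.7
  expect_equal(mspe(y, a + cc),
               mspe(y, a) + cc^2 - 2 * cc * mean(y - a), tolerance = 1e-12)
  expect_error(mspe(c(a = 1), c(b = 1)), "mismatch")
})

test_that("selection concordance counts top coincidence with deterministic ties", {
  x <- setNames(rnorm(30), paste0("g", 1:30))
  sc <- selection_concordance(x, x)
  expect_equal(sc$rank_correlation, 1)
  expect_equal(sc$coincidence, 1)
  rev <- setNames(-x, names(x))
  sc2 <- selection_concordance(x, rev, fraction = 0.1)
  expect_equal(sc2$rank_correlation, -1)
  expect_equal(sc2$coincidence, 0)
  # hand-built: top-2 sets share exactly one of two candidates
  a <- setNames(c(10, 9, 1, 2, 3, 4, 0, -1, -2, -3), paste0("g", 1:10))
  b <- setNames(c(10, 0, 1, 9, 3, 4, 2, -1, -2, -3), paste0("g", 1:10))
  expect_equal(selection_concordance(a, b, 0.2)$coincidence, 0.5)
  expect_error(selection_concordance(a, b, 0.01), "fraction")
  expect_error(selection_concordance(a, setNames(b, paste0("x", 1:10))),
               "mismatch")
})

# small weighted entry set reused by the CV tests
cv_fx <- equivalence_fixture(seed = 55)
cv_es <- equivalence_entries(cv_fx)
cv_fixed <- list(Lambda = cv_fx$truth$Lambda, Psi = cv_fx$truth$Psi,
                 sigma2_na = cv_fx$truth$sigma2_na, rho = cv_fx$truth$rho,
                 sigma2_e = 0)

test_that("two-stage cross-validation masks, predicts and aggregates correctly", {
  plan <- cv_plan("cv1", folds = 4, reps = 2, seed = 31)
  r <- cv_two_stage(make_weights(cv_es, "fw"), cv_fx$G, 1, plan,
                    fixed = cv_fixed, detail = TRUE, control = fast_ctrl)
  expect_equal(nrow(r$per_rep), 2)
  expect_true(all(abs(r$per_rep$pa) <= 1))
  expect_true(all(r$per_rep$mspe >= 0))
  # every masked cell receives exactly one prediction per repetition
  d1 <- r$detail[r$detail$rep == 1, ]
  expect_equal(nrow(unique(d1[, c("environment", "geno")])), nrow(d1))
  expect_equal(sort(unique(d1$geno)), sort(cv_fx$ids))
})

test_that("held-out records cannot leak into their own predictions", {
  plan <- cv_plan("cv1", folds = 4, reps = 1, seed = 32)
  r1 <- cv_two_stage(make_weights(cv_es, "fw"), cv_fx$G, 1, plan,
                     fixed = cv_fixed, detail = TRUE, control = fast_ctrl)
  # perturb one genotype's entries, rerun: predictions of that genotype in
  # the fold where it is masked must be unchanged (parameters are fixed, so
  # nothing about the held-out record enters the training model)
  gpert <- r1$detail$geno[1]
  es2 <- cv_es
  for (i in seq_along(es2$blocks)) {
    hit <- names(es2$blocks[[i]]$entries) == gpert
    es2$blocks[[i]]$entries[hit] <- es2$blocks[[i]]$entries[hit] + 50
  }
  r2 <- cv_two_stage(make_weights(es2, "fw"), cv_fx$G, 1, plan,
                     fixed = cv_fixed, detail = TRUE, control = fast_ctrl)
  p1 <- r1$detail[r1$detail$geno == gpert, ]
  p2 <- r2$detail[r2$detail$geno == gpert, ]
  expect_equal(p1$pred, p2$pred, tolerance = 1e-10)
  expect_equal(p2$obs - p1$obs, rep(50, nrow(p1)))
})

test_that("pool-specific runs reduce to the full run for a single pool", {
  plan <- cv_plan("cv1", folds = 4, reps = 2, seed = 33)
  pop_sim <- list(
    pedigree = data.frame(id = cv_fx$ids, parent1 = NA, parent2 = NA,
                          pool = "A", stringsAsFactors = FALSE),
    genotyped = cv_fx$ids,
    dosage = NULL)
  # dosages for G recomputation
  pop <- small_population(seed = 55)
  pop_sim$dosage <- pop$dosage
  rfull <- cv_two_stage(make_weights(cv_es, "fw"),
                        G_matrix(filter_markers(pop$dosage)), 1, plan,
                        fixed = cv_fixed, control = fast_ctrl)
  rpool <- cv_pool_specific(pop_sim, make_weights(cv_es, "fw"), "A", 1, plan,
                            fixed = cv_fixed, control = fast_ctrl)
  expect_equal(rpool$per_rep$pa, rfull$per_rep$pa, tolerance = 1e-10)
  # a pool smaller than the fold count is rejected
  pop_small <- pop_sim
  pop_small$pedigree$pool <- c(rep("A", 3), rep("B", length(cv_fx$ids) - 3))
  expect_error(cv_pool_specific(pop_small, make_weights(cv_es, "fw"), "A",
                                1, plan), "too small")
})
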