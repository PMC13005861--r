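# shared demo dataset for the stage-one tests
s1_sim <- simulate_met(demo_config(seed = 301))
s1_env <- s1_sim$plots[s1_sim$plots$environment == "ENV1", ]
s1_A <- A_matrix(s1_sim$pedigree)

test_that("the three stage-one variants fit and report their components", {
  blue <- fit_stage_one(s1_env, "blue", lr = FALSE, control = fast_ctrl)
  expect_equal(length(blue$genetic),
               length(unique(s1_env$treatment)))
  blup <- fit_stage_one(s1_env, "blup", control = fast_ctrl)
  expect_true(blup$H2 >= 0 && blup$H2 <= 1)
  expect_true(blup$lr_p["g"] >= 0 && blup$lr_p["g"] <= 1)
  ablup <- fit_stage_one(s1_env, "ablup", A = s1_A, lr = FALSE,
                         control = fast_ctrl)
  expect_true(ablup$h2 >= 0 && ablup$h2 <= 1)
  # genotypic variance roughly tracks additive + non-additive
  s2g <- blup$varcomp["g.sigma2"]
  s2sum <- ablup$varcomp["a.sigma2"] + ablup$varcomp["na.sigma2"]
  expect_lt(abs(s2g - s2sum) / max(s2g, s2sum), 0.6)
  expect_error(fit_stage_one(s1_env, "ablup"), "requires")
})

test_that("heritability formulas follow their closed forms", {
  # theta of an identity matrix of order 100 is 0.99
  expect_equal(rel_theta(diag(100)), 0.99)
  h <- heritabilities(list(sigma2_a = 1, sigma2_na = 0, sigma2_e = 1,
                           theta = 0.99))
  expect_equal(unname(h["h2"]), 0.99 / 1.99, tolerance = 1e-12)
  expect_equal(unname(heritabilities(list(sigma2_g = 0, sigma2_e = 2))["H2"]),
               0)
  expect_equal(unname(heritabilities(list(sigma2_a = 2, sigma2_na = 0,
                                          sigma2_e = 0, theta = 0.7))["h2"]),
               1)
  expect_error(heritabilities(list(sigma2_g = -1, sigma2_e = 1)),
               "nonnegative")
})

test_that("deregression with components frozen at BLUE estimates reproduces BLUEs", {
  blue <- fit_stage_one(s1_env, "blue", lr = FALSE, control = fast_ctrl)
  blup <- fit_stage_one(s1_env, "blup", lr = FALSE, control = fast_ctrl)
  # freeze at the BLUE-variant estimates: identical model, identical entries
  forced <- blup
  forced$varcomp <- blue$varcomp
  eb <- deregress(forced)
  blue_ent <- blue$genetic[names(eb$entries)]
  expect_equal(eb$entries, blue_ent, tolerance = 1e-8)
  # Q is symmetric PSD
  expect_equal(eb$Q, t(eb$Q), tolerance = 1e-10)
  expect_gt(min(eigen(eb$Q, only.values = TRUE)$values), -1e-8)
})

test_that("deregression removes shrinkage of the genetic predictions", {
  slopes <- sapply(1:5, function(r) {
    sim <- simulate_met(demo_config(seed = 300 + r))
    d1 <- sim$plots[sim$plots$environment == "ENV1", ]
    s1 <- fit_stage_one(d1, "blup", lr = FALSE, control = fast_ctrl)
    eb <- deregress(s1, control = fast_ctrl)
    truth <- sim$effects$a[, 1] + sim$effects$na[, 1]
    ids <- intersect(names(eb$entries)[eb$role != "check"], names(truth))
    c(raw = unname(coef(lm(s1$genetic[ids] ~ truth[ids]))[2]),
      der = unname(coef(lm(eb$entries[ids] ~ truth[ids]))[2]))
  })
  # deregressed entries are unshrunken (slope about 1 on the true values);
  # raw BLUPs are shrunken towards zero (slope clearly below 1)
  expect_lt(abs(mean(slopes["der", ]) - 1), 0.2)
  expect_lt(mean(slopes["raw", ]), mean(slopes["der", ]) - 0.2)
  expect_gt(var(eb <- slopes["der", ]), 0)   # sanity: non-degenerate
})

test_that("weight construction keeps Q (FW) or the inverse-diagonal rule (DW)", {
  Q <- matrix(c(2, 1, 1, 2), 2, dimnames = list(c("a", "b"), c("a", "b")))
  eb <- structure(list(environment = "E1", kind = "BLUE",
                       entries = c(a = 1, b = 2), Q = Q,
                       role = c(a = "test", b = "test"),
                       weight_mode = NULL), class = "entry_block")
  fw <- make_weights(eb, "fw")
  expect_identical(fw$W, Q)
  dw <- make_weights(eb, "dw")
  # solve(Q) has diagonal 2/3, so DW variances are 1.5
  expect_equal(diag(dw$W), c(a = 1.5, b = 1.5))
  expect_true(all(dw$W[upper.tri(dw$W)] == 0))
  # identity Q: both modes coincide
  ebI <- eb; ebI$Q <- diag(2); dimnames(ebI$Q) <- dimnames(Q)
  expect_equal(make_weights(ebI, "fw")$W, make_weights(ebI, "dw")$W)
  # diagonal Q: DW variances equal Q's diagonal
  ebD <- eb; ebD$Q <- diag(c(0.3, 0.9)); dimnames(ebD$Q) <- dimnames(Q)
  expect_equal(diag(make_weights(ebD, "dw")$W), c(a = 0.3, b = 0.9))
})

test_that("entry sets restrict, stack and preserve treatment order mapping", {
  blup <- fit_stage_one(s1_env, "blup", lr = FALSE, control = fast_ctrl)
  eb <- deregress(blup, control = fast_ctrl)
  es <- entry_set(list(eb))
  expect_equal(es$kind, "dBLUP")
  esr <- restrict_entries(es, s1_sim$genotyped)
  expect_true(all(esr$blocks[[1]]$role != "check"))
  expect_true(all(names(esr$blocks[[1]]$entries) %in% s1_sim$genotyped))
  stk <- stack_entries(make_weights(esr, "fw"))
  b <- esr$blocks[[1]]
  expect_equal(stk$data$y, unname(b$entries))
  expect_equal(unname(diag(stk$Omega)), unname(diag(b$Q)))
  # permutation equivariance: reordering treatments permutes entries and Q
  perm <- sample(length(eb$entries))
  eb2 <- eb
  eb2$entries <- eb$entries[perm]
  eb2$Q <- eb$Q[perm, perm]
  eb2$role <- eb$role[perm]
  es2 <- restrict_entries(entry_set(list(eb2)), s1_sim$genotyped)
  b2 <- es2$blocks[[1]]
  expect_equal(b2$entries[names(b$entries)], b$entries)
  expect_equal(b2$Q[names(b$entries), names(b$entries)], b$Q)
})
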