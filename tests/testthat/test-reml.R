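test_that("restricted likelihood matches closed forms on simple models", {
  set.seed(42)
  y <- rnorm(40, 5, 2)
  f <- reml(y ~ 1, data.frame(y = y))
  s2 <- var(y)   # REML of an i.i.d. normal sample is the n-1 variance
  expect_equal(unname(f$par$value), s2, tolerance = 1e-6)
  ll <- -0.5 * (39 * log(2 * pi) + 39 * log(s2) + sum((y - mean(y))^2) / s2)
  expect_equal(f$loglik, ll, tolerance = 1e-8)
})

test_that("balanced one-way REML equals the ANOVA estimators and scalar BLUP", {
  set.seed(43)
  g <- rep(sprintf("g%02d", 1:10), each = 5)
  y <- 2 + rnorm(10, 0, sqrt(3))[match(g, unique(g))] + rnorm(50, 0, 1.5)
  d <- data.frame(y = y, g = g)
  f <- reml(y ~ 1, d, random = list(ran_iid("g")))
  ms <- anova(lm(y ~ g))[["Mean Sq"]]
  expect_equal(unname(f$par$value), c((ms[1] - ms[2]) / 5, ms[2]),
               tolerance = 1e-5)
  sg <- f$par$value[1]; se <- f$par$value[2]
  gm <- tapply(y, g, mean)
  shrunk <- sg / (sg + se / 5) * (gm - mean(gm))
  expect_equal(unname(f$blups$g$blup[names(gm)]), as.vector(shrunk),
               tolerance = 1e-8)
  # near-infinite group variance: BLUPs approach the fixed group-mean deviations
  f_inf <- reml(y ~ 1, d, random = list(ran_iid("g", fixed = 1e8)),
                residual = res_iid(fixed = se))
  expect_equal(unname(f_inf$blups$g$blup[names(gm)]),
               as.vector(gm - mean(gm)), tolerance = 1e-4)
})

test_that("dense likelihood equals the contrast-basis oracle across structures", {
  set.seed(7)
  G <- crossprod(matrix(rnorm(36), 6)); G <- G / mean(diag(G))
  dimnames(G) <- list(paste0("g", 1:6), paste0("g", 1:6))
  for (case in 1:4) {
    set.seed(100 + case)
    d <- expand.grid(geno = paste0("g", 1:6),
                     environment = c("E1", "E2", "E3"),
                     rep = 1:3, stringsAsFactors = FALSE)
    d$row <- sample(1:6, nrow(d), TRUE); d$col <- sample(1:9, nrow(d), TRUE)
    # drop duplicated coordinates within environment for the spatial case
    d <- d[!duplicated(d[, c("environment", "row", "col")]), ]
    d$unit <- paste(d$environment, d$geno, d$rep, sep = ":")
    d$y <- rnorm(nrow(d))
    n <- nrow(d)
    L <- matrix(rnorm(6, sd = 0.8), 3, 2); L[1, 2] <- 0
    Psi <- runif(3, 0.2, 0.8)
    s2na <- runif(3, 0.3, 1); rho <- 0.3
    Q <- crossprod(matrix(rnorm(n * n), n)) / n
    dimnames(Q) <- list(d$unit, d$unit)
    s2 <- 1.3; rr <- 0.45; rc <- -0.25
    mi <- match(d$environment, c("E1", "E2", "E3"))
    vi <- match(d$geno, rownames(G))
    Sg <- tcrossprod(L) + diag(Psi)
    Cna <- sqrt(s2na) %o% sqrt(s2na) * (diag(3) + rho * (1 - diag(3)))
    Eg <- outer(vi, vi, "==") * outer(mi, mi, "==") * 0 + outer(vi, vi, "==")
    same_env <- outer(d$environment, d$environment, "==")
    Rsp <- s2 * (rr ^ abs(outer(d$row, d$row, "-"))) *
      (rc ^ abs(outer(d$col, d$col, "-"))) * same_env
    V <- Sg[mi, mi] * G[vi, vi] + Cna[mi, mi] * Eg + Q + Rsp
    X <- model.matrix(~environment, d)
    f <- reml(y ~ environment, d,
              random = list(
                ran_fa("geno", "environment", G, 2,
                       fixed = list(Lambda = L, Psi = Psi)),
                ran_hetcs("geno", "environment",
                          fixed = list(sigma2 = s2na, rho = rho)),
                ran_knownfull("unit", Q)),
              residual = res_ar1ar1(fixed = list(sigma2 = s2, rho_r = rr,
                                                 rho_c = rc)))
    expect_equal(f$loglik, bf_reml_ll(d$y, X, V), tolerance = 1e-8)
    # and the mixed-model solution matches brute-force GLS
    gls <- bf_gls(d$y, X, V)
    expect_equal(unname(f$beta), unname(gls$beta), tolerance = 1e-8)
  }
})

test_that("a known-covariance term with Q = cI equals an i.i.d. variance", {
  set.seed(9)
  d <- data.frame(y = rnorm(30), unit = paste0("u", 1:30))
  Q <- 0.7 * diag(30); dimnames(Q) <- list(d$unit, d$unit)
  f1 <- reml(y ~ 1, d, random = list(ran_knownfull("unit", Q)),
             residual = res_iid(fixed = 0.5))
  f2 <- reml(y ~ 1, d, residual = res_iid(fixed = 1.2))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)
})

test_that("fits are invariant to row permutation and report aliasing", {
  set.seed(10)
  d <- expand.grid(geno = paste0("g", 1:8), rep = 1:3,
                   stringsAsFactors = FALSE)
  d$grp <- rep(c("a", "b"), length.out = nrow(d))
  d$y <- rnorm(nrow(d))
  f1 <- reml(y ~ grp, d, random = list(ran_iid("geno")),
             control = fast_ctrl)
  d2 <- d[sample(nrow(d)), ]
  f2 <- reml(y ~ grp, d2, random = list(ran_iid("geno")),
             control = fast_ctrl)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$blups$geno$blup, f2$blups$geno$blup, tolerance = 1e-4)
  # duplicate of grp gets dropped with a record
  d$grp2 <- d$grp
  f3 <- reml(y ~ grp + grp2, d, random = list(ran_iid("geno")),
             control = fast_ctrl)
  expect_equal(length(f3$aliased), 1)
  expect_equal(f3$loglik, f1$loglik, tolerance = 1e-6)
})

test_that("PEV is nonnegative and AIC counts only free covariance parameters", {
  set.seed(11)
  d <- data.frame(y = rnorm(40), g = rep(paste0("g", 1:8), 5))
  f <- reml(y ~ 1, d, random = list(ran_iid("g")))
  expect_true(all(f$blups$g$pev >= 0))
  expect_equal(f$n_covpar, 2)
  expect_equal(f$aic, -2 * f$loglik + 4)
  expect_equal(AIC(f), f$aic)
  # boundary flag when the true group variance is zero
  set.seed(12)
  d0 <- data.frame(y = rnorm(60), g = rep(paste0("g", 1:12), 5))
  f0 <- reml(y ~ 1, d0, random = list(ran_iid("g")))
  expect_true(f0$par$value[1] < 0.05 * var(d0$y))
})

test_that("the boundary chi-square mixture test behaves as specified", {
  expect_equal(lr_test(10, 10, L = 1)$p_value, 1)
  expect_equal(lr_test(10 + 3.84 / 2, 10, L = 1)$p_value,
               0.5 * pchisq(3.84, 1, lower.tail = FALSE), tolerance = 1e-12)
  # L = 2: mixture weights (1/4, 1/2, 1/4)
  lr <- 5.2
  manual <- 0.25 * 0 + 0.5 * pchisq(lr, 1, lower.tail = FALSE) +
    0.25 * pchisq(lr, 2, lower.tail = FALSE)
  expect_equal(lr_test(10 + lr / 2, 10, L = 2)$p_value, manual,
               tolerance = 1e-12)
  expect_error(lr_test(10, 11, L = 1), "negative")
})
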