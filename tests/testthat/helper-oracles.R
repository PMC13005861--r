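# Independent oracles and shared fixtures, kept deliberately separate from
# the package's own computational paths.

# Restricted log-likelihood through an orthonormal error-contrast basis
# (explicit projection route, used to validate the engine's dense algebra).
bf_reml_ll <- function(y, X, V) {
  qx <- qr(X)
  K <- qr.Q(qx, complete = TRUE)[, (qx$rank + 1):length(y), drop = FALSE]
  KVK <- t(K) %*% V %*% K
  Ky <- drop(t(K) %*% y)
  -0.5 * (length(Ky) * log(2 * pi) +
            as.numeric(determinant(KVK, logarithm = TRUE)$modulus) +
            sum(Ky * solve(KVK, Ky)))
}

# Generalized-least-squares solution (fixed effects and BLUPs) computed the
# long way from the marginal covariance.
bf_gls <- function(y, X, V, Zu = NULL, Gu = NULL) {
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  out <- list(beta = drop(beta))
  if (!is.null(Zu)) {
    r <- y - X %*% beta
    out$u <- drop(Gu %*% t(Zu) %*% Vi %*% r)
  }
  out
}

# Gene-dropping Monte-Carlo oracle for the hexaploid pedigree relationship:
# founders receive unique allele labels (6 copies each); each meiosis passes
# 3 of the parent's 6 copies without replacement (no double reduction). Per
# replicate the *exact conditional* identity-by-descent probabilities are
# accumulated (match counts over all allele pairs), so the only Monte-Carlo
# noise comes from the sampled transmissions. The additive relationship is
# 6 * P(random allele of x IBD to random allele of y) off the diagonal and
# 1 + 5 * P(two distinct alleles of x IBD) on it.
gene_drop_A <- function(pedigree, n_rep = 4000, seed = 1) {
  set.seed(seed)
  ids <- as.character(pedigree$id)
  p1 <- as.character(pedigree$parent1)
  p2 <- as.character(pedigree$parent2)
  n <- length(ids)
  acc <- matrix(0, n, n, dimnames = list(ids, ids))
  for (r in seq_len(n_rep)) {
    alleles <- vector("list", n)
    names(alleles) <- ids
    counter <- 0
    for (i in seq_len(n)) {
      if (is.na(p1[i]) || p1[i] %in% c("", "0")) {
        alleles[[i]] <- counter + 1:6
        counter <- counter + 6
      } else {
        alleles[[i]] <- c(sample(alleles[[p1[i]]], 3),
                          sample(alleles[[p2[i]]], 3))
      }
    }
    for (i in seq_len(n)) {
      ai <- alleles[[i]]
      cnt <- table(ai)
      acc[i, i] <- acc[i, i] + sum(cnt * (cnt - 1)) / 30   # distinct pairs
      if (i < n) for (j in (i + 1):n)
        acc[i, j] <- acc[i, j] + sum(outer(ai, alleles[[j]], "==")) / 36
    }
  }
  P <- acc / n_rep
  A <- 6 * P
  diag(A) <- 1 + 5 * diag(P)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}

# Small genotyped population shared by several tests: two pools of founders
# crossed in a partial diallel.
small_population <- function(n_founders = c(A = 4, B = 4), n_fam = 8,
                             n_off = 32, U = 250, seed = 42) {
  fnd <- simulate_founders(sum(n_founders), U, pools = n_founders,
                           seed = seed)
  plan <- crossing_plan(split(rownames(fnd), attr(fnd, "pool")),
                        n_fam, n_off, max_offspring = 6, seed = seed + 1)
  cross <- simulate_partial_diallel(fnd, plan, seed = seed + 2)
  list(founders = fnd, cross = cross,
       dosage = rbind(fnd, cross$dosage),
       pedigree = cross$pedigree)
}

# Plot data simulated directly from the no-spatial single-stage model at
# known parameter values: used for the two-stage / single-stage equivalence
# analyses. Returns the plots, the truth, and G.
equivalence_fixture <- function(seed = 99, M = 3, n_extra = 15) {
  pop <- small_population(seed = seed)
  G <- blend(G_matrix(filter_markers(pop$dosage)), 0.02)
  ids <- rownames(G$mat)
  V <- length(ids)
  truth <- list(Lambda = matrix(c(2, 1.6, 1.2), 3, 1),
                Psi = c(0.5, 0.4, 0.3),
                sigma2_na = c(1, 0.8, 0.6), rho = 0.25,
                sigma2_b = 0.8, sigma2_e = 1.5,
                env_means = c(10, 12, 9))
  Sg <- tcrossprod(truth$Lambda) + diag(truth$Psi)
  set.seed(seed)
  a <- matrix(drop(t(chol(kronecker(Sg, G$mat))) %*% stats::rnorm(M * V)),
              V, M, dimnames = list(ids, NULL))
  Cna <- sqrt(truth$sigma2_na) %o% sqrt(truth$sigma2_na) *
    (diag(M) + truth$rho * (1 - diag(M)))
  na <- matrix(stats::rnorm(V * M), V, M) %*% chol(Cna)
  rownames(na) <- ids
  plots <- do.call(rbind, lapply(seq_len(M), function(m) {
    trt <- c(ids, sample(ids, n_extra))
    n <- length(trt)
    block <- sample(rep(1:5, length.out = n))
    beff <- stats::rnorm(5, 0, sqrt(truth$sigma2_b))
    data.frame(environment = paste0("E", m), treatment = trt, role = "test",
               pool = "P", block = block,
               y = truth$env_means[m] + a[trt, m] + na[trt, m] +
                 beff[block] + stats::rnorm(n, 0, sqrt(truth$sigma2_e)),
               stringsAsFactors = FALSE)
  }))
  list(plots = plots, truth = truth, G = G, a = a, na = na, ids = ids)
}

# Stage-one BLUE analysis of the equivalence fixture with the non-genetic
# components frozen at truth: entries and their exact covariance Q.
equivalence_entries <- function(fx) {
  blocks <- lapply(split(fx$plots, fx$plots$environment), function(d) {
    f <- reml(y ~ 0 + treatment, d,
              random = list(ran_iid("block", fixed = fx$truth$sigma2_b)),
              residual = res_iid(fixed = fx$truth$sigma2_e))
    ent <- stats::setNames(f$beta, sub("^treatment", "", names(f$beta)))
    Q <- f$beta_cov
    dimnames(Q) <- list(names(ent), names(ent))
    structure(list(environment = d$environment[1], kind = "BLUE",
                   entries = ent, Q = Q,
                   role = stats::setNames(rep("test", length(ent)),
                                          names(ent)),
                   weight_mode = NULL),
              class = "entry_block")
  })
  entry_set(blocks)
}

fast_ctrl <- reml_control(n_starts = 1)
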