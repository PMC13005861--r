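## Synthetic hexaploid multi-environment trial generator.
##
## The generator mirrors the statistical structure assumed by the evaluation
## models: a partial-diallel population bred within two gene pools, integer
## allele dosages 0-6 with polysomic inheritance (no double reduction),
## marker-based additive values with a factor-analytic across-environment
## covariance, heterogeneous compound-symmetry non-additive values, augmented
## row-column layouts, i.i.d. design effects and separable AR1xAR1 spatial
## residuals.

subseed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k)
}

#' Simulation configuration
#'
#' Returns the list of parameters that drives [simulate_met()]. The defaults
#' describe a hexaploid sweetpotato-style observational-trial series: two gene
#' pools with 19 and 20 parents crossed in a partial diallel giving 254
#' families and 1,138 test clones (13 of them without marker data), 3,120
#' loci, and six environments each laid out as a 50 x 30 augmented row-column
#' design with 10 x 10 row/column groups, 8 checks (once per block, 15
#' replicates each) and about 24% of plots allocated to replicated treatments.
#'
#' @param M number of environments.
#' @param n_parents integer vector of pool sizes (one entry per pool).
#' @param n_families,n_offspring partial-diallel family count and total
#'   offspring count; per-family sizes are drawn from `1:max_offspring`.
#' @param max_offspring largest family size.
#' @param n_ungenotyped number of test clones without marker data.
#' @param U number of simulated loci.
#' @param freq_range founder allele-frequency range (uniform draw).
#' @param n_checks number of checks.
#' @param R,C,row_group,col_group field dimensions and group sizes.
#' @param rep_fraction target fraction of replicated (check + parent) plots.
#' @param max_parent_rep maximum replicates per parent.
#' @param Lambda M x K matrix of factor loadings for the additive
#'   across-environment covariance `Lambda Lambda' + diag(Psi)` (trait units).
#' @param Psi length-M vector of specific (lack-of-fit) additive variances.
#' @param sigma2_na length-M vector of non-additive variances.
#' @param varrho common non-additive correlation between environments.
#' @param sigma2_e length-M residual variances.
#' @param rho_r,rho_c spatial autocorrelations (rows, columns), recycled to M.
#' @param sigma2_rg,sigma2_cg,sigma2_b row-group, column-group and block
#'   variances.
#' @param env_means length-M environment means (trait units).
#' @param sigma2_check variance of the fixed check effects.
#' @param missing_rate fraction of plots removed uniformly at random.
#' @param seed master seed; all sub-streams derive from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(M = 6,
                       n_parents = c(A = 19, B = 20),
                       n_families = 254, n_offspring = 1138,
                       max_offspring = 18, n_ungenotyped = 13,
                       U = 3120, freq_range = c(0.1, 0.9),
                       n_checks = 8, R = 50, C = 30,
                       row_group = 10, col_group = 10,
                       rep_fraction = 0.24, max_parent_rep = 15,
                       Lambda = NULL, Psi = NULL,
                       sigma2_na = NULL, varrho = 0.3,
                       sigma2_e = NULL, rho_r = 0.35, rho_c = 0.35,
                       sigma2_rg = 2, sigma2_cg = 2, sigma2_b = 1.5,
                       env_means = NULL, sigma2_check = 4,
                       missing_rate = 0.05, seed = 101L) {
  if (is.null(Lambda)) {
    l1 <- c(3.0, 2.8, 2.5, 1.2, 1.0, 2.0)
    l2 <- c(0.0, 1.0, -1.5, 2.5, 2.2, -1.0)
    Lambda <- cbind(rep_len(l1, M), rep_len(l2, M))
  }
  Lambda <- as.matrix(Lambda)
  if (nrow(Lambda) != M) stop("Lambda must have M rows", call. = FALSE)
  if (ncol(Lambda) > M) stop("K must not exceed M", call. = FALSE)
  if (is.null(Psi)) Psi <- rep_len(c(1.5, 1.0, 1.2, 1.5, 1.0, 0.8), M)
  if (is.null(sigma2_na)) sigma2_na <- rep_len(c(3, 2.5, 2, 3.5, 2, 2.5), M)
  if (is.null(sigma2_e)) sigma2_e <- rep_len(c(25, 35, 30, 45, 40, 20), M)
  if (is.null(env_means)) env_means <- rep_len(c(22, 18, 25, 15, 17, 28), M)
  rho_r <- rep_len(rho_r, M); rho_c <- rep_len(rho_c, M)
  stopifnot(all(Psi >= 0), all(sigma2_na >= 0), all(sigma2_e >= 0),
            abs(varrho) < 1, all(abs(rho_r) < 1), all(abs(rho_c) < 1),
            missing_rate >= 0, missing_rate < 1)
  cfg <- list(M = M, n_parents = n_parents, n_families = n_families,
              n_offspring = n_offspring, max_offspring = max_offspring,
              n_ungenotyped = n_ungenotyped, U = U, freq_range = freq_range,
              n_checks = n_checks, R = R, C = C, row_group = row_group,
              col_group = col_group, rep_fraction = rep_fraction,
              max_parent_rep = max_parent_rep, Lambda = Lambda,
              Psi = Psi, sigma2_na = sigma2_na, varrho = varrho,
              sigma2_e = sigma2_e, rho_r = rho_r, rho_c = rho_c,
              sigma2_rg = sigma2_rg, sigma2_cg = sigma2_cg, sigma2_b = sigma2_b,
              env_means = env_means, sigma2_check = sigma2_check,
              missing_rate = missing_rate, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Small demonstration configuration
#'
#' A reduced image of [sim_config()] (three environments, ten parents in two
#' pools, about a hundred clones on a 12 x 10 field, 300 loci) used for
#' examples, tests and the worked demonstration pipeline. Parameter values
#' keep the same variance structure as the full-size default.
#'
#' @param ... overrides passed to [sim_config()].
#' @export
demo_config <- function(...) {
  args <- list(M = 3, n_parents = c(A = 5, B = 5), n_families = 20,
               n_offspring = 98, max_offspring = 8, n_ungenotyped = 2,
               U = 300, n_checks = 2, R = 12, C = 10,
               row_group = 6, col_group = 5,
               Lambda = cbind(c(3.0, 2.6, 1.2), c(0, 1.0, 2.4)),
               Psi = c(1.5, 1.0, 1.2), sigma2_na = c(3, 2.5, 2),
               sigma2_e = c(25, 35, 30), env_means = c(22, 18, 25),
               missing_rate = 0.04)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

#' Simulate founder dosages
#'
#' Draws per-locus allele frequencies uniformly on `freq_range` (unless
#' `p` is supplied) and founder dosages as Binomial(6, p_u), the
#' Hardy-Weinberg dosage distribution of an autohexaploid.
#'
#' @param n_founders number of founders.
#' @param U number of loci.
#' @param freq_range range of the uniform founder-frequency draw.
#' @param p optional length-`U` vector of allele frequencies (overrides
#'   `freq_range`).
#' @param pools optional named integer vector of pool sizes; founders are
#'   labelled `<pool><i>` and a `pool` attribute is attached.
#' @param seed integer seed.
#' @return Integer matrix (founders x loci) with `pool` and `p` attributes.
#' @export
simulate_founders <- function(n_founders, U, freq_range = c(0.1, 0.9),
                              p = NULL, pools = NULL, seed = 1L) {
  stopifnot(U >= 1)
  set.seed(seed)
  if (is.null(p)) p <- stats::runif(U, freq_range[1], freq_range[2])
  stopifnot(length(p) == U, all(p >= 0), all(p <= 1))
  Z <- matrix(stats::rbinom(n_founders * U, 6L, rep(p, each = n_founders)),
              nrow = n_founders, ncol = U)
  if (!is.null(pools)) {
    stopifnot(sum(pools) == n_founders)
    pool <- rep(names(pools), times = pools)
    ids <- unlist(lapply(names(pools), function(pl)
      paste0(pl, seq_len(pools[[pl]]))))
  } else {
    pool <- rep(NA_character_, n_founders)
    ids <- paste0("F", seq_len(n_founders))
  }
  rownames(Z) <- ids
  colnames(Z) <- paste0("L", seq_len(U))
  attr(Z, "pool") <- stats::setNames(pool, ids)
  attr(Z, "p") <- p
  Z
}

#' Partial-diallel crossing plan
#'
#' Samples `n_families` distinct within-pool parent pairs (allocated to pools
#' proportionally to the number of possible pairs) and per-family offspring
#' counts from `1:max_offspring`, adjusted to total `n_offspring`.
#'
#' @param pool named list or split of parent ids by pool.
#' @param n_families number of families.
#' @param n_offspring total offspring across families.
#' @param max_offspring largest family size.
#' @param seed integer seed.
#' @return Data frame with columns `parent1`, `parent2`, `n`.
#' @export
crossing_plan <- function(pool, n_families, n_offspring,
                          max_offspring = 18, seed = 1L) {
  set.seed(seed)
  pairs_by_pool <- lapply(pool, function(ids) {
    if (length(ids) < 2) return(NULL)
    cmb <- utils::combn(ids, 2)
    data.frame(parent1 = cmb[1, ], parent2 = cmb[2, ],
               stringsAsFactors = FALSE)
  })
  pairs_by_pool <- pairs_by_pool[!vapply(pairs_by_pool, is.null, logical(1))]
  avail <- vapply(pairs_by_pool, nrow, integer(1))
  if (n_families > sum(avail))
    stop("n_families exceeds the number of possible within-pool pairs",
         call. = FALSE)
  # proportional allocation, largest remainder
  alloc <- floor(n_families * avail / sum(avail))
  rem <- n_families - sum(alloc)
  if (rem > 0) {
    frac <- n_families * avail / sum(avail) - alloc
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    alloc[add] <- alloc[add] + 1L
  }
  alloc <- pmin(alloc, avail)
  while (sum(alloc) < n_families) {
    i <- which(alloc < avail)[1]
    alloc[i] <- alloc[i] + 1L
  }
  fam <- do.call(rbind, lapply(seq_along(pairs_by_pool), function(i) {
    pb <- pairs_by_pool[[i]]
    pb[sample.int(nrow(pb), alloc[i]), , drop = FALSE]
  }))
  rownames(fam) <- NULL
  n <- sample.int(max_offspring, n_families, replace = TRUE)
  target <- max(n_families, min(n_offspring, n_families * max_offspring))
  i <- 0L
  while (sum(n) != target) {
    i <- i %% n_families + 1L
    if (sum(n) > target && n[i] > 1L) n[i] <- n[i] - 1L
    else if (sum(n) < target && n[i] < max_offspring) n[i] <- n[i] + 1L
  }
  fam$n <- n
  fam
}

#' Simulate a partial diallel
#'
#' Produces offspring dosages under polysomic inheritance without double
#' reduction: each gamete carries 3 of the parent's 6 allele copies sampled
#' without replacement, so the gamete dosage at a locus is
#' Hypergeometric(6, z_parent, 3) and the offspring dosage is the sum of the
#' two gamete dosages.
#'
#' @param founders founder dosage matrix from [simulate_founders()].
#' @param plan crossing plan (`parent1`, `parent2`, `n`) as from
#'   [crossing_plan()].
#' @param prefix prefix for offspring ids.
#' @param seed integer seed.
#' @return List with `dosage` (offspring x loci), `pedigree` (data frame
#'   `id`, `parent1`, `parent2`, `pool` for founders then offspring).
#' @export
simulate_partial_diallel <- function(founders, plan, prefix = "G", seed = 1L) {
  stopifnot(all(plan$n >= 1))
  missing_par <- setdiff(unique(c(plan$parent1, plan$parent2)),
                         rownames(founders))
  if (length(missing_par))
    stop("unknown parents in crossing plan: ",
         paste(missing_par, collapse = ", "), call. = FALSE)
  set.seed(seed)
  U <- ncol(founders)
  n_off <- sum(plan$n)
  p1 <- rep(plan$parent1, times = plan$n)
  p2 <- rep(plan$parent2, times = plan$n)
  Z1 <- founders[p1, , drop = FALSE]
  Z2 <- founders[p2, , drop = FALSE]
  # gamete dosage | parent dosage z: hypergeometric(white = z, black = 6 - z, draws = 3)
  g1 <- matrix(stats::rhyper(n_off * U, m = as.vector(Z1),
                             n = 6L - as.vector(Z1), k = 3L), nrow = n_off)
  g2 <- matrix(stats::rhyper(n_off * U, m = as.vector(Z2),
                             n = 6L - as.vector(Z2), k = 3L), nrow = n_off)
  off <- g1 + g2
  ids <- paste0(prefix, seq_len(n_off))
  rownames(off) <- ids
  colnames(off) <- colnames(founders)
  fpool <- attr(founders, "pool")
  if (is.null(fpool)) fpool <- stats::setNames(rep(NA_character_,
                                                   nrow(founders)),
                                               rownames(founders))
  ped <- rbind(
    data.frame(id = rownames(founders), parent1 = NA_character_,
               parent2 = NA_character_, pool = unname(fpool),
               stringsAsFactors = FALSE),
    data.frame(id = ids, parent1 = p1, parent2 = p2,
               pool = unname(fpool[p1]), stringsAsFactors = FALSE))
  attr(off, "pool") <- stats::setNames(unname(fpool[p1]), ids)
  list(dosage = off, pedigree = ped)
}

#' Simulate additive and non-additive genetic values
#'
#' Additive values are built marker-wise so that dosages and values are
#' mutually consistent: with `W` the centred dosage matrix and
#' `d = sum(6 p (1 - p))`, common-factor scores are `u_k = W beta_k`,
#' `beta_k ~ N(0, 1/d)`, and specific deviations `delta_m = W gamma_m`,
#' `gamma_m ~ N(0, psi_m / d)`, giving `a_m = sum_k lambda_mk u_k + delta_m`
#' with across-environment covariance approximately
#' `(Lambda Lambda' + diag(Psi)) (x) G`. Non-additive values are drawn from a
#' heterogeneous compound-symmetry covariance
#' `sqrt(D) [I + varrho (J - I)] sqrt(D) (x) I`.
#'
#' @param dosage dosage matrix (individuals x loci) of the genotyped
#'   individuals.
#' @param Lambda M x K loading matrix (trait units).
#' @param Psi length-M specific variances.
#' @param sigma2_na length-M non-additive variances.
#' @param varrho common non-additive correlation.
#' @param p optional allele frequencies used for centring (defaults to
#'   frequencies estimated from `dosage`).
#' @param seed integer seed.
#' @return List with matrices `a` and `na` (individuals x environments).
#' @export
simulate_genetic_effects <- function(dosage, Lambda, Psi, sigma2_na,
                                     varrho = 0, p = NULL, seed = 1L) {
  Lambda <- as.matrix(Lambda)
  M <- nrow(Lambda); K <- ncol(Lambda)
  stopifnot(length(Psi) == M, length(sigma2_na) == M,
            all(Psi >= 0), all(sigma2_na >= 0), abs(varrho) < 1)
  set.seed(seed)
  if (is.null(p)) p <- colMeans(dosage) / 6
  W <- sweep(dosage, 2, 6 * p)
  d <- sum(6 * p * (1 - p))
  if (d <= 0) stop("all loci monomorphic", call. = FALSE)
  n <- nrow(dosage); U <- ncol(dosage)
  beta <- matrix(stats::rnorm(U * K, sd = sqrt(1 / d)), U, K)
  u <- W %*% beta                       # n x K, Var(u_k) ~ G
  gamma <- matrix(stats::rnorm(U * M), U, M) *
    rep(sqrt(Psi / d), each = U)
  a <- u %*% t(Lambda) + W %*% gamma    # n x M
  if (all(sigma2_na == 0)) na <- matrix(0, n, M)
  else {
    Cna <- sqrt(sigma2_na) %o% sqrt(sigma2_na) *
      (diag(M) + varrho * (1 - diag(M)))
    na <- matrix(stats::rnorm(n * M), n, M) %*% chol(Cna)
  }
  dimnames(a) <- dimnames(na) <- list(rownames(dosage), NULL)
  list(a = a, na = na)
}

ar1_mat <- function(n, rho) rho ^ abs(outer(seq_len(n), seq_len(n), "-"))

#' Simulate plot phenotypes on a trial layout
#'
#' Adds, on top of the environment mean, fixed check effects, true genetic
#' values (additive plus non-additive) for non-check treatments, i.i.d.
#' row-group / column-group / block effects, and a spatial residual drawn on
#' the full grid with separable AR1(rho_r) x AR1(rho_c) correlation (via the
#' Kronecker Cholesky identity). Plots are then removed uniformly at random
#' at the configured missingness rate.
#'
#' @param layout a `trial_layout`.
#' @param m environment index (into the per-environment parameter vectors).
#' @param effects list with matrices `a` and `na` from
#'   [simulate_genetic_effects()].
#' @param check_effects named vector of fixed check effects.
#' @param config a `sim_config`.
#' @param seed integer seed.
#' @return Data frame of plot records with truth components
#'   (`mu`, `fixed_trt`, `a`, `na`, `rg_eff`, `cg_eff`, `b_eff`, `spatial`,
#'   `y`, and `missing` flag).
#' @export
simulate_phenotypes <- function(layout, m, effects, check_effects, config,
                                seed = 1L) {
  set.seed(seed)
  pl <- layout$plots
  R <- layout$R; C <- layout$C
  n_rg <- R %/% layout$row_group; n_cg <- C %/% layout$col_group
  rg_eff <- stats::rnorm(n_rg, sd = sqrt(config$sigma2_rg))
  cg_eff <- stats::rnorm(n_cg, sd = sqrt(config$sigma2_cg))
  b_eff <- stats::rnorm(n_rg * n_cg, sd = sqrt(config$sigma2_b))
  Lr <- t(chol(ar1_mat(R, config$rho_r[m])))
  Lc <- chol(ar1_mat(C, config$rho_c[m]))    # upper
  E <- sqrt(config$sigma2_e[m]) * (Lr %*% matrix(stats::rnorm(R * C), R, C) %*% Lc)
  spatial <- E[cbind(pl$row, pl$col)]

  is_check <- pl$role == "check"
  gen_a <- gen_na <- numeric(nrow(pl))
  idx <- match(pl$treatment, rownames(effects$a))
  known <- !is.na(idx)
  gen_a[known] <- effects$a[idx[known], m]
  gen_na[known] <- effects$na[idx[known], m]
  fixed_trt <- ifelse(is_check, check_effects[pl$treatment], 0)

  out <- data.frame(
    environment = layout$environment, pl,
    mu = config$env_means[m], fixed_trt = unname(fixed_trt),
    a = gen_a, na = gen_na,
    rg_eff = rg_eff[pl$row_group], cg_eff = cg_eff[pl$col_group],
    b_eff = b_eff[pl$block], spatial = spatial,
    stringsAsFactors = FALSE)
  out$y <- out$mu + out$fixed_trt + out$a + out$na +
    out$rg_eff + out$cg_eff + out$b_eff + out$spatial
  out$missing <- stats::runif(nrow(out)) < config$missing_rate
  out
}

#' Simulate a complete multi-environment augmented trial dataset
#'
#' Runs the full generator: founders, partial diallel, genetic effects,
#' per-environment augmented layouts and phenotypes. All randomness derives
#' from `config$seed` through fixed sub-streams (founders, crossing plan,
#' meiosis, genetic effects, check effects, and one stream per environment
#' for layout and phenotypes), so a configuration reproduces bit-identically.
#'
#' @param config a [sim_config()].
#' @return Object of class `met_sim`: list with `plots` (all environments,
#'   missing plots removed; truth columns retained), `plots_full` (including
#'   missing plots), `pedigree`, `dosage` (genotyped individuals x loci),
#'   `genotyped` (ids), `effects` (true `a`, `na`), `check_effects`,
#'   `layouts`, and `config`.
#' @export
simulate_met <- function(config = sim_config()) {
  cfg <- config
  founders <- simulate_founders(sum(cfg$n_parents), cfg$U,
                                freq_range = cfg$freq_range,
                                pools = cfg$n_parents,
                                seed = subseed(cfg$seed, 1))
  pool_ids <- split(rownames(founders), attr(founders, "pool")[rownames(founders)])
  plan <- crossing_plan(pool_ids, cfg$n_families, cfg$n_offspring,
                        cfg$max_offspring, seed = subseed(cfg$seed, 2))
  cross <- simulate_partial_diallel(founders, plan, seed = subseed(cfg$seed, 3))
  dosage <- rbind(founders, cross$dosage)
  pool <- c(attr(founders, "pool"), attr(cross$dosage, "pool"))

  offspring_ids <- rownames(cross$dosage)
  set.seed(subseed(cfg$seed, 4))
  ungeno <- if (cfg$n_ungenotyped > 0)
    sample(offspring_ids, cfg$n_ungenotyped) else character()
  genotyped <- setdiff(rownames(dosage), ungeno)

  effects <- simulate_genetic_effects(dosage, cfg$Lambda, cfg$Psi,
                                      cfg$sigma2_na, cfg$varrho,
                                      seed = subseed(cfg$seed, 5))
  set.seed(subseed(cfg$seed, 6))
  checks <- paste0("CK", seq_len(cfg$n_checks))
  check_effects <- stats::setNames(
    stats::rnorm(cfg$n_checks, sd = sqrt(cfg$sigma2_check)), checks)

  n_blocks <- (cfg$R %/% cfg$row_group) * (cfg$C %/% cfg$col_group)
  n_parent_plots <- cfg$R * cfg$C - cfg$n_checks * n_blocks -
    length(offspring_ids)
  if (n_parent_plots < sum(cfg$n_parents))
    stop("field too small for parents and test clones", call. = FALSE)
  preps <- parent_rep_plan(rownames(founders), cfg$R * cfg$C,
                           cfg$n_checks * n_blocks, cfg$rep_fraction,
                           cfg$max_parent_rep,
                           n_parent_plots = n_parent_plots,
                           seed = subseed(cfg$seed, 7))
  layouts <- vector("list", cfg$M)
  plots <- vector("list", cfg$M)
  for (m in seq_len(cfg$M)) {
    env <- sprintf("ENV%d", m)
    layouts[[m]] <- augmented_layout(cfg$R, cfg$C, cfg$row_group,
                                     cfg$col_group, checks, preps,
                                     offspring_ids, environment = env,
                                     seed = subseed(cfg$seed, 10 + m))
    plots[[m]] <- simulate_phenotypes(layouts[[m]], m, effects, check_effects,
                                      cfg, seed = subseed(cfg$seed, 100 + m))
  }
  plots_full <- do.call(rbind, plots)
  plots_full$pool <- ifelse(plots_full$role == "check", "C",
                            unname(pool[plots_full$treatment]))
  rownames(plots_full) <- NULL
  structure(list(plots = plots_full[!plots_full$missing, , drop = FALSE],
                 plots_full = plots_full,
                 pedigree = cross$pedigree, dosage = dosage,
                 genotyped = genotyped, effects = effects,
                 check_effects = check_effects, layouts = layouts,
                 config = cfg),
            class = "met_sim")
}

#' @export
print.met_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Simulated MET: %d environments, %d treatments (%d parents + %d clones), %d checks\n",
              cfg$M, nrow(x$pedigree), sum(cfg$n_parents),
              nrow(x$pedigree) - sum(cfg$n_parents), cfg$n_checks))
  cat(sprintf("  %d plot records (%d removed as missing), %d genotyped individuals, %d loci\n",
              nrow(x$plots), sum(x$plots_full$missing), length(x$genotyped),
              cfg$U))
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `plots.csv` (environment, row, col, treatment, role, pool, y),
#' `pedigree.csv` (id, parent1, parent2, pool) and `dosage.csv`
#' (individuals x loci) into `dir`.
#'
#' @param sim a `met_sim` object.
#' @param dir output directory (created if absent).
#' @return Invisibly, the vector of file paths.
#' @export
write_met <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- sim$plots[, c("environment", "row", "col", "treatment", "role",
                     "pool", "y")]
  f1 <- file.path(dir, "plots.csv")
  utils::write.csv(p, f1, row.names = FALSE)
  f2 <- file.path(dir, "pedigree.csv")
  utils::write.csv(sim$pedigree, f2, row.names = FALSE)
  f3 <- file.path(dir, "dosage.csv")
  utils::write.csv(data.frame(id = sim$genotyped,
                              sim$dosage[sim$genotyped, , drop = FALSE],
                              check.names = FALSE),
                   f3, row.names = FALSE)
  invisible(c(f1, f2, f3))
}
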