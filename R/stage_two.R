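## Stage two: weighted multi-environment model on first-stage entries, with
## additive factor-analytic (x) genomic covariance, heterogeneous
## compound-symmetry non-additive effects and the known first-stage error
## covariance; factor-order selection and G x E summaries.

#' Fit the weighted second-stage multi-environment model
#'
#' Fits `y* = mu + env + g + s + e` on stacked first-stage entries, with
#' `g = a + na`, additive effects `a ~ N(0, (Lambda Lambda' + Psi) (x) G)`
#' (factor-analytic order `k`), non-additive effects with heterogeneous
#' compound symmetry, `s ~ N(0, Omega)` the known first-stage error (full or
#' diagonal weights, see [make_weights()]), and an i.i.d. residual kept with
#' a small lower bound so it cannot be confounded with `Omega`.
#'
#' @param es an `entry_set` with weights attached, or a `list(data, Omega)`
#'   as returned by [stack_entries()].
#' @param G genomic `relmatrix` (or matrix); entries must be restricted to
#'   its individuals ([restrict_entries()]).
#' @param k number of latent factors (`k <= M`).
#' @param fixed optional list freezing parameters: `Lambda`, `Psi`,
#'   `sigma2_na` (length M), `rho`, `sigma2_e` (scalar).
#' @param resid_lb lower bound for the residual variance, as a fraction of
#'   `var(y*)`; set to 0 when `sigma2_e` is frozen.
#' @param control a [reml_control()].
#' @return Object of class `stage2_fit`: `fit` (`remlx`), `Lambda`, `Psi`,
#'   `Sigma_g`, `sigma2_na`, `rho`, `percent_ev`, `gebv` (matrix genotypes x
#'   environments), `gebv_mean`, `pev`, `aic`, `weight_mode`, `k`.
#' @export
fit_stage_two <- function(es, G, k, fixed = NULL, resid_lb = 1e-6,
                          control = reml_control()) {
  Gm <- .relmat(G)
  if (inherits(es, "entry_set")) {
    stk <- stack_entries(es)
    weight_mode <- es$weight_mode
  } else {
    stk <- es
    weight_mode <- attr(es, "weight_mode") %||% "fw"
  }
  d <- stk$data
  M <- length(unique(d$environment))
  if (k > M) stop("number of factors exceeds number of environments",
                  call. = FALSE)
  absent <- setdiff(unique(d$geno), rownames(Gm))
  if (length(absent))
    stop("entries for individuals absent from G: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  fa_fix <- fixed[intersect(names(fixed), c("Lambda", "Psi"))]
  if (!length(fa_fix)) fa_fix <- NULL
  na_fix <- list(sigma2 = fixed$sigma2_na, rho = fixed$rho)
  if (!length(Filter(Negate(is.null), na_fix))) na_fix <- NULL
  e_fix <- fixed$sigma2_e
  lb <- if (!is.null(e_fix)) 0 else resid_lb * stats::var(d$y)
  fit <- reml(y ~ environment, d,
              random = list(
                ran_fa("geno", "environment", Gm, k, fixed = fa_fix,
                       name = "fa"),
                ran_hetcs("geno", "environment", fixed = na_fix,
                          ids = rownames(Gm), name = "na"),
                ran_knownfull("unit", stk$Omega, name = "s")),
              residual = res_iid(fixed = e_fix, lb = lb),
              control = control)
  out <- .stage2_extract(fit, Gm, k)
  out$sigma2_e <- unname(stats::setNames(fit$par$value,
                                         fit$par$par)["residual.sigma2"]) + lb
  out$weight_mode <- weight_mode
  out$entry_kind <- if (inherits(es, "entry_set")) es$kind else NA_character_
  class(out) <- "stage2_fit"
  out
}

## shared between stage-two and single-stage fits
.stage2_extract <- function(fit, Gm, k) {
  pv <- stats::setNames(fit$par$value, fit$par$par)
  envs <- fit$blups$fa$env_levels
  M <- length(envs)
  Lambda <- matrix(0, M, k)
  lt <- which(lower.tri(Lambda, diag = TRUE))
  Lambda[lt] <- pv[sprintf("fa.lambda[%d,%d]", row(Lambda)[lt],
                           col(Lambda)[lt])]
  Psi <- unname(pv[sprintf("fa.psi[%d]", seq_len(M))])
  Sigma_g <- fit$sigma_mats$fa
  dimnames(Sigma_g) <- list(envs, envs)
  sigma2_na <- unname(pv[sprintf("na.sigma2[%d]", seq_len(M))])
  rho <- unname(pv["na.rho"])
  geno <- fit$blups$fa$geno_levels
  gebv <- matrix(fit$blups$fa$blup, nrow = length(geno), ncol = M,
                 dimnames = list(geno, envs))
  pev <- matrix(fit$blups$fa$pev, nrow = length(geno), ncol = M,
                dimnames = list(geno, envs))
  list(fit = fit, k = k, Lambda = Lambda, Psi = Psi, Sigma_g = Sigma_g,
       sigma2_na = sigma2_na, rho = rho,
       percent_ev = percent_ev(Lambda, Psi),
       gebv = gebv, gebv_mean = rowMeans(gebv), pev = pev,
       aic = fit$aic, loglik = fit$loglik)
}

#' @export
print.stage2_fit <- function(x, ...) {
  cat(sprintf("Second-stage FA(%d) fit (%s entries, %s weights): %d genotypes x %d environments\n",
              x$k, x$entry_kind %||% "?", x$weight_mode %||% "?",
              nrow(x$gebv), ncol(x$gebv)))
  cat(sprintf("  logLik = %.3f, AIC = %.3f, overall %%EV = %.1f\n",
              x$loglik, x$aic, x$percent_ev$overall))
  invisible(x)
}

#' Percentage of variance explained by the latent factors
#'
#' `pctEV_m = diag(Lambda Lambda')_m / diag(Sigma_g)_m * 100` per
#' environment, and their mean overall.
#'
#' @param Lambda M x K loading matrix.
#' @param Psi specific variances (length M).
#' @return List with `per_env` and `overall`.
#' @export
percent_ev <- function(Lambda, Psi) {
  Lambda <- as.matrix(Lambda)
  common <- rowSums(Lambda^2)
  tot <- common + Psi
  if (any(tot <= 0)) stop("zero total variance in an environment",
                          call. = FALSE)
  per <- 100 * common / tot
  list(per_env = per, overall = mean(per))
}

#' Choose the factor-analytic order
#'
#' Applies the selection rule: the smallest order whose model explains at
#' least `overall_min` percent of the total additive variance with every
#' environment at or above `env_min` percent. If no candidate qualifies, the
#' largest order is returned with a warning. An AIC table accompanies the
#' choice.
#'
#' @param fits list of `stage2_fit`s (or single-stage fits) for increasing
#'   orders.
#' @param overall_min,env_min selection thresholds (percent).
#' @return List with `k` (chosen order), `fit`, and `table`.
#' @export
select_fa_order <- function(fits, overall_min = 90, env_min = 60) {
  stopifnot(length(fits) >= 1)
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(k = f$k, overall_ev = f$percent_ev$overall,
               min_env_ev = min(f$percent_ev$per_env), aic = f$aic)))
  ok <- tab$overall_ev >= overall_min & tab$min_env_ev >= env_min
  if (any(ok)) i <- which(ok)[which.min(tab$k[ok])]
  else {
    i <- which.max(tab$k)
    warning("no candidate met the variance-explained thresholds; ",
            "returning the largest order", call. = FALSE)
  }
  list(k = tab$k[i], fit = fits[[i]], table = tab)
}

#' Additive genetic correlation matrix between environments
#'
#' `Delta Sigma_g Delta` with `Delta = diag(1/sqrt(diag(Sigma_g)))`.
#'
#' @param Sigma_g additive covariance matrix (e.g. from a `stage2_fit`).
#' @return Correlation matrix with unit diagonal.
#' @export
genetic_correlation <- function(Sigma_g) {
  if (inherits(Sigma_g, "stage2_fit")) Sigma_g <- Sigma_g$Sigma_g
  if (any(diag(Sigma_g) <= 0))
    stop("Sigma_g must have positive diagonal", call. = FALSE)
  stats::cov2cor(Sigma_g)
}

#' Partition additive variance into main-effect and interaction components
#'
#' From the across-environment additive covariance `Sigma_g`: the
#' main-effect variance is the mean of the between-environment covariances,
#' `sigma2_G = 2 sum_{m<m'} sigma_g[m,m'] / (M (M-1))`; the interaction
#' variance is `sigma2_GEI = mean(diag(Sigma_g)) - sigma2_G`; its
#' heterogeneity-of-scale part is the variance of the per-environment
#' genetic standard deviations, `sigma2_GEI_h = mean((sd_m - mean(sd))^2)`;
#' and the lack-of-correlation part is the remainder.
#'
#' @param Sigma_g additive covariance matrix (`M >= 2`).
#' @return List of class `gei_partition`: `sigma2_G`, `sigma2_GEI`,
#'   `sigma2_GEI_h`, `sigma2_GEI_l`, and `proportions` (of the total
#'   `sigma2_G + sigma2_GEI`).
#' @export
partition_gei <- function(Sigma_g) {
  if (inherits(Sigma_g, "stage2_fit")) Sigma_g <- Sigma_g$Sigma_g
  M <- nrow(Sigma_g)
  if (M < 2) stop("at least two environments required", call. = FALSE)
  off <- Sigma_g[upper.tri(Sigma_g)]
  s2G <- mean(off)
  s2GEI <- mean(diag(Sigma_g)) - s2G
  sds <- sqrt(diag(Sigma_g))
  s2h <- mean((sds - mean(sds))^2)
  s2l <- s2GEI - s2h
  tot <- s2G + s2GEI
  structure(list(sigma2_G = s2G, sigma2_GEI = s2GEI, sigma2_GEI_h = s2h,
                 sigma2_GEI_l = s2l,
                 proportions = c(main = s2G, gei_heterogeneity = s2h,
                                 gei_lack_correlation = s2l) / tot),
            class = "gei_partition")
}

#' @export
print.gei_partition <- function(x, ...) {
  cat(sprintf("Additive variance partition: main %.3f, GEI %.3f (heterogeneity %.3f + lack of correlation %.3f)\n",
              x$sigma2_G, x$sigma2_GEI, x$sigma2_GEI_h, x$sigma2_GEI_l))
  p <- round(100 * x$proportions, 1)
  cat(sprintf("  proportions: main %.1f%%, heterogeneity %.1f%%, lack of correlation %.1f%%\n",
              p[1], p[2], p[3]))
  invisible(x)
}
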