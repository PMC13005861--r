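## Single-stage benchmark: one joint REML fit of all plot records across
## environments, with genetic effects nested within environments for the
## genotyped individuals and ungenotyped treatments moved to the fixed part.

#' Fit the single-stage multi-environment model
#'
#' Fits `y = X f + g + r + c + rc + e` on plot data across all environments:
#' combined fixed effects `f` (intercept, pool, environment, checks,
#' check-by-environment, and treatments without marker data); additive
#' effects `a ~ N(0, (Lambda Lambda' + Psi) (x) G)` (factor-analytic order
#' `k`) plus heterogeneous compound-symmetry non-additive effects for the
#' genotyped treatments, nested within environments; i.i.d. row-group,
#' column-group and block effects (common variances across environments, one
#' level set per environment); and per-environment AR1 x AR1 spatial
#' residuals. Aliased fixed-effect columns (e.g. the check pool) are dropped
#' deterministically and reported on the fit.
#'
#' @param data multi-environment plot table (columns `environment`, `row`,
#'   `col`, `row_group`, `col_group`, `block`, `treatment`, `role`, `pool`,
#'   `y`).
#' @param G genomic `relmatrix` (or matrix) over the genotyped individuals.
#' @param k number of latent factors.
#' @param fixed optional frozen parameters, as in [fit_stage_two()] plus
#'   `sigma2_rg`, `sigma2_cg`, `sigma2_b` and residual
#'   `list(sigma2, rho_r, rho_c)` via `residual`.
#' @param spatial set `FALSE` to use an i.i.d. residual (used by the
#'   two-stage/single-stage equivalence analysis).
#' @param control a [reml_control()].
#' @return Object of class `singlestage_fit` with the same genetic summary
#'   components as [fit_stage_two()] (`Lambda`, `Psi`, `Sigma_g`,
#'   `sigma2_na`, `rho`, `percent_ev`, `gebv`, `gebv_mean`, `pev`, `aic`)
#'   plus per-environment heritabilities (`h2`, `H2`, using
#'   `theta = mean(diag(G)) - mean(G)`) and the fitted `remlx` object.
#' @export
fit_single_stage <- function(data, G, k, fixed = NULL, spatial = TRUE,
                             control = reml_control()) {
  Gm <- .relmat(G)
  d <- as.data.frame(data)
  need <- c("environment", "treatment", "role", "y")
  if (spatial) need <- c(need, "row", "col")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing plot-table columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (spatial && (anyNA(d$row) || anyNA(d$col)))
    stop("plot coordinates required in every environment", call. = FALSE)
  M <- length(unique(d$environment))
  if (k > M) stop("number of factors exceeds number of environments",
                  call. = FALSE)
  if (is.null(d$pool)) d$pool <- "P"
  d$geno <- ifelse(d$role != "check" & d$treatment %in% rownames(Gm),
                   d$treatment, NA_character_)
  d$check <- stats::relevel(
    factor(ifelse(d$role == "check", d$treatment, "none")), ref = "none")
  d$ungeno <- stats::relevel(
    factor(ifelse(d$role != "check" & !(d$treatment %in% rownames(Gm)),
                  d$treatment, "genotyped")), ref = "genotyped")
  for (v in c("row_group", "col_group", "block"))
    if (!is.null(d[[v]]))
      d[[paste0("env_", v)]] <- paste(d$environment, d[[v]], sep = ":")

  fa_fix <- fixed[intersect(names(fixed), c("Lambda", "Psi"))]
  if (!length(fa_fix)) fa_fix <- NULL
  na_fix <- list(sigma2 = fixed$sigma2_na, rho = fixed$rho)
  if (!length(Filter(Negate(is.null), na_fix))) na_fix <- NULL
  random <- list(
    ran_fa("geno", "environment", Gm, k, fixed = fa_fix, name = "fa"),
    ran_hetcs("geno", "environment", fixed = na_fix, ids = rownames(Gm),
              name = "na"))
  f <- function(nm) fixed[[nm]]
  des_cols <- c(row_group = "sigma2_rg", col_group = "sigma2_cg",
                block = "sigma2_b")
  for (v in names(des_cols))
    if (!is.null(d[[paste0("env_", v)]]))
      random <- c(random, list(ran_iid(paste0("env_", v),
                                       fixed = f(des_cols[[v]]), name = v)))
  residual <- if (spatial)
    res_ar1ar1(fixed = fixed$residual)
  else res_iid(fixed = fixed$sigma2_e)
  terms <- character(0)
  if (M > 1) terms <- "environment"
  if (nlevels(d$check) > 1) {
    terms <- c(terms, "check")
    if (M > 1) terms <- c(terms, "environment:check")
  }
  if (length(unique(d$pool)) > 1) terms <- c(terms, "pool")
  if (nlevels(d$ungeno) > 1) terms <- c(terms, "ungeno")
  form <- if (length(terms)) stats::reformulate(terms, response = "y")
  else y ~ 1
  fit <- reml(form, d, random = random, residual = residual,
              control = control)

  out <- .stage2_extract(fit, Gm, k)
  theta <- rel_theta(Gm)
  s2a <- diag(out$Sigma_g)
  envs <- colnames(out$Sigma_g)
  pv <- stats::setNames(fit$par$value, fit$par$par)
  s2e <- if (spatial) unname(pv[sprintf("residual.sigma2[%s]", envs)])
  else rep(unname(pv["residual.sigma2"]), M)
  out$sigma2_e <- stats::setNames(s2e, envs)
  out$theta <- theta
  out$h2 <- stats::setNames(
    theta * s2a / (theta * s2a + out$sigma2_na + s2e), envs)
  out$H2 <- stats::setNames(
    (theta * s2a + out$sigma2_na) / (theta * s2a + out$sigma2_na + s2e),
    envs)
  out$weight_mode <- "ss"
  class(out) <- c("singlestage_fit", "stage2_fit")
  out
}

#' @export
print.singlestage_fit <- function(x, ...) {
  cat(sprintf("Single-stage FA(%d) fit: %d genotypes x %d environments\n",
              x$k, nrow(x$gebv), ncol(x$gebv)))
  cat(sprintf("  logLik = %.3f, AIC = %.3f, overall %%EV = %.1f\n",
              x$loglik, x$aic, x$percent_ev$overall))
  cat(sprintf("  h2: %s\n  H2: %s\n",
              paste(sprintf("%s %.3f", names(x$h2), x$h2), collapse = ", "),
              paste(sprintf("%s %.3f", names(x$H2), x$H2), collapse = ", ")))
  invisible(x)
}

#' Corrected phenotypes from a single-stage fit
#'
#' Per plot, `y - f` with `f` the fitted fixed part; averaged per
#' genotype-environment cell. These are the single-stage analogues of the
#' second-stage entries for prediction-error computations.
#'
#' @param ss a `singlestage_fit`.
#' @param data the plot table the model was fitted to.
#' @return Data frame with `environment`, `geno`, `y_star`.
#' @export
corrected_phenotypes <- function(ss, data) {
  fit <- ss$fit
  d <- as.data.frame(data)
  if (nrow(d) != fit$n)
    stop("data does not match the fitted model", call. = FALSE)
  d$geno <- ifelse(d$role != "check" & d$treatment %in% rownames(ss$gebv),
                   d$treatment, NA_character_)
  y_star <- d$y - drop(fit$X %*% fit$beta)
  keep <- !is.na(d$geno)
  agg <- stats::aggregate(y_star[keep],
                          by = list(environment = d$environment[keep],
                                    geno = d$geno[keep]), FUN = mean)
  names(agg)[3] <- "y_star"
  agg
}
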