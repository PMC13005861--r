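## Cross-validation (CV1: untested genotypes; CV2: sparse testing of
## genotype-by-environment cells), predictive ability, theoretical accuracy,
## mean-squared prediction error and selection concordance.

#' Cross-validation plan
#'
#' @param scheme `"cv1"` (mask whole genotypes across all environments) or
#'   `"cv2"` (mask genotype-by-environment cells, stratified by environment
#'   so each fold holds about `1/folds` of every environment's cells).
#' @param folds number of folds.
#' @param reps number of repetitions (fold compositions).
#' @param seed master seed; repetition `r` uses a derived sub-stream.
#' @export
cv_plan <- function(scheme = c("cv1", "cv2"), folds = 5, reps = 30,
                    seed = 1L) {
  scheme <- match.arg(scheme)
  structure(list(scheme = scheme, folds = folds, reps = reps,
                 seed = as.integer(seed)), class = "cv_plan")
}

#' Fold assignment for one repetition
#'
#' Partitions the masking units into `plan$folds` near-equal folds,
#' optionally stratified (balanced within each stratum). Reproducible from
#' the plan seed and the repetition number.
#'
#' @param units character vector of masking units (genotypes for CV1,
#'   `environment:genotype` cells for CV2).
#' @param plan a [cv_plan()].
#' @param rep repetition number.
#' @param strata optional stratum per unit (the environment for CV2).
#' @return Named integer vector of fold ids.
#' @export
make_folds <- function(units, plan, rep = 1, strata = NULL) {
  k <- plan$folds
  if (length(units) < k)
    stop("fewer masking units than folds", call. = FALSE)
  set.seed(subseed(plan$seed, 7000 + rep))
  fold <- integer(length(units))
  if (is.null(strata)) strata <- rep(1, length(units))
  for (s in unique(strata)) {
    i <- which(strata == s)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  stats::setNames(fold, units)
}

.cv_units <- function(d, scheme) {
  if (scheme == "cv1") {
    units <- sort(unique(d$geno))
    list(units = units, strata = NULL)
  } else {
    cells <- unique(d[, c("environment", "geno")])
    cells <- cells[order(cells$environment, cells$geno), ]
    list(units = paste(cells$environment, cells$geno, sep = ":"),
         strata = cells$environment)
  }
}

.masked_rows <- function(d, scheme, masked_units) {
  if (scheme == "cv1") d$geno %in% masked_units
  else paste(d$environment, d$geno, sep = ":") %in% masked_units
}

.pa_within_env <- function(obs, pred, env) {
  vapply(split(seq_along(obs), env), function(i) {
    if (length(i) < 3 || stats::sd(obs[i]) == 0 || stats::sd(pred[i]) == 0)
      return(NA_real_)
    stats::cor(obs[i], pred[i])
  }, numeric(1))
}

#' Cross-validate a two-stage model family
#'
#' Runs CV1 or CV2 on the second-stage model: the first stage is *not*
#' re-run per fold — masking operates on the entries, mirroring the
#' evaluation of the second-stage model itself. Held-out entries are
#' predicted by the GEBVs of the model refitted on the training entries
#' (the genomic relationship propagates information to untested genotypes).
#' Predictive ability is the Pearson correlation between held-out entries
#' and predicted GEBVs, computed within environment and averaged; the
#' mean-squared prediction error compares held-out entries with GEBVs
#' directly.
#'
#' @param es weighted `entry_set` (restricted to genotyped individuals).
#' @param G genomic `relmatrix`.
#' @param k factor-analytic order.
#' @param plan a [cv_plan()].
#' @param reuse_vc estimate variance components once on the full entries and
#'   reuse across folds (fast); with `FALSE`, variance components are
#'   re-estimated in every fold.
#' @param fixed optionally freeze all second-stage parameters (list as in
#'   [fit_stage_two()]); implies no full-data fit and no leakage of held-out
#'   records into variance-component estimation.
#' @param detail keep the per-unit observed/predicted pairs.
#' @param control a [reml_control()].
#' @return Object of class `cv_result`: per-repetition table (`pa`, `mspe`),
#'   `summary` (mean and sd), the plan, the label of the family, and (with
#'   `detail = TRUE`) a `detail` data frame of held-out predictions.
#' @export
cv_two_stage <- function(es, G, k, plan, reuse_vc = TRUE, fixed = NULL,
                         detail = FALSE, control = reml_control()) {
  Gm <- .relmat(G)
  stk <- if (inherits(es, "entry_set")) stack_entries(es) else es
  d <- stk$data
  u <- .cv_units(d, plan$scheme)
  vc_full <- fixed
  if (is.null(fixed) && reuse_vc) {
    full <- fit_stage_two(es, Gm, k, control = control)
    vc_full <- list(Lambda = full$Lambda, Psi = full$Psi,
                    sigma2_na = full$sigma2_na, rho = full$rho,
                    sigma2_e = full$sigma2_e)
  }
  per_rep <- data.frame(rep = seq_len(plan$reps), pa = NA_real_,
                        mspe = NA_real_)
  failed <- 0L
  det <- if (detail) vector("list", plan$reps) else NULL
  for (r in seq_len(plan$reps)) {
    fold <- make_folds(u$units, plan, r, u$strata)
    obs <- pred <- env <- geno <- NULL
    for (f in seq_len(plan$folds)) {
      masked <- .masked_rows(d, plan$scheme, names(fold)[fold == f])
      train <- list(data = d[!masked, , drop = FALSE],
                    Omega = stk$Omega[!masked, !masked, drop = FALSE])
      vc <- vc_full
      fit <- tryCatch(
        fit_stage_two(train, Gm, k,
                      fixed = if (reuse_vc || !is.null(fixed)) vc else NULL,
                      control = control),
        error = function(e) NULL)
      if (is.null(fit)) { failed <- failed + 1L; next }
      dm <- d[masked, , drop = FALSE]
      obs <- c(obs, dm$y)
      pred <- c(pred, fit$gebv[cbind(dm$geno, dm$environment)])
      env <- c(env, dm$environment)
      geno <- c(geno, dm$geno)
    }
    if (is.null(obs)) next
    per_rep$pa[r] <- mean(.pa_within_env(obs, pred, env), na.rm = TRUE)
    per_rep$mspe[r] <- mean((obs - pred)^2)
    if (detail)
      det[[r]] <- data.frame(rep = r, environment = env, geno = geno,
                             obs = obs, pred = pred,
                             stringsAsFactors = FALSE)
  }
  structure(list(per_rep = per_rep,
                 detail = if (detail) do.call(rbind, det) else NULL,
                 summary = c(pa = mean(per_rep$pa, na.rm = TRUE),
                             pa_sd = stats::sd(per_rep$pa, na.rm = TRUE),
                             mspe = mean(per_rep$mspe, na.rm = TRUE),
                             mspe_sd = stats::sd(per_rep$mspe, na.rm = TRUE)),
                 plan = plan, failed_folds = failed,
                 family = if (inherits(es, "entry_set"))
                   sprintf("2S-%s-%s", es$kind, toupper(es$weight_mode))
                 else "2S"),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%s %s (%d folds x %d reps): predictive ability %.3f (sd %.3f), MSPE %.2f (sd %.2f)\n",
              x$family, toupper(x$plan$scheme), x$plan$folds, x$plan$reps,
              s["pa"], s["pa_sd"], s["mspe"], s["mspe_sd"]))
  if (x$failed_folds > 0)
    cat(sprintf("  %d folds failed to converge and were excluded\n",
                x$failed_folds))
  invisible(x)
}

#' Cross-validate the single-stage model
#'
#' Masks plot records of held-out genotypes (CV1) or genotype-by-environment
#' cells (CV2), refits the single-stage model on the remaining plots
#' (variance components reused from the full-data fit), and evaluates
#' held-out cells through the Pearson correlation between predicted GEBVs
#' and corrected phenotypes (within environment, averaged), the theoretical
#' accuracy ([theoretical_accuracy()]) of the masked predictions, and the
#' mean-squared prediction error against corrected phenotypes.
#'
#' @param data multi-environment plot table.
#' @param G genomic `relmatrix`.
#' @param k factor order.
#' @param plan a [cv_plan()].
#' @param spatial passed to [fit_single_stage()].
#' @param control a [reml_control()].
#' @return A `cv_result` whose per-repetition table also carries the mean
#'   theoretical accuracy `acc`.
#' @export
cv_single_stage <- function(data, G, k, plan, spatial = TRUE,
                            control = reml_control()) {
  Gm <- .relmat(G)
  d <- as.data.frame(data)
  full <- fit_single_stage(d, Gm, k, spatial = spatial, control = control)
  vc <- list(Lambda = full$Lambda, Psi = full$Psi,
             sigma2_na = full$sigma2_na, rho = full$rho)
  pv <- stats::setNames(full$fit$par$value, full$fit$par$par)
  if (spatial) {
    envs <- sort(unique(d$environment))
    vc$residual <- list(sigma2 = unname(pv[sprintf("residual.sigma2[%s]", envs)]),
                        rho_r = unname(pv[sprintf("residual.rho_r[%s]", envs)]),
                        rho_c = unname(pv[sprintf("residual.rho_c[%s]", envs)]))
  } else vc$sigma2_e <- unname(pv["residual.sigma2"])
  for (nm in c("row_group", "col_group", "block")) {
    v <- pv[paste0(nm, ".sigma2")]
    if (!is.na(v)) vc[[c(row_group = "sigma2_rg", col_group = "sigma2_cg",
                         block = "sigma2_b")[nm]]] <- unname(v)
  }
  cp <- corrected_phenotypes(full, d)
  cp$cell <- paste(cp$environment, cp$geno, sep = ":")
  dcells <- data.frame(environment = cp$environment, geno = cp$geno)
  u <- .cv_units(dcells, plan$scheme)
  Fv <- (diag(Gm)[rownames(full$gebv)] - 1) / 5
  s2a_env <- diag(full$Sigma_g)

  per_rep <- data.frame(rep = seq_len(plan$reps), pa = NA_real_,
                        acc = NA_real_, mspe = NA_real_)
  failed <- 0L
  for (r in seq_len(plan$reps)) {
    fold <- make_folds(u$units, plan, r, u$strata)
    obs <- pred <- env <- acc <- NULL
    for (f in seq_len(plan$folds)) {
      masked_units <- names(fold)[fold == f]
      dmask <- .masked_rows(
        data.frame(environment = d$environment,
                   geno = ifelse(d$role != "check" &
                                   d$treatment %in% rownames(Gm),
                                 d$treatment, NA_character_)),
        plan$scheme, masked_units)
      dmask[is.na(dmask)] <- FALSE
      fit <- tryCatch(
        fit_single_stage(d[!dmask, , drop = FALSE], Gm, k, fixed = vc,
                         spatial = spatial, control = control),
        error = function(e) NULL)
      if (is.null(fit)) { failed <- failed + 1L; next }
      cells <- cp[cp$cell %in% masked_units |
                    (plan$scheme == "cv1" & cp$geno %in% masked_units), ]
      if (!nrow(cells)) next
      obs <- c(obs, cells$y_star)
      pred <- c(pred, fit$gebv[cbind(cells$geno, cells$environment)])
      env <- c(env, cells$environment)
      acc <- c(acc, theoretical_accuracy(
        fit$pev[cbind(cells$geno, cells$environment)],
        s2a_env[cells$environment], Fv[cells$geno], quiet = TRUE))
    }
    if (is.null(obs)) next
    per_rep$pa[r] <- mean(.pa_within_env(obs, pred, env), na.rm = TRUE)
    per_rep$acc[r] <- mean(acc, na.rm = TRUE)
    per_rep$mspe[r] <- mean((obs - pred)^2)
  }
  structure(list(per_rep = per_rep,
                 summary = c(pa = mean(per_rep$pa, na.rm = TRUE),
                             pa_sd = stats::sd(per_rep$pa, na.rm = TRUE),
                             acc = mean(per_rep$acc, na.rm = TRUE),
                             mspe = mean(per_rep$mspe, na.rm = TRUE),
                             mspe_sd = stats::sd(per_rep$mspe, na.rm = TRUE)),
                 plan = plan, failed_folds = failed, family = "SS"),
            class = "cv_result")
}

#' Theoretical accuracy of a genomic prediction
#'
#' `r = sqrt(1 - PEV / (sigma2_a (1 + 5 F)))` for a hexaploid, with `F` the
#' inbreeding coefficient from the diagonal of the genomic relationship
#' matrix (`G_vv = 1 + 5 F_v`). A negative radicand (PEV exceeding the
#' genetic variance of the individual) is clipped to zero with a warning.
#'
#' @param pev prediction error variance(s).
#' @param sigma2_a additive genetic variance (scalar or vector).
#' @param F inbreeding coefficient(s), default 0.
#' @param quiet suppress the clipping warning.
#' @return Accuracies in `[0, 1]`.
#' @export
theoretical_accuracy <- function(pev, sigma2_a, F = 0, quiet = FALSE) {
  if (any(sigma2_a <= 0)) stop("sigma2_a must be positive", call. = FALSE)
  rad <- 1 - pev / (sigma2_a * (1 + 5 * F))
  if (any(rad < 0) && !quiet)
    warning("PEV exceeded sigma2_a (1 + 5F) for some individuals; ",
            "accuracy clipped to 0", call. = FALSE)
  sqrt(pmax(rad, 0))
}

#' Mean-squared prediction error
#'
#' `MSPE = mean((y_star - a_hat)^2)` over matched individuals.
#'
#' @param y_star observed entries or corrected phenotypes (named or not).
#' @param a_hat predicted GEBVs; if both vectors are named they are matched
#'   by name and must contain the same ids.
#' @return Scalar MSPE.
#' @export
mspe <- function(y_star, a_hat) {
  if (!is.null(names(y_star)) && !is.null(names(a_hat))) {
    if (!setequal(names(y_star), names(a_hat)))
      stop("mismatched ids between observed and predicted values",
           call. = FALSE)
    a_hat <- a_hat[names(y_star)]
  } else if (length(y_star) != length(a_hat))
    stop("lengths differ and no names to match on", call. = FALSE)
  mean((y_star - a_hat)^2)
}

#' Selection concordance between two candidate rankings
#'
#' Spearman rank correlation between two GEBV vectors plus the coincidence
#' among their top fraction: `|top_a intersect top_b| / ceil(fraction * n)`.
#' Ties are broken by id order.
#'
#' @param gebv_a,gebv_b named numeric vectors over the same candidates.
#' @param fraction selected fraction (default top 10 percent).
#' @return List with `rank_correlation` and `coincidence` (in `[0, 1]`).
#' @export
selection_concordance <- function(gebv_a, gebv_b, fraction = 0.10) {
  stopifnot(!is.null(names(gebv_a)), !is.null(names(gebv_b)))
  if (!setequal(names(gebv_a), names(gebv_b)))
    stop("mismatched candidate ids", call. = FALSE)
  gebv_b <- gebv_b[names(gebv_a)]
  n <- length(gebv_a)
  if (n * fraction < 1) stop("fraction too small: no candidates selected",
                             call. = FALSE)
  n_top <- ceiling(fraction * n)
  top <- function(x) names(x)[order(-x, names(x))][seq_len(n_top)]
  list(rank_correlation = stats::cor(gebv_a, gebv_b, method = "spearman"),
       coincidence = length(intersect(top(gebv_a), top(gebv_b))) / n_top)
}

#' Pool-specific cross-validation
#'
#' Reruns a two-stage cross-validation within one gene pool: genotypes are
#' subset to the pool, allele frequencies and the genomic relationship
#' matrix are recomputed on the subset, and the entry set is restricted and
#' re-weighted before [cv_two_stage()].
#'
#' @param sim a `met_sim` dataset (supplies dosages and pool labels).
#' @param es an `entry_set` (weighted; its weight mode is reapplied after
#'   restriction).
#' @param pool pool label (e.g. `"A"`).
#' @param k factor order.
#' @param plan a [cv_plan()].
#' @param ... passed to [cv_two_stage()].
#' @return A `cv_result`.
#' @export
cv_pool_specific <- function(sim, es, pool, k, plan, ...) {
  mode <- es$weight_mode
  if (is.null(mode)) stop("entry set must carry a weight mode", call. = FALSE)
  ids <- sim$pedigree$id[!is.na(sim$pedigree$pool) &
                           sim$pedigree$pool == pool]
  ids <- intersect(ids, sim$genotyped)
  if (length(ids) < plan$folds)
    stop("pool too small for the requested number of folds", call. = FALSE)
  Gp <- G_matrix(filter_markers(sim$dosage[ids, , drop = FALSE]))
  esp <- make_weights(restrict_entries(es, ids), mode)
  out <- cv_two_stage(esp, Gp, k, plan, ...)
  out$family <- paste0(out$family, "-pool", pool)
  out
}
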