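## Stage one: single-environment analysis of one augmented row-column trial,
## in three variants distinguished by the treatment of the genetic effects,
## followed by deregression and weight construction for the second stage.

.s1_prepare <- function(data) {
  d <- as.data.frame(data)
  need <- c("row", "col", "row_group", "col_group", "block", "treatment",
            "role", "y")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing plot-table columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (length(unique(d$environment %||% "E")) > 1)
    stop("stage one analyses a single environment", call. = FALSE)
  d$geno <- ifelse(d$role == "check", NA_character_, d$treatment)
  d$check <- factor(ifelse(d$role == "check", d$treatment, "none"))
  d$check <- stats::relevel(d$check, ref = "none")
  if (is.null(d$pool)) d$pool <- "P"
  d
}

.design_terms <- function(fixed = NULL) {
  f <- function(nm) if (is.null(fixed)) NULL else fixed[[nm]]
  list(ran_iid("row_group", fixed = f("row_group.sigma2")),
       ran_iid("col_group", fixed = f("col_group.sigma2")),
       ran_iid("block", fixed = f("block.sigma2")))
}

#' Fit a stage-one single-environment model
#'
#' Analyses one augmented row-column trial with the baseline plot model
#' `y = mu + pool + checks + g + rowgroup + colgroup + block + e`,
#' AR1 x AR1 spatial residual, in one of three variants:
#' \describe{
#'   \item{`"blue"`}{genetic effects fixed (treatment-means parameterisation
#'     `y ~ 0 + treatment`, which absorbs pool and check effects); returns
#'     BLUEs.}
#'   \item{`"blup"`}{`g ~ N(0, sigma2_g I)`; pool and checks fixed.}
#'   \item{`"ablup"`}{`g = a + na`, `a ~ N(0, sigma2_a A)` with the pedigree
#'     relationship matrix and `na ~ N(0, sigma2_na I)`.}
#' }
#' For the random variants the genetic variance components are tested by a
#' boundary-corrected likelihood-ratio test ([lr_test()], `L = 1` per
#' component), and heritabilities are computed (broad-sense for `"blup"`;
#' narrow-sense with the correcting factor `theta = mean(diag(A)) - mean(A)`
#' for `"ablup"`).
#'
#' @param data plot table of one environment (columns `row`, `col`,
#'   `row_group`, `col_group`, `block`, `treatment`, `role`, `pool`, `y`).
#' @param variant `"blue"`, `"blup"` or `"ablup"`.
#' @param A pedigree `relmatrix` (required for `"ablup"`).
#' @param lr run the likelihood-ratio tests (doubles the fitting work).
#' @param control a [reml_control()].
#' @return Object of class `stage1_fit`: the underlying `remlx` fit plus
#'   `variant`, `environment`, `varcomp`, `h2`, `H2`, `theta`, `lr_p`,
#'   genetic values (`genetic`), and the prepared data.
#' @export
fit_stage_one <- function(data, variant = c("blue", "blup", "ablup"),
                          A = NULL, lr = TRUE, control = reml_control()) {
  variant <- match.arg(variant)
  d <- .s1_prepare(data)
  if (all(table(d$treatment) < 2))
    stop("no replicated treatments: variance components inestimable",
         call. = FALSE)
  res <- res_ar1ar1(env = "environment", row = "row", col = "col")
  if (is.null(d$environment)) d$environment <- "E"
  des <- .design_terms()

  if (variant == "blue") {
    fit <- reml(y ~ 0 + treatment, d, random = des, residual = res,
                control = control)
    gen <- stats::setNames(fit$beta, sub("^treatment", "", names(fit$beta)))
  } else if (variant == "blup") {
    g <- ran_iid("geno", name = "g")
    fit <- reml(y ~ pool + check, d, random = c(list(g), des),
                residual = res, control = control)
    gen <- fit$blups$g$blup
  } else {
    if (is.null(A)) stop("ablup variant requires the pedigree matrix A",
                         call. = FALSE)
    a <- ran_known("geno", A, name = "a")
    na <- ran_iid("geno", name = "na")
    fit <- reml(y ~ pool + check, d, random = c(list(a, na), des),
                residual = res, control = control)
    gen <- fit$blups$a$blup
  }

  vc <- stats::setNames(fit$par$value, fit$par$par)
  env <- as.character(d$environment[1])
  s2e <- unname(vc[sprintf("residual.sigma2[%s]", env)])
  theta <- if (!is.null(A)) rel_theta(A) else NA_real_
  H2 <- h2 <- NA_real_
  if (variant == "blup") H2 <- unname(vc["g.sigma2"] / (vc["g.sigma2"] + s2e))
  if (variant == "ablup")
    h2 <- unname(theta * vc["a.sigma2"] /
                   (theta * vc["a.sigma2"] + vc["na.sigma2"] + s2e))

  lr_p <- NULL
  if (lr && variant != "blue") {
    refit <- function(random) reml(y ~ pool + check, d, random = random,
                                   residual = res, control = control)
    if (variant == "blup") {
      f0 <- refit(des)
      lr_p <- c(g = lr_test(fit$loglik, f0$loglik, L = 1)$p_value)
    } else {
      fa0 <- refit(c(list(ran_iid("geno", name = "na")), des))
      fna0 <- refit(c(list(ran_known("geno", A, name = "a")), des))
      lr_p <- c(a = lr_test(fit$loglik, fa0$loglik, L = 1)$p_value,
                na = lr_test(fit$loglik, fna0$loglik, L = 1)$p_value)
    }
  }
  structure(list(fit = fit, variant = variant, environment = env,
                 varcomp = vc, sigma2_e = s2e, theta = theta,
                 h2 = h2, H2 = H2, lr_p = lr_p, genetic = gen, data = d),
            class = "stage1_fit")
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat(sprintf("Stage-one %s fit, environment %s (n = %d)\n",
              toupper(x$variant), x$environment, x$fit$n))
  vs <- x$varcomp[!grepl("^residual\\.rho", names(x$varcomp))]
  cat("  variance components:\n")
  for (nm in names(vs)) cat(sprintf("    %-22s %10.4f\n", nm, vs[nm]))
  if (!is.na(x$H2)) cat(sprintf("  H2 = %.3f\n", x$H2))
  if (!is.na(x$h2)) cat(sprintf("  h2 = %.3f (theta = %.3f)\n", x$h2, x$theta))
  if (!is.null(x$lr_p))
    cat("  LR p-values:", paste(sprintf("%s = %.3g", names(x$lr_p), x$lr_p),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Narrow- and broad-sense heritability
#'
#' `h2 = theta sigma2_a / (theta sigma2_a + sigma2_na + sigma2_e)` and
#' `H2 = sigma2_g / (sigma2_g + sigma2_e)`, with `theta` the correcting
#' factor of the relationship matrix used for the additive effects
#' ([rel_theta()]).
#'
#' @param x a `stage1_fit`, or a named list/vector with elements among
#'   `sigma2_a`, `sigma2_na`, `sigma2_g`, `sigma2_e`.
#' @param rel relationship matrix supplying `theta` (defaults to the one
#'   stored in the fit).
#' @return Named vector `c(h2 =, H2 =)` (`NA` where components are absent).
#' @export
heritabilities <- function(x, rel = NULL) {
  if (inherits(x, "stage1_fit")) {
    v <- list(sigma2_a = unname(x$varcomp["a.sigma2"]),
              sigma2_na = unname(x$varcomp["na.sigma2"]),
              sigma2_g = unname(x$varcomp["g.sigma2"]),
              sigma2_e = x$sigma2_e)
    theta <- if (!is.null(rel)) rel_theta(rel) else x$theta
  } else {
    v <- as.list(x)
    theta <- if (!is.null(rel)) rel_theta(rel) else v$theta
  }
  gv <- function(nm) { z <- v[[nm]]; if (is.null(z)) NA_real_ else z }
  s2a <- gv("sigma2_a"); s2na <- gv("sigma2_na")
  s2g <- gv("sigma2_g"); s2e <- gv("sigma2_e")
  if (!is.na(s2e) && s2e < 0 || !is.na(s2a) && s2a < 0 ||
      !is.na(s2na) && s2na < 0 || !is.na(s2g) && s2g < 0)
    stop("variance components must be nonnegative", call. = FALSE)
  h2 <- if (!is.na(s2a)) {
    if (is.na(s2na)) s2na <- 0
    theta * s2a / (theta * s2a + s2na + s2e)
  } else NA_real_
  H2 <- if (!is.na(s2g)) s2g / (s2g + s2e) else NA_real_
  c(h2 = h2, H2 = H2)
}

#' Deregress stage-one predictions into second-stage entries
#'
#' Produces the "entries" carried to the second stage. For the BLUE variant
#' the fit already has fixed genetic effects and its estimates are returned
#' directly. For BLUP/ABLUP variants, the plot model is refitted with the
#' genetic effects as *fixed* (treatment means) while all non-genetic
#' variance components and spatial autocorrelations are frozen at the REML
#' estimates of the supplying fit — removing the shrinkage of the BLUPs
#' (hence "deregressed"). For the ABLUP variant the non-additive variance is
#' also frozen, so the fixed treatment effect targets the additive
#' component. The full covariance `Q` of the entries is taken from the
#' fixed-effect covariance of the refit.
#'
#' @param s1 a `stage1_fit`.
#' @param control a [reml_control()].
#' @return Object of class `entry_block`: `environment`, `kind` (`"BLUE"`,
#'   `"dBLUP"` or `"dABLUP"`), `entries` (named vector over treatments,
#'   checks included but flagged), `Q`, `role` (named role per treatment).
#' @export
deregress <- function(s1, control = reml_control()) {
  stopifnot(inherits(s1, "stage1_fit"))
  d <- s1$data
  vc <- s1$varcomp
  env <- s1$environment
  if (s1$variant == "blue") {
    fit <- s1$fit
    kind <- "BLUE"
  } else {
    des <- .design_terms(fixed = list(
      row_group.sigma2 = unname(vc["row_group.sigma2"]),
      col_group.sigma2 = unname(vc["col_group.sigma2"]),
      block.sigma2 = unname(vc["block.sigma2"])))
    res <- res_ar1ar1(fixed = list(
      sigma2 = unname(vc[sprintf("residual.sigma2[%s]", env)]),
      rho_r = unname(vc[sprintf("residual.rho_r[%s]", env)]),
      rho_c = unname(vc[sprintf("residual.rho_c[%s]", env)])))
    random <- des
    if (s1$variant == "ablup")
      random <- c(list(ran_iid("geno", name = "na",
                               fixed = unname(vc["na.sigma2"]))), des)
    fit <- reml(y ~ 0 + treatment, d, random = random, residual = res,
                control = control)
    kind <- if (s1$variant == "ablup") "dABLUP" else "dBLUP"
  }
  entries <- stats::setNames(fit$beta, sub("^treatment", "", names(fit$beta)))
  Q <- fit$beta_cov
  dimnames(Q) <- list(names(entries), names(entries))
  role <- stats::setNames(d$role[match(names(entries), d$treatment)],
                          names(entries))
  structure(list(environment = env, kind = kind, entries = entries, Q = Q,
                 role = role, weight_mode = NULL),
            class = "entry_block")
}

#' @export
print.entry_block <- function(x, ...) {
  cat(sprintf("Entry block %s (%s): %d entries (%d checks flagged)%s\n",
              x$environment, x$kind, length(x$entries),
              sum(x$role == "check"),
              if (!is.null(x$weight_mode))
                paste0(", weights = ", x$weight_mode) else ""))
  invisible(x)
}

#' Combine per-environment entry blocks
#'
#' @param blocks list of `entry_block`s (one per environment, same kind).
#' @return Object of class `entry_set`.
#' @export
entry_set <- function(blocks) {
  kinds <- unique(vapply(blocks, `[[`, "", "kind"))
  stopifnot(length(kinds) == 1)
  names(blocks) <- vapply(blocks, `[[`, "", "environment")
  structure(list(blocks = blocks, kind = kinds, weight_mode = NULL),
            class = "entry_set")
}

#' Restrict an entry set to given individuals
#'
#' Typically used to keep genotyped, non-check individuals before the
#' second stage; `Q` blocks are subset accordingly.
#'
#' @param es an `entry_set`.
#' @param ids individual ids to keep.
#' @return The restricted `entry_set`.
#' @export
restrict_entries <- function(es, ids) {
  es$blocks <- lapply(es$blocks, function(b) {
    keep <- names(b$entries)[names(b$entries) %in% ids & b$role != "check"]
    b$entries <- b$entries[keep]
    b$Q <- b$Q[keep, keep, drop = FALSE]
    b$role <- b$role[keep]
    b$W <- NULL
    b$weight_mode <- NULL
    b
  })
  es$weight_mode <- NULL
  es
}

.inv_ridge <- function(Q, ridge = 1e-8) {
  out <- tryCatch(solve(Q), error = function(e) NULL)
  if (is.null(out)) {
    Qr <- Q + ridge * mean(diag(Q)) * diag(nrow(Q))
    out <- tryCatch(solve(Qr), error = function(e) NULL)
    if (is.null(out)) stop("entry covariance Q singular even after ridging",
                           call. = FALSE)
    attr(out, "ridged") <- TRUE
  }
  out
}

#' Attach a weighting scheme to an entry set
#'
#' Full weights (`"fw"`) carry each environment's complete entry covariance
#' `Q` into the second stage; diagonal weights (`"dw"`) replace it by the
#' diagonal matrix with entries `1 / [Q^-1]_vv` (the classical
#' diagonal-weight approximation), discarding covariances.
#'
#' @param es an `entry_set` (or single `entry_block`).
#' @param mode `"fw"` or `"dw"`.
#' @return The entry set with per-block weight matrices `W` and
#'   `weight_mode` set.
#' @export
make_weights <- function(es, mode = c("fw", "dw")) {
  mode <- match.arg(mode)
  one <- function(b) {
    if (mode == "fw") b$W <- b$Q
    else {
      Qi <- .inv_ridge(b$Q)
      b$W <- diag(1 / diag(Qi), nrow(b$Q))
      dimnames(b$W) <- dimnames(b$Q)
    }
    b$weight_mode <- mode
    b
  }
  if (inherits(es, "entry_block")) return(one(es))
  es$blocks <- lapply(es$blocks, one)
  es$weight_mode <- mode
  es
}

#' Stack an entry set into second-stage input
#'
#' @param es an `entry_set` with weights attached ([make_weights()]).
#' @return List with `data` (columns `environment`, `geno`, `unit`, `y`) and
#'   the block-diagonal weight covariance `Omega` (dimnames = units).
#' @export
stack_entries <- function(es) {
  stopifnot(inherits(es, "entry_set"))
  if (is.null(es$weight_mode)) stop("call make_weights() first", call. = FALSE)
  dfs <- lapply(es$blocks, function(b)
    data.frame(environment = b$environment, geno = names(b$entries),
               unit = paste(b$environment, names(b$entries), sep = ":"),
               y = unname(b$entries), stringsAsFactors = FALSE))
  data <- do.call(rbind, dfs)
  rownames(data) <- NULL
  q <- nrow(data)
  Omega <- matrix(0, q, q, dimnames = list(data$unit, data$unit))
  at <- 0
  for (b in es$blocks) {
    k <- length(b$entries)
    Omega[at + seq_len(k), at + seq_len(k)] <- b$W
    at <- at + k
  }
  list(data = data, Omega = Omega)
}
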