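## Dense REML engine.
##
## Linear mixed models y = X beta + sum_t Z_t u_t + e are represented by a
## fixed-part formula plus a list of random-term objects, each carrying a
## covariance structure with free and/or frozen parameters. The restricted
## log-likelihood is evaluated by dense algebra on V = sum Z G Z' + R using
## the orthonormal error-contrast convention
##   l_R = -1/2 [ (n-p) log 2pi + log|V| + log|X'V^-1 X| - log|X'X| + y'Py ],
## and maximised by quasi-Newton iteration on transformed parameters
## (log variances, atanh correlations, unconstrained lower-triangular
## loadings). Structure contributions to V are assembled directly as n x n
## blocks through index matrices, which keeps an evaluation at O(n^2) plus
## one Cholesky factorisation.

#' Control options for [reml()]
#'
#' @param n_starts number of optimisation starts; defaults to 3 when the
#'   model contains a factor-analytic term (whose likelihood may be
#'   multimodal) and 1 otherwise.
#' @param iter_max iteration cap passed to the optimiser.
#' @param rel_tol relative convergence tolerance on the objective.
#' @param jitter_sd standard deviation of the start jitter (transformed
#'   scale) for starts beyond the first.
#' @param seed seed used only for start jitter.
#' @param verbose print optimiser progress.
#' @export
reml_control <- function(n_starts = NULL, iter_max = 500, rel_tol = 1e-8,
                         jitter_sd = 0.3, seed = 1L, verbose = FALSE) {
  list(n_starts = n_starts, iter_max = iter_max, rel_tol = rel_tol,
       jitter_sd = jitter_sd, seed = seed, verbose = verbose)
}

## ---- parameter transforms -------------------------------------------------

.to_nat <- function(theta, trans) {
  switch(trans,
         log = exp(pmin(theta, 30)),
         corr = tanh(theta),
         id = theta)
}
.to_work <- function(x, trans) {
  switch(trans,
         log = log(pmax(x, 1e-12)),
         corr = atanh(pmin(pmax(x, -0.999), 0.999)),
         id = x)
}

.partab <- function(names, trans, init, fixed_values = NULL) {
  fixed <- rep(FALSE, length(names))
  value <- init
  if (!is.null(fixed_values)) {
    stopifnot(length(fixed_values) == length(names))
    fixed <- !is.na(fixed_values)
    value[fixed] <- fixed_values[fixed]
  }
  data.frame(par = names, trans = trans, init = init, fixed = fixed,
             value = value, stringsAsFactors = FALSE)
}

## index K by possibly-NA positions, NA rows/cols contribute zero
.aug_index <- function(K, idx) {
  n <- nrow(K)
  Ka <- matrix(0, n + 1, n + 1)
  Ka[seq_len(n), seq_len(n)] <- K
  idx[is.na(idx)] <- n + 1L
  Ka[idx, idx]
}

.indicator <- function(idx, q) {
  n <- length(idx)
  Z <- matrix(0, n, q)
  ok <- !is.na(idx)
  Z[cbind(which(ok), idx[ok])] <- 1
  Z
}

## ---- random-term constructors --------------------------------------------

#' Random-term and residual constructors for [reml()]
#'
#' These helpers declare the covariance structure of each random term:
#' \describe{
#'   \item{`ran_iid(column)`}{i.i.d. effects, `sigma2 * I` over the levels of
#'     `data[[column]]`.}
#'   \item{`ran_known(column, K)`}{`sigma2 * K` for a known relationship
#'     matrix `K` (a [G_matrix()]/[A_matrix()] result or plain matrix with
#'     dimnames); data rows whose level is absent from `K` load zero.}
#'   \item{`ran_fa(geno, env, K, k)`}{factor-analytic genotype-by-environment
#'     effects with covariance `(Lambda Lambda' + diag(Psi)) (x) K`, `Lambda`
#'     an `M x k` lower-triangular loading matrix.}
#'   \item{`ran_hetcs(geno, env)`}{heterogeneous compound-symmetry
#'     genotype-by-environment effects,
#'     `sqrt(D)[I + rho (J - I)]sqrt(D) (x) I`.}
#'   \item{`ran_knownfull(column, Q)`}{an effect with fully known covariance
#'     `Q` (no free parameter), e.g. the first-stage error carried into a
#'     weighted second-stage model.}
#'   \item{`res_iid()`}{i.i.d. residual `sigma2 * I`.}
#'   \item{`res_ar1ar1(env, row, col)`}{per-environment separable spatial
#'     residual `sigma2_m AR1(rho_r_m) (x) AR1(rho_c_m)` evaluated at the
#'     observed plot coordinates.}
#' }
#' Parameters may be frozen at known values through `fixed`; frozen
#' parameters are never updated and do not count towards the AIC penalty.
#'
#' @param column,geno,env,row,col column names in `data`.
#' @param K relationship matrix (or `relmatrix` object).
#' @param k number of latent factors.
#' @param Q known covariance matrix with dimnames identifying units.
#' @param fixed frozen parameter values: a single variance for `ran_iid`/
#'   `ran_known`/`res_iid`; `list(Lambda =, Psi =)` for `ran_fa`;
#'   `list(sigma2 =, rho =)` for `ran_hetcs`; `list(sigma2 =, rho_r =,
#'   rho_c =)` (recycled over environments) for `res_ar1ar1`.
#' @param ids optional identity-block ids for `ran_hetcs` (defaults to the
#'   distinct values of `data[[geno]]`).
#' @param init optional initial values, same shapes as `fixed`.
#' @param name term label.
#' @param lb lower bound added to the residual variance of `res_iid`
#'   (guards confounding with a known-covariance term).
#' @name reml-terms
NULL

.relmat <- function(K) if (inherits(K, "relmatrix")) K$mat else as.matrix(K)

#' @rdname reml-terms
#' @export
ran_iid <- function(column, fixed = NULL, init = NULL, name = column) {
  structure(list(type = "iid", column = column, fixed = fixed, init = init,
                 name = name), class = "reml_term")
}

#' @rdname reml-terms
#' @export
ran_known <- function(column, K, fixed = NULL, init = NULL, name = column) {
  structure(list(type = "known", column = column, K = .relmat(K),
                 fixed = fixed, init = init, name = name),
            class = "reml_term")
}

#' @rdname reml-terms
#' @export
ran_fa <- function(geno, env, K, k, fixed = NULL, init = NULL, name = "fa") {
  structure(list(type = "fa", geno = geno, env = env, K = .relmat(K), k = k,
                 fixed = fixed, init = init, name = name),
            class = "reml_term")
}

#' @rdname reml-terms
#' @export
ran_hetcs <- function(geno, env, fixed = NULL, init = NULL, ids = NULL,
                      name = "hetcs") {
  structure(list(type = "hetcs", geno = geno, env = env, fixed = fixed,
                 init = init, ids = ids, name = name), class = "reml_term")
}

#' @rdname reml-terms
#' @export
ran_knownfull <- function(column, Q, name = "known_full") {
  structure(list(type = "knownfull", column = column, Q = as.matrix(Q),
                 name = name), class = "reml_term")
}

#' @rdname reml-terms
#' @export
res_iid <- function(fixed = NULL, init = NULL, lb = 0, name = "residual") {
  structure(list(type = "riid", fixed = fixed, init = init, lb = lb,
                 name = name), class = "reml_term")
}

#' @rdname reml-terms
#' @export
res_ar1ar1 <- function(env = "environment", row = "row", col = "col",
                       fixed = NULL, init = NULL, name = "residual") {
  structure(list(type = "rar1", env = env, row = row, col = col,
                 fixed = fixed, init = init, name = name),
            class = "reml_term")
}

## ---- term realisation -----------------------------------------------------

## returns list(par, covn(nat) -> n x n, blup(nat) -> list(Z, Gq, levels) | NULL)
.realize <- function(term, data, v0) {
  n <- nrow(data)
  switch(
    term$type,
    iid = {
      v <- as.character(data[[term$column]])
      lev <- sort(unique(v[!is.na(v)]))
      idx <- match(v, lev)
      E <- outer(idx, idx, function(a, b) !is.na(a) & !is.na(b) & a == b) * 1
      init <- if (!is.null(term$init)) term$init else v0 / 4
      par <- .partab(paste0(term$name, ".sigma2"), "log", init,
                     if (!is.null(term$fixed)) term$fixed else NA)
      list(par = par,
           covn = function(nat) nat[1] * E,
           blup = function(nat) list(Z = .indicator(idx, length(lev)),
                                     Gq = nat[1] * diag(length(lev)),
                                     levels = lev))
    },
    known = {
      K <- term$K
      lev <- rownames(K)
      idx <- match(as.character(data[[term$column]]), lev)
      Kn <- .aug_index(K, idx)
      init <- if (!is.null(term$init)) term$init else v0 / 4
      par <- .partab(paste0(term$name, ".sigma2"), "log", init,
                     if (!is.null(term$fixed)) term$fixed else NA)
      list(par = par,
           covn = function(nat) nat[1] * Kn,
           blup = function(nat) list(Z = .indicator(idx, nrow(K)),
                                     Gq = nat[1] * K, levels = lev))
    },
    fa = {
      K <- term$K
      lev <- rownames(K)
      envf <- factor(as.character(data[[term$env]]))
      M <- nlevels(envf); k <- term$k
      if (k > M) stop("number of factors exceeds number of environments",
                      call. = FALSE)
      mi <- as.integer(envf)
      vi <- match(as.character(data[[term$geno]]), lev)
      Vq <- nrow(K)
      Kn <- .aug_index(K, vi)
      mi0 <- mi; mi0[is.na(vi)] <- 1L   # masked by zero in Kn
      free_lam <- which(lower.tri(matrix(0, M, k), diag = TRUE))
      lam_names <- sprintf("%s.lambda[%d,%d]", term$name,
                           row(matrix(0, M, k))[free_lam],
                           col(matrix(0, M, k))[free_lam])
      psi_names <- sprintf("%s.psi[%d]", term$name, seq_len(M))
      lam_init <- rep(0, length(free_lam))
      lam_init[match(which(row(matrix(0, M, k)) == col(matrix(0, M, k)) &
                             lower.tri(matrix(0, M, k), diag = TRUE)),
                     free_lam)] <- sqrt(v0 / (4 * k))
      psi_init <- rep(v0 / 8, M)
      fixedv <- rep(NA_real_, length(free_lam) + M)
      if (!is.null(term$fixed$Lambda)) {
        L <- as.matrix(term$fixed$Lambda)
        fixedv[seq_along(free_lam)] <- L[free_lam]
      }
      if (!is.null(term$fixed$Psi))
        fixedv[length(free_lam) + seq_len(M)] <- term$fixed$Psi
      if (!is.null(term$init)) {
        L <- as.matrix(term$init$Lambda)
        lam_init <- L[free_lam]; psi_init <- term$init$Psi
      }
      par <- .partab(c(lam_names, psi_names),
                     c(rep("id", length(free_lam)), rep("log", M)),
                     c(lam_init, psi_init), fixedv)
      mk_sigma <- function(nat) {
        L <- matrix(0, M, k)
        L[free_lam] <- nat[seq_along(free_lam)]
        tcrossprod(L) + diag(nat[length(free_lam) + seq_len(M)], M)
      }
      list(par = par, M = M, k = k, free_lam = free_lam,
           covn = function(nat) {
             Sg <- mk_sigma(nat)
             Sg[mi0, mi0] * Kn
           },
           mk_sigma = mk_sigma,
           blup = function(nat) {
             q <- M * Vq
             col_idx <- ifelse(is.na(vi), NA_integer_, (mi - 1L) * Vq + vi)
             Z <- .indicator(col_idx, q)
             Gq <- kronecker(mk_sigma(nat), K)
             levels <- as.vector(outer(lev, levels(envf),
                                       function(g, e) paste(e, g, sep = ":")))
             list(Z = Z, Gq = Gq, levels = levels,
                  env_levels = levels(envf), geno_levels = lev)
           })
    },
    hetcs = {
      envf <- factor(as.character(data[[term$env]]))
      M <- nlevels(envf)
      mi <- as.integer(envf)
      g <- as.character(data[[term$geno]])
      lev <- if (!is.null(term$ids)) term$ids else sort(unique(g))
      vi <- match(g, lev)
      Eg <- (outer(vi, vi, function(a, b) !is.na(a) & !is.na(b) & a == b)) * 1
      sig_names <- sprintf("%s.sigma2[%d]", term$name, seq_len(M))
      init <- rep(v0 / 6, M); rinit <- 0.1
      fixedv <- rep(NA_real_, M + 1)
      if (!is.null(term$fixed$sigma2)) fixedv[seq_len(M)] <- term$fixed$sigma2
      if (!is.null(term$fixed$rho)) fixedv[M + 1] <- term$fixed$rho
      if (!is.null(term$init)) { init <- term$init$sigma2; rinit <- term$init$rho }
      par <- .partab(c(sig_names, paste0(term$name, ".rho")),
                     c(rep("log", M), "corr"), c(init, rinit), fixedv)
      mk_c <- function(nat) {
        s <- sqrt(nat[seq_len(M)]); rho <- nat[M + 1]
        (s %o% s) * (diag(M) + rho * (1 - diag(M)))
      }
      list(par = par, M = M,
           covn = function(nat) mk_c(nat)[mi, mi] * Eg,
           mk_c = mk_c,
           blup = function(nat) {
             Vq <- length(lev); q <- M * Vq
             col_idx <- ifelse(is.na(vi), NA_integer_, (mi - 1L) * Vq + vi)
             Z <- .indicator(col_idx, q)
             Gq <- kronecker(mk_c(nat), diag(Vq))
             levels <- as.vector(outer(lev, levels(envf),
                                       function(g, e) paste(e, g, sep = ":")))
             list(Z = Z, Gq = Gq, levels = levels,
                  env_levels = levels(envf), geno_levels = lev)
           })
    },
    knownfull = {
      Q <- term$Q
      lev <- rownames(Q)
      idx <- match(as.character(data[[term$column]]), lev)
      Qn <- .aug_index(Q, idx)
      par <- .partab(character(0), character(0), numeric(0))
      list(par = par,
           covn = function(nat) Qn,
           blup = function(nat) list(Z = .indicator(idx, nrow(Q)), Gq = Q,
                                     levels = lev))
    },
    riid = {
      init <- if (!is.null(term$init)) term$init else v0 / 2
      par <- .partab(paste0(term$name, ".sigma2"), "log",
                     max(init - term$lb, 1e-10),
                     if (!is.null(term$fixed)) max(term$fixed - term$lb, 0) else NA)
      lb <- term$lb
      list(par = par, lb = lb, residual = TRUE,
           covn = function(nat) diag(rep(nat[1] + lb, n)),
           blup = NULL)
    },
    rar1 = {
      envf <- factor(as.character(data[[term$env]]))
      M <- nlevels(envf)
      idx_by_env <- split(seq_len(n), envf)
      dr <- lapply(idx_by_env, function(i)
        abs(outer(data[[term$row]][i], data[[term$row]][i], "-")))
      dc <- lapply(idx_by_env, function(i)
        abs(outer(data[[term$col]][i], data[[term$col]][i], "-")))
      nm <- as.vector(t(outer(levels(envf), c("sigma2", "rho_r", "rho_c"),
                              function(e, p) paste0(term$name, ".", p, "[", e, "]"))))
      recyc <- function(x) rep_len(x, M)
      init <- c(rbind(recyc(if (!is.null(term$init$sigma2)) term$init$sigma2 else v0 / 2),
                      recyc(if (!is.null(term$init$rho_r)) term$init$rho_r else 0.1),
                      recyc(if (!is.null(term$init$rho_c)) term$init$rho_c else 0.1)))
      fixedv <- rep(NA_real_, 3 * M)
      if (!is.null(term$fixed))
        fixedv <- c(rbind(recyc(term$fixed$sigma2), recyc(term$fixed$rho_r),
                          recyc(term$fixed$rho_c)))
      par <- .partab(nm, rep(c("log", "corr", "corr"), M), init, fixedv)
      list(par = par, residual = TRUE,
           covn = function(nat) {
             R <- matrix(0, n, n)
             for (m in seq_len(M)) {
               s2 <- nat[3 * (m - 1) + 1]
               rr <- nat[3 * (m - 1) + 2]
               rc <- nat[3 * (m - 1) + 3]
               i <- idx_by_env[[m]]
               R[i, i] <- s2 * (rr ^ dr[[m]]) * (rc ^ dc[[m]])
             }
             R
           },
           blup = NULL)
    },
    stop("unknown term type: ", term$type, call. = FALSE))
}

## ---- restricted log-likelihood -------------------------------------------

.reml_ll <- function(V, X, y, XtX_logdet) {
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(NULL)
  logdetV <- 2 * sum(log(diag(cV)))
  Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
  Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
  XtViX <- crossprod(X, Vi_X)
  cA <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cA)) return(NULL)
  logdetA <- 2 * sum(log(diag(cA)))
  XtViy <- crossprod(X, Vi_y)
  beta <- backsolve(cA, forwardsolve(t(cA), XtViy))
  yPy <- sum(y * Vi_y) - sum(XtViy * beta)
  n <- length(y); p <- ncol(X)
  ll <- -0.5 * ((n - p) * log(2 * pi) + logdetV + logdetA - XtX_logdet + yPy)
  list(ll = ll, beta = beta, cV = cV, cA = cA, Vi_y = Vi_y, Vi_X = Vi_X,
       XtViX = XtViX)
}

## ---- main fitting function ------------------------------------------------

#' Fit a linear mixed model by REML
#'
#' The workhorse of the package: restricted maximum likelihood for dense
#' mixed models with the covariance structures used in stage-one, stage-two
#' and single-stage genomic evaluation (see [reml-terms]). With every
#' parameter frozen (`fixed` in all terms) no optimisation takes place and
#' the function returns BLUEs, BLUPs and PEVs at the supplied values —
#' Henderson's mixed-model solution.
#'
#' @param formula fixed-part formula, e.g. `y ~ environment` or
#'   `y ~ 0 + treatment`.
#' @param data data frame of plot or entry records.
#' @param random list of random terms built with the [reml-terms]
#'   constructors.
#' @param residual residual structure ([res_iid()] or [res_ar1ar1()]).
#' @param control a [reml_control()] list.
#' @return Object of class `remlx` with components `par` (natural-scale
#'   parameter table), `loglik`, `aic`, `n_covpar`, `beta`, `beta_cov`,
#'   `blups` (per random term: levels, BLUP, PEV), `fitted`, `aliased`,
#'   `convergence` and `boundary` flags.
#' @seealso [lr_test()], methods `print`, `summary`, `coef`, `vcov`,
#'   `logLik`, `AIC`, `fitted`, `residuals`, `ranef`.
#' @export
reml <- function(formula, data, random = list(), residual = res_iid(),
                 control = reml_control()) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  if (anyNA(y)) stop("response contains NA; remove missing records first",
                     call. = FALSE)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  ## drop aliased fixed-effect columns deterministically
  qrX <- qr(X)
  aliased <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    aliased <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    X <- X[, keep, drop = FALSE]
  }
  if (qr(X)$rank < ncol(X)) stop("fixed part numerically rank deficient",
                                 call. = FALSE)
  XtX_logdet <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
  v0 <- stats::var(y)

  if (inherits(random, "reml_term")) random <- list(random)
  terms_r <- lapply(random, .realize, data = data, v0 = v0)
  term_res <- .realize(residual, data = data, v0 = v0)
  all_terms <- c(terms_r, list(term_res))
  ptabs <- lapply(all_terms, `[[`, "par")
  npars <- vapply(ptabs, nrow, integer(1))
  ptab <- do.call(rbind, ptabs)
  free <- !ptab$fixed
  n_free <- sum(free)

  nat_full <- function(theta_free) {
    nat <- ptab$value
    if (n_free) {
      w <- theta_free
      nat[free] <- mapply(.to_nat, w, ptab$trans[free])
    }
    nat
  }
  split_nat <- function(nat)
    split(nat, factor(rep(seq_along(all_terms), npars),
                      levels = seq_along(all_terms)))

  build_V <- function(nat) {
    parts <- split_nat(nat)
    V <- matrix(0, n, n)
    for (i in seq_along(all_terms))
      V <- V + all_terms[[i]]$covn(parts[[i]])
    V
  }

  obj <- function(theta_free) {
    nat <- nat_full(theta_free)
    out <- .reml_ll(build_V(nat), X, y, XtX_logdet)
    if (is.null(out) || !is.finite(out$ll)) return(1e10)
    -out$ll
  }

  conv <- list(code = 0L, iterations = 0L, message = "all parameters fixed",
               starts = NULL)
  if (n_free > 0) {
    theta0 <- mapply(.to_work, ptab$init[free], ptab$trans[free])
    has_fa <- any(vapply(random, function(t) t$type == "fa", logical(1)))
    n_starts <- control$n_starts
    if (is.null(n_starts)) n_starts <- if (has_fa) 3L else 1L
    best <- NULL
    starts <- data.frame(start = seq_len(n_starts), objective = NA_real_,
                         convergence = NA_integer_)
    for (s in seq_len(n_starts)) {
      th <- theta0
      if (s > 1) {
        set.seed(control$seed + s)
        th <- theta0 + stats::rnorm(length(theta0), sd = control$jitter_sd)
      }
      fit <- tryCatch(
        stats::nlminb(th, obj,
                      control = list(iter.max = control$iter_max,
                                     eval.max = 4 * control$iter_max,
                                     rel.tol = control$rel_tol,
                                     trace = if (control$verbose) 1 else 0)),
        error = function(e) NULL)
      if (is.null(fit)) next
      starts$objective[s] <- fit$objective
      starts$convergence[s] <- fit$convergence
      better <- is.null(best) || fit$objective < best$objective - 1e-10 ||
        (abs(fit$objective - best$objective) <= 1e-10 &&
           sum(fit$par^2) < sum(best$par^2))
      if (better) best <- fit
    }
    if (is.null(best)) stop("REML optimisation failed at every start",
                            call. = FALSE)
    theta_hat <- best$par
    conv <- list(code = best$convergence, iterations = best$iterations,
                 message = best$message, starts = starts)
    if (best$convergence != 0 && !grepl("relative convergence|both X|singular convergence",
                                        tolower(best$message %||% "")))
      warning("REML optimiser reported: ", best$message, call. = FALSE)
  } else theta_hat <- numeric(0)

  nat_hat <- nat_full(theta_hat)
  V <- build_V(nat_hat)
  sol <- .reml_ll(V, X, y, XtX_logdet)
  if (is.null(sol)) stop("covariance matrix singular at the optimum",
                         call. = FALSE)
  beta <- drop(sol$beta); names(beta) <- colnames(X)
  beta_cov <- chol2inv(sol$cA)
  dimnames(beta_cov) <- list(colnames(X), colnames(X))

  ## P = Vi - ViX (X'ViX)^-1 X'Vi ; r = y - X beta ; Vi r = Viy - ViX beta
  Vi_r <- drop(sol$Vi_y - sol$Vi_X %*% sol$beta)
  PZfun <- function(Z) {
    ViZ <- backsolve(sol$cV, forwardsolve(t(sol$cV), Z))
    XtViZ <- crossprod(X, ViZ)
    ViZ - sol$Vi_X %*% backsolve(sol$cA, forwardsolve(t(sol$cA), XtViZ))
  }

  parts <- split_nat(nat_hat)
  blups <- list()
  fitted <- drop(X %*% sol$beta)
  for (i in seq_along(terms_r)) {
    bi <- all_terms[[i]]$blup(parts[[i]])
    u <- drop(bi$Gq %*% crossprod(bi$Z, Vi_r))
    PZ <- PZfun(bi$Z)
    ## PEV = Gq - Gq Z' P Z Gq  (diagonal)
    GZt <- bi$Gq %*% t(bi$Z)
    pev <- diag(bi$Gq) - rowSums((GZt %*% PZ) * bi$Gq)
    pev <- pmax(pev, 0)
    blups[[random[[i]]$name]] <-
      c(list(levels = bi$levels, blup = stats::setNames(u, bi$levels),
             pev = stats::setNames(pev, bi$levels)),
        bi[setdiff(names(bi), c("Z", "Gq", "levels"))])
    fitted <- fitted + drop(bi$Z %*% u)
  }

  ptab$value <- nat_hat
  boundary <- ptab$trans == "log" & !ptab$fixed & nat_hat < 1e-6 * max(v0, 1e-12)
  extra <- list()
  for (i in seq_along(terms_r))
    if (!is.null(all_terms[[i]]$mk_sigma))
      extra[[random[[i]]$name]] <- all_terms[[i]]$mk_sigma(parts[[i]])
    else if (!is.null(all_terms[[i]]$mk_c))
      extra[[random[[i]]$name]] <- all_terms[[i]]$mk_c(parts[[i]])

  structure(list(call = cl, n = n, p = ncol(X), X = X, par = ptab,
                 loglik = sol$ll, n_covpar = n_free,
                 aic = -2 * sol$ll + 2 * n_free,
                 beta = beta, beta_cov = beta_cov, aliased = aliased,
                 blups = blups, sigma_mats = extra,
                 fitted = fitted, y = y, residuals = y - fitted,
                 boundary = stats::setNames(boundary, ptab$par),
                 convergence = conv),
            class = "remlx")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- methods --------------------------------------------------------------

#' @export
print.remlx <- function(x, ...) {
  cat("REML fit:", deparse(x$call$formula), "\n")
  cat(sprintf("  n = %d, fixed effects = %d, free covariance parameters = %d\n",
              x$n, x$p, x$n_covpar))
  cat(sprintf("  restricted logLik = %.4f, AIC = %.4f\n", x$loglik, x$aic))
  if (length(x$aliased))
    cat("  aliased fixed-effect columns dropped:",
        paste(x$aliased, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.remlx <- function(object, ...) {
  out <- list(fit = object,
              par = object$par[, c("par", "value", "fixed")],
              beta = data.frame(estimate = object$beta,
                                se = sqrt(diag(object$beta_cov))))
  class(out) <- "summary.remlx"
  out
}

#' @export
print.summary.remlx <- function(x, ...) {
  print(x$fit)
  cat("\nCovariance parameters:\n")
  print(x$par, row.names = FALSE, digits = 5)
  cat("\nFixed effects:\n")
  print(x$beta, digits = 5)
  if (any(x$fit$boundary))
    cat("\nNote: parameters at the zero boundary:",
        paste(names(which(x$fit$boundary)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.remlx <- function(object, ...) object$beta

#' @export
vcov.remlx <- function(object, ...) object$beta_cov

#' @export
logLik.remlx <- function(object, ...) {
  structure(object$loglik, df = object$n_covpar,
            nobs = object$n - object$p, class = "logLik")
}

#' @export
AIC.remlx <- function(object, ..., k = 2) object$aic

#' @export
fitted.remlx <- function(object, ...) object$fitted

#' @export
residuals.remlx <- function(object, ...) object$residuals

#' Extract BLUPs of a random term
#'
#' @param object a [reml()] fit.
#' @param term term name (default: first random term).
#' @return Data frame with `level`, `blup`, `pev`.
#' @export
ranef <- function(object, term = NULL) {
  stopifnot(inherits(object, "remlx"))
  if (is.null(term)) term <- names(object$blups)[1]
  b <- object$blups[[term]]
  if (is.null(b)) stop("no random term named '", term, "'", call. = FALSE)
  data.frame(level = b$levels, blup = unname(b$blup), pev = unname(b$pev),
             stringsAsFactors = FALSE)
}

#' @export
plot.remlx <- function(x, ...) {
  graphics::plot(x$fitted, x$residuals, xlab = "fitted", ylab = "residual",
                 main = "REML fit residuals", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Likelihood-ratio test for variance components on the boundary
#'
#' Tests nested mixed models (same fixed part) in which `L` variance
#' components lie on the zero boundary under the null. The LR statistic is
#' referred to the chi-square mixture `sum_l 2^-L choose(L, l) chisq_l`, with
#' `chisq_0` a point mass at zero.
#'
#' @param ll_full,ll_reduced restricted log-likelihoods of full and reduced
#'   models (or `remlx` fits).
#' @param L number of boundary variance components tested.
#' @param tol tolerance for a negative LR statistic before erroring.
#' @return List with `statistic` and `p_value`.
#' @export
lr_test <- function(ll_full, ll_reduced, L = 1, tol = 1e-6) {
  if (inherits(ll_full, "remlx")) ll_full <- ll_full$loglik
  if (inherits(ll_reduced, "remlx")) ll_reduced <- ll_reduced$loglik
  stopifnot(L >= 1)
  lr <- 2 * (ll_full - ll_reduced)
  if (lr < -tol)
    stop("negative LR statistic: models mis-specified or not nested",
         call. = FALSE)
  lr <- max(lr, 0)
  if (lr == 0) return(list(statistic = 0, p_value = 1))
  w <- stats::dbinom(0:L, L, 0.5)      # 2^-L * choose(L, l)
  tails <- c(0, stats::pchisq(lr, df = seq_len(L), lower.tail = FALSE))
  list(statistic = lr, p_value = sum(w * tails))
}
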