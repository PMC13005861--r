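## End-to-end orchestration: simulate -> relationship matrices -> stage one
## -> deregression/weights -> stage two / single stage -> cross-validation,
## driven by one configuration list (or YAML file), with a reproducibility
## manifest.

#' Read plot, pedigree and dosage tables
#'
#' Plain-CSV readers matching the writers of [write_met()]: a plot table
#' (`environment,row,col,treatment,role,pool,y`), a pedigree
#' (`id,parent1,parent2[,pool]`; `0`/blank = unknown), and a dosage matrix
#' (first column `id`, remaining columns integer dosages 0-6, NA allowed).
#'
#' @param file path to the CSV file.
#' @return A data frame (`read_plots`, `read_pedigree`) or numeric matrix
#'   with row names (`read_dosage`).
#' @name met-io
NULL

#' @rdname met-io
#' @export
read_plots <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("environment", "row", "col", "treatment", "y")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("plot table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  d
}

#' @rdname met-io
#' @export
read_pedigree <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("id", "parent1", "parent2")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("pedigree lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  d
}

#' @rdname met-io
#' @export
read_dosage <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- d[[1]]
  Z <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(Z) <- "double"
  rownames(Z) <- ids
  Z
}

.variant_for <- c(BLUE = "blue", dBLUP = "blup", dABLUP = "ablup")

#' Run the full evaluation pipeline
#'
#' Executes, from one configuration: data simulation ([simulate_met()]),
#' marker QC and relationship matrices, stage-one fits per environment and
#' entry kind, deregression and weighting, second-stage fits with
#' factor-order selection, the single-stage benchmark, selection
#' concordance of every two-stage family against the single-stage GEBVs,
#' and (optionally) CV1/CV2 cross-validation.
#'
#' @param config a list (or path to a YAML file) with optional elements:
#'   `sim` (a `sim_config` or a list of overrides passed to
#'   [demo_config()]), `entry_kinds` (subset of `"BLUE"`, `"dBLUP"`,
#'   `"dABLUP"`), `weight_modes` (subset of `"fw"`, `"dw"`), `k_max`,
#'   `single_stage` (logical), `cv` (list: `schemes`, `reps`, `folds`,
#'   `seed`, `single_stage`), `lr` (stage-one LR tests), `blend_w`,
#'   `n_starts`, `out_dir`.
#' @return Object of class `experiment`: all fitted pieces plus a `manifest`
#'   (config hash, seeds, chosen orders, convergence summaries) and a
#'   `summary` table of the cross-validation results.
#' @export
run_experiment <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg_sim <- config$sim
  if (!inherits(cfg_sim, "sim_config"))
    cfg_sim <- do.call(demo_config, as.list(cfg_sim))
  entry_kinds <- config$entry_kinds %||% c("BLUE", "dBLUP", "dABLUP")
  stopifnot(all(entry_kinds %in% names(.variant_for)))
  weight_modes <- config$weight_modes %||% c("fw", "dw")
  k_max <- config$k_max %||% 2
  if (k_max > cfg_sim$M)
    stop("k_max exceeds the number of environments", call. = FALSE)
  control <- reml_control(n_starts = config$n_starts %||% 1)

  sim <- simulate_met(cfg_sim)
  panel <- filter_markers(sim$dosage[sim$genotyped, , drop = FALSE])
  G <- blend(G_matrix(panel), config$blend_w %||% 0.02)
  A <- A_matrix(sim$pedigree)

  envs <- sort(unique(sim$plots$environment))
  stage1 <- list()
  entry_sets <- list()
  for (kind in entry_kinds) {
    variant <- .variant_for[[kind]]
    fits <- lapply(envs, function(e)
      fit_stage_one(sim$plots[sim$plots$environment == e, , drop = FALSE],
                    variant, A = A, lr = isTRUE(config$lr),
                    control = control))
    names(fits) <- envs
    stage1[[kind]] <- fits
    es <- entry_set(lapply(fits, deregress, control = control))
    entry_sets[[kind]] <- restrict_entries(es, sim$genotyped)
  }

  stage2 <- list()
  for (kind in entry_kinds) for (mode in weight_modes) {
    es <- make_weights(entry_sets[[kind]], mode)
    fits <- lapply(seq_len(k_max), function(k)
      fit_stage_two(es, G, k, control = control))
    stage2[[paste(kind, mode, sep = "-")]] <- select_fa_order(fits)
  }

  ss <- NULL
  if (config$single_stage %||% TRUE) {
    fits <- lapply(seq_len(k_max), function(k)
      fit_single_stage(sim$plots, G, k, control = control))
    ss <- select_fa_order(fits)
  }

  concord <- NULL
  if (!is.null(ss)) {
    concord <- do.call(rbind, lapply(names(stage2), function(nm) {
      sc <- selection_concordance(stage2[[nm]]$fit$gebv_mean, ss$fit$gebv_mean)
      data.frame(family = paste0("2S-", nm),
                 rank_correlation = sc$rank_correlation,
                 top10_coincidence = sc$coincidence)
    }))
  }

  cv <- list()
  cv_cfg <- config$cv
  if (!is.null(cv_cfg)) {
    for (scheme in (cv_cfg$schemes %||% c("cv1", "cv2"))) {
      plan <- cv_plan(scheme, folds = cv_cfg$folds %||% 5,
                      reps = cv_cfg$reps %||% 10,
                      seed = cv_cfg$seed %||% cfg_sim$seed)
      for (nm in names(stage2)) {
        kind <- sub("-(fw|dw)$", "", nm)
        mode <- sub("^.*-", "", nm)
        es <- make_weights(entry_sets[[kind]], mode)
        cv[[paste(nm, scheme, sep = "-")]] <-
          cv_two_stage(es, G, stage2[[nm]]$k, plan, control = control)
      }
      if (isTRUE(cv_cfg$single_stage) && !is.null(ss))
        cv[[paste("ss", scheme, sep = "-")]] <-
          cv_single_stage(sim$plots, G, ss$k, plan, control = control)
    }
  }

  summary_tab <- if (length(cv)) do.call(rbind, lapply(names(cv), function(nm) {
    s <- cv[[nm]]$summary
    data.frame(run = nm, family = cv[[nm]]$family,
               scheme = toupper(cv[[nm]]$plan$scheme),
               pa = unname(s["pa"]), pa_sd = unname(s["pa_sd"]),
               mspe = unname(s["mspe"]))
  })) else NULL

  cfg_txt <- yaml::as.yaml(list(
    sim = unclass(cfg_sim)[setdiff(names(cfg_sim), c("Lambda"))],
    Lambda = as.vector(cfg_sim$Lambda),
    entry_kinds = entry_kinds, weight_modes = weight_modes, k_max = k_max))
  tf <- tempfile(fileext = ".yaml"); writeLines(cfg_txt, tf)
  manifest <- list(
    package_version = as.character(utils::packageVersion("polystage")),
    config_md5 = unname(tools::md5sum(tf)),
    seed = cfg_sim$seed,
    chosen_k = c(vapply(stage2, `[[`, 0, "k"),
                 if (!is.null(ss)) c(ss = ss$k)),
    convergence = vapply(stage2, function(x)
      x$fit$fit$convergence$code, 0L))
  unlink(tf)

  out <- structure(list(sim = sim, panel = panel, G = G, A = A,
                        stage1 = stage1, entry_sets = entry_sets,
                        stage2 = stage2, single_stage = ss,
                        concordance = concord, cv = cv,
                        summary = summary_tab, manifest = manifest,
                        config = config),
                   class = "experiment")
  if (!is.null(config$out_dir)) write_experiment(out, config$out_dir)
  out
}

#' @export
print.experiment <- function(x, ...) {
  cat("polystage experiment\n")
  cat(sprintf("  %d environments, %d genotyped individuals, seed %d\n",
              x$sim$config$M, length(x$sim$genotyped), x$manifest$seed))
  cat("  chosen factor orders:",
      paste(sprintf("%s = %d", names(x$manifest$chosen_k),
                    x$manifest$chosen_k), collapse = ", "), "\n")
  if (!is.null(x$concordance)) {
    cat("\nSelection concordance against the single-stage model:\n")
    print(x$concordance, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$summary)) {
    cat("\nCross-validation summary:\n")
    print(x$summary[, c("family", "scheme", "pa", "mspe")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write the main experiment outputs as CSV/JSON
#'
#' Writes the simulated dataset, the per-family GEBV tables, genetic
#' correlation matrices, the concordance and cross-validation summaries and
#' the manifest (JSON) into `dir`.
#'
#' @param x an `experiment`.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_experiment <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_met(x$sim, file.path(dir, "data"))
  for (nm in names(x$stage2)) {
    f <- x$stage2[[nm]]$fit
    utils::write.csv(data.frame(geno = rownames(f$gebv), f$gebv,
                                mean = f$gebv_mean, check.names = FALSE),
                     file.path(dir, paste0("gebv_2s_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(genetic_correlation(f$Sigma_g),
                     file.path(dir, paste0("gencor_2s_", nm, ".csv")))
  }
  if (!is.null(x$single_stage)) {
    f <- x$single_stage$fit
    utils::write.csv(data.frame(geno = rownames(f$gebv), f$gebv,
                                mean = f$gebv_mean, check.names = FALSE),
                     file.path(dir, "gebv_ss.csv"), row.names = FALSE)
  }
  if (!is.null(x$concordance))
    utils::write.csv(x$concordance, file.path(dir, "concordance.csv"),
                     row.names = FALSE)
  if (!is.null(x$summary))
    utils::write.csv(x$summary, file.path(dir, "cv_summary.csv"),
                     row.names = FALSE)
  jsonlite::write_json(x$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
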