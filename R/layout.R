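#' Generate an augmented row-column trial layout
#'
#' Lays out a field of `R` rows by `C` columns divided into row groups,
#' column groups and blocks (row-group x column-group intersections).
#' Every check appears exactly once per block, so that each check is
#' replicated `C/col_group` times per row group, `R/row_group` times per
#' column group, and `(R/row_group) * (C/col_group)` times in total.
#' Parents (replicated according to `parent_reps`) and unreplicated test
#' clones fill the remaining plots by unrestricted randomization.
#'
#' @param R,C field dimensions (rows, columns).
#' @param row_group,col_group number of contiguous rows (columns) forming a
#'   row (column) group. `R` and `C` must be multiples of these.
#' @param checks character vector of check ids.
#' @param parent_reps named integer vector: replicates per parent (may be
#'   empty).
#' @param tests character vector of unreplicated test-clone ids.
#' @param environment environment label stored with the layout.
#' @param seed integer seed for the randomization.
#' @return An object of class `trial_layout`: a list with the design
#'   constants and a `plots` data frame (`row`, `col`, `row_group`,
#'   `col_group`, `block`, `treatment`, `role`).
#' @examples
#' lay <- augmented_layout(R = 12, C = 10, row_group = 6, col_group = 5,
#'                         checks = c("CK1", "CK2"),
#'                         parent_reps = c(P1 = 2, P2 = 2),
#'                         tests = paste0("T", 1:100), seed = 1)
#' table(lay$plots$role)
#' @export
augmented_layout <- function(R, C, row_group, col_group, checks,
                             parent_reps = integer(), tests = character(),
                             environment = "ENV1", seed = 1L) {
  if (R %% row_group != 0 || C %% col_group != 0)
    stop("R and C must be multiples of the row-group and column-group sizes",
         call. = FALSE)
  n_rg <- R %/% row_group
  n_cg <- C %/% col_group
  n_blocks <- n_rg * n_cg
  n_check_plots <- length(checks) * n_blocks
  n_parent_plots <- sum(parent_reps)
  n_plots <- R * C
  if (n_check_plots + n_parent_plots + length(tests) != n_plots)
    stop(sprintf(
      "infeasible counts: %d check + %d parent + %d test plots != %d field plots",
      n_check_plots, n_parent_plots, length(tests), n_plots), call. = FALSE)
  if (length(checks) > row_group * col_group)
    stop("more checks than plots per block", call. = FALSE)

  set.seed(seed)
  row <- rep(seq_len(R), times = C)
  col <- rep(seq_len(C), each = R)
  rg <- (row - 1L) %/% row_group + 1L
  cg <- (col - 1L) %/% col_group + 1L
  block <- (rg - 1L) * n_cg + cg

  treatment <- character(n_plots)
  # one copy of every check per block, at random plots within the block
  for (b in seq_len(n_blocks)) {
    idx <- which(block == b)
    chk_pos <- sample(idx, length(checks))
    treatment[chk_pos] <- sample(checks)
  }
  open <- which(treatment == "")
  entries <- c(rep(names(parent_reps), times = parent_reps), tests)
  treatment[open] <- sample(entries)

  role <- rep("test", n_plots)
  role[treatment %in% checks] <- "check"
  role[treatment %in% names(parent_reps)] <- "parent"

  plots <- data.frame(row = row, col = col, row_group = rg, col_group = cg,
                      block = block, treatment = treatment, role = role,
                      stringsAsFactors = FALSE)
  plots <- plots[order(plots$row, plots$col), , drop = FALSE]
  rownames(plots) <- NULL
  structure(list(environment = environment, R = R, C = C,
                 row_group = row_group, col_group = col_group,
                 n_blocks = n_blocks, checks = checks,
                 parent_reps = parent_reps, tests = tests, plots = plots),
            class = "trial_layout")
}

#' @export
print.trial_layout <- function(x, ...) {
  cat(sprintf("Augmented row-column layout '%s': %d x %d (%d plots)\n",
              x$environment, x$R, x$C, nrow(x$plots)))
  cat(sprintf("  %d blocks (%dx%d groups); %d checks x %d reps; %d parent plots; %d test clones\n",
              x$n_blocks, x$row_group, x$col_group, length(x$checks),
              x$n_blocks, sum(x$parent_reps), length(x$tests)))
  invisible(x)
}

#' Default parent replication plan
#'
#' Draws per-parent replicate counts uniformly from `1:max_rep`, then trims or
#' pads (one replicate at a time, cycling over parents) so that the total
#' number of replicated plots (checks plus parents) matches
#' `round(rep_fraction * n_plots)`.
#'
#' @param parents character vector of parent ids.
#' @param n_plots total field plots.
#' @param n_check_plots plots already taken by checks.
#' @param rep_fraction target fraction of the field allocated to replicated
#'   treatments (checks and parents).
#' @param max_rep maximum replicates per parent.
#' @param n_parent_plots optional exact total of parent plots (overrides
#'   `rep_fraction`; used when the remaining field capacity is fixed).
#' @param seed integer seed.
#' @return Named integer vector of replicates per parent.
#' @export
parent_rep_plan <- function(parents, n_plots, n_check_plots,
                            rep_fraction = 0.24, max_rep = 15L,
                            n_parent_plots = NULL, seed = 1L) {
  set.seed(seed)
  target <- if (is.null(n_parent_plots))
    round(rep_fraction * n_plots) - n_check_plots else n_parent_plots
  target <- max(target, length(parents))
  target <- min(target, length(parents) * max_rep)
  reps <- sample.int(max_rep, length(parents), replace = TRUE)
  i <- 0L
  while (sum(reps) != target) {
    i <- i %% length(parents) + 1L
    if (sum(reps) > target && reps[i] > 1L) reps[i] <- reps[i] - 1L
    else if (sum(reps) < target && reps[i] < max_rep) reps[i] <- reps[i] + 1L
  }
  names(reps) <- parents
  reps
}
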