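## Pedigree (A) and genomic (G) relationship matrices for autohexaploids.

#' Marker quality control and imputation
#'
#' Removes loci with more than `max_missing` missing dosages, monomorphic
#' loci, and loci with minor allele frequency below `min_maf`; remaining
#' missing dosages are mean-imputed with `6 p_u`. Allele frequencies are
#' estimated from the supplied individuals as `mean(dosage)/6`, so they are
#' recomputed whenever a subset (e.g. one gene pool) is analysed.
#'
#' @param dosage matrix (individuals x loci) of integer dosages 0-6, `NA`
#'   allowed.
#' @param max_missing maximum tolerated fraction of missing dosages per locus.
#' @param min_maf minimum minor allele frequency.
#' @return List of class `dosage_panel`: `Z` (imputed dosages), `W` (centred
#'   matrix `Z - 6p`), `p` (allele frequencies of retained loci), `denom`
#'   (`sum(6 p (1-p))`), and `removed` (counts by reason).
#' @export
filter_markers <- function(dosage, max_missing = 0.10, min_maf = 0.05) {
  Z <- as.matrix(dosage)
  if (any(Z < 0 | Z > 6, na.rm = TRUE))
    stop("dosages must lie in [0, 6]", call. = FALSE)
  miss <- colMeans(is.na(Z))
  p <- colMeans(Z, na.rm = TRUE) / 6
  maf <- pmin(p, 1 - p)
  novar <- apply(Z, 2, function(z) length(unique(z[!is.na(z)])) <= 1)
  drop_missing <- miss > max_missing
  drop_mono <- !drop_missing & (is.na(maf) | novar)
  drop_maf <- !drop_missing & !drop_mono & maf < min_maf
  keep <- !(drop_missing | drop_mono | drop_maf)
  if (!any(keep)) stop("all loci removed by quality control", call. = FALSE)
  Z <- Z[, keep, drop = FALSE]
  p <- p[keep]
  for (j in which(colSums(is.na(Z)) > 0))
    Z[is.na(Z[, j]), j] <- 6 * p[j]
  W <- sweep(Z, 2, 6 * p)
  structure(list(Z = Z, W = W, p = p, denom = sum(6 * p * (1 - p)),
                 removed = c(missing = sum(drop_missing),
                             monomorphic = sum(drop_mono),
                             maf = sum(drop_maf)),
                 n_retained = sum(keep)),
            class = "dosage_panel")
}

#' @export
print.dosage_panel <- function(x, ...) {
  cat(sprintf("Dosage panel: %d individuals x %d loci (removed: %d missing, %d monomorphic, %d MAF)\n",
              nrow(x$Z), ncol(x$Z), x$removed["missing"],
              x$removed["monomorphic"], x$removed["maf"]))
  invisible(x)
}

new_relmatrix <- function(M, kind, blend_w = 0) {
  theta <- mean(diag(M)) - mean(M)
  F_v <- (diag(M) - 1) / 5
  structure(list(mat = M, kind = kind, theta = theta, F = F_v,
                 blend_w = blend_w),
            class = "relmatrix")
}

#' @export
print.relmatrix <- function(x, ...) {
  cat(sprintf("%s relationship matrix of order %d (theta = %.4f, mean F = %.4f%s)\n",
              if (x$kind == "genomic") "Genomic" else "Pedigree",
              nrow(x$mat), x$theta, mean(x$F),
              if (x$blend_w > 0) sprintf(", blended w = %g", x$blend_w) else ""))
  invisible(x)
}

#' Genomic relationship matrix for hexaploid dosages
#'
#' VanRaden-type genomic relationship adjusted for hexaploidy:
#' `G = W W' / sum(6 p_u (1 - p_u))` with `W` the centred dosage matrix.
#' The diagonal satisfies `G_vv = 1 + 5 F_v`, from which per-individual
#' inbreeding is extracted, and the correcting factor
#' `theta = mean(diag(G)) - mean(G)` is stored.
#'
#' @param panel a `dosage_panel` from [filter_markers()], or a raw dosage
#'   matrix (filtered with default thresholds).
#' @return A `relmatrix` object (fields `mat`, `kind`, `theta`, `F`,
#'   `blend_w`).
#' @export
G_matrix <- function(panel) {
  if (!inherits(panel, "dosage_panel")) panel <- filter_markers(panel)
  if (panel$denom <= 0) stop("degenerate panel: zero denominator", call. = FALSE)
  G <- tcrossprod(panel$W) / panel$denom
  dimnames(G) <- list(rownames(panel$W), rownames(panel$W))
  new_relmatrix(G, "genomic")
}

#' Pedigree relationship matrix for autohexaploids
#'
#' Numerator relationship matrix under polysomic inheritance with double
#' reduction set to zero. With gametes of 3 allele copies sampled without
#' replacement from the parent's 6, the recursions are
#' `A_ij = (A_sj + A_dj) / 2` for `j` not a descendant of `i`,
#' inbreeding `F_i = (F_s + F_d) / 5 + A_sd / 10` (the probability that two
#' distinct allele copies of `i` are identical by descent), and diagonal
#' `A_ii = 1 + 5 F_i`. Founders are non-inbred and mutually unrelated
#' (`A = I` on the founder block). Unknown parents are treated as unique
#' non-inbred founders.
#'
#' @param pedigree data frame with columns `id`, `parent1`, `parent2`
#'   (`NA`, `""` or `"0"` for unknown). Parents must precede offspring or be
#'   sortable topologically; cycles are an error.
#' @return A `relmatrix` object of order `nrow(pedigree)`.
#' @export
A_matrix <- function(pedigree) {
  ped <- pedigree
  ids <- as.character(ped$id)
  if (anyDuplicated(ids)) stop("duplicated ids in pedigree", call. = FALSE)
  norm_par <- function(x) {
    x <- as.character(x)
    x[x %in% c("", "0") | is.na(x)] <- NA
    x
  }
  p1 <- norm_par(ped$parent1); p2 <- norm_par(ped$parent2)
  unknown <- setdiff(stats::na.omit(c(p1, p2)), ids)
  if (length(unknown))
    stop("parents absent from pedigree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  n <- length(ids)
  ord <- integer(0)
  placed <- stats::setNames(rep(FALSE, n), ids)
  remaining <- seq_len(n)
  repeat {
    ready <- remaining[vapply(remaining, function(i) {
      (is.na(p1[i]) || placed[[p1[i]]]) && (is.na(p2[i]) || placed[[p2[i]]])
    }, logical(1))]
    if (!length(ready)) {
      if (length(remaining))
        stop("pedigree contains a cycle (individual its own ancestor)",
             call. = FALSE)
      break
    }
    ord <- c(ord, ready)
    placed[ids[ready]] <- TRUE
    remaining <- setdiff(remaining, ready)
    if (!length(remaining)) break
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  Fv <- stats::setNames(rep(0, n), ids)
  idx <- stats::setNames(seq_len(n), ids)
  for (i in ord) {
    s <- p1[i]; d <- p2[i]
    si <- if (is.na(s)) NA_integer_ else idx[[s]]
    di <- if (is.na(d)) NA_integer_ else idx[[d]]
    done <- idx[ids[ord[seq_len(match(i, ord) - 1L)]]]
    if (length(done)) {
      as_ <- if (is.na(si)) rep(0, length(done)) else A[si, done]
      ad_ <- if (is.na(di)) rep(0, length(done)) else A[di, done]
      A[i, done] <- A[done, i] <- (as_ + ad_) / 2
    }
    Fs <- if (is.na(si)) 0 else Fv[si]
    Fd <- if (is.na(di)) 0 else Fv[di]
    Asd <- if (is.na(si) || is.na(di)) 0 else A[si, di]
    Fv[i] <- (Fs + Fd) / 5 + Asd / 10
    A[i, i] <- 1 + 5 * Fv[i]
  }
  new_relmatrix(A, "pedigree")
}

#' Blend a relationship matrix with the identity
#'
#' Returns `(1 - w) M + w I`, the standard device to guarantee
#' invertibility of a (near-)singular relationship matrix before mixed-model
#' solving. The blending weight is recorded on the result.
#'
#' @param rel a `relmatrix` (or plain symmetric matrix).
#' @param w blending weight in `[0, 1)`.
#' @return Object of the same type with the blended matrix.
#' @export
blend <- function(rel, w = 0.02) {
  if (w < 0 || w >= 1) stop("blending weight must be in [0, 1)", call. = FALSE)
  if (inherits(rel, "relmatrix")) {
    M <- (1 - w) * rel$mat + w * diag(nrow(rel$mat))
    dimnames(M) <- dimnames(rel$mat)
    out <- new_relmatrix(M, rel$kind, blend_w = w)
    return(out)
  }
  (1 - w) * rel + w * diag(nrow(rel))
}

#' Correcting factor of a relationship matrix
#'
#' `theta = mean(diag(M)) - mean(M)`, used to place variance components
#' estimated with a relationship matrix on the scale of the reference
#' population when computing heritabilities.
#'
#' @param rel a `relmatrix` or plain matrix.
#' @return Scalar correcting factor.
#' @export
rel_theta <- function(rel) {
  M <- if (inherits(rel, "relmatrix")) rel$mat else rel
  mean(diag(M)) - mean(M)
}
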