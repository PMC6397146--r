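#' Principal component analysis of a species matrix
#'
#' Species-centred, non-standardised (covariance-based) PCA of a
#' log-transformed abundance matrix — indirect gradient analysis, with
#' environmental variables projected passively afterwards via
#' [project_env()]. Backed by [stats::prcomp()]. Axis signs are fixed by
#' forcing the largest-magnitude species loading on each axis to be
#' positive, so results are reproducible bit-for-bit.
#'
#' @param x Numeric matrix, samples x species, already log-transformed
#'   (see [log_transform()]).
#' @param n_axes Number of axes to report (default 2).
#' @param top_species How many species to flag for display, ranked by fit
#'   (fraction of a species' variance explained by the reported axes).
#' @return Object of class `"ordination"`: `eig_frac` (all eigenvalues as
#'   fractions of total variance), `sample_scores`, `species_scores`
#'   (loadings scaled by axis standard deviation), `species_fit`,
#'   `top_species`, `n_axes`, plus `sdev`, `rotation`, `center` and
#'   `scores_full` for reconstruction.
#' @export
pca_species <- function(x, n_axes = 2, top_species = 10) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 samples")
  if (ncol(x) < 2L) stop("need at least 2 species")
  if (anyNA(x)) stop("species matrix must not contain missing values")
  v <- apply(x, 2L, stats::var)
  if (all(v < .Machine$double.eps))
    stop("zero variance: the species matrix is constant")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  nax <- length(pr$sdev)
  # deterministic sign convention
  for (j in seq_len(nax)) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  k <- min(n_axes, nax)
  eig <- pr$sdev^2
  eig_frac <- eig / sum(eig)
  species_scores <- pr$rotation[, seq_len(k), drop = FALSE] %*%
    diag(pr$sdev[seq_len(k)], k)
  colnames(species_scores) <- paste0("PC", seq_len(k))
  fit <- rowSums(species_scores^2) / pmax(v, .Machine$double.eps)
  ord <- order(fit, decreasing = TRUE)
  structure(list(
    eig_frac = eig_frac,
    sample_scores = pr$x[, seq_len(k), drop = FALSE],
    species_scores = species_scores,
    species_fit = fit,
    top_species = colnames(x)[ord][seq_len(min(top_species, ncol(x)))],
    n_axes = k, sdev = pr$sdev, rotation = pr$rotation,
    center = pr$center, scores_full = pr$x), class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("PCA ordination: %d samples x %d species, %d axes reported\n",
              nrow(x$sample_scores), length(x$species_fit), x$n_axes))
  cat("  eigenvalue fractions:",
      paste(sprintf("%.3f", x$eig_frac[seq_len(x$n_axes)]), collapse = ", "), "\n")
  cat("  top species by fit:",
      paste(utils::head(x$top_species, 5L), collapse = ", "), "...\n")
  invisible(x)
}

#' Passive projection of environmental variables
#'
#' Correlates each standardized environmental variable with the sample
#' scores of the first two ordination axes, giving biplot arrow
#' coordinates. The variables never enter the decomposition (indirect
#' gradient analysis).
#'
#' @param result An [pca_species()] result.
#' @param env Data frame/matrix of environmental variables, rows aligned
#'   with the samples of the ordination (matching rownames when present).
#' @return Matrix (variables x 2) of arrow coordinates on PC1/PC2.
#' @export
project_env <- function(result, env) {
  stopifnot(inherits(result, "ordination"))
  env <- as.data.frame(env)
  sc <- result$sample_scores
  if (nrow(env) != nrow(sc))
    stop("join error: env has ", nrow(env), " rows but the ordination has ",
         nrow(sc), " samples")
  rn_e <- rownames(env)
  rn_s <- rownames(sc)
  if (!is.null(rn_e) && !is.null(rn_s) &&
      !all(rn_e == rn_s) && !any(grepl("^[0-9]+$", rn_e[1])))
    stop("join error: env rows are not aligned with ordination samples")
  k <- min(2L, ncol(sc))
  arrows <- matrix(NA_real_, ncol(env), k,
                   dimnames = list(names(env), paste0("PC", seq_len(k))))
  for (j in seq_along(env)) {
    x <- env[[j]]
    ok <- !is.na(x)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0) next
    for (a in seq_len(k))
      arrows[j, a] <- stats::cor(x[ok], sc[ok, a])
  }
  arrows
}

#' Basic ordination biplot
#'
#' Sample scores as points, the top-fitting species as labels, and
#' (optionally) environmental arrows.
#'
#' @param x An `"ordination"` object.
#' @param env_arrows Optional output of [project_env()].
#' @param ... Passed to [plot.default()].
#' @return `x`, invisibly.
#' @export
plot.ordination <- function(x, env_arrows = NULL, ...) {
  sc <- x$sample_scores
  graphics::plot(sc[, 1], sc[, 2],
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$eig_frac[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$eig_frac[2]),
                 pch = 16, col = "grey40", ...)
  sp <- x$species_scores[x$top_species, , drop = FALSE]
  sca <- 0.8 * max(abs(sc[, 1:2])) / max(abs(sp), na.rm = TRUE)
  graphics::text(sp[, 1] * sca, sp[, 2] * sca, rownames(sp),
                 col = "darkgreen", cex = 0.8)
  if (!is.null(env_arrows)) {
    ar <- env_arrows * 0.9 * max(abs(sc[, 1:2]))
    graphics::arrows(0, 0, ar[, 1], ar[, 2], length = 0.08, col = "firebrick")
    graphics::text(ar[, 1] * 1.08, ar[, 2] * 1.08, rownames(ar),
                   col = "firebrick", cex = 0.7)
  }
  invisible(x)
}
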