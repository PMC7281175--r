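#' Principal component analysis of an omics table
#'
#' Samples are observations, analytes are variables. The scaled matrix
#' (mean-centered, optionally unit-variance "autoscaled" — the GC-MS
#' metabolomics convention) is decomposed by SVD. Scores are `U %*% D`,
#' loadings are `V`; each component's sign is fixed so that the
#' largest-magnitude loading entry is positive, making the decomposition
#' deterministic.
#'
#' @param table a [peak_table()] or [gene_table()] (complete data).
#' @param n_components number of components to retain.
#' @param scaling "autoscale" (center + unit variance, default) or "center".
#'   Analytes with zero variance cannot be autoscaled and are excluded with
#'   a warning.
#' @return object of class `latent_model` with elements `method`, `scores`
#'   (sample x component), `loadings` (analyte x component), `explained`
#'   (fraction of total variance per component, non-increasing), `center`,
#'   `scale`, and `X` (the scaled matrix, for reconstruction checks).
#' @export
pca_fit <- function(table, n_components = 2,
                    scaling = c("autoscale", "center")) {
  scaling <- match.arg(scaling)
  X <- prepare_X(table, scaling)
  n_components <- min(n_components, nrow(X) - 1L, ncol(X))
  sv <- svd(X)
  flip <- apply(sv$v, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  sv$u <- sweep(sv$u, 2L, flip, "*")
  sv$v <- sweep(sv$v, 2L, flip, "*")
  keep <- seq_len(n_components)
  structure(
    list(method = "pca",
         n_components = n_components,
         scores = (sv$u %*% diag(sv$d, length(sv$d)))[, keep, drop = FALSE],
         loadings = sv$v[, keep, drop = FALSE],
         explained = (sv$d^2 / sum(sv$d^2))[keep],
         singular_values = sv$d,
         center = attr(X, "center_vec"), scale = attr(X, "scale_vec"),
         X = X),
    class = "latent_model")
}

prepare_X <- function(table, scaling) {
  stopifnot(inherits(table, "omics_table"))
  m <- table$intensities
  if (anyNA(m))
    stop("validation error: missing intensities; impute first", call. = FALSE)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("design error: need at least 2 analytes and 2 samples", call. = FALSE)
  X <- t(m)  # samples x analytes
  if (scaling == "autoscale") {
    sdv <- apply(X, 2L, stats::sd)
    if (any(sdv == 0)) {
      warning("excluding constant analyte(s) under autoscaling: ",
              paste(colnames(X)[sdv == 0], collapse = ", "))
      X <- X[, sdv > 0, drop = FALSE]
      sdv <- sdv[sdv > 0]
    }
    ctr <- colMeans(X)
    X <- scale(X, center = ctr, scale = sdv)
  } else {
    ctr <- colMeans(X)
    sdv <- rep(1, ncol(X))
    X <- scale(X, center = ctr, scale = FALSE)
  }
  out <- X[, , drop = FALSE]
  attributes(out)$dimnames <- dimnames(X)
  attr(out, "center_vec") <- ctr
  attr(out, "scale_vec") <- sdv
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

# PLS1 components for a centered X and centered univariate y.
# For a univariate response the NIPALS inner loop converges in one pass, so
# each component is the closed form w = X'y / ||X'y||, t = Xw, followed by
# deflation of X (and y) by the component.
pls1_components <- function(X, y, n_components) {
  n_components <- max(1L, min(n_components, dim(X)))
  W <- P <- matrix(0, ncol(X), n_components)
  Tm <- matrix(0, nrow(X), n_components)
  q <- numeric(n_components)
  Xd <- X; yd <- y
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { n_components <- a - 1L; break }
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    p <- drop(crossprod(Xd, t)) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, p)
    yd <- yd - qa * t
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t; q[a] <- qa
  }
  keep <- seq_len(n_components)
  list(W = W[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
       T = Tm[, keep, drop = FALSE], q = q[keep],
       n_components = n_components)
}

pls1_predict <- function(fit, Xnew) {
  # regression coefficients b = W (P'W)^-1 q
  b <- fit$W %*% solve(crossprod(fit$P, fit$W), fit$q)
  drop(Xnew %*% b)
}

vip_scores <- function(fit) {
  ss <- fit$q^2 * colSums(fit$T^2)           # y-variance explained per comp
  Wn <- sweep(fit$W, 2L, sqrt(colSums(fit$W^2)), "/")
  p <- nrow(fit$W)
  sqrt(p * drop(Wn^2 %*% ss) / sum(ss))
}

deterministic_folds <- function(groups, k) {
  # stratified round-robin assignment: within each group, samples are
  # enumerated in table order and dealt to folds 1..k in turn; no RNG, so
  # cross-validation is reproducible by construction
  fold <- integer(length(groups))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    fold[idx] <- ((seq_along(idx) - 1L) %% k) + 1L
  }
  fold
}

#' Two-class PLS-DA with VIP scores and cross-validated Q2
#'
#' Fits partial least squares regression of a +/-1 group response on the
#' autoscaled intensity matrix (PLS1; for a univariate response the NIPALS
#' inner iteration reduces to a closed form per component). Reported model
#' quality is R2Y (in-sample fraction of response variance explained) and
#' Q2 (its k-fold cross-validated counterpart, `1 - PRESS/TSS`) with
#' stratified, deterministically assigned folds. VIP scores satisfy
#' `mean(VIP^2) = 1`.
#'
#' This PLS-DA (optionally preceded by [osc_correct()]) is an open-math
#' stand-in for proprietary OPLS-DA implementations; for a two-class model
#' the predictive component and VIP ranking are equivalent in
#' interpretation.
#'
#' @param table a [peak_table()] or [gene_table()].
#' @param groups optional named group vector; defaults to `table$groups`.
#'   Exactly two distinct labels are required.
#' @param n_components number of latent components (truncated with a warning
#'   at the matrix rank).
#' @param cv_folds number of cross-validation folds (default 7); each group
#'   must have at least `cv_folds` members... at minimum every fold must
#'   retain both classes, which the stratified assignment guarantees when
#'   group sizes are >= `cv_folds`.
#' @param scaling "autoscale" or "center".
#' @return `latent_model` with `scores`, `loadings` (x-loadings), `weights`,
#'   `vip`, `r2y`, `q2`, `explained` (fraction of X variance per component),
#'   plus the fitting context used by [permutation_validate()].
#' @export
plsda_fit <- function(table, groups = NULL, n_components = 2, cv_folds = 7,
                      scaling = c("autoscale", "center")) {
  scaling <- match.arg(scaling)
  X <- prepare_X(table, scaling)
  if (is.null(groups)) groups <- table$groups
  groups <- groups[rownames(X)]
  lev <- unique(groups)
  if (length(lev) != 2L)
    stop("design error: PLS-DA needs exactly two groups, got ",
         length(lev), call. = FALSE)
  cv_folds <- min(cv_folds, min(table(groups)))
  if (cv_folds < 2L)
    stop("design error: each group needs >= 2 samples for cross-validation",
         call. = FALSE)
  y <- ifelse(groups == lev[1], 1, -1)
  rank_x <- qr(X)$rank
  if (n_components > rank_x) {
    warning("n_components reduced to matrix rank (", rank_x, ")")
    n_components <- rank_x
  }
  yc <- y - mean(y)
  fit <- pls1_components(X, yc, n_components)
  yhat <- pls1_predict(fit, X) + mean(y)
  tss <- sum((y - mean(y))^2)
  r2y <- 1 - sum((y - yhat)^2) / tss
  q2 <- plsda_q2(X, y, fit$n_components, deterministic_folds(groups, cv_folds))
  structure(
    list(method = "plsda",
         n_components = fit$n_components,
         scores = fit$T, loadings = fit$P, weights = fit$W,
         y_loadings = fit$q,
         explained = colSums(fit$T^2) * colSums(fit$P^2) / sum(X^2),
         vip = stats::setNames(vip_scores(fit), colnames(X)),
         r2y = r2y, q2 = q2,
         classes = lev, groups = groups, cv_folds = cv_folds,
         scaling = scaling, X = X, y = y),
    class = "latent_model")
}

plsda_q2 <- function(X, y, n_components, fold) {
  # X arrives already scaled (the scaling is part of the model definition,
  # applied once, as in the standard PLS-DA workflow); folds re-center only
  press <- 0
  for (k in unique(fold)) {
    test <- fold == k
    ytr <- y[!test]
    ctr <- colMeans(X[!test, , drop = FALSE])
    Xtr <- scale(X[!test, , drop = FALSE], ctr, FALSE)
    Xte <- scale(X[test, , drop = FALSE], ctr, FALSE)
    fit <- pls1_components(Xtr, ytr - mean(ytr), n_components)
    if (fit$n_components == 0L) {
      press <- press + sum((y[test] - mean(ytr))^2)
    } else {
      pred <- pls1_predict(fit, Xte) + mean(ytr)
      press <- press + sum((y[test] - pred)^2)
    }
  }
  1 - press / sum((y - mean(y))^2)
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("<latent_model: %s> %d component(s), %d samples x %d variables\n",
              x$method, x$n_components, nrow(x$scores),
              nrow(x$loadings)))
  if (x$method == "pca")
    cat("explained variance:",
        paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n")
  if (!is.null(x$q2))
    cat(sprintf("R2Y = %.3f, Q2 = %.3f (%d-fold CV)\n", x$r2y, x$q2,
                x$cv_folds))
  invisible(x)
}

#' Permutation validation of a PLS-DA model
#'
#' Refits the model under `n_perm` random permutations of the class labels
#' and reports `p = (1 + #[Q2_perm >= Q2_obs]) / (1 + n_perm)` — the
#' standard guard against an overfitted discriminant model. Reproducible
#' under a fixed seed.
#'
#' @param model a fitted `latent_model` from [plsda_fit()].
#' @param n_perm number of label permutations (a warning is issued below
#'   20, where the p-value resolution is too coarse to be useful).
#' @param seed optional integer seed.
#' @return list with `p_value`, `q2_observed`, `q2_permuted` (vector).
#' @export
permutation_validate <- function(model, n_perm = 200, seed = NULL) {
  stopifnot(inherits(model, "latent_model"), model$method == "plsda")
  if (n_perm < 20) warning("n_perm < 20 gives a very coarse p-value")
  if (!is.null(seed)) set.seed(seed)
  X <- model$X
  q2p <- vapply(seq_len(n_perm), function(i) {
    yp <- sample(model$y)
    gp <- ifelse(yp > 0, model$classes[1], model$classes[2])
    plsda_q2(X, yp, model$n_components,
             deterministic_folds(gp, model$cv_folds))
  }, numeric(1))
  list(p_value = (1 + sum(q2p >= model$q2)) / (1 + n_perm),
       q2_observed = model$q2,
       q2_permuted = q2p)
}

#' Single-component orthogonal signal correction
#'
#' Removes from the data matrix one component orthogonal to the class
#' response before PLS-DA, approximating the orthogonal filtering step of
#' OPLS-DA. Returns the corrected table.
#'
#' @param table a [peak_table()] or [gene_table()].
#' @param groups optional two-level group vector (defaults to table groups).
#' @return a table of the same class with the orthogonal component removed
#'   (intensities are replaced by corrected, autoscaled-space values mapped
#'   back to the original scale).
#' @export
osc_correct <- function(table, groups = NULL) {
  X <- prepare_X(table, "autoscale")
  if (is.null(groups)) groups <- table$groups
  groups <- groups[rownames(X)]
  lev <- unique(groups)
  stopifnot(length(lev) == 2L)
  y <- ifelse(groups == lev[1], 1, -1)
  yc <- y - mean(y)
  fit <- pls1_components(X, yc, 1L)
  # orthogonalize the first principal direction of X against the predictive
  # weight, then deflate
  p1 <- svd(X)$v[, 1]
  w_ortho <- p1 - fit$W[, 1] * sum(p1 * fit$W[, 1])
  nw <- sqrt(sum(w_ortho^2))
  if (nw < 1e-12) return(table)
  w_ortho <- w_ortho / nw
  t_o <- drop(X %*% w_ortho)
  p_o <- drop(crossprod(X, t_o)) / sum(t_o^2)
  Xc <- X - tcrossprod(t_o, p_o)
  # back to original scale; intensities may not remain strictly positive
  # after filtering, so clip at zero (documented limitation)
  m <- t(sweep(sweep(Xc, 2L, attr(X, "scale_vec"), "*"),
               2L, attr(X, "center_vec"), "+"))
  m[m < 0] <- 0
  out <- table[rownames(m), ]
  out$intensities <- m[, colnames(out$intensities), drop = FALSE]
  out
}
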