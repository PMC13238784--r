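# Run code under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# NIPALS PLS1 on pre-standardized X, y. Returns per-component weights
# (columns of unit norm), scores, x/y loadings, and the coefficient path
# B[, a] for models with 1..A components (standardized scale).
nipals_pls1 <- function(Xs, ys, ncomp) {
  n <- nrow(Xs); p <- ncol(Xs)
  W <- P <- matrix(0, p, ncomp)
  TT <- matrix(0, n, ncomp)
  q <- tt <- numeric(ncomp)
  Xd <- Xs; yd <- ys
  a_done <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # residual response orthogonal to X
    w <- w / nw
    t_a <- Xd %*% w
    tta <- sum(t_a^2)
    if (tta < 1e-12) break
    p_a <- crossprod(Xd, t_a) / tta
    q_a <- sum(yd * t_a) / tta
    W[, a] <- w; P[, a] <- p_a; TT[, a] <- t_a
    q[a] <- q_a; tt[a] <- tta
    Xd <- Xd - tcrossprod(t_a, p_a)
    yd <- yd - q_a * t_a
    a_done <- a
  }
  if (a_done == 0L)
    stop("PLS: response is orthogonal to all predictors", call. = FALSE)
  W <- W[, seq_len(a_done), drop = FALSE]
  P <- P[, seq_len(a_done), drop = FALSE]
  TT <- TT[, seq_len(a_done), drop = FALSE]
  q <- q[seq_len(a_done)]; tt <- tt[seq_len(a_done)]
  B <- matrix(0, p, a_done)
  for (a in seq_len(a_done)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    R <- Wa %*% solve(crossprod(Pa, Wa))
    B[, a] <- R %*% q[seq_len(a)]
  }
  list(W = W, P = P, scores = TT, q = q, tt = tt, B = B, ncomp = a_done)
}

standardize_cols <- function(x, what = "predictor") {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  if (any(scl == 0))
    stop("zero-variance ", what, "(s): ",
         paste(colnames(x)[scl == 0], collapse = ", "), call. = FALSE)
  list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

#' Cross-validated RMSEP of a PLS fit
#'
#' K-fold cross-validation: root mean squared error of prediction (original
#' response scale) for each component count 1..`ncomp_max`. Fold assignment
#' is seeded and deterministic.
#'
#' @param x predictor matrix (plots x predictors).
#' @param y response vector.
#' @param ncomp_max maximum number of latent components.
#' @param cv_folds number of folds (capped at n).
#' @param seed fold-assignment seed.
#' @return data.frame with `ncomp`, `rmsep`.
#' @export
cv_rmsep <- function(x, y, ncomp_max = 5, cv_folds = 10, seed = 1) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  k <- min(cv_folds, n)
  ncomp_max <- min(ncomp_max, ncol(x), n - max(2L, ceiling(n / k)) - 1L)
  ncomp_max <- max(1L, ncomp_max)
  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  sqerr <- matrix(NA_real_, n, ncomp_max)
  for (f in seq_len(k)) {
    tr <- folds != f
    std_x <- standardize_cols(x[tr, , drop = FALSE])
    std_y <- standardize_cols(matrix(y[tr]), what = "response")
    a_max <- min(ncomp_max, qr(std_x$x)$rank)
    fit <- nipals_pls1(std_x$x, as.numeric(std_y$x), a_max)
    xt <- sweep(sweep(x[!tr, , drop = FALSE], 2, std_x$center),
                2, std_x$scale, "/")
    for (a in seq_len(fit$ncomp)) {
      pred <- as.numeric(xt %*% fit$B[, a]) * std_y$scale + std_y$center
      sqerr[!tr, a] <- (y[!tr] - pred)^2
    }
    if (fit$ncomp < ncomp_max)  # rank-deficient fold: extra comps add nothing
      for (a in seq(fit$ncomp + 1L, ncomp_max))
        sqerr[!tr, a] <- sqerr[!tr, fit$ncomp]
  }
  data.frame(ncomp = seq_len(ncomp_max),
             rmsep = sqrt(colMeans(sqerr)))
}

#' Partial least squares regression with VIP scores
#'
#' Single-response PLS (NIPALS with deflation) of `y` on `x`, both
#' z-standardized internally so variable-importance-in-projection (VIP)
#' scores are comparable across predictors. With `ncomp = NULL` the number
#' of latent components is chosen by seeded K-fold cross-validation
#' (smallest RMSEP, ties to the smaller model). When `ncomp` equals the
#' rank of `x`, the coefficients coincide with ordinary least squares.
#'
#' VIP of predictor j:
#' `VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a )`, where
#' `SSY_a = q_a^2 t_a't_a` is the response sum of squares explained by
#' component a and the weight vectors `w_a` have unit norm. The VIPs always
#' satisfy `sum_j VIP_j^2 = p`.
#'
#' @param x predictor matrix or data.frame (plots x predictors), or a
#'   formula.
#' @param y response vector (AGB, typically).
#' @param ncomp number of latent components; `NULL` to select by CV.
#' @param ncomp_max maximum components considered when `ncomp = NULL`.
#' @param cv_folds folds for component selection.
#' @param seed fold-assignment seed.
#' @param ... passed between methods.
#' @return object of class `pls_vip` with components `coefficients`
#'   (original scale, incl. intercept), `coef_std`, `weights`, `loadings`,
#'   `scores`, `q`, `tt`, `vip`, `ncomp`, `fitted.values`, `residuals`,
#'   `r_squared`, `cv` (RMSEP table or NULL).
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- x[, 1] + rnorm(20, sd = 0.2)
#' fit <- pls_vip(x, y, ncomp = 2)
#' vip(fit)
pls_vip <- function(x, ...) UseMethod("pls_vip")

#' @rdname pls_vip
#' @param data data.frame for the formula interface.
#' @export
pls_vip.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  mm <- stats::model.matrix(attr(mf, "terms"), mf)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  out <- pls_vip.default(mm, y, ...)
  out$call <- match.call()
  out
}

#' @rdname pls_vip
#' @export
pls_vip.default <- function(x, y, ncomp = NULL, ncomp_max = 5,
                            cv_folds = 10, seed = 1, ...) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y))
  if (anyNA(x) || anyNA(y)) stop("NA in predictors or response",
                                 call. = FALSE)
  std_x <- standardize_cols(x)
  std_y <- standardize_cols(matrix(y), what = "response")
  rank_x <- qr(std_x$x)$rank
  cv <- NULL
  if (is.null(ncomp)) {
    cv <- cv_rmsep(x, y, min(ncomp_max, rank_x), cv_folds, seed)
    ncomp <- cv$ncomp[which.min(cv$rmsep)]
  }
  if (ncomp > rank_x)
    stop("ncomp (", ncomp, ") exceeds rank of predictor matrix (",
         rank_x, ")", call. = FALSE)
  if (ncomp >= nrow(x))
    stop("ncomp must be smaller than the number of plots", call. = FALSE)
  fit <- nipals_pls1(std_x$x, as.numeric(std_y$x), ncomp)
  ncomp <- fit$ncomp
  ssy <- fit$q^2 * fit$tt
  p <- ncol(x)
  vip <- sqrt(p * as.numeric(fit$W^2 %*% ssy) / sum(ssy))
  names(vip) <- colnames(x)
  b_std <- fit$B[, ncomp]
  b <- b_std * std_y$scale / std_x$scale
  intercept <- std_y$center - sum(b * std_x$center)
  fitted <- as.numeric(x %*% b) + intercept
  res <- y - fitted
  out <- list(
    coefficients = c("(Intercept)" = unname(intercept),
                     setNames(b, colnames(x))),
    coef_std = setNames(b_std, colnames(x)),
    weights = fit$W, loadings = fit$P, scores = fit$scores,
    q = fit$q, tt = fit$tt, vip = vip, ncomp = ncomp,
    fitted.values = fitted, residuals = res, y = y,
    r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
    x_center = std_x$center, x_scale = std_x$scale,
    y_center = std_y$center, y_scale = std_y$scale,
    cv = cv, call = match.call()
  )
  class(out) <- "pls_vip"
  out
}

#' Extract VIP scores
#' @param object a fitted [pls_vip()] or [shave_pls()] object.
#' @return named numeric vector of per-predictor VIP scores.
#' @export
vip <- function(object) {
  if (inherits(object, "pls_shave")) object <- object$model
  stopifnot(inherits(object, "pls_vip"))
  object$vip
}

#' @export
print.pls_vip <- function(x, ...) {
  cat("PLS regression (", x$ncomp, " component",
      if (x$ncomp > 1) "s", ", n = ", length(x$y), ", p = ",
      length(x$vip), ")\n", sep = "")
  cat(sprintf("  in-sample R2: %.3f\n", x$r_squared))
  v <- sort(x$vip, decreasing = TRUE)
  cat("  top VIP:", paste(sprintf("%s=%.3f", names(v)[seq_len(min(5, length(v)))],
                                  v[seq_len(min(5, length(v)))]),
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.pls_vip <- function(object, ...) {
  out <- list(fit = object, vip_table = classify_vip(object$vip))
  class(out) <- "summary.pls_vip"
  out
}

#' @export
print.summary.pls_vip <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$cv)) {
    cat("  CV RMSEP by components:\n")
    print(x$fit$cv, row.names = FALSE)
  }
  cat("  VIP classification:\n")
  print(x$vip_table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pls_vip <- function(object, standardized = FALSE, ...) {
  if (standardized) object$coef_std else object$coefficients
}

#' @export
predict.pls_vip <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  newdata <- as.matrix(newdata)
  newdata <- newdata[, names(object$coef_std), drop = FALSE]
  b <- object$coefficients
  as.numeric(newdata %*% b[-1L]) + b[1L]
}

#' @export
fitted.pls_vip <- function(object, ...) object$fitted.values

#' @export
residuals.pls_vip <- function(object, ...) object$residuals

#' VIP barplot of a PLS fit
#' @param x a [pls_vip()] object.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot.pls_vip <- function(x, ...) {
  v <- sort(x$vip, decreasing = TRUE)
  mp <- graphics::barplot(v, las = 2, ylab = "VIP",
                          main = "Variable importance in projection", ...)
  graphics::abline(h = c(0.8, 1), lty = c(3, 2))
  invisible(mp)
}

#' Classify predictors by VIP band
#'
#' Major contributors have VIP > 1; medium 0.8 < VIP <= 1; negligible
#' VIP <= 0.8. Values exactly on a band edge are classified by these
#' half-open intervals and flagged as boundary cases.
#'
#' @param vips named numeric vector of VIP scores.
#' @return data.frame sorted by descending VIP: `predictor`, `vip`, `band`,
#'   `boundary`.
#' @export
classify_vip <- function(vips) {
  stopifnot(is.numeric(vips))
  if (is.null(names(vips))) names(vips) <- paste0("X", seq_along(vips))
  band <- ifelse(vips > 1, "major",
                 ifelse(vips > 0.8, "medium", "negligible"))
  out <- data.frame(predictor = names(vips), vip = as.numeric(vips),
                    band = band,
                    boundary = abs(vips - 1) < 1e-12 |
                      abs(vips - 0.8) < 1e-12,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$vip, out$predictor), ]
  rownames(out) <- NULL
  out
}

#' Backward variable shaving for PLS
#'
#' Iteratively fits a PLS model (components chosen each iteration by seeded
#' K-fold cross-validation), records the cross-validated RMSEP, and removes
#' the `step_fraction` of current predictors with the lowest VIP (always
#' leaving at least one) until a single predictor remains. The returned
#' selection is the predictor subset whose iteration had the smallest CV
#' RMSEP (ties to the smaller subset); the final model is refitted on that
#' subset.
#'
#' @inheritParams pls_vip.default
#' @param step_fraction fraction of current predictors dropped per
#'   iteration (default 0.2).
#' @return object of class `pls_shave`: `selected` (predictor names),
#'   `model` (final [pls_vip()] refit), `vip_table`
#'   (see [classify_vip()]), `steps` (per-iteration summary), `path`
#'   (predictor sets per iteration).
#' @export
shave_pls <- function(x, y, cv_folds = 10, step_fraction = 0.2,
                      ncomp_max = 5, seed = 1) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  if (ncol(x) < 2L) stop("shaving needs at least 2 predictors",
                         call. = FALSE)
  if (step_fraction <= 0 || step_fraction >= 1)
    stop("step_fraction must be in (0, 1)", call. = FALSE)
  cur <- colnames(x)
  steps <- list(); path <- list()
  it <- 0L
  repeat {
    it <- it + 1L
    xi <- x[, cur, drop = FALSE]
    cv <- cv_rmsep(xi, y, ncomp_max, cv_folds, seed)
    a <- cv$ncomp[which.min(cv$rmsep)]
    fit <- pls_vip(xi, y, ncomp = a)
    steps[[it]] <- data.frame(iter = it, n_pred = length(cur), ncomp = a,
                              rmsep = min(cv$rmsep))
    path[[it]] <- cur
    if (length(cur) == 1L) break
    ndrop <- max(1L, floor(step_fraction * length(cur)))
    ndrop <- min(ndrop, length(cur) - 1L)
    v <- sort(fit$vip)
    cur <- setdiff(cur, names(v)[seq_len(ndrop)])
  }
  steps <- do.call(rbind, steps)
  best <- which(steps$rmsep == min(steps$rmsep))
  best <- best[which.min(steps$n_pred[best])]
  selected <- path[[best]]
  cv_best <- cv_rmsep(x[, selected, drop = FALSE], y, ncomp_max,
                      cv_folds, seed)
  model <- pls_vip(x[, selected, drop = FALSE], y,
                   ncomp = cv_best$ncomp[which.min(cv_best$rmsep)])
  out <- list(selected = selected, model = model,
              vip_table = classify_vip(model$vip),
              steps = steps, path = path,
              settings = list(cv_folds = cv_folds,
                              step_fraction = step_fraction,
                              ncomp_max = ncomp_max, seed = seed))
  class(out) <- "pls_shave"
  out
}

#' @export
print.pls_shave <- function(x, ...) {
  cat("PLS backward shaving:", max(x$steps$n_pred), "->",
      length(x$selected), "predictors over", nrow(x$steps),
      "iterations\n")
  cat(sprintf("  best CV RMSEP: %.4f (ncomp = %d)\n",
              min(x$steps$rmsep), x$model$ncomp))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  print(x$vip_table, row.names = FALSE)
  invisible(x)
}

#' @export
plot.pls_shave <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$steps$n_pred, x$steps$rmsep, type = "b",
                 xlab = "predictors retained", ylab = "CV RMSEP",
                 main = "Shaving path", ...)
  graphics::abline(v = length(x$selected), lty = 2)
  plot(x$model)
  invisible(x)
}
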