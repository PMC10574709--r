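# NIPALS PLS2 discriminant analysis with VIP scores.
#
# Conventions follow the mainstream chemometrics software the field uses for
# these models: X is centered/unit-variance scaled upstream; the one-hot
# class matrix Y is centered and unit-variance scaled inside the fit; both
# blocks are deflated per component; Q2 denominators are total (scaled) Y sum
# of squares pooled over dummy columns.

#' One-hot class indicator matrix for PLS-DA
#'
#' @param labels character or factor vector of class labels.
#' @param classes class order; defaults to sorted unique labels.
#' @return 0/1 matrix samples x classes, each row summing to 1.
#' @export
dummy_y <- function(labels, classes = NULL) {
  labels <- as.character(labels)
  classes <- classes %||% sort(unique(labels))
  if (length(classes) < 2) stop("at least two classes are required")
  Y <- vapply(classes, function(cl) as.numeric(labels == cl),
              numeric(length(labels)))
  rownames(Y) <- names(labels)
  Y
}

scale_y <- function(Y) {
  ctr <- colMeans(Y)
  sds <- apply(Y, 2, stats::sd)
  if (any(sds < .Machine$double.eps * 1e3)) {
    stop("a class indicator column has zero variance (single-class input)")
  }
  list(values = sweep(sweep(Y, 2, ctr), 2, sds, "/"), center = ctr, scale = sds)
}

# Core NIPALS PLS2: X and Ys both centered/scaled, returns weights W,
# loadings P, scores T, Y-loadings C, and per-component explained Y variance.
nipals_pls <- function(X, Ys, n_components, tol = 1e-10, max_iter = 500L) {
  n <- nrow(X)
  p <- ncol(X)
  ssx0 <- sum(X^2)
  ssy0 <- sum(Ys^2)
  W <- P <- NULL
  Ts <- NULL
  C <- NULL
  ssy_explained <- numeric(0)
  r2x <- numeric(0)
  E <- X
  F_ <- Ys
  for (a in seq_len(n_components)) {
    ssy_before <- sum(F_^2)
    if (ssy_before < ssy0 * 1e-12 || sum(E^2) < ssx0 * 1e-12) break
    # deterministic start: Y column of largest variance
    u <- F_[, which.max(apply(F_, 2, stats::var))]
    for (iter in seq_len(max_iter)) {
      w <- as.vector(crossprod(E, u))
      w <- w / sqrt(sum(w^2))
      t <- as.vector(E %*% w)
      c_ <- as.vector(crossprod(F_, t)) / sum(t^2)
      u_new <- as.vector(F_ %*% c_) / sum(c_^2)
      if (sqrt(sum((u_new - u)^2)) < tol * max(sqrt(sum(u_new^2)), 1)) {
        u <- u_new
        break
      }
      u <- u_new
    }
    # final pass with converged u
    w <- as.vector(crossprod(E, u))
    w <- w / sqrt(sum(w^2))
    s <- sign(w[which.max(abs(w))])
    w <- s * w
    t <- as.vector(E %*% w)
    c_ <- as.vector(crossprod(F_, t)) / sum(t^2)
    pl <- as.vector(crossprod(E, t)) / sum(t^2)
    E <- E - tcrossprod(t, pl)
    F_ <- F_ - tcrossprod(t, c_)
    W <- cbind(W, w)
    P <- cbind(P, pl)
    Ts <- cbind(Ts, t)
    C <- cbind(C, c_)
    ssy_explained <- c(ssy_explained, ssy_before - sum(F_^2))
    r2x <- c(r2x, sum(t^2 * sum(pl^2)) / ssx0)
  }
  list(W = W, P = P, T = Ts, C = C, ssy_explained = ssy_explained,
       r2x = r2x, ssx0 = ssx0, ssy0 = ssy0,
       r2y = ssy_explained / ssy0)
}

#' Fit a PLS-DA model
#'
#' NIPALS PLS2 regression of the scaled one-hot class matrix on the scaled
#' bucket matrix, with deflation of both blocks per component.
#'
#' @param X centered/scaled matrix (samples x variables).
#' @param Y 0/1 one-hot matrix from [dummy_y()] (scaled internally), or a
#'   label vector.
#' @param n_components number of latent components A.
#' @return a `plsda_model` with weights `W`, loadings `P`, scores `T`,
#'   Y-loadings `C`, regression coefficients `B` (on scaled X to scaled Y),
#'   cumulative `r2x_cum`/`r2y_cum`, per-component `ssy_explained`, the class
#'   order and the internal Y scaling.
#' @export
fit_plsda <- function(X, Y, n_components = 2L) {
  if (!is.matrix(Y)) Y <- dummy_y(Y)
  check_centered(X)
  stopifnot(n_components >= 1, n_components <= min(nrow(X) - 1L, ncol(X)))
  ys <- scale_y(Y)
  fit <- nipals_pls(X, ys$values, n_components)
  A <- ncol(fit$W)
  # B maps scaled X to scaled-Y predictions: B = W (P'W)^-1 C'
  Wstar <- fit$W %*% solve(crossprod(fit$P, fit$W))
  B <- Wstar %*% t(fit$C)
  structure(list(n_components = A, W = fit$W, P = fit$P, T = fit$T, C = fit$C,
                 B = B, r2x = fit$r2x, r2x_cum = cumsum(fit$r2x),
                 r2y = fit$r2y, r2y_cum = cumsum(fit$r2y),
                 ssy_explained = fit$ssy_explained,
                 classes = colnames(Y), y_center = ys$center, y_scale = ys$scale,
                 variable_names = colnames(X)),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("plsda_model: A = %d, R2X(cum) = %.3f, R2Y(cum) = %.3f\n",
              x$n_components, x$r2x_cum[x$n_components], x$r2y_cum[x$n_components]))
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' VIP_j = sqrt( p * sum_a [ SSY_a (w_aj / ||w_a||)^2 ] / sum_a SSY_a ),
#' where SSY_a is the Y variance explained by component a pooled over dummy
#' columns.  Mean square of the VIPs is 1 by construction, so VIP > 1 flags
#' above-average contributors.
#'
#' @param model a fitted `plsda_model` or `oplsda_model`.
#' @param threshold reporting threshold, default 1.0.
#' @return a `vip_result`: list with `vip` (named vector) and `threshold`.
#' @export
vip_scores <- function(model, threshold = 1.0) {
  UseMethod("vip_scores")
}

#' @export
vip_scores.plsda_model <- function(model, threshold = 1.0) {
  W <- model$W
  ssy <- model$ssy_explained
  p <- nrow(W)
  wn2 <- sweep(W, 2, sqrt(colSums(W^2)), "/")^2
  vip <- sqrt(p * as.vector(wn2 %*% ssy) / sum(ssy))
  names(vip) <- model$variable_names %||% paste0("V", seq_len(p))
  structure(list(vip = vip, threshold = threshold), class = "vip_result")
}

#' @export
vip_scores.oplsda_model <- function(model, threshold = 1.0) {
  # VIP over the predictive components of the orthogonal-filtered model
  W <- model$W_pred
  ssy <- model$ssy_explained
  p <- nrow(W)
  wn2 <- sweep(W, 2, sqrt(colSums(W^2)), "/")^2
  vip <- sqrt(p * as.vector(wn2 %*% ssy) / sum(ssy))
  names(vip) <- model$variable_names %||% paste0("V", seq_len(p))
  structure(list(vip = vip, threshold = threshold), class = "vip_result")
}

#' Predict class membership from a fitted latent-variable model
#'
#' Predicted one-hot responses are computed from the regression coefficients
#' and back-transformed to the 0/1 scale; the label is the argmax over class
#' columns, ties broken by the lowest class index.
#'
#' @param model a `plsda_model` or `oplsda_model`.
#' @param X_new matrix scaled with the TRAINING scaling record.
#' @return list with `labels` (character) and `y_pred` (matrix on the 0/1
#'   dummy scale).
#' @export
predict_class <- function(model, X_new) {
  if (is.null(dim(X_new))) X_new <- matrix(X_new, nrow = 1)
  if (ncol(X_new) != nrow(model$B)) {
    stop("column count of X_new does not match the fitted model")
  }
  Ys_hat <- X_new %*% model$B
  Y_hat <- sweep(sweep(Ys_hat, 2, model$y_scale, "*"), 2, model$y_center, "+")
  colnames(Y_hat) <- model$classes
  idx <- apply(Y_hat, 1, which.max)
  list(labels = model$classes[idx], y_pred = Y_hat)
}
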