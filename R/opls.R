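# Orthogonal projections to latent structures discriminant analysis
# (O-PLS filtering of class-orthogonal X variation followed by a PLS fit on
# the filtered block), with the S-line covariance/correlation diagnostic.

#' Fit an OPLS-DA model
#'
#' Structured X variation orthogonal to the class space is removed first:
#' each orthogonal component takes the loading of a one-component PLS fit,
#' projects out its part lying in the span of the X-side class weights
#' (for a single response this is the classical O-PLS weight
#' `w_o = p - (w'p)w`; for multi-class Y the projection is onto the span of
#' the weights of all Y columns), and deflates X by the resulting component.
#' The predictive components are then a PLS2 fit on the filtered matrix.
#' With `n_orthogonal = 0` the model degenerates to plain PLS-DA.
#'
#' @param X centered/scaled matrix.
#' @param Y one-hot matrix from [dummy_y()] or a label vector.
#' @param n_predictive number of predictive components; default
#'   `ncol(Y) - 1`.
#' @param n_orthogonal number of orthogonal components; `NULL` adds
#'   components while cross-validated Q2 improves by more than 0.01, up to
#'   `max_orthogonal`.
#' @param max_orthogonal cap for automatic selection (default 5).
#' @param folds,seed cross-validation controls for the automatic rule.
#' @return an `oplsda_model`: predictive scores/weights/loadings
#'   (`T_pred`, `W_pred`, `P_pred`), orthogonal parts (`T_orth`, `W_orth`,
#'   `P_orth`), coefficients `B` (over the original X columns), explained
#'   variance split `r2x_pred`/`r2x_orth`, cumulative `r2y_cum`, class order
#'   and Y scaling.
#' @export
fit_oplsda <- function(X, Y, n_predictive = NULL, n_orthogonal = 1L,
                       max_orthogonal = 5L, folds = 7L, seed = 1L) {
  if (!is.matrix(Y)) Y <- dummy_y(Y)
  check_centered(X)
  n_predictive <- n_predictive %||% (ncol(Y) - 1L)
  if (is.null(n_orthogonal)) {
    n_orthogonal <- choose_n_orthogonal(X, Y, n_predictive, max_orthogonal,
                                        folds, seed)
  }
  stopifnot(n_predictive >= 1, n_orthogonal >= 0)
  if (n_predictive + n_orthogonal > min(nrow(X) - 1L, ncol(X))) {
    stop("n_predictive + n_orthogonal exceeds the rank bound of X")
  }
  ys <- scale_y(Y)
  Ysc <- ys$values
  ssx0 <- sum(X^2)
  # X-side class-weight basis: weights of each scaled Y column
  Wy <- crossprod(X, Ysc)
  Wy <- qr.Q(qr(Wy))
  E <- X
  T_o <- W_o <- P_o <- NULL
  for (k in seq_len(n_orthogonal)) {
    cmp <- nipals_pls(E, Ysc, 1L)
    p <- cmp$P[, 1]
    w_o <- p - Wy %*% crossprod(Wy, p)
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12) break   # nothing orthogonal left to remove
    w_o <- as.vector(w_o) / nrm
    t_o <- as.vector(E %*% w_o)
    p_o <- as.vector(crossprod(E, t_o)) / sum(t_o^2)
    E <- E - tcrossprod(t_o, p_o)
    T_o <- cbind(T_o, t_o)
    W_o <- cbind(W_o, w_o)
    P_o <- cbind(P_o, p_o)
  }
  ss_filtered <- sum(E^2)
  fit <- nipals_pls(E, Ysc, n_predictive)
  Wstar <- fit$W %*% solve(crossprod(fit$P, fit$W))
  B_filtered <- Wstar %*% t(fit$C)
  # Coefficients over ORIGINAL X: x -> filtered x -> prediction.  Filtering
  # is x' (I - W_o P_o' ... ) applied sequentially; compose the projector.
  Fproj <- diag(ncol(X))
  if (!is.null(W_o)) {
    for (k in seq_len(ncol(W_o))) {
      Fproj <- Fproj %*% (diag(ncol(X)) - tcrossprod(W_o[, k], P_o[, k]))
    }
  }
  B <- Fproj %*% B_filtered
  r2x_orth <- if (is.null(T_o)) 0 else
    sum(vapply(seq_len(ncol(T_o)),
               function(k) sum(T_o[, k]^2) * sum(P_o[, k]^2), numeric(1))) / ssx0
  structure(list(n_predictive = ncol(fit$W),
                 n_orthogonal = if (is.null(T_o)) 0L else ncol(T_o),
                 T_pred = fit$T, W_pred = fit$W, P_pred = fit$P, C = fit$C,
                 T_orth = T_o, W_orth = W_o, P_orth = P_o,
                 B = B, ssy_explained = fit$ssy_explained,
                 r2x_pred = sum(fit$r2x) * ss_filtered / ssx0,
                 r2x_orth = r2x_orth,
                 r2y = fit$r2y, r2y_cum = cumsum(fit$r2y),
                 classes = colnames(Y), y_center = ys$center, y_scale = ys$scale,
                 variable_names = colnames(X)),
            class = "oplsda_model")
}

choose_n_orthogonal <- function(X, Y, n_predictive, max_orthogonal, folds, seed) {
  best <- cross_validate(X, Y, model_kind = "oplsda",
                         n_components = n_predictive, n_orthogonal = 0L,
                         folds = folds, seed = seed)$q2
  n_o <- 0L
  for (k in seq_len(max_orthogonal)) {
    q2 <- tryCatch(
      cross_validate(X, Y, model_kind = "oplsda",
                     n_components = n_predictive, n_orthogonal = k,
                     folds = folds, seed = seed)$q2,
      error = function(e) -Inf)
    if (q2 > best + 0.01) {
      best <- q2
      n_o <- k
    } else break
  }
  n_o
}

#' @export
print.oplsda_model <- function(x, ...) {
  cat(sprintf("oplsda_model: %d predictive + %d orthogonal, R2X = %.3f + %.3f, R2Y(cum) = %.3f\n",
              x$n_predictive, x$n_orthogonal, x$r2x_pred, x$r2x_orth,
              x$r2y_cum[length(x$r2y_cum)]))
  invisible(x)
}

#' S-line of a two-class OPLS-DA model
#'
#' For every X variable, the covariance p(cov) and Pearson correlation
#' p(corr) between the column and the first predictive score.  High |p(cov)|
#' with high |p(corr)| marks intense, reliable class markers; plotted against
#' chemical shift this is the S-line of NMR chemometrics.
#'
#' @param model a fitted `oplsda_model` (or `plsda_model`).
#' @param X the (scaled) training matrix the model was fitted on.
#' @return an `s_line` data frame: `variable`, `p_cov`, `p_corr`.
#' @export
s_line <- function(model, X) {
  t_p <- if (!is.null(model$T_pred)) model$T_pred[, 1] else model$T[, 1]
  n <- length(t_p)
  stopifnot(nrow(X) == n)
  ctr <- sweep(X, 2, colMeans(X))
  tc <- t_p - mean(t_p)
  p_cov <- as.vector(crossprod(ctr, tc)) / (n - 1)
  sds <- sqrt(colSums(ctr^2) / (n - 1))
  zero <- sds < .Machine$double.eps * 1e3
  p_corr <- p_cov / (sds * stats::sd(t_p))
  if (any(zero)) {
    warning(sum(zero), " zero-variance column(s); correlation set to 0")
    p_corr[zero] <- 0
  }
  out <- data.frame(variable = colnames(X) %||% paste0("V", seq_len(ncol(X))),
                    p_cov = p_cov, p_corr = p_corr)
  class(out) <- c("s_line", "data.frame")
  out
}
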