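# NIPALS principal component analysis with SIMCA-style cumulative R2X and
# Wold elementwise cross-validated Q2.

# One NIPALS component on a (possibly incomplete) centered matrix.
# Missing entries (NA) are skipped in each regression step, which is the
# classical Wold treatment used for cross-validation by deletion.
nipals_component <- function(E, tol = 1e-10, max_iter = 500L) {
  obs <- !is.na(E)
  E0 <- E
  E0[!obs] <- 0
  # deterministic start: column with the largest (observed) variance
  v <- apply(E, 2, function(col) stats::var(col[!is.na(col)]))
  v[is.na(v)] <- 0
  t <- E0[, which.max(v)]
  for (iter in seq_len(max_iter)) {
    # p_j = sum_i obs E_ij t_i / sum_i obs t_i^2
    num <- crossprod(E0, t)
    den <- crossprod(obs, t^2)
    p <- as.vector(num) / pmax(as.vector(den), .Machine$double.eps)
    p <- p / sqrt(sum(p^2))
    t_new <- as.vector(E0 %*% p) / pmax(as.vector(obs %*% p^2), .Machine$double.eps)
    if (sqrt(sum((t_new - t)^2)) < tol * max(sqrt(sum(t_new^2)), 1)) {
      t <- t_new
      break
    }
    t <- t_new
  }
  # sign convention: largest-magnitude loading entry positive
  s <- sign(p[which.max(abs(p))])
  if (s < 0) {
    p <- -p
    t <- -t
  }
  list(t = t, p = p)
}

check_centered <- function(X, tol = 1e-8) {
  if (max(abs(colMeans(X))) > tol) {
    stop("input matrix is not column-centered; scale it first (scale_columns)")
  }
}

#' Fit a principal component model by NIPALS
#'
#' Components are extracted sequentially from the centered (and usually
#' unit-variance scaled) matrix, in decreasing order of explained variance.
#' With `stop_rule = "q2"`, extraction stops when a component's Wold
#' cross-validated Q2 falls below `q2_threshold` (the usual significance rule
#' of chemometrics software); with `"none"` exactly `max_components` are
#' fitted.
#'
#' @param X centered numeric matrix (samples x variables).
#' @param max_components maximum number of components.
#' @param stop_rule `"none"` or `"q2"`.
#' @param q2_threshold per-component Q2 significance limit (default 0).
#' @param folds,seed cross-validation deletion groups and seed (used by the
#'   `"q2"` rule).
#' @return a `pca_model`: scores `T`, loadings `P`, `r2x` per component,
#'   `r2x_cum`, and `q2_cum` when the rule computed it.
#' @export
fit_pca <- function(X, max_components = 10L, stop_rule = c("none", "q2"),
                    q2_threshold = 0, folds = 7L, seed = 1L) {
  stop_rule <- match.arg(stop_rule)
  check_centered(X)
  max_components <- min(max_components, nrow(X) - 1L, ncol(X))
  ss_total <- sum(X^2)
  E <- X
  Ts <- NULL
  Ps <- NULL
  r2x <- numeric(0)
  q2comp <- numeric(0)
  press_ratio <- numeric(0)
  for (a in seq_len(max_components)) {
    if (sum(E^2) < ss_total * 1e-12) break
    if (stop_rule == "q2") {
      cvr <- wold_cv_component(E, folds = folds,
                               seed = derive_seed(seed, "pca-cv", a))
      if (cvr$q2 < q2_threshold) break
      q2comp <- c(q2comp, cvr$q2)
      press_ratio <- c(press_ratio, cvr$press / sum(E^2))
    }
    cmp <- nipals_component(E)
    E <- E - tcrossprod(cmp$t, cmp$p)
    Ts <- cbind(Ts, cmp$t)
    Ps <- cbind(Ps, cmp$p)
    r2x <- c(r2x, sum(cmp$t^2) / ss_total)
  }
  A <- length(r2x)
  if (A == 0) stop("no significant component could be extracted")
  colnames(Ts) <- colnames(Ps) <- paste0("PC", seq_len(A))
  structure(list(n_components = A, scores = Ts, loadings = Ps,
                 r2x = r2x, r2x_cum = cumsum(r2x),
                 q2_per_component = if (length(q2comp)) q2comp else NULL,
                 q2_cum = if (length(press_ratio)) 1 - cumprod(press_ratio) else NULL,
                 ss_total = ss_total),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d components, R2X(cum) = %.3f", x$n_components,
              x$r2x_cum[x$n_components]))
  if (!is.null(x$q2_cum)) cat(sprintf(", Q2(cum) = %.3f", x$q2_cum[length(x$q2_cum)]))
  cat("\n")
  invisible(x)
}

# Wold cross-validation of ONE component on residual matrix E: elements are
# deleted in `folds` diagonal stripes, the component refitted with the
# deletions treated as missing, and the deleted elements predicted.
wold_cv_component <- function(E, folds = 7L, seed = 1L) {
  n <- nrow(E)
  p <- ncol(E)
  set.seed(seed)
  ri <- sample(n)
  ci <- sample(p)
  group <- (outer(ri, ci, `+`)) %% folds
  press <- 0
  for (g in seq_len(folds) - 1L) {
    Eg <- E
    del <- group == g
    Eg[del] <- NA
    cmp <- nipals_component(Eg)
    pred <- tcrossprod(cmp$t, cmp$p)
    press <- press + sum((E[del] - pred[del])^2)
  }
  list(press = press, q2 = 1 - press / sum(E^2))
}

#' Cumulative cross-validated Q2 of a PCA model
#'
#' Wold elementwise cross-validation: per component, the residual matrix is
#' deleted in diagonal stripes (default 7 groups), the component is refitted
#' treating deletions as missing, and PRESS accumulates over the deleted
#' elements.  Cumulative Q2 = 1 - prod_a(PRESS_a / SS_a).
#'
#' @param X centered matrix.
#' @param n_components number of components to evaluate.
#' @param folds number of deletion groups (>= 2).
#' @param seed integer seed controlling the stripe assignment.
#' @return list with `q2_per_component` and `q2_cum` vectors.
#' @export
q2_pca <- function(X, n_components, folds = 7L, seed = 1L) {
  check_centered(X)
  stopifnot(folds >= 2, folds <= length(X))
  E <- X
  q2 <- numeric(0)
  ratio <- numeric(0)
  for (a in seq_len(n_components)) {
    cvr <- wold_cv_component(E, folds = folds, seed = derive_seed(seed, "pca-cv", a))
    q2 <- c(q2, cvr$q2)
    ratio <- c(ratio, cvr$press / sum(E^2))
    cmp <- nipals_component(E)
    E <- E - tcrossprod(cmp$t, cmp$p)
  }
  list(q2_per_component = q2, q2_cum = 1 - cumprod(ratio))
}

#' Project new (identically scaled) data onto a PCA model
#'
#' @param object a `pca_model`.
#' @param newdata matrix scaled with the training scaling record.
#' @param ... unused.
#' @return scores matrix (samples x components).
#' @export
predict.pca_model <- function(object, newdata, ...) {
  newdata %*% object$loadings
}
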