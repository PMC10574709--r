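# Cross-validated R2Y/Q2 and the permutation (validate-plot) test for the
# latent-variable classifiers.

# Stratified fold assignment; a fold that would swallow an entire class is
# repaired by moving one of that class's samples into every other fold's
# complement (practically: assignment is per class round-robin after a
# seeded shuffle, which cannot lose a class from the training side unless a
# class has fewer samples than... it can when class size < folds; then the
# class members are spread so each fold holds at most one).
make_folds <- function(labels, folds, seed) {
  set.seed(seed)
  assign <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    assign[idx] <- rep_len(sample(folds), length(idx))
  }
  # guard: training side of each fold must retain every class
  for (f in seq_len(folds)) {
    tr_labels <- labels[assign != f]
    missing <- setdiff(unique(labels), unique(tr_labels))
    for (cl in missing) {
      warning("fold ", f, " would hold every '", cl, "' sample; reassigning one")
      move <- which(labels == cl & assign == f)[1]
      assign[move] <- if (f == folds) 1L else f + 1L
    }
  }
  assign
}

#' Cross-validated R2Y and Q2 of a PLS-DA or OPLS-DA model
#'
#' Q2 = 1 - PRESS/SSY with PRESS accumulated over held-out rows of a
#' stratified k-fold split (default 7 folds, the convention of the
#' chemometrics software this mirrors).  Scaling of X is assumed done
#' globally upstream; Y is scaled on each training fold's statistics from the
#' full data (pooled dummy-column sum of squares forms the denominator).
#'
#' @param X centered/scaled matrix.
#' @param Y one-hot matrix or label vector.
#' @param n_components components (predictive components for OPLS-DA).
#' @param folds number of folds (>= 2), stratified by class.
#' @param seed integer seed for the fold assignment.
#' @param model_kind `"plsda"` or `"oplsda"`.
#' @param n_orthogonal orthogonal components for `"oplsda"`.
#' @return list with `r2y` (full-data fit), `q2`, `press`, `ssy`, and the
#'   per-fold assignment.
#' @export
cross_validate <- function(X, Y, n_components = 2L, folds = 7L, seed = 1L,
                           model_kind = c("plsda", "oplsda"),
                           n_orthogonal = 1L) {
  model_kind <- match.arg(model_kind)
  if (!is.matrix(Y)) Y <- dummy_y(Y)
  stopifnot(folds >= 2)
  if (folds > nrow(X)) stop("more folds than samples")
  labels <- colnames(Y)[apply(Y, 1, which.max)]
  assign <- make_folds(labels, folds, derive_seed(seed, "cv-folds"))
  ys <- scale_y(Y)
  press <- 0
  for (f in seq_len(folds)) {
    tr <- assign != f
    if (!any(!tr)) next
    Xtr <- X[tr, , drop = FALSE]
    # re-center the training block so the fitter sees a centered matrix
    ctr <- colMeans(Xtr)
    Xtr <- sweep(Xtr, 2, ctr)
    Xte <- sweep(X[!tr, , drop = FALSE], 2, ctr)
    fit <- if (model_kind == "plsda") {
      fit_plsda(Xtr, Y[tr, , drop = FALSE], n_components)
    } else {
      fit_oplsda(Xtr, Y[tr, , drop = FALSE], n_predictive = n_components,
                 n_orthogonal = n_orthogonal)
    }
    Ys_hat <- Xte %*% fit$B
    # put prediction on the FULL-data scaled-Y coordinates
    Y_hat <- sweep(sweep(Ys_hat, 2, fit$y_scale, "*"), 2, fit$y_center, "+")
    Ys_full <- sweep(sweep(Y[!tr, , drop = FALSE], 2, ys$center), 2, ys$scale, "/")
    Yhat_full <- sweep(sweep(Y_hat, 2, ys$center), 2, ys$scale, "/")
    press <- press + sum((Ys_full - Yhat_full)^2)
  }
  ssy <- sum(ys$values^2)
  full <- if (model_kind == "plsda") {
    fit_plsda(X, Y, n_components)
  } else {
    fit_oplsda(X, Y, n_predictive = n_components, n_orthogonal = n_orthogonal)
  }
  list(r2y = full$r2y_cum[length(full$r2y_cum)],
       r2x = if (model_kind == "plsda") full$r2x_cum[full$n_components]
             else full$r2x_pred + full$r2x_orth,
       q2 = 1 - press / ssy, press = press, ssy = ssy, folds = assign)
}

#' Choose the number of latent components by the cross-validation rule
#'
#' Components are added while cumulative Q2 improves by more than `delta`
#' (default 0.01), up to `max_components`.
#'
#' @inheritParams cross_validate
#' @param max_components cap on components.
#' @param delta minimum Q2 improvement to accept a component.
#' @return the chosen component count (at least 1).
#' @export
choose_n_components <- function(X, Y, max_components = 5L, folds = 7L,
                                seed = 1L, delta = 0.01) {
  if (!is.matrix(Y)) Y <- dummy_y(Y)
  max_components <- min(max_components, nrow(X) - 1L, ncol(X))
  best_a <- 1L
  best_q2 <- cross_validate(X, Y, 1L, folds, seed)$q2
  a <- 1L
  while (a < max_components) {
    a <- a + 1L
    q2 <- tryCatch(cross_validate(X, Y, a, folds, seed)$q2,
                   error = function(e) -Inf)
    if (q2 > best_q2 + delta) {
      best_q2 <- q2
      best_a <- a
    } else break
  }
  best_a
}

#' Permutation (validate-plot) test of a latent-variable classifier
#'
#' Refits the model `n_permutations` times with the rows of Y randomly
#' shuffled, recording for each fit the correlation of the permuted with the
#' original class matrix, R2Y and cross-validated Q2.  The first entry is the
#' unpermuted reference (correlation 1).  Intercepts of the least-squares
#' lines of R2Y and Q2 against the correlation -- including the reference
#' point, as in the standard validate plot -- diagnose over-fitting: a model
#' that genuinely learned class structure has a clearly negative Q2
#' intercept and a real Q2 above the permuted distribution.
#'
#' @inheritParams cross_validate
#' @param n_permutations number of label shuffles (the study convention is
#'   200).
#' @return a `permutation_result`: data frame `trials` (`correlation`, `r2y`,
#'   `q2`; first row unpermuted), `r2_intercept`, `q2_intercept`.
#' @export
permutation_test <- function(X, Y, n_permutations = 200L, n_components = 2L,
                             folds = 7L, seed = 1L,
                             model_kind = c("plsda", "oplsda"),
                             n_orthogonal = 1L) {
  model_kind <- match.arg(model_kind)
  if (!is.matrix(Y)) Y <- dummy_y(Y)
  if (ncol(Y) < 2 || any(apply(Y, 2, stats::sd) == 0)) {
    stop("permutation test undefined for single-class input")
  }
  stopifnot(n_permutations >= 1)
  ys <- scale_y(Y)
  ref <- cross_validate(X, Y, n_components, folds, seed, model_kind, n_orthogonal)
  rows <- data.frame(correlation = 1, r2y = ref$r2y, q2 = ref$q2)
  set.seed(derive_seed(seed, "permutation"))
  for (k in seq_len(n_permutations)) {
    perm <- sample(nrow(Y))
    Yp <- Y[perm, , drop = FALSE]
    corr <- abs(stats::cor(as.vector(ys$values),
                           as.vector(ys$values[perm, , drop = FALSE])))
    res <- tryCatch(
      cross_validate(X, Yp, n_components, folds,
                     derive_seed(seed, "perm-cv", k), model_kind, n_orthogonal),
      error = function(e) list(r2y = NA_real_, q2 = NA_real_))
    rows <- rbind(rows, data.frame(correlation = corr, r2y = res$r2y, q2 = res$q2))
  }
  ok <- stats::complete.cases(rows)
  r2_int <- unname(stats::coef(stats::lm(r2y ~ correlation, rows[ok, ]))[1])
  q2_int <- unname(stats::coef(stats::lm(q2 ~ correlation, rows[ok, ]))[1])
  structure(list(trials = rows, n_permutations = n_permutations,
                 r2_intercept = r2_int, q2_intercept = q2_int),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: %d permutations, R2 intercept = %.4f, Q2 intercept = %.4f\n",
              x$n_permutations, x$r2_intercept, x$q2_intercept))
  cat(sprintf("reference R2Y = %.3f, Q2 = %.3f; permuted Q2 95th pct = %.3f\n",
              x$trials$r2y[1], x$trials$q2[1],
              stats::quantile(x$trials$q2[-1], 0.95, na.rm = TRUE)))
  invisible(x)
}
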