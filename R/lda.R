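# Stepwise linear discriminant analysis with Fisher per-class classification
# functions, as produced by mainstream statistics software: greedy Wilks'
# lambda minimization with probability-of-F entry/removal thresholds, pooled
# within-class covariance, and canonical discriminant axes.

wilks_lambda <- function(X, labels, cols) {
  if (length(cols) == 0) return(1)
  Xs <- X[, cols, drop = FALSE]
  n <- nrow(Xs)
  classes <- unique(labels)
  Wm <- matrix(0, length(cols), length(cols))
  for (cl in classes) {
    Xi <- Xs[labels == cl, , drop = FALSE]
    Xi <- sweep(Xi, 2, colMeans(Xi))
    Wm <- Wm + crossprod(Xi)
  }
  Tt <- crossprod(sweep(Xs, 2, colMeans(Xs)))
  dW <- det(Wm)
  dT <- det(Tt)
  if (!is.finite(dW) || !is.finite(dT) || dT <= 0) return(NA_real_)
  if (dW < 0) return(NA_real_)
  dW / dT
}

# Partial F for changing the entered set from `k` to `k+1` variables
# (Rao's one-variable-added statistic): F = ((n-g-k)/(g-1)) (L_k/L_k1 - 1),
# df (g-1, n-g-k).
partial_f <- function(lambda_small, lambda_big, n, g, k) {
  if (!is.finite(lambda_big) || lambda_big <= 0) return(c(f = NA, p = NA))
  f <- ((n - g - k) / (g - 1)) * (lambda_small / lambda_big - 1)
  if (!is.finite(f) || f < 0) return(c(f = NA, p = NA))
  c(f = f, p = stats::pf(f, g - 1, n - g - k, lower.tail = FALSE))
}

#' Stepwise variable selection for linear discriminant analysis
#'
#' Greedy Wilks' lambda minimization with probability-of-F thresholds: at
#' each step the candidate with the smallest entry p-value enters if it is at
#' most `p_enter`; entered variables whose removal p-value reaches `p_remove`
#' are then removed.  Defaults (0.05 / 0.10) are the usual stepwise
#' discriminant settings.
#'
#' @param X numeric matrix (samples x variables, raw normalized-bucket
#'   units).
#' @param labels class labels, >= 2 classes with >= 2 samples each.
#' @param p_enter,p_remove probability-of-F thresholds, `p_enter < p_remove`.
#' @param max_steps safety cap on entry steps.
#' @return list with `selected` (column indices in entry order) and `record`,
#'   a data frame of entry/removal events with Wilks' lambda and F.
#' @export
stepwise_select <- function(X, labels, p_enter = 0.05, p_remove = 0.10,
                            max_steps = 50L) {
  labels <- as.character(labels)
  g <- length(unique(labels))
  n <- nrow(X)
  stopifnot(g >= 2, all(table(labels) >= 2), p_enter < p_remove)
  if (p_enter <= 0) stop("p_enter must be positive")
  selected <- integer(0)
  lambda_cur <- 1
  record <- data.frame(step = integer(0), action = character(0),
                       variable = integer(0), lambda = numeric(0),
                       F = numeric(0), p = numeric(0))
  step <- 0L
  repeat {
    step <- step + 1L
    if (step > max_steps) break
    k <- length(selected)
    if (n - g - k <= 0) break
    candidates <- setdiff(seq_len(ncol(X)), selected)
    best <- NULL
    for (j in candidates) {
      lam <- wilks_lambda(X, labels, c(selected, j))
      if (!is.finite(lam)) next   # singular within-class scatter: skip
      fp <- partial_f(lambda_cur, lam, n, g, k)
      if (is.na(fp["p"])) next
      if (is.null(best) || fp["p"] < best$p ||
          (fp["p"] == best$p && lam < best$lambda)) {
        best <- list(j = j, lambda = lam, f = fp["f"], p = fp["p"])
      }
    }
    entered <- FALSE
    if (!is.null(best) && best$p <= p_enter) {
      selected <- c(selected, best$j)
      lambda_cur <- best$lambda
      record <- rbind(record, data.frame(step = step, action = "enter",
                                         variable = best$j, lambda = best$lambda,
                                         F = unname(best$f), p = unname(best$p)))
      entered <- TRUE
    }
    # removal pass
    removed <- TRUE
    while (removed && length(selected) > 1) {
      removed <- FALSE
      k <- length(selected)
      worst <- NULL
      for (j in selected) {
        lam_wo <- wilks_lambda(X, labels, setdiff(selected, j))
        fp <- partial_f(lam_wo, lambda_cur, n, g, k - 1L)
        if (is.na(fp["p"])) next
        if (is.null(worst) || fp["p"] > worst$p) {
          worst <- list(j = j, lambda = lam_wo, f = fp["f"], p = fp["p"])
        }
      }
      if (!is.null(worst) && worst$p >= p_remove) {
        selected <- setdiff(selected, worst$j)
        lambda_cur <- worst$lambda
        record <- rbind(record, data.frame(step = step, action = "remove",
                                           variable = worst$j, lambda = worst$lambda,
                                           F = unname(worst$f), p = unname(worst$p)))
        removed <- TRUE
      }
    }
    if (!entered) break
  }
  if (length(selected) == 0) stop("stepwise selection entered no variable")
  list(selected = selected, record = record)
}

#' Fit a linear discriminant model with Fisher classification functions
#'
#' Per class g, the classification function is
#' `f_g(x) = mu_g' S^-1 x - mu_g' S^-1 mu_g / 2 + log(prior_g)` with S the
#' pooled within-class covariance; argmax over classes is the Gaussian Bayes
#' rule under a shared covariance.  Canonical axes solve the generalized
#' eigenproblem of between- versus within-class scatter and are normalized to
#' unit pooled within-class variance.
#'
#' A singular pooled covariance is ridged once by `1e-8 * trace/p` on the
#' diagonal, with a warning.
#'
#' @param X_sel matrix over the selected variables (raw units).
#' @param labels class labels; every class needs >= 2 samples.
#' @param priors named prior vector, `"equal"` (default) or `"proportional"`.
#' @param variable_names names for the coefficient rows.
#' @return an `lda_model`: `classes`, `means`, `pooled_cov`, `coefficients`
#'   (variables x classes), `intercepts`, `priors`, `canonical_axes`,
#'   `selected_variables`.
#' @export
fit_lda <- function(X_sel, labels, priors = "equal", variable_names = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  g <- length(classes)
  stopifnot(g >= 2)
  if (any(table(labels) < 2)) stop("every class needs at least two samples")
  X_sel <- as.matrix(X_sel)
  p <- ncol(X_sel)
  n <- nrow(X_sel)
  if (is.character(priors)) {
    priors <- switch(match.arg(priors, c("equal", "proportional")),
                     equal = stats::setNames(rep(1 / g, g), classes),
                     proportional = table(labels)[classes] / n)
  }
  priors <- unlist(priors)[classes]
  means <- t(vapply(classes, function(cl) colMeans(X_sel[labels == cl, , drop = FALSE]),
                    numeric(p)))
  Wm <- matrix(0, p, p)
  for (cl in classes) {
    Xi <- sweep(X_sel[labels == cl, , drop = FALSE], 2, means[cl, ])
    Wm <- Wm + crossprod(Xi)
  }
  S <- Wm / (n - g)
  if (inherits(try(solve(S), silent = TRUE), "try-error") ||
      rcond(S) < 1e-12) {
    warning("singular pooled covariance; adding ridge 1e-8 * trace/p")
    S <- S + diag(1e-8 * sum(diag(S)) / p, p)
  }
  Sinv <- solve(S)
  coefs <- Sinv %*% t(means)                       # p x g
  intercepts <- -0.5 * colSums(t(means) * coefs) + log(priors)
  # canonical axes: eigenvectors of W^-1 B, normalized so a' S a = 1
  gm <- colMeans(X_sel)
  Bm <- matrix(0, p, p)
  for (cl in classes) {
    d <- means[cl, ] - gm
    Bm <- Bm + sum(labels == cl) * tcrossprod(d)
  }
  ev <- eigen(Sinv %*% (Bm / (n - g)), symmetric = FALSE)
  keep <- seq_len(min(g - 1L, p))
  axes <- Re(ev$vectors[, keep, drop = FALSE])
  eigv <- Re(ev$values[keep])
  for (k in seq_along(keep)) {
    nrm <- sqrt(drop(t(axes[, k]) %*% S %*% axes[, k]))
    axes[, k] <- axes[, k] / nrm
    if (axes[which.max(abs(axes[, k])), k] < 0) axes[, k] <- -axes[, k]
  }
  vn <- variable_names %||% colnames(X_sel) %||% paste0("X", seq_len(p))
  rownames(coefs) <- vn
  colnames(coefs) <- classes
  structure(list(classes = classes, means = means, pooled_cov = S,
                 coefficients = coefs, intercepts = intercepts,
                 priors = priors, canonical_axes = axes,
                 canonical_eigenvalues = eigv,
                 grand_mean = gm, selected_variables = vn),
            class = "lda_model")
}

#' Construct an LDA model directly from published classification functions
#'
#' Builds an `lda_model` usable with [classify()] from a table of
#' coefficients and intercepts (classes x variables layout as printed in
#' reports); no covariance or canonical axes are available on such a model.
#'
#' @param coefficients classes x variables matrix (or variables x classes).
#' @param intercepts named numeric vector, one per class.
#' @param classes class order; defaults to `names(intercepts)`.
#' @param variable_names variable identities of the coefficient columns.
#' @return an `lda_model` restricted to classification.
#' @export
lda_from_functions <- function(coefficients, intercepts, classes = NULL,
                               variable_names = NULL) {
  classes <- classes %||% names(intercepts)
  stopifnot(!is.null(classes), length(intercepts) == length(classes))
  coefficients <- as.matrix(coefficients)
  if (nrow(coefficients) == length(classes) &&
      ncol(coefficients) != length(classes)) {
    coefficients <- t(coefficients)                 # to variables x classes
  }
  colnames(coefficients) <- classes
  if (!is.null(variable_names)) rownames(coefficients) <- variable_names
  structure(list(classes = classes, coefficients = coefficients,
                 intercepts = stats::setNames(as.numeric(intercepts), classes),
                 selected_variables = rownames(coefficients)),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("lda_model: %d classes (%s), %d variables\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              nrow(x$coefficients)))
  invisible(x)
}

#' Classify samples with Fisher classification functions
#'
#' @param model an `lda_model`.
#' @param x numeric vector over the selected variables, or a matrix with one
#'   row per sample.
#' @return list with `labels` and `scores` (samples x classes function
#'   values); ties go to the lowest class index.
#' @export
classify <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(model$coefficients)) {
    stop("expected ", nrow(model$coefficients), " variables, got ", ncol(x))
  }
  scores <- x %*% model$coefficients
  scores <- sweep(scores, 2, model$intercepts, "+")
  colnames(scores) <- model$classes
  idx <- apply(scores, 1, which.max)
  list(labels = model$classes[idx], scores = scores)
}

#' Leave-one-out cross-validated accuracy of an LDA model
#'
#' Refits the model with each sample excluded in turn and predicts it.
#'
#' @inheritParams fit_lda
#' @return list with `accuracy` and `predictions` (character vector).
#' @export
loocv <- function(X_sel, labels, priors = "equal") {
  labels <- as.character(labels)
  n <- nrow(X_sel)
  stopifnot(n >= length(unique(labels)) + 1)
  preds <- character(n)
  for (i in seq_len(n)) {
    # a left-out sample can orphan a tiny class; score it unclassifiable
    preds[i] <- tryCatch(
      classify(fit_lda(X_sel[-i, , drop = FALSE], labels[-i], priors),
               X_sel[i, ])$labels,
      error = function(e) NA_character_)
  }
  list(accuracy = mean(!is.na(preds) & preds == labels), predictions = preds)
}

#' Canonical discriminant scores
#'
#' Projects samples onto the canonical axes (axis 1 first), centered at the
#' training grand mean.
#'
#' @param model a fitted `lda_model` (from [fit_lda()]).
#' @param X matrix over the selected variables.
#' @return samples x axes score matrix.
#' @export
canonical_scores <- function(model, X) {
  if (is.null(model$canonical_axes)) {
    stop("model has no canonical axes (constructed from printed functions?)")
  }
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  sweep(X, 2, model$grand_mean) %*% model$canonical_axes
}

#' Serialize / restore an LDA model as JSON
#'
#' @param model an `lda_model`.
#' @param path JSON path.
#' @return `path` invisibly; `read_lda_json` returns the model.
#' @export
write_lda_json <- function(model, path) {
  keep <- list(classes = model$classes,
               coefficients = model$coefficients,
               intercepts = as.list(model$intercepts),
               selected_variables = model$selected_variables,
               priors = if (!is.null(model$priors)) as.list(model$priors) else NULL)
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_lda_json
#' @export
read_lda_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lda_from_functions(obj$coefficients, unlist(obj$intercepts),
                     classes = obj$classes,
                     variable_names = obj$selected_variables)
}
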