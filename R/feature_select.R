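# Two-stage VIP-screening and intersection cascade.
#
# Stage 1: PLS-DA on the full matrix, keep variables with VIP strictly above
# the threshold.  Stage 2: refit PLS-DA and OPLS-DA on the reduced matrix and
# screen each by VIP again.  The characteristic variables are the
# intersection of the two stage-2 sets, tracked by ORIGINAL variable identity
# so reduction never shifts indices.

#' Select variables by VIP from a PLS-DA fit
#'
#' @param X centered/scaled matrix.
#' @param Y one-hot matrix or label vector.
#' @param threshold VIP cut-off; strictly greater-than is used.
#' @param n_components components for the underlying fit; `NULL` chooses by
#'   the cross-validation rule.
#' @param folds,seed controls for the automatic component choice.
#' @return integer indices (ascending) of the selected columns of `X`.
#' @export
select_by_vip <- function(X, Y, threshold = 1.0, n_components = NULL,
                          folds = 7L, seed = 1L) {
  stopifnot(threshold >= 0)
  if (!is.matrix(Y)) Y <- dummy_y(Y)
  n_components <- n_components %||%
    choose_n_components(X, Y, folds = folds, seed = seed)
  fit <- fit_plsda(X, Y, n_components)
  vip <- vip_scores(fit)$vip
  sel <- unname(which(vip > threshold))
  if (length(sel) == 0) stop("VIP selection is empty at threshold ", threshold)
  sort(sel)
}

#' Run the VIP-intersection variable-selection cascade
#'
#' Reproduces the two-stage reduction: VIP screening of a full-matrix PLS-DA,
#' then VIP screening of PLS-DA and OPLS-DA refitted on the reduced matrix,
#' intersected to give the characteristic variables.
#'
#' @param X_train centered/scaled training matrix.
#' @param Y_train one-hot matrix or label vector.
#' @param threshold VIP cut-off (default 1.0, strict inequality).
#' @param folds,seed cross-validation controls for per-stage component
#'   counts.
#' @param n_orthogonal orthogonal components for the stage-2 OPLS-DA fit.
#' @return a `selection_trace`: `stage1`, `stage2_pls`, `stage2_opls`,
#'   `characteristic` (all original column indices), per-stage VIP vectors
#'   and component counts.
#' @export
intersect_cascade <- function(X_train, Y_train, threshold = 1.0,
                              folds = 7L, seed = 1L, n_orthogonal = 1L) {
  if (!is.matrix(Y_train)) Y_train <- dummy_y(Y_train)
  if (ncol(Y_train) < 2) stop("at least two classes required")
  a1 <- choose_n_components(X_train, Y_train, folds = folds,
                            seed = derive_seed(seed, "stage1"))
  fit1 <- fit_plsda(X_train, Y_train, a1)
  vip1 <- vip_scores(fit1)$vip
  stage1 <- sort(unname(which(vip1 > threshold)))
  if (length(stage1) == 0) stop("cascade stage 1 selected no variables")

  X_red <- X_train[, stage1, drop = FALSE]
  a2 <- choose_n_components(X_red, Y_train, folds = folds,
                            seed = derive_seed(seed, "stage2"))
  fit2p <- fit_plsda(X_red, Y_train, a2)
  vip2p <- vip_scores(fit2p)$vip
  stage2_pls <- sort(stage1[vip2p > threshold])
  if (length(stage2_pls) == 0) stop("cascade stage 2 (PLS-DA) selected no variables")

  fit2o <- fit_oplsda(X_red, Y_train, n_predictive = max(1L, ncol(Y_train) - 1L),
                      n_orthogonal = n_orthogonal)
  vip2o <- vip_scores(fit2o)$vip
  stage2_opls <- sort(stage1[vip2o > threshold])
  if (length(stage2_opls) == 0) stop("cascade stage 2 (OPLS-DA) selected no variables")

  characteristic <- intersect(stage2_pls, stage2_opls)
  if (length(characteristic) == 0) stop("cascade intersection is empty")
  structure(list(stage1 = stage1, stage2_pls = stage2_pls,
                 stage2_opls = stage2_opls,
                 characteristic = sort(characteristic),
                 threshold = threshold,
                 n_components = c(stage1 = a1, stage2 = a2),
                 vip = list(stage1 = vip1, stage2_pls = vip2p,
                            stage2_opls = vip2o)),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("selection_trace: %d -> %d (VIP > %g) -> PLS %d / OPLS %d -> %d characteristic\n",
              length(x$vip$stage1), length(x$stage1), x$threshold,
              length(x$stage2_pls), length(x$stage2_opls),
              length(x$characteristic)))
  invisible(x)
}

#' Export a selection trace
#'
#' Writes the trace as JSON and, when `edges` is given, a readable CSV with
#' one row per stage-1 variable: ppm window, per-stage VIPs and selection
#' flags.
#'
#' @param trace a `selection_trace`.
#' @param path output path stem; `.json` and `.csv` are appended.
#' @param edges optional bucket edge table for ppm annotation.
#' @return `path`, invisibly.
#' @export
write_selection_trace <- function(trace, path, edges = NULL) {
  jsonlite::write_json(
    list(stage1 = trace$stage1, stage2_pls = trace$stage2_pls,
         stage2_opls = trace$stage2_opls, characteristic = trace$characteristic,
         threshold = trace$threshold, n_components = as.list(trace$n_components)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  idx <- trace$stage1
  df <- data.frame(variable = names(trace$vip$stage1)[idx],
                   vip_stage1 = unname(trace$vip$stage1[idx]),
                   vip_stage2_pls = unname(trace$vip$stage2_pls),
                   vip_stage2_opls = unname(trace$vip$stage2_opls),
                   selected_pls = idx %in% trace$stage2_pls,
                   selected_opls = idx %in% trace$stage2_opls,
                   characteristic = idx %in% trace$characteristic)
  if (!is.null(edges)) {
    df$ppm_low <- edges$low[idx]
    df$ppm_high <- edges$high[idx]
  }
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}
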