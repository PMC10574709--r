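# End-to-end orchestration: species/growth-mode analysis (three classes) and
# processing-method analysis (two classes), from a single seeded config.

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analyses.  Either `cohort_dir`
#' (spectra on disk, readable by [read_cohort()]) or `design` (a
#' [cohort_design()] simulated on the fly) supplies the input spectra.
#'
#' @param design optional [cohort_design()] for synthetic input.
#' @param cohort_dir optional directory of spectra plus `labels.csv`.
#' @param range_low,range_high,width bucketing region and width (ppm).
#' @param scaling column scaling method for latent models.
#' @param train_counts named per-class training-set sizes; `NULL` uses
#'   ~60 percent of each class.
#' @param folds cross-validation folds.
#' @param vip_threshold VIP cut-off of the selection cascade.
#' @param n_permutations permutation-test rounds.
#' @param p_enter,p_remove stepwise LDA thresholds.
#' @param seed mandatory master seed.
#' @param out_dir optional directory for report and CSV artifacts.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(design = NULL, cohort_dir = NULL,
                            range_low = -0.025, range_high = 9.975,
                            width = 0.05, scaling = "uv",
                            train_counts = NULL, folds = 7L,
                            vip_threshold = 1.0, n_permutations = 200L,
                            p_enter = 0.05, p_remove = 0.10,
                            seed, out_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(width > 0, range_high > range_low, folds >= 2,
            vip_threshold >= 0, n_permutations >= 1, p_enter < p_remove)
  structure(list(design = design, cohort_dir = cohort_dir,
                 range_low = range_low, range_high = range_high,
                 width = width, scaling = scaling,
                 train_counts = train_counts, folds = as.integer(folds),
                 vip_threshold = vip_threshold,
                 n_permutations = as.integer(n_permutations),
                 p_enter = p_enter, p_remove = p_remove,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

pipeline_table <- function(config) {
  spectra <- if (!is.null(config$cohort_dir)) {
    read_cohort(config$cohort_dir)
  } else if (!is.null(config$design)) {
    simulate_cohort(config$design)
  } else {
    stop("config needs either a cohort_dir or a synthetic design")
  }
  assemble_table(spectra, config$range_low, config$range_high, config$width)
}

default_train_counts <- function(labels) {
  tab <- table(labels)
  counts <- pmax(2L, floor(0.6 * as.integer(tab)))
  stats::setNames(as.integer(counts), names(tab))
}

#' Run the species / growth-mode analysis end to end
#'
#' Bucket and TMS-normalize the cohort, split it stratified into training and
#' test sets, fit the PCA overview, run the VIP-intersection cascade,
#' stepwise LDA with LOOCV, verification PLS-DA and OPLS-DA on the
#' characteristic variables with test-set prediction, and the permutation
#' test.  All stage seeds derive from `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return a `species_report` list of per-stage metrics (also written as
#'   JSON, with CSV artifacts, when `config$out_dir` is set).
#' @export
run_species_analysis <- function(config) {
  table <- pipeline_table(config)
  labels <- table$labels
  train_counts <- config$train_counts %||% default_train_counts(labels)
  part <- split_train_test(labels, train_counts, derive_seed(config$seed, "split"))
  sc <- scale_columns(table$values[part$train, , drop = FALSE], config$scaling)
  X_tr <- sc$values
  y_tr <- labels[part$train]
  X_te <- apply_scaling(table$values[part$test, , drop = FALSE], sc)
  y_te <- labels[part$test]

  pca <- fit_pca(X_tr, max_components = 13L, stop_rule = "q2",
                 folds = config$folds, seed = derive_seed(config$seed, "pca"))

  trace <- intersect_cascade(X_tr, y_tr, config$vip_threshold,
                             folds = config$folds,
                             seed = derive_seed(config$seed, "cascade"))
  char <- trace$characteristic

  # stepwise LDA in raw normalized-bucket units over the characteristic set
  X_raw_tr <- table$values[part$train, char, drop = FALSE]
  X_raw_te <- table$values[part$test, char, drop = FALSE]
  sw <- stepwise_select(X_raw_tr, y_tr, config$p_enter, config$p_remove)
  sel <- sw$selected
  lda <- fit_lda(X_raw_tr[, sel, drop = FALSE], y_tr,
                 variable_names = colnames(X_raw_tr)[sel])
  lda_train_acc <- mean(classify(lda, X_raw_tr[, sel, drop = FALSE])$labels == y_tr)
  lda_test_acc <- mean(classify(lda, X_raw_te[, sel, drop = FALSE])$labels == y_te)
  lda_loocv <- loocv(X_raw_tr[, sel, drop = FALSE], y_tr)

  # verification latent models on the stepwise-selected variables
  selected_cols <- char[sel]
  sc_sel <- scale_columns(table$values[part$train, selected_cols, drop = FALSE],
                          config$scaling)
  Xv_tr <- sc_sel$values
  Xv_te <- apply_scaling(table$values[part$test, selected_cols, drop = FALSE], sc_sel)
  a_ver <- choose_n_components(Xv_tr, y_tr, folds = config$folds,
                               seed = derive_seed(config$seed, "verify"))
  pls <- fit_plsda(Xv_tr, dummy_y(y_tr), a_ver)
  cv_pls <- cross_validate(Xv_tr, dummy_y(y_tr), a_ver, config$folds,
                           derive_seed(config$seed, "verify"), "plsda")
  rank_cap <- min(nrow(Xv_tr) - 1L, ncol(Xv_tr))
  n_pred <- min(length(unique(y_tr)) - 1L, rank_cap)
  n_orth <- max(0L, min(1L, rank_cap - n_pred))
  opls <- fit_oplsda(Xv_tr, dummy_y(y_tr), n_predictive = n_pred,
                     n_orthogonal = n_orth)
  cv_opls <- cross_validate(Xv_tr, dummy_y(y_tr),
                            n_components = n_pred,
                            folds = config$folds,
                            seed = derive_seed(config$seed, "verify"),
                            model_kind = "oplsda", n_orthogonal = n_orth)
  pls_test_acc <- mean(predict_class(pls, Xv_te)$labels == y_te)
  opls_test_acc <- mean(predict_class(opls, Xv_te)$labels == y_te)
  pls_train_acc <- mean(predict_class(pls, Xv_tr)$labels == y_tr)
  opls_train_acc <- mean(predict_class(opls, Xv_tr)$labels == y_tr)

  perm <- permutation_test(Xv_tr, dummy_y(y_tr),
                           n_permutations = config$n_permutations,
                           n_components = a_ver, folds = config$folds,
                           seed = derive_seed(config$seed, "perm"))

  report <- list(
    n_samples = length(labels),
    n_buckets = ncol(table$values),
    train_shape = c(length(part$train), ncol(table$values)),
    n_test = length(part$test),
    pca = list(n_components = pca$n_components,
               r2x_cum = unname(pca$r2x_cum[pca$n_components]),
               q2_cum = unname(pca$q2_cum[length(pca$q2_cum)])),
    selection = list(stage1 = length(trace$stage1),
                     stage2_pls = length(trace$stage2_pls),
                     stage2_opls = length(trace$stage2_opls),
                     characteristic = length(char),
                     characteristic_variables = colnames(table$values)[char]),
    lda = list(selected_variables = colnames(X_raw_tr)[sel],
               train_accuracy = lda_train_acc,
               test_accuracy = lda_test_acc,
               loocv_accuracy = lda_loocv$accuracy),
    plsda = list(n_components = a_ver, r2x = cv_pls$r2x, r2y = cv_pls$r2y,
                 q2 = cv_pls$q2, train_accuracy = pls_train_acc,
                 test_accuracy = pls_test_acc),
    oplsda = list(r2x = cv_opls$r2x, r2y = cv_opls$r2y, q2 = cv_opls$q2,
                  train_accuracy = opls_train_acc,
                  test_accuracy = opls_test_acc),
    permutation = list(n = perm$n_permutations,
                       r2_intercept = perm$r2_intercept,
                       q2_intercept = perm$q2_intercept,
                       reference_q2 = perm$trials$q2[1]),
    seed = config$seed)
  if (!is.null(config$out_dir)) {
    write_species_artifacts(config, report, table, part, trace, lda)
  }
  structure(report, class = "species_report")
}

write_species_artifacts <- function(config, report, table, part, trace, lda) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(config$out_dir, "species_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_bucket_table(table, file.path(config$out_dir, "bucket_table.csv"))
  write_partition(part, file.path(config$out_dir, "partition.json"))
  write_selection_trace(trace, file.path(config$out_dir, "selection_trace"),
                        edges = table$edges)
  write_lda_json(lda, file.path(config$out_dir, "lda_model.json"))
  invisible(NULL)
}

#' Run the processing-method (binary) analysis end to end
#'
#' The two-class variant: binary OPLS-DA with permutation test, VIP > 1
#' screening on the OPLS-DA, then stepwise LDA with LOOCV on the screened
#' variables.
#'
#' @param config a [pipeline_config()] whose cohort carries exactly two
#'   class labels.
#' @return a `processing_report` list of metrics (JSON artifact when
#'   `out_dir` is set).
#' @export
run_processing_analysis <- function(config) {
  table <- pipeline_table(config)
  labels <- table$labels
  if (length(unique(labels)) != 2) stop("processing analysis needs exactly two classes")
  train_counts <- config$train_counts %||% default_train_counts(labels)
  part <- split_train_test(labels, train_counts, derive_seed(config$seed, "split"))
  sc <- scale_columns(table$values[part$train, , drop = FALSE], config$scaling)
  X_tr <- sc$values
  y_tr <- labels[part$train]
  X_te <- apply_scaling(table$values[part$test, , drop = FALSE], sc)
  y_te <- labels[part$test]

  opls <- fit_oplsda(X_tr, dummy_y(y_tr), n_predictive = 1L, n_orthogonal = 1L)
  cv <- cross_validate(X_tr, dummy_y(y_tr), 1L, config$folds,
                       derive_seed(config$seed, "cv"), "oplsda", 1L)
  train_acc <- mean(predict_class(opls, X_tr)$labels == y_tr)
  test_acc <- mean(predict_class(opls, X_te)$labels == y_te)
  perm <- permutation_test(X_tr, dummy_y(y_tr),
                           n_permutations = config$n_permutations,
                           n_components = 1L, folds = config$folds,
                           seed = derive_seed(config$seed, "perm"),
                           model_kind = "oplsda", n_orthogonal = 1L)
  vip <- vip_scores(opls, config$vip_threshold)
  screened <- which(vip$vip > config$vip_threshold)
  if (length(screened) == 0) stop("OPLS-DA VIP screening selected no variables")

  X_raw_tr <- table$values[part$train, screened, drop = FALSE]
  X_raw_te <- table$values[part$test, screened, drop = FALSE]
  sw <- stepwise_select(X_raw_tr, y_tr, config$p_enter, config$p_remove)
  sel <- sw$selected
  lda <- fit_lda(X_raw_tr[, sel, drop = FALSE], y_tr,
                 variable_names = colnames(X_raw_tr)[sel])
  lda_train_acc <- mean(classify(lda, X_raw_tr[, sel, drop = FALSE])$labels == y_tr)
  lda_test_acc <- mean(classify(lda, X_raw_te[, sel, drop = FALSE])$labels == y_te)
  lda_loocv <- loocv(X_raw_tr[, sel, drop = FALSE], y_tr)

  report <- list(
    n_samples = length(labels),
    train_shape = c(length(part$train), ncol(table$values)),
    n_test = length(part$test),
    oplsda = list(r2x = cv$r2x, r2y = cv$r2y, q2 = cv$q2,
                  train_accuracy = train_acc, test_accuracy = test_acc),
    permutation = list(n = perm$n_permutations,
                       r2_intercept = perm$r2_intercept,
                       q2_intercept = perm$q2_intercept,
                       reference_q2 = perm$trials$q2[1],
                       permuted_q2_p95 = unname(stats::quantile(perm$trials$q2[-1],
                                                                0.95, na.rm = TRUE))),
    vip_screened = length(screened),
    lda = list(selected_variables = colnames(X_raw_tr)[sel],
               train_accuracy = lda_train_acc,
               test_accuracy = lda_test_acc,
               loocv_accuracy = lda_loocv$accuracy),
    seed = config$seed)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "processing_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  structure(report, class = "processing_report")
}

#' Write / read a pipeline config as plain key = value text
#'
#' Only scalar fields round-trip; a synthetic design is referenced by its
#' seed and must be reconstructed by the caller.
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `path` invisibly; `read_pipeline_config` returns the config (with
#'   `design`/`cohort_dir` as stored).
#' @export
write_pipeline_config <- function(config, path) {
  scalars <- config[!vapply(config, is.null, logical(1))]
  scalars$design <- NULL
  lines <- vapply(names(scalars), function(k) {
    v <- scalars[[k]]
    paste0(k, " = ", paste(v, collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- list()
  for (p in kv) {
    val <- strsplit(p[2], ",")[[1]]
    num <- suppressWarnings(as.numeric(val))
    out[[trimws(p[1])]] <- if (all(!is.na(num))) num else val
  }
  if (!is.null(out$train_counts)) out$train_counts <- NULL  # names not stored
  do.call(pipeline_config, out[names(out) %in% names(formals(pipeline_config))])
}
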