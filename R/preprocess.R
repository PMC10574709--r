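# Spectral bucketing and bucket-table management.
#
# The study convention: the region -0.025..9.975 ppm is integrated in 0.05 ppm
# sections, giving 200 variables.  Variables are numbered V1..V200 from the
# HIGH-ppm end downwards, so V186 spans 0.675..0.725 ppm and V200 is the TMS
# anchor bucket around 0.0 ppm.  Every row is normalized so the TMS bucket
# integral equals 1.0.

#' Bucket edge table for a ppm range
#'
#' Bucket i (1-based) spans `[high - i*width, high - (i-1)*width]`, placing V1
#' at the high-ppm end of the range.
#'
#' @param range_low,range_high bucketed region bounds in ppm.
#' @param width bucket width in ppm; must tile the range exactly.
#' @return data frame with columns `variable`, `low`, `high`, `center`.
#' @export
bucket_edges <- function(range_low = -0.025, range_high = 9.975, width = 0.05) {
  n <- (range_high - range_low) / width
  if (abs(n - round(n)) > 1e-9) stop("bucket width does not tile the range")
  n <- as.integer(round(n))
  i <- seq_len(n)
  data.frame(variable = paste0("V", i),
             low = range_high - i * width,
             high = range_high - (i - 1) * width,
             center = range_high - (i - 0.5) * width)
}

#' Integrate a spectrum into fixed-width buckets
#'
#' Trapezoidal integration of the piecewise-linear trace over each bucket
#' window (windows `[low, high)` half-open on the grid, last bucket closed;
#' the continuous integrals tile the range exactly, so bucketing is additive
#' and the bucket sum equals the integral over the whole range).
#'
#' @param spectrum a `spectrum` object (fields `ppm`, `intensity`).
#' @inheritParams bucket_edges
#' @return named numeric vector of bucket integrals, V1 (high ppm) first.
#' @export
bucket_spectrum <- function(spectrum, range_low = -0.025, range_high = 9.975,
                            width = 0.05) {
  ppm <- spectrum$ppm
  if (ppm[1] > range_low || ppm[length(ppm)] < range_high) {
    stop("spectrum grid does not cover the bucketed range")
  }
  edges <- bucket_edges(range_low, range_high, width)
  # cumulative integral evaluated at every edge, high->low, then differenced
  bounds <- c(edges$high[1], edges$low)
  Fb <- trapz_cum_at(ppm, spectrum$intensity, bounds)
  vals <- Fb[-length(Fb)] - Fb[-1]   # F(high_i) - F(low_i), bounds descend
  names(vals) <- edges$variable
  vals
}

#' Normalize bucket integrals to the TMS reference bucket
#'
#' Divides every entry by the integral of the bucket containing 0.0 ppm
#' (tetramethylsilane resonance), scaling that bucket to exactly 1.0 and
#' removing the arbitrary intensity dimension of each spectrum.
#'
#' @param raw numeric vector of bucket integrals.
#' @param edges bucket edge table matching `raw`.
#' @return the normalized vector.
#' @export
normalize_to_tms <- function(raw, edges = bucket_edges()) {
  anchor <- which(edges$low <= 0 & 0 < edges$high)
  if (length(anchor) != 1) stop("no bucket contains the 0.0 ppm reference")
  ref <- raw[anchor]
  if (!is.finite(ref) || ref <= 0) stop("reference peak missing: TMS bucket integral is not positive")
  out <- raw / ref
  out[anchor] <- 1.0
  out
}

#' Assemble spectra into a normalized bucket table
#'
#' Buckets and TMS-normalizes every spectrum and stacks them into a samples x
#' variables matrix (rows in input order, columns V1..Vn descending in ppm).
#'
#' @param spectra list of `spectrum` objects.
#' @inheritParams bucket_edges
#' @param normalize TMS-normalize each row (default TRUE).
#' @return a `bucket_table`: list with `values` (matrix), `edges`,
#'   `sample_ids`, `labels`.
#' @export
assemble_table <- function(spectra, range_low = -0.025, range_high = 9.975,
                           width = 0.05, normalize = TRUE) {
  stopifnot(length(spectra) >= 2)
  edges <- bucket_edges(range_low, range_high, width)
  rows <- lapply(spectra, function(sp) {
    v <- bucket_spectrum(sp, range_low, range_high, width)
    if (normalize) v <- normalize_to_tms(v, edges)
    v
  })
  values <- do.call(rbind, rows)
  sample_ids <- vapply(spectra, function(sp) sp$sample_id %||% "", character(1))
  if (any(sample_ids == "")) sample_ids <- paste0("S", seq_along(spectra))
  rownames(values) <- sample_ids
  labels <- vapply(spectra, function(sp) sp$label %||% NA_character_, character(1))
  structure(list(values = values, edges = edges,
                 sample_ids = sample_ids, labels = labels),
            class = "bucket_table")
}

#' @export
print.bucket_table <- function(x, ...) {
  cat(sprintf("bucket_table: %d samples x %d buckets (%.3f..%.3f ppm, width %.3g)\n",
              nrow(x$values), ncol(x$values),
              min(x$edges$low), max(x$edges$high),
              x$edges$high[1] - x$edges$low[1]))
  if (!all(is.na(x$labels))) print(table(x$labels))
  invisible(x)
}

#' Column scaling for latent-variable modelling
#'
#' `center` subtracts column means; `uv` additionally divides by the column
#' standard deviation (unit variance, the SIMCA-style default for spectral
#' buckets); `pareto` divides by the square root of the standard deviation.
#' Zero-variance columns are passed through centered, with a warning.
#'
#' @param X numeric matrix (or a `bucket_table`, whose `values` are used).
#' @param method one of `"center"`, `"uv"`, `"pareto"`.
#' @return list with `values` (scaled matrix), `center`, `scale`, `method`.
#' @export
scale_columns <- function(X, method = c("uv", "center", "pareto")) {
  method <- match.arg(method)
  if (inherits(X, "bucket_table")) X <- X$values
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  zero <- sds < .Machine$double.eps * 1e3
  scl <- switch(method,
                center = rep(1, ncol(X)),
                uv = sds,
                pareto = sqrt(sds))
  if (method != "center" && any(zero)) {
    warning(sum(zero), " zero-variance column(s) passed through centered only")
    scl[zero] <- 1
  }
  values <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  list(values = values, center = ctr, scale = scl, method = method)
}

#' Apply a stored scaling record to new data
#'
#' @param X new matrix with the same columns as the training data.
#' @param record scaling record from [scale_columns()].
#' @return the scaled matrix.
#' @export
apply_scaling <- function(X, record) {
  if (inherits(X, "bucket_table")) X <- X$values
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  stopifnot(ncol(X) == length(record$center))
  sweep(sweep(X, 2, record$center), 2, record$scale, "/")
}

#' Stratified train/test split
#'
#' Randomly assigns, per class, the requested number of training samples; the
#' remainder form the test set.  Deterministic given the seed.
#'
#' @param labels character vector of class labels (or a `bucket_table`).
#' @param train_counts named integer vector: training samples per class.
#' @param seed integer seed.
#' @param allow_empty_test permit a split that leaves no test samples.
#' @return a `partition`: list with `train`, `test` (row indices),
#'   `stratum_counts`, `seed`.
#' @export
split_train_test <- function(labels, train_counts, seed, allow_empty_test = FALSE) {
  if (inherits(labels, "bucket_table")) labels <- labels$labels
  tab <- table(labels)
  for (cl in names(train_counts)) {
    if (!cl %in% names(tab)) stop("no samples with label ", cl)
    if (train_counts[[cl]] > tab[[cl]]) {
      stop("requested ", train_counts[[cl]], " training samples for ", cl,
           " but only ", tab[[cl]], " exist")
    }
  }
  set.seed(derive_seed(seed, "split"))
  train <- integer(0)
  for (cl in names(train_counts)) {
    idx <- which(labels == cl)
    train <- c(train, sort(sample(idx, train_counts[[cl]])))
  }
  train <- sort(train)
  test <- setdiff(seq_along(labels), train)
  if (length(test) == 0 && !allow_empty_test) {
    stop("split leaves an empty test set; pass allow_empty_test = TRUE to permit")
  }
  counts <- lapply(names(train_counts), function(cl) {
    c(train = sum(labels[train] == cl), test = sum(labels[test] == cl))
  })
  names(counts) <- names(train_counts)
  structure(list(train = train, test = test,
                 stratum_counts = counts, seed = as.integer(seed)),
            class = "partition")
}
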