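# Stepwise LDA, Fisher classification functions, LOOCV and canonical scores.

three_class_data <- function(seed, n_per = 15, p_noise = 4, gap = 4) {
  set.seed(seed)
  mu <- rbind(c(0, 0), c(gap, 0), c(0, gap))
  X <- do.call(rbind, lapply(1:3, function(g) {
    cbind(matrix(rnorm(n_per * 2), n_per, 2) + rep(mu[g, ], each = n_per),
          matrix(rnorm(n_per * p_noise), n_per, p_noise))
  }))
  colnames(X) <- paste0("X", seq_len(ncol(X)))
  list(X = X, labels = rep(c("A", "B", "C"), each = n_per))
}

test_that("stepwise selection enters a dominant separator first", {
  set.seed(1)
  n <- 30
  labels <- rep(c("a", "b"), each = n / 2)
  X <- cbind(sep = ifelse(labels == "a", 0, 8) + rnorm(n, sd = 0.3),
             matrix(rnorm(n * 5), n, 5))
  colnames(X) <- c("sep", paste0("noise", 1:5))
  sw <- stepwise_select(X, labels)
  expect_equal(sw$selected[1], 1)
  expect_true(all(diff(sw$record$lambda[sw$record$action == "enter"]) <= 1e-12))
  expect_error(stepwise_select(X, labels, p_enter = 0, p_remove = 0.1),
               "p_enter")
})

test_that("stepwise selection on synthetic cohorts picks marker-window buckets", {
  ok <- vapply(1:5, function(s) {
    m <- small_species_matrix(400 + s)
    tr <- intersect_cascade(m$X, m$labels, threshold = 1, seed = s)
    Xc <- m$table$values[, tr$characteristic, drop = FALSE]
    sw <- stepwise_select(Xc, m$labels)
    centers <- m$table$edges$center[tr$characteristic[sw$selected]]
    any(centers >= 0.65 & centers <= 1.80) &&
      any((centers >= 2.65 & centers <= 2.95) |
            (centers >= 4.60 & centers <= 4.70) |
            (centers >= 5.20 & centers <= 5.30) |
            (centers >= 5.50 & centers <= 5.55))
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("Fisher classification functions equal the Bayes rule with shared covariance", {
  d <- three_class_data(2)
  fit <- fit_lda(d$X, d$labels)
  set.seed(3)
  pts <- matrix(rnorm(200 * ncol(d$X), sd = 3), 200, ncol(d$X))
  scores <- classify(fit, pts)$labels
  Sinv <- solve(fit$pooled_cov)
  bayes <- apply(pts, 1, function(x) {
    d2 <- vapply(fit$classes, function(cl) {
      v <- x - fit$means[cl, ]
      drop(t(v) %*% Sinv %*% v)
    }, numeric(1))
    fit$classes[which.min(d2)]
  })
  expect_identical(scores, bayes)
})

test_that("classification is affine and invariant to intercept shifts", {
  d <- three_class_data(4)
  fit <- fit_lda(d$X, d$labels)
  x <- rnorm(ncol(d$X))
  s0 <- classify(fit, numeric(ncol(d$X)))$scores
  s1 <- classify(fit, x)$scores
  s2 <- classify(fit, 2 * x)$scores
  expect_equal(s2 - s0, 2 * (s1 - s0), tolerance = 1e-10)
  shifted <- fit
  shifted$intercepts <- fit$intercepts + 5
  expect_identical(classify(shifted, d$X)$labels, classify(fit, d$X)$labels)
  expect_error(classify(fit, x[1:3]), "variables")
})

test_that("class means classify to their own class and LOOCV is sane", {
  d <- three_class_data(5, gap = 8)   # gap far above the unit noise
  fit <- fit_lda(d$X, d$labels)
  for (cl in fit$classes) {
    expect_equal(classify(fit, fit$means[cl, ])$labels, cl)
  }
  cv <- loocv(d$X, d$labels)
  expect_equal(cv$accuracy, 1.0)
  # chance level under shuffled labels
  set.seed(6)
  acc <- vapply(1:10, function(i) loocv(d$X, sample(d$labels))$accuracy,
                numeric(1))
  expect_lt(abs(mean(acc) - 1 / 3), 0.15)
  # minimal size: n = classes + 1
  Xm <- matrix(rnorm(8), 4, 2)
  expect_no_error(loocv(Xm, c("a", "a", "b", "c")))
})

test_that("LOOCV accuracy does not beat resubstitution on average", {
  diffs <- vapply(1:20, function(s) {
    d <- three_class_data(600 + s, n_per = 8, gap = 1.5)
    fit <- fit_lda(d$X, d$labels)
    resub <- mean(classify(fit, d$X)$labels == d$labels)
    resub - loocv(d$X, d$labels)$accuracy
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})

test_that("canonical axes order separation and match MASS::lda predictions", {
  d <- three_class_data(7)
  fit <- fit_lda(d$X, d$labels)
  expect_equal(ncol(fit$canonical_axes), 2)
  expect_true(all(diff(fit$canonical_eigenvalues) <= 1e-9))
  sc <- canonical_scores(fit, d$X)
  bvar <- function(k) {
    cm <- tapply(sc[, k], d$labels, mean)
    stats::var(as.numeric(cm))
  }
  expect_gte(bvar(1), bvar(2))
  # two-class model has a single axis
  two <- fit_lda(d$X[d$labels != "C", ], d$labels[d$labels != "C"])
  expect_equal(ncol(two$canonical_axes), 1)
  skip_if_not_installed("MASS")
  mfit <- MASS::lda(d$X, grouping = d$labels, prior = rep(1 / 3, 3))
  expect_identical(classify(fit, d$X)$labels,
                   as.character(predict(mfit, d$X)$class))
})

test_that("published classification functions evaluate and round-trip", {
  model <- published_lonicera_functions()
  at_zero <- classify(model, numeric(7))
  expect_equal(unname(at_zero$scores[1, ]),
               c(-10.103, -92.660, -29.427))
  expect_equal(at_zero$labels, "cLJF")
  # spreadsheet-style evaluation agrees on random inputs
  set.seed(8)
  for (i in 1:10) {
    x <- runif(7, 0, 0.05)
    hand <- vapply(model$classes, function(cl) {
      sum(model$coefficients[, cl] * x) + model$intercepts[cl]
    }, numeric(1))
    got <- classify(model, x)
    expect_equal(unname(got$scores[1, ]), unname(hand), tolerance = 1e-10)
    expect_equal(got$labels, names(which.max(hand)))
  }
  path <- file.path(withr::local_tempdir(), "lda.json")
  write_lda_json(model, path)
  back <- read_lda_json(path)
  expect_equal(back$coefficients, model$coefficients)
  x <- runif(7, 0, 0.05)
  expect_equal(classify(back, x)$scores, classify(model, x)$scores)
})

test_that("degenerate fits are caught or ridged", {
  X <- matrix(rnorm(12), 6, 2)
  expect_error(fit_lda(X, c("a", "a", "a", "a", "a", "b")),
               "two samples")
  # collinear columns trigger the ridge path but still classify
  set.seed(9)
  Xc <- cbind(rnorm(10), 0)
  Xc <- cbind(Xc, Xc[, 1])
  labels <- rep(c("a", "b"), 5)
  Xc[labels == "b", 1] <- Xc[labels == "b", 1] + 3
  Xc[, 3] <- Xc[, 1]
  expect_warning(fit <- fit_lda(Xc, labels), "ridge")
  expect_length(classify(fit, Xc)$labels, 10)
})
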