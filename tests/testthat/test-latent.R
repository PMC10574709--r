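# PLS-DA / OPLS-DA: closed-form first-component oracle, VIP brute-force
# oracle, OPLS geometry, S-line, cross-validation and permutation test.

test_that("PLS first component matches the closed-form X'y direction", {
  X <- random_centered(20, 6, seed = 1, scale = TRUE)
  y <- X[, 1] + 0.5 * X[, 2] + rnorm(20, sd = 0.1)
  Y <- cbind(a = as.numeric(y > median(y)), b = as.numeric(y <= median(y)))
  ys <- nmrpattern:::scale_y(Y)
  fit <- fit_plsda(X, Y, 1)
  # PLS1/PLS2 first weight: dominant singular direction of X'Ys; with the
  # NIPALS start on the largest-variance Y column this is X'u iterated
  w_oracle <- svd(crossprod(X, ys$values))$u[, 1]
  w_oracle <- w_oracle * sign(w_oracle[which.max(abs(w_oracle))])
  expect_equal(as.vector(fit$W[, 1]), w_oracle, tolerance = 1e-6)
})

test_that("a perfectly predictable target is explained by one component", {
  set.seed(2)
  cls <- rep(c(TRUE, FALSE), each = 12)
  Y <- cbind(a = as.numeric(cls), b = as.numeric(!cls))
  ind <- (as.numeric(cls) - mean(cls)) / sd(cls)
  # column 3 is the exact scaled indicator; the rest are orthogonal to it
  X <- matrix(rnorm(24 * 5), 24, 5)
  X <- apply(X, 2, function(col) residuals(lm(col ~ ind)))
  X <- sweep(X, 2, apply(X, 2, sd), "/")
  X[, 3] <- ind
  fit <- fit_plsda(X, Y, 1)
  expect_gte(fit$r2y_cum[1], 0.99)
})

test_that("components up to the rank recover all X variance", {
  set.seed(3)
  T3 <- matrix(rnorm(30 * 3), 30, 3)
  P3 <- matrix(rnorm(3 * 7), 3, 7)
  X <- sweep(T3 %*% P3, 2, colMeans(T3 %*% P3))
  y <- T3[, 1] > 0
  Y <- cbind(a = as.numeric(y), b = as.numeric(!y))
  fit <- fit_plsda(X, Y, 3)
  expect_gte(fit$r2x_cum[length(fit$r2x_cum)], 0.999)
  # scores mutually orthogonal; B reproduces the T C' map on training X
  G <- crossprod(fit$T)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-6 * max(diag(G)))
  expect_equal(X %*% fit$B, tcrossprod(fit$T, fit$C), tolerance = 1e-8)
})

test_that("single-class input is rejected", {
  X <- random_centered(10, 4, seed = 4)
  Y <- cbind(a = rep(1, 10), b = rep(0, 10))
  expect_error(fit_plsda(X, Y, 1), "zero variance|single-class")
})

test_that("VIP: symmetry, normalization identity and brute-force oracle", {
  # orthonormal mean-zero columns with X'y all equal -> every VIP is 1
  H <- stats::contr.helmert(9)
  H <- sweep(H, 2, sqrt(colSums(H^2)), "/")
  y <- rowSums(H)                       # H'y = (1, ..., 1): equal weights
  fit1 <- nmrpattern:::nipals_pls(H, cbind(y), 1)
  model1 <- structure(list(W = fit1$W, ssy_explained = fit1$ssy_explained,
                           variable_names = NULL), class = "plsda_model")
  expect_equal(unname(vip_scores(model1)$vip), rep(1, ncol(H)),
               tolerance = 1e-10)
  # normalization: sum(VIP^2) = p for any fitted model
  m <- small_species_matrix(31, sizes = c(cLJF = 8, wLJF = 6, LF = 6))
  fit <- fit_plsda(m$X, dummy_y(m$labels), 3)
  v <- vip_scores(fit)$vip
  expect_equal(sum(v^2), ncol(m$X), tolerance = 1e-6)

  # independent brute-force implementation of the VIP formula, 20 x 6, A = 2
  X <- random_centered(20, 6, seed = 5, scale = TRUE)
  set.seed(6)
  cls <- sample(c("a", "b"), 20, replace = TRUE)
  fit2 <- fit_plsda(X, dummy_y(cls), 2)
  p <- ncol(X)
  ssy <- vapply(1:2, function(a) sum(fit2$T[, a]^2) * sum(fit2$C[, a]^2),
                numeric(1))
  vip_brute <- numeric(p)
  for (j in seq_len(p)) {
    acc <- 0
    for (a in 1:2) {
      acc <- acc + ssy[a] * (fit2$W[j, a] / sqrt(sum(fit2$W[, a]^2)))^2
    }
    vip_brute[j] <- sqrt(p * acc / sum(ssy))
  }
  expect_equal(unname(vip_scores(fit2)$vip), vip_brute, tolerance = 1e-10)
})

test_that("OPLS with no orthogonal component degenerates to PLS", {
  m <- small_species_matrix(7, sizes = c(cLJF = 8, LF = 8))
  Y <- dummy_y(m$labels)
  pls <- fit_plsda(m$X, Y, 1)
  opls <- fit_oplsda(m$X, Y, n_predictive = 1, n_orthogonal = 0)
  expect_equal(as.vector(opls$T_pred[, 1]), as.vector(pls$T[, 1]),
               tolerance = 1e-8)
})

test_that("orthogonal filtering removes class-orthogonal structure", {
  set.seed(8)
  n <- 40
  y <- rep(c(1, -1), each = n / 2)
  noise_dir <- rnorm(n)
  noise_dir <- residuals(lm(noise_dir ~ y))          # orthogonal to y
  load_y <- rnorm(10)
  load_o <- rnorm(10)
  X <- outer(y, load_y) + 3 * outer(noise_dir, load_o) +
    matrix(rnorm(n * 10, sd = 0.1), n, 10)
  X <- sweep(X, 2, colMeans(X))
  Y <- cbind(a = as.numeric(y > 0), b = as.numeric(y < 0))
  pls1 <- fit_plsda(X, Y, 1)
  opls1 <- fit_oplsda(X, Y, n_predictive = 1, n_orthogonal = 1)
  expect_gte(opls1$r2y_cum[1], pls1$r2y_cum[1] - 1e-10)
  # predictive score orthogonal to every orthogonal score
  expect_lt(max(abs(crossprod(opls1$T_pred, opls1$T_orth))), 1e-6)
  # R2X split never exceeds total variance
  expect_lte(opls1$r2x_pred + opls1$r2x_orth, 1 + 1e-9)
})

test_that("automatic orthogonal-component selection stays within bounds", {
  m <- small_species_matrix(17, sizes = c(cLJF = 10, LF = 8))
  fit <- fit_oplsda(m$X, dummy_y(m$labels), n_predictive = 1,
                    n_orthogonal = NULL, max_orthogonal = 3, seed = 1)
  expect_lte(fit$n_orthogonal, 3)
  rows <- c(1:3, 11:13)                       # both classes represented
  Xs <- sweep(m$X[rows, ], 2, colMeans(m$X[rows, ]))
  expect_error(fit_oplsda(Xs, dummy_y(m$labels[rows]),
                          n_predictive = 1, n_orthogonal = 10),
               "rank")
})

test_that("S-line covariance and correlation behave as specified", {
  m <- small_species_matrix(9, sizes = c(cLJF = 10, LF = 10))
  Y <- dummy_y(m$labels)
  fit <- fit_oplsda(m$X, Y, n_predictive = 1, n_orthogonal = 1)
  sl <- suppressWarnings(s_line(fit, m$X))   # TMS column is constant
  expect_true(all(sl$p_corr >= -1 - 1e-9 & sl$p_corr <= 1 + 1e-9))
  # a column equal to the predictive score correlates exactly 1
  X_aug <- cbind(m$X, tp = fit$T_pred[, 1])
  sl_aug <- suppressWarnings(s_line(fit, X_aug))
  expect_equal(sl_aug$p_corr[ncol(X_aug)], 1, tolerance = 1e-10)
  # independent noise columns stay weakly correlated at n = 60
  set.seed(10)
  for (s in 1:3) {
    noise <- matrix(rnorm(nrow(m$X) * 5), nrow(m$X), 5)
    sl_n <- s_line(fit, sweep(noise, 2, colMeans(noise)))
    expect_lt(max(abs(sl_n$p_corr)), 0.75)
  }
  # planted saponin buckets dominate |p_cov| for the LF contrast
  big <- abs(sl$p_cov)
  top <- order(big, decreasing = TRUE)[1:3]
  centers <- m$table$edges$center[top]
  expect_true(all(centers >= 0.65 & centers <= 1.80))
  # zero-variance column: correlation 0 with a warning
  expect_warning(sl_z <- s_line(fit, cbind(m$X[, 1:3], z = rep(0, nrow(m$X)))),
                 "zero-variance")
  expect_equal(sl_z$p_corr[4], 0)
})

test_that("cross-validated Q2 separates signal from permuted labels", {
  m <- small_species_matrix(11)
  Y <- dummy_y(m$labels)
  cv <- cross_validate(m$X, Y, n_components = 2, folds = 7, seed = 1)
  expect_gt(cv$q2, 0.5)
  expect_identical(cv$q2,
                   cross_validate(m$X, Y, n_components = 2, folds = 7,
                                  seed = 1)$q2)
  set.seed(12)
  q2_perm <- vapply(1:10, function(i) {
    cross_validate(m$X, Y[sample(nrow(Y)), ], n_components = 2, folds = 7,
                   seed = i)$q2
  }, numeric(1))
  expect_lt(mean(q2_perm), 0.05)
  # leave-one-out agrees qualitatively with 7-fold on separable data
  loo <- cross_validate(m$X, Y, n_components = 2, folds = nrow(m$X), seed = 1)
  expect_gt(loo$q2, 0.5)
})

test_that("permutation test records the unpermuted reference and intercepts", {
  m <- small_species_matrix(13, sizes = c(cLJF = 10, wLJF = 6, LF = 6))
  Y <- dummy_y(m$labels)
  pr <- permutation_test(m$X, Y, n_permutations = 15, n_components = 2,
                         folds = 7, seed = 1)
  expect_equal(nrow(pr$trials), 16)
  expect_equal(pr$trials$correlation[1], 1)
  cv <- cross_validate(m$X, Y, n_components = 2, folds = 7, seed = 1)
  expect_identical(pr$trials$q2[1], cv$q2)
  expect_lt(pr$q2_intercept, pr$trials$q2[1])
  Y1 <- cbind(a = rep(1, 10), b = rep(0, 10))
  expect_error(permutation_test(m$X[1:10, ], Y1, 5), "single-class")
})

test_that("class prediction maps argmax of predicted indicators", {
  m <- small_species_matrix(14)
  Y <- dummy_y(m$labels)
  fit <- fit_plsda(m$X, Y, 2)
  pred <- predict_class(fit, m$X)
  expect_equal(pred$labels, m$labels)                  # separable cohort
  expect_lt(abs(mean(rowSums(pred$y_pred)) - 1), 0.2)  # near-one-hot rows
  # a row at a class centroid goes to that class
  centroid <- colMeans(m$X[m$labels == "LF", , drop = FALSE])
  expect_equal(predict_class(fit, centroid)$labels, "LF")
  expect_error(predict_class(fit, m$X[, 1:10]), "column count|match")
})
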