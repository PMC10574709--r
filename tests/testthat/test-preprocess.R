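# Bucketing, TMS normalization, table assembly, scaling and splitting.

flat_spectrum <- function(h = 1, n = 4001) {
  structure(list(ppm = seq(-0.525, 10.475, length.out = n),
                 intensity = rep(h, n), sample_id = "flat", label = "A"),
            class = "spectrum")
}

test_that("the study bucketing yields 200 buckets with V1 at the high-ppm end", {
  edges <- bucket_edges(-0.025, 9.975, 0.05)
  expect_equal(nrow(edges), 200)
  expect_equal(edges$variable[1], "V1")
  expect_equal(edges$high[1], 9.975)
  # index placement of the stepwise-LDA variables
  expect_equal(unlist(edges[edges$variable == "V186", c("low", "high")]),
               c(low = 0.675, high = 0.725), tolerance = 1e-9)
  expect_equal(unlist(edges[edges$variable == "V184", c("low", "high")]),
               c(low = 0.775, high = 0.825), tolerance = 1e-9)
  expect_equal(unlist(edges[edges$variable == "V147", c("low", "high")]),
               c(low = 2.625, high = 2.675), tolerance = 1e-9)
  expect_equal(unlist(edges[edges$variable == "V145", c("low", "high")]),
               c(low = 2.725, high = 2.775), tolerance = 1e-9)
  expect_error(bucket_edges(0, 1, 0.3), "does not tile")
})

test_that("bucket integrals: constant trace, coverage errors, quadrature oracle", {
  v <- bucket_spectrum(flat_spectrum(h = 2))
  expect_length(v, 200)
  expect_equal(unname(v), rep(2 * 0.05, 200), tolerance = 1e-9)
  short <- structure(list(ppm = seq(0, 5, length.out = 100),
                          intensity = rep(1, 100)), class = "spectrum")
  expect_error(bucket_spectrum(short), "does not cover")

  # single narrow Lorentzian at 0.70 ppm: V186 (0.675..0.725) dominates, and
  # the integral matches fine-grid quadrature
  ppm <- default_ppm_grid()
  sp <- structure(list(ppm = ppm,
                       intensity = 3 * 0.008^2 / ((ppm - 0.70)^2 + 0.008^2)),
                  class = "spectrum")
  v <- bucket_spectrum(sp)
  expect_equal(names(which.max(v)), "V186")
  fine <- seq(0.675, 0.725, length.out = 200001)
  fy <- 3 * 0.008^2 / ((fine - 0.70)^2 + 0.008^2)
  oracle <- sum(diff(fine) * (fy[-1] + fy[-length(fy)]) / 2)
  expect_equal(unname(v["V186"]), oracle, tolerance = 1e-4)
})

test_that("bucketing is additive and sums to the full-range integral", {
  d <- small_species_design(4)
  sp <- simulate_spectrum(d, "LF", 1)
  half1 <- sp; half1$intensity <- sp$intensity * 0.3
  half2 <- sp; half2$intensity <- sp$intensity * 0.7
  expect_equal(bucket_spectrum(half1) + bucket_spectrum(half2),
               bucket_spectrum(sp), tolerance = 1e-12)
  total <- nmrpattern:::trapz_cum_at(sp$ppm, sp$intensity, c(-0.025, 9.975))
  expect_equal(sum(bucket_spectrum(sp)), total[2] - total[1],
               tolerance = 1e-9 * abs(total[2]))
})

test_that("column count is 200 regardless of grid density", {
  for (n in c(2001, 16384, 40001)) {
    sp <- flat_spectrum(n = n)
    expect_length(bucket_spectrum(sp), 200)
  }
})

test_that("TMS normalization divides by the 0.0 ppm bucket", {
  edges <- bucket_edges()
  raw <- rep(1, 200)
  raw[200] <- 2                      # V200 holds 0.0 ppm
  norm <- normalize_to_tms(raw, edges)
  expect_equal(norm[200], 1.0)
  expect_equal(norm[1], 0.5)
  expect_equal(normalize_to_tms(norm, edges), norm)   # idempotent
  bad <- raw; bad[200] <- 0
  expect_error(normalize_to_tms(bad, edges), "reference peak missing")
})

test_that("normalized tables are invariant to the spectrometer gain", {
  # the TMS anchor removes any per-sample intensity scale: multiplying the
  # whole trace by a constant leaves the normalized table unchanged
  d <- cohort_design(class_sizes = c(cLJF = 2, LF = 2), noise_sd = 0,
                     concentration_cv = 0, seed = 8)
  cohort <- simulate_cohort(d)
  gained <- lapply(cohort, function(sp) {
    sp$intensity <- sp$intensity * 2.5
    sp
  })
  t1 <- assemble_table(cohort)
  t2 <- assemble_table(gained)
  expect_equal(t1$values, t2$values, tolerance = 1e-12)
})

test_that("table assembly gives samples x 200 with stable rows and CSV round-trip", {
  d <- small_species_design(6, sizes = c(cLJF = 3, wLJF = 2, LF = 2))
  cohort <- simulate_cohort(d)
  tab <- assemble_table(cohort)
  expect_equal(dim(tab$values), c(7, 200))
  expect_equal(colnames(tab$values), paste0("V", 1:200))
  dup <- assemble_table(list(cohort[[1]], cohort[[1]]))
  expect_equal(dup$values[1, ], dup$values[2, ])
  path <- file.path(withr::local_tempdir(), "table.csv")
  write_bucket_table(tab, path)
  back <- read_bucket_table(path)
  expect_equal(back$values, tab$values, tolerance = 1e-12)
  expect_equal(back$labels, tab$labels)
})

test_that("column scaling follows the center/uv/pareto definitions", {
  X <- random_centered(10, 5, seed = 1) + 3
  uv <- scale_columns(X, "uv")
  expect_equal(apply(uv$values, 2, sd), rep(1, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(colMeans(uv$values), rep(0, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  two <- matrix(c(1, 3, 5, 9), 2, 2, byrow = TRUE)
  ctr <- scale_columns(two, "center")
  expect_equal(ctr$values, rbind(c(-2, -3), c(2, 3)), ignore_attr = TRUE)
  par <- scale_columns(X, "pareto")
  sds <- apply(X, 2, sd)
  expect_equal(par$values, sweep(uv$values, 2, sqrt(sds), "*"),
               tolerance = 1e-12)
  Xz <- cbind(X, 7)   # constant column
  expect_warning(sz <- scale_columns(Xz, "uv"), "zero-variance")
  expect_equal(unname(sz$values[, 6]), rep(0, 10))
  expect_equal(apply_scaling(X, uv), uv$values)
})

test_that("stratified splits honour the study counts and are seeded", {
  labels <- rep(c("cLJF", "wLJF", "LF"), c(77, 10, 13))
  p <- split_train_test(labels, c(cLJF = 47, wLJF = 6, LF = 8), seed = 3)
  expect_length(p$train, 61)
  expect_length(p$test, 39)
  expect_setequal(c(p$train, p$test), seq_along(labels))
  expect_equal(sum(labels[p$train] == "wLJF"), 6)
  p2 <- split_train_test(labels, c(cLJF = 47, wLJF = 6, LF = 8), seed = 3)
  expect_identical(p, p2)
  p3 <- split_train_test(labels, c(cLJF = 47, wLJF = 6, LF = 8), seed = 4)
  expect_false(identical(p$train, p3$train))
  expect_error(split_train_test(labels, c(cLJF = 99, wLJF = 6, LF = 8), seed = 1),
               "only")
  all_in <- c(cLJF = 77, wLJF = 10, LF = 13)
  expect_error(split_train_test(labels, all_in, seed = 1), "empty test set")
  expect_silent(split_train_test(labels, all_in, seed = 1,
                                 allow_empty_test = TRUE))
})
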