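make_run <- function(Y, grid, tr = 2) {
  # Y: timepoints x voxels
  structure(list(data = array(t(Y), c(grid$dim, nrow(Y))), tr = tr,
                 grid = grid, nuisance = NULL), class = "bold_run")
}

make_design <- function(X, word_names) {
  structure(list(X = X, colnames = colnames(X),
                 word_cols = seq_along(word_names), word_names = word_names,
                 catch_col = NA_integer_, run = rep(1L, nrow(X)), tr = 2),
            class = "design_matrix")
}

test_that("canonical HRF has the double-gamma shape", {
  h <- canonical_hrf(hrf_params(), tr = 2, oversample = 16)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  peak_t <- (which.max(h) - 1) * 2 / 16
  expect_equal(peak_t, 5, tolerance = 0.15)
  # doubling oversample agrees on shared grid points
  h32 <- canonical_hrf(hrf_params(), tr = 2, oversample = 32)
  expect_equal(h32[seq(1, length(h32), by = 2)], h, tolerance = 1e-12)
  expect_error(hrf_params(peak_delay = -1), "positive")
  expect_error(canonical_hrf(tr = 0), "tr")
})

test_that("design matrix has the documented drift and nuisance structure", {
  # 360 s run at TR 2 with a 128 s cutoff: floor(2*360/128) = 5 cosines
  ws <- small_words(seed = 1, n_con = 2, n_abs = 2, k = 2)
  ev <- gen_event_table(ws, n_runs = 1, n_catch = 2, n_null = 4,
                        run_duration = 360, seed = 1)
  nuis <- list(matrix(rnorm(180 * 6), 180, 6))
  d <- build_design(ev, nuisance = nuis, tr = 2, run_duration = 360)
  expect_equal(sum(grepl("_dct", d$colnames)), 5)
  expect_equal(sum(grepl("_nuis", d$colnames)), 6)
  expect_equal(nrow(d$X), 180)
  expect_equal(d$word_names, ws$words$id)
  # no events at all: only drift columns remain
  empty <- data.frame(onset = numeric(0), duration = numeric(0),
                      condition = character(0), run = integer(0))
  d0 <- build_design(empty, tr = 2, run_duration = 64)
  expect_true(all(grepl("_const|_dct", d0$colnames)))
  # event past run end is rejected
  bad <- data.frame(onset = 359, duration = 2.5, condition = ws$words$id[1],
                    run = 1)
  expect_error(build_design(bad, tr = 2, run_duration = 360), "past the end")
})

test_that("an isolated event regressor reproduces the HRF kernel shape", {
  ev <- data.frame(onset = 20, duration = 2.5, condition = "w001", run = 1)
  d <- build_design(ev, tr = 2, run_duration = 120, hp_cutoff = 1e6)
  reg <- d$X[, "w001"]
  expect_equal(sum(reg[1:10]), 0)        # nothing before onset
  expect_gt(max(reg), 0.5)               # convolved response present
  expect_equal(which.max(reg), 13, tolerance = 1)  # onset 20 s + ~5 s peak
})

test_that("OLS betas match the explicit normal-equations oracle", {
  set.seed(7)
  grid <- grid_spec(c(2, 2, 1))
  X <- cbind(w001 = rnorm(20), w002 = rnorm(20), const = 1)
  Y <- matrix(rnorm(20 * 4), 20, 4)
  fit <- fit_glm(list(make_run(Y, grid)), make_design(X, c("w001", "w002")),
                 global_mean = FALSE)
  oracle <- solve(t(X) %*% X) %*% t(X) %*% Y
  expect_equal(unname(fit$betas), unname(oracle), tolerance = 1e-10)
  # t statistics against the textbook formula
  res <- Y - X %*% oracle
  sig2 <- colSums(res^2) / (20 - 3)
  xtxinv <- solve(t(X) %*% X)
  t_or <- oracle[1, ] / sqrt(sig2 * xtxinv[1, 1])
  expect_equal(unname(fit$t_words[1, ]), unname(t_or), tolerance = 1e-10)
  expect_equal(fit$df, 17)
})

test_that("noiseless forward simulation is recovered exactly", {
  ws <- small_words(seed = 2, n_con = 2, n_abs = 3, k = 2)
  g <- grid_spec(c(3, 3, 3))
  roi <- box_roi("A", g, 1:2, 1:2, 1:2)
  truth <- ground_truth(ws, encoding_strength = effect_map("A", default = 1),
                        seed = 2)
  sub <- gen_subject_patterns(truth, ws, "native", list(roi), noise_sd = 1,
                              seed = 3)
  ev <- gen_event_table(ws, n_runs = 2, n_catch = 2, n_null = 4,
                        run_duration = 60, lead_in = 6, seed = 4)
  runs <- gen_bold_runs(sub, ev, noise_sd = 0, seed = 5, run_duration = 60)
  des <- build_design(ev, nuisance = lapply(runs, `[[`, "nuisance"),
                      run_duration = 60)
  fit <- suppressWarnings(fit_glm(runs, des))
  expect_equal(unname(fit$betas[seq_len(5), ]),
               unname(sub$patterns[des$word_names, ]), tolerance = 1e-6)
})

test_that("contrasts combine word betas with their oracle t", {
  set.seed(8)
  grid <- grid_spec(c(2, 1, 1))
  X <- cbind(w001 = c(rep(1, 10), rep(0, 10)),
             w002 = c(rep(0, 10), rep(1, 10)), const = 1)
  X[, 1:2] <- X[, 1:2] + rnorm(40, sd = 0.1)
  beta_true <- rbind(3, 1, 0.5)
  Y <- X %*% cbind(beta_true, beta_true) + matrix(rnorm(40, sd = 0.2), 20, 2)
  fit <- fit_glm(list(make_run(Y, grid)), make_design(X, c("w001", "w002")),
                 global_mean = FALSE)
  con <- contrast_map(fit, c(1, -1))
  # oracle by explicit algebra
  xtxinv <- solve(t(X) %*% X)
  b <- solve(t(X) %*% X) %*% t(X) %*% Y
  res <- Y - X %*% b
  sig2 <- colSums(res^2) / fit$df
  w <- c(1, -1, 0)
  expect_equal(con$beta, drop(t(w) %*% b), tolerance = 1e-10)
  expect_equal(con$t, drop(t(w) %*% b) /
                 sqrt(drop(t(w) %*% xtxinv %*% w) * sig2),
               tolerance = 1e-10)
  zero <- contrast_map(fit, c(0, 0))
  expect_true(all(zero$beta == 0) && all(zero$t == 0))
  expect_error(contrast_map(fit, c(1, -1, 0)), "length")
})

test_that("t statistics under pure noise follow the central t distribution", {
  set.seed(9)
  grid <- grid_spec(c(25, 20, 20))       # 10^4 voxels
  X <- cbind(w001 = rnorm(30), const = 1)
  Y <- matrix(rnorm(30 * 10000), 30, 10000)
  fit <- fit_glm(list(make_run(Y, grid)), make_design(X, "w001"),
                 global_mean = FALSE)
  q95 <- unname(stats::quantile(fit$t_words[1, ], 0.95))
  expect_equal(q95, stats::qt(0.95, fit$df), tolerance = 0.05)
})

test_that("Gaussian smoothing preserves constants and unit mass", {
  vol <- array(2.5, c(8, 8, 8))
  expect_equal(smooth_volume(vol, fwhm = 6, voxel_mm = 2), vol)
  delta <- array(0, c(15, 15, 15)); delta[8, 8, 8] <- 1
  sm <- smooth_volume(delta, fwhm = 6, voxel_mm = 2)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_identical(smooth_volume(delta, fwhm = 0), delta)
  expect_error(smooth_volume(delta, fwhm = -1), "non-negative")
  # masked smoothing never leaks outside and renormalises at edges
  mask <- array(FALSE, c(15, 15, 15)); mask[4:12, 4:12, 4:12] <- TRUE
  ones <- array(1, c(15, 15, 15))
  msm <- smooth_masked(ones, mask, fwhm = 6, voxel_mm = 2)
  expect_true(all(is.na(msm[!mask])))
  expect_equal(msm[mask], rep(1, sum(mask)), tolerance = 1e-8)
})
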