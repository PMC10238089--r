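#' Canonical HRF parameters
#'
#' Double-gamma haemodynamic response function parameters (delays and
#' dispersions in seconds; the undershoot is scaled down by
#' `peak_undershoot_ratio`). Defaults are the conventional (6, 16, 1, 1, 6)
#' parameterisation with a 32 s kernel.
#'
#' @param peak_delay,undershoot_delay gamma means, s.
#' @param peak_dispersion,undershoot_dispersion gamma dispersions.
#' @param peak_undershoot_ratio peak-to-undershoot amplitude ratio.
#' @param kernel_length kernel support, s.
#' @return list of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       peak_undershoot_ratio = 6, kernel_length = 32) {
  p <- list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
            peak_dispersion = peak_dispersion,
            undershoot_dispersion = undershoot_dispersion,
            peak_undershoot_ratio = peak_undershoot_ratio,
            kernel_length = kernel_length)
  if (any(unlist(p) <= 0)) stop("all HRF parameters must be positive", call. = FALSE)
  structure(p, class = "hrf_params")
}

#' Sample the canonical double-gamma HRF
#'
#' Difference of two gamma densities (response minus undershoot divided by
#' the ratio), sampled every `tr / oversample` seconds from 0 to
#' `kernel_length`, scaled to unit peak.
#'
#' @param params an `hrf_params`.
#' @param tr repetition time, s.
#' @param oversample samples per TR (microtime resolution).
#' @return numeric vector of kernel values.
#' @export
canonical_hrf <- function(params = hrf_params(), tr = 2, oversample = 16) {
  if (tr <= 0) stop("'tr' must be positive", call. = FALSE)
  if (oversample < 1) stop("'oversample' must be at least 1", call. = FALSE)
  dt <- tr / oversample
  t <- seq(0, params$kernel_length, by = dt)
  h <- stats::dgamma(t, shape = params$peak_delay / params$peak_dispersion,
                     scale = params$peak_dispersion) -
    stats::dgamma(t, shape = params$undershoot_delay / params$undershoot_dispersion,
                  scale = params$undershoot_dispersion) /
      params$peak_undershoot_ratio
  h / max(h)
}

dct_basis <- function(n_scan, tr, hp_cutoff) {
  k_max <- floor(2 * n_scan * tr / hp_cutoff)
  if (k_max < 1) return(matrix(numeric(0), n_scan, 0))
  t <- seq_len(n_scan) - 1
  sapply(seq_len(k_max), function(k) cos(pi * k * (2 * t + 1) / (2 * n_scan)))
}

#' Build a condition-rich concatenated design matrix
#'
#' One regressor per word condition spanning all runs plus a single pooled
#' catch regressor, each built as a 2.5 s (per-event) boxcar at microtime
#' resolution, convolved with the canonical HRF and sampled once per TR;
#' per-run discrete-cosine drift columns implement the high-pass filter
#' (periods above `hp_cutoff`), alongside per-run constants and any supplied
#' per-run nuisance columns (e.g. 6 motion parameters).
#'
#' @param events data frame with columns `onset` (s), `duration` (s),
#'   `condition` (word id, or `"catch"`), `run` (integer).
#' @param nuisance optional list (one element per run) of `T_r x q` nuisance
#'   matrices.
#' @param tr repetition time, s.
#' @param run_duration run length in s (scalar or per-run vector).
#' @param hp_cutoff high-pass cutoff period, s (default 128).
#' @param hrf an `hrf_params`.
#' @param microtime microtime bins per TR (default 16); regressors are
#'   sampled at bin `microtime_onset` (0-based, default 8).
#' @param microtime_onset sampling bin within each TR.
#' @return list of class `design_matrix` with the matrix `X`, column names,
#'   `word_cols`, `word_names`, `catch_col`, `run` (row-wise run index) and
#'   `tr`.
#' @export
build_design <- function(events, nuisance = NULL, tr = 2, run_duration = 360,
                         hp_cutoff = 128, hrf = hrf_params(),
                         microtime = 16, microtime_onset = 8) {
  runs <- sort(unique(events$run))
  if (!length(runs)) runs <- 1L
  run_duration <- rep_len(run_duration, length(runs))
  words <- sort(unique(as.character(events$condition[events$condition != "catch"])))
  kernel <- canonical_hrf(hrf, tr = tr, oversample = microtime)
  dt <- tr / microtime

  task_blocks <- list(); drift_blocks <- list(); row_run <- integer(0)
  for (ri in seq_along(runs)) {
    r <- runs[ri]
    ev <- events[events$run == r, , drop = FALSE]
    if (any(ev$onset + ev$duration > run_duration[ri] + 1e-9)) {
      stop("event extends past the end of run ", r, call. = FALSE)
    }
    n_scan <- as.integer(round(run_duration[ri] / tr))
    n_bins <- n_scan * microtime
    regress_one <- function(sel) {
      u <- numeric(n_bins)
      for (i in which(sel)) {
        a <- floor(ev$onset[i] / dt) + 1
        b <- min(n_bins, ceiling((ev$onset[i] + ev$duration[i]) / dt))
        u[a:b] <- 1
      }
      x <- convolve(u, rev(kernel), type = "open")[seq_len(n_bins)]
      x[(seq_len(n_scan) - 1) * microtime + microtime_onset + 1]
    }
    task <- matrix(0, n_scan, length(words) + 1,
                   dimnames = list(NULL, c(words, "catch")))
    for (w in words) {
      sel <- ev$condition == w
      if (any(sel)) task[, w] <- regress_one(sel)
    }
    if (any(ev$condition == "catch")) task[, "catch"] <- regress_one(ev$condition == "catch")

    dct <- dct_basis(n_scan, tr, hp_cutoff)
    drift <- cbind(const = rep(1, n_scan), dct)
    colnames(drift) <- c(sprintf("run%d_const", r),
                         if (ncol(dct)) sprintf("run%d_dct%d", r, seq_len(ncol(dct))))
    if (!is.null(nuisance)) {
      nu <- as.matrix(nuisance[[ri]])
      if (nrow(nu) != n_scan) stop("nuisance rows do not match run ", r, call. = FALSE)
      colnames(nu) <- sprintf("run%d_nuis%d", r, seq_len(ncol(nu)))
      drift <- cbind(drift, nu)
    }
    task_blocks[[ri]] <- task
    drift_blocks[[ri]] <- drift
    row_run <- c(row_run, rep(r, n_scan))
  }
  task <- do.call(rbind, task_blocks)
  if (length(words) &&
      any(colSums(abs(task[, words, drop = FALSE])) == 0)) {
    stop("a word condition has no events in any run", call. = FALSE)
  }
  has_catch <- any(events$condition == "catch")
  if (!has_catch) task <- task[, colnames(task) != "catch", drop = FALSE]
  # block-diagonal drift/nuisance
  p_drift <- vapply(drift_blocks, ncol, 0L)
  drift <- matrix(0, nrow(task), sum(p_drift))
  cn <- character(0); at_row <- 1; at_col <- 1
  for (ri in seq_along(runs)) {
    nr <- nrow(drift_blocks[[ri]]); nc <- ncol(drift_blocks[[ri]])
    drift[at_row:(at_row + nr - 1), at_col:(at_col + nc - 1)] <- drift_blocks[[ri]]
    cn <- c(cn, colnames(drift_blocks[[ri]]))
    at_row <- at_row + nr; at_col <- at_col + nc
  }
  colnames(drift) <- cn
  X <- cbind(task, drift)
  structure(list(X = X, colnames = colnames(X),
                 word_cols = seq_along(words), word_names = words,
                 catch_col = if (has_catch) length(words) + 1L else NA_integer_,
                 run = row_run, tr = tr),
            class = "design_matrix")
}

#' Fit the voxelwise ordinary least squares GLM
#'
#' Concatenates the runs' masked voxel time series, optionally appends each
#' run's mean-centred spatial-mean time series as a global-mean column,
#' prunes collinear drift/nuisance columns (with a warning), and fits OLS per
#' voxel. Per-word t statistics are computed for the word-versus-baseline
#' contrast.
#'
#' @param runs list of `bold_run` objects (see [gen_bold_runs()]).
#' @param design a `design_matrix` whose rows match the concatenated runs.
#' @param mask optional `roi_spec` restricting the fitted voxels (defaults to
#'   the whole grid).
#' @param global_mean logical; append per-run global-mean predictors.
#' @return list of class `glm_result`: `betas` (coefficients x voxels),
#'   `sigma2`, `df`, `t_words` (words x voxels), `xtx_inv`, `word_cols`,
#'   `word_names`, `colnames`, `mask_idx`, `grid`.
#' @export
fit_glm <- function(runs, design, mask = NULL, global_mean = TRUE) {
  grid <- runs[[1]]$grid
  if (is.null(mask)) {
    mask_idx <- seq_len(n_voxels(grid))
  } else {
    mask_idx <- roi_indices(mask)
    if (!length(mask_idx)) stop("empty mask", call. = FALSE)
  }
  Y <- do.call(rbind, lapply(runs, function(r) {
    d <- r$data
    t_len <- dim(d)[4]
    matrix(d, ncol = t_len)[mask_idx, , drop = FALSE] |> t()
  }))
  X <- design$X
  if (nrow(Y) != nrow(X)) {
    stop("total timepoints (", nrow(Y), ") do not match design rows (",
         nrow(X), ")", call. = FALSE)
  }
  if (global_mean) {
    gcols <- matrix(0, nrow(X), length(runs))
    at <- 1
    for (ri in seq_along(runs)) {
      t_len <- dim(runs[[ri]]$data)[4]
      gm <- rowMeans(matrix(runs[[ri]]$data, ncol = t_len) |> t())
      gcols[at:(at + t_len - 1), ri] <- gm - mean(gm)
      at <- at + t_len
    }
    colnames(gcols) <- sprintf("run%d_gmean", seq_along(runs))
    X <- cbind(X, gcols)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- sort(qx$pivot[seq_len(qx$rank)])
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    if (any(seq_along(design$word_names) %in% setdiff(seq_len(ncol(X)), keep))) {
      stop("design is rank deficient in the word regressors", call. = FALSE)
    }
    warning("pruned collinear design columns: ", paste(dropped, collapse = ", "),
            call. = FALSE)
    X <- X[, keep, drop = FALSE]
    qx <- qr(X)
  }
  betas <- qr.coef(qx, Y)
  res <- Y - X %*% betas
  df <- nrow(X) - qx$rank
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  wc <- match(design$word_names, colnames(X))
  se <- sqrt(outer(diag(xtx_inv)[wc], sigma2))
  t_words <- betas[wc, , drop = FALSE] / se
  t_words[, sigma2 == 0] <- 0
  rownames(t_words) <- design$word_names
  structure(list(betas = betas, sigma2 = sigma2, df = df, t_words = t_words,
                 xtx_inv = xtx_inv, word_cols = wc,
                 word_names = design$word_names, colnames = colnames(X),
                 mask_idx = mask_idx, grid = grid),
            class = "glm_result")
}

#' Linear contrast over the word regressors
#'
#' Returns the contrast effect (weighted combination of word betas) and its t
#' statistic per voxel. The abstract-greater-than-concrete contrast is the
#' difference of type means, i.e. weights `+1/n_abstract` and
#' `-1/n_concrete`.
#'
#' @param result a `glm_result`.
#' @param weights numeric vector, one weight per word condition (in
#'   `result$word_names` order).
#' @return list with vectors `beta` and `t` over the masked voxels, plus
#'   `mask_idx` and `grid`.
#' @export
contrast_map <- function(result, weights) {
  if (length(weights) != length(result$word_names)) {
    stop("'weights' length must equal the number of word conditions", call. = FALSE)
  }
  wc <- result$word_cols
  cb <- drop(crossprod(weights, result$betas[wc, , drop = FALSE]))
  cvar <- drop(crossprod(weights, result$xtx_inv[wc, wc] %*% weights))
  t <- cb / sqrt(cvar * result$sigma2)
  t[result$sigma2 == 0 | cvar == 0] <- 0
  list(beta = cb, t = t, mask_idx = result$mask_idx, grid = result$grid)
}

#' Contrast weights for the abstractness effect
#'
#' @param word_types character vector of `"concrete"` / `"abstract"` labels
#'   in word order.
#' @return numeric weights summing the abstract mean minus the concrete mean.
#' @export
abstractness_weights <- function(word_types) {
  w <- ifelse(word_types == "abstract", 1 / sum(word_types == "abstract"),
              -1 / sum(word_types == "concrete"))
  as.numeric(w)
}
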