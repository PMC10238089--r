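#' Generate a synthetic word-stimulus set
#'
#' Emulates a condition-rich word set: `n_concrete + n_abstract` words
#' partitioned into `k_categories` semantic categories (allocated to the two
#' word types proportionally, every category non-empty). Each word receives a
#' latent semantic embedding (its category's Gaussian centre plus
#' within-category jitter), a binary silhouette glyph, and a sub-syllabic
#' phonological code of four onset/rhyme tokens (two per syllable).
#'
#' @param n_concrete,n_abstract word counts per type (defaults 40 / 50).
#' @param k_categories number of semantic categories (default 10).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param embed_dim embedding dimensionality (default 8).
#' @param between_sd,within_sd standard deviations of the category centres
#'   and the within-category jitter.
#' @param domain_sep separation between the concrete and abstract domain
#'   means along the first embedding axis, emulating the superordinate
#'   object/non-object split of real semantic spaces (default 2.5).
#' @param min_sep minimum pairwise distance between category centres;
#'   centres are redrawn until separated, so planted categories are
#'   recoverable by construction (default 3).
#' @param silhouette_dim silhouette image size in pixels.
#' @param n_onsets,n_rhymes alphabet sizes for the phonological tokens;
#'   smaller alphabets give more cross-word sharing.
#' @return list of class `word_set`: `words` (data frame of `id`, `type`,
#'   `category`), `embedding` (words x dims), `silhouettes` (named list of
#'   binary matrices), `phon_units` (named list of token vectors).
#' @export
gen_word_set <- function(n_concrete = 40, n_abstract = 50, k_categories = 10,
                         seed = 1, embed_dim = 8, between_sd = 1,
                         within_sd = 0.2, domain_sep = 2.5, min_sep = 3,
                         silhouette_dim = c(64, 64),
                         n_onsets = 20, n_rhymes = 15) {
  if (n_concrete < 1 || n_abstract < 1) {
    stop("word counts must be positive", call. = FALSE)
  }
  n <- n_concrete + n_abstract
  if (k_categories < 1 || k_categories > n) {
    stop("'k_categories' must lie in 1..n_words", call. = FALSE)
  }
  type <- rep(c("concrete", "abstract"), c(n_concrete, n_abstract))
  # allocate categories to types proportionally, at least one per type when possible
  if (k_categories == 1) {
    k_con <- if (n_concrete > 0) 1L else 0L
    category <- rep(1L, n)
  } else {
    k_con <- max(1L, min(k_categories - 1L, round(k_categories * n_concrete / n)))
    k_abs <- k_categories - k_con
    category <- c(sort(rep_len(seq_len(k_con), n_concrete)),
                  sort(rep_len(k_con + seq_len(k_abs), n_abstract)))
  }
  ids <- sprintf("w%03d", seq_len(n))
  cat_domain <- ifelse(seq_len(k_categories) <= k_con, 1, -1)
  withr::with_seed(seed, {
    # centres: domain offset along axis 1, redrawn until pairwise separated
    best <- NULL; best_sep <- -Inf
    for (try in seq_len(500)) {
      ctr <- matrix(stats::rnorm(k_categories * embed_dim, sd = between_sd),
                    k_categories, embed_dim)
      ctr[, 1] <- ctr[, 1] + cat_domain * domain_sep / 2
      sep <- if (k_categories > 1) min(stats::dist(ctr)) else Inf
      if (sep > best_sep) { best <- ctr; best_sep <- sep }
      if (best_sep >= min_sep) break
    }
    centers <- best
    embedding <- centers[category, , drop = FALSE] +
      matrix(stats::rnorm(n * embed_dim, sd = within_sd), n, embed_dim)
    silhouettes <- lapply(seq_len(n), function(i) {
      gen_blob_glyph(silhouette_dim)
    })
    phon_units <- lapply(seq_len(n), function(i) {
      c(paste0("o", sample.int(n_onsets, 1)), paste0("r", sample.int(n_rhymes, 1)),
        paste0("o", sample.int(n_onsets, 1)), paste0("r", sample.int(n_rhymes, 1)))
    })
  })
  rownames(embedding) <- ids
  names(silhouettes) <- ids
  names(phon_units) <- ids
  structure(list(words = data.frame(id = ids, type = type,
                                    category = as.integer(category)),
                 embedding = embedding, silhouettes = silhouettes,
                 phon_units = phon_units),
            class = "word_set")
}

# random union-of-ellipses binary glyph; always contains both 0s and 1s
gen_blob_glyph <- function(dim = c(64, 64), n_blobs = 3) {
  gx <- matrix(seq_len(dim[1]), dim[1], dim[2])
  gy <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  im <- matrix(0, dim[1], dim[2])
  for (b in seq_len(n_blobs)) {
    cx <- stats::runif(1, 0.25, 0.75) * dim[1]
    cy <- stats::runif(1, 0.25, 0.75) * dim[2]
    rx <- stats::runif(1, 0.08, 0.2) * dim[1]
    ry <- stats::runif(1, 0.08, 0.2) * dim[2]
    im <- pmax(im, ((gx - cx) / rx)^2 + ((gy - cy) / ry)^2 <= 1)
  }
  im
}

#' Ground truth for the two-group forward simulation
#'
#' Holds the unobservable generative quantities the downstream analyses try
#' to recover: the latent semantic embedding, the per-ROI-by-group semantic
#' encoding strength (pattern signal for the semantic structure), the
#' per-ROI-by-group univariate abstractness effect (mean activation
#' difference, abstract minus concrete), and the behavioural noise level.
#'
#' @param words a `word_set`.
#' @param encoding_strength numeric matrix, ROI names x group names, of
#'   non-negative pattern signal strengths (missing ROI/group means 0).
#' @param abstractness_effect numeric matrix, ROI names x group names.
#' @param behavioral_noise_sd standard deviation of the additive symmetric
#'   noise on behavioural distance matrices.
#' @param seed integer seed fixing the ROI pattern projections shared by all
#'   subjects.
#' @return list of class `ground_truth`.
#' @export
ground_truth <- function(words, encoding_strength = NULL,
                         abstractness_effect = NULL,
                         behavioral_noise_sd = 0.1, seed = 1) {
  if (!is.null(encoding_strength) && any(encoding_strength < 0)) {
    stop("'encoding_strength' must be non-negative", call. = FALSE)
  }
  structure(list(semantic_embedding = words$embedding,
                 encoding_strength = encoding_strength,
                 abstractness_effect = abstractness_effect,
                 behavioral_noise_sd = behavioral_noise_sd,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Build an ROI-by-group effect matrix
#'
#' @param rois character vector of ROI names.
#' @param groups character vector of group names.
#' @param default fill value.
#' @return named numeric matrix.
#' @export
effect_map <- function(rois, groups = c("native", "delayed"), default = 0) {
  matrix(default, length(rois), length(groups),
         dimnames = list(rois, groups))
}

lookup_effect <- function(m, roi, group) {
  if (is.null(m)) return(0)
  if (!roi %in% rownames(m) || !group %in% colnames(m)) return(0)
  m[roi, group]
}

#' Ground-truth behavioural distance RDM
#'
#' Euclidean distances between the latent semantic embeddings, rescaled so
#' the off-diagonal entries span `[0, 1]`.
#'
#' @param words a `word_set`.
#' @return an `rdm`.
#' @export
truth_rdm <- function(words) {
  d <- as.matrix(stats::dist(words$embedding))
  rescale_rdm(d, labels = words$words$id)
}

rescale_rdm <- function(d, labels) {
  off <- d[lower.tri(d)]
  rng <- range(off)
  if (diff(rng) > 0) d <- (d - rng[1]) / diff(rng)
  d[d < 0] <- 0
  diag(d) <- 0
  d <- (d + t(d)) / 2
  rdm(d, labels = labels)
}

#' Simulate subjects' behavioural distance matrices
#'
#' Each subject's RDM is the ground-truth embedding distance matrix plus
#' i.i.d. symmetric Gaussian noise (sd `truth$behavioral_noise_sd`),
#' rescaled to `[0, 1]` with a zero diagonal.
#'
#' @param truth a `ground_truth`.
#' @param words a `word_set`.
#' @param n_subjects number of subjects (at least 1).
#' @param seed integer seed.
#' @return list of `rdm` objects, one per subject.
#' @export
gen_behavioral_rdms <- function(truth, words, n_subjects, seed = 1) {
  if (n_subjects < 1) stop("'n_subjects' must be at least 1", call. = FALSE)
  d0 <- as.matrix(stats::dist(words$embedding))
  n <- nrow(d0)
  withr::with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      noise <- matrix(0, n, n)
      noise[lower.tri(noise)] <- stats::rnorm(n * (n - 1) / 2,
                                              sd = truth$behavioral_noise_sd)
      noise <- noise + t(noise)
      rescale_rdm(d0 + noise, labels = words$words$id)
    })
  })
}

#' Simulate one subject's per-word activation patterns
#'
#' Within each ROI, word `w`'s voxel pattern is
#' `encoding_strength[roi, group]` times a fixed seeded linear projection of
#' the word's semantic embedding, plus `abstractness_effect[roi, group]` for
#' abstract words, plus Gaussian noise; voxels outside every ROI contain pure
#' noise. The projection is drawn from `truth$seed`, so it is identical
#' across subjects and the neural RDM geometry mirrors the behavioural
#' geometry by construction.
#'
#' @param truth a `ground_truth`.
#' @param words a `word_set`.
#' @param group group label (must match a column of the effect matrices to
#'   produce signal).
#' @param rois list of disjoint `roi_spec` objects on one grid.
#' @param noise_sd positive voxel noise standard deviation.
#' @param seed integer subject seed.
#' @param subject_id optional subject identifier.
#' @return list of class `subject_data`: `id`, `group`, `patterns`
#'   (words x voxels matrix of surrogate t values), `grid`, `word_ids`.
#' @export
gen_subject_patterns <- function(truth, words, group, rois, noise_sd = 1,
                                 seed = 1, subject_id = NULL) {
  if (noise_sd <= 0) stop("'noise_sd' must be positive", call. = FALSE)
  check_disjoint_rois(rois)
  grid <- rois[[1]]$grid
  nv <- n_voxels(grid)
  n_words <- nrow(words$words)
  emb <- words$embedding
  d <- ncol(emb)
  projections <- withr::with_seed(truth$seed, lapply(rois, function(r) {
    k <- length(roi_indices(r))
    matrix(stats::rnorm(k * d), k, d) / sqrt(d)
  }))
  abstract <- words$words$type == "abstract"
  patterns <- withr::with_seed(seed,
    matrix(stats::rnorm(n_words * nv, sd = noise_sd), n_words, nv))
  for (i in seq_along(rois)) {
    roi <- rois[[i]]
    idx <- roi_indices(roi)
    strength <- lookup_effect(truth$encoding_strength, roi$name, group)
    abstr <- lookup_effect(truth$abstractness_effect, roi$name, group)
    if (strength != 0) {
      patterns[, idx] <- patterns[, idx] + strength * emb %*% t(projections[[i]])
    }
    if (abstr != 0) patterns[abstract, idx] <- patterns[abstract, idx] + abstr
  }
  rownames(patterns) <- words$words$id
  structure(list(id = subject_id, group = group, patterns = patterns,
                 grid = grid, word_ids = words$words$id),
            class = "subject_data")
}

#' Simulate a run-wise event table
#'
#' Each run holds one trial per target word plus `n_catch` catch trials in
#' pseudo-random order, with `n_null` 2.5 s null slots sampled uniformly
#' without replacement to jitter the stimulus train; runs start with a
#' `lead_in` fixation and end with a rest period filling the run to
#' `run_duration` seconds.
#'
#' @param words a `word_set`.
#' @param n_runs number of runs (default 10).
#' @param n_catch catch trials per run (default 14).
#' @param n_null null slots per run (default 30).
#' @param trial_dur trial duration in s (default 2.5).
#' @param lead_in initial fixation in s (default 12).
#' @param run_duration run length in s (default 360).
#' @param seed integer seed.
#' @return data frame with `onset`, `duration`, `condition`, `run`; onsets
#'   strictly increasing within run.
#' @export
gen_event_table <- function(words, n_runs = 10, n_catch = 14, n_null = 30,
                            trial_dur = 2.5, lead_in = 12, run_duration = 360,
                            seed = 1) {
  ids <- words$words$id
  n_slots <- length(ids) + n_catch + n_null
  if (lead_in + n_slots * trial_dur > run_duration) {
    stop("trials do not fit into the run duration", call. = FALSE)
  }
  withr::with_seed(seed, {
    out <- lapply(seq_len(n_runs), function(r) {
      null_slots <- sort(sample.int(n_slots, n_null))
      trial_slots <- setdiff(seq_len(n_slots), null_slots)
      conds <- sample(c(ids, rep("catch", n_catch)))
      data.frame(onset = lead_in + (trial_slots - 1) * trial_dur,
                 duration = trial_dur, condition = conds, run = r)
    })
  })
  do.call(rbind, out)
}

#' Forward-simulate BOLD runs from per-word patterns
#'
#' Voxel time series are the design-matrix forward model: each word's
#' HRF-convolved regressor scaled by that word's voxel pattern amplitude,
#' plus per-run cosine drift and motion-coupled components and Gaussian
#' noise. Simulated motion parameters are returned as each run's nuisance
#' block.
#'
#' @param subject a `subject_data` whose `patterns` supply the amplitudes.
#' @param events event table referencing only this subject's words.
#' @param hrf an `hrf_params`.
#' @param noise_sd temporal noise sd.
#' @param seed integer seed.
#' @param tr repetition time, s.
#' @param run_duration run length, s.
#' @param drift_sd sd of the random drift coefficients (default 0.5).
#' @param motion_sd sd of the motion random-walk increments (default 0.02).
#' @param baseline constant baseline signal (default 100).
#' @return list of `bold_run` objects: `data` (4D array), `tr`, `grid`,
#'   `nuisance` (T x 6 motion block).
#' @export
gen_bold_runs <- function(subject, events, hrf = hrf_params(), noise_sd = 1,
                          seed = 1, tr = 2, run_duration = 360,
                          drift_sd = 0.5, motion_sd = 0.02, baseline = 100) {
  grid <- subject$grid
  nv <- n_voxels(grid)
  if (ncol(subject$patterns) != nv) {
    stop("pattern grid does not match the subject grid", call. = FALSE)
  }
  unknown <- setdiff(setdiff(unique(events$condition), "catch"),
                     subject$word_ids)
  if (length(unknown)) {
    stop("events reference unknown words: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  runs <- sort(unique(events$run))
  withr::with_seed(seed, {
    nuisance <- lapply(runs, function(r) {
      n_scan <- as.integer(round(run_duration / tr))
      apply(matrix(stats::rnorm(n_scan * 6, sd = motion_sd), n_scan, 6), 2, cumsum)
    })
    design <- build_design(events, nuisance = nuisance, tr = tr,
                           run_duration = run_duration, hrf = hrf)
    p <- ncol(design$X)
    gamma <- matrix(0, p, nv)
    gamma[seq_along(design$word_names), ] <-
      subject$patterns[design$word_names, , drop = FALSE]
    drift_cols <- grep("_dct|_nuis", design$colnames)
    gamma[drift_cols, ] <- stats::rnorm(length(drift_cols) * nv, sd = drift_sd)
    gamma[grep("_const", design$colnames), ] <- baseline
    Y <- design$X %*% gamma
    if (noise_sd > 0) {
      Y <- Y + matrix(stats::rnorm(length(Y), sd = noise_sd), nrow(Y), ncol(Y))
    }
  })
  out <- vector("list", length(runs))
  at <- 1
  for (ri in seq_along(runs)) {
    n_scan <- sum(design$run == runs[ri])
    block <- Y[at:(at + n_scan - 1), , drop = FALSE]
    at <- at + n_scan
    out[[ri]] <- structure(list(data = array(t(block), c(grid$dim, n_scan)),
                                tr = tr, grid = grid,
                                nuisance = nuisance[[ri]]),
                           class = "bold_run")
  }
  out
}
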