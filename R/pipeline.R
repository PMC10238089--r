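#' Default pipeline configuration
#'
#' All tunable constants of the end-to-end pipeline in one list: grid and
#' trial timing, HRF, high-pass cutoff (128 s), smoothing FWHMs (2 mm for
#' RSA inputs, 6 mm univariate / searchlight-z), searchlight radius (8 mm),
#' cluster-forming voxel p (0.001), fROI size (50), bootstrap count (5000),
#' group sizes (16 native / 23 delayed) and every seed. The default demo
#' scales the grid and simulation sizes down so the full pipeline runs on a
#' laptop; the study-scale values are in comments where they differ.
#'
#' @param ... named overrides merged over the defaults (one level deep).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    groups = list(native = 16, delayed = 23),
    words = list(n_concrete = 40, n_abstract = 50, k_categories = 10),
    grid = list(dim = c(16, 16, 16), voxel_mm = c(2, 2, 2)),  # study scale: 24^3
    rois = list(dATL = list(x = c(3, 6), y = c(3, 6), z = c(3, 6)),
                pMTG = list(x = c(10, 13), y = c(3, 6), z = c(3, 6)),
                IFG = list(x = c(3, 6), y = c(10, 13), z = c(10, 13))),
    encoding_strength = list(dATL = c(native = 1.0, delayed = 0.3),
                             pMTG = c(native = 0.6, delayed = 0.5),
                             IFG = c(native = 0.5, delayed = 0.4)),
    abstractness_effect = list(dATL = c(native = 0.8, delayed = 0.2),
                               pMTG = c(native = 0.5, delayed = 0.4),
                               IFG = c(native = 0.5, delayed = 0.4)),
    pattern_noise_sd = 1,
    behavioral = list(n_subjects = 32, noise_sd = 0.5),
    cluster = list(k_max = 15, n_ref = 20, n_start = 10),
    tr = 2, trial_duration = 2.5, hp_cutoff = 128,
    smooth_fwhm_rsa = 2, smooth_fwhm_univariate = 6,
    searchlight = list(enable = FALSE, radius = 8, n_perm = 500,
                       voxel_p = 0.001),
    froi = list(n_top = 50),
    mediation = list(n_boot = 1000),   # study scale: 5000
    out_dir = NULL)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of overrides over [pipeline_config()] defaults.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  # polynomial rolling hash of the serialized YAML text; provenance stamp
  txt <- yaml::as.yaml(unclass(cfg))
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

as_effect_matrix <- function(lst) {
  if (is.null(lst)) return(NULL)
  groups <- unique(unlist(lapply(lst, names)))
  m <- matrix(0, length(lst), length(groups),
              dimnames = list(names(lst), groups))
  for (r in names(lst)) m[r, names(lst[[r]])] <- unlist(lst[[r]])
  m
}

#' Run the end-to-end two-group pipeline on simulated data
#'
#' Simulates the word set, behavioural RDMs and both subject groups'
#' per-word activation patterns, then runs every analysis stage: gap
#' statistic categorisation of the behavioural matrix, stimulus-property
#' model RDMs, ROI-level partial-Spearman RSA with one-sample and Welch
#' group tests, optional searchlight RSA with permutation cluster
#' correction, univariate ROI and cross-validated fROI abstractness
#' analyses with the mixed ANOVA, the cohort demographics table, and a
#' bootstrap mediation of the dATL group effect. Result tables are written
#' to `cfg$out_dir` (when set) as tab-separated text stamped with the
#' configuration hash; all randomness flows from the config seeds.
#'
#' @param cfg a `pipeline_config`.
#' @return list of result tables (invisibly also written to disk).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  t0 <- Sys.time()
  hash <- config_hash(cfg)
  log_msg <- function(...) message(sprintf("[semrsa %s] ", hash), sprintf(...))
  log_msg("pipeline start (seed %d)", cfg$seed)

  words <- gen_word_set(cfg$words$n_concrete, cfg$words$n_abstract,
                        cfg$words$k_categories, seed = cfg$seed)
  grid <- grid_spec(cfg$grid$dim, cfg$grid$voxel_mm)
  rois <- lapply(names(cfg$rois), function(nm) {
    b <- cfg$rois[[nm]]
    box_roi(nm, grid, b$x[1]:b$x[2], b$y[1]:b$y[2], b$z[1]:b$z[2])
  })
  names(rois) <- names(cfg$rois)
  truth <- ground_truth(words,
                        encoding_strength = as_effect_matrix(cfg$encoding_strength),
                        abstractness_effect = as_effect_matrix(cfg$abstractness_effect),
                        behavioral_noise_sd = cfg$behavioral$noise_sd,
                        seed = cfg$seed)

  # behavioural stage: average -> gap-statistic categories -> model RDMs
  beh <- gen_behavioral_rdms(truth, words, cfg$behavioral$n_subjects,
                             seed = cfg$seed + 1)
  beh_avg <- average_rdms(beh)
  assign <- cluster_words(beh_avg, k_max = cfg$cluster$k_max,
                          n_ref = cfg$cluster$n_ref, seed = cfg$seed,
                          n_start = cfg$cluster$n_start)
  log_msg("gap statistic selected k = %d", assign$k)
  models <- stimulus_rdm_bundle(
    semantic_categorical = categorical_rdm(assign),
    semantic_continuous = beh_avg,
    visual = silhouette_rdm(words$silhouettes),
    phonological = phonological_rdm(words$phon_units))
  covs <- list(models$visual, models$phonological)

  # subject simulation (pattern level)
  subjects <- list()
  si <- 0
  for (gname in names(cfg$groups)) {
    for (k in seq_len(cfg$groups[[gname]])) {
      si <- si + 1
      subjects[[si]] <- gen_subject_patterns(
        truth, words, gname, rois, noise_sd = cfg$pattern_noise_sd,
        seed = cfg$seed * 10000 + si,
        subject_id = sprintf("%s%02d", gname, k))
    }
  }

  # ROI-level RSA + group stats
  rsa_rows <- list()
  for (nm in names(rois)) {
    res <- roi_rsa(subjects, rois[[nm]], models$semantic_categorical, covs)
    g1 <- names(cfg$groups)[1]; g2 <- names(cfg$groups)[2]
    by_group <- split(res$z, res$group)[c(g1, g2)]
    w <- welch_t(by_group[[g1]], by_group[[g2]])
    one <- lapply(by_group, function(z) one_sample_t(z, tail = "one"))
    rsa_rows[[nm]] <- stats::setNames(data.frame(
      roi = nm,
      mean(by_group[[g1]]), mean(by_group[[g2]]),
      one[[g1]]$statistic, one[[g1]]$p,
      one[[g2]]$statistic, one[[g2]]$p,
      w$statistic, w$df, w$p,
      unname(w$effect_size["hedges_g"])),
      c("roi", paste0("mean_z_", c(g1, g2)),
        paste0(c("t_", "p_"), g1), paste0(c("t_", "p_"), g2),
        "welch_t", "welch_df", "welch_p", "hedges_g"))
  }
  rsa_table <- do.call(rbind, rsa_rows)

  # univariate ROI + cross-validated fROI
  word_types <- words$words$type
  uni_rows <- list(); froi_rows <- list()
  for (nm in names(rois)) {
    idx <- roi_indices(rois[[nm]])
    recs <- do.call(rbind, lapply(subjects, function(s) {
      pb <- pattern_betas(s, idx, word_types)
      data.frame(subject = s$id, group = s$group,
                 beta_abstract = pb["abstract"], beta_concrete = pb["concrete"])
    }))
    an <- abstractness_anova(recs)
    uni_rows[[nm]] <- cbind(roi = nm, an)
    # split-half surrogate folds with independent noise for the fROI stage
    cv <- do.call(rbind, lapply(seq_along(subjects), function(i) {
      s <- subjects[[i]]
      fa <- pattern_fold(gen_subject_patterns(truth, words, s$group, rois,
                                              noise_sd = cfg$pattern_noise_sd,
                                              seed = cfg$seed * 20000 + i),
                         word_types)
      fb <- pattern_fold(gen_subject_patterns(truth, words, s$group, rois,
                                              noise_sd = cfg$pattern_noise_sd,
                                              seed = cfg$seed * 30000 + i),
                         word_types)
      est <- froi_crossval(fa, fb, rois[[nm]], n_top = cfg$froi$n_top)
      data.frame(subject = s$id, group = s$group,
                 beta_abstract = est$beta_abstract,
                 beta_concrete = est$beta_concrete)
    }))
    froi_rows[[nm]] <- cbind(roi = nm, abstractness_anova(cv))
  }
  uni_table <- do.call(rbind, uni_rows)
  froi_table <- do.call(rbind, froi_rows)

  # searchlight (optional)
  search_table <- NULL
  if (isTRUE(cfg$searchlight$enable)) {
    mask <- roi_spec("analysis", array(TRUE, grid$dim), grid)
    maps <- lapply(subjects, function(s)
      searchlight_rsa(s, mask, radius = cfg$searchlight$radius,
                      model = models$semantic_categorical, covariates = covs,
                      smooth_fwhm = cfg$smooth_fwhm_univariate))
    grp <- vapply(subjects, function(s) s$group, "")
    ct <- group_map_test(maps[grp == names(cfg$groups)[1]],
                         maps[grp == names(cfg$groups)[2]],
                         voxel_p = cfg$searchlight$voxel_p,
                         n_perm = cfg$searchlight$n_perm, seed = cfg$seed)
    search_table <- ct$clusters
  }

  # demographics table + mediation of the dATL group effect
  demo <- group_stats_table(signer_demographics())
  res_datl <- roi_rsa(subjects, rois[[1]], models$semantic_categorical, covs)
  grp01 <- as.numeric(factor(res_datl$group,
                             levels = names(cfg$groups))) - 1
  med_seed <- cfg$seed + 7
  mediator <- withr::with_seed(med_seed,
    stats::rnorm(length(grp01), mean = grp01, sd = 1))  # proxy rating variable
  med <- mediation_bootstrap(grp01, mediator, res_datl$z,
                             n_boot = cfg$mediation$n_boot, seed = med_seed)
  med_table <- data.frame(effect = c("acme", "ade", "total"),
                          estimate = c(med$acme, med$ade, med$total),
                          ci_lo = med$ci[1, ], ci_hi = med$ci[2, ],
                          p = med$p)

  out <- list(config_hash = hash, category_k = assign$k, rsa = rsa_table,
              univariate = uni_table, froi = froi_table,
              searchlight = search_table, demographics = demo,
              mediation = med_table)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("rsa", "univariate", "froi", "demographics", "mediation")) {
      tab <- out[[nm]]
      tab$config_hash <- hash
      utils::write.table(format(tab, digits = 6),
                         file.path(cfg$out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(search_table)) {
      st <- search_table; st$config_hash <- hash
      utils::write.table(format(st, digits = 6),
                         file.path(cfg$out_dir, "searchlight_clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  log_msg("pipeline done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  invisible(out)
}

#' Pattern-level type means for one subject
#'
#' Mean pattern amplitude per word type over a voxel set — the pattern-level
#' analogue of [roi_mean_betas()] used when subjects are simulated directly
#' at the per-word pattern stage.
#'
#' @param subject a `subject_data`.
#' @param idx linear voxel indices.
#' @param word_types type labels in word order.
#' @return named numeric vector `c(abstract=, concrete=)`.
#' @export
pattern_betas <- function(subject, idx, word_types) {
  p <- subject$patterns[, idx, drop = FALSE]
  c(abstract = mean(p[word_types == "abstract", , drop = FALSE]),
    concrete = mean(p[word_types == "concrete", , drop = FALSE]))
}

#' Pattern-level fROI fold
#'
#' Builds a [froi_fold()]-compatible object directly from per-word patterns:
#' the selection statistic is the abstract-minus-concrete mean pattern per
#' voxel and the estimation quantities are the word-type voxel means.
#'
#' @param subject a `subject_data` (one independent data fold).
#' @param word_types type labels in word order.
#' @return a `froi_fold`.
#' @export
pattern_fold <- function(subject, word_types) {
  pa <- colMeans(subject$patterns[word_types == "abstract", , drop = FALSE])
  pc <- colMeans(subject$patterns[word_types == "concrete", , drop = FALSE])
  structure(list(t_con = pa - pc, beta_abstract = pa, beta_concrete = pc,
                 mask_idx = seq_len(ncol(subject$patterns)),
                 grid = subject$grid),
            class = "froi_fold")
}
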