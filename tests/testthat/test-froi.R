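test_that("ROI mean betas reduce to single-voxel values and planted effects", {
  ws <- small_words(seed = 1, n_con = 3, n_abs = 3, k = 2)
  g <- grid_spec(c(2, 2, 1))
  X <- cbind(diag(6), const = 1)[rep(1:6, 3), ]
  colnames(X) <- c(ws$words$id, "const")
  set.seed(1)
  Y <- matrix(rnorm(18 * 4), 18, 4)
  design <- structure(list(X = X, colnames = colnames(X), word_cols = 1:6,
                           word_names = ws$words$id, catch_col = NA,
                           run = rep(1L, 18), tr = 2),
                      class = "design_matrix")
  run <- structure(list(data = array(t(Y), c(g$dim, 18)), tr = 2, grid = g,
                        nuisance = NULL), class = "bold_run")
  fit <- suppressWarnings(fit_glm(list(run), design, global_mean = FALSE))
  one_vox <- roi_spec("v1", 1L, g)
  rec <- roi_mean_betas(fit, one_vox, ws$words$type)
  wb <- fit$betas[1:6, 1]
  expect_equal(rec$beta_abstract, mean(wb[ws$words$type == "abstract"]))
  expect_equal(rec$beta_concrete, mean(wb[ws$words$type == "concrete"]))
  expect_error(roi_mean_betas(fit, roi_spec("none", integer(0), g),
                              ws$words$type), "empty")
})

test_that("fROI selection recovers an embedded selective subregion", {
  ws <- small_words(seed = 2)
  g <- grid_spec(c(10, 10, 5))             # 500-voxel constraint
  constraint <- roi_spec("dATL", array(TRUE, g$dim), g)
  sub_idx <- which(array(seq_len(500), g$dim) <= 60)  # 60-voxel subregion
  subregion <- roi_spec("sub", sub_idx, g)
  abst <- effect_map("sub"); abst["sub", "native"] <- 1
  truth <- ground_truth(ws, abstractness_effect = abst, seed = 2)
  hit_rate <- vapply(1:10, function(s) {
    fa <- pattern_fold(gen_subject_patterns(truth, ws, "native",
                                            list(subregion), 0.5,
                                            seed = 2 * s), ws$words$type)
    fb <- pattern_fold(gen_subject_patterns(truth, ws, "native",
                                            list(subregion), 0.5,
                                            seed = 2 * s + 1), ws$words$type)
    est <- froi_crossval(fa, fb, constraint, n_top = 50)
    mean(attr(est, "sel_a") %in% sub_idx)
  }, 0)
  expect_gte(mean(hit_rate >= 0.8), 0.9)
})

test_that("fROI tie-breaking is deterministic by ascending voxel index", {
  g <- grid_spec(c(4, 2, 1))
  constraint <- roi_spec("c", array(TRUE, g$dim), g)
  fold <- structure(list(t_con = c(1, 3, 3, 2, 3, 0, 1, 2),
                         beta_abstract = 1:8, beta_concrete = rep(0, 8),
                         mask_idx = 1:8, grid = g), class = "froi_fold")
  est1 <- froi_crossval(fold, fold, constraint, n_top = 3)
  # top t = 3 at indices 2, 3, 5; deterministic repeat
  expect_equal(sort(attr(est1, "sel_a")), c(2, 3, 5))
  expect_identical(est1, froi_crossval(fold, fold, constraint, n_top = 3))
  # ties beyond the cut: t=2 at indices 4 and 8 -> lower index wins
  est2 <- froi_crossval(fold, fold, constraint, n_top = 4)
  expect_equal(sort(attr(est2, "sel_a")), c(2, 3, 4, 5))
  expect_warning(froi_crossval(fold, fold, constraint, n_top = 20), "smaller")
})

test_that("cross-validation removes the selection bias of naive estimates", {
  ws <- small_words(seed = 3)
  g <- grid_spec(c(6, 6, 6))
  roi <- roi_spec("dATL", array(TRUE, g$dim), g)
  truth <- ground_truth(ws, seed = 3)     # null: no abstractness anywhere
  cv <- naive <- numeric(40)
  for (s in 1:40) {
    fa <- pattern_fold(gen_subject_patterns(truth, ws, "native", list(roi),
                                            1, seed = 2 * s), ws$words$type)
    fb <- pattern_fold(gen_subject_patterns(truth, ws, "native", list(roi),
                                            1, seed = 2 * s + 1), ws$words$type)
    est <- froi_crossval(fa, fb, roi, n_top = 50)
    cv[s] <- est$beta_abstract - est$beta_concrete
    sel <- order(-fa$t_con)[1:50]
    naive[s] <- mean(fa$beta_abstract[sel] - fa$beta_concrete[sel])
  }
  expect_gt(mean(naive), mean(cv))                      # strict ordering
  expect_gt(mean(naive), 0.2)                           # visibly inflated
  expect_lt(abs(mean(cv)), 3 * stats::sd(cv) / sqrt(40))
})

test_that("the mixed ANOVA matches the sums-of-squares oracle", {
  # balanced 2-per-group case, oracle computed from first principles
  rec <- data.frame(subject = paste0("s", 1:4),
                    group = rep(c("g1", "g2"), each = 2),
                    beta_abstract = c(1.2, 0.8, 2.0, 1.5),
                    beta_concrete = c(0.3, 0.5, 0.9, 1.1))
  an <- abstractness_anova(rec)
  y <- c(rec$beta_abstract, rec$beta_concrete)
  grp <- rep(rec$group, 2); wt <- rep(c("A", "C"), each = 4)
  subj <- rep(rec$subject, 2)
  gm <- mean(y)
  ss_group <- sum(tapply(y, grp, function(v) length(v) * (mean(v) - gm)^2))
  ss_subj <- sum(tapply(y, subj, function(v) length(v) * (mean(v) - gm)^2))
  ss_wt <- sum(tapply(y, wt, function(v) length(v) * (mean(v) - gm)^2))
  cellm <- tapply(y, list(grp, wt), mean)
  ss_cells <- 2 * sum((cellm - gm)^2)
  ss_int <- ss_cells - ss_group - ss_wt
  ss_tot <- sum((y - gm)^2)
  ss_err_b <- ss_subj - ss_group
  ss_err_w <- ss_tot - ss_subj - ss_wt - ss_int
  f_or <- c(group = (ss_group / 1) / (ss_err_b / 2),
            word_type = (ss_wt / 1) / (ss_err_w / 2),
            interaction = (ss_int / 1) / (ss_err_w / 2))
  expect_equal(an$F, unname(f_or), tolerance = 1e-10)
  expect_equal(an$df1, rep(1, 3))
  expect_equal(an$df2, rep(2, 3))
})

test_that("interaction F equals the squared pooled t on paired differences", {
  set.seed(5)
  rec <- data.frame(subject = paste0("s", 1:39),
                    group = rep(c("native", "delayed"), c(16, 23)),
                    beta_abstract = rnorm(39), beta_concrete = rnorm(39))
  an <- abstractness_anova(rec)
  d <- rec$beta_abstract - rec$beta_concrete
  tt <- stats::t.test(d[rec$group == "native"], d[rec$group == "delayed"],
                      var.equal = TRUE)
  expect_equal(an$F[an$effect == "group:word_type"],
               unname(tt$statistic^2), tolerance = 1e-8)
})

test_that("the ANOVA detects identical groups and tiny groups", {
  rec <- data.frame(subject = paste0("s", 1:6),
                    group = rep(c("a", "b"), each = 3),
                    beta_abstract = rep(c(1, 2.2, 3.1), 2),
                    beta_concrete = rep(c(0.4, 0.1, 2.5), 2))
  an <- abstractness_anova(rec)
  expect_equal(an$F[an$effect == "group:word_type"], 0, tolerance = 1e-10)
  bad <- rec[c(1, 4:6), ]
  expect_error(abstractness_anova(bad), "at least 2")
})
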