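test_that("neural RDM is the pairwise Pearson distance of patterns", {
  p <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  r <- neural_rdm(p)
  expect_equal(unclass(r)["a", "b"], 0)            # perfectly correlated
  expect_equal(unclass(r)["a", "c"], 2)            # perfectly anticorrelated
  # independent hand computation for an arbitrary 3x4 pattern set
  q <- rbind(a = c(0.3, -1, 2, 0.5), b = c(1, 0, -0.5, 2),
             c = c(-2, 1, 1, 0))
  rq <- neural_rdm(q)
  hand <- function(x, y) {
    1 - sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(unclass(rq)["a", "b"], hand(q["a", ], q["b", ]), tolerance = 1e-12)
  expect_equal(unclass(rq)["a", "c"], hand(q["a", ], q["c", ]), tolerance = 1e-12)
  expect_equal(unclass(rq)["b", "c"], hand(q["b", ], q["c", ]), tolerance = 1e-12)
  expect_error(neural_rdm(rbind(a = c(1, 1, 1), b = c(1, 2, 3))), "a")
  expect_error(neural_rdm(p[, 1, drop = FALSE]), "2 voxels")
})

test_that("adding a constant to one condition's pattern leaves its row unchanged", {
  set.seed(2)
  p <- matrix(rnorm(5 * 8), 5, 8, dimnames = list(paste0("c", 1:5), NULL))
  r1 <- neural_rdm(p)
  p2 <- p; p2[3, ] <- p2[3, ] + 7
  expect_equal(neural_rdm(p2), r1)
})

test_that("partial Spearman matches the explicit rank-regression oracle", {
  set.seed(3)
  for (i in 1:10) {
    tv <- runif(15); mv <- runif(15); c1 <- runif(15); c2 <- runif(15)
    target <- rdm_from_lower(tv, 6); model <- rdm_from_lower(mv, 6)
    covs <- list(rdm_from_lower(c1, 6), rdm_from_lower(c2, 6))
    expect_equal(partial_spearman(target, model, covs),
                 oracle_partial_spearman(tv, mv, list(c1, c2)),
                 tolerance = 1e-10)
    expect_equal(partial_spearman(target, model),
                 oracle_spearman(tv, mv), tolerance = 1e-12)
  }
  r <- rdm_from_lower(runif(15), 6)
  expect_equal(partial_spearman(r, r), 1)
  expect_error(partial_spearman(r, r, list(r)), "zero variance")
})

test_that("pure-noise covariates barely move the plain Spearman", {
  ws <- gen_word_set(40, 50, 10, seed = 6, silhouette_dim = c(8, 8))
  truth <- ground_truth(ws, behavioral_noise_sd = 0.3, seed = 6)
  target <- gen_behavioral_rdms(truth, ws, 1, seed = 1)[[1]]
  model <- truth_rdm(ws)
  set.seed(6)
  for (i in 1:5) {
    noise_cov <- rdm_from_lower(runif(4005), 90, ws$words$id)
    plain <- partial_spearman(target, model)
    partial <- partial_spearman(target, model, list(noise_cov))
    expect_lt(abs(plain - partial), 0.02)
  }
})

test_that("sphere membership follows centre-to-centre mm distance", {
  g <- grid_spec(c(24, 24, 24), c(2, 2, 2))
  mask <- roi_spec("all", array(TRUE, g$dim), g)
  expect_length(sphere_indices(mask, c(12, 12, 12), 0), 1)
  expect_length(sphere_indices(mask, c(12, 12, 12), 2), 7)
  # independent lattice enumeration for the 8 mm sphere on a 2 mm grid
  count <- 0
  for (i in -4:4) for (j in -4:4) for (k in -4:4) {
    if ((2 * i)^2 + (2 * j)^2 + (2 * k)^2 <= 64) count <- count + 1
  }
  expect_equal(count, 257)
  expect_length(sphere_indices(mask, c(12, 12, 12), 8), count)
  # clipped at the grid boundary, never padded
  expect_lt(length(sphere_indices(mask, c(1, 1, 1), 8)), count)
  expect_error(sphere_indices(mask, c(0, 5, 5), 8), "inside")
})

test_that("searchlight equals ROI RSA when the sphere is the ROI", {
  ws <- small_words(seed = 7)
  g <- grid_spec(c(9, 9, 9))
  centre <- c(5, 5, 5)
  full <- roi_spec("all", array(TRUE, g$dim), g)
  ball_idx <- sphere_indices(full, centre, 4)
  ball <- roi_spec("ball", ball_idx, g)
  enc <- effect_map("ball"); enc["ball", "native"] <- 0.8
  truth <- ground_truth(ws, encoding_strength = enc, seed = 7)
  sub <- gen_subject_patterns(truth, ws, "native", list(ball), 1, seed = 8)
  model <- categorical_rdm(stats::setNames(ws$words$category, ws$words$id))
  vis <- silhouette_rdm(ws$silhouettes)
  zmap <- searchlight_rsa(sub, ball, radius = 4, model = model,
                          covariates = list(vis), smooth_fwhm = 0)
  centre_lin <- centre[1] + (centre[2] - 1) * 9 + (centre[3] - 1) * 81
  z_roi <- roi_rsa(list(sub), ball, model, list(vis))$z
  expect_equal(zmap[centre_lin], z_roi, tolerance = 1e-12)
  expect_true(all(is.na(zmap[!ball$mask])))
  expect_equal(dim(zmap), g$dim)
})

test_that("searchlight on pure noise stays near zero", {
  ws <- small_words(seed = 8)
  g <- grid_spec(c(7, 7, 7))
  mask <- roi_spec("all", array(TRUE, g$dim), g)
  truth <- ground_truth(ws, seed = 8)
  sub <- gen_subject_patterns(truth, ws, "native",
                              list(roi_spec("A", array(TRUE, g$dim), g)),
                              1, seed = 9)
  model <- categorical_rdm(stats::setNames(ws$words$category, ws$words$id))
  zmap <- searchlight_rsa(sub, mask, radius = 4, model = model)
  zs <- zmap[!is.na(zmap)]
  expect_lt(abs(mean(zs)), 2 * stats::sd(zs) / sqrt(length(zs)) + 0.02)
})

test_that("cluster labelling uses 26-neighbour connectivity", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE   # diagonal touch: one cluster
  m[4, 4, 4] <- TRUE                       # isolated: its own cluster
  lab <- label_clusters(m)
  expect_equal(lab[1, 1, 1], lab[2, 2, 2])
  expect_true(lab[4, 4, 4] != lab[1, 1, 1] && lab[4, 4, 4] > 0)
  expect_equal(sum(lab > 0), 3)
})

test_that("group map testing finds planted clusters and ignores null data", {
  set.seed(10)
  dims <- c(8, 8, 8)
  blob <- array(0, dims); blob[3:5, 3:5, 3:5] <- 1.5
  maps_sig <- lapply(1:10, function(i) blob + array(rnorm(512, sd = 0.5), dims))
  ct <- group_map_test(maps_sig, voxel_p = 0.001, n_perm = 200, seed = 1)
  expect_gt(nrow(ct$clusters), 0)
  expect_lt(ct$clusters$p_fwe[1], 0.05)
  peak <- c(ct$clusters$peak_x[1], ct$clusters$peak_y[1], ct$clusters$peak_z[1])
  expect_true(all(peak >= 3 & peak <= 5))
  # identical groups: the two-sample test has no suprathreshold voxels
  ct2 <- group_map_test(maps_sig[1:5], maps_sig[1:5], voxel_p = 0.001,
                        n_perm = 100, seed = 1)
  expect_equal(nrow(ct2$clusters), 0)
  expect_warning(group_map_test(maps_sig, n_perm = 50, seed = 1), "coarse")
  expect_error(group_map_test(maps_sig[1]), "at least 2")
})
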