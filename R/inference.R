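#' Label connected suprathreshold clusters
#'
#' Connected-component labelling of a logical 3D array under 26-neighbour
#' connectivity.
#'
#' @param mask logical 3D array.
#' @return integer array of cluster labels (0 = background).
#' @export
label_clusters <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(labels)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  current <- 0L
  in_set <- array(FALSE, d); in_set[idx] <- TRUE
  visited <- array(FALSE, d)
  for (seed_vox in idx) {
    if (visited[seed_vox]) next
    current <- current + 1L
    queue <- seed_vox
    visited[seed_vox] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      labels[v] <- current
      cv <- arrayInd(v, d)
      cand <- sweep(nb, 2, as.integer(cv), `+`)
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
            cand[, 2] >= 1 & cand[, 2] <= d[2] &
            cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      ci <- cand[, 1] + (cand[, 2] - 1) * d[1] + (cand[, 3] - 1) * d[1] * d[2]
      new <- ci[in_set[ci] & !visited[ci]]
      visited[new] <- TRUE
      queue <- c(queue, new)
    }
  }
  labels
}

#' Group-level map inference with permutation cluster-extent FWE
#'
#' Voxelwise one-sample (when `maps_b` is `NULL`) or two-sample (Welch) t
#' statistics, thresholded at the uncorrected voxel p-value `voxel_p`;
#' cluster-level family-wise error is controlled by permutation of the
#' maximum suprathreshold cluster extent (sign-flipping for the one-sample
#' test, group-label shuffling for the two-sample test), with 26-neighbour
#' connectivity. Degenerate-variance voxels are excluded.
#'
#' @param maps_a list of 3D arrays (or subject-by-voxel matrix plus `dim`
#'   attribute) for group A.
#' @param maps_b optional list for group B.
#' @param voxel_p primary cluster-forming threshold (default 0.001).
#' @param n_perm number of permutations (default 1000; below 100 warns).
#' @param seed integer seed.
#' @param tail `"greater"` tests A's mean (or A minus B) above zero;
#'   `"two.sided"` thresholds on `|t|`.
#' @return list of class `cluster_table`: data frame `clusters` (id, extent,
#'   peak voxel coordinates, peak t, corrected p), the `t_map` array, the
#'   threshold used, and the permutation max-extent distribution.
#' @export
group_map_test <- function(maps_a, maps_b = NULL, voxel_p = 0.001,
                           n_perm = 1000, seed = 1, tail = "greater") {
  if (n_perm < 100) warning("n_perm < 100 gives a coarse FWE estimate", call. = FALSE)
  dimg <- dim(maps_a[[1]])
  A <- t(vapply(maps_a, as.numeric, numeric(prod(dimg))))
  if (nrow(A) < 2) stop("need at least 2 maps per group", call. = FALSE)
  two_sample <- !is.null(maps_b)
  if (two_sample) {
    B <- t(vapply(maps_b, as.numeric, numeric(prod(dimg))))
    if (nrow(B) < 2) stop("need at least 2 maps per group", call. = FALSE)
  }
  valid <- !colAnyNA(A) & (if (two_sample) !colAnyNA(B) else TRUE)

  t_of <- function(Xa, Xb = NULL) {
    n1 <- nrow(Xa)
    m1 <- colMeans(Xa)
    v1 <- (colSums(Xa^2) - n1 * m1^2) / (n1 - 1)
    if (is.null(Xb)) {
      tt <- m1 / sqrt(v1 / n1)
    } else {
      n2 <- nrow(Xb)
      m2 <- colMeans(Xb)
      v2 <- (colSums(Xb^2) - n2 * m2^2) / (n2 - 1)
      tt <- (m1 - m2) / sqrt(v1 / n1 + v2 / n2)
    }
    tt[!is.finite(tt)] <- 0
    tt
  }
  df <- if (two_sample) nrow(A) + nrow(B) - 2 else nrow(A) - 1
  thr <- stats::qt(1 - if (tail == "two.sided") voxel_p / 2 else voxel_p, df)
  above <- function(tt) {
    s <- if (tail == "two.sided") abs(tt) else tt
    s > thr & valid
  }
  max_extent <- function(tt) {
    supra <- above(tt)
    if (!any(supra)) return(0L)
    labs <- label_clusters(array(supra, dimg))
    max(tabulate(labs[labs > 0]))
  }

  t_obs <- t_of(A, if (two_sample) B)
  supra_obs <- above(t_obs)
  lab_obs <- label_clusters(array(supra_obs, dimg))

  perm_max <- integer(n_perm)
  withr::with_seed(seed, {
    if (!two_sample) {
      n <- nrow(A)
      for (p in seq_len(n_perm)) {
        s <- sample(c(-1, 1), n, replace = TRUE)
        perm_max[p] <- max_extent(t_of(s * A))
      }
    } else {
      All <- rbind(A, B)
      n1 <- nrow(A); n <- nrow(All)
      for (p in seq_len(n_perm)) {
        ia <- sample.int(n, n1)
        perm_max[p] <- max_extent(t_of(All[ia, , drop = FALSE],
                                       All[-ia, , drop = FALSE]))
      }
    }
  })

  ids <- setdiff(unique(as.integer(lab_obs)), 0L)
  clusters <- do.call(rbind, lapply(ids, function(id) {
    vox <- which(lab_obs == id)
    peak <- vox[which.max(abs(t_obs[vox]))]
    pc <- arrayInd(peak, dimg)
    data.frame(cluster = id, extent = length(vox),
               peak_x = pc[1], peak_y = pc[2], peak_z = pc[3],
               peak_t = t_obs[peak],
               p_fwe = (1 + sum(perm_max >= length(vox))) / (n_perm + 1))
  }))
  if (is.null(clusters)) {
    clusters <- data.frame(cluster = integer(0), extent = integer(0),
                           peak_x = integer(0), peak_y = integer(0),
                           peak_z = integer(0), peak_t = numeric(0),
                           p_fwe = numeric(0))
  } else {
    clusters <- clusters[order(-clusters$extent), , drop = FALSE]
  }
  structure(list(clusters = clusters, t_map = array(t_obs, dimg),
                 threshold = thr, df = df, perm_max = perm_max),
            class = "cluster_table")
}

colAnyNA <- function(m) colSums(is.na(m)) > 0

#' Write a cluster table as delimited text
#'
#' @param x a `cluster_table`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(x, path) {
  utils::write.table(format(x$clusters, digits = 6), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
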