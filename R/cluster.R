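#' Gap-statistic k-means categorisation of an RDM
#'
#' Embeds the conditions by classical multidimensional scaling of the
#' dissimilarity matrix (`n_dims` coordinates), runs k-means on the
#' embedding for k = 1..`k_max`, and selects the number of clusters by the
#' gap statistic against `n_ref` uniform reference datasets drawn over the
#' bounding box of the embedded points, with the first-SE-max selection
#' rule.
#'
#' @param x an `rdm`.
#' @param k_max maximum number of clusters considered (`2 <= k_max < n`).
#' @param n_ref number of uniform reference datasets for the gap statistic
#'   (at least 10).
#' @param seed integer seed; fixes both the k-means restarts and the
#'   reference draws.
#' @param n_start number of k-means restarts per k (default 50).
#' @param n_dims MDS embedding dimensionality (default 8; capped at the
#'   number of positive eigenvalues).
#' @return a `category_assignment`: list with `labels` (named integer vector
#'   of cluster ids in `1..k`), `k`, and `gap_curve` (data frame of per-k gap
#'   statistic and standard error).
#' @export
cluster_words <- function(x, k_max, n_ref = 50, seed = 1, n_start = 50,
                          n_dims = 8) {
  validate_rdm(x)
  n <- nrow(x)
  if (k_max < 2 || k_max >= n) {
    stop("'k_max' must satisfy 2 <= k_max < n", call. = FALSE)
  }
  if (n_ref < 10) stop("'n_ref' must be at least 10", call. = FALSE)
  feats <- suppressWarnings(
    stats::cmdscale(stats::as.dist(unclass(x)), k = min(n_dims, n - 1)))
  withr::with_seed(seed, {
    gap <- cluster::clusGap(feats, FUNcluster = kmeans_pp,
                            K.max = k_max, B = n_ref,
                            nstart = n_start, iter.max = 50,
                            spaceH0 = "original", verbose = FALSE)
    tab <- gap$Tab
    k_opt <- cluster::maxSE(tab[, "gap"], tab[, "SE.sim"],
                            method = "firstSEmax")
    ids <- kmeans_pp(feats, k_opt, nstart = n_start, iter.max = 50)$cluster
  })
  names(ids) <- rdm_labels(x)
  structure(
    list(labels = ids, k = as.integer(k_opt),
         gap_curve = data.frame(k = seq_len(k_max),
                                gap = tab[, "gap"], se = tab[, "SE.sim"])),
    class = "category_assignment")
}

#' k-means with k-means++ seeding and restarts
#'
#' Standard `stats::kmeans` refinement from k-means++ initial centres
#' (first centre uniform, subsequent centres sampled with probability
#' proportional to squared distance from the nearest chosen centre),
#' repeated `nstart` times keeping the solution with the lowest total
#' within-cluster sum of squares.
#'
#' @param x numeric feature matrix (rows are items).
#' @param centers number of clusters.
#' @param nstart number of restarts.
#' @param iter.max maximum Lloyd/Hartigan-Wong iterations.
#' @return a `stats::kmeans` fit object.
#' @export
kmeans_pp <- function(x, centers, nstart = 50, iter.max = 50) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- centers
  if (k <= 1) {
    return(stats::kmeans(x, centers = matrix(colMeans(x), 1), iter.max = iter.max))
  }
  best <- NULL
  for (r in seq_len(nstart)) {
    ctr_idx <- integer(k)
    ctr_idx[1] <- sample.int(n, 1)
    d2 <- rowSums((x - x[rep(ctr_idx[1], n), , drop = FALSE])^2)
    for (j in 2:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      ctr_idx[j] <- sample.int(n, 1, prob = probs)
      d2 <- pmin(d2, rowSums((x - x[rep(ctr_idx[j], n), , drop = FALSE])^2))
    }
    fit <- suppressWarnings(
      stats::kmeans(x, centers = x[ctr_idx, , drop = FALSE],
                    iter.max = iter.max))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Write a category assignment as two-column delimited text
#'
#' @param assignment a `category_assignment`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path) {
  df <- data.frame(label = names(assignment$labels),
                   cluster = as.integer(assignment$labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two cluster assignments of the same
#' items; 1 means identical partitions up to relabelling.
#'
#' @param a,b integer vectors of cluster ids.
#' @return scalar in `[-1, 1]` (1 for identical partitions).
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length", call. = FALSE)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
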