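#' Neural RDM from a pattern set
#'
#' One minus the Pearson correlation between each pair of condition
#' patterns, computed over voxels.
#'
#' @param patterns condition-by-voxel numeric matrix (rownames are condition
#'   labels) with at least 2 voxels.
#' @return an `rdm`.
#' @export
neural_rdm <- function(patterns) {
  if (ncol(patterns) < 2) stop("need at least 2 voxels", call. = FALSE)
  sds <- apply(patterns, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(patterns)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("undefined correlation: zero-variance pattern for condition ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m <- 1 - stats::cor(t(patterns))
  m[m < 0] <- 0          # clamp negative rounding error
  m <- (m + t(m)) / 2
  diag(m) <- 0
  labs <- rownames(patterns)
  if (is.null(labs)) labs <- paste0("cond", seq_len(nrow(patterns)))
  rdm(m, labels = labs)
}

#' Partial Spearman correlation between RDMs
#'
#' Vectorizes all matrices, rank-transforms each vector (average ranks for
#' ties), and returns the partial Pearson correlation of the ranked target
#' and ranked model given the ranked covariates: both are residualised on
#' the covariates (with intercept) and the residuals correlated. With no
#' covariates this is the plain Spearman correlation.
#'
#' @param target,model `rdm` objects with identical labels.
#' @param covariates list of `rdm` covariates (possibly empty).
#' @return partial correlation scalar.
#' @export
partial_spearman <- function(target, model, covariates = list()) {
  labs <- rdm_labels(target)
  for (m in c(list(model), covariates)) {
    if (!identical(rdm_labels(m), labs)) {
      stop("all RDMs must share labels and order", call. = FALSE)
    }
  }
  rt <- rank(vectorize_rdm(target))
  rm_ <- rank(vectorize_rdm(model))
  if (length(covariates) == 0) {
    return(cor_guarded(rt, rm_))
  }
  Z <- cbind(1, vapply(covariates, function(cv) rank(vectorize_rdm(cv)),
                       numeric(length(rt))))
  qz <- qr(Z)
  cor_guarded(qr.resid(qz, rt), qr.resid(qz, rm_))
}

cor_guarded <- function(x, y) {
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    stop("undefined correlation: residual has zero variance", call. = FALSE)
  }
  stats::cor(x, y)
}

#' ROI-level RSA across subjects
#'
#' Per subject: extract the ROI voxel patterns, build the neural RDM,
#' compute the partial Spearman correlation with the model RDM given the
#' covariate RDMs, and Fisher-z transform (`atanh`) the result. A subject
#' whose computation fails raises an error naming that subject.
#'
#' @param subjects list of `subject_data`.
#' @param roi an `roi_spec` (non-empty on every subject's grid).
#' @param model model `rdm`.
#' @param covariates list of covariate `rdm`s.
#' @return data frame with `subject`, `group`, `z`.
#' @export
roi_rsa <- function(subjects, roi, model, covariates = list()) {
  idx <- roi_indices(roi)
  if (!length(idx)) stop("empty ROI", call. = FALSE)
  rows <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    sid <- if (is.null(s$id)) paste0("sub", i) else s$id
    z <- tryCatch({
      nr <- neural_rdm(s$patterns[, idx, drop = FALSE])
      atanh(partial_spearman(nr, model, covariates))
    }, error = function(e) {
      stop("ROI RSA failed for subject ", sid, ": ", conditionMessage(e),
           call. = FALSE)
    })
    data.frame(subject = sid, group = s$group, z = z)
  })
  do.call(rbind, rows)
}

#' Voxel indices of a searchlight sphere
#'
#' All in-mask voxels whose centre-to-centre Euclidean distance in mm from
#' the centre voxel is at most `radius` (inclusive). Spheres are clipped to
#' the mask, not padded.
#'
#' @param mask an `roi_spec` defining the analysis mask.
#' @param center integer voxel coordinate (1-based, length 3).
#' @param radius sphere radius in mm.
#' @return vector of linear voxel indices.
#' @export
sphere_indices <- function(mask, center, radius) {
  grid <- mask$grid
  if (any(center < 1) || any(center > grid$dim)) {
    stop("'center' must lie inside the grid", call. = FALSE)
  }
  off <- sphere_offsets(radius, grid$voxel_mm)
  pts <- sweep(off, 2, as.integer(center), `+`)
  ok <- pts[, 1] >= 1 & pts[, 1] <= grid$dim[1] &
        pts[, 2] >= 1 & pts[, 2] <= grid$dim[2] &
        pts[, 3] >= 1 & pts[, 3] <= grid$dim[3]
  pts <- pts[ok, , drop = FALSE]
  idx <- pts[, 1] + (pts[, 2] - 1) * grid$dim[1] +
    (pts[, 3] - 1) * grid$dim[1] * grid$dim[2]
  idx[mask$mask[idx]]
}

sphere_offsets <- function(radius, voxel_mm) {
  r <- floor(radius / voxel_mm)
  g <- expand.grid(i = -r[1]:r[1], j = -r[2]:r[2], k = -r[3]:r[3])
  d2 <- (g$i * voxel_mm[1])^2 + (g$j * voxel_mm[2])^2 + (g$k * voxel_mm[3])^2
  as.matrix(g[d2 <= radius^2 + 1e-9, , drop = FALSE])
}

#' Whole-mask searchlight RSA for one subject
#'
#' For every in-mask voxel, extracts the patterns inside the sphere, builds
#' the neural RDM and computes the partial Spearman correlation with the
#' model. The correlation map is Fisher-z transformed and then smoothed with
#' a `smooth_fwhm` Gaussian kernel (within the mask). Spheres with fewer
#' than 2 usable voxels yield `NA`.
#'
#' @param subject a `subject_data`.
#' @param mask an `roi_spec` analysis mask.
#' @param radius sphere radius in mm (default 8).
#' @param model model `rdm`.
#' @param covariates list of covariate `rdm`s.
#' @param smooth_fwhm FWHM in mm for the post-hoc smoothing (default 6; 0
#'   disables).
#' @return 3D array of smoothed Fisher-z values, `NA` outside the mask.
#' @export
searchlight_rsa <- function(subject, mask, radius = 8, model,
                            covariates = list(), smooth_fwhm = 6) {
  grid <- mask$grid
  labs <- rdm_labels(model)
  pat <- subject$patterns[labs, , drop = FALSE]
  n_pair <- length(labs) * (length(labs) - 1) / 2
  rm_ <- rank(vectorize_rdm(model))
  if (length(covariates)) {
    Z <- cbind(1, vapply(covariates, function(cv) rank(vectorize_rdm(cv)),
                         numeric(n_pair)))
    qz <- qr(Z)
    rm_res <- qr.resid(qz, rm_)
  } else {
    qz <- NULL
    rm_res <- rm_ - mean(rm_)
  }
  rm_norm <- sqrt(sum(rm_res^2))
  off <- sphere_offsets(radius, grid$voxel_mm)
  dimg <- grid$dim
  in_mask <- which(mask$mask)
  coords <- arrayInd(in_mask, dimg)
  zmap <- array(NA_real_, dimg)
  for (vi in seq_along(in_mask)) {
    pts <- sweep(off, 2, coords[vi, ], `+`)
    ok <- pts[, 1] >= 1 & pts[, 1] <= dimg[1] &
          pts[, 2] >= 1 & pts[, 2] <= dimg[2] &
          pts[, 3] >= 1 & pts[, 3] <= dimg[3]
    idx <- pts[ok, 1] + (pts[ok, 2] - 1) * dimg[1] +
      (pts[ok, 3] - 1) * dimg[1] * dimg[2]
    idx <- idx[mask$mask[idx]]
    if (length(idx) < 2) next
    x <- pat[, idx, drop = FALSE]
    v <- 1 - stats::cor(t(x))
    if (anyNA(v)) next
    v[v < 0] <- 0
    rt <- rank(v[lower.tri(v)])
    rt_res <- if (is.null(qz)) rt - mean(rt) else qr.resid(qz, rt)
    den <- sqrt(sum(rt_res^2)) * rm_norm
    if (den < 1e-12) next
    zmap[in_mask[vi]] <- atanh(sum(rt_res * rm_res) / den)
  }
  if (smooth_fwhm > 0) {
    usable <- mask$mask & !is.na(zmap)
    zmap <- smooth_masked(zmap, usable, smooth_fwhm, grid$voxel_mm)
  }
  zmap
}
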