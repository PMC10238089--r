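#' Read and write NIfTI volumes
#'
#' Thin wrappers around RNifti preserving data (within float32), voxel size
#' and grid shape across a round trip.
#'
#' @param vol numeric 3D or 4D array.
#' @param path file path (`.nii` / `.nii.gz`).
#' @param voxel_mm voxel edge lengths in mm.
#' @param tr repetition time in s for 4D data (stored in the time pixdim).
#' @return `read_volume` returns a list with `data`, `voxel_mm` and (for 4D)
#'   `tr`; `write_volume` returns `path` invisibly.
#' @export
write_volume <- function(vol, path, voxel_mm = c(2, 2, 2), tr = NULL) {
  pd <- as.numeric(voxel_mm)
  if (length(dim(vol)) == 4) pd <- c(pd, if (is.null(tr)) 1 else tr)
  img <- RNifti::asNifti(structure(vol, pixdim = pd))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  pd <- RNifti::pixdim(img)
  d <- dim(img)
  out <- list(data = array(as.vector(img), dim(img)), voxel_mm = pd[1:3])
  if (length(d) == 4) out$tr <- pd[4]
  out
}

#' Check two volumes share a grid
#'
#' Errors (rather than silently resampling) when shapes or voxel sizes
#' disagree.
#'
#' @param a,b lists as returned by [read_volume()], or arrays.
#' @param tol tolerance on voxel sizes in mm.
#' @return `TRUE`, invisibly.
#' @export
check_same_grid <- function(a, b, tol = 1e-4) {
  da <- if (is.list(a)) dim(a$data)[1:3] else dim(a)[1:3]
  db <- if (is.list(b)) dim(b$data)[1:3] else dim(b)[1:3]
  if (!identical(da, db)) stop("grid shapes differ", call. = FALSE)
  if (is.list(a) && is.list(b) &&
      max(abs(a$voxel_mm - b$voxel_mm)) > tol) {
    stop("voxel sizes differ between volumes", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read / write event tables as tab-separated text
#'
#' Columns: `onset` (s), `duration` (s), `condition`, `run`.
#'
#' @param events event data frame.
#' @param path file path.
#' @return `read_events` returns the data frame; `write_events` the path,
#'   invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path)
  needed <- c("onset", "duration", "condition", "run")
  if (!all(needed %in% names(ev))) {
    stop("event table must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  ev
}

#' Group statistics table from summary moments
#'
#' Consumes a subject-metadata summary table (one row per variable, with each
#' group's printed mean, SD and n) and emits Welch's t, Satterthwaite df,
#' two-tailed p and Hedges' g per variable — the standard cohort
#' demographics comparison.
#'
#' @param summary_table data frame with columns `variable`, `mean_1`, `sd_1`,
#'   `n_1`, `mean_2`, `sd_2`, `n_2` (group 1 vs group 2).
#' @return data frame with `variable`, `t`, `df`, `p`, `hedges_g`.
#' @export
group_stats_table <- function(summary_table) {
  rows <- lapply(seq_len(nrow(summary_table)), function(i) {
    r <- summary_table[i, ]
    st <- welch_t_summary(r$mean_1, r$sd_1, r$n_1, r$mean_2, r$sd_2, r$n_2)
    data.frame(variable = r$variable, t = st$statistic, df = st$df,
               p = st$p, hedges_g = unname(st$effect_size["hedges_g"]))
  })
  do.call(rbind, rows)
}

#' Bundled cohort demographics summary
#'
#' Loads the package's summary table of the two signer cohorts (native,
#' n = 16; delayed, n = 23): group means and SDs of the demographic,
#' language-background and head-motion variables, plus the published t and
#' Hedges' g values for comparison.
#'
#' @return data frame in [group_stats_table()] input format with extra
#'   columns `published_t`, `published_g`.
#' @export
signer_demographics <- function() {
  path <- system.file("extdata", "signer_demographics.tsv", package = "semrsa",
                      mustWork = TRUE)
  utils::read.delim(path)
}
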