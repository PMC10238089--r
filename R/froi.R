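#' ROI-mean betas per word type
#'
#' Averages each word type's betas across its word regressors and across the
#' ROI voxels, yielding one abstract and one concrete mean activation per
#' subject and ROI.
#'
#' @param result a `glm_result`.
#' @param roi an `roi_spec` on the same grid.
#' @param word_types character vector of `"concrete"` / `"abstract"` labels
#'   in `result$word_names` order.
#' @return data frame with `roi`, `beta_abstract`, `beta_concrete`.
#' @export
roi_mean_betas <- function(result, roi, word_types) {
  idx <- roi_indices(roi)
  if (!length(idx)) stop("empty ROI", call. = FALSE)
  cols <- match(idx, result$mask_idx)
  if (anyNA(cols)) stop("ROI extends outside the fitted mask", call. = FALSE)
  wb <- result$betas[result$word_cols, cols, drop = FALSE]
  data.frame(roi = roi$name,
             beta_abstract = mean(wb[word_types == "abstract", , drop = FALSE]),
             beta_concrete = mean(wb[word_types == "concrete", , drop = FALSE]))
}

#' Per-fold summaries for the fROI analysis
#'
#' Reduces one data fold (e.g. the odd or even runs) to the three voxelwise
#' quantities the cross-validated fROI procedure needs: the
#' abstract-greater-than-concrete contrast t map used for voxel selection,
#' and the two word-type mean beta maps used for estimation.
#'
#' @param result a `glm_result` fitted on that fold's runs.
#' @param word_types `"concrete"`/`"abstract"` labels in word order.
#' @return list of class `froi_fold` with vectors `t_con`, `beta_abstract`,
#'   `beta_concrete` over the masked voxels, plus `mask_idx` and `grid`.
#' @export
froi_fold <- function(result, word_types) {
  con <- contrast_map(result, abstractness_weights(word_types))
  wb <- result$betas[result$word_cols, , drop = FALSE]
  structure(list(t_con = con$t,
                 beta_abstract = colMeans(wb[word_types == "abstract", , drop = FALSE]),
                 beta_concrete = colMeans(wb[word_types == "concrete", , drop = FALSE]),
                 mask_idx = result$mask_idx, grid = result$grid),
            class = "froi_fold")
}

#' Cross-validated functional ROI estimate
#'
#' Within the anatomical constraint, selects the `n_top` voxels with the
#' highest abstract-greater-than-concrete t values in fold A and averages
#' the word-type betas of those voxels in fold B; then swaps the folds and
#' averages the two estimates. Ties in the selection are broken by ascending
#' linear voxel index, so the procedure is deterministic. If the constraint
#' holds fewer than `n_top` voxels, all of them are used with a warning.
#'
#' @param fold_a,fold_b `froi_fold` objects from the two run partitions.
#' @param constraint an `roi_spec` anatomical constraint.
#' @param n_top number of selective voxels (default 50; 100 is the common
#'   variant).
#' @return data frame with `roi`, `beta_abstract`, `beta_concrete`, and the
#'   selected voxel indices of both folds as attributes `sel_a`, `sel_b`.
#' @export
froi_crossval <- function(fold_a, fold_b, constraint, n_top = 50) {
  if (!identical(fold_a$mask_idx, fold_b$mask_idx)) {
    stop("folds were fitted on different masks", call. = FALSE)
  }
  idx <- roi_indices(constraint)
  if (length(idx) < n_top) {
    warning("constraint smaller than n_top; using all ", length(idx),
            " voxels", call. = FALSE)
    n_top <- length(idx)
  }
  pick <- function(fold) {
    cols <- match(idx, fold$mask_idx)
    if (anyNA(cols)) stop("constraint outside the fitted mask", call. = FALSE)
    t_vals <- fold$t_con[cols]
    ord <- order(-t_vals, idx)          # ties: lower linear index first
    cols[ord[seq_len(n_top)]]
  }
  est <- function(sel_cols, fold) {
    c(abstract = mean(fold$beta_abstract[sel_cols]),
      concrete = mean(fold$beta_concrete[sel_cols]))
  }
  sel_a <- pick(fold_a)
  sel_b <- pick(fold_b)
  e1 <- est(sel_a, fold_b)   # select on A, estimate on B
  e2 <- est(sel_b, fold_a)   # select on B, estimate on A
  out <- data.frame(roi = constraint$name,
                    beta_abstract = mean(c(e1["abstract"], e2["abstract"])),
                    beta_concrete = mean(c(e1["concrete"], e2["concrete"])))
  attr(out, "sel_a") <- fold_a$mask_idx[sel_a]
  attr(out, "sel_b") <- fold_b$mask_idx[sel_b]
  out
}

#' Mixed two-way ANOVA for the abstractness effect
#'
#' Word type (concrete/abstract) as the within-subject factor and group as
#' the between-subject factor, with unbalanced group sizes allowed; the
#' classical univariate mixed-model decomposition via `stats::aov` with a
#' subject error stratum. The interaction term is fitted last, so its F is
#' invariant to the sums-of-squares ordering.
#'
#' @param records data frame with columns `subject`, `group`,
#'   `beta_abstract`, `beta_concrete` (one row per subject).
#' @return data frame of effects (`group`, `word_type`,
#'   `group:word_type`) with `df1`, `df2`, `F`, `p`.
#' @export
abstractness_anova <- function(records) {
  counts <- table(records$group)
  if (length(counts) != 2 || any(counts < 2)) {
    stop("need two groups with at least 2 subjects each", call. = FALSE)
  }
  long <- data.frame(
    subject = factor(rep(records$subject, 2)),
    group = factor(rep(records$group, 2)),
    word_type = factor(rep(c("abstract", "concrete"), each = nrow(records))),
    beta = c(records$beta_abstract, records$beta_concrete))
  fit <- stats::aov(beta ~ group * word_type + Error(subject/word_type),
                    data = long)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: subject:word_type"]][[1]]
  eff <- function(tab, name) {
    row <- trimws(rownames(tab)) == name
    err <- trimws(rownames(tab)) == "Residuals"
    data.frame(effect = name, df1 = tab[row, "Df"], df2 = tab[err, "Df"],
               F = tab[row, "F value"], p = tab[row, "Pr(>F)"])
  }
  out <- rbind(eff(between, "group"),
               eff(within, "word_type"),
               eff(within, "group:word_type"))
  rownames(out) <- NULL
  out
}
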