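#' Visual silhouette dissimilarity
#'
#' Pairwise one-minus-Pearson correlation distance between flattened binary
#' silhouette images, the low-level visual control model for written-word
#' stimuli.
#'
#' @param images list of same-shaped binary (0/1) matrices, one per stimulus;
#'   grayscale images are binarized at 0.5. Names, if present, become
#'   condition labels.
#' @return an `rdm`.
#' @export
silhouette_rdm <- function(images) {
  if (!is.list(images) || length(images) < 2) {
    stop("'images' must be a list of at least two images", call. = FALSE)
  }
  dims <- dim(images[[1]])
  labs <- names(images)
  if (is.null(labs)) labs <- paste0("cond", seq_along(images))
  flat <- vapply(images, function(im) {
    if (!identical(dim(im), dims)) {
      stop("all silhouette images must share one shape", call. = FALSE)
    }
    as.numeric(im >= 0.5)
  }, numeric(prod(dims)))
  sds <- apply(flat, 2, stats::sd)
  if (any(sds == 0)) {
    stop("undefined correlation: constant silhouette for stimulus ",
         paste(labs[sds == 0], collapse = ", "), call. = FALSE)
  }
  m <- 1 - stats::cor(flat)
  diag(m) <- 0
  rdm(m, labels = labs)
}

#' Sub-syllabic phonological dissimilarity
#'
#' One minus the Dice overlap of the two words' sub-syllabic unit multisets
#' (onset and rhyme tokens, two per syllable):
#' `1 - 2 * |intersection| / (|units_i| + |units_j|)`. Symmetric, in `[0, 1]`,
#' and invariant to unit order within a word.
#'
#' @param phon_units list of character vectors of unit symbols, one per word
#'   (a disyllabic word has 4 units). Names, if present, become labels.
#' @return an `rdm`.
#' @export
phonological_rdm <- function(phon_units) {
  if (!is.list(phon_units) || length(phon_units) < 2) {
    stop("'phon_units' must be a list of at least two unit vectors", call. = FALSE)
  }
  if (any(lengths(phon_units) == 0)) {
    stop("every word needs at least one phonological unit", call. = FALSE)
  }
  labs <- names(phon_units)
  if (is.null(labs)) labs <- paste0("cond", seq_along(phon_units))
  n <- length(phon_units)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    ui <- phon_units[[i]]
    for (j in (i + 1):n) {
      uj <- phon_units[[j]]
      shared <- sum(pmin(table(factor(ui, levels = unique(c(ui, uj)))),
                         table(factor(uj, levels = unique(c(ui, uj))))))
      d <- 1 - 2 * shared / (length(ui) + length(uj))
      m[i, j] <- m[j, i] <- d
    }
  }
  rdm(m, labels = labs)
}

#' Bundle the stimulus model RDMs
#'
#' Convenience container holding the categorical and continuous semantic
#' models together with the two low-level control models, checked for a
#' shared label order.
#'
#' @param semantic_categorical,semantic_continuous,visual,phonological `rdm`
#'   objects with identical labels.
#' @return list of class `stimulus_rdm_bundle`.
#' @export
stimulus_rdm_bundle <- function(semantic_categorical, semantic_continuous,
                                visual, phonological) {
  mats <- list(semantic_categorical = semantic_categorical,
               semantic_continuous = semantic_continuous,
               visual = visual, phonological = phonological)
  labs <- rdm_labels(mats[[1]])
  for (nm in names(mats)) {
    if (!identical(rdm_labels(mats[[nm]]), labs)) {
      stop("label order mismatch in '", nm, "'", call. = FALSE)
    }
  }
  structure(mats, class = "stimulus_rdm_bundle")
}
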