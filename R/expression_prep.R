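#' Prepare an expression matrix from raw RPM values
#'
#' Applies the standard small-RNA preprocessing chain: values are
#' transformed to `log2(RPM + 1)`; per feature, entries farther than
#' `sd_limit` standard deviations from the feature mean (mean and SD
#' computed once, on all non-missing values, in a single pass) are masked
#' missing; features absent (RPM exactly 0) in more than `max_absent`
#' samples are dropped. A provenance report records every masked entry and
#' dropped feature.
#'
#' @param raw_rpm numeric matrix, samples x features, non-negative RPM.
#' @param max_absent maximum tolerated number of absent samples per
#'   feature (default 20).
#' @param sd_limit outlier threshold in SD multiples (default 3).
#' @param feature_coords optional coordinates passed through to the result.
#' @return An [expression_matrix()] whose `present` slot records raw
#'   RPM > 0, with attribute `"provenance"`: list of `masked` (sample,
#'   feature, value) and `dropped` (feature, n_absent) data.frames.
#' @export
prepare_expression <- function(raw_rpm, max_absent = 20, sd_limit = 3,
                               feature_coords = NULL) {
  raw_rpm <- as.matrix(raw_rpm)
  bad <- which(raw_rpm < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("negative RPM at sample ", rownames(raw_rpm)[bad[1, 1]] %||%
           bad[1, 1], ", feature ", colnames(raw_rpm)[bad[1, 2]] %||%
           bad[1, 2])
  }
  sample_ids <- rownames(raw_rpm) %||% sprintf("S%04d", seq_len(nrow(raw_rpm)))
  feature_ids <- colnames(raw_rpm) %||% sprintf("F%04d", seq_len(ncol(raw_rpm)))

  vals <- log2(raw_rpm + 1)
  masked <- vector("list", ncol(vals))
  for (j in seq_len(ncol(vals))) {
    v <- vals[, j]
    m <- mean(v, na.rm = TRUE)
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) next
    out_idx <- which(!is.na(v) & abs(v - m) > sd_limit * s)
    if (length(out_idx) > 0L) {
      masked[[j]] <- data.frame(sample = sample_ids[out_idx],
                                feature = feature_ids[j],
                                value = v[out_idx],
                                stringsAsFactors = FALSE)
      vals[out_idx, j] <- NA
    }
  }
  masked <- do.call(rbind, masked) %||%
    data.frame(sample = character(0), feature = character(0),
               value = numeric(0))

  n_absent <- colSums(raw_rpm == 0, na.rm = TRUE) +
    colSums(is.na(raw_rpm))
  keep <- n_absent <= max_absent
  dropped <- data.frame(feature = feature_ids[!keep],
                        n_absent = unname(n_absent[!keep]),
                        stringsAsFactors = FALSE)

  if (!is.null(feature_coords)) {
    feature_coords <- feature_coords[
      feature_coords$feature_id %in% feature_ids[keep], , drop = FALSE]
  }
  present <- !is.na(raw_rpm) & raw_rpm > 0
  out <- expression_matrix(vals[, keep, drop = FALSE], sample_ids,
                           feature_ids[keep], feature_coords,
                           present[, keep, drop = FALSE])
  attr(out, "provenance") <- list(masked = masked, dropped = dropped)
  out
}

#' Categorize a somatic copy-number segment value
#'
#' Maps a log2 copy-ratio to gain (+1), neutral (0) or loss (-1) with a
#' symmetric threshold.
#'
#' @param segment_value log2 copy-ratio (vectorized).
#' @param threshold gain/loss cutoff on |log2 ratio| (default 0.3).
#' @return Integer categories in `{-1, 0, +1}`.
#' @export
categorize_cnv <- function(segment_value, threshold = 0.3) {
  stopifnot(all(is.finite(segment_value) | is.na(segment_value)))
  out <- integer(length(segment_value))
  out[segment_value > threshold] <- 1L
  out[segment_value < -threshold] <- -1L
  out[is.na(segment_value)] <- NA_integer_
  out
}

#' Categorize promoter methylation from probe beta values
#'
#' Averages the available TSS200/TSS1500 probe betas and converts the mean
#' to an ordinal level 0-3: the category is the number of cutpoints at or
#' below the mean (boundary values fall in the lower category).
#'
#' @param probe_betas numeric vector of beta values in `[0, 1]` (`NA`
#'   allowed).
#' @param cutpoints increasing cutpoints (default quartiles 0.25, 0.5,
#'   0.75).
#' @return Integer category in `{0, 1, 2, 3}`, or `NA` when no probe is
#'   available.
#' @export
categorize_methylation <- function(probe_betas, cutpoints = c(0.25, 0.5, 0.75)) {
  b <- probe_betas[!is.na(probe_betas)]
  if (length(b) == 0L) return(NA_integer_)
  if (any(b < 0 | b > 1)) stop("beta values must lie in [0, 1]")
  m <- mean(b)
  sum(cutpoints < m)
}
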