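#' Augment pressure rows with their four statistical features
#'
#' For each sample the maximum, minimum, mean and standard deviation of the
#' four channel pressures are appended, giving the 8-feature representation
#' `(p1, p2, p3, p4, p_max, p_min, p_mean, p_std)` in that fixed order. The
#' standard deviation uses the population (divide-by-4) form
#' `sqrt(mean((p - p_mean)^2))`, not the n-1 sample form. The first four
#' columns are the inputs, bit-exact.
#'
#' @param data a [posture_dataset()] (label optional).
#' @return Data frame with one row per input row: the eight feature columns
#'   followed by `label` when present.
#' @export
extract_features <- function(data) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) stop("empty dataset", call. = FALSE)
  p <- as.matrix(data[pressure_cols()])
  p_mean <- rowMeans(p)
  out <- data.frame(
    p1 = p[, 1], p2 = p[, 2], p3 = p[, 3], p4 = p[, 4],
    p_max = apply(p, 1, max),
    p_min = apply(p, 1, min),
    p_mean = p_mean,
    p_std = sqrt(rowMeans((p - p_mean)^2))
  )
  if ("label" %in% names(data)) out$label <- data$label
  rownames(out) <- NULL
  out
}

#' Names of the eight model-input features, in canonical order
#' @return Character vector of length 8.
#' @export
feature_cols <- function() {
  c("p1", "p2", "p3", "p4", "p_max", "p_min", "p_mean", "p_std")
}

# Feature matrix (n x 8) from a feature table or raw dataset.
feature_matrix <- function(data) {
  if (!all(feature_cols() %in% names(data))) data <- extract_features(data)
  as.matrix(data[feature_cols()])
}
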