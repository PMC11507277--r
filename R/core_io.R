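#' Posture label vocabulary
#'
#' The four target sleep postures in their fixed code order. Codes 0--3 are
#' assigned in this order and the mapping is stable across runs, which fixes
#' the layout of every confusion matrix and probability column downstream.
#'
#' @return Character vector `c("supine", "side", "fetus", "prone")`.
#' @export
posture_levels <- function() c("supine", "side", "fetus", "prone")

#' Integer code of a posture label
#'
#' @param label character or factor of posture names.
#' @return Integer codes in 0..3 (supine = 0, side = 1, fetus = 2, prone = 3).
#' @export
posture_code <- function(label) {
  f <- parse_posture_labels(label)
  as.integer(f) - 1L
}

# Case-insensitive parse of posture names into the canonical factor.
# `context` is used in error messages (e.g. a row index).
parse_posture_labels <- function(x, context = NULL) {
  lv <- posture_levels()
  xc <- tolower(trimws(as.character(x)))
  bad <- which(!(xc %in% lv))
  if (length(bad) > 0) {
    where <- if (is.null(context)) sprintf("element %d", bad[1]) else context[bad[1]]
    stop(sprintf("unknown posture label '%s' at %s; expected one of %s",
                 as.character(x)[bad[1]], where,
                 paste(lv, collapse = ", ")), call. = FALSE)
  }
  factor(xc, levels = lv)
}

pressure_cols <- function() c("p1", "p2", "p3", "p4")

#' Construct a posture dataset
#'
#' A posture dataset is a data frame with numeric columns `p1..p4` (airbag
#' pressures in kPa: back, waist, buttocks, legs) and an optional `label`
#' factor over [posture_levels()]. Pressures must be finite and non-negative.
#'
#' @param pressures data frame or matrix with columns `p1..p4`.
#' @param label optional labels (character or factor), parsed
#'   case-insensitively against the vocabulary.
#' @param provenance free-text source tag stored as an attribute.
#' @param seed optional integer seed recorded as an attribute.
#' @return A `posture_dataset` (data frame subclass).
#' @export
posture_dataset <- function(pressures, label = NULL, provenance = "unknown",
                            seed = NULL) {
  pressures <- as.data.frame(pressures)
  missing_cols <- setdiff(pressure_cols(), names(pressures))
  if (length(missing_cols) > 0) {
    stop("missing pressure column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- pressures[pressure_cols()]
  for (cl in pressure_cols()) {
    v <- d[[cl]]
    if (!is.numeric(v)) stop("column ", cl, " is not numeric", call. = FALSE)
    if (any(!is.finite(v))) {
      stop(sprintf("non-finite pressure in column %s at row %d",
                   cl, which(!is.finite(v))[1]), call. = FALSE)
    }
    if (any(v < 0)) {
      stop(sprintf("negative pressure in column %s at row %d",
                   cl, which(v < 0)[1]), call. = FALSE)
    }
  }
  if (!is.null(label)) {
    if (length(label) != nrow(d)) {
      stop("label length does not match number of rows", call. = FALSE)
    }
    d$label <- parse_posture_labels(label)
  }
  structure(d,
            provenance = provenance,
            seed = seed,
            class = c("posture_dataset", "data.frame"))
}

#' @export
print.posture_dataset <- function(x, ...) {
  cat(sprintf("<posture_dataset> %d samples (%s)\n", nrow(x),
              attr(x, "provenance") %||% "unknown"))
  if ("label" %in% names(x)) print(table(x$label))
  NextMethod()
}

#' Read a posture dataset from CSV
#'
#' Expects a comma-separated UTF-8 file with a header. The default schema is
#' `p1,p2,p3,p4,label`; `schema` remaps nonstandard column names, e.g.
#' `c(p1 = "back_kpa")` reads pressure channel 1 from column `back_kpa`.
#' Labels are parsed case-insensitively; an unknown label is an error naming
#' the offending row and value. Row order is preserved.
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping canonical names
#'   (`p1..p4`, `label`) to file column names.
#' @return A [posture_dataset()].
#' @export
read_posture_csv <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  canon <- c(pressure_cols(), "label")
  colmap <- stats::setNames(canon, canon)
  if (!is.null(schema)) colmap[names(schema)] <- unname(schema)
  need <- colmap[pressure_cols()]
  absent <- need[!(need %in% names(raw))]
  if (length(absent) > 0) {
    stop("schema error: column '", absent[1], "' (for ",
         names(absent)[1], ") not present in ", path, call. = FALSE)
  }
  cols <- lapply(pressure_cols(), function(cl) {
    v <- raw[[colmap[[cl]]]]
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num) & !is.na(v))) {
      bad <- which(is.na(num) & !is.na(v))[1]
      stop(sprintf("parse error: cell '%s' in column %s at data row %d is not a number",
                   v[bad], colmap[[cl]], bad), call. = FALSE)
    }
    if (anyNA(num)) {
      stop(sprintf("parse error: missing value in column %s at data row %d",
                   colmap[[cl]], which(is.na(num))[1]), call. = FALSE)
    }
    num
  })
  d <- as.data.frame(stats::setNames(cols, pressure_cols()))
  label <- NULL
  if (colmap[["label"]] %in% names(raw)) {
    lab_raw <- raw[[colmap[["label"]]]]
    label <- parse_posture_labels(lab_raw,
                                  context = sprintf("data row %d", seq_along(lab_raw)))
  }
  posture_dataset(d, label = label, provenance = path)
}

#' Write a posture dataset to CSV
#'
#' Comma-separated, header `p1,p2,p3,p4,label`, "." decimal, UTF-8. The
#' written file round-trips through [read_posture_csv()] with pressures
#' preserved well beyond 6 decimals and labels exact.
#'
#' @param data a [posture_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_posture_csv <- function(data, path) {
  out <- as.data.frame(data)[, intersect(c(pressure_cols(), "label"), names(data))]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a dataset into train and test parts
#'
#' Random, seeded partition with an 80/20 default. Stratified splitting (the
#' default) allocates `round(test_fraction * n_c)` test samples per class so
#' class proportions are preserved to within one sample per class. The RNG
#' draws index positions, so re-splitting a shuffled copy with the same seed
#' yields a different membership: the seed controls the randomness, not the
#' data order.
#'
#' @param data a [posture_dataset()] with labels.
#' @param test_fraction fraction of rows assigned to the test part, in (0,1).
#' @param stratified preserve per-class proportions (default `TRUE`).
#' @param seed integer seed.
#' @return `list(train = , test = )` of posture datasets; the two index sets
#'   partition `seq_len(nrow(data))` exactly.
#' @export
split_dataset <- function(data, test_fraction = 0.2, stratified = TRUE,
                          seed = 0L) {
  stopifnot(is.data.frame(data), nrow(data) >= 2)
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  n <- nrow(data)
  test_idx <- with_seed(seed, {
    if (stratified) {
      if (!("label" %in% names(data))) {
        stop("stratified split requires labels", call. = FALSE)
      }
      cls <- as.character(data$label)
      counts <- table(cls)
      if (any(counts < 2)) {
        stop("stratification error: class '", names(counts)[counts < 2][1],
             "' has fewer than 2 members", call. = FALSE)
      }
      idx <- integer(0)
      for (lv in posture_levels()) {
        members <- which(cls == lv)
        if (length(members) == 0) next
        n_test <- round(test_fraction * length(members))
        n_test <- max(1L, min(length(members) - 1L, n_test))
        idx <- c(idx, members[sample.int(length(members), n_test)])
      }
      sort(idx)
    } else {
      n_test <- max(1L, min(n - 1L, round(test_fraction * n)))
      sort(sample.int(n, n_test))
    }
  })
  # subsetting keeps every column (including derived features on a feature
  # table); only the provenance tag is refreshed
  take <- function(idx, part) {
    out <- data[idx, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "provenance") <- paste0(attr(data, "provenance") %||% "unknown",
                                      ":", part)
    attr(out, "seed") <- seed
    out
  }
  list(train = take(-test_idx, "train"), test = take(test_idx, "test"))
}
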