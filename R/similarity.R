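#' Reference class means in feature space
#'
#' Averages feature vectors per timeseries, then per class, yielding one
#' mean feature vector per reference class.
#'
#' @param features A tibble with `F*` columns plus `class` and `series`
#'   columns.
#' @return A tibble of class means (`class` plus `F*` columns), one row per
#'   class, of class `reference_set`.
#' @export
reference_means <- function(features) {
  stopifnot(all(c("class", "series") %in% names(features)))
  if (any(table(features$class) == 0)) stop("empty class")
  out <- features |>
    dplyr::group_by(.data$class, .data$series) |>
    dplyr::summarise(dplyr::across(dplyr::matches("^F\\d+$"), mean),
                     .groups = "drop") |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(dplyr::across(dplyr::matches("^F\\d+$"), mean),
                     .groups = "drop")
  if (nrow(out) == 0) stop("no classes in feature table")
  class(out) <- c("reference_set", class(out))
  out
}

#' Euclidean similarity scores against reference classes
#'
#' Distance of each candidate's mean feature vector to every reference
#' class mean. Low score means high similarity; `rank` is the ascending
#' rank of the candidates within each class (ties broken by candidate id).
#'
#' @param candidates A tibble with a `candidate` id column and `F*` columns
#'   (one mean feature vector per candidate).
#' @param reference A [reference_means()] table.
#' @return A long tibble: `candidate`, `class`, `score`, `rank`.
#' @export
similarity_score <- function(candidates, reference) {
  fc <- as.matrix(dplyr::select(candidates, dplyr::matches("^F\\d+$")))
  fr <- as.matrix(dplyr::select(reference, dplyr::matches("^F\\d+$")))
  if (ncol(fc) != ncol(fr)) stop("feature dimension mismatch: ",
                                 ncol(fc), " vs ", ncol(fr))
  if (!"candidate" %in% names(candidates)) {
    candidates$candidate <- as.character(seq_len(nrow(candidates)))
  }
  out <- purrr::map_dfr(seq_len(nrow(fr)), function(k) {
    d <- sqrt(rowSums(sweep(fc, 2, fr[k, ])^2))
    tibble::tibble(candidate = candidates$candidate,
                   class = reference$class[k], score = d)
  })
  out |>
    dplyr::group_by(.data$class) |>
    dplyr::arrange(.data$score, .data$candidate, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$class, .data$rank)
}

#' Rank candidates for one reference class
#'
#' Stable ascending sort of the score table restricted to `class`; ties are
#' broken by candidate id (lexicographic).
#'
#' @param scores Output of [similarity_score()] (or any tibble with
#'   `candidate`, `class`, `score`).
#' @param class Reference class label to rank against.
#' @return A tibble ordered by ascending score with a `rank` column.
#' @export
rank_simulations <- function(scores, class) {
  sel <- scores[scores$class == class, , drop = FALSE]
  if (nrow(sel) == 0) stop("no candidates scored against class '", class, "'")
  sel <- sel[order(sel$score, sel$candidate), , drop = FALSE]
  sel$rank <- seq_len(nrow(sel))
  sel
}

#' Per-snapshot classification fractions
#'
#' Classifies every mask of a series with the trained classifier and
#' reports the fraction of frames assigned to each class.
#'
#' @param classifier A `shape_classifier`.
#' @param masks List of normalized masks, a `normalized_series`, or a
#'   feature tibble already containing a `predicted` column.
#' @return A tibble `class`, `n`, `fraction` covering all classifier
#'   classes (zero rows included); fractions sum to 1.
#' @export
per_snapshot_classification <- function(classifier, masks) {
  pred <- if (is.data.frame(masks) && "predicted" %in% names(masks)) {
    factor(masks$predicted, levels = classifier$classes)
  } else {
    extract_features(classifier, masks)$predicted
  }
  if (length(pred) == 0) stop("empty series")
  tb <- table(pred)
  tibble::tibble(class = names(tb), n = as.integer(tb),
                 fraction = as.integer(tb) / length(pred))
}

#' Mean feature vector of a simulation's mask series
#'
#' Time-averages the feature vectors of a normalized series after
#' discarding a burn-in fraction of the frames.
#'
#' @param classifier A `shape_classifier`.
#' @param norm A `normalized_series` (or list of masks).
#' @param burn_in Fraction of initial frames discarded (default 0.1).
#' @return A one-row tibble of mean `F*` values.
#' @export
mean_feature_vector <- function(classifier, norm, burn_in = 0.1) {
  ft <- extract_features(classifier, norm)
  n <- nrow(ft)
  keep <- ft[seq(floor(burn_in * n) + 1L, n), , drop = FALSE]
  dplyr::summarise(keep, dplyr::across(dplyr::matches("^F\\d+$"), mean))
}
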