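#' Define a questionnaire scale
#'
#' Bundles the information needed to score an ordinal questionnaire scale:
#' which item columns belong to it, which are reverse-keyed, the response
#' range, the missingness tolerance, and whether the summed score should be
#' square-root transformed before standardization (used for right-skewed
#' scales).
#'
#' @param items Character vector of item column names (ordered).
#' @param reverse_coded Logical, recycled to the item count: which items are
#'   reverse-keyed.
#' @param item_range Length-2 integer range of valid responses
#'   (min, max), used for reverse-coding.
#' @param sqrt_transform Should [transform_scores()] apply a square root?
#' @param max_missing_fraction Children with a missing-item fraction at or
#'   above this receive a missing score (default 0.5: exactly half missing
#'   is already too much).
#' @return A `scale_definition` object. `scale_length` equals the number of
#'   items.
#' @export
scale_definition <- function(items, reverse_coded = FALSE,
                             item_range = c(0L, 3L),
                             sqrt_transform = FALSE,
                             max_missing_fraction = 0.5) {
  items <- as.character(items)
  reverse_coded <- rep_len(as.logical(reverse_coded), length(items))
  stopifnot(length(item_range) == 2, item_range[1] < item_range[2],
            max_missing_fraction > 0, max_missing_fraction <= 1)
  structure(list(items = items, reverse_coded = reverse_coded,
                 item_range = as.numeric(item_range),
                 scale_length = length(items),
                 sqrt_transform = isTRUE(sqrt_transform),
                 max_missing_fraction = max_missing_fraction),
            class = "scale_definition")
}

#' Score a questionnaire scale with missingness-tolerant sum scoring
#'
#' Reverse-keyed items are inverted first (`min + max - value`). A child's
#' score is the mean of their available items multiplied by the scale
#' length — a sum score prorated for item missingness. Children whose
#' missing-item fraction is at or above `def$max_missing_fraction` receive
#' `NA`.
#'
#' @param items A tibble with `child_id` and the item columns named in
#'   `def$items` (e.g. from [simulate_item_responses()]).
#' @param def A [scale_definition()].
#' @return A tibble with `child_id`, `score`, `missing_fraction`.
#' @export
#' @examples
#' it <- tibble::tibble(child_id = "c1", item_1 = 1, item_2 = 0,
#'                      item_3 = 1, item_4 = NA, item_5 = NA, item_6 = 1)
#' def <- scale_definition(paste0("item_", 1:6), item_range = c(0, 1))
#' score_scale(it, def)$score  # mean(1,0,1,1) * 6 = 4.5
score_scale <- function(items, def) {
  stopifnot(inherits(def, "scale_definition"))
  missing_cols <- setdiff(def$items, names(items))
  if (length(missing_cols))
    abort(paste0("item columns not found: ",
                 paste(missing_cols, collapse = ", ")))
  m <- as.matrix(items[, def$items, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(def$reverse_coded)) {
    rc <- which(def$reverse_coded)
    m[, rc] <- def$item_range[1] + def$item_range[2] - m[, rc]
  }
  miss_frac <- rowMeans(is.na(m))
  score <- rowMeans(m, na.rm = TRUE) * def$scale_length
  score[miss_frac >= def$max_missing_fraction] <- NA_real_
  score[is.nan(score)] <- NA_real_
  tibble(child_id = items$child_id, score = score,
         missing_fraction = miss_frac)
}

#' Transform and standardize scale scores
#'
#' Optionally applies a square-root transformation (for right-skewed
#' scales), then z-standardizes over the non-missing children so the
#' analysed measure has mean 0 and standard deviation 1.
#'
#' @param scores Numeric vector of scale scores (NA allowed), or a tibble
#'   from [score_scale()] (its `score` column is used and returned
#'   augmented).
#' @param sqrt_transform Apply `sqrt()` first? Defaults to the scale
#'   definition when one is given via `def`.
#' @param def Optional [scale_definition()] supplying `sqrt_transform`.
#' @return Same shape as the input: a numeric vector, or the input tibble
#'   with a `score_std` column.
#' @export
transform_scores <- function(scores, sqrt_transform = NULL, def = NULL) {
  tab <- NULL
  if (is.data.frame(scores)) {
    tab <- scores
    scores <- scores$score
  }
  if (is.null(sqrt_transform))
    sqrt_transform <- if (!is.null(def)) def$sqrt_transform else FALSE
  x <- as.numeric(scores)
  if (sqrt_transform) {
    if (any(x < 0, na.rm = TRUE))
      abort("negative scores cannot be square-root transformed.")
    x <- sqrt(x)
  }
  ok <- !is.na(x)
  if (sum(ok) < 2) abort("need at least two non-missing scores.")
  s <- sd(x[ok])
  if (s == 0) abort("scores are constant; cannot standardize.")
  z <- (x - mean(x[ok])) / s
  if (is.null(tab)) z else dplyr::mutate(tab, score_std = z)
}
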