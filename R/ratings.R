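RATING_LEVELS <- 1:4
RATING_PHASES <- c("baseline", "after_beautiful", "after_least")

#' Load and validate a beauty-rating table
#'
#' Ratings live on an integer 1-4 scale where 1 = most beautiful and
#' 4 = least beautiful (school-grade convention).  The table is long format:
#' one row per participant x image x phase, with phase one of `"baseline"`,
#' `"after_beautiful"`, `"after_least"`.
#'
#' Validation rules: rows with out-of-range or non-integer ratings are
#' rejected with a diagnostic warning; duplicated
#' (participant, image, phase) triples are a hard error; the baseline phase,
#' if present, must be complete (every participant rated every image).
#'
#' @param x CSV file path or a data frame with columns `participant_id`,
#'   `image_id`, `phase`, `rating`.
#' @return A validated tibble with those four columns (`rating` integer).
#' @export
load_ratings <- function(x) {
  df <- if (is.character(x)) {
    readr::read_csv(x, show_col_types = FALSE)
  } else {
    tibble::as_tibble(x)
  }
  needed <- c("participant_id", "image_id", "phase", "rating")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("ratings table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  df <- dplyr::mutate(
    df,
    participant_id = as.character(.data$participant_id),
    image_id = as.character(.data$image_id),
    phase = as.character(.data$phase)
  )
  bad_phase <- setdiff(unique(df$phase), RATING_PHASES)
  if (length(bad_phase) > 0) {
    abort(paste0("unknown phase label(s): ", paste(bad_phase, collapse = ", ")))
  }
  ok <- !is.na(df$rating) & df$rating %in% RATING_LEVELS
  if (any(!ok)) {
    warn(sprintf(
      "rejected %d row(s) with ratings outside the integer 1-4 scale", sum(!ok)
    ))
    df <- df[ok, , drop = FALSE]
  }
  df$rating <- as.integer(df$rating)
  dup <- duplicated(df[, c("participant_id", "image_id", "phase")])
  if (any(dup)) {
    abort(sprintf(
      "%d duplicated (participant, image, phase) row(s); ratings must be unique", sum(dup)
    ))
  }
  base <- df[df$phase == "baseline", , drop = FALSE]
  if (nrow(base) > 0) {
    p <- dplyr::n_distinct(base$participant_id)
    i <- dplyr::n_distinct(base$image_id)
    if (nrow(base) != p * i) {
      abort(sprintf(
        "baseline phase incomplete: %d rows for %d participants x %d images",
        nrow(base), p, i
      ))
    }
  }
  df[, needed]
}

#' Ratings as a participant-by-image matrix
#'
#' @param ratings a validated ratings tibble (see [load_ratings()]).
#' @param phase which phase to extract (default `"baseline"`).
#' @return Numeric matrix, rows = participants (sorted ids), columns =
#'   images (sorted ids).
#' @export
ratings_matrix <- function(ratings, phase = "baseline") {
  df <- ratings[ratings$phase == phase, , drop = FALSE]
  if (nrow(df) == 0) abort(sprintf("no rows for phase '%s'", phase))
  wide <- tidyr::pivot_wider(
    df[, c("participant_id", "image_id", "rating")],
    names_from = "image_id", values_from = "rating"
  )
  wide <- dplyr::arrange(wide, .data$participant_id)
  m <- as.matrix(wide[, sort(setdiff(names(wide), "participant_id")), drop = FALSE])
  rownames(m) <- wide$participant_id
  m
}
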