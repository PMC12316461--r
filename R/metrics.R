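#' Tube-test relative dominance
#'
#' An animal's relative dominance is its proportion of wins across all its
#' contests in the selected testing days of the round-robin tube test.
#' Within a closed round-robin cohort every contest produces exactly one win
#' and one loss, so scores average 0.5.
#'
#' @param contests Data frame with columns `day`, `subject_a`, `subject_b`,
#'   `winner`. `winner` may be a subject id or `"a"`/`"b"`.
#' @param days_used Optional vector of days to include (e.g. `3:4`); default
#'   all days.
#'
#' @return Tibble `subject`, `n_contests`, `n_wins`, `dominance`, one row per
#'   subject with at least one contest. Subjects with no contests in
#'   `days_used` are absent (and named in attribute `"excluded"`).
#' @export
#' @examples
#' contests <- gen_tube_contests(c(a = 2, b = 0), days = 3, seed = 1)
#' relative_dominance(contests)
relative_dominance <- function(contests, days_used = NULL) {
  stopifnot(is.data.frame(contests))
  need <- c("day", "subject_a", "subject_b", "winner")
  miss <- setdiff(need, names(contests))
  if (length(miss)) stop_sociodyn("missing columns: ", paste(miss, collapse = ", "))
  if (any(contests$subject_a == contests$subject_b)) {
    stop_sociodyn("self-contests are not allowed")
  }
  all_subjects <- unique(c(contests$subject_a, contests$subject_b))
  if (!is.null(days_used)) {
    contests <- contests[contests$day %in% days_used, , drop = FALSE]
  }
  winner_id <- ifelse(contests$winner == "a", contests$subject_a,
                      ifelse(contests$winner == "b", contests$subject_b,
                             contests$winner))
  if (!all(winner_id == contests$subject_a | winner_id == contests$subject_b)) {
    stop_sociodyn("winner must be 'a', 'b', or one of the two subject ids")
  }
  long <- tibble::tibble(
    subject = c(contests$subject_a, contests$subject_b),
    won = c(winner_id == contests$subject_a, winner_id == contests$subject_b)
  )
  out <- long |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(n_contests = dplyr::n(), n_wins = sum(.data$won),
                     .groups = "drop") |>
    dplyr::mutate(dominance = .data$n_wins / .data$n_contests)
  excluded <- setdiff(all_subjects, out$subject)
  if (length(excluded)) {
    warning("subject(s) with no contests in days_used excluded: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  }
  attr(out, "excluded") <- excluded
  out
}

#' Social:object preference ratio
#'
#' Time spent in the social side of the three-chamber arena divided by time
#' spent in the object side. Values above 1 indicate social preference. Rows
#' with zero object time get `NA` (undefined ratio) with a warning.
#'
#' @param zones Data frame with columns `social_zone_s` and `object_zone_s`
#'   (other columns pass through).
#' @param log_ratio Also add a `log_social_object_ratio` column (natural
#'   log), symmetric about 0 (default FALSE).
#'
#' @return The input tibble with a `social_object_ratio` column appended.
#' @export
social_object_ratio <- function(zones, log_ratio = FALSE) {
  stopifnot(is.data.frame(zones))
  miss <- setdiff(c("social_zone_s", "object_zone_s"), names(zones))
  if (length(miss)) stop_sociodyn("missing columns: ", paste(miss, collapse = ", "))
  if (any(zones$social_zone_s < 0 | zones$object_zone_s < 0, na.rm = TRUE)) {
    stop_sociodyn("zone times must be nonnegative")
  }
  zero <- zones$object_zone_s == 0
  if (any(zero, na.rm = TRUE)) {
    warning(sum(zero, na.rm = TRUE),
            " session(s) with zero object time: ratio undefined (NA)",
            call. = FALSE)
  }
  out <- tibble::as_tibble(zones) |>
    dplyr::mutate(social_object_ratio = ifelse(.data$object_zone_s > 0,
                                               .data$social_zone_s /
                                                 .data$object_zone_s,
                                               NA_real_))
  if (log_ratio) {
    out <- dplyr::mutate(out,
                         log_social_object_ratio = log(.data$social_object_ratio))
  }
  out
}

#' Stimulation ON minus OFF difference score
#'
#' @param on,off Numeric vectors of a metric measured in the stimulated and
#'   unstimulated sessions.
#' @return `on - off`, antisymmetric under swapping arguments.
#' @export
on_off_difference <- function(on, off) {
  stopifnot(length(on) == length(off))
  on - off
}

#' Pearson correlation matrix of baseline behavioral measures
#'
#' Symmetric matrix of pairwise Pearson correlation coefficients across
#' subjects, using pairwise-complete observations. Constant columns are
#' flagged and their rows/columns set to `NA` (except the unit diagonal).
#'
#' @param measures Data frame of numeric measures, one row per subject;
#'   non-numeric columns (ids) are dropped.
#'
#' @return Correlation matrix with attribute `"flagged"` naming any constant
#'   columns.
#' @export
baseline_correlation_matrix <- function(measures) {
  stopifnot(is.data.frame(measures))
  num <- measures[vapply(measures, is.numeric, logical(1))]
  if (ncol(num) < 2L) stop_sociodyn("need at least 2 numeric measures")
  if (nrow(num) < 3L) stop_sociodyn("need at least 3 subjects")
  const <- vapply(num, function(x) sd(x, na.rm = TRUE) == 0, logical(1))
  flagged <- names(num)[const]
  if (length(flagged)) {
    warning("constant measure(s), correlations undefined: ",
            paste(flagged, collapse = ", "), call. = FALSE)
  }
  m <- suppressWarnings(stats::cor(as.matrix(num), use = "pairwise.complete.obs",
                                   method = "pearson"))
  m[flagged, ] <- NA_real_
  m[, flagged] <- NA_real_
  diag(m) <- 1
  attr(m, "flagged") <- flagged
  m
}
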