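#' Pose track
#'
#' Per-frame keypoint coordinates (cm) for a tracked mouse, together with the
#' camera frame rate, arena geometry, and cup positions. Only the nose, head
#' and neck keypoints are required by the interaction-detection rule; any
#' other keypoints are carried along untouched.
#'
#' @param data Data frame in long form (`frame`, `keypoint`, `x_cm`, `y_cm`)
#'   or wide form (`frame`, `nose_x`, `nose_y`, `head_x`, `head_y`, `neck_x`,
#'   `neck_y`, ...). Missing keypoints are `NA`.
#' @param frame_rate Frames per second (> 0).
#' @param arena Optional named numeric `c(width, height)` in cm.
#' @param cups Data frame with columns `stimulus` (`"social"`/`"object"`),
#'   `x`, `y` (center, cm), `diameter` (cm).
#'
#' @return An object of class `pose_track`.
#' @export
pose_track <- function(data, frame_rate, arena = NULL, cups = NULL) {
  stopifnot(is.data.frame(data), frame_rate > 0)
  if ("keypoint" %in% names(data)) {
    data <- data |>
      tidyr::pivot_wider(id_cols = "frame", names_from = "keypoint",
                         values_from = c("x_cm", "y_cm"),
                         names_glue = "{keypoint}_{sub('_cm', '', .value)}") |>
      dplyr::arrange(.data$frame)
  }
  need <- c("nose_x", "nose_y", "head_x", "head_y")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    stop_sociodyn("pose data lacks required keypoint columns: ",
                  paste(miss, collapse = ", "))
  }
  for (col in c("neck_x", "neck_y")) {
    if (!col %in% names(data)) data[[col]] <- NA_real_
  }
  if (!is.null(cups)) {
    stopifnot(all(c("stimulus", "x", "y", "diameter") %in% names(cups)))
  }
  structure(
    list(data = tibble::as_tibble(data), frame_rate = frame_rate,
         arena = arena, cups = if (is.null(cups)) NULL else tibble::as_tibble(cups)),
    class = "pose_track"
  )
}

#' @export
print.pose_track <- function(x, ...) {
  cat("<pose_track> ", nrow(x$data), " frames @ ", x$frame_rate, " fps",
      if (!is.null(x$cups)) paste0(", ", nrow(x$cups), " cups"), "\n", sep = "")
  invisible(x)
}

#' Per-frame head-direction unit vectors
#'
#' The heading is the unit vector from the neck keypoint toward the head
#' keypoint; when the neck is missing the head-to-nose vector is used
#' instead. Frames where neither pair is available, or where the pair is
#' coincident (zero-length direction), are flagged undefined.
#'
#' @param track A [pose_track()].
#'
#' @return Tibble with columns `frame`, `dx`, `dy` (unit vector, `NA` when
#'   undefined) and `defined`.
#' @export
head_direction <- function(track) {
  stopifnot(inherits(track, "pose_track"))
  d <- track$data
  dx <- d$head_x - d$neck_x
  dy <- d$head_y - d$neck_y
  # fallback: head -> nose when the neck keypoint is absent
  use_fb <- is.na(dx) | is.na(dy)
  dx[use_fb] <- d$nose_x[use_fb] - d$head_x[use_fb]
  dy[use_fb] <- d$nose_y[use_fb] - d$head_y[use_fb]
  len <- sqrt(dx^2 + dy^2)
  defined <- !is.na(len) & len > 0
  dx <- ifelse(defined, dx / len, NA_real_)
  dy <- ifelse(defined, dy / len, NA_real_)
  tibble::tibble(frame = d$frame, dx = dx, dy = dy, defined = defined)
}

#' Frame-level detection of cup interaction
#'
#' A frame counts as an interaction with a cup when (a) the nose lies within
#' `distance_factor` times the cup diameter of the cup (center by default),
#' and (b) the cup center lies within a cone of full apex angle
#' `2 * cone_half_angle_deg` in front of the head, measured around the
#' head-direction vector. Frames with a missing nose or undefined heading are
#' negative; their count is reported in the `n_undefined` attribute.
#'
#' @param track A [pose_track()].
#' @param cup One-row data frame (or list) with `x`, `y`, `diameter`.
#' @param distance_factor Multiple of the cup diameter defining the proximity
#'   threshold (default 1.3).
#' @param cone_half_angle_deg Half the apex angle of the head cone (default
#'   45, i.e. a 90-degree cone).
#' @param distance_to `"center"` (default) measures nose to cup center;
#'   `"edge"` subtracts the cup radius first.
#'
#' @return Logical vector, one element per frame.
#' @export
detect_interaction <- function(track, cup, distance_factor = 1.3,
                               cone_half_angle_deg = 45,
                               distance_to = c("center", "edge")) {
  stopifnot(inherits(track, "pose_track"))
  distance_to <- match.arg(distance_to)
  cup <- as.list(cup)
  d <- track$data
  hd <- head_direction(track)
  dist <- sqrt((d$nose_x - cup$x)^2 + (d$nose_y - cup$y)^2)
  if (distance_to == "edge") dist <- dist - cup$diameter / 2
  near <- !is.na(dist) & dist <= distance_factor * cup$diameter
  # angle between heading and head -> cup-center vector
  cx <- cup$x - d$head_x
  cy <- cup$y - d$head_y
  clen <- sqrt(cx^2 + cy^2)
  cosang <- (hd$dx * cx + hd$dy * cy) / clen
  in_cone <- hd$defined & !is.na(cosang) &
    cosang >= cos(cone_half_angle_deg * pi / 180)
  # coincident head and cup center: direction undefined, treat as in front
  in_cone[hd$defined & !is.na(clen) & clen == 0] <- TRUE
  out <- near & in_cone
  out[is.na(out)] <- FALSE
  attr(out, "n_undefined") <- sum(!hd$defined | is.na(dist))
  out
}

#' Binary interaction vector on a fixed time base
#'
#' @param values Binary (0/1 or logical) vector, one element per bin.
#' @param bin_width Bin width in seconds (default 0.040).
#' @param stimulus `"social"`, `"object"`, or `NA`.
#' @param origin Session time of the start of bin 1 (s).
#'
#' @return An object of class `interaction_vector`.
#' @export
interaction_vector <- function(values, bin_width = 0.040,
                               stimulus = NA_character_, origin = 0) {
  values <- as.integer(as.logical(values))
  if (anyNA(values)) stop_sociodyn("interaction values must be binary, not NA")
  stopifnot(bin_width > 0)
  structure(list(values = values, bin_width = bin_width, stimulus = stimulus,
                 origin = origin),
            class = "interaction_vector")
}

#' @export
print.interaction_vector <- function(x, ...) {
  cat("<interaction_vector> ", length(x$values), " bins x ",
      x$bin_width * 1000, " ms (", sum(x$values), " positive)",
      if (!is.na(x$stimulus)) paste0(", stimulus: ", x$stimulus), "\n", sep = "")
  invisible(x)
}

#' @export
length.interaction_vector <- function(x) length(x$values)

#' Aggregate a frame-level detection vector into fixed-width time bins
#'
#' Frames are mapped onto every bin they overlap in time; under the default
#' `"any"` rule a bin is positive when any overlapping frame is positive,
#' under `"majority"` when more than half are. The output has
#' `ceiling(duration / bin_width)` bins.
#'
#' @param framewise Logical/binary vector, one element per frame.
#' @param frame_rate Frames per second.
#' @param bin_width Bin width in seconds (default 0.040).
#' @param rule `"any"` (default) or `"majority"`.
#' @param stimulus Optional stimulus label carried into the result.
#'
#' @return An [interaction_vector()].
#' @export
binarize_bins <- function(framewise, frame_rate, bin_width = 0.040,
                          rule = c("any", "majority"), stimulus = NA_character_) {
  rule <- match.arg(rule)
  stopifnot(frame_rate > 0, bin_width > 0)
  framewise <- as.logical(framewise)
  framewise[is.na(framewise)] <- FALSE
  n_frames <- length(framewise)
  duration <- n_frames / frame_rate
  n_bins <- ceiling(duration / bin_width - 1e-9)
  eps <- 1e-9
  i <- seq_len(n_frames)
  first_bin <- pmin(floor((i - 1) / frame_rate / bin_width + eps) + 1L, n_bins)
  last_bin <- pmin(ceiling(i / frame_rate / bin_width - eps), n_bins)
  pos <- integer(n_bins)
  tot <- integer(n_bins)
  for (f in i) {
    b <- first_bin[f]:last_bin[f]
    tot[b] <- tot[b] + 1L
    if (framewise[f]) pos[b] <- pos[b] + 1L
  }
  vals <- if (rule == "any") pos > 0L else pos * 2L > tot
  interaction_vector(vals, bin_width = bin_width, stimulus = stimulus)
}

#' Extract discrete interaction trials from a binary vector
#'
#' Candidate interactions are maximal runs of positive bins; runs separated
#' by a pause shorter than `merge_gap` seconds are merged (rule c), merged
#' candidates shorter than `min_duration` seconds are discarded (rule a), and
#' a candidate beginning less than `refractory` seconds after the end of the
#' previous accepted interaction is discarded (rule b). Rules are applied in
#' that order.
#'
#' @param vec An [interaction_vector()].
#' @param min_duration Minimum trial duration, s (default 1).
#' @param merge_gap Pauses shorter than this are bridged, s (default 1.5).
#' @param refractory Minimum time since the previous accepted interaction's
#'   end, s (default 5).
#'
#' @return Tibble with columns `stimulus`, `onset_s`, `offset_s`, in time
#'   order.
#' @export
extract_trials <- function(vec, min_duration = 1, merge_gap = 1.5,
                           refractory = 5) {
  stopifnot(inherits(vec, "interaction_vector"))
  bw <- vec$bin_width
  runs <- true_runs(vec$values == 1L)
  empty <- tibble::tibble(stimulus = character(), onset_s = numeric(),
                          offset_s = numeric())
  if (nrow(runs) == 0L) return(empty)
  onset <- vec$origin + (runs$start - 1L) * bw
  offset <- vec$origin + runs$end * bw
  # (c) merge candidates separated by a pause < merge_gap
  m_on <- onset[1L]
  m_off <- offset[1L]
  merged_on <- numeric(0)
  merged_off <- numeric(0)
  if (nrow(runs) > 1L) {
    for (r in 2:nrow(runs)) {
      if (onset[r] - m_off < merge_gap - 1e-9) {
        m_off <- offset[r]
      } else {
        merged_on <- c(merged_on, m_on)
        merged_off <- c(merged_off, m_off)
        m_on <- onset[r]
        m_off <- offset[r]
      }
    }
  }
  merged_on <- c(merged_on, m_on)
  merged_off <- c(merged_off, m_off)
  # (a) minimum duration
  keep <- merged_off - merged_on >= min_duration - 1e-9
  merged_on <- merged_on[keep]
  merged_off <- merged_off[keep]
  # (b) refractory relative to the previous accepted interaction's end
  acc_on <- numeric(0)
  acc_off <- numeric(0)
  last_off <- -Inf
  for (r in seq_along(merged_on)) {
    if (merged_on[r] - last_off >= refractory - 1e-9 || !length(acc_on)) {
      acc_on <- c(acc_on, merged_on[r])
      acc_off <- c(acc_off, merged_off[r])
      last_off <- merged_off[r]
    }
  }
  tibble::tibble(stimulus = rep(vec$stimulus %||% NA_character_, length(acc_on)),
                 onset_s = acc_on, offset_s = acc_off)
}
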