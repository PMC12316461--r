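#' Z-score a calcium trace over the whole session
#'
#' @param values Raw fluorescence/activity values, one per frame.
#' @param frame_rate Acquisition rate, Hz (default 20).
#' @param cell Optional cell identifier.
#'
#' @return Object of class `z_trace` with unit-variance, zero-mean `values`.
#' @export
zscore_trace <- function(values, frame_rate = 20, cell = NA_character_) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop_sociodyn("trace contains missing or non-finite values")
  }
  s <- sd(values)
  if (s == 0) stop_sociodyn("constant trace: z-score undefined (SD = 0)")
  structure(list(values = (values - mean(values)) / s,
                 frame_rate = frame_rate, cell = cell),
            class = "z_trace")
}

#' @export
print.z_trace <- function(x, ...) {
  cat("<z_trace> ", length(x$values), " frames @ ", x$frame_rate, " fps\n",
      sep = "")
  invisible(x)
}

#' Resample a z-scored trace onto the behavior time base
#'
#' Calcium frames (e.g. 50 ms at 20 fps) are mapped onto the 40-ms behavior
#' bins by nearest-frame assignment (default) or linear interpolation of the
#' trace at bin centers.
#'
#' @param z A [zscore_trace()] result (or numeric vector with `frame_rate`).
#' @param n_bins Number of behavior bins to produce.
#' @param bin_width Behavior bin width, s (default 0.040).
#' @param frame_rate Required when `z` is a bare numeric vector.
#' @param method `"nearest"` (default) or `"linear"`.
#'
#' @return Numeric vector of length `n_bins`.
#' @export
align_to_bins <- function(z, n_bins, bin_width = 0.040, frame_rate = NULL,
                          method = c("nearest", "linear")) {
  method <- match.arg(method)
  if (inherits(z, "z_trace")) {
    frame_rate <- z$frame_rate
    z <- z$values
  }
  if (is.null(frame_rate)) stop_sociodyn("frame_rate required")
  n_frames <- length(z)
  frame_times <- (seq_len(n_frames) - 0.5) / frame_rate
  bin_times <- (seq_len(n_bins) - 0.5) * bin_width
  if (method == "nearest") {
    idx <- pmin(pmax(round(bin_times * frame_rate + 0.5), 1L), n_frames)
    z[idx]
  } else {
    stats::approx(frame_times, z, xout = bin_times, rule = 2)$y
  }
}

# Shared auROC machinery. thresholds are fixed per trace; each time bin is
# assigned the index of the highest threshold it reaches (z >= t), so a
# permutation only needs a re-tabulation over the shifted positive bins.
auroc_from_counts <- function(pos_counts, neg_counts, n_pos, n_neg) {
  tpr <- rev(cumsum(rev(pos_counts))) / n_pos
  fpr <- rev(cumsum(rev(neg_counts))) / n_neg
  x <- c(0, rev(fpr), 1)
  y <- c(0, rev(tpr), 1)
  trapz(x, y)
}

#' Threshold-sweep ROC curve of a neural trace against a behavior vector
#'
#' Binary activity vectors are generated at `n_thresholds` (default 100)
#' linearly spaced thresholds spanning the minimum to maximum z-score of the
#' trace (activity = z at or above threshold). Each threshold yields a true
#' positive rate (fraction of behavior-positive bins active) and a false
#' positive rate (fraction of behavior-negative bins active); the area under
#' the resulting ROC curve (trapezoidal, with (0,0) and (1,1) appended)
#' measures how strongly the neuron is modulated by the behavior. 0.5 means
#' no modulation; values toward 1 (0) mean elevated (suppressed) activity
#' during the behavior.
#'
#' @param z Numeric z-scored activity, one value per behavior bin (see
#'   [align_to_bins()]).
#' @param behavior An [interaction_vector()] or binary vector of the same
#'   length, with at least one positive and one negative bin.
#' @param n_thresholds Number of threshold steps (default 100).
#'
#' @return Object of class `roc_curve`: `thresholds`, `fpr`, `tpr`, `auroc`.
#' @export
roc_auroc <- function(z, behavior, n_thresholds = 100) {
  if (inherits(behavior, "interaction_vector")) behavior <- behavior$values
  behavior <- as.integer(as.logical(behavior))
  z <- as.numeric(z)
  if (length(z) != length(behavior)) {
    stop_sociodyn("z trace (", length(z), ") and behavior vector (",
                  length(behavior), ") differ in length")
  }
  n_pos <- sum(behavior == 1L)
  n_neg <- sum(behavior == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop_sociodyn("behavior vector needs both positive and negative bins")
  }
  thresholds <- seq(min(z), max(z), length.out = n_thresholds)
  idx <- findInterval(z, thresholds)        # z >= thresholds[k] iff idx >= k
  pos_counts <- tabulate(idx[behavior == 1L], nbins = n_thresholds)
  neg_counts <- tabulate(idx[behavior == 0L], nbins = n_thresholds)
  tpr <- rev(cumsum(rev(pos_counts))) / n_pos
  fpr <- rev(cumsum(rev(neg_counts))) / n_neg
  structure(
    list(thresholds = thresholds, fpr = fpr, tpr = tpr,
         auroc = trapz(c(0, rev(fpr), 1), c(0, rev(tpr), 1)),
         n_pos = n_pos, n_neg = n_neg),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> auROC = ", format(x$auroc, digits = 4), " (",
      x$n_pos, " positive / ", x$n_neg, " negative bins)\n", sep = "")
  invisible(x)
}

#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  dat <- tibble::tibble(fpr = c(0, rev(object$fpr), 1),
                        tpr = c(0, rev(object$tpr), 1))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  subtitle = sprintf("auROC = %.3f", object$auroc)) +
    ggplot2::theme_minimal()
}

#' Circular-shift permutation null distribution of auROC
#'
#' Each of `n_perm` permutations circularly shifts the behavior vector by a
#' uniformly random offset in \{1, ..., T-1\} (never 0, so no draw reproduces
#' the observed alignment) and recomputes the threshold-sweep auROC. The
#' rotation preserves the behavior vector's autocorrelation while destroying
#' its alignment with the trace.
#'
#' @inheritParams roc_auroc
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; results are reproducible given (inputs, seed).
#'
#' @return Numeric vector of `n_perm` null auROC values.
#' @export
circular_shift_null <- function(z, behavior, n_perm = 1000, seed = NULL,
                                n_thresholds = 100) {
  if (inherits(behavior, "interaction_vector")) behavior <- behavior$values
  behavior <- as.integer(as.logical(behavior))
  z <- as.numeric(z)
  T_bins <- length(behavior)
  if (T_bins < 2L) stop_sociodyn("need at least 2 bins to shift")
  if (length(z) != T_bins) stop_sociodyn("z and behavior differ in length")
  n_pos <- sum(behavior == 1L)
  n_neg <- T_bins - n_pos
  if (n_pos == 0L || n_neg == 0L) {
    stop_sociodyn("behavior vector needs both positive and negative bins")
  }
  thresholds <- seq(min(z), max(z), length.out = n_thresholds)
  idx <- findInterval(z, thresholds)
  all_counts <- tabulate(idx, nbins = n_thresholds)
  pos0 <- which(behavior == 1L) - 1L        # 0-based positive positions
  with_seed(seed, {
    offsets <- sample.int(T_bins - 1L, n_perm, replace = TRUE)
    vapply(offsets, function(off) {
      shifted_pos <- ((pos0 + off) %% T_bins) + 1L
      pc <- tabulate(idx[shifted_pos], nbins = n_thresholds)
      auroc_from_counts(pc, all_counts - pc, n_pos, n_neg)
    }, numeric(1))
  })
}

#' Classify a neuron's response from its auROC and permutation null
#'
#' Excited when the observed auROC exceeds the 97.5th percentile of the null
#' distribution; inhibited when it falls below the 2.5th percentile; none
#' otherwise. Percentiles use the linear-interpolation convention
#' (`stats::quantile` type 7) and the comparison is strict, matching
#' "exceeded".
#'
#' @param auroc Observed auROC.
#' @param null Numeric vector of null auROC values.
#' @param level Two-sided significance level (default 0.05).
#'
#' @return `"excited"`, `"inhibited"`, or `"none"`.
#' @export
classify_response <- function(auroc, null, level = 0.05) {
  if (length(null) == 0L) stop_sociodyn("empty null distribution")
  lo <- quantile(null, level / 2, names = FALSE, type = 7)
  hi <- quantile(null, 1 - level / 2, names = FALSE, type = 7)
  if (auroc > hi) "excited" else if (auroc < lo) "inhibited" else "none"
}

#' Score one neuron against one stimulus
#'
#' Convenience wrapper chaining [roc_auroc()], [circular_shift_null()] and
#' [classify_response()].
#'
#' @inheritParams circular_shift_null
#' @param cell,stimulus Identifiers carried into the result.
#'
#' @return Object of class `neuron_response` with `auroc`, `null`,
#'   `classification`.
#' @export
score_neuron <- function(z, behavior, n_perm = 1000, seed = NULL,
                         cell = NA_character_, stimulus = NA_character_,
                         n_thresholds = 100) {
  roc <- roc_auroc(z, behavior, n_thresholds = n_thresholds)
  null <- circular_shift_null(z, behavior, n_perm = n_perm, seed = seed,
                              n_thresholds = n_thresholds)
  structure(
    list(cell = cell, stimulus = stimulus, auroc = roc$auroc, roc = roc,
         null = null, classification = classify_response(roc$auroc, null)),
    class = "neuron_response"
  )
}

#' @export
print.neuron_response <- function(x, ...) {
  cat("<neuron_response> auROC = ", format(x$auroc, digits = 4), " -> ",
      x$classification, " (", length(x$null), " permutations)\n", sep = "")
  invisible(x)
}

#' @method tidy neuron_response
#' @export
tidy.neuron_response <- function(x, ...) {
  tibble::tibble(
    cell = x$cell, stimulus = x$stimulus, auroc = x$auroc,
    null_lo = quantile(x$null, 0.025, names = FALSE),
    null_hi = quantile(x$null, 0.975, names = FALSE),
    classification = x$classification
  )
}

#' Event-triggered average of a z-scored trace
#'
#' Averages the trace in a symmetric window around each trial onset
#' (default 5 s before and after). Trials whose window is truncated by the
#' session edges are excluded; their count is in attribute `"n_excluded"`.
#'
#' @param z A [zscore_trace()] result, or numeric vector plus `frame_rate`.
#' @param trials Tibble from [extract_trials()] (uses `onset_s`), or numeric
#'   onset times in seconds.
#' @param window Window half-width in seconds (default 5).
#' @param frame_rate Required when `z` is a bare vector.
#'
#' @return Object of class `peri_event`: `time` (s, relative to onset),
#'   `average`, `snippets` (trials x time matrix), `n_trials`.
#' @export
event_triggered_average <- function(z, trials, window = 5, frame_rate = NULL) {
  if (inherits(z, "z_trace")) {
    frame_rate <- z$frame_rate
    z <- z$values
  }
  if (is.null(frame_rate)) stop_sociodyn("frame_rate required")
  onsets <- if (is.data.frame(trials)) trials$onset_s else as.numeric(trials)
  if (length(onsets) == 0L) stop_sociodyn("no trials supplied")
  half <- round(window * frame_rate)
  n <- length(z)
  onset_frames <- round(onsets * frame_rate) + 1L
  ok <- onset_frames - half >= 1L & onset_frames + half <= n
  if (!any(ok)) stop_sociodyn("no trial has a full +/-", window, " s window")
  snippets <- t(vapply(onset_frames[ok], function(f) {
    z[(f - half):(f + half)]
  }, numeric(2L * half + 1L)))
  out <- structure(
    list(time = (seq(-half, half)) / frame_rate,
         average = colMeans(snippets), snippets = snippets,
         n_trials = sum(ok)),
    class = "peri_event"
  )
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' @export
print.peri_event <- function(x, ...) {
  cat("<peri_event> ", x$n_trials, " trials, window ",
      format(min(x$time)), " to ", format(max(x$time)), " s\n", sep = "")
  invisible(x)
}

#' @method autoplot peri_event
#' @export
autoplot.peri_event <- function(object, ...) {
  se <- apply(object$snippets, 2, sd) / sqrt(object$n_trials)
  dat <- tibble::tibble(time = object$time, mean = object$average,
                        lo = object$average - se, hi = object$average + se)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::labs(x = "Time from onset (s)", y = "z-scored activity") +
    ggplot2::theme_minimal()
}

#' Cluster peri-event response profiles
#'
#' Each cell's social and object peri-event averages are concatenated into
#' one profile row; rows are clustered agglomeratively (Ward's method,
#' Euclidean distance) and the tree is cut at `cut_factor` times the maximum
#' linkage height to yield flat clusters.
#'
#' @param profiles Numeric matrix, one row per cell (e.g.
#'   `cbind(social_avg, object_avg)`), or a data frame of numeric columns.
#' @param cut_factor Fraction of the maximum linkage height at which the
#'   tree is pruned (default 0.770).
#'
#' @return Object of class `profile_clustering`: `tree` (an `hclust`),
#'   `clusters` (integer labels), `cut_height`, `n_clusters`.
#' @export
cluster_response_profiles <- function(profiles, cut_factor = 0.770) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L) stop_sociodyn("need at least 2 cells to cluster")
  tree <- stats::hclust(stats::dist(profiles, method = "euclidean"),
                        method = "ward.D2")
  h <- cut_factor * max(tree$height)
  clusters <- stats::cutree(tree, h = h)
  structure(
    list(tree = tree, clusters = clusters, cut_height = h,
         n_clusters = length(unique(clusters))),
    class = "profile_clustering"
  )
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat("<profile_clustering> ", length(x$clusters), " cells -> ",
      x$n_clusters, " clusters (cut at ", format(x$cut_height, digits = 4),
      ")\n", sep = "")
  invisible(x)
}

#' Per-animal response proportions and their behavioral correlate
#'
#' Summarizes permutation-classified single-cell responses per animal
#' (proportion excited and inhibited per stimulus) and, when a behavior
#' metric is supplied, correlates the proportion of socially excited neurons
#' with the social:object preference ratio across animals (Pearson).
#'
#' @param responses Data frame with columns `animal`, `cell`, `stimulus`,
#'   `classification`.
#' @param metrics Optional data frame with columns `animal` and
#'   `social_object_ratio`.
#'
#' @return Object of class `population_summary` with `by_animal` (tibble) and
#'   `correlation` (an `htest`, or `NULL`).
#' @export
population_summary <- function(responses, metrics = NULL) {
  stopifnot(is.data.frame(responses))
  need <- c("animal", "cell", "stimulus", "classification")
  miss <- setdiff(need, names(responses))
  if (length(miss)) stop_sociodyn("missing columns: ", paste(miss, collapse = ", "))
  by_animal <- responses |>
    dplyr::group_by(.data$animal, .data$stimulus) |>
    dplyr::summarise(
      n_cells = dplyr::n_distinct(.data$cell),
      prop_excited = mean(.data$classification == "excited"),
      prop_inhibited = mean(.data$classification == "inhibited"),
      .groups = "drop"
    )
  correlation <- NULL
  if (!is.null(metrics)) {
    soc <- by_animal |>
      dplyr::filter(.data$stimulus == "social") |>
      dplyr::inner_join(tibble::as_tibble(metrics), by = "animal")
    if (nrow(soc) < 3L) {
      stop_sociodyn("need at least 3 animals for the correlation")
    }
    if (sd(soc$prop_excited) == 0 || sd(soc$social_object_ratio) == 0) {
      warning("zero variance across animals: correlation undefined",
              call. = FALSE)
    } else {
      correlation <- stats::cor.test(soc$prop_excited, soc$social_object_ratio,
                                     method = "pearson")
    }
  }
  structure(list(by_animal = by_animal, correlation = correlation),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat("<population_summary> ", dplyr::n_distinct(x$by_animal$animal),
      " animals\n", sep = "")
  print(x$by_animal)
  if (!is.null(x$correlation)) {
    cat("prop_excited(social) vs social:object ratio: r = ",
        format(unname(x$correlation$estimate), digits = 3), ", p = ",
        format.pval(x$correlation$p.value), "\n", sep = "")
  }
  invisible(x)
}

#' @method glance population_summary
#' @export
glance.population_summary <- function(x, ...) {
  tibble::tibble(
    n_animals = dplyr::n_distinct(x$by_animal$animal),
    r = if (is.null(x$correlation)) NA_real_ else unname(x$correlation$estimate),
    p_value = if (is.null(x$correlation)) NA_real_ else x$correlation$p.value
  )
}
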