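#' Current-clamp recording container
#'
#' Holds the per-cell sweep set of the intrinsic-property protocol (1-s
#' current steps from -120 to +260 pA in 20 pA increments), plus optional
#' optogenetic-stimulation sweeps (averaged Vm around an 8-pulse, 30-Hz light
#' train) and firing data (spike times around light onset under constant
#' positive current).
#'
#' @param step_sweeps Named list, one element per step current (names are
#'   the current in pA, e.g. `"-120"`), each a data frame with columns
#'   `time_s`, `vm_mV`. All sweeps share `step_onset_s`/`step_offset_s`.
#' @param step_onset_s,step_offset_s Step window within each sweep, s.
#' @param opto Optional list with `time_s`, `vm_mV`, `stim_onset_s` (time of
#'   the first light pulse) and optionally `pulse_times_s`.
#' @param firing Optional list with `spike_times_s` and `light_onset_s`.
#' @param cell,region Identifiers.
#'
#' @return Object of class `ephys_recording`.
#' @export
ephys_recording <- function(step_sweeps, step_onset_s = 0.25,
                            step_offset_s = 1.25, opto = NULL, firing = NULL,
                            cell = NA_character_, region = NA_character_) {
  stopifnot(is.list(step_sweeps), length(step_sweeps) > 0)
  if (is.null(names(step_sweeps)) || anyNA(suppressWarnings(as.numeric(names(step_sweeps))))) {
    stop_sociodyn("step_sweeps must be named by step current in pA")
  }
  structure(
    list(step_sweeps = step_sweeps, step_onset_s = step_onset_s,
         step_offset_s = step_offset_s, opto = opto, firing = firing,
         cell = cell, region = region),
    class = "ephys_recording"
  )
}

#' @export
print.ephys_recording <- function(x, ...) {
  cat("<ephys_recording> ", length(x$step_sweeps), " current steps (",
      paste(range(as.numeric(names(x$step_sweeps))), collapse = " to "),
      " pA)", if (!is.null(x$opto)) ", opto sweep",
      if (!is.null(x$firing)) ", firing sweep", "\n", sep = "")
  invisible(x)
}

step_currents <- function(rec) as.numeric(names(rec$step_sweeps))

get_sweep <- function(rec, current) {
  i <- which(abs(step_currents(rec) - current) < 1e-9)
  if (length(i) != 1L) return(NULL)
  rec$step_sweeps[[i]]
}

#' Detect action potentials in a membrane-potential trace
#'
#' A spike is an upward crossing of `threshold_mV` (default 0 mV), with a
#' refractory period so one spike is not counted twice.
#'
#' @param time_s,vm_mV Sweep samples.
#' @param threshold_mV Crossing threshold (default 0).
#' @param refractory_s Minimum inter-spike interval (default 0.002).
#'
#' @return Numeric vector of spike times (s).
#' @export
detect_spikes <- function(time_s, vm_mV, threshold_mV = 0,
                          refractory_s = 0.002) {
  above <- vm_mV >= threshold_mV
  cross <- which(above[-1L] & !above[-length(above)]) + 1L
  if (length(cross) == 0L) return(numeric(0))
  times <- time_s[cross]
  keep <- c(TRUE, diff(times) >= refractory_s)
  # enforce refractory sequentially (diff-based filter is sufficient for
  # monotone spike trains; re-run until stable for safety)
  while (!all(keep)) {
    times <- times[keep]
    keep <- c(TRUE, diff(times) >= refractory_s)
  }
  times
}

#' Voltage sag amplitude at the -120 pA step
#'
#' Sag (attributable to the hyperpolarization-activated cation current,
#' I_h) is the difference between the peak instantaneous and steady-state
#' membrane potential during the -120 pA step: peak is the minimum Vm within
#' the step window, steady state the mean over the final 200 ms of the step.
#'
#' @param rec An [ephys_recording()].
#' @param steady_window_s Length of the steady-state window (default 0.2).
#' @param smooth_s Boxcar width applied before taking the peak (default
#'   2 ms); the raw minimum of a noisy sweep is biased downward by the
#'   extreme-value statistics of the noise.
#'
#' @return Sag amplitude in mV (>= 0 up to noise).
#' @export
sag_amplitude <- function(rec, steady_window_s = 0.2, smooth_s = 0.002) {
  stopifnot(inherits(rec, "ephys_recording"))
  sweep <- get_sweep(rec, -120)
  if (is.null(sweep)) stop_sociodyn("no -120 pA sweep: sag undefined")
  dt <- stats::median(diff(sweep$time_s))
  vm <- smooth_boxcar(sweep$vm_mV, round(smooth_s / dt))
  inwin <- sweep$time_s >= rec$step_onset_s & sweep$time_s <= rec$step_offset_s
  peak <- min(vm[inwin])
  steady <- mean(sweep$vm_mV[sweep$time_s >= rec$step_offset_s - steady_window_s &
                               sweep$time_s <= rec$step_offset_s])
  steady - peak
}

# Mean Vm of a sweep over an absolute time window.
window_mean <- function(sweep, from, to) {
  mean(sweep$vm_mV[sweep$time_s >= from & sweep$time_s <= to])
}

#' Ramp ratio of the largest subthreshold depolarizing step
#'
#' The ratio of the mean membrane-potential deflection 900-1000 ms after
#' step onset to the deflection 100-200 ms after onset, on the largest
#' depolarizing step that evoked no action potentials. Deflections are
#' measured from the pre-step baseline, so the ratio is well defined away
#' from zero absolute potentials. Values above 1 indicate a ramping
#' depolarization, ~1 a plateau.
#'
#' @param rec An [ephys_recording()].
#' @param spike_threshold_mV Spike-detection threshold (default 0 mV).
#'
#' @return Ramp ratio, or `NA` (with a message attribute) when no
#'   subthreshold depolarizing step exists.
#' @export
ramp_ratio <- function(rec, spike_threshold_mV = 0) {
  stopifnot(inherits(rec, "ephys_recording"))
  currents <- sort(step_currents(rec)[step_currents(rec) > 0])
  best <- NA_real_
  for (cur in currents) {
    sweep <- get_sweep(rec, cur)
    inwin <- sweep$time_s >= rec$step_onset_s & sweep$time_s <= rec$step_offset_s
    spikes <- detect_spikes(sweep$time_s[inwin], sweep$vm_mV[inwin],
                            threshold_mV = spike_threshold_mV)
    if (length(spikes) == 0L) best <- cur
  }
  if (is.na(best)) return(NA_real_)
  sweep <- get_sweep(rec, best)
  baseline <- window_mean(sweep, 0, rec$step_onset_s)
  early <- window_mean(sweep, rec$step_onset_s + 0.1, rec$step_onset_s + 0.2) - baseline
  late <- window_mean(sweep, rec$step_onset_s + 0.9, rec$step_onset_s + 1.0) - baseline
  late / early
}

#' Firing delay at rheobase
#'
#' Rheobase is the lowest current step that elicits at least one action
#' potential; the firing delay is the latency from step onset to the first
#' spike on that step.
#'
#' @inheritParams ramp_ratio
#'
#' @return Delay in ms, or `NA` when no step elicits a spike.
#' @export
firing_delay <- function(rec, spike_threshold_mV = 0) {
  stopifnot(inherits(rec, "ephys_recording"))
  for (cur in sort(step_currents(rec)[step_currents(rec) > 0])) {
    sweep <- get_sweep(rec, cur)
    inwin <- sweep$time_s >= rec$step_onset_s & sweep$time_s <= rec$step_offset_s
    spikes <- detect_spikes(sweep$time_s[inwin], sweep$vm_mV[inwin],
                            threshold_mV = spike_threshold_mV)
    if (length(spikes) > 0L) {
      return((spikes[1L] - rec$step_onset_s) * 1000)
    }
  }
  NA_real_
}

#' Maximum instantaneous firing frequency in the first 100 ms
#'
#' The maximum of 1/ISI over all pairs of consecutive spikes that both fall
#' within the first 100 ms of a depolarizing step, maximized over steps.
#'
#' @inheritParams ramp_ratio
#' @param window_s Early window length (default 0.1).
#'
#' @return Frequency in Hz, or `NA` when fewer than two spikes ever occur in
#'   the window.
#' @export
max_inst_freq <- function(rec, window_s = 0.1, spike_threshold_mV = 0) {
  stopifnot(inherits(rec, "ephys_recording"))
  best <- NA_real_
  for (cur in step_currents(rec)[step_currents(rec) > 0]) {
    sweep <- get_sweep(rec, cur)
    inwin <- sweep$time_s >= rec$step_onset_s & sweep$time_s <= rec$step_offset_s
    spikes <- detect_spikes(sweep$time_s[inwin], sweep$vm_mV[inwin],
                            threshold_mV = spike_threshold_mV)
    spikes <- spikes[spikes <= rec$step_onset_s + window_s]
    if (length(spikes) >= 2L) {
      f <- max(1 / diff(spikes))
      if (is.na(best) || f > best) best <- f
    }
  }
  best
}

#' Membrane capacitance from the smallest hyperpolarizing step
#'
#' Fits a single-exponential charging curve
#' \eqn{V(t) = V_0 + \Delta V (1 - e^{-t/\tau})} to the onset of the
#' smallest-magnitude hyperpolarizing step; with input resistance
#' \eqn{R = \Delta V / I}, capacitance is \eqn{C = \tau / R}. This is an
#' approximation based on the membrane time constant rather than a full
#' charge-integration method.
#'
#' @param rec An [ephys_recording()].
#' @param fit_window_s Window after step onset used for the fit (default 0.15).
#'
#' @return Capacitance in pF, or `NA` when the fit fails.
#' @export
estimate_capacitance <- function(rec, fit_window_s = 0.15) {
  stopifnot(inherits(rec, "ephys_recording"))
  neg <- step_currents(rec)[step_currents(rec) < 0]
  if (length(neg) == 0L) return(NA_real_)
  cur <- neg[which.min(abs(neg))]
  sweep <- get_sweep(rec, cur)
  baseline <- window_mean(sweep, 0, rec$step_onset_s)
  sel <- sweep$time_s >= rec$step_onset_s &
    sweep$time_s <= rec$step_onset_s + fit_window_s
  t <- sweep$time_s[sel] - rec$step_onset_s
  v <- sweep$vm_mV[sel] - baseline
  dv0 <- window_mean(sweep, rec$step_offset_s - 0.2, rec$step_offset_s) - baseline
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ dV * (1 - exp(-t / tau)),
                      start = list(dV = dv0, tau = 0.02),
                      lower = c(dV = -Inf, tau = 1e-5),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NA_real_)
  cf <- stats::coef(fit)
  R_MOhm <- abs(cf[["dV"]] / cur) * 1000   # mV / pA -> MOhm
  tau_ms <- cf[["tau"]] * 1000
  unname(tau_ms / R_MOhm * 1000)           # ms / MOhm -> nF -> pF
}

#' Extract the full intrinsic feature set of one cell
#'
#' @param rec An [ephys_recording()].
#' @param capacitance Include the capacitance estimate (default TRUE).
#'
#' @return One-row tibble: `cell`, `region`, `sag_mV`, `ramp_ratio`,
#'   `firing_delay_ms`, `max_freq_inst_hz`, `capacitance_pF`.
#' @export
extract_ephys_features <- function(rec, capacitance = TRUE) {
  tibble::tibble(
    cell = rec$cell, region = rec$region,
    sag_mV = sag_amplitude(rec),
    ramp_ratio = ramp_ratio(rec),
    firing_delay_ms = firing_delay(rec),
    max_freq_inst_hz = max_inst_freq(rec),
    capacitance_pF = if (capacitance) estimate_capacitance(rec) else NA_real_
  )
}

#' Optogenetic PSP metrics from an averaged sweep
#'
#' Using the 5 s before light onset as baseline: the EPSP peak is the
#' maximum deflection above baseline in a fast window after the first pulse;
#' the IPSP trough is the minimum deflection over the 5.5 s following onset;
#' IPSP decay tau comes from a single-exponential least-squares fit from the
#' trough until the first return to baseline; total voltage area is the
#' signed trapezoidal integral of the deflection over 0-5.5 s after onset.
#' A PSP counts as present when its amplitude exceeds
#' `detect_k` x baseline SD (and `min_amplitude_mV`).
#'
#' @param opto List with `time_s`, `vm_mV`, `stim_onset_s` (or an
#'   [ephys_recording()] with an `$opto` component).
#' @param epsp_window_s Fast search window for the EPSP peak (default 0.1 s
#'   after the first pulse).
#' @param area_window_s Extent of the voltage-area/trough window (default 5.5).
#' @param detect_k Baseline-SD multiple for presence calls (default 3).
#' @param min_amplitude_mV Absolute floor for presence calls (default 0.5).
#' @param epsp_smooth_s,ipsp_smooth_s Boxcar widths (s) applied before
#'   reading the fast peak and slow trough respectively; raw extrema of a
#'   noisy sweep are biased by the noise's extreme-value statistics.
#' @param iei_pre_s,iei_post_s Optional mean inter-event intervals of firing
#'   5 s before/after light (see [iei_change()]); used for classification.
#'
#' @return Object of class `psp_metrics` (also a one-row list): amplitudes,
#'   latencies, `ipsp_decay_tau_s`, `voltage_area_mV_s`, presence flags,
#'   `response_class`.
#' @export
psp_metrics <- function(opto, epsp_window_s = 0.1, area_window_s = 5.5,
                        detect_k = 3, min_amplitude_mV = 0.5,
                        epsp_smooth_s = 0.005, ipsp_smooth_s = 0.05,
                        iei_pre_s = NA_real_, iei_post_s = NA_real_) {
  if (inherits(opto, "ephys_recording")) {
    if (is.null(opto$opto)) stop_sociodyn("recording has no opto sweep")
    opto <- opto$opto
  }
  t <- opto$time_s
  v <- opto$vm_mV
  t0 <- opto$stim_onset_s
  pre <- t >= t0 - 5 & t < t0
  if (!any(pre)) stop_sociodyn("need 5 s of pre-stimulus baseline")
  baseline <- mean(v[pre])
  defl <- v - baseline
  dt <- stats::median(diff(t))
  defl_fast <- smooth_boxcar(defl, round(epsp_smooth_s / dt))
  defl_slow <- smooth_boxcar(defl, round(ipsp_smooth_s / dt))
  fast <- t >= t0 & t <= t0 + epsp_window_s
  slow <- t >= t0 & t <= t0 + area_window_s
  epsp_peak <- max(defl_fast[fast])
  epsp_lat <- (t[fast][which.max(defl_fast[fast])] - t0) * 1000
  ipsp_trough <- min(defl_slow[slow])
  trough_idx <- which(slow)[which.min(defl_slow[slow])]
  ipsp_lat <- (t[trough_idx] - t0) * 1000
  floor_fast <- max(detect_k * sd(defl_fast[pre]), min_amplitude_mV)
  floor_slow <- max(detect_k * sd(defl_slow[pre]), min_amplitude_mV)
  has_epsp <- epsp_peak > floor_fast
  has_ipsp <- -ipsp_trough > floor_slow
  # IPSP decay tau: single exponential from trough to first baseline return
  ipsp_tau <- NA_real_
  if (has_ipsp) {
    after <- seq(trough_idx, max(which(slow)))
    ret <- which(defl_slow[after] >= 0)[1L]
    end_idx <- if (is.na(ret)) max(which(slow)) else after[ret]
    tt <- t[trough_idx:end_idx] - t[trough_idx]
    vv <- defl_slow[trough_idx:end_idx]
    if (length(tt) >= 5L) {
      fit <- tryCatch(
        minpack.lm::nlsLM(vv ~ A * exp(-tt / tau),
                          start = list(A = defl_slow[trough_idx],
                                       tau = max(diff(range(tt)) / 3, 0.05)),
                          lower = c(A = -Inf, tau = 1e-4),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL
      )
      if (!is.null(fit)) ipsp_tau <- unname(stats::coef(fit)[["tau"]])
    }
  }
  area <- trapz(t[slow], defl[slow])
  out <- structure(
    list(epsp_peak_mV = epsp_peak, ipsp_trough_mV = ipsp_trough,
         epsp_onset_latency_ms = epsp_lat, ipsp_trough_latency_ms = ipsp_lat,
         ipsp_decay_tau_s = ipsp_tau, voltage_area_mV_s = area,
         has_epsp = has_epsp, has_ipsp = has_ipsp,
         iei_pre_s = iei_pre_s, iei_post_s = iei_post_s,
         response_class = NA_character_),
    class = "psp_metrics"
  )
  out$response_class <- classify_opto_response(out)
  out
}

#' @export
print.psp_metrics <- function(x, ...) {
  cat("<psp_metrics> class: ", x$response_class,
      sprintf(" | EPSP %.2f mV, IPSP %.2f mV, area %.2f mV*s",
              x$epsp_peak_mV, x$ipsp_trough_mV, x$voltage_area_mV_s), "\n",
      sep = "")
  invisible(x)
}

#' @method tidy psp_metrics
#' @export
tidy.psp_metrics <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Classify an optogenetic response
#'
#' Firing data takes precedence: a decrease in action-potential inter-event
#' interval (IEI) with light is an excitation, an increase an inhibition.
#' Otherwise the PSP rule applies: EPSP only = excitation, IPSP only =
#' inhibition, both = mixed, neither = none. With
#' `resolve_mixed = TRUE` (used for dendrogram annotation) a mixed response
#' is resolved to excitation when the total voltage area over 0-5.5 s is
#' positive and inhibition when negative.
#'
#' @param metrics A [psp_metrics()] result.
#' @param resolve_mixed Resolve mixed responses by voltage-area sign.
#'
#' @return `"excitation"`, `"inhibition"`, `"mixed"`, or `"none"`.
#' @export
classify_opto_response <- function(metrics, resolve_mixed = FALSE) {
  if (!is.na(metrics$iei_pre_s) && !is.na(metrics$iei_post_s)) {
    if (metrics$iei_post_s < metrics$iei_pre_s) return("excitation")
    if (metrics$iei_post_s > metrics$iei_pre_s) return("inhibition")
  }
  cls <- if (metrics$has_epsp && metrics$has_ipsp) "mixed"
  else if (metrics$has_epsp) "excitation"
  else if (metrics$has_ipsp) "inhibition"
  else "none"
  if (cls == "mixed" && resolve_mixed) {
    cls <- if (metrics$voltage_area_mV_s >= 0) "excitation" else "inhibition"
  }
  cls
}

#' Mean inter-event interval before and after light onset
#'
#' @param spike_times_s Spike times (s).
#' @param light_onset_s Time of the first light pulse (s).
#' @param window_s Window length on each side (default 5).
#'
#' @return Named list `iei_pre_s`, `iei_post_s` (`NA` when fewer than two
#'   spikes in a window).
#' @export
iei_change <- function(spike_times_s, light_onset_s, window_s = 5) {
  pre <- spike_times_s[spike_times_s >= light_onset_s - window_s &
                         spike_times_s < light_onset_s]
  post <- spike_times_s[spike_times_s >= light_onset_s &
                          spike_times_s < light_onset_s + window_s]
  mean_iei <- function(x) if (length(x) >= 2L) mean(diff(x)) else NA_real_
  list(iei_pre_s = mean_iei(pre), iei_post_s = mean_iei(post))
}

#' Cluster cells by baseline intrinsic properties
#'
#' Each feature is max-min normalized to [0, 1]; cells are clustered
#' agglomeratively on Euclidean distance with Ward's linkage, and the two
#' top-level clusters are reported. Typical feature menus: ramp ratio, max
#' firing frequency, firing delay and voltage sag (central amygdala), or
#' capacitance in place of ramp ratio (posterior basolateral amygdala).
#' Rows with missing feature values are dropped and counted.
#'
#' @param features Data frame with one row per cell, containing
#'   `feature_cols` plus optionally `cell` and `response_class` columns.
#' @param feature_cols Character vector of feature columns to use.
#' @param k Number of flat clusters to report (default 2).
#'
#' @return Object of class `baseline_clustering`: `tree`, `clusters` (tibble
#'   of cell, cluster, and response class when present), `n_dropped`,
#'   `composition` (cluster x response-class counts when available).
#' @export
cluster_baseline <- function(features, feature_cols, k = 2L) {
  stopifnot(is.data.frame(features))
  miss <- setdiff(feature_cols, names(features))
  if (length(miss)) stop_sociodyn("missing feature columns: ",
                                  paste(miss, collapse = ", "))
  complete <- stats::complete.cases(features[feature_cols])
  n_dropped <- sum(!complete)
  dat <- features[complete, , drop = FALSE]
  if (nrow(dat) < 2L) stop_sociodyn("need at least 2 cells with complete features")
  X <- as.matrix(dat[feature_cols])
  rng <- apply(X, 2L, range)
  const <- rng[2L, ] - rng[1L, ] == 0
  if (any(const)) {
    stop_sociodyn("constant feature (max = min): ",
                  paste(feature_cols[const], collapse = ", "))
  }
  Xn <- sweep(sweep(X, 2L, rng[1L, ], "-"), 2L, rng[2L, ] - rng[1L, ], "/")
  tree <- stats::hclust(stats::dist(Xn, method = "euclidean"),
                        method = "ward.D2")
  cl <- stats::cutree(tree, k = k)
  clusters <- tibble::tibble(
    cell = if ("cell" %in% names(dat)) dat$cell else seq_len(nrow(dat)),
    cluster = cl
  )
  composition <- NULL
  if ("response_class" %in% names(dat)) {
    clusters$response_class <- dat$response_class
    composition <- clusters |>
      dplyr::count(.data$cluster, .data$response_class) |>
      tidyr::pivot_wider(names_from = "response_class", values_from = "n",
                         values_fill = 0L)
  }
  structure(
    list(tree = tree, clusters = clusters, normalized = Xn,
         n_dropped = n_dropped, composition = composition, k = k),
    class = "baseline_clustering"
  )
}

#' @export
print.baseline_clustering <- function(x, ...) {
  cat("<baseline_clustering> ", nrow(x$clusters), " cells -> ", x$k,
      " clusters", if (x$n_dropped > 0) paste0(" (", x$n_dropped,
                                               " dropped for missing features)"),
      "\n", sep = "")
  if (!is.null(x$composition)) print(x$composition)
  invisible(x)
}
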