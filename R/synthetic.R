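# Synthetic-data generators. Every input class the pipeline consumes can be
# generated with planted ground truth, so recovery of known structure is
# testable end to end. All generators are deterministic given (spec, seed).

#' Markov sequence specification
#'
#' @param P_true Row-stochastic transition matrix (rows sum to 1 within
#'   1e-12); dimnames give the state labels unless `states` is supplied.
#' @param T_bins Sequence length in 1-s bins (>= 2).
#' @param states Optional state labels.
#' @param category_map Optional label -> social/nonsocial map.
#' @param seed Integer seed.
#'
#' @return Object of class `markov_spec`.
#' @export
markov_spec <- function(P_true, T_bins, states = NULL, category_map = NULL,
                        seed = 1L) {
  P_true <- as.matrix(P_true)
  if (nrow(P_true) != ncol(P_true)) stop_sociodyn("P_true must be square")
  if (any(P_true < 0) || any(abs(rowSums(P_true) - 1) > 1e-12)) {
    stop_sociodyn("P_true rows must be nonnegative and sum to 1 (within 1e-12)")
  }
  if (T_bins < 2) stop_sociodyn("T_bins must be >= 2")
  if (is.null(states)) {
    states <- rownames(P_true) %||% LETTERS[seq_len(nrow(P_true))]
  }
  dimnames(P_true) <- list(states, states)
  if (!is.null(category_map)) check_category_map(category_map, states)
  structure(list(P_true = P_true, T_bins = as.integer(T_bins), states = states,
                 category_map = category_map, seed = seed),
            class = "markov_spec")
}

# Stationary distribution of a row-stochastic matrix (left eigenvector for
# eigenvalue 1); uniform fallback when it is not unique or not real.
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which(abs(e$values - 1) < 1e-8)
  if (length(i) != 1L) return(rep(1 / nrow(P), nrow(P)))
  v <- Re(e$vectors[, i])
  if (max(abs(Im(e$vectors[, i]))) > 1e-8) return(rep(1 / nrow(P), nrow(P)))
  v <- v / sum(v)
  if (any(v < -1e-10)) return(rep(1 / nrow(P), nrow(P)))
  pmax(v, 0) / sum(pmax(v, 0))
}

#' Generate a behavior sequence from a first-order Markov chain
#'
#' The initial state is drawn from the stationary distribution of `P_true`
#' (uniform fallback when it is not unique), removing burn-in bias at small
#' `T_bins`; each subsequent state is drawn from the row of the current
#' state.
#'
#' @param spec A [markov_spec()].
#'
#' @return A [behavior_sequence()] of length `T_bins`.
#' @export
gen_markov_sequence <- function(spec) {
  stopifnot(inherits(spec, "markov_spec"))
  P <- spec$P_true
  k <- nrow(P)
  iid <- all(abs(sweep(P, 2L, P[1L, ], "-")) < 1e-15)
  with_seed(spec$seed, {
    pi0 <- stationary_distribution(P)
    if (iid) {
      # all rows equal: the chain is an iid draw from the common row
      s <- sample.int(k, spec$T_bins, replace = TRUE, prob = P[1L, ])
    } else {
      cp <- t(apply(P, 1L, cumsum))
      u <- stats::runif(spec$T_bins)
      s <- integer(spec$T_bins)
      s[1L] <- sample.int(k, 1L, prob = pi0)
      for (t in 2:spec$T_bins) {
        s[t] <- sum(u[t] > cp[s[t - 1L], ]) + 1L
      }
    }
    behavior_sequence(spec$states[s], alphabet = spec$states,
                      category_map = spec$category_map)
  })
}

#' Pose-session scenario
#'
#' Describes a three-chamber-style session to synthesize: arena size, cup
#' geometry, frame rate, planted interaction bouts, and keypoint jitter.
#'
#' @param arena Named numeric `c(width, height)` in cm (default the
#'   57.5 x 22.5 cm chamber footprint).
#' @param cups Data frame `stimulus`, `x`, `y`, `diameter` (cm); must lie
#'   inside the arena.
#' @param duration_s Session length, s.
#' @param frame_rate Frames per second (> 0).
#' @param bouts Data frame `stimulus`, `onset_s`, `offset_s`; bouts must be
#'   non-overlapping and inside the session.
#' @param keypoint_noise_sd Gaussian jitter SD added to every keypoint, cm.
#' @param seed Integer seed.
#'
#' @return Object of class `pose_scenario`.
#' @export
pose_scenario <- function(arena = c(width = 57.5, height = 22.5),
                          cups = default_cups(), duration_s = 60,
                          frame_rate = 20, bouts = NULL,
                          keypoint_noise_sd = 0, seed = 1L) {
  stopifnot(frame_rate > 0, duration_s > 0, keypoint_noise_sd >= 0)
  cups <- tibble::as_tibble(cups)
  stopifnot(all(c("stimulus", "x", "y", "diameter") %in% names(cups)))
  r <- cups$diameter / 2
  if (any(cups$x - r < 0 | cups$x + r > arena[["width"]] |
            cups$y - r < 0 | cups$y + r > arena[["height"]])) {
    stop_sociodyn("cups must lie inside the arena")
  }
  if (is.null(bouts)) {
    bouts <- tibble::tibble(stimulus = character(), onset_s = numeric(),
                            offset_s = numeric())
  }
  bouts <- tibble::as_tibble(bouts)
  if (nrow(bouts) > 0L) {
    if (any(bouts$onset_s < 0 | bouts$offset_s > duration_s |
              bouts$onset_s >= bouts$offset_s)) {
      stop_sociodyn("bouts must lie inside the session with onset < offset")
    }
    b <- bouts[order(bouts$onset_s), ]
    if (nrow(b) > 1L && any(b$onset_s[-1L] < b$offset_s[-nrow(b)])) {
      stop_sociodyn("bouts must not overlap (one animal, one place at a time)")
    }
  }
  structure(list(arena = arena, cups = cups, duration_s = duration_s,
                 frame_rate = frame_rate, bouts = bouts,
                 keypoint_noise_sd = keypoint_noise_sd, seed = seed),
            class = "pose_scenario")
}

#' Default cup layout for the synthetic three-chamber arena
#' @return Tibble of two cups (social left, object right).
#' @export
default_cups <- function() {
  tibble::tibble(stimulus = c("social", "object"),
                 x = c(8, 49.5), y = c(11.25, 11.25), diameter = c(8, 8))
}

#' Synthesize a pose session with planted interaction bouts
#'
#' During each planted bout the nose is placed inside the detection
#' envelope of the bout's cup (within 1.3x the cup diameter of the center,
#' with the cup dead ahead of the head direction); outside bouts the animal
#' random-walks with its nose kept well clear of both cups (beyond 1.5x the
#' diameter). Nose, head, neck and trunk keypoints are emitted with optional
#' Gaussian jitter. Ground truth is returned at frame resolution: a frame is
#' truly interacting when its midpoint falls inside a planted bout.
#'
#' @param scn A [pose_scenario()].
#'
#' @return List with `track` (a [pose_track()]) and `truth` (named list of
#'   logical frame vectors, one per cup stimulus).
#' @export
gen_pose_session <- function(scn) {
  stopifnot(inherits(scn, "pose_scenario"))
  n_frames <- round(scn$duration_s * scn$frame_rate)
  mid_t <- (seq_len(n_frames) - 0.5) / scn$frame_rate
  cups <- scn$cups
  w <- scn$arena[["width"]]
  h <- scn$arena[["height"]]
  # which bout (if any) each frame belongs to
  bout_of <- rep(NA_integer_, n_frames)
  for (b in seq_len(nrow(scn$bouts))) {
    bout_of[mid_t >= scn$bouts$onset_s[b] & mid_t < scn$bouts$offset_s[b]] <- b
  }
  with_seed(scn$seed, {
    nose <- matrix(NA_real_, n_frames, 2L)
    head <- matrix(NA_real_, n_frames, 2L)
    neck <- matrix(NA_real_, n_frames, 2L)
    clear_of_cups <- function(p) {
      all(sqrt((p[1L] - cups$x)^2 + (p[2L] - cups$y)^2) > 1.5 * cups$diameter)
    }
    # start position away from cups
    pos <- c(w / 2, h / 2)
    while (!clear_of_cups(pos)) {
      pos <- c(stats::runif(1, 2, w - 2), stats::runif(1, 2, h - 2))
    }
    heading <- stats::runif(1, 0, 2 * pi)
    for (f in seq_len(n_frames)) {
      b <- bout_of[f]
      if (!is.na(b)) {
        cup <- cups[cups$stimulus == scn$bouts$stimulus[b], ][1L, ]
        # nose at 0.6x diameter from the cup center, pointing at the cup
        phi <- stats::runif(1, 0, 2 * pi)
        np <- c(cup$x, cup$y) + 0.6 * cup$diameter * c(cos(phi), sin(phi))
        u <- c(cup$x, cup$y) - np
        u <- u / sqrt(sum(u^2))
        nose[f, ] <- np
        head[f, ] <- np - 1.5 * u
        neck[f, ] <- np - 3.0 * u
        pos <- np
      } else {
        # random walk, resampling steps that come too close to a cup
        for (try in 1:50) {
          step <- stats::rnorm(2L, 0, 1.0)
          cand <- pmin(pmax(pos + step, 2), c(w - 2, h - 2))
          if (clear_of_cups(cand)) break
          cand <- pos
        }
        if (!clear_of_cups(cand)) cand <- c(w / 2, h / 2)
        dir <- cand - pos
        if (sqrt(sum(dir^2)) > 1e-6) heading <- atan2(dir[2L], dir[1L])
        pos <- cand
        u <- c(cos(heading), sin(heading))
        nose[f, ] <- pos
        head[f, ] <- pos - 1.5 * u
        neck[f, ] <- pos - 3.0 * u
      }
    }
    if (scn$keypoint_noise_sd > 0) {
      jit <- function(m) m + matrix(stats::rnorm(length(m), 0,
                                                 scn$keypoint_noise_sd),
                                    nrow(m), ncol(m))
      nose <- jit(nose); head <- jit(head); neck <- jit(neck)
    }
    dat <- tibble::tibble(
      frame = seq_len(n_frames),
      nose_x = nose[, 1L], nose_y = nose[, 2L],
      head_x = head[, 1L], head_y = head[, 2L],
      neck_x = neck[, 1L], neck_y = neck[, 2L],
      trunk_x = neck[, 1L] - (head[, 1L] - neck[, 1L]),
      trunk_y = neck[, 2L] - (head[, 2L] - neck[, 2L])
    )
    truth <- lapply(setNames(cups$stimulus, cups$stimulus), function(s) {
      tr <- rep(FALSE, n_frames)
      idx <- which(!is.na(bout_of))
      tr[idx] <- scn$bouts$stimulus[bout_of[idx]] == s
      tr
    })
    list(track = pose_track(dat, frame_rate = scn$frame_rate,
                            arena = scn$arena, cups = cups),
         truth = truth)
  })
}

#' Calcium-population specification
#'
#' @param n_cells Number of cells.
#' @param frame_rate Acquisition rate, Hz (default 20).
#' @param duration_s Session length, s.
#' @param cell_classes Data frame `cell`, `stimulus`, `class`
#'   (excited/inhibited/none); defaults to all-none for the stimuli supplied
#'   at generation time.
#' @param response_amplitude Transient amplitude in noise-SD units... in the
#'   raw trace's units (z-scoring is the pipeline's job).
#' @param transient_decay_tau Transient decay time constant, s (default 0.5,
#'   GCaMP7f-like).
#' @param noise_sd Gaussian noise SD (> 0).
#' @param seed Integer seed.
#'
#' @return Object of class `calcium_spec`.
#' @export
calcium_spec <- function(n_cells, frame_rate = 20, duration_s = 300,
                         cell_classes = NULL, response_amplitude = 1,
                         transient_decay_tau = 0.5, noise_sd = 0.2,
                         seed = 1L) {
  stopifnot(n_cells >= 1, frame_rate > 0, duration_s > 0,
            response_amplitude >= 0, transient_decay_tau > 0, noise_sd > 0)
  structure(list(n_cells = as.integer(n_cells), frame_rate = frame_rate,
                 duration_s = duration_s, cell_classes = cell_classes,
                 response_amplitude = response_amplitude,
                 transient_decay_tau = transient_decay_tau,
                 noise_sd = noise_sd, seed = seed),
            class = "calcium_spec")
}

#' Synthesize a calcium-trace population with planted responses
#'
#' Each trace is Gaussian noise plus, for cells planted as excited to a
#' stimulus, an exponential-decay transient of the stated amplitude at every
#' event onset of that stimulus (inhibited cells get the negative). Traces
#' are returned raw; z-scoring is the analysis pipeline's job.
#'
#' @param spec A [calcium_spec()].
#' @param events Named list of [interaction_vector()]s (or logical frame
#'   vectors at the calcium frame rate), one per stimulus; onsets are the
#'   starts of positive runs.
#'
#' @return List with `traces` (cells x frames matrix), `frame_rate`, and
#'   `truth` (tibble `cell`, `stimulus`, `class`).
#' @export
gen_calcium_population <- function(spec, events) {
  stopifnot(inherits(spec, "calcium_spec"), is.list(events),
            !is.null(names(events)))
  n_frames <- round(spec$duration_s * spec$frame_rate)
  onset_frames <- lapply(events, function(ev) {
    if (inherits(ev, "interaction_vector")) {
      runs <- true_runs(ev$values == 1L)
      onset_t <- (runs$start - 1L) * ev$bin_width
      f <- round(onset_t * spec$frame_rate) + 1L
    } else {
      ev <- as.logical(ev)
      if (length(ev) != n_frames) {
        stop_sociodyn("event vector length (", length(ev),
                      ") does not match the session (", n_frames, " frames)")
      }
      f <- true_runs(ev)$start
    }
    f[f <= n_frames]
  })
  classes <- spec$cell_classes
  if (is.null(classes)) {
    classes <- tidyr::expand_grid(cell = seq_len(spec$n_cells),
                                  stimulus = names(events)) |>
      dplyr::mutate(class = "none")
  }
  classes <- tibble::as_tibble(classes)
  stopifnot(all(c("cell", "stimulus", "class") %in% names(classes)))
  bad <- setdiff(unique(classes$class), c("excited", "inhibited", "none"))
  if (length(bad)) stop_sociodyn("unknown cell class: ", paste(bad, collapse = ", "))
  # exponential transient kernel sampled at the frame rate
  kern_len <- ceiling(5 * spec$transient_decay_tau * spec$frame_rate)
  kernel <- spec$response_amplitude *
    exp(-(seq_len(kern_len) - 1L) / (spec$transient_decay_tau * spec$frame_rate))
  with_seed(spec$seed, {
    traces <- matrix(stats::rnorm(spec$n_cells * n_frames, 0, spec$noise_sd),
                     nrow = spec$n_cells)
    for (r in seq_len(nrow(classes))) {
      if (classes$class[r] == "none") next
      sgn <- if (classes$class[r] == "excited") 1 else -1
      stim <- classes$stimulus[r]
      if (!stim %in% names(onset_frames)) {
        stop_sociodyn("no event vector for stimulus: ", stim)
      }
      for (f in onset_frames[[stim]]) {
        span <- f:min(f + kern_len - 1L, n_frames)
        traces[classes$cell[r], span] <-
          traces[classes$cell[r], span] + sgn * kernel[seq_along(span)]
      }
    }
    rownames(traces) <- paste0("cell", seq_len(spec$n_cells))
    list(traces = traces, frame_rate = spec$frame_rate, truth = classes)
  })
}

#' Electrophysiological cell archetype
#'
#' Named bundle of planted intrinsic and synaptic properties from which
#' [gen_ephys_cell()] synthesizes sweeps. Typical archetypes: late-firing
#' (large sag, long delay), regular-firing, pyramidal (large capacitance),
#' interneuron (small capacitance, fast firing).
#'
#' @param name Label.
#' @param sag_mV Planted voltage sag at -120 pA (>= 0).
#' @param ramp_ratio_true Planted late/early deflection ratio.
#' @param firing_delay_ms Planted first-spike latency at rheobase.
#' @param max_freq_hz Planted maximum instantaneous firing frequency.
#' @param capacitance_pF Membrane capacitance.
#' @param input_resistance_MOhm Input resistance (sets step deflections).
#' @param resting_mV Resting potential.
#' @param rheobase_pA Lowest current step that fires.
#' @param psp_type `"EPSP"`, `"IPSP"`, `"mixed"`, or `"none"`.
#' @param epsp_amplitude_mV,ipsp_amplitude_mV PSP amplitudes (>= 0; zero
#'   amplitudes are only consistent with `psp_type = "none"`).
#' @param ipsp_tau_s IPSP decay time constant, s.
#' @param noise_sd_mV Gaussian noise SD added to every sweep.
#'
#' @return Object of class `ephys_archetype`.
#' @export
ephys_archetype <- function(name = "regular-firing", sag_mV = 2,
                            ramp_ratio_true = 1.0, firing_delay_ms = 50,
                            max_freq_hz = 60, capacitance_pF = 100,
                            input_resistance_MOhm = 150, resting_mV = -70,
                            rheobase_pA = 120, psp_type = "none",
                            epsp_amplitude_mV = 0, ipsp_amplitude_mV = 0,
                            ipsp_tau_s = 1, noise_sd_mV = 0.2) {
  psp_type <- match.arg(psp_type, c("EPSP", "IPSP", "mixed", "none"))
  stopifnot(sag_mV >= 0, max_freq_hz > 0, firing_delay_ms >= 0,
            epsp_amplitude_mV >= 0, ipsp_amplitude_mV >= 0, ipsp_tau_s > 0)
  has_e <- epsp_amplitude_mV > 0
  has_i <- ipsp_amplitude_mV > 0
  consistent <- switch(psp_type,
                       EPSP = has_e && !has_i, IPSP = has_i && !has_e,
                       mixed = has_e && has_i, none = !has_e && !has_i)
  if (!consistent) {
    stop_sociodyn("psp_type '", psp_type,
                  "' inconsistent with the PSP amplitudes supplied")
  }
  structure(as.list(environment())[c(
    "name", "sag_mV", "ramp_ratio_true", "firing_delay_ms", "max_freq_hz",
    "capacitance_pF", "input_resistance_MOhm", "resting_mV", "rheobase_pA",
    "psp_type", "epsp_amplitude_mV", "ipsp_amplitude_mV", "ipsp_tau_s",
    "noise_sd_mV")],
    class = "ephys_archetype")
}

#' The standard current-step protocol
#'
#' 1-s steps in 20 pA increments from -120 to +260 pA, 10 kHz sampling,
#' 0.25 s pre- and post-step baseline.
#'
#' @param currents_pA Step currents (default `seq(-120, 260, by = 20)`).
#' @param dt_s Sample interval (default 1e-4).
#' @param onset_s,offset_s Step window (defaults 0.25/1.25).
#' @param sweep_s Total sweep length (default 1.5).
#' @return List describing the protocol.
#' @export
default_step_protocol <- function(currents_pA = seq(-120, 260, by = 20),
                                  dt_s = 1e-4, onset_s = 0.25,
                                  offset_s = 1.25, sweep_s = 1.5) {
  list(currents_pA = currents_pA, dt_s = dt_s, onset_s = onset_s,
       offset_s = offset_s, sweep_s = sweep_s)
}

# Triangular spike waveform added at each planted spike time: 0.5 ms rise to
# +30 mV, 1 ms fall. The 0-mV upward crossing lands within ~0.4 ms of the
# planted time.
add_spikes <- function(vm, times, spike_times, peak_mV = 30) {
  for (ts in spike_times) {
    rise <- times >= ts & times < ts + 5e-4
    fall <- times >= ts + 5e-4 & times < ts + 15e-4
    vm[rise] <- peak_mV - (peak_mV - vm[rise]) * (1 - (times[rise] - ts) / 5e-4)
    vm[fall] <- vm[fall] + (peak_mV - vm[fall]) *
      (1 - (times[fall] - ts - 5e-4) / 1e-3)
  }
  vm
}

#' Synthesize one cell's current-clamp recording from an archetype
#'
#' Step sweeps show the archetype's sag (a double-exponential
#' hyperpolarization transient riding on the steady-state deflection at
#' -120 pA), its subthreshold ramp, and spiking at and above the planted
#' rheobase with the planted first-spike latency; the instantaneous
#' frequency in the first 100 ms reaches the planted maximum on the
#' strongest step. The optogenetic sweep carries the archetype's PSP shape
#' around an 8-pulse 30-Hz train. Ground-truth features are returned
#' alongside.
#'
#' @param arch An [ephys_archetype()].
#' @param protocol A [default_step_protocol()].
#' @param seed Integer seed.
#' @param opto Also synthesize the optogenetic sweep (default TRUE).
#'
#' @return List with `recording` (an [ephys_recording()]) and `truth`
#'   (one-row tibble of planted feature values).
#' @export
gen_ephys_cell <- function(arch, protocol = default_step_protocol(),
                           seed = 1L, opto = TRUE) {
  stopifnot(inherits(arch, "ephys_archetype"))
  if (!any(abs(protocol$currents_pA + 120) < 1e-9)) {
    stop_sociodyn("protocol must include a -120 pA step (sag undefined without it)")
  }
  times <- seq(0, protocol$sweep_s, by = protocol$dt_s)
  on <- protocol$onset_s
  off <- protocol$offset_s
  instep <- times >= on & times <= off
  tau_m <- arch$input_resistance_MOhm * arch$capacitance_pF / 1e6  # s
  tau_sag <- 0.1
  tau_rise <- 0.01
  # double-exponential sag transient normalized to unit peak
  sag_shape <- function(t) {
    hraw <- exp(-t / tau_sag) - exp(-t / tau_rise)
    tpk <- log(tau_sag / tau_rise) / (1 / tau_rise - 1 / tau_sag)
    hraw / (exp(-tpk / tau_sag) - exp(-tpk / tau_rise))
  }
  with_seed(seed, {
    sweeps <- lapply(protocol$currents_pA, function(I) {
      vm <- rep(arch$resting_mV, length(times))
      defl <- I * arch$input_resistance_MOhm / 1000   # mV
      t_rel <- times[instep] - on
      charge <- 1 - exp(-t_rel / max(tau_m, 1e-4))
      if (I < 0) {
        vm[instep] <- arch$resting_mV + defl * charge
        if (abs(I + 120) < 1e-9 && arch$sag_mV > 0) {
          # scale the transient so the waveform minimum sits exactly
          # sag_mV below the steady-state deflection (the charging curve
          # overlaps the transient, so unit peak scaling would undershoot)
          base <- defl * charge
          shp <- sag_shape(t_rel)
          cc <- stats::uniroot(
            function(c) min(base - c * shp) - (defl - arch$sag_mV),
            lower = 0, upper = 4 * arch$sag_mV + 1
          )$root
          vm[instep] <- arch$resting_mV + base - cc * shp
        }
        # decay back after step end
        post <- times > off
        vm[post] <- arch$resting_mV +
          defl * exp(-(times[post] - off) / max(tau_m, 1e-4))
      } else if (I > 0 && I < arch$rheobase_pA) {
        # subthreshold: planted ramp from the early-window deflection
        d_early <- defl
        ramp <- d_early * (1 + (arch$ramp_ratio_true - 1) * (t_rel - 0.15) / 0.8)
        vm[instep] <- arch$resting_mV + ramp * pmin(charge / charge[t_rel >= 0.05][1L], 1)
        post <- times > off
        vm[post] <- arch$resting_mV +
          (vm[instep][sum(instep)] - arch$resting_mV) *
          exp(-(times[post] - off) / max(tau_m, 1e-4))
      } else if (I >= arch$rheobase_pA) {
        # subthreshold-like depolarization capped below spike threshold
        plateau <- min(defl, 0.6 * abs(arch$resting_mV))
        vm[instep] <- arch$resting_mV + plateau * charge
        top <- max(protocol$currents_pA)
        if (abs(I - top) < 1e-9) {
          # strongest step: immediate burst carrying the planted max
          # instantaneous frequency, then relaxing
          isi0 <- 1 / arch$max_freq_hz
          st <- on + 0.01
          spikes <- st
          isi <- isi0
          while (st + isi < off - 1e-3 && length(spikes) < 60) {
            st <- st + isi
            spikes <- c(spikes, st)
            isi <- isi * 1.6
          }
        } else {
          delay_s <- (arch$firing_delay_ms / 1000) * (arch$rheobase_pA / I)^2
          if (abs(I - arch$rheobase_pA) < 1e-9) {
            delay_s <- arch$firing_delay_ms / 1000
          }
          isi <- 1 / (0.5 * arch$max_freq_hz)
          spikes <- seq(on + delay_s, off - 1e-3, by = isi)
          if (length(spikes) == 0L) spikes <- on + delay_s
        }
        vm <- add_spikes(vm, times, spikes)
      }
      vm <- vm + stats::rnorm(length(vm), 0, arch$noise_sd_mV)
      tibble::tibble(time_s = times, vm_mV = vm)
    })
    names(sweeps) <- as.character(protocol$currents_pA)
    opto_sweep <- NULL
    if (opto) {
      ot <- seq(-5.5, 6, by = 1e-3)
      defl <- rep(0, length(ot))
      pulses <- (0:7) / 30
      if (arch$epsp_amplitude_mV > 0) {
        e_rise <- 0.003
        e_decay <- 0.04
        kern <- function(t) ifelse(t < 0, 0, exp(-t / e_decay) - exp(-t / e_rise))
        resp <- Reduce(`+`, lapply(pulses, function(p) kern(ot - p)))
        defl <- defl + arch$epsp_amplitude_mV * resp / max(resp)
      }
      if (arch$ipsp_amplitude_mV > 0) {
        i_rise <- 0.1
        ik <- ifelse(ot < 0, 0, exp(-ot / arch$ipsp_tau_s) - exp(-ot / i_rise))
        defl <- defl - arch$ipsp_amplitude_mV * ik / max(ik)
      }
      opto_sweep <- list(
        time_s = ot + 5.5,
        vm_mV = arch$resting_mV + defl +
          stats::rnorm(length(ot), 0, arch$noise_sd_mV),
        stim_onset_s = 5.5,
        pulse_times_s = 5.5 + pulses
      )
    }
    rec <- ephys_recording(sweeps, step_onset_s = on, step_offset_s = off,
                           opto = opto_sweep, cell = arch$name)
    truth <- tibble::tibble(
      name = arch$name, sag_mV = arch$sag_mV,
      ramp_ratio = arch$ramp_ratio_true,
      firing_delay_ms = arch$firing_delay_ms,
      max_freq_inst_hz = arch$max_freq_hz,
      capacitance_pF = arch$capacitance_pF,
      psp_type = arch$psp_type,
      epsp_amplitude_mV = arch$epsp_amplitude_mV,
      ipsp_amplitude_mV = arch$ipsp_amplitude_mV,
      ipsp_tau_s = arch$ipsp_tau_s
    )
    list(recording = rec, truth = truth)
  })
}

#' Generate a feature-space population from archetype centers
#'
#' Draws per-cell intrinsic features as Gaussian deviates around each
#' archetype's planted values, optionally coupling the opto response class
#' to the archetype (e.g. late-firing cells enriched for excitation).
#'
#' @param archetypes List of [ephys_archetype()]s (or a named list of
#'   feature centers).
#' @param n_per Cells per archetype.
#' @param feature_sd Named numeric SDs per feature (defaults to 1/8 of the
#'   between-archetype range).
#' @param response_probs Optional named list: for each archetype name, a
#'   probability vector over response classes.
#' @param seed Integer seed.
#'
#' @return Tibble, one row per cell: `cell`, `archetype`, features, and
#'   `response_class` when `response_probs` given.
#' @export
gen_feature_population <- function(archetypes, n_per = 20, feature_sd = NULL,
                                   response_probs = NULL, seed = 1L) {
  feats <- c("sag_mV", "ramp_ratio_true", "firing_delay_ms", "max_freq_hz",
             "capacitance_pF")
  centers <- do.call(rbind, lapply(archetypes, function(a) {
    unlist(a[feats])
  }))
  out_names <- c("sag_mV", "ramp_ratio", "firing_delay_ms",
                 "max_freq_inst_hz", "capacitance_pF")
  if (is.null(feature_sd)) {
    spread <- apply(centers, 2L, function(x) diff(range(x)))
    feature_sd <- pmax(spread / 8, c(0.1, 0.02, 2, 1, 2))
  }
  with_seed(seed, {
    rows <- lapply(seq_along(archetypes), function(i) {
      a <- archetypes[[i]]
      vals <- vapply(seq_along(feats), function(j) {
        stats::rnorm(n_per, centers[i, j], feature_sd[j])
      }, numeric(n_per))
      d <- tibble::as_tibble(as.data.frame(vals))
      names(d) <- out_names
      d$archetype <- a$name
      if (!is.null(response_probs)) {
        pr <- response_probs[[a$name]]
        d$response_class <- sample(names(pr), n_per, replace = TRUE, prob = pr)
      }
      d
    })
    dplyr::bind_rows(rows) |>
      dplyr::mutate(cell = paste0("cell", dplyr::row_number()),
                    .before = 1L)
  })
}

#' Simulate round-robin tube-test contests
#'
#' All pairs of subjects meet once per day; the higher-ranked subject wins
#' with probability given by a logistic function of the latent-rank gap
#' (an infinite gap is deterministic).
#'
#' @param latent_ranks Named numeric vector of latent dominance scores.
#' @param days Number of round-robin days (default 2).
#' @param beta Logistic slope on the rank difference (default 1).
#' @param seed Integer seed.
#'
#' @return Tibble `day`, `subject_a`, `subject_b`, `winner` (subject id).
#' @export
gen_tube_contests <- function(latent_ranks, days = 2, beta = 1, seed = 1L) {
  if (length(latent_ranks) < 2L) stop_sociodyn("need at least 2 subjects")
  ids <- names(latent_ranks) %||% paste0("m", seq_along(latent_ranks))
  names(latent_ranks) <- ids
  pairs <- utils::combn(ids, 2L)
  with_seed(seed, {
    rows <- lapply(seq_len(days), function(d) {
      p_a <- stats::plogis(beta * (latent_ranks[pairs[1L, ]] -
                                     latent_ranks[pairs[2L, ]]))
      a_wins <- stats::runif(ncol(pairs)) < p_a
      tibble::tibble(day = d, subject_a = pairs[1L, ], subject_b = pairs[2L, ],
                     winner = ifelse(a_wins, pairs[1L, ], pairs[2L, ]))
    })
    dplyr::bind_rows(rows)
  })
}
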