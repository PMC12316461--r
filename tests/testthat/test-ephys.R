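# Noise-free sweep builders for arithmetic checks on the definitions.
flat_step_sweep <- function(levels_fn, dt = 1e-3, sweep_s = 1.5,
                            onset = 0.25, offset = 1.25) {
  t <- seq(0, sweep_s, by = dt)
  tibble::tibble(time_s = t, vm_mV = levels_fn(t))
}

test_that("sag is steady-state minus peak on the -120 pA step", {
  # piecewise sweep: baseline -70, dips to -100, settles at -90
  sweep <- flat_step_sweep(function(t) {
    ifelse(t < 0.25, -70, ifelse(t < 0.45, -100, ifelse(t <= 1.25, -90, -70)))
  })
  rec <- ephys_recording(list(`-120` = sweep))
  expect_equal(sag_amplitude(rec), 10)
  expect_error(sag_amplitude(ephys_recording(list(`-100` = sweep))), "-120")

  # ohmic synthetic cell: ~0 sag
  g <- gen_ephys_cell(ephys_archetype(sag_mV = 0, noise_sd_mV = 0.05),
                      seed = 70)
  expect_lt(abs(sag_amplitude(g$recording)), 0.3)
})

test_that("ramp ratio divides late by early deflection on the top subthreshold step", {
  # flat plateau: ratio 1
  plateau <- flat_step_sweep(function(t) {
    ifelse(t >= 0.25 & t <= 1.25, -60, -70)
  })
  rec <- ephys_recording(list(`20` = plateau, `-120` = plateau))
  expect_equal(ramp_ratio(rec), 1.0, tolerance = 1e-9)

  # linear ramp: deflection 7.25 + 5 (t - onset) averages 8 mV over the
  # 100-200 ms window (center 150 ms) and 12 mV over 900-1000 ms -> 1.5
  ramp <- flat_step_sweep(function(t) {
    ifelse(t >= 0.25 & t <= 1.25, -70 + 7.25 + 5 * (t - 0.25), -70)
  })
  rec2 <- ephys_recording(list(`40` = ramp))
  expect_equal(ramp_ratio(rec2), 1.5, tolerance = 5e-3)

  # spiking steps are excluded: add a suprathreshold sweep above
  spiking <- flat_step_sweep(function(t) {
    ifelse(t > 0.3 & t < 0.302, 30, -55)
  })
  rec3 <- ephys_recording(list(`40` = ramp, `60` = spiking))
  expect_equal(ramp_ratio(rec3), 1.5, tolerance = 5e-3)

  # no subthreshold depolarizing step -> NA
  expect_true(is.na(ramp_ratio(ephys_recording(list(`-120` = plateau)))))
})

test_that("firing delay uses the lowest spiking step (rheobase)", {
  sub <- flat_step_sweep(function(t) ifelse(t >= 0.25 & t <= 1.25, -60, -70))
  spike_at <- function(ts) {
    flat_step_sweep(function(t) {
      v <- rep(-55, length(t))
      for (s in ts) v[t >= s & t < s + 0.002] <- 25
      v
    })
  }
  rec <- ephys_recording(list(`20` = sub, `40` = spike_at(0.5),
                              `60` = spike_at(0.3)))
  expect_equal(firing_delay(rec), 250, tolerance = 2)
  # raising all currents by one increment keeps rheobase at the lowest
  # spiking step
  rec2 <- ephys_recording(list(`40` = sub, `60` = spike_at(0.5),
                               `80` = spike_at(0.3)))
  expect_equal(firing_delay(rec2), 250, tolerance = 2)
  expect_true(is.na(firing_delay(ephys_recording(list(`20` = sub)))))
})

test_that("max instantaneous frequency uses spike pairs within 100 ms", {
  spike_at <- function(ts) {
    flat_step_sweep(function(t) {
      v <- rep(-55, length(t))
      for (s in ts) v[t >= s & t < s + 0.002] <- 25
      v
    }, dt = 1e-4)
  }
  # two spikes 10 ms apart inside the window -> 100 Hz
  rec <- ephys_recording(list(`100` = spike_at(c(0.26, 0.27))))
  expect_equal(max_inst_freq(rec), 100, tolerance = 2)
  # second pair outside the first 100 ms is ignored
  rec2 <- ephys_recording(list(`100` = spike_at(c(0.26, 0.27, 0.40, 0.402))))
  expect_equal(max_inst_freq(rec2), 100, tolerance = 2)
  # single spike per step -> missing
  rec3 <- ephys_recording(list(`100` = spike_at(0.26),
                               `120` = spike_at(0.30)))
  expect_true(is.na(max_inst_freq(rec3)))
})

test_that("intrinsic features are invariant to a constant Vm offset", {
  arch <- ephys_archetype("probe", sag_mV = 6, ramp_ratio_true = 1.3,
                          firing_delay_ms = 100, max_freq_hz = 50,
                          noise_sd_mV = 0.1)
  g <- gen_ephys_cell(arch, seed = 71)
  rec <- g$recording
  shifted <- rec
  shifted$step_sweeps <- lapply(rec$step_sweeps, function(s) {
    s$vm_mV <- s$vm_mV + 4
    s
  })
  expect_equal(sag_amplitude(shifted), sag_amplitude(rec), tolerance = 1e-9)
  expect_equal(ramp_ratio(shifted), ramp_ratio(rec), tolerance = 1e-9)
  # spike detection at the fixed 0 mV threshold still sees the spikes
  expect_equal(firing_delay(shifted), firing_delay(rec), tolerance = 1)
  expect_equal(max_inst_freq(shifted), max_inst_freq(rec), tolerance = 1)
})

test_that("planted features are recovered across seeded cells", {
  arch <- ephys_archetype("late-firing", sag_mV = 10, ramp_ratio_true = 1.4,
                          firing_delay_ms = 250, max_freq_hz = 80,
                          psp_type = "IPSP", ipsp_amplitude_mV = 5,
                          ipsp_tau_s = 1.0, noise_sd_mV = 0.2)
  for (i in 1:10) {
    g <- gen_ephys_cell(arch, seed = 100 + i)
    f <- extract_ephys_features(g$recording, capacitance = FALSE)
    expect_lt(abs(f$sag_mV - 10), 0.5)
    expect_lt(abs(f$ramp_ratio - 1.4), 0.05)
    expect_lt(abs(f$firing_delay_ms - 250), 10)
    expect_lt(abs(f$max_freq_inst_hz - 80), 5)
    pm <- psp_metrics(g$recording)
    expect_lt(abs(pm$ipsp_decay_tau_s - 1.0) / 1.0, 0.1)
  }
})

test_that("PSP metrics and classification follow the amplitude/area rules", {
  # flat sweep: everything 0, class none
  t <- seq(0, 11, by = 1e-3)
  flat <- list(time_s = t, vm_mV = rep(-70, length(t)), stim_onset_s = 5.5)
  pm <- psp_metrics(flat)
  expect_equal(pm$epsp_peak_mV, 0)
  expect_equal(pm$ipsp_trough_mV, 0)
  expect_equal(pm$voltage_area_mV_s, 0)
  expect_identical(pm$response_class, "none")

  # EPSP only -> excitation, positive area
  e <- gen_ephys_cell(ephys_archetype(psp_type = "EPSP",
                                      epsp_amplitude_mV = 4,
                                      noise_sd_mV = 0.1), seed = 80)
  pme <- psp_metrics(e$recording)
  expect_identical(pme$response_class, "excitation")
  expect_gt(pme$voltage_area_mV_s, 0)

  # IPSP only -> inhibition
  i <- gen_ephys_cell(ephys_archetype(psp_type = "IPSP",
                                      ipsp_amplitude_mV = 5,
                                      noise_sd_mV = 0.1), seed = 81)
  pmi <- psp_metrics(i$recording)
  expect_identical(pmi$response_class, "inhibition")

  # mixed with dominant IPSP -> mixed; area tiebreak annotates inhibition
  m <- gen_ephys_cell(ephys_archetype(psp_type = "mixed",
                                      epsp_amplitude_mV = 3,
                                      ipsp_amplitude_mV = 6,
                                      ipsp_tau_s = 1.5,
                                      noise_sd_mV = 0.1), seed = 82)
  pmm <- psp_metrics(m$recording)
  expect_identical(pmm$response_class, "mixed")
  expect_identical(classify_opto_response(pmm, resolve_mixed = TRUE),
                   "inhibition")

  # IEI rule takes precedence: pre 0.2 s, post 0.1 s -> excitation
  pm_iei <- psp_metrics(i$recording, iei_pre_s = 0.2, iei_post_s = 0.1)
  expect_identical(pm_iei$response_class, "excitation")
  expect_equal(iei_change(c(0.5, 1.0, 2.0, 5.6, 5.7, 5.8), 5.5),
               list(iei_pre_s = 0.75, iei_post_s = 0.1))
})

test_that("baseline clustering separates planted archetypes", {
  arch1 <- ephys_archetype("late-firing", sag_mV = 10, ramp_ratio_true = 1.5,
                           firing_delay_ms = 300, max_freq_hz = 30)
  arch2 <- ephys_archetype("regular-firing", sag_mV = 2,
                           ramp_ratio_true = 1.0, firing_delay_ms = 20,
                           max_freq_hz = 90)
  pop <- gen_feature_population(
    list(arch1, arch2), n_per = 20,
    response_probs = list(`late-firing` = c(excitation = 0.9,
                                            inhibition = 0.1),
                          `regular-firing` = c(excitation = 0.1,
                                               inhibition = 0.9)),
    seed = 90)
  cl <- cluster_baseline(pop, c("sag_mV", "ramp_ratio", "firing_delay_ms",
                                "max_freq_inst_hz"))
  expect_equal(adjusted_rand(cl$clusters$cluster, pop$archetype), 1)
  # normalization maps each feature onto [0, 1] exactly
  expect_equal(unname(apply(cl$normalized, 2, min)), rep(0, 4))
  expect_equal(unname(apply(cl$normalized, 2, max)), rep(1, 4))
  # planted coupling: each cluster enriched for its response class
  comp <- dplyr::count(cl$clusters, cluster, response_class) |>
    tidyr::pivot_wider(names_from = response_class, values_from = n,
                       values_fill = 0L)
  lf_cluster <- cl$clusters$cluster[pop$archetype == "late-firing"][1]
  lf <- comp[comp$cluster == lf_cluster, ]
  rf <- comp[comp$cluster != lf_cluster, ]
  expect_gt(lf$excitation, lf$inhibition)
  expect_gt(rf$inhibition, rf$excitation)

  # constant feature errors with its name
  pop2 <- dplyr::mutate(pop, sag_mV = 5)
  expect_error(cluster_baseline(pop2, c("sag_mV", "ramp_ratio")), "sag_mV")

  # rows with missing features are dropped and counted
  pop3 <- pop
  pop3$ramp_ratio[3] <- NA
  cl3 <- cluster_baseline(pop3, c("sag_mV", "ramp_ratio", "firing_delay_ms",
                                  "max_freq_inst_hz"))
  expect_equal(cl3$n_dropped, 1)
  expect_equal(nrow(cl3$clusters), 39)
})
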