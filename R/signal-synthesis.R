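# Synthetic e-tongue / e-nose signal generator.
#
# The generator emulates the measurement campaign the downstream analysis
# expects: five marked-age classes (3, 5, 8, 10, 20 years) x 40 replicate
# samples, each measured by a 3-electrode pulse-voltammetric e-tongue (two
# waveforms, MRPV and MSPV) and a 12-sensor MOS e-nose. Amplitude structure
# is age-dependent and channels of the same instrument share per-sample
# multiplicative factors, so that features extracted from the same device
# are more correlated with each other than across devices.

ETONGUE_ELECTRODES <- c("E1", "E2", "E3")
ENOSE_SENSORS <- paste0("S", 1:12)
DEFAULT_AGES <- c(3, 5, 8, 10, 20)

# Mean plateau amplitudes (mV) per MOS sensor for the youngest class; the
# S10 value matches the ~2200 mV plateau a TGS2603 sensor shows for a
# 3-year wine.
ENOSE_BASE_MV <- c(S1 = 900, S2 = 2400, S3 = 1500, S4 = 2600, S5 = 1800,
                   S6 = 800, S7 = 2100, S8 = 1300, S9 = 1100, S10 = 2200,
                   S11 = 2500, S12 = 1700)

# Peak-current scale (uA per volt of applied step) per modified electrode;
# electrodes are sensitive to tyrosine, ascorbic acid and glucose whose
# levels rise with aging.
ETONGUE_BASE_UA <- c(E1 = 12, E2 = 10, E3 = 15)

# Monotone age-to-amplitude factors. One e-nose channel (S11) is made
# deliberately non-monotone at 10 years: real score plots show the 10-year
# class breaking the otherwise monotone ordering along the first component.
ENOSE_AGE_FACTOR <- c("3" = 1.00, "5" = 1.08, "8" = 1.16, "10" = 1.22, "20" = 1.32)
ENOSE_AGE_FACTOR_S11 <- c("3" = 1.00, "5" = 1.20, "8" = 1.10, "10" = 0.95, "20" = 1.30)
ETONGUE_AGE_FACTOR <- c("3" = 1.00, "5" = 1.15, "8" = 1.32, "10" = 1.45, "20" = 1.75)

ENOSE_MAX_MV <- 3500

#' Age-class specification for the synthetic generator
#'
#' Describes one marked-age class: how many replicate samples to draw and the
#' mean response amplitude of every channel (mV for the 12 e-nose sensors,
#' uA-per-volt sensitivity for the 3 e-tongue electrodes).
#'
#' @param age_years marked age in years.
#' @param n_samples number of replicate wine samples (default 40).
#' @param channel_amplitudes named numeric vector over channels `E1..E3`,
#'   `S1..S12`; all values must be non-negative. Defaults to the built-in
#'   age-dependent amplitude map.
#' @param noise_sd relative noise level (fraction of amplitude) applied both
#'   multiplicatively to per-trace amplitudes and, scaled down, additively to
#'   individual samples. Default 0.05.
#' @return An object of class `age_class_spec`.
#' @seealso [default_age_specs()], [simulate_dataset()]
#' @export
age_class_spec <- function(age_years, n_samples = 40,
                           channel_amplitudes = default_channel_amplitudes(age_years),
                           noise_sd = 0.05) {
  if (n_samples <= 0) stopf("n_samples must be positive")
  if (any(channel_amplitudes < 0)) stopf("channel amplitudes must be >= 0")
  if (is.null(names(channel_amplitudes))) {
    stopf("channel_amplitudes must be a named vector")
  }
  structure(
    list(age_years = age_years, n_samples = as.integer(n_samples),
         channel_amplitudes = channel_amplitudes, noise_sd = noise_sd),
    class = "age_class_spec"
  )
}

#' Default channel amplitude map for one age class
#'
#' @param age_years one of 3, 5, 8, 10, 20 (other ages interpolate the
#'   monotone factor linearly on log-age).
#' @return Named numeric vector over `E1..E3` and `S1..S12`.
#' @export
default_channel_amplitudes <- function(age_years) {
  key <- as.character(age_years)
  if (key %in% names(ENOSE_AGE_FACTOR)) {
    f_en <- ENOSE_AGE_FACTOR[[key]]
    f_s11 <- ENOSE_AGE_FACTOR_S11[[key]]
    f_et <- ETONGUE_AGE_FACTOR[[key]]
  } else {
    la <- log(as.numeric(age_years))
    lref <- log(DEFAULT_AGES)
    f_en <- stats::approx(lref, ENOSE_AGE_FACTOR, xout = la, rule = 2)$y
    f_s11 <- stats::approx(lref, ENOSE_AGE_FACTOR_S11, xout = la, rule = 2)$y
    f_et <- stats::approx(lref, ETONGUE_AGE_FACTOR, xout = la, rule = 2)$y
  }
  en <- ENOSE_BASE_MV * f_en
  en[["S11"]] <- ENOSE_BASE_MV[["S11"]] * f_s11
  et <- ETONGUE_BASE_UA * f_et
  c(et, en)
}

#' Default study design: five age classes, 40 samples each
#'
#' @param n_samples replicate samples per class (default 40, i.e. 200 total).
#' @param noise_sd relative noise level (default 0.05).
#' @return List of five [age_class_spec()] objects for ages 3, 5, 8, 10, 20.
#' @export
default_age_specs <- function(n_samples = 40, noise_sd = 0.05) {
  lapply(DEFAULT_AGES, function(a) {
    age_class_spec(a, n_samples = n_samples, noise_sd = noise_sd)
  })
}

#' Multi-frequency pulse programs for the e-tongue
#'
#' A pulse program describes the excitation waveform applied to a working
#' electrode: an ordered list of frequency phases (each a frequency and a
#' duration), a sampling interval, the waveform kind and the potential level
#' of every step within one period. `pulse_program_mrpv()` is the
#' multi-frequency rectangle pulse voltammetry program (1 Hz for 11 s, 10 Hz
#' for 1.1 s, 100 Hz for 0.11 s; total 12.21 s); `pulse_program_mspv()` is
#' the staircase variant (1 Hz for 7 s, 10 Hz for 0.7 s, 100 Hz for 0.07 s;
#' total 7.77 s). The default sampling interval of 0.002 s reproduces the
#' instrument's raw data counts: 12.21/0.002 x 3 electrodes = 18315 points
#' for MRPV and 7.77/0.002 x 3 = 11655 for MSPV.
#'
#' @param phases data.frame with columns `freq_hz`, `duration_s`.
#' @param sampling_interval sampling interval in seconds (> 0).
#' @param waveform_kind `"rectangle"` or `"staircase"`.
#' @param potential_levels potential (V) of each step within one period.
#' @return An object of class `pulse_program`.
#' @export
pulse_program <- function(phases, sampling_interval = 0.002,
                          waveform_kind = c("rectangle", "staircase"),
                          potential_levels = c(0.8, 0)) {
  waveform_kind <- match.arg(waveform_kind)
  if (sampling_interval <= 0) stopf("sampling_interval must be positive")
  if (!all(c("freq_hz", "duration_s") %in% names(phases))) {
    stopf("phases needs columns freq_hz and duration_s")
  }
  structure(
    list(phases = phases, sampling_interval = sampling_interval,
         waveform_kind = waveform_kind, potential_levels = potential_levels),
    class = "pulse_program"
  )
}

#' @rdname pulse_program
#' @export
pulse_program_mrpv <- function(sampling_interval = 0.002) {
  pulse_program(
    data.frame(freq_hz = c(1, 10, 100), duration_s = c(11, 1.1, 0.11)),
    sampling_interval = sampling_interval,
    waveform_kind = "rectangle",
    potential_levels = c(0.8, 0)
  )
}

#' @rdname pulse_program
#' @export
pulse_program_mspv <- function(sampling_interval = 0.002) {
  pulse_program(
    data.frame(freq_hz = c(1, 10, 100), duration_s = c(7, 0.7, 0.07)),
    sampling_interval = sampling_interval,
    waveform_kind = "staircase",
    potential_levels = c(0.2, 0.4, 0.6, 0.8)
  )
}

#' Duration, sample count and raw data count of a pulse program
#'
#' `program_duration()` is the sum of phase durations (s).
#' `pulse_sample_count()` is the number of samples one electrode records:
#' `floor(duration / sampling_interval)`. `pulse_data_count()` is the total
#' raw data count across electrodes computed by the protocol arithmetic
#' `duration / sampling_interval x n_electrodes` (18315 for the default MRPV
#' program, 11655 for MSPV).
#'
#' @param program a [pulse_program()].
#' @param n_electrodes number of working electrodes (default 3).
#' @return A numeric scalar.
#' @export
program_duration <- function(program) sum(program$phases$duration_s)

#' @rdname program_duration
#' @export
pulse_sample_count <- function(program) {
  as.integer(floor(program_duration(program) / program$sampling_interval + 1e-9))
}

#' @rdname program_duration
#' @export
pulse_data_count <- function(program, n_electrodes = 3) {
  round(program_duration(program) / program$sampling_interval * n_electrodes, 6)
}

# Step table of a pulse program: one row per potential step over the whole
# program, with absolute start time, duration and potential level.
program_steps <- function(program) {
  lv <- program$potential_levels
  out <- vector("list", nrow(program$phases))
  t0 <- 0
  for (i in seq_len(nrow(program$phases))) {
    freq <- program$phases$freq_hz[i]
    dur <- program$phases$duration_s[i]
    period <- 1 / freq
    n_per <- round(dur * freq)
    step_dur <- period / length(lv)
    n_steps <- n_per * length(lv)
    start <- t0 + (seq_len(n_steps) - 1) * step_dur
    out[[i]] <- data.frame(start = start, duration = step_dur,
                           level = rep(lv, n_per))
    t0 <- t0 + dur
  }
  do.call(rbind, out)
}

#' Signal trace
#'
#' One channel's sampled response for one wine sample: uniformly sampled
#' times (s) and values (uA for e-tongue currents, mV for e-nose voltages).
#'
#' @param sample_id sample identifier.
#' @param device `"etongue"` or `"enose"`.
#' @param channel_id channel label (`"E1a"`..`"E3b"` electrode+waveform, or
#'   `"S1"`..`"S12"`).
#' @param time_s numeric vector of sampling times, strictly increasing.
#' @param value numeric vector, same length as `time_s`.
#' @return An object of class `signal_trace`.
#' @export
signal_trace <- function(sample_id, device, channel_id, time_s, value) {
  if (length(time_s) != length(value)) stopf("time and value lengths differ")
  if (any(diff(time_s) <= 0)) stopf("times must be strictly increasing")
  structure(
    list(sample_id = as.character(sample_id), device = device,
         channel_id = channel_id, time_s = time_s, value = value),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %s %s/%s: %d points over [%.3g, %.3g] s\n",
              x$sample_id, x$device, x$channel_id, length(x$time_s),
              x$time_s[1], x$time_s[length(x$time_s)]))
  invisible(x)
}

# E-nose response shape: exponential rise normalised to reach exactly the
# plateau amplitude at t = t_plateau, flat plateau to t_clean, then
# exponential decay back toward baseline.
enose_curve <- function(t, amplitude, baseline = 0, tau_rise = 3,
                        tau_decay = 40, t_plateau = 10, t_clean = 50) {
  rise <- (1 - exp(-pmin(t, t_plateau) / tau_rise)) /
    (1 - exp(-t_plateau / tau_rise))
  v <- baseline + amplitude * rise
  dec <- t > t_clean
  v[dec] <- baseline + amplitude * exp(-(t[dec] - t_clean) / tau_decay)
  v
}

simulate_enose_trace_impl <- function(age_spec, sensor_id, baseline = 0,
                                      tau_rise = 3, tau_decay = 40,
                                      t_end = 230, dt = 1,
                                      sample_id = "s1") {
  amp_mean <- age_spec$channel_amplitudes[[sensor_id]]
  nsd <- age_spec$noise_sd
  amp <- amp_mean * (1 + if (nsd > 0) nsd * stats::rnorm(1) else 0)
  t <- seq(0, t_end, by = dt)
  v <- enose_curve(t, amp, baseline = baseline, tau_rise = tau_rise,
                   tau_decay = tau_decay)
  if (nsd > 0) v <- v + stats::rnorm(length(v), 0, nsd * 0.1 * abs(amp_mean))
  v <- pmin(pmax(v, 0), ENOSE_MAX_MV)
  signal_trace(sample_id, "enose", sensor_id, t, v)
}

#' Simulate one e-nose sensor trace
#'
#' Adsorption/desorption response of a MOS gas sensor over 0-230 s sampled
#' at 1 Hz: rapid rise to the plateau amplitude within 10 s, stable plateau
#' until the 50th second (exposure phase), then exponential decay toward
#' baseline during cleaning (50-230 s). The plateau amplitude is drawn from
#' the class's channel amplitude with multiplicative Gaussian noise; values
#' are clipped to the instrument range 0-3500 mV.
#'
#' @param age_spec an [age_class_spec()].
#' @param sensor_id one of `"S1"`..`"S12"`.
#' @param seed integer RNG seed.
#' @param baseline baseline voltage (mV), default 0.
#' @param tau_rise,tau_decay rise/decay time constants (s).
#' @param sample_id identifier stored in the trace.
#' @return A [signal_trace()].
#' @export
simulate_enose_trace <- function(age_spec, sensor_id, seed, baseline = 0,
                                 tau_rise = 3, tau_decay = 40,
                                 sample_id = "s1") {
  if (!sensor_id %in% ENOSE_SENSORS) {
    stopf("unknown sensor_id '%s'; valid channels: %s",
          sensor_id, paste(ENOSE_SENSORS, collapse = ", "))
  }
  with_seed(seed, simulate_enose_trace_impl(
    age_spec, sensor_id, baseline = baseline, tau_rise = tau_rise,
    tau_decay = tau_decay, sample_id = sample_id))
}

simulate_etongue_trace_impl <- function(age_spec, electrode_id, program,
                                        tau = 0.05, iss_frac = 0.35,
                                        sample_id = "s1",
                                        waveform_code = NULL) {
  steps <- program_steps(program)
  dt <- program$sampling_interval
  n <- pulse_sample_count(program)
  t <- (1:n) * dt
  nsd <- age_spec$noise_sd
  amp_mean <- age_spec$channel_amplitudes[[electrode_id]]
  amp <- amp_mean * (1 + if (nsd > 0) nsd * stats::rnorm(1) else 0)
  idx <- findInterval(t - 1e-12, steps$start)
  t_in <- t - steps$start[idx]
  i_peak <- amp * steps$level[idx]
  i_ss <- iss_frac * i_peak
  v <- i_ss + (i_peak - i_ss) * exp(-t_in / tau)
  if (nsd > 0) v <- v + stats::rnorm(n, 0, nsd * 0.1 * abs(amp_mean))
  code <- waveform_code %||%
    if (program$waveform_kind == "rectangle") "a" else "b"
  signal_trace(sample_id, "etongue", paste0(electrode_id, code), t, v)
}

#' Simulate one e-tongue electrode trace
#'
#' Current response of a modified working electrode under a multi-frequency
#' pulse program. Within every potential step the current follows a
#' capacitive-decay transient `i(t) = I_ss + (I_peak - I_ss) exp(-t/tau)`,
#' where the peak current is linear in the applied potential level and in
#' the class's analyte-level parameter for that electrode. The trace has
#' `floor(duration / sampling_interval)` samples.
#'
#' @param age_spec an [age_class_spec()].
#' @param electrode_id one of `"E1"`, `"E2"`, `"E3"`.
#' @param program a [pulse_program()].
#' @param seed integer RNG seed.
#' @param tau transient time constant (s), default 0.05.
#' @param iss_frac steady-state current as a fraction of the peak current.
#' @param sample_id identifier stored in the trace.
#' @return A [signal_trace()] with channel id `<electrode><a|b>` (a = MRPV
#'   rectangle, b = MSPV staircase).
#' @export
simulate_etongue_trace <- function(age_spec, electrode_id, program, seed,
                                   tau = 0.05, iss_frac = 0.35,
                                   sample_id = "s1") {
  if (!electrode_id %in% ETONGUE_ELECTRODES) {
    stopf("unknown electrode_id '%s'; valid channels: %s",
          electrode_id, paste(ETONGUE_ELECTRODES, collapse = ", "))
  }
  with_seed(seed, simulate_etongue_trace_impl(
    age_spec, electrode_id, program, tau = tau, iss_frac = iss_frac,
    sample_id = sample_id))
}

#' Simulate a full labelled dataset of e-tongue and e-nose traces
#'
#' Draws, for every class and replicate sample, 3 electrodes x 2 waveforms
#' e-tongue traces and 12 e-nose sensor traces (18 traces per sample; the
#' default design yields 200 samples). Channels of the same device share a
#' per-sample multiplicative factor, so features extracted from the same
#' device end up more correlated with each other than across devices —
#' the multicollinearity structure the fusion stage is designed to prune.
#'
#' @param specs list of [age_class_spec()] objects; ages must be distinct.
#' @param seed integer RNG seed; identical seeds give identical datasets.
#' @param program_mrpv,program_mspv the two [pulse_program()]s.
#' @param tau,iss_frac,tau_rise,tau_decay curve-shape constants, see the
#'   trace simulators.
#' @return A list with `traces` (list of [signal_trace()]) and `labels`
#'   (data.frame `sample_id`, `age_years`).
#' @export
simulate_dataset <- function(specs = default_age_specs(), seed = 1,
                             program_mrpv = pulse_program_mrpv(),
                             program_mspv = pulse_program_mspv(),
                             tau = 0.05, iss_frac = 0.35,
                             tau_rise = 3, tau_decay = 40) {
  ages <- vapply(specs, function(s) s$age_years, numeric(1))
  if (anyDuplicated(ages)) stopf("duplicate age classes in spec list")
  with_seed(seed, {
    traces <- list()
    sample_id <- character(0)
    age_years <- numeric(0)
    for (sp in specs) {
      nsd <- sp$noise_sd
      for (i in seq_len(sp$n_samples)) {
        sid <- sprintf("y%02d_s%02d", sp$age_years, i)
        # shared per-sample device factors drive within-device correlation
        g_et <- 1 + if (nsd > 0) nsd * stats::rnorm(1) else 0
        g_en <- 1 + if (nsd > 0) nsd * stats::rnorm(1) else 0
        amps <- sp$channel_amplitudes
        amps[ETONGUE_ELECTRODES] <- amps[ETONGUE_ELECTRODES] * g_et
        amps[ENOSE_SENSORS] <- amps[ENOSE_SENSORS] * g_en
        sp_i <- sp
        sp_i$channel_amplitudes <- amps
        for (e in ETONGUE_ELECTRODES) {
          traces[[length(traces) + 1L]] <- simulate_etongue_trace_impl(
            sp_i, e, program_mrpv, tau = tau, iss_frac = iss_frac,
            sample_id = sid, waveform_code = "a")
          traces[[length(traces) + 1L]] <- simulate_etongue_trace_impl(
            sp_i, e, program_mspv, tau = tau, iss_frac = iss_frac,
            sample_id = sid, waveform_code = "b")
        }
        for (s in ENOSE_SENSORS) {
          traces[[length(traces) + 1L]] <- simulate_enose_trace_impl(
            sp_i, s, tau_rise = tau_rise, tau_decay = tau_decay,
            sample_id = sid)
        }
        sample_id <- c(sample_id, sid)
        age_years <- c(age_years, sp$age_years)
      }
    }
    list(traces = traces,
         labels = data.frame(sample_id = sample_id, age_years = age_years))
  })
}
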