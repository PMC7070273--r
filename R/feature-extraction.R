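# Area-method feature extraction.
#
# Every trace is reduced to integrals of the response curve over defined
# time windows ("area method"): per e-tongue trace one area per frequency
# phase (3 phases x 2 waveforms x 3 electrodes = 18 features), per e-nose
# trace the exposure-window area (0-50 s, "taste") and the cleaning-window
# area (50-230 s, "aftertaste"), 12 sensors x 2 = 24 features.

#' Canonical feature name sets
#'
#' `etongue_feature_names()` returns `E{1..3}{a,b}{1..3}` (electrode x
#' waveform x frequency phase, 18 names; or 6 names `E{1..3}{a,b}` when
#' phases are collapsed); `enose_feature_names()` returns `S{1..12}a{1,2}`
#' (24 names).
#'
#' @param collapse_phases if `TRUE`, one area per electrode x waveform.
#' @return Character vector of feature names in canonical column order.
#' @export
etongue_feature_names <- function(collapse_phases = FALSE) {
  if (collapse_phases) {
    as.vector(t(outer(ETONGUE_ELECTRODES, c("a", "b"), paste0)))
  } else {
    unlist(lapply(ETONGUE_ELECTRODES, function(e) {
      unlist(lapply(c("a", "b"), function(w) paste0(e, w, 1:3)))
    }))
  }
}

#' @rdname etongue_feature_names
#' @export
enose_feature_names <- function() {
  unlist(lapply(ENOSE_SENSORS, function(s) paste0(s, "a", 1:2)))
}

#' Area under a response curve
#'
#' Trapezoidal integral of a trace over a time window. Window boundaries
#' that fall between sampling points are handled by linear interpolation;
#' windows sharing a boundary are exactly additive.
#'
#' @param trace a [signal_trace()].
#' @param t_start,t_end window in seconds, within the trace span.
#' @return Numeric scalar, units value x seconds.
#' @export
area_under_curve <- function(trace, t_start, t_end) {
  t <- trace$time_s
  v <- trace$value
  if (t_start >= t_end) stopf("t_start must be < t_end")
  eps <- 1e-9
  if (t_start < t[1] - eps || t_end > t[length(t)] + eps) {
    stopf("window [%g, %g] outside trace span [%g, %g]",
          t_start, t_end, t[1], t[length(t)])
  }
  t_start <- max(t_start, t[1])
  t_end <- min(t_end, t[length(t)])
  inner <- t > t_start & t < t_end
  tt <- c(t_start, t[inner], t_end)
  vv <- c(stats::approx(t, v, xout = t_start)$y, v[inner],
          stats::approx(t, v, xout = t_end)$y)
  pracma::trapz(tt, vv)
}

# Index traces by sample_id, returning a named list of channel -> trace maps.
group_traces <- function(traces, device) {
  traces <- Filter(function(tr) tr$device == device, traces)
  out <- list()
  for (tr in traces) {
    out[[tr$sample_id]][[tr$channel_id]] <- tr
  }
  out
}

attach_ages <- function(sample_ids, labels) {
  if (is.null(labels)) return(NULL)
  m <- match(sample_ids, labels$sample_id)
  if (anyNA(m)) stopf("labels missing for samples: %s",
                      paste(sample_ids[is.na(m)], collapse = ", "))
  labels$age_years[m]
}

#' Extract e-tongue area features
#'
#' One area per frequency phase per waveform per electrode. Phase windows
#' are the consecutive 1 Hz, 10 Hz and 100 Hz segments of each pulse
#' program (boundaries at the cumulative phase durations, clipped to the
#' trace span). Yields the 18-column table `E1a1..E3b3`, or a 6-column
#' table (whole-waveform areas `E1a..E3b`) when `collapse_phases = TRUE`.
#'
#' @param traces list of [signal_trace()] objects (other devices ignored).
#' @param program_mrpv,program_mspv the [pulse_program()]s that produced the
#'   `a` and `b` traces; their phase durations define the windows.
#' @param labels optional data.frame `sample_id`, `age_years`.
#' @param collapse_phases collapse the three phase areas per waveform into
#'   one whole-waveform area.
#' @return A [feature_table()] with rows sorted by sample id.
#' @export
extract_etongue_features <- function(traces, program_mrpv = pulse_program_mrpv(),
                                     program_mspv = pulse_program_mspv(),
                                     labels = NULL, collapse_phases = FALSE) {
  by_sample <- group_traces(traces, "etongue")
  if (length(by_sample) == 0) stopf("no e-tongue traces supplied")
  sample_ids <- sort(names(by_sample))
  programs <- list(a = program_mrpv, b = program_mspv)
  needed <- as.vector(t(outer(ETONGUE_ELECTRODES, c("a", "b"), paste0)))
  fnames <- etongue_feature_names(collapse_phases)
  mat <- matrix(NA_real_, length(sample_ids), length(fnames),
                dimnames = list(sample_ids, fnames))
  for (sid in sample_ids) {
    chans <- by_sample[[sid]]
    missing <- setdiff(needed, names(chans))
    if (length(missing) > 0) {
      stopf("sample %s is missing e-tongue traces: %s",
            sid, paste(missing, collapse = ", "))
    }
    for (w in c("a", "b")) {
      prog <- programs[[w]]
      bnd <- cumsum(c(0, prog$phases$duration_s))
      for (e in ETONGUE_ELECTRODES) {
        tr <- chans[[paste0(e, w)]]
        span <- range(tr$time_s)
        if (collapse_phases) {
          mat[sid, paste0(e, w)] <-
            area_under_curve(tr, span[1], min(bnd[length(bnd)], span[2]))
        } else {
          for (f in seq_len(nrow(prog$phases))) {
            t0 <- max(bnd[f], span[1])
            t1 <- min(bnd[f + 1], span[2])
            mat[sid, paste0(e, w, f)] <- area_under_curve(tr, t0, t1)
          }
        }
      }
    }
  }
  feature_table(mat, age_years = attach_ages(sample_ids, labels))
}

#' Extract e-nose area features
#'
#' Per sensor: `S{k}a1` = area over the exposure window 0-50 s (taste
#' information) and `S{k}a2` = area over the cleaning window 50-230 s
#' (aftertaste information); 24 features per sample.
#'
#' @param traces list of [signal_trace()] objects (other devices ignored).
#' @param labels optional data.frame `sample_id`, `age_years`.
#' @param t_split,t_end window boundaries in seconds (defaults 50 and 230).
#' @return A [feature_table()] with rows sorted by sample id.
#' @export
extract_enose_features <- function(traces, labels = NULL,
                                   t_split = 50, t_end = 230) {
  by_sample <- group_traces(traces, "enose")
  if (length(by_sample) == 0) stopf("no e-nose traces supplied")
  sample_ids <- sort(names(by_sample))
  fnames <- enose_feature_names()
  mat <- matrix(NA_real_, length(sample_ids), length(fnames),
                dimnames = list(sample_ids, fnames))
  for (sid in sample_ids) {
    chans <- by_sample[[sid]]
    missing <- setdiff(ENOSE_SENSORS, names(chans))
    if (length(missing) > 0) {
      stopf("sample %s is missing e-nose traces: %s",
            sid, paste(missing, collapse = ", "))
    }
    for (s in ENOSE_SENSORS) {
      tr <- chans[[s]]
      if (max(tr$time_s) < t_end - 1e-9) {
        stopf("sample %s sensor %s trace ends at %g s, before %g s",
              sid, s, max(tr$time_s), t_end)
      }
      mat[sid, paste0(s, "a1")] <- area_under_curve(tr, tr$time_s[1], t_split)
      mat[sid, paste0(s, "a2")] <- area_under_curve(tr, t_split, t_end)
    }
  }
  feature_table(mat, age_years = attach_ages(sample_ids, labels))
}
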