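# Synthetic blood-volume-pulse sessions with HRV-band structure, sparse
# high-arousal "event" chunks, additive noise and motion-artifact impulses,
# and weak session-level labels. Every downstream stage of the package is
# testable against this generator's known chunk-level ground truth.

#' Default IBI modulation bands (HF / LF / VLF)
#'
#' Sinusoidal inter-beat-interval modulations centred in the canonical
#' heart-rate-variability bands: HF (parasympathetic, 0.15-0.4 Hz),
#' LF (mixed sympathetic/parasympathetic, 0.04-0.15 Hz) and
#' VLF (slow hormonal/thermoregulatory influences, < 0.04 Hz).
#'
#' @param phases Numeric vector of 3 phases in radians (HF, LF, VLF).
#' @return List of modulation bands, each `list(freq, amplitude, phase)`
#'   with `freq` in Hz and `amplitude` in seconds of peak IBI deviation.
#' @export
default_bands <- function(phases = c(0, 0, 0)) {
  list(
    list(freq = 0.25, amplitude = 0.03, phase = phases[1]),  # HF
    list(freq = 0.10, amplitude = 0.04, phase = phases[2]),  # LF
    list(freq = 0.02, amplitude = 0.05, phase = phases[3])   # VLF
  )
}

#' Specification of one synthetic BVP session
#'
#' @param duration_s Session length in seconds.
#' @param fs Sampling rate in Hz; fixed at 30.
#' @param hr_base Baseline heart rate in beats per minute (30-180).
#' @param bands List of IBI modulation bands (see [default_bands()]).
#' @param noise_sd Additive white-noise standard deviation (waveform units;
#'   the systolic pulse peak has unit amplitude).
#' @param artifact_rate Motion-artifact impulses per minute.
#' @param event_chunks Integer vector of 0-based 128-frame chunk indices in
#'   which a high-arousal event is implanted.
#' @param event_hr_surge Heart-rate surge (bpm) added inside event chunks.
#' @param event_gain Multiplicative pulse-amplitude factor inside event chunks.
#' @param label_arousal,label_valence `"low"` or `"high"`. By construction
#'   `label_arousal == "high"` iff `event_chunks` is non-empty.
#' @param seed Integer seed driving all randomness for this session.
#' @return A validated `session_spec` list.
#' @export
session_spec <- function(duration_s, fs = 30, hr_base = 70,
                         bands = list(), noise_sd = 0,
                         artifact_rate = 0, event_chunks = integer(0),
                         event_hr_surge = 20, event_gain = 1.5,
                         label_valence = "low", seed = 1L) {
  if (fs != 30) stop("session_spec: fs is fixed at 30 Hz")
  if (hr_base < 30 || hr_base > 180) stop("session_spec: hr_base must lie in [30, 180] bpm")
  n_chunks <- floor(duration_s * fs / 128)
  event_chunks <- as.integer(sort(unique(event_chunks)))
  if (length(event_chunks) > 0 &&
      (min(event_chunks) < 0 || max(event_chunks) > n_chunks - 1)) {
    stop("session_spec: event_chunks must be 0-based indices below ", n_chunks)
  }
  base_ibi <- 60 / (hr_base + max(0, event_hr_surge * (length(event_chunks) > 0)))
  amps <- vapply(bands, function(b) b$amplitude, numeric(1))
  if (length(amps) && any(amps < 0)) stop("session_spec: band amplitudes must be >= 0")
  if (length(amps) && any(amps >= 0.5 * base_ibi)) {
    stop("session_spec: a band amplitude reaches half the baseline IBI")
  }
  if (sum(amps) >= base_ibi) {
    stop("session_spec: total modulation amplitude >= baseline IBI would allow non-positive intervals")
  }
  structure(list(
    duration_s = duration_s, fs = fs, hr_base = hr_base, bands = bands,
    noise_sd = noise_sd, artifact_rate = artifact_rate,
    event_chunks = event_chunks, event_hr_surge = event_hr_surge,
    event_gain = event_gain,
    label_arousal = if (length(event_chunks) > 0) "high" else "low",
    label_valence = label_valence,
    n_chunks = n_chunks, seed = as.integer(seed)
  ), class = "session_spec")
}

# TRUE for each time in `t` that falls inside an event chunk of `spec`.
in_event_chunk <- function(t, spec) {
  if (length(spec$event_chunks) == 0L) return(rep(FALSE, length(t)))
  chunk <- floor(t * spec$fs / 128)
  chunk %in% spec$event_chunks
}

#' Generate beat times for a synthetic session
#'
#' Beats start at t = 0; the n-th inter-beat interval is
#' `60 / hr(t_n) + sum_b amplitude_b * sin(2 pi freq_b t_n + phase_b)`,
#' where `hr(t)` is `hr_base`, raised by `event_hr_surge` while `t_n` lies
#' inside an event chunk.
#'
#' @param spec A [session_spec()].
#' @return Strictly increasing numeric vector of beat times in seconds,
#'   covering `[0, duration_s)`.
#' @export
generate_beat_times <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  beats <- numeric(ceiling(spec$duration_s * spec$hr_base / 60) + 16L)
  t <- 0
  n <- 0L
  while (t < spec$duration_s) {
    n <- n + 1L
    if (n > length(beats)) beats <- c(beats, numeric(length(beats)))
    beats[n] <- t
    hr <- spec$hr_base + spec$event_hr_surge * in_event_chunk(t, spec)
    ibi <- 60 / hr
    for (b in spec$bands) {
      ibi <- ibi + b$amplitude * sin(2 * pi * b$freq * t + b$phase)
    }
    if (ibi <= 0) stop("generate_beat_times: non-positive inter-beat interval")
    t <- t + ibi
  }
  beats[seq_len(n)]
}

# Two-lobe PPG pulse template added in place: a systolic Gaussian (sd 60 ms,
# unit amplitude) plus a smaller dicrotic Gaussian (relative amplitude 0.35,
# delay 250 ms, sd 90 ms).
PULSE_SYS_SD <- 0.060
PULSE_DIC_SD <- 0.090
PULSE_DIC_AMP <- 0.35
PULSE_DIC_DELAY <- 0.250

#' Render a BVP waveform from beat times
#'
#' Superimposes a two-lobe pulse template (systolic + dicrotic Gaussian) at
#' each beat, scales pulses inside event chunks by `event_gain`, then adds
#' white noise (`noise_sd`) and Poisson-placed motion-artifact impulses
#' (amplitude 5x the pulse peak, 3 samples wide) at `artifact_rate` per
#' minute. Deterministic given `spec$seed`.
#'
#' @param beat_times Numeric vector of beat times within `[0, duration_s)`.
#' @param spec A [session_spec()].
#' @return Numeric waveform of length `round(duration_s * fs)`.
#' @export
render_waveform <- function(beat_times, spec) {
  stopifnot(inherits(spec, "session_spec"))
  if (length(beat_times) && (min(beat_times) < 0 || max(beat_times) >= spec$duration_s)) {
    stop("render_waveform: beat times must lie in [0, duration_s)")
  }
  n <- round(spec$duration_s * spec$fs)
  w <- numeric(n)
  halfwin <- ceiling((PULSE_DIC_DELAY + 5 * PULSE_DIC_SD) * spec$fs)
  lead <- ceiling(5 * PULSE_SYS_SD * spec$fs)
  gains <- ifelse(in_event_chunk(beat_times, spec), spec$event_gain, 1)
  for (i in seq_along(beat_times)) {
    tb <- beat_times[i]
    c0 <- floor(tb * spec$fs)
    idx <- max(0L, c0 - lead):min(n - 1L, c0 + halfwin)
    tt <- idx / spec$fs - tb
    w[idx + 1L] <- w[idx + 1L] + gains[i] *
      (exp(-tt^2 / (2 * PULSE_SYS_SD^2)) +
         PULSE_DIC_AMP * exp(-(tt - PULSE_DIC_DELAY)^2 / (2 * PULSE_DIC_SD^2)))
  }
  set.seed(spec$seed)
  if (spec$noise_sd > 0) w <- w + stats::rnorm(n, 0, spec$noise_sd)
  if (spec$artifact_rate > 0) {
    k <- stats::rpois(1, spec$artifact_rate * spec$duration_s / 60)
    if (k > 0) {
      pos <- sample.int(n - 3L, k, replace = TRUE)
      sgn <- sample(c(-1, 1), k, replace = TRUE)
      for (j in seq_len(k)) {
        w[pos[j]:(pos[j] + 2L)] <- w[pos[j]:(pos[j] + 2L)] + 5 * sgn[j]
      }
    }
  }
  w
}

#' Chunk-level saliency mask for a synthetic session
#'
#' Ground truth for attention-localization diagnostics: `mask[i] = 1` iff
#' chunk `i - 1` (0-based) holds an implanted event.
#'
#' @param spec A [session_spec()].
#' @return Integer 0/1 vector with one entry per chunk.
#' @export
implant_saliency <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  mask <- integer(spec$n_chunks)
  mask[spec$event_chunks + 1L] <- 1L
  mask
}

round_half_up <- function(x) floor(x + 0.5)

#' Generate a synthetic weak-label dataset
#'
#' Builds `n_sessions` synthetic BVP sessions at 30 Hz. Exactly
#' `round(n_sessions * class_fraction_high)` sessions are high-arousal, each
#' with a uniformly drawn number of event chunks from `event_count_range`;
#' low-arousal sessions have none. Arousal ratings are drawn uniformly from
#' 5-9 (high) or 1-4 (low); valence ratings are uniform on 1-9 and, unless
#' `valence_hr_shift > 0`, physiologically inert. Fully deterministic given
#' `seed`.
#'
#' @param n_sessions Number of sessions (>= 2).
#' @param class_fraction_high Fraction of high-arousal sessions, in (0, 1).
#' @param event_count_range Length-2 integer range of event chunks per
#'   high-arousal session.
#' @param duration_s Session duration in seconds.
#' @param noise_sd Additive noise standard deviation.
#' @param seed Integer master seed.
#' @param artifact_rate Artifact impulses per minute.
#' @param event_hr_surge Heart-rate surge (bpm) inside event chunks.
#' @param event_gain Pulse-amplitude gain inside event chunks.
#' @param hr_range Range from which each session's baseline heart rate is
#'   drawn uniformly (bpm).
#' @param valence_hr_shift Optional sustained baseline-HR shift (bpm) for
#'   high-valence sessions; 0 disables any valence physiology.
#' @return A `pm_dataset` list with elements `manifest` (data.frame),
#'   `waveforms` (named list of numeric vectors), `masks` (named list of
#'   saliency masks) and `specs`.
#' @export
generate_dataset <- function(n_sessions, class_fraction_high = 0.5,
                             event_count_range = c(3, 3),
                             duration_s = 86, noise_sd = 0.05, seed = 1L,
                             artifact_rate = 2, event_hr_surge = 20,
                             event_gain = 1.5, hr_range = c(60, 90),
                             valence_hr_shift = 0) {
  if (n_sessions < 2) stop("generate_dataset: need at least 2 sessions")
  if (class_fraction_high <= 0 || class_fraction_high >= 1) {
    stop("generate_dataset: class_fraction_high must be in (0, 1)")
  }
  n_chunks <- floor(duration_s * 30 / 128)
  if (max(event_count_range) > n_chunks) {
    stop("generate_dataset: event_count_range exceeds the ", n_chunks,
         " chunks per session")
  }
  set.seed(seed)
  n_high <- round_half_up(n_sessions * class_fraction_high)
  is_high <- sample(rep(c(TRUE, FALSE), c(n_high, n_sessions - n_high)))
  ids <- sprintf("S%04d", seq_len(n_sessions))
  session_seeds <- sample.int(.Machine$integer.max - 1L, n_sessions)

  specs <- vector("list", n_sessions)
  waveforms <- vector("list", n_sessions)
  masks <- vector("list", n_sessions)
  rating_a <- integer(n_sessions)
  rating_v <- integer(n_sessions)
  for (i in seq_len(n_sessions)) {
    rating_a[i] <- if (is_high[i]) sample(5:9, 1) else sample(1:4, 1)
    rating_v[i] <- sample(1:9, 1)
    ev <- integer(0)
    if (is_high[i]) {
      k <- if (event_count_range[1] == event_count_range[2]) {
        event_count_range[1]
      } else {
        sample(event_count_range[1]:event_count_range[2], 1)
      }
      ev <- sort(sample.int(n_chunks, k) - 1L)
    }
    hr <- stats::runif(1, hr_range[1], hr_range[2]) +
      valence_hr_shift * (rating_v[i] >= 5)
    specs[[i]] <- session_spec(
      duration_s = duration_s, hr_base = hr,
      bands = default_bands(stats::runif(3, 0, 2 * pi)),
      noise_sd = noise_sd, artifact_rate = artifact_rate,
      event_chunks = ev, event_hr_surge = event_hr_surge,
      event_gain = event_gain,
      label_valence = if (rating_v[i] >= 5) "high" else "low",
      seed = session_seeds[i])
    waveforms[[i]] <- render_waveform(generate_beat_times(specs[[i]]), specs[[i]])
    masks[[i]] <- implant_saliency(specs[[i]])
  }
  names(waveforms) <- ids
  names(masks) <- ids
  names(specs) <- ids
  manifest <- data.frame(
    session_id = ids,
    file = paste0(ids, ".csv"),
    fs = 30L,
    n_samples = vapply(waveforms, length, integer(1)),
    rating_arousal = rating_a,
    rating_valence = rating_v,
    split = "unassigned",
    seed = session_seeds,
    stringsAsFactors = FALSE
  )
  rownames(manifest) <- NULL
  structure(list(manifest = manifest, waveforms = waveforms,
                 masks = masks, specs = specs),
            class = "pm_dataset")
}
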