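# Seeded surrogate-EEG generator.
#
# Surrogate model: 1/f^alpha colored-noise background (unit sd) + narrow-band
# sinusoidal components with random phase/frequency jitter + class-specific
# transients (biphasic interictal spikes at Poisson times; rhythmic 3-12 Hz
# high-amplitude bursts for the ictal class) + additive white noise.
# Amplitudes are on an arbitrary unit scale (background sd 1); the class
# structure is what matters, not physiological realism.

#' Construct a surrogate-class profile
#'
#' @param class_name Surrogate class label, one of `"A"`..`"E"` (mirrors the
#'   Bonn sets: healthy eyes-open, healthy eyes-closed, interictal
#'   contralateral, interictal epileptogenic-zone, ictal).
#' @param background_exponent Spectral slope alpha of the 1/f^alpha background.
#' @param band_peaks List of numeric triplets `c(center_hz, bandwidth_hz,
#'   relative_power)`; each contributes a random-phase sinusoid whose
#'   frequency is jittered uniformly within the bandwidth and whose power
#'   (in units of background variance) is `relative_power`.
#' @param spike_rate Interictal spike events per second (Poisson).
#' @param spike_amplitude Peak amplitude of the biphasic spike template,
#'   in background-sd units.
#' @param burst_amplitude_gain Carrier amplitude of ictal rhythmic bursts in
#'   background-sd units; 0 disables bursts.
#' @param burst_band Two-element numeric, Hz range the burst carrier
#'   frequencies are drawn from.
#' @param noise_sd Additive white-noise standard deviation.
#' @return Object of class `class_profile`.
#' @export
class_profile <- function(class_name,
                          background_exponent = 1,
                          band_peaks = list(),
                          spike_rate = 0,
                          spike_amplitude = 0,
                          burst_amplitude_gain = 0,
                          burst_band = c(3, 12),
                          noise_sd = 0.3) {
  stopifnot(class_name %in% c("A", "B", "C", "D", "E"))
  nonneg <- c(background_exponent, spike_rate, spike_amplitude,
              burst_amplitude_gain, noise_sd,
              unlist(band_peaks, use.names = FALSE))
  if (any(!is.finite(nonneg)) || any(nonneg < 0)) {
    stop("class_profile: rates, gains, powers and sds must be finite and >= 0",
         call. = FALSE)
  }
  for (p in band_peaks) {
    if (length(p) != 3L) {
      stop("class_profile: each band peak is c(center_hz, bandwidth_hz, power)",
           call. = FALSE)
    }
  }
  stopifnot(length(burst_band) == 2L, burst_band[1] < burst_band[2])
  structure(
    list(class_name = class_name,
         background_exponent = background_exponent,
         band_peaks = band_peaks,
         spike_rate = spike_rate,
         spike_amplitude = spike_amplitude,
         burst_amplitude_gain = burst_amplitude_gain,
         burst_band = burst_band,
         noise_sd = noise_sd),
    class = "class_profile"
  )
}

#' Default surrogate profiles for the five classes
#'
#' A: weak 8-13 Hz alpha over a 1/f background (healthy, eyes open).
#' B: dominant alpha peak (healthy, eyes closed).
#' C: slowed background with sparse interictal spikes (contralateral
#' hippocampus). D: more slowing and frequent, larger spikes (epileptogenic
#' zone). E: rhythmic 3-12 Hz bursts at `burst_amplitude_gain` times the
#' background sd (ictal).
#'
#' @param burst_amplitude_gain Ictal burst gain, default 5.
#' @return Named list of [class_profile()]s, one per class `"A"`..`"E"`.
#' @export
default_profiles <- function(burst_amplitude_gain = 5) {
  list(
    A = class_profile("A", background_exponent = 1.0,
                      band_peaks = list(c(10, 2, 0.5))),
    B = class_profile("B", background_exponent = 1.0,
                      band_peaks = list(c(10, 2, 1.5))),
    C = class_profile("C", background_exponent = 1.3,
                      band_peaks = list(c(6, 2, 0.6)),
                      spike_rate = 0.3, spike_amplitude = 3),
    D = class_profile("D", background_exponent = 1.5,
                      band_peaks = list(c(5, 2, 0.6)),
                      spike_rate = 0.7, spike_amplitude = 4),
    E = class_profile("E", background_exponent = 1.0,
                      burst_amplitude_gain = burst_amplitude_gain)
  )
}

# 1/f^alpha noise via spectral shaping, scaled to unit sd.
.colored_noise <- function(n, alpha) {
  w <- stats::rnorm(n)
  if (alpha == 0) return(w)
  sp <- stats::fft(w)
  # two-sided frequency index; DC term zeroed so the background is mean-free
  k <- c(0, seq_len(n - 1))
  k <- pmin(k, n - k)
  shape <- c(0, k[-1]^(-alpha / 2))
  x <- Re(stats::fft(sp * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

# biphasic spike template (derivative-of-Gaussian), peak amplitude 1
.spike_template <- function(fs, sigma_s = 0.02) {
  t <- seq(-3 * sigma_s, 3 * sigma_s, by = 1 / fs)
  s <- -t / sigma_s * exp(-t^2 / (2 * sigma_s^2))
  s / max(abs(s))
}

#' Generate one surrogate EEG record
#'
#' Deterministic given `(profile, n_points, fs, seed)`.
#'
#' @param profile A [class_profile()].
#' @param n_points Number of samples (default mirrors the Bonn records).
#' @param fs Sampling frequency in Hz.
#' @param seed Integer seed.
#' @return An [eeg_record()] whose `set_id` is the profile's class.
#' @export
generate_record <- function(profile, n_points = BONN_N_POINTS, fs = BONN_FS,
                            seed = 1L) {
  stopifnot(inherits(profile, "class_profile"))
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 1) {
    stop("generate_record: n_points must be >= 1", call. = FALSE)
  }
  n_points <- as.integer(n_points)
  for (p in profile$band_peaks) {
    if (p[1] >= fs / 2) {
      stop("generate_record: band peak center must lie below fs/2",
           call. = FALSE)
    }
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  tt <- (seq_len(n_points) - 1) / fs
  dur <- n_points / fs
  x <- .colored_noise(n_points, profile$background_exponent)

  for (p in profile$band_peaks) {
    f0 <- p[1] + stats::runif(1, -p[2] / 2, p[2] / 2)
    amp <- sqrt(2 * p[3])
    x <- x + amp * sin(2 * pi * f0 * tt + stats::runif(1, 0, 2 * pi))
  }

  if (profile$spike_rate > 0 && profile$spike_amplitude > 0) {
    tpl <- .spike_template(fs)
    n_spikes <- stats::rpois(1, profile$spike_rate * dur)
    if (n_spikes > 0) {
      at <- sort(as.integer(stats::runif(n_spikes, 1, n_points - length(tpl))))
      for (i0 in at) {
        idx <- i0:(i0 + length(tpl) - 1L)
        x[idx] <- x[idx] + profile$spike_amplitude *
          stats::runif(1, 0.8, 1.2) * tpl
      }
    }
  }

  if (profile$burst_amplitude_gain > 0) {
    t_cur <- stats::runif(1, 0, 0.5)
    while (t_cur < dur) {
      blen <- stats::runif(1, 1.5, 3)
      f0 <- stats::runif(1, profile$burst_band[1], profile$burst_band[2])
      ph <- stats::runif(1, 0, 2 * pi)
      i0 <- max(1L, as.integer(t_cur * fs) + 1L)
      i1 <- min(n_points, as.integer((t_cur + blen) * fs))
      if (i1 > i0) {
        idx <- i0:i1
        env <- sin(pi * seq_along(idx) / length(idx))^2  # Hann envelope
        x[idx] <- x[idx] + profile$burst_amplitude_gain * env *
          sin(2 * pi * f0 * tt[idx] + ph)
      }
      t_cur <- t_cur + blen + stats::runif(1, 0.3, 1.2)  # inter-burst gap
    }
  }

  x <- x + stats::rnorm(n_points, sd = profile$noise_sd)
  eeg_record(x, fs = fs, set_id = profile$class_name,
             source_id = sprintf("synthetic_%s_seed%d",
                                 profile$class_name, as.integer(seed)))
}

#' Generate a balanced surrogate dataset mirroring the Bonn layout
#'
#' Produces `5 * n_per_class` records (classes A-E). Per-record seeds are
#' derived deterministically from the master seed, so equal seeds give
#' bit-identical datasets.
#'
#' @param n_per_class Records per class.
#' @param n_points Samples per record.
#' @param fs Sampling frequency in Hz.
#' @param seed Master integer seed.
#' @param profiles Named list of [class_profile()]s (default
#'   [default_profiles()]).
#' @return List of [eeg_record()]s ordered A, then B, ... then E.
#' @export
generate_dataset <- function(n_per_class = 100L, n_points = BONN_N_POINTS,
                             fs = BONN_FS, seed = 1L,
                             profiles = default_profiles()) {
  stopifnot(n_per_class >= 1)
  out <- vector("list", 5L * n_per_class)
  k <- 0L
  for (ci in seq_along(profiles)) {
    for (ri in seq_len(n_per_class)) {
      k <- k + 1L
      rec_seed <- (as.integer(seed) + 97L * (k - 1L)) %% 2147483647L
      rec <- generate_record(profiles[[ci]], n_points = n_points, fs = fs,
                             seed = rec_seed)
      rec$source_id <- sprintf("%s%03d_seed%d", rec$set_id, ri, rec_seed)
      out[[k]] <- rec
    }
  }
  out
}

#' Write surrogate records as a Bonn-layout directory tree
#'
#' Creates one folder per set (using `folder_map`) and writes each record as
#' a one-sample-per-line text file, so [load_set()] reads them unchanged.
#'
#' @param records List of [eeg_record()]s.
#' @param dir Output root directory (created if needed).
#' @param folder_map Set-to-folder mapping, default [BONN_FOLDER_MAP].
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(records, dir, folder_map = BONN_FOLDER_MAP) {
  counts <- integer(0)
  for (rec in records) {
    sub <- file.path(dir, folder_map[[rec$set_id]])
    if (!dir.exists(sub)) dir.create(sub, recursive = TRUE)
    n <- if (rec$set_id %in% names(counts)) counts[[rec$set_id]] + 1L else 1L
    counts[rec$set_id] <- n
    write_record(rec, file.path(sub, sprintf("%s%03d.txt",
                                             folder_map[[rec$set_id]], n)))
  }
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
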