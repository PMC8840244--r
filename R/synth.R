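#' Synthetic waveform generator configuration
#'
#' Study conditions for the ground-truth-labelled PPG/ECG/ABP fixture
#' generator. Label distributions default to the large-corpus population
#' statistics (SBP 132.609 +/- 21.703, DBP 63.705 +/- 9.978 mmHg),
#' truncated to the cleaning windows \[80, 190\] / \[50, 120\] with pulse
#' pressure forced into \[20, 120\]. Segments are generated with a margin
#' of `2 x 25` samples beyond 1024 so the derivative stage can trim to
#' exactly 1024 aligned samples.
#'
#' @param n_records Number of segments.
#' @param fs Sampling rate (Hz).
#' @param length Samples per segment (default 1024 + 50 margin).
#' @param hr_range Heart-rate interval in bpm, drawn uniformly per record.
#' @param sbp_mean,sbp_sd,dbp_mean,dbp_sd Label moments in mmHg.
#' @param sbp_range,dbp_range,pp_range Truncation windows in mmHg.
#' @param noise_sd White-noise level as a fraction of the pulse amplitude.
#' @param drift_amplitude Baseline-drift amplitude as a fraction of the
#'   pulse amplitude (0 disables).
#' @param drift_freq Drift frequency in Hz (sub-cardiac).
#' @param distortion_fraction Fraction of records receiving a random
#'   corruption (double-peak, irregular-height, irregular-interval).
#' @param ptt_offset Pulse-transit delay of PPG behind the ECG R-peak, s.
#' @param seed Integer seed fixing the whole draw.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_records = 100, fs = 125, length = 1074,
                         hr_range = c(50, 90),
                         sbp_mean = 132.609, sbp_sd = 21.703,
                         dbp_mean = 63.705, dbp_sd = 9.978,
                         sbp_range = c(80, 190), dbp_range = c(50, 120),
                         pp_range = c(20, 120),
                         noise_sd = 0.02, drift_amplitude = 0,
                         drift_freq = 0.2, distortion_fraction = 0,
                         ptt_offset = 0.25, seed = 1L) {
  if (dbp_mean >= sbp_mean) abort("dbp_mean must be below sbp_mean")
  if (distortion_fraction < 0 || distortion_fraction > 1) {
    abort("distortion_fraction must be in [0, 1]")
  }
  if (drift_freq >= 0.5) abort("drift must be sub-cardiac (< 0.5 Hz)")
  structure(as.list(environment()), class = "synth_config")
}

# single-peaked beta-like beat shape on phase [0, 1); the exponents move the
# systolic peak position/width with SBP and the decay with DBP, so waveform
# morphology carries the blood-pressure information even after per-segment
# normalization. A small fixed dicrotic shoulder adds realism but stays
# below the peak-detection prominence floor.
beat_shape <- function(phase, a, b, dicrotic = 0.08) {
  peak <- a / (a + b) # analytic argmax of the beta bump
  s <- phase^a * (1 - phase)^b / (peak^a * (1 - peak)^b)
  s + dicrotic * exp(-(phase - 0.6)^2 / (2 * 0.1^2))
}

shape_exponents <- function(sbp, dbp) {
  list(abp_a = 1.6 + 2.0 * (sbp - 80) / 110,
       abp_b = 2.8 + 2.5 * (dbp - 50) / 70,
       ppg_a = 1.8 + 2.4 * (sbp - 80) / 110,
       ppg_b = 2.6 + 3.5 * (dbp - 50) / 70)
}

rnorm_trunc <- function(mean, sd, lo, hi) {
  for (i in 1:1000) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  stats::runif(1, lo, hi)
}

# Truncating N(mu, sigma) to [lo, hi] shrinks both moments, so drawing with
# the target moments as parent parameters would undershoot them. Solve for
# parent parameters whose *truncated* moments equal the targets, using the
# closed-form truncated-normal moments in a fixed-point iteration.
trunc_parent_params <- function(target_mean, target_sd, lo, hi) {
  mu <- target_mean; sigma <- target_sd
  for (it in 1:50) {
    a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
    Z <- stats::pnorm(b) - stats::pnorm(a)
    if (Z < 1e-12) break
    da <- stats::dnorm(a); db <- stats::dnorm(b)
    m <- mu + sigma * (da - db) / Z
    v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
    if (v <= 0) break
    mu <- mu + (target_mean - m)
    sigma <- sigma * target_sd / sqrt(v)
  }
  list(mean = mu, sd = sigma)
}

#' Generate a synthetic segment store with ground truth
#'
#' Per record: draw heart rate and truncated-normal SBP/DBP, build a
#' beat-periodic phase, render the ABP beat so the waveform extrema hit
#' DBP/SBP exactly (up to sampling of the peak), render a PPG pulse whose
#' amplitude grows strictly with pulse pressure and whose shape depends on
#' SBP/DBP, render an ECG R-spike train leading the PPG by the
#' pulse-transit offset, then add white noise, optional drift, and the
#' configured fraction of labelled distortions. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return List with `segments` (a `segment_tbl`) and `truth` (tibble:
#'   `segment_id`, `subject_id`, true `sbp`/`dbp`/`map`, `hr`,
#'   `distorted`, `kind`, `beat_starts` list-column).
#' @export
generate_segments <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_records
    L <- cfg$length
    tt <- (seq_len(L) - 1) / cfg$fs
    ids <- sprintf("syn%05d", seq_len(n))
    subj <- sprintf("subj%03d", 1 + (seq_len(n) - 1) %% max(1, ceiling(n / 4)))
    n_dist <- round(cfg$distortion_fraction * n)
    dist_idx <- if (n_dist > 0) sample.int(n, n_dist) else integer()
    kinds <- c("double-peak", "irregular-height", "irregular-interval")

    ppg_l <- abp_l <- ecg_l <- vector("list", n)
    truth <- vector("list", n)
    sbp_par <- trunc_parent_params(cfg$sbp_mean, cfg$sbp_sd,
                                   cfg$sbp_range[1], cfg$sbp_range[2])
    dbp_par <- trunc_parent_params(cfg$dbp_mean, cfg$dbp_sd,
                                   cfg$dbp_range[1], cfg$dbp_range[2])
    for (i in seq_len(n)) {
      hr <- runif(1, cfg$hr_range[1], cfg$hr_range[2])
      # redraw only DBP on a pulse-pressure violation so the SBP marginal
      # keeps the matched truncated-normal moments exactly
      sbp <- rnorm_trunc(sbp_par$mean, sbp_par$sd,
                         cfg$sbp_range[1], cfg$sbp_range[2])
      repeat {
        dbp <- rnorm_trunc(dbp_par$mean, dbp_par$sd,
                           cfg$dbp_range[1], cfg$dbp_range[2])
        pp <- sbp - dbp
        if (pp >= cfg$pp_range[1] && pp <= cfg$pp_range[2]) break
      }
      period <- 60 / hr
      phase0 <- runif(1)
      ptot <- tt / period + phase0
      phase <- ptot - floor(ptot)
      ex <- shape_exponents(sbp, dbp)

      abp_s <- beat_shape(phase, ex$abp_a, ex$abp_b)
      fine <- beat_shape(seq(0, 1, length.out = 4096), ex$abp_a, ex$abp_b)
      abp_s <- (abp_s - min(fine)) / (max(fine) - min(fine))
      abp <- dbp + (sbp - dbp) * abp_s

      pptot <- (tt - cfg$ptt_offset) / period + phase0
      pphase <- pptot - floor(pptot)
      ppg_s <- beat_shape(pphase, ex$ppg_a, ex$ppg_b)
      finep <- beat_shape(seq(0, 1, length.out = 4096), ex$ppg_a, ex$ppg_b)
      ppg_s <- (ppg_s - min(finep)) / (max(finep) - min(finep))
      amp <- 0.5 + 0.01 * pp # strictly increasing in pulse pressure
      ppg <- amp * ppg_s

      ecg <- exp(-(pmin(phase, 1 - phase))^2 / (2 * 0.012^2)) +
        0.15 * exp(-(phase - 0.35)^2 / (2 * 0.05^2)) +
        0.10 * exp(-(phase - 0.85)^2 / (2 * 0.03^2))

      beat_starts <- which(diff(floor(ptot)) == 1) + 1L

      distorted <- i %in% dist_idx
      kind <- if (distorted) sample(kinds, 1) else NA_character_
      if (distorted) {
        w <- distort_channels(ppg, abp, beat_starts, kind,
                              dbp = dbp, pp = pp)
        ppg <- w$ppg; abp <- w$abp
      }

      ppg <- ppg + rnorm(L, 0, cfg$noise_sd * amp)
      abp <- abp + rnorm(L, 0, cfg$noise_sd * pp)
      ecg <- ecg + rnorm(L, 0, cfg$noise_sd)
      if (cfg$drift_amplitude > 0) {
        ph_d <- runif(3, 0, 2 * pi)
        dr <- function(k, scale) {
          cfg$drift_amplitude * scale * sin(2 * pi * cfg$drift_freq * tt + ph_d[k])
        }
        ppg <- ppg + dr(1, amp)
        abp <- abp + dr(2, pp)
        ecg <- ecg + dr(3, 1)
      }
      ppg_l[[i]] <- ppg; abp_l[[i]] <- abp; ecg_l[[i]] <- ecg
      truth[[i]] <- tibble::tibble(
        segment_id = ids[i], subject_id = subj[i], sbp = sbp, dbp = dbp,
        map = dbp + (sbp - dbp) / 3, hr = hr, distorted = distorted,
        kind = kind, beat_starts = list(beat_starts))
    }
    segments <- segment_tbl(ids, subj, cfg$fs, ppg = ppg_l, abp = abp_l,
                            ecg = ecg_l,
                            metadata = list(source = "synthetic",
                                            history = character()))
    list(segments = segments, truth = dplyr::bind_rows(truth))
  })
}

# corruption kernels shared by generate_segments() and inject_distortion()
distort_channels <- function(ppg, abp, beat_starts, kind, dbp = min(abp),
                             pp = max(abp) - min(abp)) {
  L <- length(ppg)
  bounds <- unique(c(1L, beat_starts, L + 1L))
  n_beats <- length(bounds) - 1L
  if (kind == "blank") {
    return(list(ppg = rep(0, L), abp = rep(0, L)))
  }
  if (kind == "double-peak") {
    mids <- floor((bounds[-length(bounds)] + bounds[-1]) / 2)
    spike <- rep(0, L)
    for (m in mids) {
      idx <- max(1, m - 4):min(L, m + 4)
      spike[idx] <- spike[idx] + exp(-(idx - m)^2 / (2 * 1.5^2))
    }
    return(list(ppg = ppg + 0.6 * (max(ppg) - min(ppg)) * spike,
                abp = abp + 0.6 * pp * spike))
  }
  if (kind == "irregular-height") {
    s <- runif(n_beats, 0.5, 1.5)
    for (k in seq_len(n_beats)) {
      idx <- bounds[k]:(bounds[k + 1] - 1L)
      ppg[idx] <- ppg[idx] * s[k]
      abp[idx] <- dbp + (abp[idx] - dbp) * s[k]
    }
    return(list(ppg = ppg, abp = abp))
  }
  if (kind == "irregular-interval") {
    s <- runif(n_beats, 0.5, 1.5)
    # piecewise time warp: stretch each beat by s_k, then resample
    src <- numeric(0)
    for (k in seq_len(n_beats)) {
      idx <- bounds[k]:(bounds[k + 1] - 1L)
      src <- c(src, seq(bounds[k], bounds[k + 1] - 1,
                        length.out = max(2, round(length(idx) * s[k]))))
    }
    src <- src[seq_len(min(length(src), L))]
    if (length(src) < L) src <- c(src, rep(src[length(src)], L - length(src)))
    return(list(ppg = approx(seq_len(L), ppg, xout = src, rule = 2)$y,
                abp = approx(seq_len(L), abp, xout = src, rule = 2)$y))
  }
  abort(sprintf("unknown distortion kind: %s", kind))
}

#' Inject a named distortion into one segment
#'
#' Applies a labelled corruption (the failure modes the quality screen must
#' catch) to the PPG and ABP channels of segment `segment_id`.
#'
#' @param segments A `segment_tbl`.
#' @param segment_id Which record to corrupt.
#' @param kind One of `"double-peak"`, `"irregular-height"`,
#'   `"irregular-interval"`, `"blank"`.
#' @param beat_starts Sample indices of beat onsets (from the generator's
#'   ground truth); inferred from detected ABP peaks when missing.
#' @return The segment table with the corrupted record.
#' @export
inject_distortion <- function(segments, segment_id,
                              kind = c("double-peak", "irregular-height",
                                       "irregular-interval", "blank"),
                              beat_starts = NULL) {
  kind <- match.arg(kind)
  i <- match(segment_id, segments$segment_id)
  if (is.na(i)) abort(sprintf("unknown segment_id %s", segment_id))
  ppg <- segments$ppg[[i]]
  abp <- segments$abp[[i]]
  if (is.null(beat_starts)) {
    pk <- detect_peaks(abp, 0.25 * (max(abp) - min(abp)))
    beat_starts <- pk$index
  }
  w <- distort_channels(ppg, abp, beat_starts, kind)
  segments$ppg[[i]] <- w$ppg
  segments$abp[[i]] <- w$abp
  if (kind == "blank" && !is.null(segments$ecg[[i]])) {
    segments$ecg[[i]] <- rep(0, length(segments$ecg[[i]]))
  }
  segments
}

#' Inject sinusoidal baseline drift
#'
#' Adds a sub-cardiac sinusoid, scaled to each channel's amplitude, to every
#' channel of the selected records (all by default). The return value also
#' carries the injected drift curves in attribute `"drift"` so tests can
#' compare against the clean original.
#'
#' @param segments A `segment_tbl`.
#' @param amplitude Drift amplitude as a fraction of each channel's range.
#' @param freq Drift frequency in Hz (must be sub-cardiac, < 0.5).
#' @param phase Radian phase of the sinusoid.
#' @param ids Segment ids to modify (default all).
#' @return Modified segment table.
#' @export
inject_drift <- function(segments, amplitude, freq = 0.2, phase = 0,
                         ids = NULL) {
  if (freq >= 0.5) abort("drift must be sub-cardiac (< 0.5 Hz)")
  if (amplitude == 0) return(segments)
  ids <- ids %||% segments$segment_id
  drifts <- list()
  for (i in which(segments$segment_id %in% ids)) {
    for (ch in intersect(c("ppg", "ecg", "abp"), names(segments))) {
      x <- segments[[ch]][[i]]
      if (is.null(x) || !length(x)) next
      tt <- (seq_along(x) - 1) / segments$fs[i]
      d <- amplitude * (max(x) - min(x)) * sin(2 * pi * freq * tt + phase)
      segments[[ch]][[i]] <- x + d
      drifts[[paste(segments$segment_id[i], ch, sep = ".")]] <- d
    }
  }
  attr(segments, "drift") <- drifts
  segments
}
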