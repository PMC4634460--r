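#' Parametric beat template
#'
#' One synthetic pulse is the sum of two smooth unimodal bumps: a dominant
#' systolic wave followed by a smaller diastolic (reflection) wave,
#' mirroring the two-wave morphology of a fingertip pulse. The systolic
#' bump is a two-piece Gaussian whose rising side is narrower than its
#' falling side (`systolic_skew < 0`), reproducing the fast upstroke and
#' slow decay of arterial pulses; a symmetric Gaussian would make the APG
#' b/a amplitude ratio identical for every subject, which real cohorts do
#' not show. Centres and widths are expressed as fractions of the beat
#' period so the waveform shape is invariant to heart rate; amplitudes are
#' in arbitrary units. The bumps are evaluated with circularly wrapped
#' distance, so a beat takes exactly the same value at its start and end
#' and consecutive equal-period beats join with no discontinuity.
#'
#' @param systolic_amp,diastolic_amp Bump amplitudes (a.u.);
#'   `systolic_amp > diastolic_amp > 0` unless both are zero.
#' @param systolic_center,diastolic_center Bump centres as fractions of the
#'   period, `0 < systolic_center < diastolic_center < 1`.
#' @param systolic_width,diastolic_width Gaussian standard deviations as
#'   fractions of the period; both positive.
#' @param systolic_skew Asymmetry of the systolic bump in `(-0.8, 0.8)`:
#'   the rising-side width is `systolic_width * (1 + skew)` and the
#'   falling-side width `systolic_width * (1 - skew)`, so negative values
#'   give the physiologic fast-rise/slow-fall shape.
#'
#' @return An object of class `beat_template`.
#' @export
#' @examples
#' tpl <- beat_template()
#' pulse <- generate_beat(tpl, period = 1, fs = 367)
#' length(pulse)
beat_template <- function(systolic_amp = 1, systolic_center = 0.35,
                          systolic_width = 0.13, diastolic_amp = 0.15,
                          diastolic_center = 0.78, diastolic_width = 0.12,
                          systolic_skew = -0.2) {
  zero <- systolic_amp == 0 && diastolic_amp == 0
  if (!zero && !(systolic_amp > diastolic_amp && diastolic_amp > 0)) {
    stop("need systolic_amp > diastolic_amp > 0 (or both zero)", call. = FALSE)
  }
  if (systolic_width <= 0 || diastolic_width <= 0) {
    stop("widths must be positive", call. = FALSE)
  }
  if (!(0 < systolic_center && systolic_center < diastolic_center && diastolic_center < 1)) {
    stop("need 0 < systolic_center < diastolic_center < 1", call. = FALSE)
  }
  if (abs(systolic_skew) >= 0.8) stop("systolic_skew must lie in (-0.8, 0.8)", call. = FALSE)
  structure(
    list(systolic_amp = systolic_amp, systolic_center = systolic_center,
         systolic_width = systolic_width, diastolic_amp = diastolic_amp,
         diastolic_center = diastolic_center, diastolic_width = diastolic_width,
         systolic_skew = systolic_skew),
    class = "beat_template"
  )
}

#' Per-stage generator parameters
#'
#' Everything that varies between protocol stages: the heart-rate
#' distribution, the beat-to-beat jitter feeding heart-rate variability, the
#' additive noise level, and a dimensionless amplitude multiplier carrying
#' the heat-stress effect on pulse volume.
#'
#' @param hr_mean,hr_sd Cohort heart-rate mean and between-subject SD (bpm).
#' @param hr_jitter_sd Beat-to-beat heart-rate jitter SD (bpm); drives RMSSD.
#' @param noise_sd Additive white-Gaussian noise SD (a.u.).
#' @param amp_scale Amplitude multiplier encoding the stress effect on
#'   pulse volume (1 = baseline).
#' @param template A [beat_template()].
#' @return An object of class `stage_params`.
#' @export
stage_params <- function(hr_mean, hr_sd, hr_jitter_sd = 3, noise_sd = 0.05,
                         amp_scale = 1, template = beat_template()) {
  if (hr_mean <= 0) stop("hr_mean must be positive", call. = FALSE)
  if (hr_sd < 0 || hr_jitter_sd < 0 || noise_sd < 0) {
    stop("hr_sd, hr_jitter_sd and noise_sd must be non-negative", call. = FALSE)
  }
  if (amp_scale <= 0) stop("amp_scale must be positive", call. = FALSE)
  stopifnot(inherits(template, "beat_template"))
  structure(
    list(hr_mean = hr_mean, hr_sd = hr_sd, hr_jitter_sd = hr_jitter_sd,
         noise_sd = noise_sd, amp_scale = amp_scale, template = template),
    class = "stage_params"
  )
}

#' Default stage parameters for a heat-stress cohort
#'
#' The study conditions the generator emulates: resting heart rate
#' 76.0 +/- 14.7 bpm before exercise and 133.1 / 143.9 / 138.2 bpm
#' (SD 29.9 / 23.6 / 25.7) after the three exercise bouts. Post-exercise
#' amplitude multipliers are the square roots of the observed aa-energy
#' ratios relative to baseline (energy scales with amplitude squared, with
#' a numerically calibrated correction for the band-pass filter's slightly
#' different attenuation at each heart rate), so PPG aa energies fall by
#' the observed 27--29% after heat stress. All stages share one beat
#' template whose widths are period fractions: the faster post-exercise
#' beats are absolutely narrower and steeper, so APG amplitudes and
#' energies rise sharply while the shape-governed APG b/a ratio stays
#' nearly unchanged. Beat-to-beat jitter is larger at rest (3 bpm vs
#' 2 bpm), reproducing the post-stress drop in RMSSD expected from reduced
#' parasympathetic control.
#'
#' @param effect Scales the departure of each post-exercise stage from
#'   baseline: `effect = 1` is the study-like default, `effect = 0` gives a
#'   null cohort (all stages drawn from the baseline distribution).
#' @return Named list of four [stage_params()] (`BE`, `E1`, `E2`, `E3`).
#' @export
#' @examples
#' heat_stress_stages()$E1$hr_mean
heat_stress_stages <- function(effect = 1) {
  stopifnot(is.numeric(effect), length(effect) == 1L, effect >= 0)
  key <- format(effect, digits = 15)
  hit <- .stage_cache[[key]]
  if (!is.null(hit)) return(hit)
  be <- list(hr_mean = 76.0, hr_sd = 14.7, jit = 3)
  ex <- list(
    E1 = list(hr_mean = 133.1, hr_sd = 29.9, jit = 2, energy_ratio = 580 / 790),
    E2 = list(hr_mean = 143.9, hr_sd = 23.6, jit = 2, energy_ratio = 560 / 790),
    E3 = list(hr_mean = 138.2, hr_sd = 25.7, jit = 2, energy_ratio = 560 / 790)
  )
  blend <- function(x, y) x + effect * (y - x)
  base_tpl <- beat_template()
  out <- list(BE = stage_params(be$hr_mean, be$hr_sd, hr_jitter_sd = be$jit,
                                amp_scale = 1, template = base_tpl))
  # filtered aa energy of a unit-amplitude noiseless record at the stage's
  # mean heart rate and template; used to calibrate amp_scale so the mean
  # aa-energy ratio to baseline equals `er` by construction
  unit_energy <- function(tpl, hr) {
    # deterministic (no jitter, no noise); preserve the caller's RNG state
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    st <- stage_params(hr, 0, hr_jitter_sd = 0, noise_sd = 0, template = tpl)
    rec <- generate_record(st, duration = 20, fs = 367, seed = 1L)
    proc <- process_signal(rec$record)
    energy_aa(proc$ppg_filtered, rec$fiducials) /
      diff(range(rec$fiducials$a))  # per-sample, span-normalized
  }
  e_be <- unit_energy(base_tpl, be$hr_mean)
  for (nm in names(ex)) {
    p <- ex[[nm]]
    hr <- blend(be$hr_mean, p$hr_mean)
    er <- blend(1, p$energy_ratio)
    out[[nm]] <- stage_params(
      hr, blend(be$hr_sd, p$hr_sd),
      hr_jitter_sd = blend(be$jit, p$jit),
      amp_scale = sqrt(er * e_be / unit_energy(base_tpl, hr)),
      template = base_tpl
    )
  }
  .stage_cache[[key]] <- out
  out
}

# calibration cache: the amp_scale computation filters a few reference
# records, which is worth doing only once per effect size
.stage_cache <- new.env(parent = emptyenv())

# Apply subject-level morphology modifiers to a stage template: a common
# width factor, a diastolic amplitude factor, a diastolic centre shift and
# an additive systolic skew shift.
modify_template <- function(template, width_mult = 1, dia_amp_mult = 1,
                            dia_shift = 0, skew_shift = 0) {
  dia_amp <- template$diastolic_amp * dia_amp_mult
  # respect the template invariants under extreme subject draws
  dia_amp <- min(dia_amp, 0.95 * template$systolic_amp)
  dia_center <- template$diastolic_center + dia_shift
  dia_center <- min(max(dia_center, template$systolic_center + 0.05), 0.95)
  beat_template(
    systolic_amp = template$systolic_amp,
    systolic_center = template$systolic_center,
    systolic_width = template$systolic_width * width_mult,
    diastolic_amp = dia_amp,
    diastolic_center = dia_center,
    diastolic_width = template$diastolic_width * width_mult,
    systolic_skew = min(max(template$systolic_skew + skew_shift, -0.7), 0)
  )
}

#' Cohort-level generator configuration
#'
#' @param n_subjects Number of subjects (>= 2); each contributes one record
#'   per stage, paired through subject-level random effects.
#' @param fs Sampling rate in Hz.
#' @param duration Record duration in seconds.
#' @param seed Integer seed; all subject- and record-level randomness is
#'   derived deterministically from it.
#' @param stages Named list of [stage_params()], e.g. [heat_stress_stages()].
#' @param subject_amp_sd SD of the subject-level log-amplitude factor
#'   (multiplicative, shared across stages).
#' @param subject_width_sd SD of the subject-level log-width factor
#'   (beat-morphology heterogeneity, shared across stages).
#' @param subject_dia_amp_sd SD of the subject-level log diastolic-amplitude
#'   factor (strength of the reflection wave).
#' @param subject_dia_shift_sd SD of the subject-level diastolic centre
#'   shift, in fractions of the beat period.
#' @param subject_skew_sd SD of the subject-level additive shift on the
#'   systolic skew (upstroke/decay asymmetry); the main source of
#'   between-subject spread in APG amplitude ratios.
#' @param paired If `TRUE` (default, the within-subject study design) the
#'   subject-level random effects are drawn once per subject and shared
#'   across stages. If `FALSE` every record draws its own effects, making
#'   records independent -- the exchangeable null needed to calibrate
#'   leave-one-out error rates, since shared subject effects leak identity
#'   between a held-out record and its opposite-label siblings.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 40, fs = 367, duration = 20, seed = 1,
                          stages = heat_stress_stages(), subject_amp_sd = 0.065,
                          subject_width_sd = 0.05, subject_dia_amp_sd = 0.10,
                          subject_dia_shift_sd = 0.02, subject_skew_sd = 0.15,
                          paired = TRUE) {
  if (n_subjects < 2) stop("n_subjects must be at least 2", call. = FALSE)
  if (fs <= 14) stop("fs must exceed twice the 7 Hz passband edge", call. = FALSE)
  if (duration * 30 / 60 < 3) stop("duration too short to hold 3 beats at 30 bpm", call. = FALSE)
  stopifnot(length(stages) >= 1L, !is.null(names(stages)))
  for (s in stages) stopifnot(inherits(s, "stage_params"))
  structure(
    list(n_subjects = as.integer(n_subjects), fs = fs, duration = duration,
         seed = as.integer(seed), stages = stages, subject_amp_sd = subject_amp_sd,
         subject_width_sd = subject_width_sd,
         subject_dia_amp_sd = subject_dia_amp_sd,
         subject_dia_shift_sd = subject_dia_shift_sd,
         subject_skew_sd = subject_skew_sd, paired = isTRUE(paired)),
    class = "cohort_config"
  )
}

#' Generate one synthetic pulse
#'
#' Evaluates the two-bump template over one beat period. Wrapped-distance
#' evaluation makes the segment periodic: it starts and ends near baseline
#' at exactly the same level, so consecutive beats concatenate continuously.
#'
#' @param template A [beat_template()].
#' @param period Beat period in seconds.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of `round(period * fs)` samples.
#' @export
generate_beat <- function(template, period, fs) {
  stopifnot(inherits(template, "beat_template"))
  if (!is.numeric(period) || period <= 0) stop("`period` must be positive", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive", call. = FALSE)
  len <- round(period * fs)
  fr <- (seq_len(len) - 1) / len
  wrap <- function(d) d - round(d)  # circular distance in beat fractions
  ds <- wrap(fr - template$systolic_center)
  w_sys <- template$systolic_width *
    ifelse(ds < 0, 1 + template$systolic_skew, 1 - template$systolic_skew)
  template$systolic_amp * exp(-ds^2 / (2 * w_sys^2)) +
    template$diastolic_amp *
    exp(-wrap(fr - template$diastolic_center)^2 / (2 * template$diastolic_width^2))
}

clamp_hr <- function(hr) pmin(220, pmax(30, hr))

#' Generate one synthetic record with ground-truth fiducials
#'
#' Concatenates beats whose periods are drawn from the stage heart-rate
#' distribution (clamped to the physiologic 30--220 bpm range), scales the
#' waveform by the stage and subject amplitude factors, and adds white
#' Gaussian noise. Ground-truth a/b fiducials are derived from the
#' *noise-free* signal by running it through the same preprocessing chain
#' (bandpass + second derivative) and locating waves from the known beat
#' onsets, so they are exactly the indices a perfect annotator would mark.
#'
#' @param stage A [stage_params()].
#' @param duration Record duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Optional integer seed set before any random draw.
#' @param subject_amp Subject-level multiplicative amplitude factor.
#' @param subject_hr_z Subject-level z-score shared across stages; the
#'   subject's stage heart rate is `hr_mean + subject_hr_z * hr_sd`.
#' @param subject_width Subject-level multiplicative factor on both template
#'   widths (beat-morphology heterogeneity, shared across stages).
#' @param subject_dia_amp,subject_dia_shift Subject-level diastolic-wave
#'   modifiers: a multiplicative amplitude factor and an additive centre
#'   shift (fraction of the period).
#' @param subject_skew Subject-level additive shift on the systolic skew;
#'   pulse asymmetry varies strongly between individuals, which is what
#'   makes APG amplitude ratios noisy in real cohorts.
#' @param subject_id,stage_label Metadata stored in the record.
#' @return List with elements `record` (a [ppg_record()] with noise),
#'   `fiducials` (a [fiducial_set()], 0-based), `onsets` (0-based beat
#'   starts) and `clean` (the noise-free samples).
#' @export
#' @examples
#' rec <- generate_record(heat_stress_stages()$BE, seed = 7)
#' rec$record
#' rec$fiducials
generate_record <- function(stage, duration = 20, fs = 367, seed = NULL,
                            subject_amp = 1, subject_hr_z = 0, subject_width = 1,
                            subject_dia_amp = 1, subject_dia_shift = 0,
                            subject_skew = 0,
                            subject_id = "S01", stage_label = "BE") {
  stopifnot(inherits(stage, "stage_params"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- round(duration * fs)
  hr_base <- clamp_hr(stage$hr_mean + subject_hr_z * stage$hr_sd)
  if (n < round(60 / hr_base * fs)) {
    stop("duration too short to fit one beat", call. = FALSE)
  }
  tpl <- if (subject_width == 1 && subject_dia_amp == 1 &&
               subject_dia_shift == 0 && subject_skew == 0) {
    stage$template
  } else {
    modify_template(stage$template, subject_width, subject_dia_amp,
                    subject_dia_shift, subject_skew)
  }
  segs <- list()
  onsets <- integer(0)
  total <- 0L
  while (total < n) {
    hr_i <- clamp_hr(hr_base + rnorm(1L, 0, stage$hr_jitter_sd))
    seg <- generate_beat(tpl, 60 / hr_i, fs)
    onsets <- c(onsets, total)
    segs[[length(segs) + 1L]] <- seg
    total <- total + length(seg)
  }
  clean <- unlist(segs, use.names = FALSE)[seq_len(n)] * stage$amp_scale * subject_amp
  onsets <- onsets[onsets < n]
  proc <- process_signal(ppg_record(clean, fs, subject_id, stage_label))
  fid <- withCallingHandlers(
    locate_ab_waves(proc$apg, onsets),
    warning = function(w) invokeRestart("muffleWarning")  # edge beats are expected drops
  )
  # beats whose filtering is perturbed by the record boundaries are not
  # trustworthy ground truth: drop the first and last located beat
  if (fid$n_beats > 2L) {
    keep <- 2L:(fid$n_beats - 1L)
    fid <- fiducial_set(fid$a[keep], fid$b[intersect(keep, seq_along(fid$b))],
                        n_samples = n)
  }
  noisy <- clean + rnorm(n, 0, stage$noise_sd)
  list(record = ppg_record(noisy, fs, subject_id, stage_label),
       fiducials = fid, onsets = onsets, clean = clean)
}

record_seed <- function(base, subject, stage_index) {
  as.integer((as.numeric(base) + 7919 * subject + 104729 * stage_index) %% 2147483629)
}

#' Generate a paired synthetic cohort
#'
#' One record per subject and stage. Pairing is built in through two
#' subject-level random effects drawn once and shared across stages: a
#' multiplicative log-normal amplitude factor and a heart-rate z-score
#' applied to each stage's distribution. Every record's randomness comes
#' from a substream derived deterministically from the cohort seed, so the
#' same configuration always reproduces the identical cohort.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per record: `subject_id`, `stage` (factor),
#'   `record` (list of [ppg_record()]), `fiducials` (list of
#'   [fiducial_set()]).
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 3, seed = 42)
#' cohort <- generate_cohort(cfg)
#' nrow(cohort)  # 3 subjects x 4 stages
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  stage_names <- names(config$stages)
  draw_effects <- function() {
    list(amp = exp(rnorm(1L, 0, config$subject_amp_sd)),
         hr_z = rnorm(1L),
         width = exp(rnorm(1L, 0, config$subject_width_sd)),
         dia_amp = exp(rnorm(1L, 0, config$subject_dia_amp_sd)),
         dia_shift = rnorm(1L, 0, config$subject_dia_shift_sd),
         skew = rnorm(1L, 0, config$subject_skew_sd))
  }
  rows <- purrr::map(seq_len(config$n_subjects), function(s) {
    set.seed(record_seed(config$seed, s, 0L))
    shared <- draw_effects()
    sid <- sprintf("S%02d", s)
    purrr::imap(config$stages, function(sp, nm) {
      k <- match(nm, stage_names)
      rs <- record_seed(config$seed, s, k)
      eff <- if (config$paired) shared else {
        set.seed((rs + 777L) %% 2147483629L)  # effects stream distinct from the record stream
        draw_effects()
      }
      rec <- generate_record(
        sp, duration = config$duration, fs = config$fs, seed = rs,
        subject_amp = eff$amp, subject_hr_z = eff$hr_z,
        subject_width = eff$width, subject_dia_amp = eff$dia_amp,
        subject_dia_shift = eff$dia_shift, subject_skew = eff$skew,
        subject_id = sid, stage_label = nm
      )
      tibble::tibble(subject_id = sid, stage = nm,
                     record = list(rec$record), fiducials = list(rec$fiducials))
    }) |> purrr::list_rbind()
  })
  out <- purrr::list_rbind(rows)
  out$stage <- factor(out$stage, levels = stage_names)
  out
}
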