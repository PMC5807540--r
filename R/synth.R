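# Synthetic staged sleep EEG with ground truth.
#
# The generator emulates the signal features the downstream pipeline is
# sensitive to: a 1/f background with stage-dependent level and slope,
# sigma-band spindle bursts with a raised-cosine (Hann) envelope and a
# centroparietal gain topography, isolated negative half-wave slow waves with
# a frontal topography, occasional broadband high-power artifact epochs, and
# two-group cohorts in which group B carries multiplicative amplitude
# deficits while event densities are shared.

#' Semi-Markov sleep-stage profile
#'
#' Dwell times are geometric in 30-s epochs with the given means; transitions
#' follow the embedded chain `trans` (rows = from, columns = to).  Transitions
#' into REM are redirected to N2 before `rem_latency_min` minutes, and an
#' initial wake bout with mean `sleep_latency_min` precedes the chain.
#'
#' @param mean_bout_min named numeric: mean bout length per stage, minutes.
#' @param trans 5 x 5 row-stochastic matrix over `W,N1,N2,N3,REM`.
#' @param sleep_latency_min mean initial wake bout, minutes (0 disables).
#' @param rem_latency_min earliest REM onset, minutes.
#' @return Profile list, class `stage_profile`.
#' @export
stage_profile <- function(mean_bout_min = c(W = 1.5, N1 = 1.5, N2 = 10,
                                            N3 = 7, REM = 7),
                          trans = NULL, sleep_latency_min = 5,
                          rem_latency_min = 60) {
  if (is.null(trans)) {
    trans <- rbind(
      W   = c(W = 0,    N1 = 0.80, N2 = 0.20, N3 = 0,    REM = 0),
      N1  = c(W = 0.10, N1 = 0,    N2 = 0.85, N3 = 0,    REM = 0.05),
      N2  = c(W = 0.05, N1 = 0.10, N2 = 0,    N3 = 0.50, REM = 0.35),
      N3  = c(W = 0.05, N1 = 0.05, N2 = 0.90, N3 = 0,    REM = 0),
      REM = c(W = 0.10, N1 = 0.30, N2 = 0.60, N3 = 0,    REM = 0))
  }
  if (!all(SLEEP_STAGES %in% names(mean_bout_min)))
    stopf("mean_bout_min must name all stages")
  if (all(mean_bout_min <= 0)) stopf("degenerate profile: all-zero dwell times")
  if (any(mean_bout_min <= 0)) stopf("mean bout lengths must be positive")
  if (any(abs(rowSums(trans) - 1) > 1e-8)) stopf("trans rows must sum to 1")
  structure(list(mean_bout_min = mean_bout_min[SLEEP_STAGES],
                 trans = trans[SLEEP_STAGES, SLEEP_STAGES],
                 sleep_latency_min = sleep_latency_min,
                 rem_latency_min = rem_latency_min),
            class = "stage_profile")
}

#' Stationary stage fractions of a profile
#'
#' Long-run expected fraction of epochs per stage: the stationary
#' distribution of the embedded transition chain weighted by mean dwell
#' times.  Initial wake and the REM-latency redirection perturb finite
#' realizations away from these values by a few percentage points.
#'
#' @param profile a [stage_profile()].
#' @return Named numeric summing to 1.
#' @export
stationary_stage_fractions <- function(profile) {
  P <- profile$trans
  ev <- eigen(t(P))
  k <- which.min(abs(ev$values - 1))
  pi0 <- abs(Re(ev$vectors[, k]))
  pi0 <- pi0 / sum(pi0)
  w <- pi0 * profile$mean_bout_min
  setNames(w / sum(w), SLEEP_STAGES)
}

#' Generate a synthetic hypnogram
#'
#' @param total_min total recording length in minutes (>= 30).
#' @param seed RNG seed (reproducible).
#' @param profile a [stage_profile()].
#' @return A [hypnogram()] spanning `total_min` minutes.
#' @export
generate_hypnogram <- function(total_min, seed, profile = stage_profile()) {
  if (total_min < 30) stopf("total_min must be >= 30")
  with_seed(seed, {
    n_ep <- as.integer(round(total_min * 2))
    m_ep <- profile$mean_bout_min * 2      # mean dwell in epochs
    draw_dwell <- function(st) 1L + stats::rgeom(1, 1 / m_ep[[st]])
    stages <- character(0)
    if (profile$sleep_latency_min > 0) {
      d <- 1L + stats::rgeom(1, 1 / (profile$sleep_latency_min * 2))
      stages <- rep("W", d)
      cur <- "W"
    } else {
      cur <- sample(SLEEP_STAGES, 1, prob = profile$trans["W", ] + 1e-12)
      stages <- rep(cur, draw_dwell(cur))
    }
    while (length(stages) < n_ep) {
      nxt <- sample(SLEEP_STAGES, 1, prob = profile$trans[cur, ] + 1e-12)
      if (nxt == "REM" && length(stages) * 0.5 < profile$rem_latency_min)
        nxt <- "N2"
      stages <- c(stages, rep(nxt, draw_dwell(nxt)))
      cur <- nxt
    }
    hypnogram(stages[seq_len(n_ep)], lights_off = 0, lights_on = n_ep * 30)
  })
}

#' Synthetic recording configuration
#'
#' Defaults define the reference simulation conditions; see the methods
#' vignette for the rationale behind each value.  Amplitudes are sigma-band
#' envelope peaks (spindles) or half-wave negative peaks (slow waves) at the
#' channel of maximal topographic gain, in microvolts.
#'
#' @param n_channels,fs channel count and sampling rate.
#' @param background per-stage RMS (µV) and 1/f exponent of the noise floor,
#'   plus `delta_scale`, an amplitude multiplier applied below 4.5 Hz (the
#'   slow-wave deficit handle; 1 = none).
#' @param spindle density (events/min per stage), frequency distribution (Hz),
#'   burst duration (s), envelope peak (µV), event/subject log-normal CVs,
#'   topographic Gaussian width (radians of great-circle distance) and
#'   optional `center` channel label (defaults to a centroparietal site).
#' @param slow slow-wave density, half-wave duration range (s), negative peak
#'   amplitude (µV, magnitude), CVs, topography as for spindles (frontal
#'   default center).
#' @param artifact rate of broadband high-power epochs (per hour) and their
#'   amplitude gain relative to the stage RMS.
#' @return Config list, class `synth_config`.
#' @export
synth_config <- function(n_channels = 64, fs = 128,
  background = list(rms = c(W = 15, N1 = 20, N2 = 25, N3 = 35, REM = 15),
                    alpha = c(W = 1.0, N1 = 1.5, N2 = 1.5, N3 = 1.5, REM = 1.0),
                    delta_scale = 1),
  spindle = list(density = c(W = 0, N1 = 0, N2 = 2.5, N3 = 1, REM = 0),
                 freq_mean = 13.5, freq_sd = 0.6,
                 dur_mean = 1.0, dur_sd = 0.15, dur_range = c(0.6, 1.5),
                 amp_peak = 260, amp_cv = 0.10,
                 subject_amp_cv = 0.12, subject_density_cv = 0.20,
                 topo_sigma = 0.9, topo_floor = 0.65, center = NULL),
  slow = list(density = c(W = 0, N1 = 0, N2 = 3, N3 = 8, REM = 0),
              dur_range = c(0.3, 0.9),
              npamp = 80, amp_cv = 0.25,
              subject_amp_cv = 0.15, subject_density_cv = 0.20,
              topo_sigma = 1.1, topo_floor = 0.5, center = NULL),
  artifact = list(rate_per_h = 2, gain = 6)) {
  cfg <- list(n_channels = n_channels, fs = fs, background = background,
              spindle = spindle, slow = slow, artifact = artifact)
  if (fs <= 0) stopf("fs must be > 0")
  if (any(cfg$spindle$density < 0) || any(cfg$slow$density < 0))
    stopf("densities must be >= 0")
  if (cfg$spindle$dur_mean <= 0 || any(cfg$slow$dur_range <= 0))
    stopf("durations must be > 0")
  structure(cfg, class = "synth_config")
}

# unit-RMS 1/f^alpha noise (flattened below 0.5 Hz, no DC); delta_scale
# multiplies amplitude at frequencies <= 4.5 Hz.  Matrix n x nch.
shaped_noise_matrix <- function(n, nch, fs, alpha, delta_scale = 1) {
  W <- matrix(stats::rnorm(n * nch), nch, n)
  f <- (0:(n - 1)) * fs / n
  fr <- pmin(f, fs - f)
  g <- pmax(fr, 0.5)^(-alpha / 2)
  g[1] <- 0
  norm <- sqrt(mean(g^2))
  g_full <- g * ifelse(fr <= 4.5, delta_scale, 1)
  t(apply_gains(W, list(g_full / norm))[[1]])
}

# Topographic gain: Gaussian bump (great-circle distance from a center
# channel) on a uniform floor, so events remain expressed - and detectable -
# across the whole scalp while peaking at the center.
topo_gain <- function(mon, center_label, sigma, floor = 0) {
  P <- mon$positions / sqrt(rowSums(mon$positions^2))
  c0 <- P[match(center_label, mon$labels), ]
  d <- acos(pmin(pmax(P %*% c0, -1), 1))
  as.numeric(floor + (1 - floor) * exp(-d^2 / (2 * sigma^2)))
}

#' Generate a synthetic recording with ground truth
#'
#' Background, spindles, slow waves and artifacts are layered as described in
#' [synth_config()].  Events are generated at recording level (one amplitude
#' draw per event) and projected to channels through the topographic gain, so
#' neighboring channels carry spatially correlated signals.
#'
#' @param hyp a [hypnogram()].
#' @param mon a [montage()] with `config$n_channels` channels.
#' @param config a [synth_config()].
#' @param seed RNG seed.
#' @param truth_min_gain record ground-truth rows only for channels whose
#'   topographic gain is at least this value.
#' @return List with `recording` ([new_recording()]), `truth` (data frame:
#'   channel, kind, start_s, end_s, amp, freq, gain) and the resolved centers.
#' @export
generate_recording <- function(hyp, mon, config = synth_config(), seed = 1,
                               truth_min_gain = 0.25) {
  if (length(mon$labels) != config$n_channels)
    stopf("montage has %d channels but config expects %d",
          length(mon$labels), config$n_channels)
  fs <- config$fs
  spe <- as.integer(round(30 * fs))
  n_ep <- n_epochs(hyp)
  n <- n_ep * spe
  nch <- config$n_channels
  st_ep <- hyp$stages

  with_seed(seed, {
    # subject-level factors
    sp <- config$spindle; sw <- config$slow; bg <- config$background
    subj_sp_amp <- exp(stats::rnorm(1, 0, sp$subject_amp_cv))
    subj_sp_den <- exp(stats::rnorm(1, 0, sp$subject_density_cv))
    subj_sw_amp <- exp(stats::rnorm(1, 0, sw$subject_amp_cv))
    subj_sw_den <- exp(stats::rnorm(1, 0, sw$subject_density_cv))

    # background: one shaped series per distinct 1/f exponent, generated
    # over that class's epochs only (noise continuity across stage
    # transitions is not required; the RMS steps there anyway)
    rms_ps <- rep(bg$rms[st_ep], each = spe)
    alpha_ep <- bg$alpha[st_ep]
    X <- matrix(0, nch, n)
    for (a in unique(alpha_ep)) {
      sel_ep <- which(alpha_ep == a)
      sel <- rep((sel_ep - 1L) * spe, each = spe) + seq_len(spe)
      S <- t(shaped_noise_matrix(length(sel), nch, fs, a, bg$delta_scale %||% 1))
      X[, sel] <- S * rep(rms_ps[sel], each = nch)
    }

    centers <- list(
      spindle = sp$center %||% nearest_channel(mon, c(0, -0.45, 0.89)),
      slow = sw$center %||% nearest_channel(mon, c(0, 0.77, 0.64)))
    g_sp <- topo_gain(mon, centers$spindle, sp$topo_sigma, sp$topo_floor %||% 0)
    g_sw <- topo_gain(mon, centers$slow, sw$topo_sigma, sw$topo_floor %||% 0)

    truth <- list()
    add_truth <- function(kind, start, end, amp_ch, freq, gains) {
      keep <- which(gains >= truth_min_gain)
      if (!length(keep)) return()
      truth[[length(truth) + 1L]] <<- data.frame(
        channel = mon$labels[keep], kind = kind, start_s = start,
        end_s = end, amp = amp_ch[keep], freq = freq, gain = gains[keep])
    }

    t_ep0 <- (seq_len(n_ep) - 1L) * 30

    # spindles: Hann-enveloped sinusoid bursts in N2/N3
    for (stage in names(sp$density)[sp$density > 0]) {
      eps <- which(st_ep == stage)
      if (!length(eps)) next
      n_ev <- stats::rpois(1, sp$density[[stage]] * subj_sp_den * length(eps) * 0.5)
      if (n_ev == 0L) next
      ev_ep <- sample(eps, n_ev, replace = TRUE)
      dur <- pmin(pmax(stats::rnorm(n_ev, sp$dur_mean, sp$dur_sd),
                       sp$dur_range[1]), sp$dur_range[2])
      freq <- stats::rnorm(n_ev, sp$freq_mean, sp$freq_sd)
      amp <- sp$amp_peak * subj_sp_amp * exp(stats::rnorm(n_ev, 0, sp$amp_cv))
      off <- stats::runif(n_ev, 0, 30 - dur)
      phase <- stats::runif(n_ev, 0, 2 * pi)
      for (e in seq_len(n_ev)) {
        t0 <- t_ep0[ev_ep[e]] + off[e]
        i0 <- floor(t0 * fs) + 1L
        i1 <- min(floor((t0 + dur[e]) * fs), n)
        tt <- ((i0:i1) - 1) / fs - t0
        env <- 0.5 * (1 - cos(2 * pi * tt / dur[e]))
        wave <- env * sin(2 * pi * freq[e] * tt + phase[e])
        X[, i0:i1] <- X[, i0:i1] + (g_sp * amp[e]) %o% wave
        add_truth("spindle", t0, t0 + dur[e], g_sp * amp[e], freq[e], g_sp)
      }
    }

    # slow waves: isolated negative half-sine deflections in N2/N3
    for (stage in names(sw$density)[sw$density > 0]) {
      eps <- which(st_ep == stage)
      if (!length(eps)) next
      n_ev <- stats::rpois(1, sw$density[[stage]] * subj_sw_den * length(eps) * 0.5)
      if (n_ev == 0L) next
      ev_ep <- sample(eps, n_ev, replace = TRUE)
      dur <- stats::runif(n_ev, sw$dur_range[1], sw$dur_range[2])
      amp <- sw$npamp * subj_sw_amp * exp(stats::rnorm(n_ev, 0, sw$amp_cv))
      off <- stats::runif(n_ev, 0, 30 - dur)
      for (e in seq_len(n_ev)) {
        t0 <- t_ep0[ev_ep[e]] + off[e]
        i0 <- floor(t0 * fs) + 1L
        i1 <- min(floor((t0 + dur[e]) * fs), n)
        tt <- ((i0:i1) - 1) / fs - t0
        wave <- -sin(pi * tt / dur[e])
        X[, i0:i1] <- X[, i0:i1] + (g_sw * amp[e]) %o% wave
        add_truth("slow_wave", t0, t0 + dur[e], -g_sw * amp[e],
                  1 / (2 * dur[e]), g_sw)
      }
    }

    # artifacts: broadband high-power epochs on all channels
    n_art <- stats::rpois(1, config$artifact$rate_per_h * n_ep / 120)
    if (n_art > 0L) {
      art_ep <- sample.int(n_ep, min(n_art, n_ep))
      for (e in art_ep) {
        idx <- (e - 1L) * spe + seq_len(spe)
        X[, idx] <- X[, idx] +
          matrix(stats::rnorm(nch * spe, 0,
                              config$artifact$gain * bg$rms[st_ep[e]]),
                 nch, spe)
        truth[[length(truth) + 1L]] <- data.frame(
          channel = ".all", kind = "artifact", start_s = (e - 1) * 30,
          end_s = e * 30, amp = NA_real_, freq = NA_real_, gain = NA_real_)
      }
    }

    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(channel = character(), kind = character(),
                 start_s = numeric(), end_s = numeric(), amp = numeric(),
                 freq = numeric(), gain = numeric())
    list(recording = new_recording(X, fs, labels = mon$labels),
         truth = truth, centers = centers)
  })
}

#' Two-group effect specification for synthetic cohorts
#'
#' Multiplicative deficits applied to group B.  `spindle_amp` scales the
#' spindle envelope peak; `sw_amp` scales both the inserted slow-wave
#' amplitude and the delta-band (<= 4.5 Hz) background, which reduces
#' slow-wave amplitude and slopes while preserving the zero-crossing rate
#' (density); `spindle_density` and `sw_density` scale event rates.
#'
#' @param spindle_amp,sw_amp,spindle_density,sw_density positive multipliers.
#' @return Named list.
#' @export
cohort_effect <- function(spindle_amp = 1, sw_amp = 1,
                          spindle_density = 1, sw_density = 1) {
  eff <- list(spindle_amp = spindle_amp, sw_amp = sw_amp,
              spindle_density = spindle_density, sw_density = sw_density)
  if (any(unlist(eff) <= 0)) stopf("effect multipliers must be > 0")
  eff
}

# config for one subject of a given group
subject_config <- function(config, group, effect) {
  if (group == "B") {
    config$spindle$amp_peak <- config$spindle$amp_peak * effect$spindle_amp
    config$spindle$density <- config$spindle$density * effect$spindle_density
    config$slow$npamp <- config$slow$npamp * effect$sw_amp
    config$slow$density <- config$slow$density * effect$sw_density
    config$background$delta_scale <-
      (config$background$delta_scale %||% 1) * effect$sw_amp
  }
  config
}

#' Generate a two-group synthetic cohort
#'
#' Per-subject seeds are derived deterministically from the master seed, so
#' the cohort is reproducible and individual subjects can be regenerated in
#' isolation (see [cohort_subject()]).
#'
#' @param n_per_group subjects per group (>= 2).
#' @param effect a [cohort_effect()]; group A is unaffected.
#' @param duration_min recording length per subject, minutes.
#' @param mon montage; defaults to [make_montage()] of the configured size.
#' @param config a [synth_config()].
#' @param seed master seed.
#' @param profile [stage_profile()] for the hypnograms.
#' @return List of subjects, each `list(id, group, hypnogram, recording,
#'   truth)`.  For large cohorts prefer [cohort_subject()] to generate one
#'   subject at a time.
#' @export
generate_cohort <- function(n_per_group, effect = cohort_effect(),
                            duration_min = 30, mon = NULL,
                            config = synth_config(), seed = 1,
                            profile = stage_profile()) {
  if (n_per_group < 2) stopf("need at least 2 subjects per group")
  man <- cohort_manifest(n_per_group, seed)
  lapply(seq_len(nrow(man)), function(i)
    cohort_subject(man, i, effect, duration_min, mon, config, profile))
}

#' Cohort manifest: subject ids, groups and derived seeds
#' @param n_per_group subjects per group.
#' @param seed master seed.
#' @return Data frame with columns `id`, `group`, `seed`.
#' @export
cohort_manifest <- function(n_per_group, seed) {
  n <- 2L * n_per_group
  data.frame(
    id = sprintf("S%02d", seq_len(n)),
    group = rep(c("A", "B"), each = n_per_group),
    seed = derive_seeds(seed, 2L * n)[seq_len(n)],
    hyp_seed = derive_seeds(seed, 2L * n)[n + seq_len(n)])
}

#' Generate a single cohort subject
#' @param man a [cohort_manifest()].
#' @param i row index into the manifest.
#' @inheritParams generate_cohort
#' @return `list(id, group, hypnogram, recording, truth)`.
#' @export
cohort_subject <- function(man, i, effect = cohort_effect(),
                           duration_min = 30, mon = NULL,
                           config = synth_config(), profile = stage_profile()) {
  if (is.null(mon)) mon <- make_montage(config$n_channels)
  cfg <- subject_config(config, man$group[i], effect)
  hyp <- generate_hypnogram(duration_min, man$hyp_seed[i], profile)
  gr <- generate_recording(hyp, mon, cfg, man$seed[i])
  list(id = man$id[i], group = man$group[i], hypnogram = hyp,
       recording = gr$recording, truth = gr$truth)
}
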