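#' Packaged anchor table of group hemodynamics
#'
#' Group mean and between-animal standard deviation of cardiac output (CO,
#' L/min), mean arterial pressure (MAP, mmHg) and central venous pressure
#' (CVP, mmHg) for the three experimental groups
#' (pentobarbital-euvolemia, VF-euvolemia, VF-hypovolemia) at the four
#' analysis times: baseline T0 = -20 s, equilibration T1 = 30 s, peak
#' T2 = 300 s and plateau T3 = 600 s relative to arrest.
#'
#' @return Tibble with columns `group`, `channel`, `time_s`, `mean`, `sd`.
#' @export
anchor_table <- function() {
  g <- rep(c("pento_eu", "vf_eu", "vf_hypo"), each = 12L)
  ch <- rep(rep(c("co", "map", "cvp"), each = 4L), times = 3L)
  tt <- rep(c(-20, 30, 300, 600), times = 9L)
  m <- c(4.3, 0, 0, 0,    47, 16, 14, 15,      12, 15, 14, 14,
         3, 0, 0, 0,      53, 17, 17.9, 11,    11, 15, 22.9, 16,
         2.4, 0, 0, 0,    45, 14.8, 16.2, 9,   9, 13.3, 19.4, 13)
  s <- c(1.2, 0, 0, 0,    3.7, 2.5, 2.8, 2.9,  2.9, 3.1, 3.3, 3.5,
         1.2, 0, 0, 0,    4.7, 2.2, 1.6, 0.8,  6, 4.6, 5, 3.7,
         0, 0, 0, 0,      5.6, 1.1, 1.1, 1.6,  3.3, 2.9, 3.1, 3.1)
  tibble::tibble(group = g, channel = ch, time_s = tt, mean = m, sd = s)
}

#' Group mean (or dispersion) curve through the anchor points
#'
#' Continuous curve on `[-60, 615]` s: constant at the baseline anchor up to
#' arrest; a fast exponential transition (time constant `tau`) from baseline
#' to the T1 anchor over `(0, 30]` s, renormalized to pass through T1
#' exactly; shape-preserving monotone cubic (smoothstep Hermite) segments
#' between the T1, T2 and T3 anchors on `[30, 600]`, with zero slope at the
#' anchors so each segment is strictly monotone; constant after 600 s.
#' Evaluated at the anchor times it returns the anchor values exactly.
#'
#' @param group,channel Group and channel name (see [anchor_table()]).
#' @param anchors Anchor tibble; defaults to the packaged table.
#' @param what `"mean"` or `"sd"` — which anchor column to interpolate.
#' @param tau Transition time constant (s) for the arrest drop; `NULL`
#'   selects 5 s for the pressures and an instantaneous drop for CO (flow
#'   ceases at once at arrest).
#' @return A vectorized function of time (s).
#' @export
group_mean_curve <- function(group, channel, anchors = anchor_table(),
                             what = c("mean", "sd"), tau = NULL) {
  what <- match.arg(what)
  tau <- tau %||% (if (channel == "co") 0 else 5)
  a <- dplyr::filter(anchors, .data$group == !!group, .data$channel == !!channel)
  a <- dplyr::arrange(a, .data$time_s)
  if (nrow(a) != 4L) abort(paste0("anchors missing for ", group, "/", channel))
  v <- a[[what]]
  t_anchor <- a$time_s
  v0 <- v[1]; v1 <- v[2]
  # monotone Hermite segments with zero slope at the anchors
  sp <- function(t) {
    out <- numeric(length(t))
    for (seg in 2:3) {
      ta <- t_anchor[seg]; tb <- t_anchor[seg + 1]
      sel <- if (seg == 2) t >= ta & t < tb else t >= ta & t <= tb
      u <- (t[sel] - ta) / (tb - ta)
      out[sel] <- v[seg] + (v[seg + 1] - v[seg]) * (3 * u^2 - 2 * u^3)
    }
    out
  }
  decay <- if (tau > 0) {
    function(t) (exp(-t / tau) - exp(-30 / tau)) / (1 - exp(-30 / tau))
  } else {
    function(t) numeric(length(t))
  }
  function(t) {
    out <- numeric(length(t))
    pre <- t <= 0
    trans <- t > 0 & t < t_anchor[2]
    late <- t >= t_anchor[2] & t <= 600
    post <- t > 600
    out[pre] <- v0
    out[trans] <- v1 + (v0 - v1) * decay(t[trans])
    out[late] <- sp(t[late])
    out[post] <- v[4]
    out
  }
}

#' Cohort specification for the synthetic generator
#'
#' @param n Named animal counts per group. Default 7 pentobarbital and the
#'   7 VF animals split into 4 euvolemic and 3 hypovolemic.
#' @param fs Sampling rate (Hz).
#' @param baseline_hr Baseline heart rate of the pulsatile carrier (bpm).
#' @param pulse_amp Peak-to-peak carrier amplitude per channel (mmHg for
#'   pressures, L/min for CO); the arterial default gives a systolic minus
#'   diastolic excursion of about 30 mmHg around the MAP anchor.
#' @param noise_sd Within-trace white-noise standard deviation per channel
#'   (band-limited below `noise_cutoff` before use).
#' @param noise_cutoff Low-pass shaping cutoff for the noise (Hz).
#' @param channel_cor Correlation of the per-animal offsets across channels.
#' @param offset_scale Multiplier on the between-animal offsets (0 for a
#'   noiseless cohort).
#' @param seed Integer seed; every animal derives its own substream.
#' @param t_start,t_end Trace span (s relative to arrest).
#' @return A `zf_cohort_spec` list.
#' @export
cohort_spec <- function(n = c(pento_eu = 7L, vf_eu = 4L, vf_hypo = 3L),
                        fs = 200, baseline_hr = 100,
                        pulse_amp = c(abp = 30, cvp = 4, co = 2),
                        noise_sd = c(abp = 2, cvp = 2, co = 0.005),
                        noise_cutoff = 5,
                        channel_cor = 0.8, offset_scale = 1,
                        seed = 1L, t_start = -60, t_end = 615) {
  stopifnot(fs > 1, all(n >= 1))
  structure(
    list(n = n, fs = fs, baseline_hr = baseline_hr, pulse_amp = pulse_amp,
         noise_sd = noise_sd, noise_cutoff = noise_cutoff,
         channel_cor = channel_cor, offset_scale = offset_scale,
         seed = as.integer(seed), t_start = t_start, t_end = t_end),
    class = "zf_cohort_spec"
  )
}

#' Noiseless cohort specification
#'
#' All noise terms and between-animal offsets set to zero and one animal
#' per group: each trace is the group mean curve with its pulsatile carrier.
#' @param ... Overrides passed to [cohort_spec()].
#' @export
noiseless_cohort_spec <- function(...) {
  cohort_spec(n = c(pento_eu = 1L, vf_eu = 1L, vf_hypo = 1L),
              noise_sd = c(abp = 0, cvp = 0, co = 0), offset_scale = 0, ...)
}

animal_seed <- function(spec, group, animal_id) {
  gi <- match(group, c("pento_eu", "vf_eu", "vf_hypo"))
  (spec$seed * 10007L + gi * 1009L + as.integer(animal_id) * 7L) %% 2147483647L
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

channel_offsets <- function(spec) {
  z_common <- rnorm(1)
  rho <- spec$channel_cor
  z <- rho * z_common + sqrt(1 - rho^2) * rnorm(3)
  setNames(spec$offset_scale * z, c("abp", "cvp", "co"))
}

shaped_noise <- function(n_samp, sd_raw, fs, cutoff) {
  if (sd_raw <= 0) return(numeric(n_samp))
  bf <- signal::butter(2, min(cutoff / (fs / 2), 0.99))
  as.numeric(signal::filtfilt(bf, rnorm(n_samp, sd = sd_raw)))
}

#' Synthesize one animal recording
#'
#' Per-channel trace = group mean curve + a per-animal offset (one standard
#' normal draw per channel, correlated across channels, scaled by the
#' interpolated between-animal SD curve) + band-limited Gaussian noise + a
#' pulsatile carrier at the baseline heart rate before arrest (zeroed at
#' t = 0, when the pulse ceases). The CO channel goes to zero (up to the
#' configured small noise) after arrest.
#'
#' @param group Group name.
#' @param animal_id Integer id within the group.
#' @param spec A [cohort_spec()].
#' @param anchors Anchor tibble.
#' @return Trace tibble with `time_s`, `abp_mmhg`, `cvp_mmhg`, `co_l_min`,
#'   `label` (group) and `animal`.
#' @export
synthesize_animal <- function(group, animal_id, spec = cohort_spec(),
                              anchors = anchor_table()) {
  with_local_seed(animal_seed(spec, group, animal_id), {
    tt <- seq(spec$t_start, spec$t_end, by = 1 / spec$fs)
    n_samp <- length(tt)
    z <- channel_offsets(spec)
    carrier_gate <- as.numeric(tt < 0)
    f_hr <- spec$baseline_hr / 60
    chans <- purrr::imap(c(abp = "map", cvp = "cvp", co = "co"), function(anchor_ch, ch) {
      mu <- group_mean_curve(group, anchor_ch, anchors, "mean")(tt)
      sdv <- group_mean_curve(group, anchor_ch, anchors, "sd")(tt)
      carrier <- (spec$pulse_amp[[ch]] / 2) * sin(2 * pi * f_hr * tt) * carrier_gate
      mu + z[[ch]] * sdv + carrier +
        shaped_noise(n_samp, spec$noise_sd[[ch]], spec$fs, spec$noise_cutoff)
    })
    tr <- tibble::tibble(
      time_s = tt, abp_mmhg = chans$abp, cvp_mmhg = chans$cvp,
      co_l_min = chans$co, label = group, animal = paste0(group, "_", animal_id)
    )
    attr(tr, "fs") <- spec$fs
    tr
  })
}

#' Synthesize a full cohort
#'
#' One trace per animal across the three groups; deterministic for a given
#' seed, with an independent substream per animal. Optionally writes one
#' CSV per animal plus a JSON manifest.
#'
#' @param spec A [cohort_spec()].
#' @param anchors Anchor tibble.
#' @param dir Output directory (created if needed); `NULL` for in-memory.
#' @return List with `traces` (stacked tibble) and `manifest`.
#' @export
synthesize_cohort <- function(spec = cohort_spec(), anchors = anchor_table(),
                              dir = NULL) {
  traces <- purrr::imap(spec$n, function(ng, group) {
    purrr::map(seq_len(ng), ~ synthesize_animal(group, .x, spec, anchors))
  })
  traces <- dplyr::bind_rows(purrr::flatten(traces))
  manifest <- list(
    groups = as.list(spec$n), seed = spec$seed, fs = spec$fs,
    n_traces = length(unique(traces$animal)),
    anchor_checksum = rlang::hash(anchor_table_matrix(anchors)),
    files = character(0)
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- purrr::map_chr(unique(traces$animal), function(a) {
      f <- file.path(dir, paste0(a, ".csv"))
      write_trace(dplyr::filter(traces, .data$animal == a), f)
      f
    })
    manifest$files <- files
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(traces = traces, manifest = manifest)
}

anchor_table_matrix <- function(anchors) {
  round(as.matrix(anchors[, c("time_s", "mean", "sd")]), 9)
}

#' Fast synthesis of per-animal time-point values
#'
#' Draws animal values directly at the analysis time points (mean curve +
#' offset x dispersion + independent noise), skipping full-rate trace
#' synthesis. With `sd_mode = "anchored"` the offset scales with the local
#' anchor SD (the study model); with `"constant"` it is held at the
#' baseline SD, giving a compound-symmetric covariance (used for null
#' calibration of the repeated-measures tests).
#'
#' @param group Group whose curves to draw from.
#' @param n Number of animals.
#' @param spec A [cohort_spec()] (noise/offset/seed settings are used).
#' @param anchors Anchor tibble.
#' @param times Time points (s).
#' @param sd_mode `"anchored"` or `"constant"`.
#' @param id_offset Offset added to animal ids (distinct substreams).
#' @return Tibble: `animal`, `group`, `channel`, `time_s`, `value`.
#' @export
synthesize_timepoints <- function(group, n, spec = cohort_spec(),
                                  anchors = anchor_table(),
                                  times = c(-20, 30, 300, 600),
                                  sd_mode = c("anchored", "constant"),
                                  id_offset = 0L) {
  sd_mode <- match.arg(sd_mode)
  purrr::map_dfr(seq_len(n), function(i) {
    with_local_seed(animal_seed(spec, group, i + id_offset), {
      z <- channel_offsets(spec)
      purrr::imap_dfr(c(abp = "map", cvp = "cvp", co = "co"), function(anchor_ch, ch) {
        mu <- group_mean_curve(group, anchor_ch, anchors, "mean")(times)
        sdv <- group_mean_curve(group, anchor_ch, anchors, "sd")(times)
        if (sd_mode == "constant") sdv <- rep(sdv[1], length(times))
        noise_here <- spec$noise_sd[[ch]] * 0.05
        tibble::tibble(
          animal = paste0(group, "_", i + id_offset), group = group,
          channel = anchor_ch, time_s = times,
          value = mu + z[[ch]] * sdv + rnorm(length(times), sd = noise_here)
        )
      })
    })
  })
}
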