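#' The reflex controller
#'
#' The short-term pressure control acts in four stages, once per controller
#' tick: (I) afferent smoothing — windowed means of aortic-arch pressure,
#' aortic pulse pressure, and right-atrial pressure; (II) error formation
#' against fixed set points and arctangent saturation with separate bounds
#' for the arterial baroreflex (ABR) and the cardiopulmonary reflex (CPR);
#' (III) convolution of the scaled errors with unit-area impulse-response
#' kernels representing parasympathetic and sympathetic arcs; (IV) static
#' gains mapping each arc onto its effectors: heart rate, cardiac
#' contractility, microvascular resistance, and venous unstressed volume.
#' @name reflex
NULL

parse_reflex_config <- function(raw, comp) {
  if (is.null(raw)) return(NULL)
  arcs <- purrr::map_dfr(raw$arcs, function(a) {
    tibble::tibble(
      name = a$name, source = a$source, class = a$class,
      delay = a$delay, peak = a$peak, end = a$end, rate_hz = a$rate_hz,
      g_hr = a$g_hr %||% 0, g_contract = a$g_contract %||% 0,
      g_resist = a$g_resist %||% 0, g_vu = a$g_vu %||% 0
    )
  })
  stopifnot(all(arcs$source %in% c("abp", "pp", "cvp")),
            all(arcs$class %in% c("abr", "cpr")))
  arcs$kernel <- purrr::pmap(arcs[, c("delay", "peak", "end", "rate_hz")],
                             function(delay, peak, end, rate_hz) {
                               triangular_kernel(delay, peak, end, rate_hz)
                             })
  w <- comp$V_unstressed * comp$venous_tone
  list(
    enabled = isTRUE(raw$enabled),
    window_n = as.integer(raw$window_n %||% 250L),
    tick_hz = raw$tick_hz %||% 200,
    setpoints = raw$setpoints,
    limits = raw$limits,
    arcs = arcs,
    vu_weights = if (sum(w) > 0) w / sum(w) else w
  )
}

#' Discretized unit-area triangular kernel
#'
#' Impulse response rising linearly from `delay` to `peak` and falling back
#' to zero at `end`, sampled at `rate_hz` and normalized so the discrete
#' weights sum to one (unit steady-state gain).
#'
#' @param delay,peak,end Kernel knots (s), `delay <= peak <= end`.
#' @param rate_hz Discretization rate (Hz).
#' @return Numeric weight vector summing to 1.
#' @export
triangular_kernel <- function(delay, peak, end, rate_hz) {
  stopifnot(delay <= peak, peak <= end, end > 0, rate_hz > 0)
  tt <- seq(0, end, by = 1 / rate_hz)
  w <- numeric(length(tt))
  rise <- tt >= delay & tt <= peak
  fall <- tt > peak & tt <= end
  if (peak > delay) w[rise] <- (tt[rise] - delay) / (peak - delay) else w[tt == peak] <- 1
  if (end > peak) w[fall] <- (end - tt[fall]) / (end - peak)
  s <- sum(w)
  if (s <= 0) {
    abort("kernel has zero area after discretization; increase rate_hz",
          class = "zf_config_error")
  }
  w / s
}

#' Afferent integration (Step I)
#'
#' Arithmetic mean of the last `window_n` samples of an afferent pressure
#' buffer. During warm-up (fewer than `window_n` samples) the buffer is
#' padded with its first sample.
#'
#' @param buffer Numeric vector of recent samples, oldest first.
#' @param window_n Window length in samples (default 250).
#' @return Smoothed value (mmHg).
#' @export
integrate_afferent <- function(buffer, window_n = 250L) {
  if (length(buffer) == 0) {
    abort("afferent buffer is empty: controller not warmed up",
          class = "zf_controller_error")
  }
  if (length(buffer) < window_n) {
    buffer <- c(rep(buffer[1], window_n - length(buffer)), buffer)
  }
  mean(tail(buffer, window_n))
}

#' Error signal (Step II)
#'
#' @param integrated Smoothed afferent value (mmHg).
#' @param setpoint Set point (mmHg).
#' @return `integrated - setpoint`.
#' @export
error_signal <- function(integrated, setpoint) integrated - setpoint

#' Arctangent saturation (Step II)
#'
#' `phi(e) = (2 L / pi) * atan(pi * e / (2 L))`: odd, unit slope at zero,
#' bounded strictly by the limit `L` in magnitude.
#'
#' @param error Error signal (mmHg), vectorized.
#' @param limit Saturation bound `L > 0` (18 for ABR arcs, 5 for CPR arcs).
#' @return Scaled error, `|phi| < L`.
#' @export
saturate <- function(error, limit) {
  stopifnot(limit > 0)
  (2 * limit / pi) * atan(pi * error / (2 * limit))
}

#' Causal convolution of a scaled-error sequence with an arc kernel (Step III)
#'
#' `y[n] = sum_j k[j] x[n - j]`, with the input padded with its first value
#' before the record starts (warm start), so a constant input yields that
#' constant output from the first sample.
#'
#' @param scaled_errors Scaled-error sequence at the kernel's rate.
#' @param kernel Unit-area kernel weights (see [triangular_kernel()]).
#' @return Efferent sequence, same length as `scaled_errors`.
#' @export
convolve_arc <- function(scaled_errors, kernel) {
  if (abs(sum(kernel) - 1) > 1e-6) {
    abort("kernel does not have unit area after discretization",
          class = "zf_config_error")
  }
  n <- length(scaled_errors)
  x <- c(rep(scaled_errors[1], length(kernel) - 1L), scaled_errors)
  out <- numeric(n)
  for (i in seq_len(n)) {
    seg <- x[(i + length(kernel) - 1L):i]
    out[i] <- sum(kernel * seg)
  }
  out
}

#' Map efferent arc outputs onto effectors (Step IV)
#'
#' Heart rate and unstressed volume receive additive corrections
#' (`base + sum(gain * efferent)`); contractility and microvascular
#' resistance receive multiplicative-fractional ones
#' (`base * (1 + sum(gain * efferent))`). Outputs are clamped to
#' physiological floors: `HR >= 0`, scales `>= 0.1`.
#'
#' @param efferents Named or positional numeric vector, one value per arc.
#' @param arcs The arc table of a reflex config (gains per effector).
#' @param base List with `HR` (bpm); contractility and resistance scales
#'   start at 1 and the unstressed-volume shift at 0 mL.
#' @return List: `HR`, `contract_scale`, `resist_scale`, `dVu` (mL).
#' @export
apply_gains <- function(efferents, arcs, base = list(HR = 72)) {
  stopifnot(length(efferents) == nrow(arcs))
  list(
    HR = max(0, base$HR + sum(arcs$g_hr * efferents)),
    contract_scale = max(0.1, 1 + sum(arcs$g_contract * efferents)),
    resist_scale = max(0.1, 1 + sum(arcs$g_resist * efferents)),
    dVu = sum(arcs$g_vu * efferents)
  )
}

#' Create a reflex controller state
#'
#' Reference (pure-R) implementation of the discrete controller, one tick
#' per call of [controller_step()]. The compiled simulator embeds the same
#' logic; this object exists for direct inspection and testing.
#'
#' @param config A reflex config (the `reflex` element of a `zf_model`).
#' @param base_hr Baseline heart rate (bpm).
#' @return A `zf_controller` list.
#' @export
reflex_controller <- function(config, base_hr = 72) {
  structure(
    list(config = config, base_hr = base_hr,
         buffers = list(abp = numeric(0), pp = numeric(0), cvp = numeric(0)),
         histories = purrr::map(seq_len(nrow(config$arcs)), ~ numeric(0)),
         decim = purrr::map_int(seq_len(nrow(config$arcs)), ~ 0L),
         tick = 0L),
    class = "zf_controller"
  )
}

#' One controller tick (Steps I-IV composed)
#'
#' @param ctrl A `zf_controller`.
#' @param observed List with `abp` (aortic-arch pressure), `pp` (aortic
#'   pulse pressure; 0 during arrest), `cvp` (right-atrial pressure), mmHg.
#' @param disabled If TRUE, effectors are pinned at base for the entire run.
#' @return List with the updated `ctrl` and the `effectors` list.
#' @export
controller_step <- function(ctrl, observed, disabled = FALSE) {
  cfg <- ctrl$config
  ctrl$tick <- ctrl$tick + 1L
  for (ch in c("abp", "pp", "cvp")) {
    buf <- c(ctrl$buffers[[ch]], observed[[ch]])
    if (length(buf) > cfg$window_n) buf <- tail(buf, cfg$window_n)
    ctrl$buffers[[ch]] <- buf
  }
  sp <- c(abp = cfg$setpoints$arterial, pp = cfg$setpoints$pulse,
          cvp = cfg$setpoints$venous)
  scaled <- purrr::imap_dbl(sp, function(s, ch) {
    lim <- if (ch == "cvp") cfg$limits$cpr else cfg$limits$abr
    saturate(error_signal(integrate_afferent(ctrl$buffers[[ch]], cfg$window_n), s), lim)
  })
  efferents <- numeric(nrow(cfg$arcs))
  for (i in seq_len(nrow(cfg$arcs))) {
    arc <- cfg$arcs[i, ]
    every <- max(1L, as.integer(round(cfg$tick_hz / arc$rate_hz)))
    if (ctrl$tick %% every == 1L || every == 1L || length(ctrl$histories[[i]]) == 0) {
      ctrl$histories[[i]] <- c(ctrl$histories[[i]], scaled[[arc$source]])
      nk <- length(arc$kernel[[1]])
      if (length(ctrl$histories[[i]]) > nk) {
        ctrl$histories[[i]] <- tail(ctrl$histories[[i]], nk)
      }
    }
    k <- arc$kernel[[1]]
    h <- ctrl$histories[[i]]
    hp <- c(rep(h[1], max(0, length(k) - length(h))), h)
    efferents[i] <- sum(k * rev(hp))
  }
  eff <- if (disabled) {
    list(HR = ctrl$base_hr, contract_scale = 1, resist_scale = 1, dVu = 0)
  } else {
    apply_gains(efferents, cfg$arcs, base = list(HR = ctrl$base_hr))
  }
  list(ctrl = ctrl, effectors = eff)
}
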