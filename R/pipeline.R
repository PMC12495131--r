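#' Zero-phase low-pass filtering of a hemodynamic trace
#'
#' Third-order Butterworth low-pass (default cut-off 0.5 Hz) applied in the
#' forward and reverse direction for a zero-phase response, per channel.
#' Edges are handled by odd (anti-symmetric) reflection padding over six
#' filter time constants, which preserves both level and slope; residual
#' boundary transients are confined to a few filter time constants at each
#' end of the record.
#'
#' @param trace Trace tibble (`time_s`, `abp_mmhg`, `cvp_mmhg`, `co_l_min`).
#' @param cutoff Cut-off frequency (Hz).
#' @param order Filter order.
#' @return The trace with each channel replaced by its mean (filtered)
#'   signal.
#' @export
lowpass_mean <- function(trace, cutoff = 0.5, order = 3) {
  fs <- trace_fs(trace)
  if (fs <= 1) abort("sampling rate must exceed 1 Hz")
  n <- nrow(trace)
  pad <- ceiling(6 * fs / cutoff)
  if (n <= pad / 2) {
    abort(paste0("trace too short for a ", cutoff,
                 " Hz filter: need more than ", ceiling(3 * fs / cutoff),
                 " samples (6 filter time constants), got ", n))
  }
  pad <- min(pad, n - 1L)
  bf <- signal::butter(order, cutoff / (fs / 2))
  filt1 <- function(x) {
    xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
    y <- signal::filtfilt(bf, xp)
    y[(pad + 1L):(pad + n)]
  }
  out <- dplyr::mutate(trace, dplyr::across(
    dplyr::any_of(c("abp_mmhg", "cvp_mmhg", "co_l_min")), filt1))
  attr(out, "fs") <- fs
  out
}

#' Extract the four analysis time points
#'
#' Channel values of a mean (filtered) trace at the analysis times T0 =
#' -20 s, T1 = 30 s, T2 = 300 s and T3 = 600 s, each taken as the average
#' over a +/- 1 s window around the nominal time to damp residual ripple.
#'
#' @param mean_trace A filtered trace (see [lowpass_mean()]). If an
#'   `animal` column is present, values are extracted per animal.
#' @param times Analysis times (s).
#' @param window Half-width of the averaging window (s).
#' @return Tibble with `channel` (`map`, `cvp`, `co`), `time_s`, `value`,
#'   plus `label`/`animal` when present.
#' @export
extract_timepoints <- function(mean_trace, times = c(-20, 30, 300, 600),
                               window = 1) {
  span <- range(mean_trace$time_s)
  if (span[1] > min(times) - window || span[2] < max(times)) {
    abort(paste0("trace spans [", span[1], ", ", span[2],
                 "] s but extraction needs [", min(times) - window, ", ",
                 max(times), "] s"))
  }
  one <- function(tr) {
    purrr::map_dfr(times, function(tp) {
      w <- tr[abs(tr$time_s - tp) <= window + 1e-9, ]
      tibble::tibble(
        channel = c("map", "cvp", "co"), time_s = tp,
        value = c(mean(w$abp_mmhg), mean(w$cvp_mmhg), mean(w$co_l_min))
      )
    })
  }
  if ("animal" %in% names(mean_trace)) {
    out <- mean_trace |>
      dplyr::group_by(.data$animal, .data$label) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
    dplyr::rename(out, group = "label")
  } else {
    one(mean_trace)
  }
}

#' Range-normalized root-mean-square error between two mean signals
#'
#' RMSE between a simulated and a reference signal on a common time grid,
#' divided by the reference range (max minus min over the comparison
#' window) and expressed in percent. Values below 5 percent are
#' conventionally read as high agreement.
#'
#' Numeric-vector inputs are compared directly. Trace inputs are compared
#' per channel over `window` (default the 0-600 s post-arrest window), the
#' simulated trace being linearly resampled onto the reference grid; if
#' the traces do not cover the window it is clipped to the overlap and the
#' result flagged.
#'
#' @param sim,ref Numeric vectors on a common grid, or (filtered) traces.
#' @param channels Channels to compare for trace input.
#' @param window Comparison window (s) for trace input.
#' @param normalize `"range"` (default) or `"mean"` denominator.
#' @return Percent nRMSE (scalar for vectors; tibble with one row per
#'   channel for traces, with attribute `clipped`).
#' @export
normalized_rmse <- function(sim, ref, channels = c("map", "cvp"),
                            window = c(0, 600), normalize = c("range", "mean")) {
  normalize <- match.arg(normalize)
  if (is.numeric(sim) && is.numeric(ref)) {
    stopifnot(length(sim) == length(ref))
    return(nrmse_vec(sim, ref, normalize))
  }
  cols <- c(map = "abp_mmhg", cvp = "cvp_mmhg", co = "co_l_min")
  lo <- max(window[1], min(sim$time_s), min(ref$time_s))
  hi <- min(window[2], max(sim$time_s), max(ref$time_s))
  if (hi <= lo) abort("no overlap between traces and comparison window")
  clipped <- lo > window[1] + 1e-9 || hi < window[2] - 1e-9
  refw <- ref[ref$time_s >= lo & ref$time_s <= hi, ]
  out <- purrr::map_dfr(channels, function(ch) {
    rv <- refw[[cols[[ch]]]]
    sv <- approx(sim$time_s, sim[[cols[[ch]]]], xout = refw$time_s)$y
    tibble::tibble(channel = ch, nrmse_pct = nrmse_vec(sv, rv, normalize))
  })
  attr(out, "clipped") <- clipped
  attr(out, "window") <- c(lo, hi)
  out
}

nrmse_vec <- function(sim, ref, normalize = "range") {
  denom <- if (normalize == "range") diff(range(ref)) else mean(ref)
  if (!is.finite(denom) || denom <= 0) {
    abort("reference range is zero; normalized RMSE undefined")
  }
  100 * sqrt(mean((sim - ref)^2)) / denom
}

#' Per-animal time-point summaries for a cohort of traces
#'
#' Filters each animal's trace to mean signals and extracts the analysis
#' time points — the full processing chain applied per animal.
#'
#' @param traces Stacked trace tibble with `animal` and `label` columns.
#' @param ... Passed to [extract_timepoints()].
#' @return Tibble: `animal`, `group`, `channel`, `time_s`, `value`.
#' @export
cohort_timepoints <- function(traces, ...) {
  traces |>
    dplyr::group_split(.data$animal) |>
    purrr::map_dfr(function(tr) {
      attr(tr, "fs") <- NULL
      extract_timepoints(lowpass_mean(tr), ...)
    })
}

#' Group statistics on time-point summaries
#'
#' The prespecified contrasts of the study: within-group change over
#' T1-T3 (repeated-measures one-way ANOVA per group and channel);
#' group-by-time interaction of each VF group against the pentobarbital
#' group, and over all three groups (mixed two-way ANOVA on T1-T3, the
#' interaction term tested within subjects); the arterio-venous difference
#' (MAP vs CVP) at 600 s (paired two-sided t-test per group); and
#' Shapiro-Wilk normality screens of the within-group residuals. Standard
#' test machinery is delegated to `stats::aov`, `stats::t.test` and
#' `stats::shapiro.test`; all p-values are two-sided.
#'
#' @param summaries Tibble from [cohort_timepoints()] or
#'   [synthesize_timepoints()] (`animal`, `group`, `channel`, `time_s`,
#'   `value`).
#' @param within_times Time points of the within-subject factor.
#' @param alpha Significance level used by [glance()].
#' @return A `zf_stats` object; see [tidy.zf_stats()].
#' @export
group_statistics <- function(summaries, within_times = c(30, 300, 600),
                             alpha = 0.05) {
  req <- c("animal", "group", "channel", "time_s", "value")
  if (!all(req %in% names(summaries))) {
    abort(paste0("summaries must have columns ", paste(req, collapse = ", ")))
  }
  if (!all(is.finite(summaries$value))) abort("non-finite values in summaries")
  counts <- summaries |>
    dplyr::distinct(.data$animal, .data$group) |>
    dplyr::count(.data$group)
  if (any(counts$n < 2)) {
    abort("need at least 2 animals per group for the group statistics")
  }
  d <- summaries |>
    dplyr::filter(.data$time_s %in% within_times,
                  .data$channel %in% c("map", "cvp")) |>
    dplyr::mutate(time_f = factor(.data$time_s), animal_f = factor(.data$animal),
                  group_f = factor(.data$group))

  tests <- list()
  # within-group change over time (one-way RM ANOVA)
  for (gr in unique(d$group)) {
    for (ch in c("map", "cvp")) {
      di <- dplyr::filter(d, .data$group == gr, .data$channel == ch)
      f <- aov(value ~ time_f + Error(animal_f), data = di)
      tab <- summary(f)[["Error: Within"]][[1]]
      tests[[length(tests) + 1L]] <- tibble::tibble(
        test = "rm_anova_time", group = gr, channel = ch,
        statistic = tab["time_f", "F value"], p_value = tab["time_f", "Pr(>F)"])
    }
  }
  # interaction vs pentobarbital and over all groups (mixed two-way ANOVA)
  inter_p <- function(di) {
    f <- aov(value ~ group_f * time_f + Error(animal_f), data = di)
    tab <- summary(f)[["Error: Within"]][[1]]
    row <- grep("group_f:time_f", rownames(tab))
    c(tab[row, "F value"], tab[row, "Pr(>F)"])
  }
  groups <- unique(d$group)
  for (ch in c("map", "cvp")) {
    if ("pento_eu" %in% groups) {
      for (gr in setdiff(groups, "pento_eu")) {
        di <- dplyr::filter(d, .data$group %in% c("pento_eu", gr),
                            .data$channel == ch)
        di$group_f <- droplevels(di$group_f)
        fp <- inter_p(di)
        tests[[length(tests) + 1L]] <- tibble::tibble(
          test = "rm_anova_interaction_vs_pento", group = gr, channel = ch,
          statistic = fp[1], p_value = fp[2])
      }
    }
    if (length(groups) > 1) {
      fp <- inter_p(dplyr::filter(d, .data$channel == ch))
      tests[[length(tests) + 1L]] <- tibble::tibble(
        test = "rm_anova_interaction_all", group = "all", channel = ch,
        statistic = fp[1], p_value = fp[2])
    }
  }
  # MAP vs CVP at 600 s (paired t)
  for (gr in unique(summaries$group)) {
    w <- summaries |>
      dplyr::filter(.data$group == gr, .data$time_s == 600,
                    .data$channel %in% c("map", "cvp")) |>
      tidyr::pivot_wider(id_cols = "animal", names_from = "channel",
                         values_from = "value")
    tt <- t.test(w$cvp, w$map, paired = TRUE)
    tests[[length(tests) + 1L]] <- tibble::tibble(
      test = "paired_t_cvp_vs_map_600s", group = gr, channel = "cvp-map",
      statistic = unname(tt$statistic), p_value = tt$p.value)
  }
  # normality screens (Shapiro-Wilk on within-group centered residuals)
  for (gr in unique(d$group)) {
    for (ch in c("map", "cvp")) {
      di <- dplyr::filter(d, .data$group == gr, .data$channel == ch) |>
        dplyr::group_by(.data$time_s) |>
        dplyr::mutate(resid = .data$value - mean(.data$value)) |>
        dplyr::ungroup()
      p <- tryCatch(shapiro.test(di$resid)$p.value, error = function(e) NA_real_)
      tests[[length(tests) + 1L]] <- tibble::tibble(
        test = "shapiro_wilk", group = gr, channel = ch,
        statistic = NA_real_, p_value = p)
    }
  }
  structure(list(tests = dplyr::bind_rows(tests), data = summaries,
                 alpha = alpha),
            class = "zf_stats")
}

#' Tidy the group-statistics result
#'
#' @param x A `zf_stats` object.
#' @param ... Unused.
#' @return Tibble with one row per test: `test`, `group`, `channel`,
#'   `statistic`, `p_value`.
#' @method tidy zf_stats
#' @export
tidy.zf_stats <- function(x, ...) x$tests

#' One-line summary of the group-statistics result
#'
#' @param x A `zf_stats` object.
#' @param ... Unused.
#' @return Tibble with animal/group/test counts and the number of tests
#'   significant at the configured alpha.
#' @method glance zf_stats
#' @export
glance.zf_stats <- function(x, ...) {
  tibble::tibble(
    n_animals = dplyr::n_distinct(x$data$animal),
    n_groups = dplyr::n_distinct(x$data$group),
    n_tests = nrow(x$tests),
    n_significant = sum(x$tests$p_value < x$alpha, na.rm = TRUE),
    alpha = x$alpha
  )
}

#' @export
print.zf_stats <- function(x, ...) {
  cat("Group statistics:", nrow(x$tests), "tests on",
      dplyr::n_distinct(x$data$animal), "animals\n")
  print(x$tests, n = nrow(x$tests))
  invisible(x)
}
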