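#' Match alert episodes between two signal variants
#'
#' A candidate episode is confirmed when some reference episode overlaps it
#' within `window_s` seconds; each reference episode can confirm at most one
#' candidate (greedy, in start order). Used to decide which raw alerts
#' survive filtering: raw episodes unconfirmed by the reference variant are
#' counted as false positives.
#'
#' @param candidate,reference Episode tibbles as returned by
#'   [alert_episodes()].
#' @param window_s Matching slack in seconds (default 2, the alert reset
#'   time).
#' @param sample_period_s Sampling period used to place episode indices on
#'   the time axis.
#' @return A list with integer elements `confirmed` and `false_positive`
#'   (`confirmed + false_positive == nrow(candidate)`).
#' @examples
#' run <- load_fixture("raw_running")
#' eps <- alert_episodes(flag_series(run))
#' match_episodes(eps, eps)         # all confirmed
#' match_episodes(eps, eps[0, ])    # empty reference: all false
#' @export
match_episodes <- function(candidate, reference, window_s = 2,
                           sample_period_s = 1) {
  stopifnot(is.data.frame(candidate), is.data.frame(reference),
            window_s >= 0, sample_period_s > 0)
  if (nrow(candidate) == 0L) {
    return(list(confirmed = 0L, false_positive = 0L))
  }
  cand <- dplyr::arrange(candidate, .data$start_index)
  ref <- dplyr::arrange(reference, .data$start_index)
  t0 <- function(i) (i - 1) * sample_period_s
  used <- rep(FALSE, nrow(ref))
  confirmed <- 0L
  for (i in seq_len(nrow(cand))) {
    lo <- t0(cand$start_index[i]) - window_s
    hi <- t0(cand$end_index[i]) + window_s
    hit <- which(!used & t0(ref$end_index) >= lo & t0(ref$start_index) <= hi)
    if (length(hit) > 0L) {
      used[hit[1]] <- TRUE
      confirmed <- confirmed + 1L
    }
  }
  list(confirmed = confirmed,
       false_positive = nrow(cand) - confirmed)
}

#' Compare alert behaviour across smoothing variants
#'
#' Runs the alert engine on the raw session and on each smoothed variant,
#' groups flags into episodes, and scores the raw episodes against the
#' reference variant (the last filter in `specs`; by default the Gaussian
#' filter, the better-performing smoother). Raw episodes unmatched by the
#' reference are reported as false positives; the true-positive percentage is
#' `confirmed / raw episodes * 100`, defined as 100 when no raw alert was
#' raised (no alarms, hence no false alarms). Note the reference variant is
#' an explicit convention, not clinical ground truth.
#'
#' @param session A raw [vital_session].
#' @param specs List of [filter_spec]s; the last one is the reference
#'   variant. Defaults to moving average (window 5) then Gaussian (sigma 2),
#'   both with length-preserving reflect edges.
#' @param config An [alert_config].
#' @param matching_window_s Episode matching slack in seconds; defaults to
#'   the config's refractory time.
#' @return An `alert_eval` object; see [tidy()] and [glance()] methods.
#' @examples
#' ev <- compare_filters(load_fixture("raw_running"))
#' glance(ev)$raw_episodes
#' @export
compare_filters <- function(session,
                            specs = list(
                              filter_spec("moving_average", edge_policy = "reflect"),
                              filter_spec("gaussian", edge_policy = "reflect")),
                            config = alert_config(),
                            matching_window_s = NULL) {
  stopifnot(inherits(session, "vital_session"), is.list(specs),
            length(specs) >= 1L,
            all(purrr::map_lgl(specs, inherits, "filter_spec")))
  matching_window_s <- matching_window_s %||% config$refractory_s
  period <- sample_period(session)

  episodes_of <- function(s) {
    alert_episodes(flag_series(s, config), sample_period_s = period,
                   merge_gap_s = config$refractory_s, hr_bpm = s$hr_bpm)
  }
  variant_names <- make.unique(c("raw", purrr::map_chr(specs, "kind")), sep = "_")
  sessions <- c(list(session), purrr::map(specs, ~ smooth_session(session, .x)))
  episodes <- purrr::map(sessions, episodes_of)
  names(sessions) <- names(episodes) <- variant_names

  ref <- episodes[[length(episodes)]]
  raw_eps <- episodes[["raw"]]
  scored <- match_episodes(raw_eps, ref, window_s = matching_window_s,
                           sample_period_s = period)
  n_raw <- nrow(raw_eps)
  structure(list(
    variant_names = variant_names,
    reference_variant = variant_names[length(variant_names)],
    episode_counts = purrr::map_int(episodes, nrow),
    episodes = episodes,
    confirmed_count = scored$confirmed,
    false_positive_count = scored$false_positive,
    true_positive_pct = if (n_raw == 0L) 100 else 100 * scored$confirmed / n_raw,
    matching_window_s = matching_window_s,
    config = config,
    phase = session_phase(session)
  ), class = "alert_eval")
}

#' @export
print.alert_eval <- function(x, ...) {
  cat(sprintf("<alert_eval> phase '%s', reference variant '%s'\n",
              x$phase, x$reference_variant))
  counts <- paste(sprintf("%s: %d", names(x$episode_counts), x$episode_counts),
                  collapse = ", ")
  cat(" episodes  ", counts, "\n", sep = "")
  cat(sprintf(" raw alerts confirmed %d, false %d (true-positive %.1f%%)\n",
              x$confirmed_count, x$false_positive_count, x$true_positive_pct))
  invisible(x)
}

#' Tidy methods for alert evaluations
#'
#' `tidy()` returns one row per signal variant with its episode count;
#' `glance()` returns a one-row summary of the false-alarm arithmetic.
#'
#' @param x An `alert_eval` from [compare_filters()].
#' @param ... Unused.
#' @return A tibble.
#' @examples
#' ev <- compare_filters(load_fixture("raw_running"))
#' tidy(ev)
#' glance(ev)
#' @method tidy alert_eval
#' @export
tidy.alert_eval <- function(x, ...) {
  tibble::tibble(
    variant = names(x$episode_counts),
    n_episodes = as.integer(x$episode_counts),
    is_reference = names(x$episode_counts) == x$reference_variant
  )
}

#' @rdname tidy.alert_eval
#' @method glance alert_eval
#' @export
glance.alert_eval <- function(x, ...) {
  tibble::tibble(
    phase = x$phase,
    raw_episodes = as.integer(x$episode_counts[["raw"]]),
    reference_episodes = as.integer(x$episode_counts[[x$reference_variant]]),
    confirmed = as.integer(x$confirmed_count),
    false_positives = as.integer(x$false_positive_count),
    true_positive_pct = x$true_positive_pct,
    matching_window_s = x$matching_window_s
  )
}
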