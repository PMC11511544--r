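#' Plot a vital session
#'
#' Faceted time-series view of the five measurement channels, with flagged
#' samples (alert = 1) marked on the heart-rate panel.
#'
#' @param object A [vital_session].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' ggplot2::autoplot(load_fixture("raw_running"))
#' @method autoplot vital_session
#' @export
autoplot.vital_session <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("hr_bpm", "spo2_pct", "ambient_c", "body_c", "speed_cm_s"),
    names_to = "channel", values_to = "value")
  flagged <- dplyr::filter(tibble::as_tibble(object), .data$alert == 1)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(
      data = dplyr::mutate(flagged, channel = "hr_bpm", value = .data$hr_bpm),
      colour = "firebrick", size = 1.6) +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("Vital session (%s)", session_phase(object)))
}

#' Compare raw and smoothed traces of one channel
#'
#' Overlays the raw series with each filtered variant, the view used to judge
#' how well a filter suppresses artifact spikes while tracking the signal.
#'
#' @param session A raw [vital_session].
#' @param specs List of [filter_spec]s (length-preserving edges recommended).
#' @param channel Channel to display (default `"hr_bpm"`).
#' @return A ggplot object.
#' @examples
#' plot_filter_comparison(load_fixture("raw_running"))
#' @export
plot_filter_comparison <- function(session,
                                   specs = list(
                                     filter_spec("moving_average",
                                                 edge_policy = "reflect"),
                                     filter_spec("gaussian",
                                                 edge_policy = "reflect")),
                                   channel = "hr_bpm") {
  stopifnot(inherits(session, "vital_session"), channel %in% names(session))
  nm <- make.unique(c("raw", purrr::map_chr(specs, "kind")), sep = "_")
  traces <- c(list(tibble::as_tibble(session)),
              purrr::map(specs, ~ tibble::as_tibble(smooth_session(session, .x))))
  names(traces) <- nm
  long <- dplyr::bind_rows(
    purrr::map(traces, ~ dplyr::select(.x, "time_s",
                                       value = dplyr::all_of(channel))),
    .id = "variant")
  long$variant <- factor(long$variant, levels = nm)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value,
                                     colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = channel, colour = NULL,
                  title = sprintf("Raw vs smoothed %s (%s)", channel,
                                  session_phase(session)))
}

#' @rdname tidy.alert_eval
#' @param object An `alert_eval`.
#' @method autoplot alert_eval
#' @export
autoplot.alert_eval <- function(object, ...) {
  d <- tidy(object)
  d$variant <- factor(d$variant, levels = d$variant)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$variant, y = .data$n_episodes,
                                  fill = .data$is_reference)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "alert episodes",
                  title = "Alert episodes per signal variant")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
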