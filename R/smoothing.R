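#' Smoothing filter specification
#'
#' Two smoothers are provided, matching the on-glove processing chain: an
#' unweighted moving average (default window 5) and a Gaussian-weighted
#' average (default sigma 2 samples, kernel truncated at `truncate` sigmas).
#' Two edge policies are supported: `"complete_only"` emits a value only where
#' the full window fits inside the series (output is shorter than the input),
#' while `"reflect"` pads the series by edge-inclusive reflection and
#' preserves its length.
#'
#' @param kind `"moving_average"` or `"gaussian"`.
#' @param window Odd positive window width for the moving average.
#' @param sigma Positive kernel standard deviation (in samples) for the
#'   Gaussian filter.
#' @param truncate Gaussian kernel half-width in sigmas (default 4).
#' @param edge_policy `"complete_only"` or `"reflect"`.
#' @return A `filter_spec` object.
#' @examples
#' filter_spec("moving_average", window = 5)
#' filter_spec("gaussian", sigma = 2, edge_policy = "reflect")
#' @export
filter_spec <- function(kind = c("moving_average", "gaussian"),
                        window = 5L, sigma = 2, truncate = 4,
                        edge_policy = c("complete_only", "reflect")) {
  kind <- match.arg(kind)
  edge_policy <- match.arg(edge_policy)
  window <- as.integer(window)
  stopifnot(window >= 1L, window %% 2L == 1L, sigma > 0, truncate > 0)
  structure(list(kind = kind, window = window, sigma = sigma,
                 truncate = truncate, edge_policy = edge_policy),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  detail <- if (x$kind == "moving_average") {
    sprintf("window %d", x$window)
  } else {
    sprintf("sigma %g, truncate %g", x$sigma, x$truncate)
  }
  cat(sprintf("<filter_spec> %s (%s, edges: %s)\n", x$kind, detail, x$edge_policy))
  invisible(x)
}

# Edge-inclusive reflection padding: (c b a | a b c ... | z y x)
pad_reflect <- function(x, h) {
  if (h == 0L) return(x)
  n <- length(x)
  if (n == 1L) return(rep(x, 2L * h + 1L))
  idx <- c(pmin(h:1, n), seq_len(n), pmax(n - (1:h) + 1L, 1L))
  x[idx]
}

convolve_centered <- function(x, weights, edge_policy) {
  h <- (length(weights) - 1L) %/% 2L
  n <- length(x)
  if (edge_policy == "complete_only") {
    if (n < length(weights)) {
      abort(sprintf("series of length %d shorter than filter support %d",
                    n, length(weights)))
    }
    out <- stats::filter(x, weights, method = "convolution", sides = 2)
    as.numeric(out[(h + 1L):(n - h)])
  } else {
    padded <- pad_reflect(x, h)
    out <- stats::filter(padded, weights, method = "convolution", sides = 2)
    as.numeric(out[(h + 1L):(h + n)])
  }
}

#' Moving-average smoothing
#'
#' Replaces each point by the unweighted mean of the `window` points centred
#' on it. Under `edge_policy = "complete_only"` the output has
#' `length(series) - window + 1` values, the j-th being the mean of inputs
#' `j, ..., j + window - 1`; under `"reflect"` the series is reflection-padded
#' and the output keeps the input length.
#'
#' @param series Numeric vector.
#' @inheritParams filter_spec
#' @return Numeric vector of smoothed values.
#' @examples
#' moving_average(c(73.46, 74.21, 75.25, 79.82, 79.67), window = 5)
#' @export
moving_average <- function(series, window = 5L,
                           edge_policy = c("complete_only", "reflect")) {
  edge_policy <- match.arg(edge_policy)
  window <- as.integer(window)
  stopifnot(is.numeric(series), window >= 1L, window %% 2L == 1L)
  convolve_centered(series, rep(1 / window, window), edge_policy)
}

#' Gaussian smoothing
#'
#' Convolution with a discrete Gaussian kernel of half-width
#' `ceiling(truncate * sigma)` samples and weights proportional to
#' `exp(-k^2 / (2 sigma^2))`, normalised to sum to one so that a constant
#' series is reproduced exactly.
#'
#' @inheritParams moving_average
#' @inheritParams filter_spec
#' @return Numeric vector of smoothed values.
#' @examples
#' gaussian_smooth(sin(1:30 / 3) + rnorm(30, sd = 0.1), sigma = 2)
#' @export
gaussian_smooth <- function(series, sigma = 2, truncate = 4,
                            edge_policy = c("reflect", "complete_only")) {
  edge_policy <- match.arg(edge_policy)
  stopifnot(is.numeric(series), length(series) > 0L)
  if (sigma <= 0) abort("sigma must be positive")
  convolve_centered(series, gaussian_kernel(sigma, truncate), edge_policy)
}

#' @rdname gaussian_smooth
#' @export
gaussian_kernel <- function(sigma = 2, truncate = 4) {
  if (sigma <= 0) abort("sigma must be positive")
  half <- ceiling(truncate * sigma)
  k <- seq(-half, half)
  w <- exp(-k^2 / (2 * sigma^2))
  w / sum(w)
}

#' Smooth every measurement channel of a session
#'
#' Applies one filter independently to `hr_bpm`, `spo2_pct`, `ambient_c`,
#' `body_c` and `speed_cm_s`. The alert flag is never smoothed; it should be
#' recomputed on the smoothed channels with [flag_series()]. Under
#' `"complete_only"` edges the returned session is shorter and keeps the
#' `index`, `time_s` and `alert` values of the window-centre rows.
#'
#' @param session A [vital_session].
#' @param spec A [filter_spec].
#' @return A [vital_session] of smoothed channels.
#' @examples
#' ma <- smooth_session(load_fixture("raw_resting"),
#'                      filter_spec("moving_average", window = 5))
#' head(ma$hr_bpm, 3)
#' @export
smooth_session <- function(session, spec = filter_spec()) {
  stopifnot(inherits(session, "vital_session"), inherits(spec, "filter_spec"))
  channels <- c("hr_bpm", "spo2_pct", "ambient_c", "body_c", "speed_cm_s")
  smooth1 <- function(x) {
    if (spec$kind == "moving_average") {
      moving_average(x, window = spec$window, edge_policy = spec$edge_policy)
    } else {
      gaussian_smooth(x, sigma = spec$sigma, truncate = spec$truncate,
                      edge_policy = spec$edge_policy)
    }
  }
  smoothed <- purrr::map(as.list(session)[channels], smooth1)
  n_out <- length(smoothed[[1]])
  keep <- if (n_out == nrow(session)) {
    seq_len(nrow(session))
  } else {
    h <- (nrow(session) - n_out) %/% 2L
    seq.int(h + 1L, h + n_out)
  }
  out <- tibble::as_tibble(session)[keep, c("index", "time_s", "alert")]
  out <- dplyr::bind_cols(out, tibble::as_tibble(smoothed))
  # smoothing can leave tiny negative speeds only through FP round-off
  out$speed_cm_s <- pmax(out$speed_cm_s, 0)
  vital_session(out, phase = session_phase(session),
                sample_period_s = sample_period(session))
}
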