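#' Stimulus protocol
#'
#' A sorted, non-overlapping list of stimulus pulses within the recording
#' span, e.g. a single 30 min chitin exposure after 30 min of buffer, or ten
#' 1 min pulses delivered every 4 min.
#'
#' @param on_s,off_s Numeric vectors of pulse start/end times in seconds
#'   (equal length; `0 <= on < off <= duration`).
#' @param duration_s Recording duration in seconds.
#' @return An object of class `stimulus_protocol`: a data frame with columns
#'   `on_s`, `off_s` and attribute `duration_s`.
#' @export
stimulus_protocol <- function(on_s, off_s, duration_s) {
  if (length(on_s) != length(off_s))
    stop("`on_s` and `off_s` must have equal length", call. = FALSE)
  check_positive(duration_s, "duration_s")
  o <- order(on_s)
  on_s <- on_s[o]; off_s <- off_s[o]
  if (length(on_s)) {
    if (any(on_s < 0) || any(off_s > duration_s) || any(on_s >= off_s))
      stop("pulses must satisfy 0 <= on < off <= duration", call. = FALSE)
    if (length(on_s) > 1 && any(on_s[-1] < off_s[-length(off_s)]))
      stop("pulses must not overlap", call. = FALSE)
  }
  structure(data.frame(on_s = as.numeric(on_s), off_s = as.numeric(off_s)),
            duration_s = as.numeric(duration_s),
            class = c("stimulus_protocol", "data.frame"))
}

#' Regular pulse train protocol
#'
#' @param n_pulses Number of pulses.
#' @param pulse_s Pulse duration, seconds.
#' @param period_s Onset-to-onset period, seconds.
#' @param first_on_s Onset of the first pulse, seconds.
#' @param duration_s Recording duration; defaults to the last pulse offset
#'   plus one period.
#' @return A [stimulus_protocol()].
#' @export
pulse_train <- function(n_pulses, pulse_s, period_s, first_on_s = 0,
                        duration_s = NULL) {
  on <- first_on_s + period_s * (seq_len(n_pulses) - 1)
  if (is.null(duration_s)) duration_s <- max(on) + pulse_s + period_s
  stimulus_protocol(on, on + pulse_s, duration_s)
}

#' Protocol duration, seconds
#' @param protocol A [stimulus_protocol()].
#' @export
protocol_duration <- function(protocol) attr(protocol, "duration_s")

#' Per-frame stimulus state
#' @param protocol A [stimulus_protocol()].
#' @param times Numeric vector of times (seconds).
#' @return Logical vector: stimulus on at each time (`on <= t < off`).
#' @export
stimulus_state <- function(protocol, times) {
  on <- rep(FALSE, length(times))
  for (i in seq_len(nrow(protocol)))
    on <- on | (times >= protocol$on_s[i] & times < protocol$off_s[i])
  on
}

#' Read/write a stimulus protocol as JSON
#'
#' The on-disk form is `{"duration_s": d, "pulses": [{"on_s": .., "off_s": ..}]}`.
#'
#' @param protocol A [stimulus_protocol()].
#' @param path File path.
#' @return `read_protocol()` returns a [stimulus_protocol()];
#'   `write_protocol()` returns `path` invisibly.
#' @export
write_protocol <- function(protocol, path) {
  jsonlite::write_json(
    list(duration_s = protocol_duration(protocol),
         pulses = as.data.frame(protocol)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- x$pulses
  if (is.null(p) || length(p) == 0 || nrow(as.data.frame(p)) == 0)
    return(stimulus_protocol(numeric(), numeric(), x$duration_s))
  stimulus_protocol(p$on_s, p$off_s, x$duration_s)
}
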