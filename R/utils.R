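# Small shared helpers: clock arithmetic, seed fan-out, validation.

#' Parse a "HH:MM" clock string to seconds past midnight
#' @param x character vector like "07:00" or "15:30"
#' @return numeric seconds past midnight
#' @keywords internal
clock_to_s <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) < 2L) stop("clock time must be 'HH:MM': ", paste(p, collapse = ":"))
    as.numeric(p[1L]) * 3600 + as.numeric(p[2L]) * 60 + if (length(p) >= 3L) as.numeric(p[3L]) else 0
  }, numeric(1))
}

#' Format seconds-past-midnight (possibly spanning days) as "HH:MM:SS"
#' @keywords internal
s_to_clock <- function(s) {
  s <- s %% 86400
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, round(s %% 60))
}

#' Is the lab lit at trial time `t`?
#'
#' @param t seconds since fish entry (may be negative for blank cycles)
#' @param start_clock_s trial start, seconds past midnight
#' @param lights_on_s,lights_off_s photoperiod anchors, seconds past midnight
#' @return logical vector
#' @keywords internal
lights_on_at <- function(t, start_clock_s, lights_on_s, lights_off_s) {
  clock <- (start_clock_s + t) %% 86400
  clock >= lights_on_s & clock < lights_off_s
}

#' Time (s since entry) of the k-th lights-on event after entry
#' @keywords internal
nth_lights_on <- function(k, start_clock_s, lights_on_s) {
  first <- (lights_on_s - start_clock_s) %% 86400
  first + (k - 1) * 86400
}

# Derive a reproducible sub-seed < 2^31 from a base seed and a stream label.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a scalar in [%s, %s]", name, lower, upper), call. = FALSE)
  invisible(x)
}
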