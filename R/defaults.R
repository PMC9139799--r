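#' Default condition means for the cohort simulator
#'
#' Compositional means (min/day) of the 4-part daily composition of sleep
#' (SL), sedentary behaviour (SB), light physical activity (LPA) and
#' moderate-to-vigorous physical activity (MVPA) under two schooling
#' conditions of the motivating study of high-school students: regular
#' onsite schooling versus remote online schooling. These are the
#' simulator's default latent condition means.
#'
#' @return list with named 4-part vectors `onsite` and `online`.
#' @export
default_condition_means <- function() {
  list(
    onsite = c(SL = 431.9, SB = 730.5, LPA = 252.5, MVPA = 25.2),
    online = c(SL = 468.9, SB = 755.0, LPA = 201.5, MVPA = 14.5)
  )
}

# clock-time helpers ---------------------------------------------------------

#' Convert "HH:MM" clock strings to seconds since midnight
#'
#' Accepts "24:00" (= 86400) so half-open windows ending at midnight can be
#' written in diaries. Vectorised; `NA`/empty strings map to `NA`.
#' @param x character vector of "HH:MM" times.
#' @return numeric seconds since midnight.
#' @export
hhmm_to_sec <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & nzchar(x)
  if (any(ok)) {
    parts <- strsplit(x[ok], ":", fixed = TRUE)
    out[ok] <- vapply(parts, function(p) {
      as.numeric(p[1]) * 3600 + as.numeric(p[2]) * 60
    }, numeric(1))
  }
  if (any(out[!is.na(out)] < 0 | out[!is.na(out)] > 86400))
    stop("hhmm_to_sec: time outside 00:00..24:00")
  out
}

#' @rdname hhmm_to_sec
#' @param s numeric seconds since midnight.
#' @export
sec_to_hhmm <- function(s) {
  sprintf("%02d:%02d", s %/% 3600, (s %% 3600) %/% 60)
}
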