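#' Response apparatus geometry
#'
#' Describes the loudspeaker/LED array and the button box used for categorical
#' localization responses: four speakers at -15, -5, +5 and +15 degrees
#' azimuth and an array of 12 pushbuttons spanning the same width. Buttons
#' are uniformly spaced; with the default spacing of 10/3 degrees per button,
#' buttons 2, 5, 8 and 11 sit exactly at the four speaker positions and one
#' flanking button lies beyond each outer speaker.
#'
#' @param speaker_azimuths Numeric vector of speaker azimuths in degrees.
#' @param button_count Number of response buttons (left to right).
#' @param button_spacing Degrees per button unit.
#'
#' @return An object of class `apparatus`.
#' @export
#' @examples
#' app <- apparatus()
#' button_center(c(2, 5, 8, 11), app)  # the four speaker positions
apparatus <- function(speaker_azimuths = c(-15, -5, 5, 15),
                      button_count = 12L,
                      button_spacing = 10 / 3) {
  stopifnot(is.numeric(speaker_azimuths), length(speaker_azimuths) >= 1,
            button_count >= 1, button_spacing > 0)
  structure(
    list(
      speaker_azimuths = as.numeric(speaker_azimuths),
      button_count = as.integer(button_count),
      button_spacing = button_spacing
    ),
    class = "apparatus"
  )
}

#' @export
print.apparatus <- function(x, ...) {
  cat("<apparatus> ", x$button_count, " buttons, ",
      format(x$button_spacing, digits = 4), " deg/button; speakers at ",
      paste(x$speaker_azimuths, collapse = ", "), " deg\n", sep = "")
  invisible(x)
}

#' Azimuth of a button center
#'
#' Button `i` of an n-button array is centered at `(i - (n + 1) / 2) *
#' spacing`, i.e. the array is symmetric about straight ahead (0 degrees).
#'
#' @param index Button index (vectorized), each in `1..button_count`.
#' @param app An [apparatus()].
#' @return Azimuth(s) in degrees.
#' @export
button_center <- function(index, app = apparatus()) {
  if (!is.numeric(index) || any(!is.finite(index)) ||
      any(index != round(index)) ||
      any(index < 1) || any(index > app$button_count)) {
    stop("`index` must be integer(s) in 1..", app$button_count, call. = FALSE)
  }
  (index - (app$button_count + 1) / 2) * app$button_spacing
}

#' Bin a continuous location into a button response
#'
#' Each button owns the half-open interval `[center - spacing/2,
#' center + spacing/2)`; locations beyond the outer edges clip to the first or
#' last button. This is the discretization applied to every continuous model
#' estimate before it is compared with observed button presses.
#'
#' @param location Numeric vector of azimuths in degrees (finite).
#' @param app An [apparatus()].
#' @return Integer button indices in `1..button_count`.
#' @export
bin_response <- function(location, app = apparatus()) {
  if (!is.numeric(location) || any(!is.finite(location))) {
    stop("`location` must be finite numeric", call. = FALSE)
  }
  n <- app$button_count
  idx <- floor(location / app$button_spacing + (n + 1) / 2 - 0.5) + 1L
  as.integer(pmin(pmax(idx, 1L), n))
}
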