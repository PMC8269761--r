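#' Fixed-optotype acuity scale
#'
#' Geometry of a fixed-size optotype viewed at a variable distance. The
#' optotype subtends 5 arcmin (demand 0.0 logMAR) at the reference distance;
#' halving the distance adds `log10(2)` (about three lines) to the logMAR
#' demand. The legal test range runs from `min_distance_cm` to
#' `max_distance_cm` on a grid of whole `line_step` increments.
#'
#' With the defaults (300 cm reference, 15--300 cm range, 0.1 logMAR lines)
#' the grid has 14 levels spanning 0.0 to 1.3 logMAR. The last grid distance
#' is 15.04 cm; the nominal 15 cm bound is its rounded display value and the
#' grid point is treated as inside the legal range.
#'
#' @param reference_distance_cm Distance (cm) at which the optotype demand
#'   equals `reference_logmar`. Default 300.
#' @param reference_logmar logMAR demand at the reference distance. Default 0.
#' @param min_distance_cm,max_distance_cm Legal test range (cm).
#' @param line_step Size of one acuity line in logMAR. Default 0.1.
#' @return An object of class `acuity_scale`.
#' @examples
#' sc <- acuity_scale()
#' distance_to_logmar(300, sc)  # 0.0
#' distance_to_logmar(30, sc)   # 1.0
#' @export
acuity_scale <- function(reference_distance_cm = 300,
                         reference_logmar = 0,
                         min_distance_cm = 15,
                         max_distance_cm = 300,
                         line_step = 0.1) {
  stopifnot(
    is.numeric(reference_distance_cm), reference_distance_cm > 0,
    is.numeric(reference_logmar), is.finite(reference_logmar),
    is.numeric(min_distance_cm), min_distance_cm > 0,
    is.numeric(max_distance_cm), max_distance_cm > 0,
    is.numeric(line_step), line_step >= 0
  )
  if (min_distance_cm > max_distance_cm) {
    stop("`min_distance_cm` must not exceed `max_distance_cm`", call. = FALSE)
  }
  structure(
    list(
      reference_distance_cm = as.numeric(reference_distance_cm),
      reference_logmar = as.numeric(reference_logmar),
      min_distance_cm = as.numeric(min_distance_cm),
      max_distance_cm = as.numeric(max_distance_cm),
      line_step = as.numeric(line_step)
    ),
    class = "acuity_scale"
  )
}

#' @export
print.acuity_scale <- function(x, ...) {
  cat(sprintf(
    "<acuity_scale> %g logMAR at %g cm; range %g-%g cm; %g logMAR/line (%d grid levels)\n",
    x$reference_logmar, x$reference_distance_cm,
    x$min_distance_cm, x$max_distance_cm, x$line_step,
    length(grid_logmars(x))
  ))
  invisible(x)
}

#' Convert viewing distance to logMAR demand
#'
#' The demand of the fixed optotype at distance `d` is
#' `reference_logmar + log10(reference_distance / d)`: moving closer enlarges
#' the retinal angle, so demand increases (larger logMAR) as distance falls.
#' The value is continuous, not snapped to the line grid.
#'
#' @param distance_cm Viewing distance(s) in cm; must be positive.
#' @param scale An [acuity_scale()].
#' @return logMAR demand, same length as `distance_cm`.
#' @examples
#' distance_to_logmar(40)  # 0.875, i.e. about 0.9 logMAR
#' @export
distance_to_logmar <- function(distance_cm, scale = acuity_scale()) {
  stopifnot(inherits(scale, "acuity_scale"), is.numeric(distance_cm))
  if (any(!is.finite(distance_cm)) || any(distance_cm <= 0)) {
    stop("`distance_cm` must be positive and finite", call. = FALSE)
  }
  scale$reference_logmar + log10(scale$reference_distance_cm / distance_cm)
}

#' Convert logMAR demand to viewing distance
#'
#' Inverse of [distance_to_logmar()]: `d = reference_distance *
#' 10^(reference_logmar - v)`.
#'
#' @param logmar logMAR demand(s); any finite value.
#' @inheritParams distance_to_logmar
#' @return Distance(s) in cm.
#' @examples
#' logmar_to_distance(1.0)  # 30
#' @export
logmar_to_distance <- function(logmar, scale = acuity_scale()) {
  stopifnot(inherits(scale, "acuity_scale"), is.numeric(logmar), all(is.finite(logmar)))
  scale$reference_distance_cm * 10^(scale$reference_logmar - logmar)
}

#' Distance reduction worth one acuity line
#'
#' How far the phone must move toward the subject, from distance `d`, for the
#' optotype demand to increase by exactly one line (`line_step` logMAR):
#' `r = d * (1 - 10^(-line_step))`. The fraction `r / d` is constant, so at
#' short test distances a small movement changes the score by a whole line
#' (8.2 cm at 40 cm), while at long distances much larger movements are
#' needed (61.7 cm at 300 cm).
#'
#' @inheritParams distance_to_logmar
#' @return Reduction(s) in cm.
#' @examples
#' one_line_distance_reduction(40)  # 8.23 cm, approximately 8 cm
#' @export
one_line_distance_reduction <- function(distance_cm, scale = acuity_scale()) {
  stopifnot(inherits(scale, "acuity_scale"), is.numeric(distance_cm))
  if (any(!is.finite(distance_cm)) || any(distance_cm <= 0)) {
    stop("`distance_cm` must be positive and finite", call. = FALSE)
  }
  distance_cm * (1 - 10^(-scale$line_step))
}

#' Grid of legal logMAR levels
#'
#' Whole-line demands from `reference_logmar` up to the level corresponding
#' to the minimum distance. For the defaults: 0.0, 0.1, ..., 1.3 (14 levels).
#'
#' @inheritParams distance_to_logmar
#' @return Numeric vector of logMAR levels, ascending.
#' @export
grid_logmars <- function(scale = acuity_scale()) {
  stopifnot(inherits(scale, "acuity_scale"))
  worst <- distance_to_logmar(scale$min_distance_cm, scale)
  if (scale$line_step == 0) {
    return(scale$reference_logmar)
  }
  k <- floor((worst - scale$reference_logmar) / scale$line_step + 1e-9)
  k <- max(k, 0)
  scale$reference_logmar + scale$line_step * (0:k)
}

#' Grid of legal test distances
#'
#' Distances for each whole-line grid level, sorted descending (farthest,
#' easiest demand first). For the defaults: 300, 238.3, ..., 30 (11th
#' entry), ..., 15.04 cm; 14 distances.
#'
#' @inheritParams distance_to_logmar
#' @return Numeric vector of distances in cm, descending.
#' @examples
#' grid_distances()[11]  # exactly 30
#' @export
grid_distances <- function(scale = acuity_scale()) {
  logmar_to_distance(grid_logmars(scale), scale)
}

#' Physical optotype height implied by the scale
#'
#' A standard letter optotype subtends 5 arcmin overall at its threshold
#' distance. The fixed render size implied by the reference point is
#' therefore `2 * reference_distance * tan(2.5 arcmin)`, about 4.36 mm for
#' a 0.0 logMAR demand at 300 cm. This is a derived documentation value, not
#' a calibrated screen measurement.
#'
#' @inheritParams distance_to_logmar
#' @return Height in mm.
#' @export
optotype_physical_height <- function(scale = acuity_scale()) {
  stopifnot(inherits(scale, "acuity_scale"))
  d_mm <- scale$reference_distance_cm * 10
  2 * d_mm * tan((2.5 / 60) * pi / 180)
}
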