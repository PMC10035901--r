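#' Arena and calibration specification
#'
#' Describes the circular recording arena and the camera calibration needed
#' to express tracker output in millimetres. The default geometry is a
#' 120 mm diameter arena filmed at 24 frames per second, the standard setup
#' for group recordings of walking Drosophila.
#'
#' @param radius_mm Arena radius in mm (default 60, i.e. a 120 mm disc).
#' @param fps Recording frame rate in frames per second (default 24).
#' @param px_per_mm Pixels per millimetre of the raw coordinates. `NULL`
#'   (default) means the input is already in mm.
#' @param center_x,center_y Arena centre in the *input* coordinate system
#'   (same units as the raw coordinates). Positions are re-expressed
#'   relative to this centre, so internally the arena centre is the origin.
#'
#' @return An object of class `arena_spec`.
#' @examples
#' arena_spec()                      # 120 mm arena, 24 fps, input in mm
#' arena_spec(px_per_mm = 8.5)      # raw pixel coordinates
#' @export
arena_spec <- function(radius_mm = 60, fps = 24, px_per_mm = NULL,
                       center_x = 0, center_y = 0) {
  if (!is.numeric(radius_mm) || length(radius_mm) != 1L || radius_mm <= 0)
    stop("`radius_mm` must be a single positive number", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("`fps` must be a single positive number", call. = FALSE)
  if (!is.null(px_per_mm) &&
      (!is.numeric(px_per_mm) || length(px_per_mm) != 1L || px_per_mm <= 0))
    stop("`px_per_mm` must be NULL or a single positive number", call. = FALSE)
  structure(
    list(radius_mm = as.numeric(radius_mm), fps = as.numeric(fps),
         px_per_mm = if (is.null(px_per_mm)) NULL else as.numeric(px_per_mm),
         center_x = as.numeric(center_x), center_y = as.numeric(center_y)),
    class = "arena_spec")
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("<arena_spec> radius %g mm, %g fps, calibration %s\n",
              x$radius_mm, x$fps,
              if (is.null(x$px_per_mm)) "none (mm input)"
              else sprintf("%g px/mm", x$px_per_mm)))
  invisible(x)
}

is_arena_spec <- function(x) inherits(x, "arena_spec")
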