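#' The isocline of perfect order
#'
#' The isocline is the curve that separates filled from empty cells in a
#' perfectly nested matrix of a given size and fill. We work in display
#' coordinates on the unit square: x is the column position (0 at the left,
#' where the broadest phage sits after packing) and y is the row position
#' (0 at the top, the most susceptible bacterium). Presences pack into the
#' top-left corner, so the isocline runs monotonically downward from the
#' top-right towards the bottom-left.
#'
#' The curve family is the superellipse `x^p + y^p = 1` (presence on the side
#' containing the origin) for fills of at least 50%, and its reflection
#' through the anti-diagonal, `(1-x)^p + (1-y)^p = 1` (presence on the side
#' *not* containing (1,1)), for fills below 50%. The presence-side area has
#' the closed form `Gamma(1 + 1/p)^2 / Gamma(1 + 2/p)` (or one minus it on the
#' reflected branch), and the single shape parameter is solved so that this
#' area equals `fill/100`. Reflecting an isocline through the anti-diagonal
#' therefore yields exactly the isocline of the complementary fill.
#'
#' @param fill fill percentage, strictly between 0 and 100.
#' @param rows,cols matrix dimensions (recorded for cell-centre queries).
#' @return an object of class `"pbin_isocline"` with fields `fill`,
#'   `shape_parameter` (p on the upper branch, 1/p on the reflected branch,
#'   always positive), `rows`, `cols`.
#' @examples
#' iso <- compute_isocline(50, 20, 20)
#' iso$shape_parameter # 1: the anti-diagonal itself
#' @export
compute_isocline <- function(fill, rows, cols) {
  if (!is.numeric(fill) || length(fill) != 1L || fill <= 0 || fill >= 100) {
    abort("degenerate fill: the isocline requires 0 < fill < 100")
  }
  a <- fill / 100
  flipped <- a < 0.5
  target <- if (flipped) 1 - a else a
  p <- solve_superellipse(target)
  structure(
    list(fill = fill,
         shape_parameter = if (flipped) 1 / p else p,
         p = p, flipped = flipped,
         rows = as.integer(rows), cols = as.integer(cols)),
    class = "pbin_isocline")
}

# area between the superellipse x^p + y^p = 1 and the axes
superellipse_area <- function(p) exp(2 * lgamma(1 + 1 / p) - lgamma(1 + 2 / p))

# solve superellipse_area(p) = a for a in [0.5, 1)
solve_superellipse <- function(a) {
  if (abs(a - 0.5) < 1e-15) return(1)
  hi <- 2
  while (superellipse_area(hi) < a) hi <- hi * 2
  uniroot(function(p) superellipse_area(p) - a, c(1, hi),
          tol = .Machine$double.eps^0.9)$root
}

# signed side function: negative on the presence side, positive on the
# absence side, zero on the curve. Vectorised over x, y.
iso_side <- function(iso, x, y) {
  if (iso$flipped) {
    1 - ((1 - x)^iso$p + (1 - y)^iso$p)
  } else {
    x^iso$p + y^iso$p - 1
  }
}

#' Evaluate the isocline
#'
#' Returns the y (row-fraction, measured from the packed top edge) at which
#' the isocline crosses a given x in (0, 1); strictly decreasing in x.
#'
#' @param iso an isocline from [compute_isocline()].
#' @param x positions in (0, 1).
#' @return y values in (0, 1).
#' @export
isocline_y <- function(iso, x) {
  stopifnot(inherits(iso, "pbin_isocline"))
  if (iso$flipped) {
    inner <- 1 - (1 - x)^iso$p
    inner <- pmin(pmax(inner, 0), 1)
    1 - inner^(1 / iso$p)
  } else {
    inner <- pmin(pmax(1 - x^iso$p, 0), 1)
    inner^(1 / iso$p)
  }
}

# presence-side area (closed form); used by tests and the area invariant
iso_area <- function(iso) {
  a <- superellipse_area(iso$p)
  if (iso$flipped) 1 - a else a
}

#' @export
print.pbin_isocline <- function(x, ...) {
  cat(sprintf(
    "Isocline of perfect order: fill %.4g%%, shape parameter %.6g (%d x %d)\n",
    x$fill, x$shape_parameter, x$rows, x$cols))
  invisible(x)
}
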