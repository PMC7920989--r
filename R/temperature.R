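#' Nestedness temperature
#'
#' The temperature T of a packed binary host-range matrix measures its
#' deviation from perfect nestedness on a 0--100 scale: 0 for a perfectly
#' nested matrix, rising as unexpected cells (absences on the presence side of
#' the isocline of perfect order, presences on the absence side) appear far
#' from the isocline. Each cell centre is mapped into the unit square with the
#' packed corner (most susceptible bacterium, broadest phage) at the top left.
#' For an unexpected cell, d is the distance from the cell centre to the
#' isocline along the fixed 45-degree diagonal through that centre and D is
#' the full chord length of that diagonal across the unit square; the cell's
#' unexpectedness is (d/D)^2. T is the mean unexpectedness over *all* cells
#' (expected cells contribute 0) scaled by K = 100/0.04145, the classic
#' normalisation under which temperatures span 0--100, and clamped to that
#' range.
#'
#' @param data a binary host-range tibble with no empty rows or columns and
#'   fill strictly between 0 and 100% (see [prune_redundant()]); scored in its
#'   current row/column order.
#' @return a `pbin_nestedness` object; see [pack_ntc()] for the fields.
#' @export
nestedness_temperature <- function(data) {
  m <- validate_host_range(data, binary = TRUE)
  check_packable(m)
  ctx <- temp_context(nrow(m), ncol(m), sum(m))
  new_nestedness(m, seq_len(nrow(m)), seq_len(ncol(m)), ctx,
                 method = "as_is", seed = NA_integer_)
}

# K: classic normalisation so that T ranges 0..100
.temp_K <- 100 / 0.04145

# ---- penalty-grid context ----------------------------------------------------
# For a fixed shape and fill the geometry is fixed; only which value sits at
# which grid position changes under permutation. Precompute, per position:
#   u  = (d/D)^2 distance score to the isocline along the 45-degree diagonal
#   side = sign of the isocline side function at the cell centre
# Then T(perm) = K/(R*C) * [ sum(P0) + sum((P1 - P0) * A[perm]) ], where
# P0 penalises a 0 sitting on the presence side and P1 a 1 on the absence
# side. This makes a temperature evaluation a single indexed sum, which the
# genetic packer and the null models rely on. Contexts are memoised by
# (rows, cols, ones).
temp_cache <- new.env(parent = emptyenv())

temp_context <- function(rows, cols, ones) {
  key <- paste(rows, cols, ones, sep = "x")
  hit <- temp_cache[[key]]
  if (!is.null(hit)) return(hit)

  fill <- 100 * ones / (rows * cols)
  iso <- compute_isocline(fill, rows, cols)
  x <- matrix((seq_len(cols) - 0.5) / cols, rows, cols, byrow = TRUE)
  y <- matrix((seq_len(rows) - 0.5) / rows, rows, cols)
  side <- iso_side(iso, x, y)

  # root of side((x,y) + t*(1,1)) = 0 by vectorised bisection; the side
  # function is strictly increasing along the diagonal on both branches.
  t_lo <- -pmin(x, y)
  t_hi <- pmin(1 - x, 1 - y)
  lo <- t_lo; hi <- t_hi
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    fm <- iso_side(iso, x + mid, y + mid)
    below <- fm < 0
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  troot <- (lo + hi) / 2
  d <- sqrt(2) * abs(troot)
  D <- sqrt(2) * (t_hi - t_lo)
  u <- (d / D)^2

  ctx <- list(
    rows = rows, cols = cols, ones = ones, fill = fill, iso = iso,
    d = d, D = D, u = u, side = side,
    P0 = u * (side < 0),   # cost of an absence at this position
    P1 = u * (side > 0))   # cost of a presence at this position
  ctx$S0 <- sum(ctx$P0)
  ctx$Pd <- ctx$P1 - ctx$P0
  temp_cache[[key]] <- ctx
  ctx
}

# temperature of matrix m viewed under row/col index permutations rp, cp
temp_eval <- function(m, rp, cp, ctx) {
  raw <- .temp_K / (ctx$rows * ctx$cols) *
    (ctx$S0 + sum(ctx$Pd * m[rp, cp, drop = FALSE]))
  min(max(raw, 0), 100)
}

# ---- result object -----------------------------------------------------------

# m: binary matrix in INPUT order; rp/cp: permutations packing it
new_nestedness <- function(m, rp, cp, ctx, method, seed,
                           p_value = NA_real_, control = NULL) {
  mp <- m[rp, cp, drop = FALSE]
  unexpected <- which((mp == 1 & ctx$side > 0) | (mp == 0 & ctx$side < 0),
                      arr.ind = TRUE)
  utab <- tibble(
    bacterium = rownames(mp)[unexpected[, 1L]],
    phage = colnames(mp)[unexpected[, 2L]],
    row = as.integer(unexpected[, 1L]),
    col = as.integer(unexpected[, 2L]),
    value = mp[unexpected],
    d = ctx$d[unexpected],
    D = ctx$D[unexpected])
  structure(
    list(packed = hr_tibble(mp),
         row_permutation = as.integer(rp),
         col_permutation = as.integer(cp),
         temperature = temp_eval(m, rp, cp, ctx),
         fill = ctx$fill,
         rows = ctx$rows, cols = ctx$cols,
         isocline = ctx$iso,
         unexpected = utab,
         p_value = p_value,
         method = method,
         seed = seed,
         control = control),
    class = "pbin_nestedness")
}

#' @export
print.pbin_nestedness <- function(x, ...) {
  cat(sprintf("Nestedness of a %d x %d infection network (%s packing)\n",
              x$rows, x$cols, x$method))
  cat(sprintf("  temperature T = %.4g, fill f = %.4g%%, %d unexpected cells\n",
              x$temperature, x$fill, nrow(x$unexpected)))
  if (!is.na(x$p_value)) {
    cat(sprintf("  null-model p-value = %.4g\n", x$p_value))
  }
  invisible(x)
}
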