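#' Synthetic host-range matrices
#'
#' Generators for the four structures used throughout the package's
#' simulation studies: perfectly nested binary matrices (the gene-for-gene
#' coevolution extreme), independent random matrices, block-modular matrices
#' (the matching-allele extreme), and quantitative matrices with planted
#' groups of similar lysis profiles. All generators are bit-reproducible
#' under a fixed seed and label rows `B01, B02, ...` and columns
#' `P01, P02, ...`.
#'
#' @name simulate_pbin
NULL

pbin_labels <- function(n, prefix) sprintf("%s%0*d", prefix,
                                           max(2L, nchar(n)), seq_len(n))

#' @describeIn simulate_pbin Perfectly nested binary matrix: the presences
#'   are exactly the cell centres on the presence side of the isocline of
#'   perfect order, at the fill (in percent) for which the isocline
#'   separates its own presence set exactly (a fixed point of the
#'   count-versus-area map), so packing returns temperature 0 by
#'   construction. At extreme fills a perfectly nested matrix of the full
#'   requested shape would carry empty or duplicate all-one lines, which the
#'   packers refuse; the generator therefore shrinks to the largest sub-shape
#'   on which the side set needs no pruning. Realized fill and shape are
#'   recorded in the `"realized_fill"` / `"requested_fill"` attributes.
#'   Output is in packed order; `seed` is accepted for interface uniformity
#'   but the construction is deterministic.
#' @param rows,cols matrix dimensions.
#' @param fill requested fill percentage in (0, 100).
#' @param seed integer seed.
#' @export
sim_nested <- function(rows, cols, fill, seed = 1L) {
  stopifnot(rows >= 1L, cols >= 1L, fill > 0, fill < 100)
  R <- as.integer(rows); C <- as.integer(cols)
  f_cur <- fill
  repeat {
    if (R < 1L || C < 1L) {
      abort("no prunable-free perfectly nested matrix exists for this shape/fill")
    }
    cells <- nested_side_set(R, C, f_cur)
    if (is.null(cells)) {
      # no exactly separable presence count on this grid: retry on the
      # nearest smaller sub-shape (closest achievable, reported via attrs)
      if (R >= C) R <- R - 1L else C <- C - 1L
      next
    }
    rs <- rowSums(cells); cs <- colSums(cells)
    keep_r <- which(rs > 0)
    full_r <- which(rs == ncol(cells))
    if (length(full_r) > 1L) keep_r <- setdiff(keep_r, full_r[-1L])
    keep_c <- which(cs > 0)
    full_c <- which(cs == nrow(cells))
    if (length(full_c) > 1L) keep_c <- setdiff(keep_c, full_c[-1L])
    if (length(keep_r) == nrow(cells) && length(keep_c) == ncol(cells)) break
    # retarget the fill of the occupied sub-grid: "the same nested matrix
    # with its empty and redundant full lines removed"
    kept <- cells[keep_r, keep_c, drop = FALSE]
    R <- nrow(kept); C <- ncol(kept)
    f_cur <- 100 * sum(kept) / length(kept)
    if (f_cur <= 0 || f_cur >= 100) {
      abort("no prunable-free perfectly nested matrix exists for this shape/fill")
    }
  }
  dimnames(cells) <- list(pbin_labels(nrow(cells), "B"),
                          pbin_labels(ncol(cells), "P"))
  out <- hr_tibble(cells)
  attr(out, "realized_fill") <- 100 * sum(cells) / length(cells)
  attr(out, "requested_fill") <- fill
  out
}

# presence set {isocline side < 0} at the separable one-count nearest the
# target fill: a fixed point of m -> #(centres on the presence side of the
# isocline with area m / (R*C)), which exists on the finite chain because
# the count is non-decreasing in m
nested_side_set <- function(R, C, fill) {
  x <- matrix((seq_len(C) - 0.5) / C, R, C, byrow = TRUE)
  y <- matrix((seq_len(R) - 0.5) / R, R, C)
  total <- R * C
  side_at <- function(m) iso_side(compute_isocline(100 * m / total, R, C), x, y)
  target <- max(1L, min(total - 1L, as.integer(round(total * fill / 100))))
  for (delta in 0:(total - 1L)) {
    for (cand in unique(c(target + delta, target - delta))) {
      if (cand < 1L || cand > total - 1L) next
      s <- side_at(cand)
      if (sum(s < 0) == cand) return((s < 0) * 1)
    }
  }
  NULL
}

#' @describeIn simulate_pbin Random binary matrix with i.i.d. cells,
#'   `P(1) = fill/100`.
#' @export
sim_random <- function(rows, cols, fill, seed = 1L) {
  stopifnot(rows >= 1L, cols >= 1L, fill > 0, fill < 100)
  cells <- withr::with_seed(as.integer(seed), {
    matrix(rbinom(rows * cols, 1L, fill / 100), rows, cols)
  })
  dimnames(cells) <- list(pbin_labels(rows, "B"), pbin_labels(cols, "P"))
  hr_tibble(cells)
}

#' @describeIn simulate_pbin Block-modular binary matrix: rows and columns
#'   are split into `n_modules` contiguous blocks (as equal as possible);
#'   within-block cells are 1 with probability `within_density`,
#'   between-block cells with probability `between_density`. The planted
#'   partition is attached as attribute `"planted"` (a list with
#'   `row_modules` and `col_modules`).
#' @param n_modules number of modules (>= 2).
#' @param within_density,between_density interaction probabilities inside
#'   and between modules, in `[0, 1]`.
#' @export
sim_modular <- function(rows, cols, n_modules = 2L, within_density = 0.9,
                        between_density = 0.05, seed = 1L) {
  stopifnot(n_modules >= 2L,
            within_density >= 0, within_density <= 1,
            between_density >= 0, between_density <= 1)
  if (n_modules > rows || n_modules > cols) {
    abort("`n_modules` cannot exceed either matrix dimension")
  }
  rmod <- sort(rep_len(seq_len(n_modules), rows))
  cmod <- sort(rep_len(seq_len(n_modules), cols))
  prob <- ifelse(outer(rmod, cmod, "=="), within_density, between_density)
  cells <- withr::with_seed(as.integer(seed), {
    matrix(rbinom(rows * cols, 1L, prob), rows, cols)
  })
  dimnames(cells) <- list(pbin_labels(rows, "B"), pbin_labels(cols, "P"))
  out <- hr_tibble(cells)
  attr(out, "planted") <- list(row_modules = rmod, col_modules = cmod)
  out
}

#' @describeIn simulate_pbin Quantitative matrix with planted phage profile
#'   groups: each group has a template profile of integer cross-streak
#'   scores 0--3 over the hosts (templates are resampled until every pair is
#'   at least `min_separation` apart in per-host root-mean-square score);
#'   each phage is its group template plus normal noise of standard
#'   deviation `noise_sd`, rounded back to the 0--3 integer grid and
#'   clipped. Planted group membership is attached as attribute `"planted"`.
#' @param n_groups number of planted profile groups.
#' @param noise_sd within-group noise standard deviation (score units).
#' @param min_separation minimum per-host RMS score difference between two
#'   group templates (default 1.5).
#' @export
sim_quantitative <- function(rows, cols, n_groups = 3L, noise_sd = 0.25,
                             min_separation = 1.5, seed = 1L) {
  stopifnot(rows >= 1L, cols >= n_groups, n_groups >= 1L, noise_sd >= 0)
  withr::with_seed(as.integer(seed), {
    templates <- matrix(sample(0:3, rows, replace = TRUE), rows, 1L)
    tries <- 0L
    while (ncol(templates) < n_groups) {
      cand <- sample(0:3, rows, replace = TRUE)
      rms <- sqrt(colMeans((templates - cand)^2))
      if (all(rms >= min_separation)) {
        templates <- cbind(templates, cand)
      }
      tries <- tries + 1L
      if (tries > 10000L) {
        abort("could not place templates this far apart; lower `min_separation`")
      }
    }
    group <- rep_len(seq_len(n_groups), cols)
    noise <- matrix(rnorm(rows * cols, sd = noise_sd), rows, cols)
    cells <- templates[, group, drop = FALSE] + noise
    cells <- pmin(pmax(round(cells), 0), 3)
    dimnames(cells) <- list(pbin_labels(rows, "B"), pbin_labels(cols, "P"))
    out <- hr_tibble(cells)
    attr(out, "planted") <- group
    out
  })
}

#' Shuffle the rows and columns of a host-range table
#'
#' Utility for round-trip experiments: permutes rows and columns uniformly at
#' random under `seed` (labels travel with their profiles).
#'
#' @param data host-range tibble.
#' @param seed integer seed.
#' @return the shuffled tibble.
#' @export
shuffle_host_range <- function(data, seed = 1L) {
  m <- hr_matrix(data)
  withr::with_seed(as.integer(seed), {
    hr_tibble(m[sample.int(nrow(m)), sample.int(ncol(m)), drop = FALSE])
  })
}
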