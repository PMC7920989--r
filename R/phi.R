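#' Estimate the phage cocktail size from network properties
#'
#' The cocktail size estimator combines three properties of a packed
#' phage-bacteria infection network: the number of target bacteria b (which
#' sets the biocontrol target), the nestedness temperature T (hotter networks
#' carry less generalist phages, so more isolates are needed) and the fill f
#' (a denser matrix means broader host ranges, so fewer are needed). The
#' default logarithmic form is
#'
#' \deqn{\Phi = \lfloor \log_n( b T / f + n ) \rfloor,\qquad n = 2,}
#'
#' whose integer part (floor, not rounding) is taken; with `n = 2` it yields
#' cocktails of 1--10 phages for networks of up to a couple of hundred
#' bacteria, and equals 1 whenever T = 0 (a perfectly nested network needs
#' only its most generalist phage). The experimental root form is
#' `floor((b*T/f + n)^(1/n))`. T and f are both on the 0--100 scale, so their
#' ratio is scale-invariant.
#'
#' @param b number of bacterial strains in the input matrix (pre-pruning),
#'   a positive integer.
#' @param temperature packed nestedness temperature, 0--100.
#' @param fill matrix fill percentage, in (0, 100].
#' @param n estimator order, a positive integer (default 2).
#' @param equation `"log"` (default) or `"root"`.
#' @return integer cocktail size(s); arguments are vectorised and recycled.
#' @examples
#' phi_cocktail_size(7, 0, 71.4)     # 1
#' phi_cocktail_size(113, 11.6, 6.2) # 7
#' @export
phi_cocktail_size <- function(b, temperature, fill, n = 2L,
                              equation = c("log", "root")) {
  equation <- match.arg(equation)
  if (length(n) != 1L || !is.numeric(n) || n < 1 || n != floor(n)) {
    abort("`n` must be a single positive integer")
  }
  k <- max(length(b), length(temperature), length(fill))
  b <- rep_len(b, k); temperature <- rep_len(temperature, k)
  fill <- rep_len(fill, k)
  if (any(fill <= 0)) abort("`fill` must be positive (cocktail size undefined at fill 0)")
  if (any(temperature < 0)) abort("`temperature` must be non-negative")
  if (any(b < 1)) abort("`b` must be a positive count of bacteria")
  inner <- b * temperature / fill + n
  val <- switch(equation,
                log = log(inner, base = n),
                root = inner^(1 / n))
  # tiny guard so exactly-integer inner values floor correctly
  as.integer(floor(val + 1e-9))
}

# frozen checksum of the packaged survey; guards against silent fixture edits
.meta_md5 <- "f0e130a50808b3b8d5ef8ef3c7db6554"

#' Survey of 35 published phage-bacteria infection networks
#'
#' A packaged table of 35 experimental host-range studies spanning dairy,
#' clinical, livestock, plant, sewage and laboratory sources: for each study
#' the number of bacterial strains `b`, number of phages, matrix fill `f`
#' (percent), packed nestedness temperature `T`, whether the matrix was
#' significantly nested, and the published cocktail size estimate
#' `phi_printed`. On load the estimator is recomputed from each row's
#' `(b, T, f)` via [phi_cocktail_size()] and returned as `phi`, together with
#' a `phi_match` flag; the file's checksum is verified first.
#'
#' @return a tibble with 35 rows and columns `study`, `bacteria_source`,
#'   `bacteria`, `phage_source`, `phages`, `fill`, `temperature`, `nested`,
#'   `phi_printed`, `phi`, `phi_match`.
#' @examples
#' meta <- pbin_meta_survey()
#' all(meta$phi_match)  # TRUE: 35/35 reproduced
#' range(meta$phi)      # 1 .. 7
#' @export
pbin_meta_survey <- function() {
  path <- system.file("extdata", "pbin_meta_survey.csv",
                      package = "pbindesign", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, .meta_md5)) {
    abort(sprintf("packaged survey fixture is corrupted (md5 %s)", sum))
  }
  meta <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(meta) != 35L) abort("survey fixture must contain exactly 35 records")
  meta |>
    mutate(
      phi = phi_cocktail_size(.data$bacteria, .data$temperature, .data$fill),
      phi_match = .data$phi == .data$phi_printed)
}
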