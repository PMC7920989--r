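#' Null-model significance of a nestedness temperature
#'
#' Generates `n_null` random matrices of the same shape and expected fill as
#' the observed (pruned) matrix, packs each one with the *same* method and
#' settings that produced `result`, and reports the add-one p-value
#' `p = (1 + #\{null T <= observed T\}) / (n_null + 1)`; a lower temperature
#' means a more nested matrix, so small p indicates significant nestedness.
#'
#' Null draws that are degenerate -- fill of 0 or 100%, or any empty row or
#' column -- are resampled, giving up after `100 * n_null` attempts.
#'
#' @param data the pruned binary host-range tibble that `result` was packed
#'   from.
#' @param result a `pbin_nestedness` from [pack_ntc()] or [pack_genetic()].
#' @param n_null number of null matrices (default 1000).
#' @param model `"equiprobable_fill"` (each cell is 1 with probability
#'   fill/100, the default) or `"proportional_marginals"` (cell probability
#'   is the mean of its row and column incidence, preserving expected
#'   marginals).
#' @param seed integer seed for null generation (and for the genetic packer's
#'   per-null sub-seeds).
#' @return `result` with `p_value` filled in and the null configuration
#'   echoed in `$null_model`.
#' @export
nestedness_significance <- function(data, result, n_null = 1000L,
                                    model = c("equiprobable_fill",
                                              "proportional_marginals"),
                                    seed = 1L) {
  m <- validate_host_range(data, binary = TRUE)
  check_packable(m)
  model <- match.arg(model)
  stopifnot(inherits(result, "pbin_nestedness"))
  if (n_null < 1L) abort("`n_null` must be at least 1")
  if (result$rows != nrow(m) || result$cols != ncol(m)) {
    abort("`result` was not produced from `data` (shape mismatch)")
  }

  R <- nrow(m); C <- ncol(m)
  prob <- switch(model,
    equiprobable_fill = matrix(sum(m) / length(m), R, C),
    proportional_marginals =
      (matrix(rowSums(m) / C, R, C) + matrix(colSums(m) / R, R, C,
                                             byrow = TRUE)) / 2)

  null_T <- withr::with_seed(as.integer(seed), {
    out <- numeric(n_null)
    attempts <- 0L
    max_attempts <- 100L * n_null
    for (i in seq_len(n_null)) {
      repeat {
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          abort(sprintf(
            "null model produced only degenerate matrices (%d attempts)",
            attempts))
        }
        nm <- matrix(rbinom(R * C, 1L, prob), R, C)
        s <- sum(nm)
        degenerate <- s == 0L || s == R * C ||
          any(rowSums(nm) == 0L) || any(colSums(nm) == 0L)
        if (!degenerate) break
      }
      out[i] <- pack_temperature(nm, result)
    }
    out
  })

  result$p_value <- (1 + sum(null_T <= result$temperature)) / (n_null + 1)
  result$null_model <- list(model = model, n_null = as.integer(n_null),
                            seed = as.integer(seed))
  result
}

# pack a bare 0/1 matrix with the same method/config as `result`; T only
pack_temperature <- function(nm, result) {
  ctx <- temp_context(nrow(nm), ncol(nm), sum(nm))
  if (result$method == "genetic") {
    sub_seed <- sample.int(.Machine$integer.max, 1L)
    ind <- withr::with_seed(sub_seed, ga_search(nm, ctx, result$control))
    temp_eval(nm, ind$rp, ind$cp, ctx)
  } else {
    ord <- ntc_orders(nm)
    temp_eval(nm, ord$rp, ord$cp, ctx)
  }
}
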