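#' Tidy a packed nestedness result
#'
#' Returns one row per unexpected cell -- a presence on the absence side of
#' the isocline or an absence on the presence side -- with its packed-matrix
#' position, the distance d to the isocline along the cell's 45-degree
#' diagonal, and the full chord length D.
#'
#' @param x a `pbin_nestedness` object.
#' @param ... unused.
#' @return a tibble with columns `bacterium`, `phage`, `row`, `col`,
#'   `value`, `d`, `D`.
#' @export
tidy.pbin_nestedness <- function(x, ...) x$unexpected

#' Glance at a packed nestedness result
#'
#' @param x a `pbin_nestedness` object.
#' @param ... unused.
#' @return a one-row tibble: `temperature`, `fill`, `rows`, `cols`,
#'   `n_unexpected`, `p_value`, `method`, `seed`.
#' @export
glance.pbin_nestedness <- function(x, ...) {
  tibble(temperature = x$temperature, fill = x$fill,
         rows = x$rows, cols = x$cols,
         n_unexpected = nrow(x$unexpected),
         p_value = x$p_value, method = x$method, seed = x$seed)
}

#' Tidy a bipartite modularity partition
#'
#' @param x a `pbin_modularity` object.
#' @param ... unused.
#' @return a tibble with columns `label`, `side` (bacterium/phage), `module`.
#' @export
tidy.pbin_modularity <- function(x, ...) {
  bind_rows(
    x$bacteria |> rename(label = "bacterium") |> mutate(side = "bacterium"),
    x$phages |> rename(label = "phage") |> mutate(side = "phage")) |>
    relocate("label", "side", "module")
}

#' @export
glance.pbin_modularity <- function(x, ...) {
  tibble(Qb = x$Qb, n_modules = x$n_modules,
         restarts = x$restarts, seed = x$seed)
}

#' Tidy a phage clustering
#'
#' @param x a `phage_clusters` object.
#' @param ... unused.
#' @return the per-phage assignment tibble (`phage`, `cluster`, `R`, `V`).
#' @export
tidy.phage_clusters <- function(x, ...) x$assignments

#' @export
glance.phage_clusters <- function(x, ...) {
  tibble(k = x$k, n_phages = nrow(x$assignments),
         wss = x$wss[x$k], threshold = x$threshold)
}

#' Tidy a cocktail design
#'
#' @param x a `cocktail_design` object.
#' @param ... unused.
#' @return the selected-phage tibble (`phage`, `cluster`, `R`, `V`).
#' @export
tidy.cocktail_design <- function(x, ...) x$selected

#' @export
glance.cocktail_design <- function(x, ...) {
  tibble(phi = x$phi, coverage = x$coverage,
         mean_virulence = x$mean_virulence,
         supplemented = x$supplemented,
         n_combinations = x$n_combinations)
}
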