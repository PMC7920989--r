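#' Run the packing pipeline end to end
#'
#' Reads (or accepts) a quantitative host-range table, binarizes it, prunes
#' empty and redundant all-presence lines, packs it with one or both packers,
#' and optionally attaches null-model significance. When `output_dir` is
#' given, the packed matrix (CSV, in packed order) and a JSON report
#' (orderings, temperature, fill, p-value, seed and configuration echo, plus
#' the pruning report) are written there.
#'
#' @param input a file path (see [read_host_range()]) or a host-range tibble.
#' @param orientation passed to [read_host_range()] for file input.
#' @param threshold binarization cutoff (see [binarize()]).
#' @param collapse_full passed to [prune_redundant()].
#' @param packer `"ntc"`, `"genetic"`, or `"both"`.
#' @param control [ga_control()] settings for the genetic packer.
#' @param n_null nulls for [nestedness_significance()]; 0 skips the test.
#' @param null_model null model name (see [nestedness_significance()]).
#' @param seed integer seed governing the genetic search and the nulls.
#' @param output_dir directory for the packed CSV and JSON report, or `NULL`.
#' @return a list of class `"pbin_pack_report"` with elements `input_shape`,
#'   `prune`, `fill`, and one `pbin_nestedness` per requested packer
#'   (`$ntc`, `$genetic`).
#' @export
run_pack <- function(input, orientation = "bacteria_rows", threshold = 0,
                     collapse_full = TRUE, packer = c("ntc", "genetic", "both"),
                     control = ga_control(), n_null = 0L,
                     null_model = "equiprobable_fill", seed = 1L,
                     output_dir = NULL) {
  packer <- match.arg(packer)
  q <- if (is.character(input)) read_host_range(input, orientation) else input
  input_shape <- c(bacteria = nrow(q), phages = ncol(q) - 1L)
  b <- binarize(q, threshold = threshold)
  pruned <- prune_redundant(b, collapse_full = collapse_full)

  out <- list(input_shape = input_shape,
              prune = prune_report(pruned),
              fill = matrix_fill(pruned))
  if (packer %in% c("ntc", "both")) {
    res <- pack_ntc(pruned)
    if (n_null > 0L) {
      res <- nestedness_significance(pruned, res, n_null = n_null,
                                     model = null_model, seed = seed)
    }
    out$ntc <- res
  }
  if (packer %in% c("genetic", "both")) {
    res <- pack_genetic(pruned, control = control, seed = seed)
    if (n_null > 0L) {
      res <- nestedness_significance(pruned, res, n_null = n_null,
                                     model = null_model, seed = seed)
    }
    out$genetic <- res
  }
  class(out) <- "pbin_pack_report"
  if (!is.null(output_dir)) write_pack_report(out, pruned, output_dir)
  out
}

write_pack_report <- function(report, pruned, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (method in intersect(c("ntc", "genetic"), names(report))) {
    write_host_range(report[[method]]$packed,
                     file.path(output_dir, paste0("packed_", method, ".csv")))
  }
  jsonlite::write_json(report_json(report),
                       file.path(output_dir, "pack_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}

report_json <- function(report) {
  enc <- function(res) {
    if (is.null(res)) return(NULL)
    list(method = res$method,
         temperature = res$temperature,
         fill = res$fill,
         rows = res$rows, cols = res$cols,
         p_value = if (is.na(res$p_value)) NULL else res$p_value,
         seed = if (is.na(res$seed)) NULL else res$seed,
         row_permutation = res$row_permutation,
         col_permutation = res$col_permutation,
         n_unexpected = nrow(res$unexpected),
         control = if (is.null(res$control)) NULL else unclass(res$control),
         null_model = res$null_model)
  }
  list(input_shape = as.list(report$input_shape),
       prune = report$prune,
       fill = report$fill,
       ntc = enc(report$ntc),
       genetic = enc(report$genetic))
}

#' @export
print.pbin_pack_report <- function(x, ...) {
  cat(sprintf("Packing report: input %d bacteria x %d phages, pruned fill %.4g%%\n",
              x$input_shape[["bacteria"]], x$input_shape[["phages"]], x$fill))
  for (method in intersect(c("ntc", "genetic"), names(x))) print(x[[method]])
  invisible(x)
}

#' Design a phage cocktail from a quantitative host-range matrix
#'
#' The full pipeline: binarize and prune, pack (genetic packer by default),
#' estimate the cocktail size phi from (b, T, f) -- where b is the bacteria
#' count of the *input* matrix and T and f come from the packed, pruned
#' binary matrix -- then Ward-cluster the quantitative lysis profiles and
#' select one phage per cluster by exhaustive combination search.
#'
#' @inheritParams run_pack
#' @param phi_n estimator order (see [phi_cocktail_size()]).
#' @param phi_equation `"log"` or `"root"`.
#' @param phi override the estimated cocktail size (`NULL` = use estimate).
#' @param k override the elbow-selected number of clusters.
#' @param min_range cluster host-range filter in percent (see
#'   [select_cocktail()]).
#' @return a list of class `"pbin_design_report"`: `pack` (the
#'   `pbin_nestedness`), `phi`, `phi_inputs`, `clusters`, `cocktail`.
#' @export
run_design <- function(input, orientation = "bacteria_rows", threshold = 0,
                       collapse_full = TRUE, packer = c("genetic", "ntc"),
                       control = ga_control(), phi_equation = "log",
                       phi_n = 2L, phi = NULL, k = NULL, min_range = 30,
                       seed = 1L, output_dir = NULL) {
  packer <- match.arg(packer)
  q <- if (is.character(input)) read_host_range(input, orientation) else input
  b_input <- nrow(q)
  bin <- binarize(q, threshold = threshold)
  pruned <- prune_redundant(bin, collapse_full = collapse_full)
  packres <- if (packer == "genetic") {
    pack_genetic(pruned, control = control, seed = seed)
  } else {
    pack_ntc(pruned)
  }
  phi_est <- phi_cocktail_size(b_input, packres$temperature, packres$fill,
                               n = phi_n, equation = phi_equation)
  phi_used <- as.integer(phi %||% phi_est)
  clusters <- cluster_phages(q, k = k, threshold = threshold)
  cocktail <- select_cocktail(q, clusters, phi = phi_used,
                              min_range = min_range, threshold = threshold)
  out <- list(pack = packres,
              phi = phi_used,
              phi_estimate = phi_est,
              phi_inputs = list(b = b_input,
                                temperature = packres$temperature,
                                fill = packres$fill,
                                n = phi_n, equation = phi_equation),
              clusters = clusters,
              cocktail = cocktail)
  class(out) <- "pbin_design_report"
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(phi = out$phi, phi_estimate = out$phi_estimate,
           phi_inputs = out$phi_inputs,
           temperature = packres$temperature,
           fill = packres$fill,
           method = packres$method,
           seed = packres$seed,
           clusters = clusters$clusters |> mutate(
             members = purrr::map_chr(.data$members, paste, collapse = ",")),
           selected = out$cocktail$selected,
           coverage = out$cocktail$coverage,
           virulence = out$cocktail$virulence),
      file.path(output_dir, "design_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    export_dendrogram(clusters, file.path(output_dir, "phage_dendrogram.nwk"))
  }
  out
}

#' @export
print.pbin_design_report <- function(x, ...) {
  cat(sprintf("Cocktail design: phi = %d (T = %.4g, f = %.4g%%, b = %d)\n",
              x$phi, x$phi_inputs$temperature, x$phi_inputs$fill,
              x$phi_inputs$b))
  print(x$cocktail)
  invisible(x)
}

#' Validate the packaged infection-network survey
#'
#' Recomputes the cocktail size estimator for each of the 35 packaged survey
#' records from its printed (b, T, f) and compares with the published value.
#'
#' @return a list with `n`, `matches`, `phi_min`, `phi_max` and the survey
#'   `table`.
#' @examples
#' run_meta()$matches # 35
#' @export
run_meta <- function() {
  meta <- pbin_meta_survey()
  list(n = nrow(meta),
       matches = sum(meta$phi_match),
       phi_min = min(meta$phi),
       phi_max = max(meta$phi),
       table = meta)
}
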