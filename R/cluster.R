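#' Cluster phages by their quantitative lysis profiles
#'
#' Phage lysis profiles (the columns of a quantitative host-range table) are
#' clustered by agglomerative hierarchical clustering with Ward's linkage on
#' Euclidean distances (the squared-update `ward.D2` convention). When `k` is
#' not given it is chosen by the elbow method on the total within-cluster sum
#' of squares (see [elbow_k()]).
#'
#' For each cluster two host-range summaries are reported: `R_union`, the
#' percentage of bacteria lysed by at least one member (the realised range if
#' any member is picked for a cocktail), and `R_mean`, the mean of the member
#' host ranges. `V` is the mean lysis score over all member-by-host cells.
#' The per-host susceptibility `S` (mean score over all phages) is reported
#' alongside.
#'
#' @param data quantitative host-range tibble with at least two phages.
#' @param k number of clusters; chosen by the elbow method when `NULL`.
#' @param k_max largest k scanned by the elbow method (default: number of
#'   phages).
#' @param threshold lysis cutoff used when computing host ranges (see
#'   [binarize()]).
#' @return an object of class `"phage_clusters"`: list with `assignments`
#'   (tibble phage/cluster/R/V), `clusters` (per-cluster summary), `hosts`
#'   (per-host susceptibility S), `k`, `wss`, `hclust`, `threshold`.
#' @export
cluster_phages <- function(data, k = NULL, k_max = NULL, threshold = 0) {
  m <- validate_host_range(data)
  p <- ncol(m)
  if (p < 2L) abort("clustering needs at least two phages")
  if (!is.null(k) && (k < 1L || k > p)) {
    abort(sprintf("`k` must be between 1 and the number of phages (%d)", p))
  }
  profiles <- t(m) # phages x hosts
  hc <- hclust(dist(profiles), method = "ward.D2")

  k_max <- as.integer(k_max %||% p)
  wss <- vapply(seq_len(k_max), function(kk) {
    wss_total(profiles, cutree(hc, k = kk))
  }, numeric(1))
  if (is.null(k)) k <- elbow_k(wss)

  cl <- cutree(hc, k = k)
  bin <- m > threshold
  per_phage <- tibble(
    phage = colnames(m),
    cluster = as.integer(cl),
    R = 100 * colMeans(bin),
    V = colMeans(m))
  per_cluster <- per_phage |>
    group_by(.data$cluster) |>
    summarise(
      n = dplyr::n(),
      members = list(.data$phage),
      R_union = 100 * mean(
        rowSums(bin[, .data$phage, drop = FALSE]) > 0),
      R_mean = mean(.data$R),
      V = mean(m[, .data$phage]),
      .groups = "drop")
  hosts <- tibble(bacterium = rownames(m), S = rowMeans(m))

  structure(
    list(assignments = per_phage, clusters = per_cluster, hosts = hosts,
         k = as.integer(k), wss = wss, hclust = hc, threshold = threshold),
    class = "phage_clusters")
}

wss_total <- function(profiles, cl) {
  sum(vapply(split(seq_len(nrow(profiles)), cl), function(idx) {
    sub <- profiles[idx, , drop = FALSE]
    sum(scale(sub, scale = FALSE)^2)
  }, numeric(1)))
}

#' Choose the number of clusters by the elbow method
#'
#' Given the total within-cluster sum of squares for k = 1..k_max, picks the
#' k with the sharpest curvature, i.e. the maximum second difference
#' `wss[k-1] - 2*wss[k] + wss[k+1]` over interior k, with a flat reference of
#' zero at k = 1 so that a featureless (e.g. linear) decline yields k = 1.
#' Ties go to the smallest k; fewer than three points also yield 1.
#'
#' @param wss non-increasing numeric vector of within-cluster sums of squares.
#' @return the chosen k as an integer.
#' @examples
#' elbow_k(c(100, 20, 18, 17)) # 2
#' elbow_k(c(40, 30, 20, 10))  # 1 (linear: no elbow)
#' @export
elbow_k <- function(wss) {
  k_max <- length(wss)
  if (any(diff(wss) > 1e-8)) abort("`wss` must be non-increasing in k")
  if (k_max < 3L) return(1L)
  curv <- c(0, wss[seq_len(k_max - 2L)] - 2 * wss[seq(2L, k_max - 1L)] +
              wss[seq(3L, k_max)])
  which.max(curv) # ties -> smallest k; curv[1] is the k = 1 reference
}

#' Export the phage dendrogram in Newick format
#'
#' @param clusters a [cluster_phages()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_dendrogram <- function(clusters, path) {
  stopifnot(inherits(clusters, "phage_clusters"))
  ape::write.tree(ape::as.phylo(clusters$hclust), file = path)
  invisible(path)
}

#' @export
print.phage_clusters <- function(x, ...) {
  cat(sprintf("Ward clustering of %d phage lysis profiles into %d clusters\n",
              nrow(x$assignments), x$k))
  print(x$clusters |> select(-"members"), ...)
  invisible(x)
}
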