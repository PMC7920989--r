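#' Select cocktail members, one phage per cluster
#'
#' Implements the cluster-guided combination search: clusters whose (union)
#' host range falls below `min_range` are discarded, the survivors are sorted
#' by decreasing range (ties: higher mean virulence, then input order), the
#' top `phi` clusters contribute one phage each, and *all* one-phage-per-
#' cluster combinations are enumerated and scored lexicographically by
#' coverage (percent of bacteria lysed by at least one selected phage) and
#' then by the mean over bacteria of the best selected lysis score. If fewer
#' than `phi` clusters survive the filter, additional picks are drawn from
#' the broadest clusters, in order, and the design is flagged as
#' supplemented.
#'
#' @param data the quantitative host-range tibble the clusters were built
#'   from.
#' @param clusters a [cluster_phages()] result on `data`.
#' @param phi cocktail size, a positive integer (see [phi_cocktail_size()]).
#' @param min_range minimum cluster host range in percent (default 30);
#'   clusters strictly below it are discarded.
#' @param threshold lysis cutoff for coverage (see [binarize()]).
#' @param max_combinations above this many candidate combinations the
#'   exhaustive search is replaced by a slot-wise greedy selection, with a
#'   warning.
#' @return an object of class `"cocktail_design"`: list with `selected`
#'   (tibble phage/cluster/R/V), `phi`, `coverage`, `virulence` (per-strain
#'   expected scores, max and mean over the selection), `supplemented`,
#'   `n_combinations`, `min_range`, `threshold`.
#' @export
select_cocktail <- function(data, clusters, phi, min_range = 30,
                            threshold = 0, max_combinations = 1e5) {
  m <- validate_host_range(data)
  stopifnot(inherits(clusters, "phage_clusters"))
  if (length(phi) != 1L || phi < 1L || phi != floor(phi)) {
    abort("`phi` must be a single positive integer")
  }
  phi <- as.integer(phi)

  surv <- clusters$clusters |>
    filter(.data$R_union >= min_range) |>
    arrange(desc(.data$R_union), desc(.data$V), .data$cluster)
  if (nrow(surv) == 0L) {
    abort(sprintf(
      "no cluster reaches a host range of %g%% (best is %.3g%%): %s",
      min_range, max(clusters$clusters$R_union),
      "isolate broader phages or lower `min_range`"))
  }

  # slot -> cluster assignment; cycle through the broadest clusters if the
  # filter left fewer clusters than phi
  slot_cluster <- integer(0)
  sizes <- setNames(surv$n, surv$cluster)
  used <- setNames(integer(nrow(surv)), surv$cluster)
  ci <- 1L
  while (length(slot_cluster) < phi) {
    id <- as.character(surv$cluster[ci])
    if (used[id] < sizes[id]) {
      slot_cluster <- c(slot_cluster, surv$cluster[ci])
      used[id] <- used[id] + 1L
    }
    ci <- if (ci == nrow(surv)) 1L else ci + 1L
    if (all(used == sizes) && length(slot_cluster) < phi) {
      abort(sprintf(
        "only %d phages available in clusters passing the filter; phi = %d",
        sum(sizes), phi))
    }
  }
  supplemented <- length(slot_cluster) > nrow(surv) ||
    anyDuplicated(slot_cluster) > 0L

  members <- clusters$assignments
  per_cluster_members <- split(members$phage, members$cluster)
  slots_per_cluster <- table(slot_cluster)
  bin <- m > threshold

  # per-cluster combinations of distinct members, then cartesian product
  cluster_ids <- as.integer(names(slots_per_cluster))
  combo_sets <- lapply(cluster_ids, function(id) {
    mem <- per_cluster_members[[as.character(id)]]
    utils::combn(mem, slots_per_cluster[[as.character(id)]],
                 simplify = FALSE)
  })
  n_comb <- prod(vapply(combo_sets, length, numeric(1)))

  if (n_comb <= max_combinations) {
    grid <- expand.grid(lapply(combo_sets, seq_along))
    best <- NULL; best_cov <- -Inf; best_vir <- -Inf
    for (i in seq_len(nrow(grid))) {
      sel <- unlist(lapply(seq_along(combo_sets), function(j) {
        combo_sets[[j]][[grid[i, j]]]
      }))
      cov <- 100 * mean(rowSums(bin[, sel, drop = FALSE]) > 0)
      vir <- mean(apply(m[, sel, drop = FALSE], 1L, max))
      if (cov > best_cov + 1e-12 ||
          (cov > best_cov - 1e-12 && vir > best_vir + 1e-12)) {
        best <- sel; best_cov <- cov; best_vir <- vir
      }
    }
  } else {
    warn(sprintf(
      "%.3g candidate combinations exceed `max_combinations`; %s",
      n_comb, "falling back to slot-wise greedy selection"))
    best <- character(0)
    for (cl_id in slot_cluster) {
      cand <- setdiff(per_cluster_members[[as.character(cl_id)]], best)
      scores <- vapply(cand, function(ph) {
        sel <- c(best, ph)
        c(100 * mean(rowSums(bin[, sel, drop = FALSE]) > 0),
          mean(apply(m[, sel, drop = FALSE], 1L, max)))
      }, numeric(2))
      pick <- order(-scores[1L, ], -scores[2L, ])[1L]
      best <- c(best, cand[pick])
    }
    best_cov <- 100 * mean(rowSums(bin[, best, drop = FALSE]) > 0)
    best_vir <- mean(apply(m[, best, drop = FALSE], 1L, max))
  }

  sel_tab <- members |>
    filter(.data$phage %in% best) |>
    arrange(match(.data$phage, best))
  virulence <- tibble(
    bacterium = rownames(m),
    virulence_max = apply(m[, best, drop = FALSE], 1L, max),
    virulence_mean = rowMeans(m[, best, drop = FALSE]))

  structure(
    list(selected = sel_tab, phi = phi,
         coverage = best_cov,
         mean_virulence = best_vir,
         virulence = virulence,
         supplemented = supplemented,
         n_combinations = n_comb,
         min_range = min_range, threshold = threshold),
    class = "cocktail_design")
}

#' @export
print.cocktail_design <- function(x, ...) {
  cat(sprintf(
    "Phage cocktail of %d: coverage %.3g%%, mean best lysis score %.3g\n",
    x$phi, x$coverage, x$mean_virulence))
  print(x$selected, ...)
  if (x$supplemented) {
    cat("note: fewer clusters than phi survived the range filter;",
        "extra members drawn from the broadest clusters\n")
  }
  invisible(x)
}
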