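#' Pack a binary matrix with the heuristic temperature-calculator sort
#'
#' The heuristic packer alternately reorders columns and then rows by
#' descending marginal totals, iterating the column/row pass exactly eight
#' times. Ties on the marginal total are broken by the weighted position of
#' the presences (profiles concentrated towards the packed corner rank first)
#' and finally by the incoming order, so the procedure is fully deterministic.
#'
#' @param data pruned binary host-range tibble (no empty lines, fill strictly
#'   inside (0, 100); see [prune_redundant()]).
#' @return a `pbin_nestedness` object with fields `packed` (the reordered
#'   tibble), `row_permutation`/`col_permutation` (indices into the input),
#'   `temperature`, `fill`, `unexpected` (per-cell d and D records),
#'   `isocline`, `method`, and `p_value` (`NA` until
#'   [nestedness_significance()] fills it).
#' @examples
#' b <- sim_nested(10, 10, fill = 40)
#' pack_ntc(b)$temperature # 0 by construction
#' @export
pack_ntc <- function(data) {
  m <- validate_host_range(data, binary = TRUE)
  check_packable(m)
  ord <- ntc_orders(m)
  ctx <- temp_context(nrow(m), ncol(m), sum(m))
  new_nestedness(m, ord$rp, ord$cp, ctx, method = "ntc", seed = NA_integer_)
}

# eight alternating column-then-row marginal sorts; returns index permutations
ntc_orders <- function(m) {
  rp <- seq_len(nrow(m))
  cp <- seq_len(ncol(m))
  for (pass in 1:8) {
    cur <- m[rp, cp, drop = FALSE]
    cs <- colSums(cur)
    wc <- apply(cur, 2L, presence_centroid)
    cp <- cp[order(-cs, wc)]
    cur <- m[rp, cp, drop = FALSE]
    rs <- rowSums(cur)
    wr <- apply(cur, 1L, presence_centroid)
    rp <- rp[order(-rs, wr)]
  }
  list(rp = rp, cp = cp)
}

# mean position of the presences in a 0/1 profile (lower = closer to the
# packed corner); empty profiles sit at the centre so they sort last stably
presence_centroid <- function(v) {
  idx <- which(v == 1)
  if (length(idx) == 0L) (length(v) + 1) / 2 else mean(idx)
}

#' Genetic-algorithm settings for [pack_genetic()]
#'
#' Defaults follow the classic matrix-packing setup: a population of 1,000
#' candidate orderings evolved for up to 2,000 generations with elitist
#' selection. Tests and routine desk use run far smaller budgets; the
#' generation count is a ceiling, and the search stops early once the best
#' temperature has stagnated for `stagnation_patience` generations.
#'
#' @param population_size number of candidate (row, column) orderings, >= 2.
#' @param generations maximum number of generations, >= 1.
#' @param elite_fraction fraction of the population carried over unchanged.
#' @param mutation_rate per-offspring probability of each mutation operator
#'   (a random adjacent transposition and a random block reversal).
#' @param stagnation_patience generations without improvement before stopping.
#' @return a list of class `"pbin_ga_control"`.
#' @export
ga_control <- function(population_size = 1000L, generations = 2000L,
                       elite_fraction = 0.05, mutation_rate = 0.3,
                       stagnation_patience = 200L) {
  if (population_size < 2L) abort("`population_size` must be at least 2")
  if (generations < 1L) abort("`generations` must be at least 1")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 elite_fraction = elite_fraction,
                 mutation_rate = mutation_rate,
                 crossover = "order_crossover",
                 stagnation_patience = as.integer(stagnation_patience)),
            class = "pbin_ga_control")
}

#' Pack a binary matrix with a genetic algorithm
#'
#' Searches the space of row and column permutations for the ordering that
#' minimises the nestedness temperature. The initial population contains the
#' descending-marginal ordering, the eight-pass heuristic ordering
#' ([pack_ntc()]), and random permutations; fitness is the negative
#' temperature, selection is elitist (so the final temperature can never
#' exceed either seeded ordering's temperature), offspring are produced by
#' order crossover applied to the row and column permutations independently,
#' and mutation applies a random adjacent transposition and a random block
#' reversal, each at `mutation_rate`. A fixed `seed` makes the whole run
#' bit-reproducible.
#'
#' @inheritParams pack_ntc
#' @param control a [ga_control()] list.
#' @param seed integer seed for the search.
#' @return a `pbin_nestedness` object (see [pack_ntc()]), with the control
#'   settings echoed in `$control`.
#' @export
pack_genetic <- function(data, control = ga_control(), seed = 1L) {
  m <- validate_host_range(data, binary = TRUE)
  check_packable(m)
  stopifnot(inherits(control, "pbin_ga_control"))
  ctx <- temp_context(nrow(m), ncol(m), sum(m))
  res <- withr::with_seed(as.integer(seed), ga_search(m, ctx, control))
  new_nestedness(m, res$rp, res$cp, ctx, method = "genetic",
                 seed = as.integer(seed), control = control)
}

ga_search <- function(m, ctx, control) {
  R <- nrow(m); C <- ncol(m)
  pop_n <- control$population_size
  score <- function(ind) sum(ctx$Pd * m[ind$rp, ind$cp, drop = FALSE])

  marg <- list(rp = order(-rowSums(m)), cp = order(-colSums(m)))
  ntc <- ntc_orders(m)
  pop <- vector("list", pop_n)
  pop[[1L]] <- marg
  pop[[2L]] <- ntc
  if (pop_n > 2L) {
    for (i in 3:pop_n) {
      pop[[i]] <- list(rp = sample.int(R), cp = sample.int(C))
    }
  }
  fit <- vapply(pop, score, numeric(1))

  n_elite <- max(1L, ceiling(control$elite_fraction * pop_n))
  best <- min(fit)
  stagnation <- 0L

  for (gen in seq_len(control$generations)) {
    ord <- order(fit)
    pop <- pop[ord]; fit <- fit[ord]
    children <- vector("list", pop_n - n_elite)
    child_fit <- numeric(pop_n - n_elite)
    for (k in seq_along(children)) {
      pa <- tournament(fit, pop_n)
      pb <- tournament(fit, pop_n)
      child <- list(rp = ox_crossover(pop[[pa]]$rp, pop[[pb]]$rp),
                    cp = ox_crossover(pop[[pa]]$cp, pop[[pb]]$cp))
      if (runif(1) < control$mutation_rate) {
        child$rp <- mut_adjacent(child$rp)
        child$cp <- mut_adjacent(child$cp)
      }
      if (runif(1) < control$mutation_rate) {
        child$rp <- mut_reversal(child$rp)
        child$cp <- mut_reversal(child$cp)
      }
      children[[k]] <- child
      child_fit[k] <- score(child)
    }
    pop <- c(pop[seq_len(n_elite)], children)
    fit <- c(fit[seq_len(n_elite)], child_fit)
    gen_best <- min(fit)
    if (gen_best < best - 1e-15) {
      best <- gen_best
      stagnation <- 0L
    } else {
      stagnation <- stagnation + 1L
      if (stagnation >= control$stagnation_patience) break
    }
  }
  pop[[which.min(fit)]]
}

# binary tournament on raw penalty scores (lower is fitter)
tournament <- function(fit, n) {
  ij <- sample.int(n, 2L)
  if (fit[ij[1L]] <= fit[ij[2L]]) ij[1L] else ij[2L]
}

# order crossover: keep a random slice of `a`, fill the rest in `b`'s order
ox_crossover <- function(a, b) {
  n <- length(a)
  if (n < 2L) return(a)
  cuts <- sort(sample.int(n, 2L))
  seg <- a[cuts[1L]:cuts[2L]]
  child <- integer(n)
  child[cuts[1L]:cuts[2L]] <- seg
  child[-(cuts[1L]:cuts[2L])] <- b[!(b %in% seg)]
  child
}

mut_adjacent <- function(p) {
  n <- length(p)
  if (n < 2L) return(p)
  i <- sample.int(n - 1L, 1L)
  p[c(i, i + 1L)] <- p[c(i + 1L, i)]
  p
}

mut_reversal <- function(p) {
  n <- length(p)
  if (n < 2L) return(p)
  ij <- sort(sample.int(n, 2L))
  p[ij[1L]:ij[2L]] <- rev(p[ij[1L]:ij[2L]])
  p
}
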