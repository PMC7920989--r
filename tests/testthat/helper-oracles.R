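# Independent oracles used across the suite. These re-derive expected values
# from first principles (or by exhaustive enumeration) without touching the
# package's own code paths, except where the enumeration deliberately reuses
# the temperature definition to isolate the optimiser under test.

# transpose a host-range tibble
hr_t <- function(data) {
  m <- as.matrix(data[-1])
  rownames(m) <- data$bacterium
  out <- tibble::as_tibble(t(m), .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(bacterium = colnames(m)), out)
}

hr_mat <- function(data) {
  m <- as.matrix(data[-1])
  storage.mode(m) <- "double"
  rownames(m) <- data$bacterium
  m
}

hr_tbl <- function(m) {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(bacterium = rownames(m)), out)
}

rand_binary_tbl <- function(rows, cols, p = 0.5, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      m <- matrix(rbinom(rows * cols, 1, p), rows, cols)
      if (all(rowSums(m) > 0) && all(colSums(m) > 0) &&
          sum(m) > 0 && sum(m) < rows * cols) break
    }
    dimnames(m) <- list(paste0("b", seq_len(rows)), paste0("p", seq_len(cols)))
    hr_tbl(m)
  })
}

# all permutations of a vector, one per row
all_perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L, 1L))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], all_perms(v[-i]))
  }))
}

# exhaustive minimum temperature over every row x column ordering; reuses the
# package temperature definition so that it isolates the *optimiser*
brute_min_temperature <- function(data) {
  m <- hr_mat(data)
  ctx <- pbindesign:::temp_context(nrow(m), ncol(m), sum(m))
  rp_all <- all_perms(seq_len(nrow(m)))
  cp_all <- all_perms(seq_len(ncol(m)))
  best <- Inf
  for (i in seq_len(nrow(rp_all))) {
    for (j in seq_len(nrow(cp_all))) {
      tt <- pbindesign:::temp_eval(m, rp_all[i, ], cp_all[j, ], ctx)
      if (tt < best) best <- tt
    }
  }
  best
}

# independent re-implementation of the eight-pass alternating marginal sort
ntc_oracle_orders <- function(m) {
  centroid <- function(v) if (sum(v) == 0) (length(v) + 1) / 2 else mean(which(v == 1))
  rp <- seq_len(nrow(m)); cp <- seq_len(ncol(m))
  for (pass in 1:8) {
    cur <- m[rp, cp, drop = FALSE]
    cp <- cp[order(-colSums(cur), apply(cur, 2, centroid))]
    cur <- m[rp, cp, drop = FALSE]
    rp <- rp[order(-rowSums(cur), apply(cur, 1, centroid))]
  }
  list(rp = rp, cp = cp)
}

# direct double-loop Barber Qb (no matrix algebra shortcuts)
qb_oracle <- function(data, g, h) {
  m <- hr_mat(data)
  tot <- sum(m)
  acc <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (g[i] == h[j]) {
        acc <- acc + m[i, j] - sum(m[i, ]) * sum(m[, j]) / tot
      }
    }
  }
  acc / tot
}

# independent exhaustive cocktail search following the written selection
# contract: filter clusters by union range, sort by (range desc, V desc,
# cluster id), assign slots cycling the sorted list, enumerate every distinct
# selection, score by (coverage, mean best score), return the winning set
cocktail_oracle <- function(data, clusters, phi, min_range = 30,
                            threshold = 0) {
  m <- hr_mat(data)
  bin <- m > threshold
  tab <- clusters$clusters
  tab <- tab[tab$R_union >= min_range, ]
  tab <- tab[order(-tab$R_union, -tab$V, tab$cluster), ]
  stopifnot(nrow(tab) > 0)
  slots <- integer(0)
  taken <- stats::setNames(integer(nrow(tab)), tab$cluster)
  i <- 1L
  while (length(slots) < phi) {
    id <- as.character(tab$cluster[i])
    if (taken[id] < tab$n[tab$cluster == as.integer(id)]) {
      slots <- c(slots, as.integer(id)); taken[id] <- taken[id] + 1L
    }
    i <- if (i == nrow(tab)) 1L else i + 1L
  }
  member_list <- split(clusters$assignments$phage,
                       clusters$assignments$cluster)
  cand <- expand.grid(lapply(slots, function(id) {
    member_list[[as.character(id)]]
  }), stringsAsFactors = FALSE)
  keep <- apply(cand, 1L, function(r) !anyDuplicated(r))
  cand <- cand[keep, , drop = FALSE]
  key <- apply(cand, 1L, function(r) paste(sort(r), collapse = "|"))
  cand <- cand[!duplicated(key), , drop = FALSE]
  bc <- -Inf; bv <- -Inf; optima <- list()
  for (r in seq_len(nrow(cand))) {
    sel <- unlist(cand[r, ], use.names = FALSE)
    cov <- 100 * mean(rowSums(bin[, sel, drop = FALSE]) > 0)
    vir <- mean(apply(m[, sel, drop = FALSE], 1, max))
    if (cov > bc + 1e-12 || (cov > bc - 1e-12 && vir > bv + 1e-12)) {
      optima <- list(sort(sel)); bc <- cov; bv <- vir
    } else if (abs(cov - bc) <= 1e-12 && abs(vir - bv) <= 1e-12) {
      optima <- c(optima, list(sort(sel))) # co-optimal tie
    }
  }
  list(phages = optima[[1]], optima = optima, coverage = bc, virulence = bv)
}
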