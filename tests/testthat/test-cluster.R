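test_that("the elbow rule follows curvature with ties to the smallest k", {
  expect_identical(elbow_k(c(100, 20, 18, 17)), 2L) # dominant drop at k = 2
  expect_identical(elbow_k(c(40, 30, 20, 10)), 1L)  # linear: no elbow
  expect_identical(elbow_k(c(10, 5)), 1L)           # too short to bend
  expect_error(elbow_k(c(10, 12, 5)), "non-increasing")
})

test_that("identical profiles collapse to one cluster", {
  m <- matrix(rep(c(0, 2, 3, 1), 4), 4, 4,
              dimnames = list(paste0("b", 1:4), paste0("p", 1:4)))
  cl <- cluster_phages(hr_tbl(m))
  expect_identical(cl$k, 1L)
  expect_true(all(cl$assignments$cluster == 1L))
})

test_that("planted profile groups are recovered exactly", {
  q <- sim_quantitative(20, 12, n_groups = 2, noise_sd = 0.2, seed = 13)
  cl <- cluster_phages(q)
  expect_identical(cl$k, 2L)
  planted <- attr(q, "planted")
  tab <- table(cl$assignments$cluster, planted)
  expect_true(all(rowSums(tab > 0) == 1)) # one planted group per cluster
})

test_that("the elbow sees three well-separated planted groups", {
  q <- sim_quantitative(24, 15, n_groups = 3, noise_sd = 0.15, seed = 19)
  profiles <- t(hr_mat(q))
  hc <- stats::hclust(dist(profiles), method = "ward.D2")
  wss <- vapply(1:10, function(k) {
    cl <- stats::cutree(hc, k)
    sum(vapply(split(seq_len(nrow(profiles)), cl), function(i) {
      sum(scale(profiles[i, , drop = FALSE], scale = FALSE)^2)
    }, numeric(1)))
  }, numeric(1))
  expect_identical(elbow_k(wss), 3L)
  expect_identical(cluster_phages(q)$k, 3L)
})

test_that("forcing k to the number of phages yields singletons", {
  q <- sim_quantitative(10, 6, n_groups = 3, noise_sd = 0.4, seed = 23)
  cl <- cluster_phages(q, k = 6)
  expect_identical(sort(unique(cl$assignments$cluster)), 1:6)
  m <- hr_mat(q)
  # each singleton cluster's V is that phage's mean score
  merged <- dplyr::left_join(cl$assignments,
                             cl$clusters, by = "cluster")
  expect_equal(merged$V.y, colMeans(m)[merged$phage], ignore_attr = TRUE)
  expect_error(cluster_phages(q, k = 7), "between 1 and")
})

test_that("cluster summaries report union range, mean range, V and S", {
  m <- rbind(b1 = c(3, 0, 0), b2 = c(0, 3, 0), b3 = c(0, 0, 3),
             b4 = c(0, 0, 0))
  colnames(m) <- c("p1", "p2", "p3")
  cl <- cluster_phages(hr_tbl(m), k = 2)
  expect_identical(nrow(cl$clusters), 2L)
  # susceptibility is the per-host mean over all phages
  expect_equal(cl$hosts$S, rowMeans(m), ignore_attr = TRUE)
  # the union range of a cluster can exceed each member's own range
  pooled <- cl$clusters[cl$clusters$n > 1, ]
  if (nrow(pooled) == 1) expect_gte(pooled$R_union, pooled$R_mean)
})

test_that("the dendrogram exports as readable Newick", {
  q <- sim_quantitative(8, 5, n_groups = 2, noise_sd = 0.3, seed = 29)
  cl <- cluster_phages(q)
  tf <- withr::local_tempfile(fileext = ".nwk")
  export_dendrogram(cl, tf)
  tree <- ape::read.tree(tf)
  expect_setequal(tree$tip.label, cl$assignments$phage)
})
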