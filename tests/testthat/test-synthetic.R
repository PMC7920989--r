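test_that("generators are bit-reproducible under a fixed seed", {
  expect_identical(sim_random(12, 9, 40, seed = 5), sim_random(12, 9, 40, seed = 5))
  expect_identical(sim_modular(10, 10, 2, seed = 5), sim_modular(10, 10, 2, seed = 5))
  expect_identical(sim_quantitative(10, 8, 2, seed = 5),
                   sim_quantitative(10, 8, 2, seed = 5))
  expect_false(identical(sim_random(12, 9, 40, seed = 5),
                         sim_random(12, 9, 40, seed = 6)))
})

test_that("nested matrices have a monotone staircase boundary and pack to 0", {
  for (f in c(10, 50)) {
    b <- sim_nested(20, 20, fill = f)
    m <- hr_mat(b)
    expect_true(all(diff(rowSums(m)) <= 0))
    expect_true(all(diff(colSums(m)) <= 0))
    # presences form a prefix of each row (true nestedness, not just sums)
    expect_true(all(apply(m, 1, function(r) all(diff(r) <= 0))))
    # needs no pruning: no empty lines, at most one full row/column
    expect_true(all(rowSums(m) > 0) && all(colSums(m) > 0))
    expect_lte(sum(rowSums(m) == ncol(m)), 1L)
    expect_lte(sum(colSums(m) == nrow(m)), 1L)
    expect_equal(pack_ntc(b)$temperature, 0, tolerance = 1e-12)
  }
  b <- sim_nested(20, 20, fill = 10)
  m <- hr_mat(b)
  # extreme fills shrink to the pruning-free nested core; the attribute
  # reports the fill actually realized on the returned shape
  expect_lte(nrow(m), 20L)
  expect_equal(attr(b, "realized_fill"), 100 * sum(m) / length(m))
})

test_that("a shuffled nested matrix round-trips through the genetic packer", {
  b <- sim_nested(12, 12, fill = 35)
  shuffled <- shuffle_host_range(b, seed = 8)
  res <- pack_genetic(shuffled, ga_control(population_size = 40,
                                           generations = 60,
                                           stagnation_patience = 30),
                      seed = 2)
  expect_equal(res$temperature, 0, tolerance = 1e-12)
})

test_that("random matrices hit the requested fill on average", {
  fills <- vapply(1:60, function(s) matrix_fill(sim_random(40, 40, 50, seed = s)),
                  numeric(1))
  se <- stats::sd(fills) / sqrt(length(fills))
  expect_lt(abs(mean(fills) - 50), 3 * se + 0.5)
})

test_that("random ensembles run hotter than nested ones", {
  t_rand <- vapply(1:5, function(s) {
    pack_ntc(rand_binary_tbl(20, 20, 0.5, seed = s))$temperature
  }, numeric(1))
  t_nested <- pack_ntc(sim_nested(20, 20, 50))$temperature
  expect_gt(min(t_rand), t_nested)
})

test_that("modular generator plants the partition it reports", {
  mod <- sim_modular(9, 12, n_modules = 3, within_density = 1,
                     between_density = 0, seed = 9)
  planted <- attr(mod, "planted")
  m <- hr_mat(mod)
  expect_identical(dim(m), c(9L, 12L))
  within <- outer(planted$row_modules, planted$col_modules, "==")
  expect_true(all(m[within] == 1))
  expect_true(all(m[!within] == 0))
})

test_that("quantitative groups are identical at zero noise and integer-valued", {
  q <- sim_quantitative(15, 9, n_groups = 3, noise_sd = 0, seed = 14)
  m <- hr_mat(q)
  planted <- attr(q, "planted")
  for (g in unique(planted)) {
    cols <- m[, planted == g, drop = FALSE]
    expect_true(all(cols == cols[, 1]))
  }
  expect_true(all(m %in% 0:3))
})
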