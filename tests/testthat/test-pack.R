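test_that("the heuristic packer fixes an already-packed nested matrix", {
  b <- sim_nested(10, 10, fill = 35)
  res <- pack_ntc(b)
  expect_identical(res$row_permutation, seq_len(nrow(b)))
  expect_identical(res$col_permutation, seq_len(ncol(b) - 1L))
  expect_equal(res$temperature, 0, tolerance = 1e-12)
})

test_that("the heuristic packer recovers a shuffled nested matrix", {
  b <- sim_nested(10, 10, fill = 40)
  shuffled <- shuffle_host_range(b, seed = 21)
  res <- pack_ntc(shuffled)
  expect_equal(res$temperature, 0, tolerance = 1e-12)
})

test_that("the heuristic packer agrees with an independent 8-pass sort", {
  for (seed in c(2, 5, 8)) {
    b <- rand_binary_tbl(4, 4, p = 0.5, seed = seed)
    m <- hr_mat(b)
    res <- pack_ntc(b)
    oracle <- ntc_oracle_orders(m)
    expect_identical(res$row_permutation, as.integer(oracle$rp))
    expect_identical(res$col_permutation, as.integer(oracle$cp))
    ctx <- pbindesign:::temp_context(4, 4, sum(m))
    expect_equal(res$temperature,
                 pbindesign:::temp_eval(m, oracle$rp, oracle$cp, ctx),
                 tolerance = 1e-9)
  }
})

test_that("the genetic packer finds the global optimum of a shuffled nested matrix", {
  b <- sim_nested(15, 15, fill = 40)
  shuffled <- shuffle_host_range(b, seed = 3)
  res <- pack_genetic(shuffled,
                      ga_control(population_size = 60, generations = 80,
                                 stagnation_patience = 40), seed = 1)
  expect_equal(res$temperature, 0, tolerance = 1e-12)
})

test_that("seeding and elitism keep the genetic packer at or below the heuristic", {
  ctrl <- ga_control(population_size = 30, generations = 25,
                     stagnation_patience = 25)
  for (seed in 1:8) {
    b <- rand_binary_tbl(12, 12, p = 0.4, seed = 100 + seed)
    t_ntc <- pack_ntc(b)$temperature
    t_gen <- pack_genetic(b, ctrl, seed = seed)$temperature
    expect_lte(t_gen, t_ntc + 1e-12)
  }
})

test_that("a fixed seed makes the genetic packer bit-reproducible", {
  b <- rand_binary_tbl(10, 8, p = 0.5, seed = 42)
  ctrl <- ga_control(population_size = 25, generations = 20,
                     stagnation_patience = 20)
  r1 <- pack_genetic(b, ctrl, seed = 7)
  r2 <- pack_genetic(b, ctrl, seed = 7)
  expect_identical(r1$row_permutation, r2$row_permutation)
  expect_identical(r1$col_permutation, r2$col_permutation)
  expect_identical(r1$temperature, r2$temperature)
})

test_that("the genetic packer attains the exhaustive minimum on a small matrix", {
  b <- rand_binary_tbl(4, 4, p = 0.5, seed = 17)
  best <- brute_min_temperature(b)
  res <- pack_genetic(b, ga_control(population_size = 60, generations = 60,
                                    stagnation_patience = 40), seed = 5)
  expect_equal(res$temperature, best, tolerance = 1e-9)
})

test_that("packers reject degenerate input", {
  full <- hr_tbl(matrix(1, 3, 3, dimnames = list(letters[1:3], LETTERS[1:3])))
  expect_error(pack_ntc(full), "degenerate")
  expect_error(pack_genetic(full), "degenerate")
})
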