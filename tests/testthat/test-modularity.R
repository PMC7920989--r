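test_that("Qb is zero for the fully connected single-module network", {
  m <- hr_tbl(matrix(1, 4, 6, dimnames = list(paste0("b", 1:4),
                                              paste0("p", 1:6))))
  expect_equal(barber_qb(m, rep(1, 4), rep(1, 6)), 0, tolerance = 1e-12)
})

test_that("k equal complete modules give Qb = 1 - 1/k, matching a direct sum", {
  two <- sim_modular(10, 10, n_modules = 2, within_density = 1,
                     between_density = 0, seed = 1)
  planted <- attr(two, "planted")
  expect_equal(barber_qb(two, planted$row_modules, planted$col_modules), 0.5,
               tolerance = 1e-12)
  expect_equal(qb_oracle(two, planted$row_modules, planted$col_modules), 0.5,
               tolerance = 1e-12)

  three <- sim_modular(12, 12, n_modules = 3, within_density = 1,
                       between_density = 0, seed = 2)
  p3 <- attr(three, "planted")
  expect_equal(barber_qb(three, p3$row_modules, p3$col_modules), 2 / 3,
               tolerance = 1e-12)
})

test_that("matrix-form Qb equals the double-loop definition on random input", {
  b <- rand_binary_tbl(7, 9, p = 0.4, seed = 12)
  g <- rep_len(1:3, 7); h <- rep_len(1:3, 9)
  expect_equal(barber_qb(b, g, h), qb_oracle(b, g, h), tolerance = 1e-12)
})

test_that("moving one phage off the planted partition lowers Qb", {
  two <- sim_modular(10, 10, n_modules = 2, within_density = 1,
                     between_density = 0, seed = 1)
  planted <- attr(two, "planted")
  wrong <- planted$col_modules
  wrong[1] <- 2
  expect_lt(barber_qb(two, planted$row_modules, wrong),
            barber_qb(two, planted$row_modules, planted$col_modules))
})

test_that("lp_brim recovers planted blocks and their closed-form Qb", {
  two <- sim_modular(10, 12, n_modules = 2, within_density = 1,
                     between_density = 0, seed = 5)
  fit <- lp_brim(two, seed = 3, restarts = 10)
  expect_equal(fit$Qb, 0.5, tolerance = 1e-9)
  planted <- attr(two, "planted")
  # identical partition up to relabelling
  expect_identical(length(unique(paste(fit$bacteria$module,
                                       planted$row_modules))), 2L)

  ones <- hr_tbl(matrix(1, 3, 3, dimnames = list(letters[1:3],
                                                 LETTERS[1:3])))
  fit1 <- lp_brim(ones, seed = 1, restarts = 3)
  expect_equal(fit1$Qb, 0, tolerance = 1e-12)
  expect_identical(fit1$n_modules, 1L)
})

test_that("lp_brim is deterministic for a fixed seed and improves on noise", {
  noisy <- sim_modular(14, 14, n_modules = 2, within_density = 0.9,
                       between_density = 0.05, seed = 7)
  f1 <- lp_brim(noisy, seed = 11, restarts = 5)
  f2 <- lp_brim(noisy, seed = 11, restarts = 5)
  expect_identical(f1$bacteria, f2$bacteria)
  expect_identical(f1$phages, f2$phages)
  expect_identical(f1$Qb, f2$Qb)
  # recovered labels agree with the planting for nearly all nodes
  planted <- attr(noisy, "planted")
  agree <- function(fit) {
    all_lab <- c(fit$bacteria$module, fit$phages$module)
    all_pl <- c(planted$row_modules, planted$col_modules)
    max(mean(all_lab == all_pl), mean(all_lab != all_pl)) # up to relabel (k=2)
  }
  expect_gte(agree(f1), 0.95)
})
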