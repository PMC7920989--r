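test_that("read/write round-trips labels and values bit-exactly", {
  q <- tibble::tibble(bacterium = c("Ec 1", "Ec-2", "K12"),
                      `phi A` = c(0, 1.5, 3), phiB = c(2.25, 0, 0.5))
  for (ext in c(".csv", ".tsv")) {
    tf <- withr::local_tempfile(fileext = ext)
    write_host_range(q, tf)
    back <- read_host_range(tf)
    expect_identical(back$bacterium, q$bacterium)
    expect_identical(names(back), names(q))
    expect_identical(as.matrix(back[-1]), as.matrix(q[-1]))
  }
})

test_that("phages_rows orientation transposes, and transposing is an involution", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",s1,s2,s3", "phiA,0,1.5,3", "phiB,2,0,1"), tf)
  as_phage_rows <- read_host_range(tf, orientation = "phages_rows")
  expect_identical(as_phage_rows$bacterium, c("s1", "s2", "s3"))
  expect_identical(names(as_phage_rows)[-1], c("phiA", "phiB"))
  straight <- read_host_range(tf)
  expect_identical(hr_mat(as_phage_rows), t(hr_mat(straight)))
})

test_that("malformed input is rejected with a useful message", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",p1,p2", "s1,0,3.5", "s2,1,0"), tf)
  expect_error(read_host_range(tf), "\\[0, 3\\]")

  writeLines(c(",p1,p2", "s1,0,oops", "s2,1,0"), tf)
  expect_error(read_host_range(tf), "non-numeric.*oops.*s1.*p2")

  writeLines(c(",p1,p1", "s1,0,1", "s2,1,0"), tf)
  expect_error(read_host_range(tf), "duplicate phage")

  writeLines(c(",p1,p2", "s1,0", "s2,1,0"), tf)
  expect_error(read_host_range(tf), "ragged")
})

test_that("binarize follows the strict-threshold definition and computes fill", {
  q <- hr_tbl(matrix(c(0, 3, 1, 0), 2, 2,
                     dimnames = list(c("a", "b"), c("x", "y"))))
  b <- binarize(q)
  expect_identical(unname(hr_mat(b)), matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(matrix_fill(b), 50)

  zero <- hr_tbl(matrix(0, 3, 2, dimnames = list(letters[1:3], c("x", "y"))))
  expect_equal(matrix_fill(binarize(zero)), 0)
  expect_error(binarize(q, threshold = 3), "\\[0, 3\\)")
})

test_that("binarize is monotone in the threshold", {
  q <- sim_quantitative(12, 8, n_groups = 2, noise_sd = 0.6, seed = 11)
  prev <- hr_mat(binarize(q, 0))
  for (t in c(0.5, 1, 1.9, 2.5)) {
    cur <- hr_mat(binarize(q, t))
    expect_true(all(cur <= prev)) # raising t never creates a 1
    prev <- cur
  }
})

test_that("generated quantitative fill equals an independent positive count", {
  q <- sim_quantitative(10, 10, n_groups = 3, noise_sd = 0.4, seed = 3)
  m <- hr_mat(q)
  expect_equal(matrix_fill(binarize(q)), 100 * sum(m > 0) / 100)
})

test_that("pruning removes empty lines and collapses duplicate full lines", {
  m <- matrix(c(1, 1,
                0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("r1", "r2"), c("c1", "c2")))
  pr <- prune_redundant(hr_tbl(m))
  expect_identical(pr$bacterium, "r1")
  expect_identical(prune_report(pr)$removed_empty_rows, "r2")

  # three identical all-one rows among five: keep the first, drop two
  m5 <- rbind(full1 = c(1, 1, 1), a = c(1, 0, 0), full2 = c(1, 1, 1),
              b = c(0, 1, 0), full3 = c(1, 1, 1))
  colnames(m5) <- c("c1", "c2", "c3")
  pr5 <- prune_redundant(hr_tbl(m5))
  rep5 <- prune_report(pr5)
  expect_identical(rep5$collapsed_full_rows, c("full2", "full3"))
  expect_identical(rep5$representative_row, "full1")
  expect_true("full1" %in% pr5$bacterium)
  # removed + retained labels reconstruct the input label set
  expect_setequal(c(pr5$bacterium, rep5$removed_empty_rows,
                    rep5$collapsed_full_rows), rownames(m5))
})

test_that("pruning is idempotent and the identity on clean matrices", {
  clean <- rand_binary_tbl(6, 5, p = 0.5, seed = 4)
  once <- prune_redundant(clean)
  expect_identical(hr_mat(once), hr_mat(clean))
  expect_length(prune_report(once)$removed_empty_rows, 0)

  messy <- hr_tbl(rbind(f1 = c(1, 1, 1, 0), f2 = c(1, 1, 1, 0),
                        a = c(1, 0, 1, 0), z = c(0, 0, 0, 0)) |>
                    `colnames<-`(c("c1", "c2", "c3", "c4")))
  once <- prune_redundant(messy)
  twice <- prune_redundant(once)
  expect_identical(hr_mat(twice), hr_mat(once))

  all_zero <- hr_tbl(matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                     c("x", "y"))))
  expect_error(prune_redundant(all_zero), "empty the matrix")
})
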