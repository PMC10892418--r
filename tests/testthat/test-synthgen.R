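test_that("generation is a pure function of the seed", {
  spec <- study_district_specs()$specs$Xiaodian
  a <- generate_samples(spec, seed = 4)
  b <- generate_samples(spec, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a, generate_samples(spec, seed = 5)))
  expect_equal(nrow(a), 35)
  expect_true(all(a$x >= spec$bbox[1] & a$x <= spec$bbox[3]))
  expect_true(all(a$y >= spec$bbox[2] & a$y <= spec$bbox[4]))
})

test_that("a zero CV collapses the lognormal to its mean", {
  spec <- district_spec("Flat", n = 20,
                        mean = setNames(c(12, 0.1, 0.2, 60, 20, 30, 90), metals()),
                        cv = setNames(rep(0, 7), metals()))
  s <- generate_samples(spec, seed = 1)
  expect_equal(unique(s$As), 12, tolerance = 1e-12)
  expect_equal(unique(s$Zn), 90, tolerance = 1e-12)
})

test_that("moments are recovered at large n within the stated bands", {
  spec <- study_district_specs()$specs$Xiaodian
  spec$n <- 10000L
  s <- generate_samples(spec, seed = 42)
  expect_equal(mean(s$As), 12.33, tolerance = 0.02 * 12.33)
  cv_as <- 100 * sd(s$As) / mean(s$As)
  expect_equal(cv_as, 27.90, tolerance = 0.05 * 27.90)
  expect_true(all(as.matrix(s[, metals()]) > 0))
  upper <- matrix(spec$upper, nrow(s), 7, byrow = TRUE)
  expect_true(all(as.matrix(s[, metals()]) <= upper))
})

test_that("unsatisfiable plausibility bounds fail with the metal named", {
  spec <- district_spec("Bad", n = 5,
                        mean = setNames(rep(10, 7), metals()),
                        cv = setNames(rep(1, 7), metals()),
                        lower = setNames(c(1000, rep(0, 6)), metals()),
                        upper = setNames(c(1001, rep(Inf, 6)), metals()))
  expect_error(generate_samples(spec, seed = 1), "As")
})

test_that("correlation targets are validated and repaired to PSD", {
  expect_error(repair_correlation(matrix(1:4, 2)), "symmetric")
  bad_diag <- diag(2); bad_diag[1, 1] <- 2
  expect_error(repair_correlation(bad_diag), "diagonal")

  # an indefinite 'correlation' gets projected to a PSD one
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_lt(min(eigen(R, only.values = TRUE)$values), -1e-8)
  fixed <- repair_correlation(R)
  expect_gte(min(eigen(fixed, only.values = TRUE)$values), -1e-8)
  expect_equal(diag(fixed), rep(1, 3), tolerance = 1e-8)
})

test_that("the shipped study fixture matches the sampling design", {
  s <- study_fixture(seed = 1)
  expect_equal(nrow(s), 110)
  expect_equal(sum(s$district == "Xiaodian"), 35)
  expect_equal(sum(s$district == "Jinyuan"), 35)
  expect_equal(sum(s$district == "Qingxu"), 40)
  expect_false(anyDuplicated(s$sample_id) > 0)
  expect_true(all(as.matrix(s[, metals()]) > 0))

  # byte-identical CSV export under the same seed
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_samples(study_fixture(seed = 1), p1)
  write_samples(study_fixture(seed = 1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the study design table carries the per-district targets", {
  tab <- study_district_specs()$table
  expect_equal(nrow(tab), 21)
  cd <- tab[tab$district == "Xiaodian" & tab$metal == "Cd", ]
  expect_equal(cd$min, 0.11)
  expect_equal(cd$max, 0.69)
  expect_true(all(tab$min < tab$max))
  expect_true(all(tab$min <= tab$mean & tab$mean <= tab$max))
})
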