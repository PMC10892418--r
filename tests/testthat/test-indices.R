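test_that("igeo matches its closed form and rejects the log-domain edge", {
  expect_equal(igeo(1.5 * 0.08, 0.08), 0)
  expect_equal(igeo(0.69, 0.08), 2.5236, tolerance = 5e-5)
  expect_equal(as.character(classify_values(igeo(0.69, 0.08), "igeo")),
               "moderately to heavily polluted")
  # the 1.5-margin boundary case lands exactly on the lightly-polluted floor
  expect_equal(as.character(classify_values(igeo(1.5 * 7.6, 7.6), "igeo")),
               "lightly polluted")
  expect_error(igeo(0, 0.08), "positive")
  expect_error(igeo(1, -1), "positive")
})

test_that("single pollution index is the plain ratio", {
  expect_equal(single_pollution_index(0.6, 0.6), 1)
  expect_equal(single_pollution_index(0.69, 0.6), 1.15)
  expect_equal(single_pollution_index(0, 0.6), 0)
  expect_error(single_pollution_index(-1, 0.6), ">= 0")
})

test_that("nemerow dialects match hand-evaluated closed forms and their bounds", {
  r <- c(1, 0, 0, 0, 0, 0, 0)
  expect_equal(nemerow(r), 0.714286, tolerance = 1e-6)
  expect_equal(nemerow(r, "arithmetic"), 0.571429, tolerance = 1e-6)
  expect_equal(nemerow(rep(0.37, 7)), 0.37)
  expect_equal(nemerow(rep(0.37, 7), "arithmetic"), 0.37)
  expect_error(nemerow(numeric(0)), "non-empty")

  # each dialect stays within its own closed-form bracket
  withr::local_seed(5)
  for (i in 1:200) {
    v <- stats::runif(7, 0, 4)
    rms <- nemerow(v); ari <- nemerow(v, "arithmetic")
    expect_gte(rms, max(v) / sqrt(2)); expect_lte(rms, max(v))
    expect_gte(ari, mean(v)); expect_lte(ari, max(v))
  }
})

test_that("er reproduces the worked endpoint values", {
  expect_equal(er(0.11, 0.6, 30), 5.50)
  expect_equal(round_half_up(er(0.84, 3.4, 40), 2), 9.88)
  expect_equal(er(0, 0.6, 30), 0)
})

test_that("peri sums the seven Er components and is linear", {
  zero <- setNames(rep(0, 7), metals())
  expect_equal(as.numeric(peri(zero)), 0)

  xd <- c(As = 12.33, Hg = 0.07, Cd = 0.27, Cr = 59.15,
          Pb = 21.52, Cu = 30.03, Zn = 97.18)
  v <- peri(xd)
  expect_equal(as.numeric(v), 22.1871, tolerance = 1e-4)
  expect_equal(sum(attr(v, "components")), as.numeric(v))
  expect_equal(as.numeric(peri(2 * xd)), 2 * as.numeric(v))
  expect_error(peri(xd[-1]), "missing metal")

  # mean of per-sample PERI equals PERI of the mean concentration vector
  s <- random_samples(50, seed = 3)
  per_sample <- vapply(seq_len(nrow(s)),
                       function(i) as.numeric(peri(s[i, ])), numeric(1))
  mean_vec <- colMeans(as.matrix(s[, metals()]))
  expect_equal(mean(per_sample), as.numeric(peri(mean_vec)), tolerance = 1e-12)
})

test_that("each index is strictly increasing in concentration", {
  cs <- seq(0.05, 100, length.out = 50)
  expect_true(all(diff(igeo(cs, 5)) > 0))
  expect_true(all(diff(single_pollution_index(cs, 5)) > 0))
  expect_true(all(diff(er(cs, 5, 3)) > 0))
})

test_that("index_table emits 23 graded rows per sample and matches the oracle", {
  one <- toy_samples()[1, ]
  tab <- index_table(one)
  expect_equal(nrow(tab), 23)
  expect_equal(sum(tab$index_name == "Igeo"), 7)
  expect_equal(nrow(index_table(toy_samples()[0, ])), 0)

  # grades are recomputable from values under the matching scheme
  full <- index_table(toy_samples())
  for (ix in unique(full$index_name)) {
    part <- full[full$index_name == ix, ]
    scheme <- switch(ix, Igeo = "igeo", P_single = "pn", P_N = "pn",
                     Er = "er", PERI = "peri")
    expect_equal(part$grade, as.character(classify_values(part$value, scheme)))
  }

  # straight-line re-evaluation agrees to machine precision
  s <- random_samples(40, seed = 8)
  got <- index_table(s)
  want <- oracle_indices(s)
  merged <- merge(got, want, by = c("sample_id", "metal", "index_name"))
  expect_equal(nrow(merged), nrow(got))
  expect_lt(max(abs(merged$value.x - merged$value.y)), 1e-10)
})

test_that("index_table substitutes half the detection limit for Igeo only", {
  s <- toy_samples()[1, ]
  s$Hg <- 0
  tab <- index_table(s)
  refs <- reference_set()
  ig_hg <- tab$value[tab$index_name == "Igeo" & tab$metal == "Hg"]
  expect_equal(ig_hg, log2((refs$detection[["Hg"]] / 2) / (1.5 * refs$background[["Hg"]])))
  expect_equal(tab$value[tab$index_name == "Er" & tab$metal == "Hg"], 0)
  expect_equal(tab$value[tab$index_name == "P_single" & tab$metal == "Hg"], 0)
})

test_that("grade frequencies give district percentages on the district count", {
  fab <- function(n_in, n_total) {
    tibble::tibble(
      sample_id = paste0("S", seq_len(n_total)), district = "D", metal = "Cd",
      index_name = "Igeo",
      value = c(rep(1.5, n_in), rep(-0.5, n_total - n_in)),
      grade = c(rep("moderately polluted", n_in),
                rep("unpolluted", n_total - n_in))
    )
  }
  gf <- grade_frequency(fab(9, 35))
  expect_equal(gf$percentage[gf$grade == "moderately polluted"], 25.71)
  expect_equal(sum(gf$count), 35)
  expect_equal(sum(gf$percentage), 100, tolerance = 0.05)

  gf2 <- grade_frequency(fab(40, 40))
  expect_equal(gf2$percentage[gf2$grade == "moderately polluted"], 100)

  gf3 <- grade_frequency(fab(1, 40))
  expect_equal(gf3$percentage[gf3$grade == "moderately polluted"], 2.50)
  expect_error(grade_frequency(fab(1, 40)[0, ]), "empty")
})

test_that("er ranges equal Er at the district concentration extremes", {
  s <- toy_samples("Xiaodian")
  rng <- er_range_table(index_table(s))
  as_row <- rng[rng$metal == "As", ]
  expect_equal(round_half_up(as_row$er_min, 2), 3.12)
  expect_equal(round_half_up(as_row$er_max, 2), 10.70)

  one <- er_range_table(index_table(s[1, ]))
  expect_equal(one$er_min, one$er_max)
})
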