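test_that("series scaling multiplies counts by the sampling interval", {
  expect_equal(series_total(37, 12), 444)
  expect_equal(series_total(0, 12), 0)
  expect_equal(series_total(123, 1), 123)
  expect_equal(series_total(c(2, 5), 12), c(24, 60))
  expect_error(series_total(-1), ">= 0")
})

test_that("double-label proportions convert to bounded absolute estimates", {
  expect_equal(double_label_absolute(25, 50, 1200), 600)
  expect_equal(double_label_absolute(0, 50, 1200), 0)
  expect_equal(double_label_absolute(50, 50, 1200), 1200)
  # bounded by the total-marker estimate for any admissible sample
  for (k in 0:50)
    expect_lte(double_label_absolute(k, 50, 987), 987)
  expect_error(double_label_absolute(51, 50, 100), "sample_size")
  expect_error(double_label_absolute(1, 0, 100), "> 0")
})

test_that("optical fractionator combines the three inverse sampling fractions", {
  est <- fractionator_estimate(100)
  expect_equal(as.numeric(est), 32000)  # 100 * 12 * (12000/900) * (40/20)
  f <- attr(est, "factors")
  expect_equal(unname(f["section"]), 12)
  expect_equal(unname(f["area"]), 12000 / 900)
  expect_equal(unname(f["height"]), 2)
  expect_equal(as.numeric(fractionator_estimate(0)), 0)
  # exhaustive limit: frame = grid, disector = slice, interval 1
  ex <- fractionator_spec(frame = c(100, 100), grid = c(100, 100),
                          disector_height = 40, slice_thickness = 40,
                          series_interval = 1, guard_zone = 0)
  expect_equal(as.numeric(fractionator_estimate(57, ex)), 57)
})

test_that("fractionator estimate is linear in sum_Q and in the area fraction", {
  s <- fractionator_spec()
  expect_equal(as.numeric(fractionator_estimate(200, s)),
               2 * as.numeric(fractionator_estimate(100, s)))
  half_area <- fractionator_spec(frame = c(30, 15))  # half the frame area
  expect_equal(as.numeric(fractionator_estimate(100, half_area)),
               2 * as.numeric(fractionator_estimate(100, s)))
})

test_that("invalid fractionator geometry is rejected", {
  expect_error(fractionator_spec(frame = c(200, 30)), "fit inside")
  expect_error(fractionator_spec(disector_height = 38, guard_zone = 5),
               "exceeds")
  expect_error(fractionator_spec(series_interval = 0), "positive")
})

count_means <- function(ctr = 300, mptp3 = 600) {
  tps <- c("baseline", "3", "6", "10", "14", "18")
  grid <- expand.grid(treatment = c("CTR", "MPTP"), time_point = tps,
                      stringsAsFactors = FALSE)
  grid$marker <- "Iba1"
  grid$mean <- ifelse(grid$treatment == "MPTP" & grid$time_point == "3",
                      mptp3, ctr)
  grid
}

test_that("count simulator: zero-sd limit, determinism, mean targeting", {
  m <- count_means()
  m$sd <- 0
  tab <- simulate_counts(m, n_per_group = 4, seed = 1)
  expect_true(all(tab$value == tab$raw_count))
  expect_true(all(tab$value[tab$treatment == "CTR"] == 300))
  expect_true(all(tab$value[tab$treatment == "MPTP" & tab$time_point == "3"] == 600))

  m2 <- count_means(); m2$sd <- 80
  a <- simulate_counts(m2, n_per_group = 5, seed = 4)
  b <- simulate_counts(m2, n_per_group = 5, seed = 4)
  expect_identical(a, b)
  expect_true(all(a$value == round(a$value)))  # integer counts

  # negative binomial targeting: large-sample mean close to specification
  m3 <- data.frame(marker = "Iba1", treatment = "CTR", time_point = "3",
                   mean = 400, sd = 90)
  big <- simulate_counts(m3, n_per_group = 4000, seed = 5)
  expect_lt(abs(mean(big$value) - 400), 3 * 90 / sqrt(4000))
  expect_lt(abs(sd(big$value) - 90) / 90, 0.1)
})
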