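test_that("sample moments match hand-computed values on the 4-point toy", {
  m <- compute_moments(toy_df())
  expect_equal(m$mean1, 2.5)
  expect_equal(m$mean2, 4.5)
  expect_equal(m$var1, 5 / 3)
  expect_equal(m$var2, 13 / 3)
  expect_equal(m$cov12, 8 / 3)
  d <- moment_derived(m)
  expect_equal(d$d_bar, 2)
  expect_equal(d$var_d, 2 / 3)
  expect_equal(d$rho, 8 / sqrt(65))
})

test_that("identical waves give zero change and unit correlation", {
  m <- compute_moments(data.frame(y1 = c(1, 2, 3), y2 = c(1, 2, 3)))
  d <- moment_derived(m)
  expect_equal(d$d_bar, 0)
  expect_equal(d$rho, 1)
  expect_equal(d$var_d, 0)
})

test_that("input validation catches short, degenerate and incomplete data", {
  expect_error(compute_moments(data.frame(y1 = 1:2, y2 = 2:3)), "at least 3")
  expect_error(compute_moments(data.frame(y1 = c(1, 1, 1), y2 = c(1, 2, 3))),
               "zero variance")
  expect_warning(
    s <- paired_sample(data.frame(y1 = c(1, 2, 3, NA), y2 = c(2, 3, 4, 5))),
    "Dropped 1"
  )
  expect_equal(nrow(s), 3)
  expect_error(paired_sample(data.frame(a = 1:3)), "not found")
})

test_that("the n denominator rescales all second moments by (n-1)/n", {
  x <- toy_df()
  m1 <- compute_moments(x, denominator = "n-1")
  m2 <- compute_moments(x, denominator = "n")
  expect_equal(m2$var1, m1$var1 * 3 / 4)
  expect_equal(m2$var2, m1$var2 * 3 / 4)
  expect_equal(m2$cov12, m1$cov12 * 3 / 4)
  expect_equal(moment_derived(m2)$rho, moment_derived(m1)$rho)
})

test_that("centering on the wave-1 mean shifts means only", {
  x <- data.frame(y1 = c(1, 2, 3), y2 = c(2, 3, 4))
  cx <- center_on_wave1(x)
  expect_equal(cx$y1, c(-1, 0, 1))
  expect_equal(cx$y2, c(0, 1, 2))
  expect_equal(centering_record(cx)$offset, 2)
  expect_true(centering_record(cx)$applied)

  set.seed(101)
  for (i in 1:20) {
    x <- rbvn(sample(5:80, 1), mu1 = runif(1, -3, 3), mu2 = runif(1, -3, 3),
              s1 = runif(1, 0.3, 2), s2 = runif(1, 0.3, 2),
              rho = runif(1, -0.8, 0.8))
    cx <- center_on_wave1(x)
    m <- compute_moments(x)
    mc <- compute_moments(cx)
    # differences unchanged element-wise; mean1 exactly 0 after centering
    expect_equal(cx$y2 - cx$y1, x$y2 - x$y1)
    expect_equal(mc$mean1, 0, tolerance = 1e-12)
    expect_equal(mc$mean2, moment_derived(m)$d_bar, tolerance = 1e-12)
    # second moments invariant to the common shift
    expect_equal(mc$var1, m$var1, tolerance = 1e-12)
    expect_equal(mc$var2, m$var2, tolerance = 1e-12)
    expect_equal(mc$cov12, m$cov12, tolerance = 1e-12)
    expect_equal(moment_derived(mc)$var_d, moment_derived(m)$var_d,
                 tolerance = 1e-12)
  }
})

test_that("summary statistics round-trip through moments_from_summary", {
  set.seed(7)
  for (i in 1:10) {
    x <- rbvn(30, mu2 = -0.4, rho = runif(1, -0.9, 0.9))
    m <- compute_moments(x)
    m2 <- moments_from_summary(m$n, m$mean1, sqrt(m$var1),
                               m$mean2, sqrt(m$var2),
                               moment_derived(m)$rho)
    expect_equal(m2$cov12, m$cov12, tolerance = 1e-12)
    expect_equal(tidy(m2), tidy(m), tolerance = 1e-12)
  }
  # independence case and the derived difference variance
  m0 <- moments_from_summary(24, 0, 1, -0.3, 1, rho = 0)
  expect_equal(moment_derived(m0)$var_d, 2)
  m5 <- moments_from_summary(24, 0, 1, -0.3, 1, rho = 0.5)
  expect_equal(moment_derived(m5)$var_d, 1)
  expect_equal(moment_derived(m5)$d_bar, -0.3)
  expect_error(moments_from_summary(24, 0, 1, -0.3, 1, rho = 1), "strictly")
  expect_error(moments_from_summary(24, 0, -1, -0.3, 1, rho = 0.5), "positive")
})

test_that("CSV and summary-config readers parse the supported layouts", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("y1,y2", "1,2", "2,4", "3,5", "4,7"), csv)
  x <- read_paired_csv(csv)
  expect_equal(x$y2, c(2, 4, 5, 7))

  csv2 <- tempfile(fileext = ".csv")
  writeLines(c("id,baseline,followup", "a,1,2", "b,2,4", "c,3,5"), csv2)
  x2 <- read_paired_csv(csv2, y1 = "baseline", y2 = "followup", id = "id")
  expect_named(x2, c("y1", "y2", "id"))

  yml <- tempfile(fileext = ".yaml")
  writeLines(c("n: 24", "mean1: 0", "sd1: 1", "mean2: -0.3", "sd2: 1",
               "rho_grid:", "  min: 0", "  max: 0.9", "  step: 0.1"), yml)
  cfg <- read_summary_config(yml)
  expect_equal(cfg$rho_grid, seq(0, 0.9, 0.1))

  js <- tempfile(fileext = ".json")
  writeLines('{"n": 24, "mean1": 0, "sd1": 1, "mean2": -0.3, "sd2": 1, "rho": 0.5}', js)
  expect_equal(read_summary_config(js)$rho, 0.5)

  bad <- tempfile(fileext = ".yaml")
  writeLines(c("n: 24", "mean1: 0"), bad)
  expect_error(read_summary_config(bad), "missing field")
  writeLines(c("n: 24", "mean1: 0", "sd1: 1", "mean2: -0.3", "sd2: 1"), bad)
  expect_error(read_summary_config(bad), "rho")
})
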