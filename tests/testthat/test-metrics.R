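test_that("boundary extraction interpolates steps and ramps to the exact crossing", {
  expect_equal(boundary_position(c(49.5, 50.5), c(100, 0)), 50)
  ap <- seq(40, 60, by = 1)
  ramp <- seq(100, 0, length.out = length(ap))
  expect_equal(boundary_position(ap, ramp), 50)
  expect_error(boundary_position(ap, rep(100, length(ap))), "never crosses")
  expect_error(boundary_position(ap, rep(0, length(ap))), "positive maximum")
})

test_that("boundary position is invariant to uniform scaling of the profile", {
  ap <- lattice_config()$ap_pos
  prof <- 100 / (1 + exp((ap - 47) / 2)) + 5 * sin(ap / 3)^2
  b1 <- boundary_position(ap, prof)
  b2 <- boundary_position(ap, prof * 37.5)
  expect_equal(b1, b2)
})

test_that("non-monotonic profiles yield the anterior-most downward crossing", {
  ap <- 1:10
  v <- c(10, 10, 3, 9, 8, 4, 2, 1, 0, 0)   # dips below half (5) early
  expect_lt(boundary_position(ap, v), 3)
})

test_that("peak detection finds interior maxima and reports no-peak otherwise", {
  ap <- lattice_config()$ap_pos
  prof <- rep(0, 60); prof[36] <- 100; prof[35] <- 60; prof[37] <- 60
  expect_equal(peak_position(ap, prof, window = c(40, 70)), 55.5)
  # a monotone profile has no local maximum inside the window
  mono <- 100 - ap
  expect_true(is.na(peak_position(ap, mono, window = c(40, 55))))
  # global argmax without the local-max requirement
  expect_equal(peak_position(ap, mono, local = FALSE, smooth = FALSE), 20.5)
  expect_error(peak_position(ap, prof, window = c(10, 50)), "window")
})

test_that("trough ratio divides the pre-peak minimum by the peak height", {
  ap <- lattice_config()$ap_pos
  prof <- rep(100, 60)
  prof[ap > 40 & ap < 44] <- 92        # window plateau below the peak
  prof[ap > 43 & ap < 46] <- 89        # the trough
  prof[ap >= 46 & ap < 50] <- c(90, 95, 100, 96)
  prof[ap >= 50] <- pmax(0, 96 - 25 * (ap[ap >= 50] - 49.5))
  expect_equal(trough_ratio(ap, prof), 0.89)
  # flat approach to a modest peak: ratio = plateau / peak
  flat <- rep(50, 60); flat[28:30] <- c(52, 58, 53)
  expect_equal(trough_ratio(ap, flat), 50 / 58)
  # no peak propagates as NA
  expect_true(is.na(trough_ratio(ap, 100 - ap)))
})

test_that("positional SD uses the n-1 sample estimator and reports unusable replicates", {
  ap <- seq(40, 60, by = 1)
  mk <- function(b) 100 / (1 + exp((ap - b) / 0.5))
  same <- rbind(mk(50), mk(50), mk(50))
  expect_equal(positional_sd(same, ap)$sd, 0)
  two <- rbind(mk(44), mk(46))
  expect_equal(positional_sd(two, ap, smooth = FALSE)$sd, sqrt(2),
               tolerance = 1e-3)
  # undefined boundary excluded and reported
  three <- rbind(mk(44), mk(46), rep(100, length(ap)))
  ps <- positional_sd(three, ap)
  expect_equal(ps$excluded, 3L)
  expect_length(ps$positions, 2)
  expect_error(positional_sd(rbind(mk(44), rep(100, length(ap))), ap),
               "fewer than 2")
})

test_that("positional SD is invariant to a constant AP offset", {
  ap <- seq(40, 60, by = 1)
  mk <- function(b) 100 / (1 + exp((ap - b) / 0.5))
  m <- rbind(mk(44), mk(45.5), mk(47))
  s1 <- positional_sd(m, ap, smooth = FALSE)$sd
  s2 <- positional_sd(m, ap + 7.3, smooth = FALSE)$sd
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("the variance F-test matches the F distribution", {
  eq <- variance_f_test(1.3, 25, 1.3, 25)
  expect_equal(eq$F, 1)
  expect_equal(eq$p, 1)
  ft <- variance_f_test(2, 25, 1, 25)     # sd ratio 2 -> F = 4
  expect_equal(ft$F, 4)
  expect_equal(ft$p, 2 * pf(4, 24, 24, lower.tail = FALSE))
  dg <- variance_f_test(0, 10, 1, 10)
  expect_true(dg$degenerate)
})

test_that("within-nucleus noise matches hand computation and the naive loop", {
  # identical loci: zero noise
  expect_equal(noise_in_nuc(c(5, 9), c(5, 9), c(50, 51), 50)$value, 0)
  # two nuclei, (3,1) and (1,3): sqrt((1 + 1)/1)
  nn <- noise_in_nuc(c(3, 1), c(1, 3), c(50, 51), 50)
  expect_equal(nn$value, sqrt(2))
  expect_equal(nn$m, 2L)

  set.seed(11)
  A <- rpois(200, 40); B <- rpois(200, 40)
  ap <- runif(200, 40, 60)
  b <- 50
  got <- noise_in_nuc(A, B, ap, b)
  # independent naive-loop oracle of the same estimator
  acc <- 0; m <- 0L
  for (i in seq_along(A)) {
    if (ap[i] >= b - 5 && ap[i] <= b + 5 && A[i] > 0 && B[i] > 0) {
      m <- m + 1L
      acc <- acc + ((A[i] - B[i]) / ((A[i] + B[i]) / 2))^2
    }
  }
  expect_identical(got$m, m)
  expect_equal(got$value, sqrt(acc / (m - 1)), tolerance = 1e-12)
})

test_that("within-nucleus noise is symmetric and scale invariant", {
  set.seed(3)
  A <- rpois(80, 30) + 1; B <- rpois(80, 30) + 1
  ap <- runif(80, 44, 56)
  v1 <- noise_in_nuc(A, B, ap, 50)$value
  v2 <- noise_in_nuc(B, A, ap, 50)$value
  v3 <- noise_in_nuc(3 * A, 3 * B, ap, 50)$value
  expect_equal(v1, v2)
  expect_equal(v1, v3)
  expect_error(noise_in_nuc(c(1, 0), c(1, 0), c(50, 51), 50), "fewer than 2")
})

test_that("the pooled two-sample t-test separates and equates groups correctly", {
  same <- two_sample_t(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$p, 1)
  far <- two_sample_t(c(0, 0.001, -0.001), c(1, 1.001, 0.999))
  expect_lt(far$p, 1e-10)
  dg <- two_sample_t(c(1, 1), c(1, 1))
  expect_true(dg$degenerate)
  expect_equal(dg$p, 1)
})

test_that("jaggedness counts strict sign changes of the first difference", {
  expect_equal(jaggedness(1:4, c(10, 5, 8, 3)), 2)
  expect_equal(jaggedness(1:5, c(10, 8, 6, 4, 2)), 0)
  expect_equal(jaggedness(1:5, c(10, 8, 8, 4, 2)), 0)   # plateaus not changes
  expect_equal(jaggedness(1:6, c(1, 3, 2, 4, 3, 5), window = c(2, 5)), 2)
})
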