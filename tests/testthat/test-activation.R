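test_that("length constant matches the closed form and scales as sqrt(a)", {
  # hand evaluation: sqrt(80 kOhm cm^2 * 1e-4 cm / (2 * 0.05 kOhm cm))
  # = sqrt(0.08) cm = 2.8284 mm
  expect_equal(length_constant(cable_constants()), sqrt(0.08) * 10,
               tolerance = 1e-12)
  l1 <- length_constant(cable_constants(a = 1))
  l4 <- length_constant(cable_constants(a = 4))
  expect_equal(l4, 2 * l1, tolerance = 1e-12)
  expect_error(cable_constants(n_layers = 0), "positive")
  expect_error(cable_constants(rho_i = -1), "positive")
})

test_that("the cable filter has unit DC gain and an exponential impulse response", {
  s <- seq(0, 40, by = 0.05)
  lambda <- length_constant(cable_constants())
  # DC gain
  vf <- lowpass_filter(rep(2.5, length(s)), s, lambda)
  expect_lt(max(abs(vf - 2.5)), 1e-10)
  # impulse response: two-sided exponential decaying by e over one lambda
  v <- numeric(length(s)); j <- which.min(abs(s - 20)); v[j] <- 1
  vf <- lowpass_filter(v, s, lambda)
  interior <- abs(s - 20) < 10
  expect_equal(
    vf[interior] / vf[j],
    exp(-abs(s[interior] - 20) / lambda),
    tolerance = 1e-3
  )
  # lambda much smaller than the spacing: the filter tends to the identity
  v2 <- sin(s)
  expect_equal(lowpass_filter(v2, s, 1e-6), v2, tolerance = 1e-9)
  expect_error(lowpass_filter(v2, rev(s), lambda), "increasing")
})

test_that("filtering is smoothing and does not create curvature", {
  set.seed(5)
  s <- cumsum(runif(80, 0.05, 0.2))
  v <- rnorm(80)
  vf <- lowpass_filter(v, s, 2.8)
  expect_lte(total_variation(vf), total_variation(v))
  # linear profile stays linear on an even grid: curvature ~ 0 away from
  # the ends (uneven quadrature introduces only O(ds^2) wiggle, not tested)
  se <- seq(0, 16, by = 0.1)
  vlin <- 3 * se + 1
  vf2 <- lowpass_filter(vlin, se, 0.5)
  d2 <- second_derivative(vf2, se)
  # residual curvature comes only from the truncated kernel tails and dies
  # off exponentially with distance from the ends (here 12 lambda)
  inner <- which(se > 6 & se < 10)
  expect_lt(max(abs(d2[inner])), 1e-3)
})

test_that("finite-difference formulas are exact on their reference profiles", {
  # forward difference: exact for linear V on any spacing
  set.seed(2)
  s <- cumsum(runif(20, 0.1, 0.5))
  d <- first_derivative(2 * s, s)
  expect_equal(d[-20], rep(2, 19), tolerance = 1e-12)
  expect_true(is.na(d[20]))
  expect_equal(first_derivative(c(0, 1), c(0, 1))[1L], 1)
  # node-by-node re-evaluation oracle on a random profile
  v <- rnorm(50); s50 <- cumsum(runif(50, 0.05, 0.3))
  expect_equal(first_derivative(v, s50)[-50],
               (v[-1] - v[-50]) / (s50[-1] - s50[-50]), tolerance = 1e-12)

  # second difference: exactly 2 for V = s^2 on uneven spacing
  s3 <- c(0, 0.7, 1.8)
  expect_equal(second_derivative(s3^2, s3)[2L], 2, tolerance = 1e-12)
  s10 <- cumsum(c(0, runif(9, 0.05, 0.4)))
  d2 <- second_derivative(s10^2, s10)
  expect_equal(d2[2:9], rep(2, 8), tolerance = 1e-10)
  expect_true(is.na(d2[1L]) && is.na(d2[10L]))
  # zero on linear and constant profiles
  expect_equal(max(abs(second_derivative(5 * s10 - 2, s10)[2:9])), 0,
               tolerance = 1e-10)
  expect_equal(max(abs(second_derivative(rep(1, 10), s10)[2:9])), 0)
  expect_error(first_derivative(1, 1), "2 nodes")
  expect_error(second_derivative(c(1, 2), c(0, 1)), "3 nodes")
})

test_that("the activating function scales linearly with the fiber diameter", {
  v2 <- c(NA, -1, 0, 2, NA)
  # capacity held fixed so only the diameter varies
  f1 <- activating_function(v2, cable_constants(d = 2, c = 1e-10))
  f2 <- activating_function(v2, cable_constants(d = 4, c = 1e-10))
  expect_equal(f1[3L], 0)
  expect_equal(f2, 2 * f1)
  expect_equal(sign(f1[!is.na(f1)]), sign(v2[!is.na(v2)]))
  # argmax of f coincides with argmax of the second derivative
  set.seed(3)
  prof <- rnorm(30)
  f <- activating_function(prof, cable_constants())
  expect_equal(which.max(f), which.max(prof))
})

test_that("the decay-rate estimator recovers constructed slopes", {
  s <- seq(0, 25, by = 0.1)
  es <- 12
  # exact 0.18 dB/mm decline toward the base, 0.05 toward the apex
  v <- ifelse(s <= es, 10^(-0.18 * (es - s) / 20), 10^(-0.05 * (s - es) / 20))
  fb <- decay_rate(s, v, es, "basal")
  fa <- decay_rate(s, v, es, "apical")
  expect_lt(abs(fb$rate_db_per_mm - 0.18), 0.005)
  expect_lt(abs(fa$rate_db_per_mm - 0.05), 0.005)
  expect_gt(fb$r_squared, 0.999)
  # invariant to overall scaling of V
  fb2 <- decay_rate(s, 37 * v, es, "basal")
  expect_equal(fb2$rate_db_per_mm, fb$rate_db_per_mm, tolerance = 1e-12)
  # constant profile: zero rate
  f0 <- decay_rate(s, rep(2, length(s)), es, "basal")
  expect_equal(f0$rate_db_per_mm, 0, tolerance = 1e-12)
  expect_error(decay_rate(s[1:10], v[1:10], 0.5, "basal"), "5 samples")
  expect_error(decay_rate(s, v * 0, es, "basal"), "non-positive")
})

test_that("model comparison reports differences, ratios and sign flips", {
  s <- seq(0, 5, by = 0.05)
  pts <- cbind(s, 0, 0)
  mkprof <- function(v) {
    fp <- cochleafield:::new_fiber_path(pts)
    activation_profile(fp, v, lambda = 1e-6)  # identity filter
  }
  v <- 1 + exp(-s)
  p1 <- mkprof(v)
  # identical profiles: zero RD, unit ratios, no flips
  cmp0 <- compare_models(p1, mkprof(v))
  expect_equal(cmp0$max_abs_rd_percent, 0)
  expect_equal(cmp0$max_ratio_d2V, 1, tolerance = 1e-12)
  expect_equal(cmp0$n_sign_flip_segments, 0L)

  # curvature flipped on s in [1.0, 1.4] (C^1 piecewise quadratic) is
  # reported as exactly the interior nodes of that interval
  a <- 1.0; b <- 1.4
  v_ori <- s^2
  v_sim <- v_ori
  mid <- s >= a & s <= b
  v_sim[mid] <- a^2 + 2 * a * (s[mid] - a) - (s[mid] - a)^2
  vb <- a^2 + 2 * a * (b - a) - (b - a)^2
  sb <- 2 * a - 2 * (b - a)
  after <- s > b
  v_sim[after] <- vb + sb * (s[after] - b) + (s[after] - b)^2
  cmp1 <- compare_models(mkprof(v_ori), mkprof(v_sim))
  segs <- cmp1$per_fiber[[1L]]$sign_flip_segments
  expect_equal(nrow(segs), 1L)
  expect_equal(unname(segs[1L, "s_start"]), a + 0.05, tolerance = 1e-9)
  expect_equal(unname(segs[1L, "s_end"]), b - 0.05, tolerance = 1e-9)

  # doubled profile: extrema ratio 2, convergence never reached
  w <- sin(2 * pi * s)
  cmp2 <- compare_models(mkprof(2 * w), mkprof(w))
  expect_equal(cmp2$per_fiber[[1L]]$ratio_d2V, 2, tolerance = 1e-9)
  expect_equal(cmp2$per_fiber[[1L]]$ratio_dV, 2, tolerance = 1e-9)

  # mismatched sampling is refused
  short <- cochleafield:::new_fiber_path(pts[1:50, ])
  p_short <- activation_profile(short, v[1:50], lambda = 1e-6)
  expect_error(compare_models(p1, p_short), "mismatched")
})
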