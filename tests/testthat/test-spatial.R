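test_that("pairwise Pearson handles perfect, anti- and zero correlation", {
  x <- rep(c(0L, 1L), 50L)
  r <- cbind(x, x, 1L - x)
  pv <- pairwise_pearson(r)
  expect_equal(pv$value[pv$i == 0 & pv$j == 1], 1)
  expect_equal(pv$value[pv$i == 0 & pv$j == 2], -1)
  # constant columns are excluded with a count
  r2 <- cbind(x, rep(1L, 100L))
  pv2 <- pairwise_pearson(r2)
  expect_equal(nrow(pv2), 0L)
  expect_equal(attr(pv2, "n_excluded"), 1L)
})

test_that("log-spaced binning reproduces hand-binned means", {
  # three pairs at distances 110 / 450 / 1400 with values 0.3 / 0.2 / 0.1
  d <- c(110, 450, 1400)
  v <- c(0.3, 0.2, 0.1)
  cv <- bin_by_distance(v, d, n_bins = 3L, d_min = 100, d_max_bin = 1500,
                        min_pairs_per_bin = 1L)
  expect_equal(cv$mean_value, c(0.3, 0.2, 0.1))
  expect_equal(cv$pair_count, c(1L, 1L, 1L))
  # edges strictly increasing with equal ratios (log spacing)
  edges <- c(cv$bin_lo, cv$bin_hi[3])
  expect_true(all(diff(edges) > 0))
  ratios <- edges[-1] / edges[-4]
  expect_equal(max(ratios) - min(ratios), 0, tolerance = 1e-12)
  # centers inside their bins
  expect_true(all(cv$bin_center > cv$bin_lo & cv$bin_center < cv$bin_hi))
})

test_that("equidistant pairs collapse to a single occupied bin", {
  cv <- bin_by_distance(c(0.5, 0.1, 0.3), c(200, 200, 200), n_bins = 4L,
                        d_min = 50, d_max_bin = 800, min_pairs_per_bin = 1L)
  occ <- which(cv$pair_count > 0)
  expect_length(occ, 1L)
  expect_equal(cv$mean_value[occ], 0.3)
  # empty bins retained with zero counts and undefined means
  expect_true(all(is.na(cv$mean_value[-occ])))
})

test_that("noiseless exponential curves are recovered exactly", {
  d <- exp(seq(log(20), log(2800), length.out = 15))
  curve <- data.frame(bin_lo = d, bin_hi = d, bin_center = d,
                      mean_value = 0.01 + (0.1 - 0.01) * exp(-d / 500),
                      pair_count = 100L)
  class(curve) <- c("distance_curve", "data.frame")
  fit <- fit_exponential_decay(curve)
  expect_true(fit$converged)
  expect_equal(fit$c0, 0.1, tolerance = 1e-6)
  expect_equal(fit$c_inf, 0.01, tolerance = 1e-6)
  expect_equal(fit$lam, 500, tolerance = 1e-6)

  # model limits: d = 0 gives C0, d -> Inf gives C_inf
  cd <- function(dd) fit$c_inf + (fit$c0 - fit$c_inf) * exp(-dd / fit$lam)
  expect_equal(cd(0), fit$c0)
  expect_equal(cd(1e12), fit$c_inf)

  # flat curve is flagged unidentifiable
  flat <- curve
  flat$mean_value <- rep(0.05, 15)
  ff <- fit_exponential_decay(flat)
  expect_true(ff$unidentifiable)
  expect_true(is.na(ff$lam))

  expect_error(fit_exponential_decay(curve[1:3, ]), "4 occupied bins")
})

test_that("lambda is recovered within 5% under small bin noise", {
  d <- exp(seq(log(20), log(2800), length.out = 20))
  truth <- 0.01 + (0.1 - 0.01) * exp(-d / 500)
  set.seed(515)
  lams <- vapply(1:100, function(i) {
    curve <- data.frame(bin_lo = d, bin_hi = d, bin_center = d,
                        mean_value = truth + rnorm(20, 0, 0.005),
                        pair_count = 100L)
    class(curve) <- c("distance_curve", "data.frame")
    fit_exponential_decay(curve)$lam
  }, numeric(1))
  expect_lt(abs(median(lams) - 500) / 500, 0.05)
})

test_that("normalization maps the fitted curve onto exp(-d/lambda)", {
  d <- exp(seq(log(20), log(2800), length.out = 12))
  curve <- data.frame(bin_lo = d, bin_hi = d, bin_center = d,
                      mean_value = 0.02 + 0.08 * exp(-d / 400),
                      pair_count = 10L)
  class(curve) <- c("distance_curve", "data.frame")
  fit <- fit_exponential_decay(curve)
  norm <- normalized_curve(curve, fit)
  expect_equal(norm$mean_value, exp(-d / fit$lam), tolerance = 1e-6)
  # endpoints of the normalization map
  expect_equal((fit$c0 - fit$c_inf) / (fit$c0 - fit$c_inf), 1)
  expect_equal((fit$c_inf - fit$c_inf) / (fit$c0 - fit$c_inf), 0)
})

test_that("effective length matches its closed form and limits", {
  fit <- structure(list(c0 = 0.1, c_inf = 0.01, lam = 500, converged = TRUE,
                        unidentifiable = FALSE), class = "decay_fit")
  eff <- effective_length(fit, d0 = 100, dmax = 1500)
  closed <- (0.01 * 1400 + 0.09 * 500 * (exp(-100 / 500) - exp(-1500 / 500))) / 0.1
  expect_equal(eff$lambda_eff, closed, tolerance = 1e-9)

  # c_inf = 0, d0 -> 0, dmax -> Inf: lambda_eff -> lambda
  fit0 <- structure(list(c0 = 0.1, c_inf = 0, lam = 500, converged = TRUE,
                         unidentifiable = FALSE), class = "decay_fit")
  eff0 <- effective_length(fit0, d0 = 1e-9, dmax = 5e5)
  expect_equal(eff0$lambda_eff, 500, tolerance = 1e-3)

  # flat integrand: c0 = c_inf = c gives dmax - d0
  fitc <- structure(list(c0 = 0.05, c_inf = 0.05, lam = 300, converged = TRUE,
                         unidentifiable = FALSE), class = "decay_fit")
  expect_equal(effective_length(fitc, 100, 1500)$lambda_eff, 1400,
               tolerance = 1e-9)

  expect_error(effective_length(fit, d0 = 1500, dmax = 100), "d0")
  fitneg <- structure(list(c0 = -0.1, c_inf = 0, lam = 500, converged = TRUE,
                           unidentifiable = FALSE), class = "decay_fit")
  expect_error(effective_length(fitneg), "positive")
})

test_that("model-free trapezoid length approximates the closed form", {
  d <- exp(seq(log(20), log(2800), length.out = 40))
  curve <- data.frame(bin_lo = d, bin_hi = d, bin_center = d,
                      mean_value = 0.01 + 0.09 * exp(-d / 500),
                      pair_count = 100L)
  class(curve) <- c("distance_curve", "data.frame")
  raw <- effective_length_raw(curve, d0 = 100, dmax = 1500)
  # model-free version normalizes by the first bin mean inside the window
  # (not the fitted d = 0 intercept); compare against the matching
  # closed-form integral
  cd <- function(dd) 0.01 + 0.09 * exp(-dd / 500)
  d_first <- min(d[d >= 100])
  expected <- integrate(cd, 100, 1500)$value / cd(d_first)
  expect_equal(raw$lambda_eff, expected, tolerance = 0.02)
  expect_error(effective_length_raw(curve, 1400, 1500), "2 occupied bins")
})

test_that("lambda_eff increases monotonically with lambda", {
  effs <- vapply(seq(100, 2000, by = 100), function(l) {
    fit <- structure(list(c0 = 0.1, c_inf = 0.01, lam = l, converged = TRUE,
                          unidentifiable = FALSE), class = "decay_fit")
    effective_length(fit)$lambda_eff
  }, numeric(1))
  expect_true(all(diff(effs) > 0))
})

test_that("the binning/fitting path runs unchanged on any per-pair scalar", {
  fx <- small_fixture(n = 40L, tt = 4000L, seed = 33L)
  pv <- pairwise_pearson(fx$raster, fx$positions)
  # replace values by an arbitrary decaying scalar; same pipeline applies
  pv$value <- 2 + 3 * exp(-pv$distance_um / 600)
  prof <- spatial_profile(pv, min_pairs_per_bin = 5)
  expect_true(prof$fit$converged)
  # bin means average the exponential across each log bin, so the fitted
  # length agrees only approximately with the generating one
  expect_equal(prof$lambda, 600, tolerance = 0.05)
})
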