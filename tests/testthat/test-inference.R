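make_lm_data <- function(n = 120, beta = 0.4, sigma = 0.3, seed = 99) {
  set.seed(seed)
  x <- rnorm(n)
  tibble::tibble(x = x, y = 1 + beta * x + rnorm(n, 0, sigma))
}

test_that("a noiseless linear relation is recovered with near-zero spread", {
  d <- tibble::tibble(x = seq(-2, 2, length.out = 40))
  d$y <- 2 * d$x + 5
  fit <- fit_gaussian_lm(d, "y", "x", draws = 500, warmup = 500, seed = 2)
  b <- tidy(fit)[tidy(fit)$parameter == "beta_x", ]
  expect_equal(b$mean, 2, tolerance = 0.01)
  expect_lt(b$sd, 0.05)
  expect_true(b$clarity)
  a <- tidy(fit)[tidy(fit)$parameter == "alpha", ]
  # the exact least-squares solution lies inside every 95% interval
  expect_true(a$ci95_low <= 5 && 5 <= a$ci95_high)
  expect_true(b$ci95_low <= 2 && 2 <= b$ci95_high)
})

test_that("the MCMC fit agrees with the analytic conjugate posterior", {
  d <- make_lm_data(n = 150)
  mc <- fit_gaussian_lm(d, "y", "x", draws = 2000, warmup = 1000, seed = 3)
  an <- fit_gaussian_conjugate(d, "y", "x", draws = 8000, seed = 4)
  for (p in c("alpha", "beta_x", "sigma")) {
    m1 <- tidy(mc)[tidy(mc)$parameter == p, ]
    m2 <- tidy(an)[tidy(an)$parameter == p, ]
    expect_equal(m1$mean, m2$mean, tolerance = 0.03)
    expect_equal(m1$sd, m2$sd, tolerance = 0.25)
  }
})

test_that("degenerate designs and illegal transforms raise data errors", {
  d <- make_lm_data(n = 30)
  d$const <- 1
  expect_error(fit_gaussian_lm(d, "y", c("x", "const"), draws = 100,
                               warmup = 100),
               "constant predictor")
  d2 <- make_lm_data(n = 30)
  d2$x[5] <- -1
  expect_error(
    fit_gaussian_lm(d2, "y", "x", transforms = c(x = "log10"),
                    draws = 100, warmup = 100),
    "row\\(s\\): 5")
  expect_error(fit_gaussian_lm(d[1:3, ], "y", "x"), "more rows")
})

test_that("fits are bit-reproducible for a fixed seed", {
  d <- make_lm_data(n = 60)
  f1 <- fit_gaussian_lm(d, "y", "x", draws = 300, warmup = 300, seed = 7)
  f2 <- fit_gaussian_lm(d, "y", "x", draws = 300, warmup = 300, seed = 7)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_gaussian_lm(d, "y", "x", draws = 300, warmup = 300, seed = 8)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("group-mean contrasts back-transform to rate ratios and antisymmetrize", {
  set.seed(12)
  n_per <- 60
  truth <- c(neither = log10(0.05), neophytes_only = log10(0.05),
             hybrids_only = log10(0.15), both = log10(0.15))
  rt <- purrr::imap_dfr(truth, function(m, g) tibble::tibble(
    genus = paste(g, seq_len(n_per)),
    log10_rate = rnorm(n_per, m, 0.25),
    group = factor(g, levels = names(truth)),
    monotypic = FALSE, extreme = FALSE
  ))
  fit <- fit_group_means(rt, draws = 1500, warmup = 1000, seed = 5)
  ctr <- fit$contrasts
  b41 <- ctr[ctr$contrast == "both - neither", ]
  expect_true(b41$ratio_ci95_low <= 3 && 3 <= b41$ratio_ci95_high)
  # antisymmetry of the underlying difference draws
  d_ab <- fit$draws[, "both"] - fit$draws[, "neither"]
  d_ba <- fit$draws[, "neither"] - fit$draws[, "both"]
  expect_identical(d_ab, -d_ba)
  # a constant shift of delta = log10(2) gives exactly ratio 2
  expect_equal(10^0.30103, 2, tolerance = 1e-4)

  rt_missing <- rt[rt$group != "both", ]
  expect_error(fit_group_means(rt_missing, draws = 100, warmup = 100),
               "both")
})

test_that("the varying-slope footprint model needs at least two usable triplets", {
  obs <- tibble::tibble(
    triplet_id = "T1",
    taxon_type = rep(c("hybrid", "native", "neophyte"), each = 5),
    hfi = rnorm(15, 25, 2)
  )
  expect_error(fit_varying_slopes(obs, draws = 100, warmup = 100),
               "at least 2 triplets")
  obs_bad <- dplyr::mutate(obs, taxon_type = "parental")
  expect_error(fit_varying_slopes(obs_bad, draws = 100, warmup = 100),
               "unknown taxon_type")
})

test_that("identical footprint values yield null contrasts without clarity", {
  set.seed(9)
  obs <- tidyr::expand_grid(
    triplet_id = sprintf("T%d", 1:6),
    taxon_type = c("hybrid", "native", "neophyte"),
    rep = 1:8
  )
  obs$hfi <- 25
  # tiny jitter keeps the likelihood proper without creating signal
  obs$hfi <- obs$hfi + rnorm(nrow(obs), 0, 1e-3)
  fit <- fit_varying_slopes(obs, draws = 800, warmup = 800, seed = 11)
  expect_true(all(abs(fit$contrasts$mean) < 0.01))
  expect_false(any(fit$contrasts$clarity))
})

test_that("slope-to-percent conversion matches the printed interpretations", {
  # the cross-country slope: a 20% neophyte increase means ~5% more hybrids
  expect_equal(round(slope_percent_change(0.26, 1.2)), 5)
  # the cross-genus ratio slope: ~12% increase
  expect_equal(round(slope_percent_change(0.64, 1.2)), 12)
  expect_equal(slope_percent_change(1, 1.2), 20, tolerance = 1e-12)
  expect_equal(slope_percent_change(0, 3), 0)
  expect_equal(slope_percent_change(0.26, 1.2), 4.854512,
               tolerance = 1e-6)
  expect_error(slope_percent_change(0.3, 0), "positive")
})

test_that("tidiers expose summaries and diagnostics in broom style", {
  d <- make_lm_data(n = 50)
  fit <- fit_gaussian_lm(d, "y", "x", draws = 400, warmup = 400, seed = 1)
  td <- tidy(fit)
  expect_true(all(c("parameter", "mean", "ci95_low", "ci95_high",
                    "clarity") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(is.logical(gl$diagnostics_ok))
  expect_s3_class(autoplot(fit), "ggplot")
})
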