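#' Bayesian Gaussian linear regression
#'
#' Fits `y ~ Normal(alpha + X beta, sigma)` by MCMC under weakly informative
#' priors scaled to the data: `beta_k ~ Normal(0, 2.5 sd(y)/sd(x_k))`,
#' `alpha ~ Normal(mean(y), 2.5 sd(y))`, `sigma ~ half-Student-t(3, sd(y))`.
#' Per-variable transforms (`"log10"` or `"identity"`) are applied before
#' fitting; a log10 transform of a column containing nonpositive values is a
#' data error listing the offending rows (count tables should be restricted
#' or offset upstream). A slope is flagged "statistically clear" when its
#' equal-tailed 95% credible interval excludes zero.
#'
#' @param data A data frame.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor columns.
#' @param transforms Named character vector mapping variable names to
#'   `"log10"` or `"identity"`; unnamed variables default to identity.
#' @param draws Posterior draws kept per chain after warmup.
#' @param warmup Adaptation + burn-in iterations per chain.
#' @param chains Number of MCMC chains (>= 2 for convergence diagnostics).
#' @param seed Integer seed controlling the sampler.
#' @return An object of class `bhm_lm` with elements `summary` (a posterior
#'   summary tibble), `draws` (matrix, merged chains), `diagnostics`
#'   (split-chain R-hat and effective sample size per parameter),
#'   `diagnostics_ok`, and the model metadata. Methods: [tidy()],
#'   [glance()], [autoplot()].
#' @export
fit_gaussian_lm <- function(data, response, predictors,
                            transforms = NULL,
                            draws = 2000, warmup = 1000, chains = 2,
                            seed = 1L) {
  prep <- prepare_lm_data(data, response, predictors, transforms)
  y <- prep$y
  X <- prep$X
  p <- ncol(X)
  sd_y <- sd(y)
  sd_x <- apply(X, 2, sd)
  if (any(sd_x == 0)) {
    stop("constant predictor column(s): ",
         paste(colnames(X)[sd_x == 0], collapse = ", "),
         " (not identifiable)", call. = FALSE)
  }
  if (length(y) <= p + 2) {
    stop("need more rows than predictors + 2", call. = FALSE)
  }
  # predictors are centered for the sampler (decorrelates the intercept
  # from the slopes); the intercept is transformed back afterwards
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  model <- "
  model {
    for (i in 1:N) {
      mu[i] <- alpha_c + inprod(X[i, ], beta)
      y[i] ~ dnorm(mu[i], tau)
    }
    alpha_c ~ dnorm(mean_y, 1 / pow(2.5 * sd_y, 2))
    for (k in 1:P) { beta[k] ~ dnorm(0, 1 / pow(2.5 * sd_y / sd_x[k], 2)) }
    tau <- pow(sigma, -2)
    sigma ~ dt(0, 1 / pow(sd_y, 2), 3) T(0,)
  }"
  jd <- list(y = y, X = Xc, N = length(y), P = p,
             mean_y = mean(y), sd_y = sd_y, sd_x = sd_x)
  fit <- run_jags(model, jd, c("alpha_c", "beta", "sigma"),
                  draws = draws, warmup = warmup, chains = chains,
                  seed = seed)
  mat <- fit$draws
  if (p == 1L && "beta" %in% colnames(mat)) {
    colnames(mat)[colnames(mat) == "beta"] <- "beta[1]"
  }
  colnames(mat) <- sub("^beta\\[(\\d+)\\]$", "b_\\1", colnames(mat))
  for (k in seq_len(p)) {
    colnames(mat)[colnames(mat) == paste0("b_", k)] <-
      paste0("beta_", colnames(X)[k])
  }
  beta_cols <- paste0("beta_", colnames(X))
  mat[, "alpha_c"] <- mat[, "alpha_c"] -
    as.vector(mat[, beta_cols, drop = FALSE] %*% xbar)
  colnames(mat)[colnames(mat) == "alpha_c"] <- "alpha"
  smry <- summarise_draws(mat) |>
    dplyr::mutate(clarity = .data$ci95_low > 0 | .data$ci95_high < 0)
  diag <- fit$diagnostics
  nm <- diag$parameter
  nm[nm == "alpha_c"] <- "alpha"
  if (p == 1L) nm[nm == "beta"] <- "beta[1]"
  nm <- sub("^beta\\[(\\d+)\\]$", "b_\\1", nm)
  for (k in seq_len(p)) {
    nm[nm == paste0("b_", k)] <- paste0("beta_", colnames(X)[k])
  }
  diag$parameter <- nm
  structure(
    list(summary = smry, draws = mat, diagnostics = diag,
         diagnostics_ok = diagnostics_ok(diag),
         response = response, predictors = colnames(X),
         transforms = prep$transforms, n = length(y), seed = seed),
    class = "bhm_lm"
  )
}

#' Conjugate Gaussian regression posterior (analytic reference)
#'
#' Exact posterior sampling for the same Gaussian linear model under the
#' noninformative Jeffreys prior `p(alpha, beta, sigma^2) ~ 1/sigma^2`:
#' `sigma^2` is drawn from its scaled inverse-chi-square marginal and the
#' coefficients from their conditional normal. Serves as an independent
#' closed-form reference for the MCMC fit on non-hierarchical problems.
#'
#' @inheritParams fit_gaussian_lm
#' @return An object of class `bhm_lm` (with `sampler = "conjugate"`).
#' @export
fit_gaussian_conjugate <- function(data, response, predictors,
                                   transforms = NULL, draws = 4000,
                                   seed = 1L) {
  prep <- prepare_lm_data(data, response, predictors, transforms)
  y <- prep$y
  X <- cbind(alpha = 1, prep$X)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop("need more rows than predictors + 2", call. = FALSE)
  XtX <- crossprod(X)
  ch <- tryCatch(chol(XtX), error = function(e)
    stop("design matrix is rank-deficient (not identifiable)", call. = FALSE))
  bhat <- backsolve(ch, forwardsolve(t(ch), crossprod(X, y)))
  resid <- y - X %*% bhat
  s2 <- sum(resid^2) / (n - p)
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sigma2 <- (n - p) * s2 / stats::rchisq(draws, df = n - p)
  Z <- matrix(rnorm(draws * p), draws, p)
  # beta | sigma2 ~ N(bhat, sigma2 (X'X)^-1); R^-1 Z' has covariance (X'X)^-1
  Binv <- backsolve(ch, diag(p))
  coefs <- sweep(Z %*% t(Binv), 1, sqrt(sigma2), `*`) +
    matrix(bhat, draws, p, byrow = TRUE)
  mat <- cbind(coefs, sqrt(sigma2))
  colnames(mat) <- c("alpha", paste0("beta_", colnames(prep$X)), "sigma")
  smry <- summarise_draws(mat) |>
    dplyr::mutate(clarity = .data$ci95_low > 0 | .data$ci95_high < 0)
  structure(
    list(summary = smry, draws = mat,
         diagnostics = tibble(parameter = colnames(mat), rhat = NA_real_,
                              ess = as.numeric(draws)),
         diagnostics_ok = TRUE, response = response,
         predictors = colnames(prep$X), transforms = prep$transforms,
         n = n, seed = seed, sampler = "conjugate"),
    class = "bhm_lm"
  )
}

#' Posterior group means of log10 diversification rates with contrasts
#'
#' Fits the cell-means form of `d_i ~ Normal(alpha + beta_group_i, sigma)`
#' to the log10 net diversification rate and derives all pairwise group
#' contrasts from the posterior draws. Because the response is on the log10
#' scale, each contrast is back-transformed as `10^difference`, a ratio of
#' diversification rates between groups. Monotypic genera (rate 0, log10
#' undefined) and, optionally, extreme-rate genera are excluded here, not in
#' the rate table.
#'
#' @param rate_table Output of [build_rate_table()].
#' @param exclude_monotypic Drop monotypic genera (default `TRUE`; they have
#'   no defined log10 rate, so `FALSE` only matters when an offset was
#'   applied upstream).
#' @param exclude_extreme Drop genera flagged as extreme-rate outliers
#'   (default `FALSE`; a robustness toggle).
#' @inheritParams fit_gaussian_lm
#' @return An object of class `bhm_groups`: `group_summary` (posterior mean
#'   log10 rate per group, plus `rate_mean`, the posterior mean of
#'   `10^log10-mean`), `contrasts` (pairwise differences with 66%/95%
#'   intervals and back-transformed ratio summaries), `draws`,
#'   `diagnostics`, `diagnostics_ok`.
#' @export
fit_group_means <- function(rate_table, exclude_monotypic = TRUE,
                            exclude_extreme = FALSE,
                            draws = 2000, warmup = 1000, chains = 2,
                            seed = 1L) {
  dat <- rate_table
  if (exclude_monotypic) dat <- dplyr::filter(dat, !.data$monotypic)
  if (exclude_extreme) dat <- dplyr::filter(dat, !.data$extreme)
  dat <- dplyr::filter(dat, !is.na(.data$log10_rate))
  lv <- levels(dat$group)
  counts <- table(factor(dat$group, levels = lv))
  if (any(counts == 0)) {
    stop("empty group(s) after exclusions: ",
         paste(lv[counts == 0], collapse = ", "), call. = FALSE)
  }
  y <- dat$log10_rate
  g <- as.integer(dat$group)
  model <- "
  model {
    for (i in 1:N) { y[i] ~ dnorm(m[g[i]], tau) }
    for (k in 1:K) { m[k] ~ dnorm(mean_y, 1 / pow(2.5 * sd_y, 2)) }
    tau <- pow(sigma, -2)
    sigma ~ dt(0, 1 / pow(sd_y, 2), 3) T(0,)
  }"
  jd <- list(y = y, g = g, N = length(y), K = length(lv),
             mean_y = mean(y), sd_y = sd(y))
  fit <- run_jags(model, jd, c("m", "sigma"), draws = draws,
                  warmup = warmup, chains = chains, seed = seed)
  mat <- fit$draws
  m_cols <- paste0("m[", seq_along(lv), "]")
  colnames(mat)[match(m_cols, colnames(mat))] <- lv
  group_summary <- summarise_draws(mat[, lv, drop = FALSE]) |>
    dplyr::rename(group = "parameter") |>
    dplyr::mutate(rate_mean = colMeans(10^mat[, lv, drop = FALSE]),
                  n_genera = as.integer(counts[.data$group]))
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  contrasts <- purrr::map_dfr(pairs, function(pr) {
    d <- mat[, pr[2]] - mat[, pr[1]]
    contrast_row(pr[2], pr[1], d, ratio = TRUE)
  })
  diag <- rename_diag(fit$diagnostics, c(m_cols, "sigma"),
                      c(lv, "sigma"))
  structure(
    list(group_summary = group_summary, contrasts = contrasts,
         draws = mat, diagnostics = diag,
         diagnostics_ok = diagnostics_ok(diag),
         n = length(y), excluded = attr(dat, "excluded"), seed = seed),
    class = "bhm_groups"
  )
}

#' Hierarchical varying-slope model of footprint by taxon type
#'
#' Fits `hfi ~ Normal(alpha_triplet + beta_type,triplet, sigma)`: every
#' triplet (a hybrid with its native and neophyte parent) carries its own
#' intercept and its own type effects, partially pooled toward
#' population-level type means. Hierarchical centering is used for the
#' group-level terms (it mixes far better than the non-centered form at
#' this data scale). Population-level mean HFI per type and the three
#' pairwise posterior differences (hybrid - native, hybrid - neophyte,
#' native - neophyte) are returned with 66% and 95% equal-tailed intervals.
#'
#' @param observations Output of [triplet_observations()]: columns
#'   `triplet_id`, `taxon_type` (hybrid/native/neophyte), `hfi`.
#' @inheritParams fit_gaussian_lm
#' @return An object of class `bhm_hfi`: `type_summary`, `contrasts`,
#'   `draws`, `diagnostics`, `diagnostics_ok`.
#' @export
fit_varying_slopes <- function(observations, draws = 4000, warmup = 2000,
                               chains = 2, seed = 1L) {
  need <- c("triplet_id", "taxon_type", "hfi")
  stopifnot(all(need %in% names(observations)))
  obs <- observations |>
    dplyr::filter(!is.na(.data$hfi)) |>
    dplyr::mutate(taxon_type = as.character(.data$taxon_type))
  bad_type <- setdiff(unique(obs$taxon_type),
                      c("hybrid", "native", "neophyte"))
  if (length(bad_type) > 0L) {
    stop("unknown taxon_type: ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  n_types <- obs |>
    dplyr::group_by(.data$triplet_id) |>
    dplyr::summarise(k = dplyr::n_distinct(.data$taxon_type),
                     .groups = "drop")
  keep <- n_types$triplet_id[n_types$k >= 2]
  dropped <- setdiff(n_types$triplet_id, keep)
  obs <- dplyr::filter(obs, .data$triplet_id %in% keep)
  if (length(keep) < 2L) {
    stop("need at least 2 triplets with >= 2 taxon types; got ",
         length(keep), call. = FALSE)
  }
  trip <- match(obs$triplet_id, keep)
  model <- "
  model {
    for (i in 1:N) {
      mu[i] <- u[trip[i]] + d_nat[i] * b_nat[trip[i]] +
               d_neo[i] * b_neo[trip[i]]
      y[i] ~ dnorm(mu[i], tau)
    }
    for (j in 1:J) {
      u[j] ~ dnorm(beta_hyb, tau_u)
      b_nat[j] ~ dnorm(beta_nat, tau_b)
      b_neo[j] ~ dnorm(beta_neo, tau_b)
    }
    beta_hyb ~ dnorm(mean_y, 1 / pow(2.5 * sd_y, 2))
    beta_nat ~ dnorm(0, 1 / pow(2.5 * sd_y, 2))
    beta_neo ~ dnorm(0, 1 / pow(2.5 * sd_y, 2))
    tau <- pow(sigma, -2)
    sigma ~ dt(0, 1 / pow(sd_y, 2), 3) T(0,)
    tau_u <- pow(s_u, -2)
    s_u ~ dt(0, 1 / pow(sd_y, 2), 3) T(0,)
    tau_b <- pow(s_b, -2)
    s_b ~ dt(0, 1 / pow(sd_y, 2), 3) T(0,)
    m_hybrid <- beta_hyb
    m_native <- beta_hyb + beta_nat
    m_neophyte <- beta_hyb + beta_neo
  }"
  jd <- list(y = obs$hfi, trip = trip,
             d_nat = as.numeric(obs$taxon_type == "native"),
             d_neo = as.numeric(obs$taxon_type == "neophyte"),
             N = nrow(obs), J = length(keep),
             mean_y = mean(obs$hfi), sd_y = sd(obs$hfi))
  # only the population-level quantities are monitored and reported; the
  # group-level scales are nuisance parameters whose slow mixing would
  # otherwise dominate the effective-sample budget
  fit <- run_jags(model, jd,
                  c("m_hybrid", "m_native", "m_neophyte", "sigma"),
                  draws = draws, warmup = warmup, chains = chains,
                  seed = seed)
  mat <- fit$draws
  type_cols <- c(hybrid = "m_hybrid", native = "m_native",
                 neophyte = "m_neophyte")
  type_summary <- summarise_draws(mat[, type_cols, drop = FALSE]) |>
    dplyr::mutate(parameter = names(type_cols)) |>
    dplyr::rename(taxon_type = "parameter")
  prs <- list(c("hybrid", "native"), c("hybrid", "neophyte"),
              c("native", "neophyte"))
  contrasts <- purrr::map_dfr(prs, function(pr) {
    d <- mat[, type_cols[pr[1]]] - mat[, type_cols[pr[2]]]
    contrast_row(pr[1], pr[2], d, ratio = FALSE)
  })
  structure(
    list(type_summary = type_summary, contrasts = contrasts, draws = mat,
         diagnostics = fit$diagnostics,
         diagnostics_ok = diagnostics_ok(fit$diagnostics),
         n = nrow(obs), n_triplets = length(keep),
         dropped_triplets = dropped, seed = seed),
    class = "bhm_hfi"
  )
}

#' Convert a log10-log10 slope into a percent change
#'
#' For a regression of a log10 response on a log10 predictor with slope `b`,
#' a multiplicative change of the predictor by `predictor_factor` changes
#' the response by `100 * (predictor_factor^b - 1)` percent.
#'
#' @param b Slope(s) on the log10-log10 scale.
#' @param predictor_factor Positive multiplicative change of the predictor
#'   (e.g. 1.2 for a 20% increase).
#' @return Percent change(s) of the response.
#' @examples
#' slope_percent_change(0.26, 1.2)  # ~4.9%
#' @export
slope_percent_change <- function(b, predictor_factor) {
  if (any(!is.finite(predictor_factor)) || any(predictor_factor <= 0)) {
    stop("predictor_factor must be positive", call. = FALSE)
  }
  100 * (predictor_factor^b - 1)
}

## -- internal machinery ------------------------------------------------------

prepare_lm_data <- function(data, response, predictors, transforms) {
  vars <- c(response, predictors)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0L) {
    stop("data is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tr <- setNames(rep("identity", length(vars)), vars)
  if (!is.null(transforms)) {
    bad <- setdiff(transforms, c("log10", "identity"))
    if (length(bad) > 0L) stop("unknown transform: ", bad[1], call. = FALSE)
    tr[names(transforms)] <- transforms
  }
  cols <- lapply(vars, function(v) {
    x <- as.numeric(data[[v]])
    if (tr[[v]] == "log10") {
      bad_rows <- which(!is.na(x) & x <= 0)
      if (length(bad_rows) > 0L) {
        stop("log10 transform of '", v, "' undefined for row(s): ",
             paste(head(bad_rows, 10), collapse = ", "), call. = FALSE)
      }
      x <- log10(x)
    }
    x
  })
  names(cols) <- vars
  df <- as_tibble(cols)
  cc <- stats::complete.cases(df)
  if (!all(cc)) {
    stop("missing values after transform in row(s): ",
         paste(head(which(!cc), 10), collapse = ", "), call. = FALSE)
  }
  list(y = df[[response]],
       X = as.matrix(df[predictors]),
       transforms = tr)
}

run_jags <- function(model_string, data, monitor, draws, warmup, chains,
                     seed, adapt = NULL) {
  adapt <- adapt %||% max(500L, warmup %/% 2L)
  inits <- lapply(seq_len(chains), function(k) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + k - 1L)
  })
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = chains,
                          n.adapt = adapt, quiet = TRUE)
  update(jm, warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitor, n.iter = draws,
                              progress.bar = "none")
  mat <- as.matrix(samp)
  rhat <- rep(NA_real_, ncol(mat))
  if (chains >= 2) {
    gd <- tryCatch(coda::gelman.diag(samp, autoburnin = FALSE,
                                     multivariate = FALSE),
                   error = function(e) NULL)
    if (!is.null(gd)) {
      rhat <- gd$psrf[match(colnames(mat), rownames(gd$psrf)), 1]
    }
  }
  ess_all <- coda::effectiveSize(samp)
  ess <- as.numeric(ess_all)[match(colnames(mat), names(ess_all))]
  list(draws = mat,
       diagnostics = tibble(parameter = colnames(mat), rhat = rhat,
                            ess = ess))
}

summarise_draws <- function(mat) {
  purrr::map_dfr(colnames(mat), function(cn) {
    d <- mat[, cn]
    q <- quantile(d, c(0.025, 0.17, 0.5, 0.83, 0.975), names = FALSE)
    tibble(parameter = cn, mean = mean(d), sd = sd(d), median = q[3],
           ci66_low = q[2], ci66_high = q[4],
           ci95_low = q[1], ci95_high = q[5])
  })
}

contrast_row <- function(a, b, d, ratio = FALSE) {
  q <- quantile(d, c(0.025, 0.17, 0.5, 0.83, 0.975), names = FALSE)
  row <- tibble(
    contrast = paste(a, "-", b), level_a = a, level_b = b,
    mean = mean(d), sd = sd(d), median = q[3],
    ci66_low = q[2], ci66_high = q[4], ci95_low = q[1], ci95_high = q[5],
    clarity = q[1] > 0 | q[5] < 0
  )
  if (ratio) {
    r <- 10^d
    rq <- quantile(r, c(0.025, 0.5, 0.975), names = FALSE)
    row <- dplyr::mutate(row, ratio_mean = mean(r), ratio_median = rq[2],
                         ratio_ci95_low = rq[1], ratio_ci95_high = rq[3])
  }
  row
}

diagnostics_ok <- function(diag, rhat_max = 1.01, ess_min = 400) {
  rh <- diag$rhat[!is.na(diag$rhat)]
  all(rh < rhat_max) && all(diag$ess >= ess_min, na.rm = TRUE)
}

rename_diag <- function(diag, from, to) {
  idx <- match(diag$parameter, from)
  diag$parameter[!is.na(idx)] <- to[idx[!is.na(idx)]]
  diag
}
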