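sim_smooth_table <- function(n = 300, f = function(pa, size, eqr0) 0,
                             noise = 0.5, n_prov = 4, seed = 1) {
  set.seed(seed)
  pa <- sqrt(runif(n))           # transformed cover, denser near 1
  size <- runif(n, 0.5, 3)       # log10 km2
  eqr0 <- runif(n, 0.15, 0.95)
  prov <- sample(paste0("p", seq_len(n_prov)), n, replace = TRUE)
  data.frame(site_id = paste0("s", 1:n),
             pct_per_year = f(pa, size, eqr0) + rnorm(n, 0, noise),
             pa = pa, size = size, eqr0 = eqr0,
             latitude = runif(n, 45, 55), longitude = runif(n, 0, 20),
             ts_length = sample(10:30, n, TRUE), provider = prov,
             stringsAsFactors = FALSE)
}

test_that("square-root proportion transform maps percent to [0, 1]", {
  expect_equal(sqrt_prop(0), 0)
  expect_equal(sqrt_prop(100), 1)
  expect_equal(sqrt_prop(25), 0.5)
  expect_error(sqrt_prop(-1), "negative")
})

test_that("spline bases have the declared dimension and penalty rank", {
  set.seed(2)
  b <- spline_basis(runif(100), k = 10)
  expect_equal(ncol(b$values), 10)
  expect_equal(nrow(b$values), 100)
  S <- b$penalty[[1]]
  expect_equal(S, t(S), tolerance = 1e-10)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
  # thin-plate penalty null space in 1-d is the linear polynomial: rank k - 2
  expect_equal(sum(ev > 1e-8 * max(ev)), 8)
  expect_warning(spline_basis(rep(1:5, 4), k = 10), "reducing")
  expect_error(spline_basis(rep(1, 10)), "constant")
})

test_that("tensor bases are row-wise Kronecker products with marginal penalties", {
  set.seed(3)
  b1 <- spline_basis(runif(50), k = 4)
  b2 <- spline_basis(runif(50), k = 3)
  tb <- tensor_basis(b1, b2)
  expect_equal(ncol(tb$values), 12)
  expect_length(tb$penalty, 2)
  for (S in tb$penalty) {
    expect_equal(S, t(S), tolerance = 1e-10)
    expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > -1e-8))
  }
  # one-column second margin reduces to the first basis scaled by it
  one <- structure(list(values = matrix(2, 50, 1), penalty = list(),
                        k = 1, spec = NULL), class = "smooth_basis")
  tb2 <- tensor_basis(b1, one)
  expect_equal(tb2$values, 2 * b1$values)
  expect_error(tensor_basis(b1, spline_basis(runif(40), k = 3)), "mismatch")
})

test_that("a pure linear signal is recovered exactly through the penalty null space", {
  tab <- sim_smooth_table(n = 200, f = function(pa, size, eqr0) 1 + 2 * pa,
                          noise = 1e-8, seed = 4)
  fit <- fit_gamm(tab)
  pred <- predict(fit$model, newdata = tab)
  expect_equal(as.numeric(pred), tab$pct_per_year, tolerance = 1e-5)
  # smooth terms collapse toward their null spaces
  expect_lt(fit$edf[["ti(pa,size)"]], 1.2)
  expect_lt(fit$edf[["ti(pa,eqr0)"]], 1.2)
})

test_that("smooth fits track a known nonlinear signal below the noise floor", {
  f <- function(pa, size, eqr0) sin(3 * pa) + 0 * size
  tab <- sim_smooth_table(n = 200, f = f, noise = 0.3, seed = 5)
  fit <- fit_gamm(tab)
  pred <- predict(fit$model, newdata = tab, exclude = "s(provider)")
  rmse <- sqrt(mean((as.numeric(pred) - f(tab$pa, tab$size, tab$eqr0))^2))
  expect_lt(rmse, 0.3)
})

test_that("small subsets are refused", {
  tab <- sim_smooth_table(n = 20, seed = 6)
  expect_error(fit_gamm(tab), "too small")
})

test_that("Wald tests separate interaction-present from interaction-absent signals", {
  # multiplicative truth: interaction detected, and better than additive-only
  tab <- sim_smooth_table(n = 400,
                          f = function(pa, size, eqr0) 2 * pa * (1 - eqr0),
                          noise = 0.3, seed = 7)
  fit <- fit_gamm(tab)
  w <- wald_smooth(fit, "ti(pa,eqr0)")
  expect_lt(w$p_raw, 0.01)
  expect_gte(w$statistic, 0)
  expect_true(w$edf >= 1 - 1e-6 && w$edf <= 16)
  # additive truth: interaction term stays near its floor
  tab0 <- sim_smooth_table(n = 400,
                           f = function(pa, size, eqr0) 2 * pa + eqr0,
                           noise = 0.3, seed = 8)
  fit0 <- fit_gamm(tab0)
  w0 <- wald_smooth(fit0, "ti(pa,eqr0)")
  expect_gt(w0$p_raw, 0.01)
  expect_lt(fit0$edf[["ti(pa,eqr0)"]], fit$edf[["ti(pa,eqr0)"]] + 1)
  expect_error(wald_smooth(fit, "ti(nope)"), "not in fit")
})

test_that("provider offsets are absorbed by the random-intercept block", {
  tab <- sim_smooth_table(n = 300, f = function(pa, size, eqr0) 1 + 2 * pa,
                          noise = 0.2, n_prov = 4, seed = 9)
  fit1 <- fit_gamm(tab)
  tab2 <- tab
  off <- c(p1 = 1, p2 = -1, p3 = 0.5, p4 = -0.5)
  tab2$pct_per_year <- tab2$pct_per_year + off[tab2$provider]
  fit2 <- fit_gamm(tab2)
  c1 <- predict_pa_effect(fit1, eqr0_values = 0.5)
  c2 <- predict_pa_effect(fit2, eqr0_values = 0.5)
  expect_equal(c1$prediction, c2$prediction, tolerance = 0.1)
})

test_that("effect curves respect conditioning, grids, and intervals", {
  tab <- sim_smooth_table(n = 300,
                          f = function(pa, size, eqr0) 3 * pa * (1 - eqr0),
                          noise = 0.2, seed = 10)
  fit <- fit_gamm(tab)
  cu <- predict_pa_effect(fit)
  expect_setequal(unique(cu$eqr0), c(0.2, 0.4, 0.6, 0.8))
  expect_true(all(cu$ci_low <= cu$prediction & cu$prediction <= cu$ci_high))
  # interaction truth: curve slope decreases with initial quality
  slopes <- vapply(c(0.2, 0.4, 0.6, 0.8), function(e0) {
    s <- cu[cu$eqr0 == e0, ]
    unname(coef(lm(prediction ~ pa, data = s))[2])
  }, 0)
  expect_true(all(diff(slopes) < 0))
  # single-point grid
  one <- predict_pa_effect(fit, eqr0_values = 0.5, pa_grid = 0.5)
  expect_equal(nrow(one), 1)
  # out-of-range grid clipped with a warning
  expect_warning(predict_pa_effect(fit, eqr0_values = 0.5, pa_grid = c(0.5, 99)),
                 "clipped")
})

test_that("in the heavy-penalty limit the smooth model matches its parametric null space", {
  tab <- sim_smooth_table(n = 250, f = function(pa, size, eqr0) 1 + 1.5 * pa +
                            0.5 * size - eqr0, noise = 0.3, n_prov = 1, seed = 11)
  fit <- fit_gamm(tab)
  # force all smoothing parameters to near-infinity: each term collapses to
  # its penalty null space -- linear main effects plus the bilinear products
  # retained by the pure-interaction tensors
  heavy <- mgcv::gam(formula(fit$model), data = tab,
                     sp = rep(1e10, length(fit$model$sp)))
  lin <- lm(pct_per_year ~ pa + size + eqr0 + pa:size + pa:eqr0 +
              latitude + longitude + ts_length, data = tab)
  expect_equal(as.numeric(predict(heavy, newdata = tab)),
               as.numeric(predict(lin, newdata = tab)), tolerance = 1e-3)
})

test_that("the smooth analysis grid runs end to end with BH within families", {
  study <- get_shared_study()
  trends <- suppressWarnings(trend_table(study$series))
  covars <- study$sites[, c("site_id", "latitude", "longitude", "ts_length",
                            "provider")]
  sizes <- data.frame(site_id = study$sites$site_id,
                      size_km2 = vapply(study$sites$site_id, function(s)
                        study$scale_polys[[s]]$full$area_km2, 0))
  res <- run_smooth_models(trends, study$cover, covars, sizes, min_n = 30)
  expect_true(!is.null(res$tests))
  expect_true(all(res$tests$p_adjusted >= res$tests$p_raw - 1e-12))
  expect_true(all(res$tests$edf >= 0))
  if (!is.null(res$curves))
    expect_true(all(res$curves$ci_low <= res$curves$ci_high))
})
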