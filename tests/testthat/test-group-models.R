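sim_group_table <- function(n = 100, effect = 0, prov_sd = 0, res_sd = 1,
                            n_prov = 4, seed = 1) {
  set.seed(seed)
  prov <- sample(paste0("p", seq_len(n_prov)), n, replace = TRUE)
  off <- setNames(rnorm(n_prov, 0, prov_sd), paste0("p", seq_len(n_prov)))
  g <- rep(c(FALSE, TRUE), length.out = n)
  data.frame(site_id = paste0("s", 1:n),
             pct_per_year = 1 + effect * g + off[prov] + rnorm(n, 0, res_sd),
             group = g,
             latitude = runif(n, 45, 55), longitude = runif(n, 0, 20),
             ts_length = sample(10:30, n, TRUE), provider = prov,
             stringsAsFactors = FALSE)
}

test_that("a single provider degrades gracefully to ordinary least squares", {
  tab <- sim_group_table(n = 60, effect = 1.2, n_prov = 1, seed = 2)
  fit <- fit_lmm(tab)
  expect_equal(fit$provider_variance, 0)
  ref <- lm(pct_per_year ~ group + latitude + longitude + ts_length, data = tab)
  expect_equal(fit$fixed$estimate[fit$fixed$term == "groupyes"],
               unname(coef(ref)["groupTRUE"]), tolerance = 1e-10)
})

test_that("with orthogonal covariates the group coefficient is the difference of means", {
  n <- 40
  g <- rep(c(FALSE, TRUE), each = n / 2)
  set.seed(3)
  cov_block <- data.frame(latitude = rep(runif(n / 2, 45, 50), 2),
                          longitude = rep(runif(n / 2, 5, 9), 2),
                          ts_length = rep(sample(10:30, n / 2, TRUE), 2))
  tab <- cbind(data.frame(pct_per_year = ifelse(g, 2, 1) + rnorm(n, 0, 0.3),
                          group = g, provider = "p1",
                          site_id = paste0("s", 1:n)), cov_block)
  fit <- fit_lmm(tab)
  dm <- mean(tab$pct_per_year[g]) - mean(tab$pct_per_year[!g])
  expect_equal(fit$fixed$estimate[fit$fixed$term == "groupyes"], dm,
               tolerance = 1e-8)
})

test_that("lme4-backed fits recover known group effects and provider variance", {
  tab <- sim_group_table(n = 400, effect = 1.5, prov_sd = 0.5, res_sd = 1,
                         n_prov = 8, seed = 4)
  fit <- fit_lmm(tab)
  est <- fit$fixed$estimate[fit$fixed$term == "groupyes"]
  expect_equal(est, 1.5, tolerance = 0.3)
  expect_gt(fit$provider_variance, 0)
  expect_gt(fit$loglik_reml, -Inf)
  # ML loglik of full model is >= reduced model's by construction
  red <- fit_lmm(tab, include_group = FALSE)
  expect_gte(fit$loglik_ml, red$loglik_ml - 1e-6)
})

test_that("rank-deficient designs are reported with the aliased column", {
  tab <- sim_group_table(n = 50, seed = 5)
  tab$longitude <- tab$latitude  # aliased
  expect_error(fit_lmm(tab), "aliased|rank")
})

test_that("likelihood-ratio tests follow the chi-squared reference", {
  mk <- function(ll, k, n = 100) structure(list(loglik_ml = ll, n_fixed = k, n = n),
                                           class = "lmm_fit")
  expect_equal(lrt(mk(-50, 5), mk(-50, 4)),
               data.frame(statistic = 0, df = 1, p_raw = 1))
  out <- lrt(mk(-50 + 3.841459 / 2, 5), mk(-50, 4))
  expect_equal(out$p_raw, 0.05, tolerance = 1e-4)
  # negative differences clip to zero
  expect_equal(lrt(mk(-51, 5), mk(-50, 4))$statistic, 0)
  expect_error(lrt(mk(-50, 4), mk(-50, 5)), "more fixed terms")
  expect_error(lrt(mk(-50, 5, n = 100), mk(-50, 4, n = 90)), "same data")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.123), 0.123)
  set.seed(6)
  for (rep in 1:100) {
    p <- runif(sample(2:12, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    # monotone in the raw p-values
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("group means and intervals are exact in the zero-noise limit", {
  n <- 40
  g <- rep(c(FALSE, TRUE), each = n / 2)
  set.seed(8)
  tab <- data.frame(site_id = paste0("s", 1:n),
                    pct_per_year = ifelse(g, 2, 1),
                    group = g,
                    latitude = rep(runif(n / 2, 45, 50), 2),
                    longitude = rep(runif(n / 2, 5, 9), 2),
                    ts_length = rep(sample(10:30, n / 2, TRUE), 2),
                    provider = "p1", stringsAsFactors = FALSE)
  # zero residuals: summary.lm warns about an essentially perfect fit
  fit <- suppressWarnings(fit_lmm(tab))
  gm <- group_mean_ci(fit)
  expect_equal(gm$mean, c(1, 2), tolerance = 1e-6)
  expect_lt(max(gm$ci_high - gm$ci_low), 1e-6)
  # symmetric design -> equal interval widths
  tab$pct_per_year <- tab$pct_per_year + rnorm(n, 0, 0.2)
  gm2 <- group_mean_ci(fit_lmm(tab))
  expect_equal(gm2$ci_high[1] - gm2$ci_low[1], gm2$ci_high[2] - gm2$ci_low[2],
               tolerance = 1e-6)
  expect_error(group_mean_ci(fit_lmm(tab, include_group = FALSE)), "group term")
})

test_that("group mean coverage reaches its nominal level", {
  set.seed(7)
  hits <- 0; reps <- 200
  for (r in 1:reps) {
    tab <- sim_group_table(n = 80, effect = 0.8, prov_sd = 0, res_sd = 1,
                           n_prov = 1, seed = 700 + r)
    gm <- group_mean_ci(fit_lmm(tab))
    truth <- c(1, 1.8)
    hits <- hits + all(gm$ci_low <= truth & truth <= gm$ci_high)
  }
  # joint coverage of the two intervals: at least ~90% of replicates
  expect_gte(hits / reps, 0.88)
})

test_that("the analysis grid produces 24 tests with within-family BH", {
  study <- get_shared_study()
  trends <- suppressWarnings(trend_table(study$series))
  covars <- study$sites[, c("site_id", "latitude", "longitude", "ts_length",
                            "provider")]
  res <- suppressWarnings(run_group_models(trends, study$cover, covars))
  expect_equal(nrow(res$tests), 24)
  expect_equal(unique(table(res$tests$metric)), 8L)
  expect_equal(unique(table(res$tests$family)), 12L)
  # classification counts sum to the included total at every scale
  expect_true(all(res$tests$n_group + res$tests$n_ref == res$tests$n))
  # adjusted p monotone in raw p within each family
  for (key in unique(paste(res$tests$metric, res$tests$family))) {
    sub <- res$tests[paste(res$tests$metric, res$tests$family) == key, ]
    sub <- sub[!is.na(sub$p_raw), ]
    if (nrow(sub) > 1) {
      o <- order(sub$p_raw)
      expect_true(all(diff(sub$p_adjusted[o]) >= -1e-12))
      expect_true(all(sub$p_adjusted >= sub$p_raw - 1e-12))
    }
  }
})
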