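# Analysis set 1: categorical group comparisons.
#
# Site-level rates of biodiversity change (percent per year) are related to
# the protected / unprotected (or gained / no-gain) classification at each
# upstream scale with linear mixed models: fixed terms for the group flag,
# site latitude, longitude, and time-series length, and a random intercept
# for the data provider. The group term is tested by dropping it and
# comparing full and reduced models fitted by maximum likelihood with a
# likelihood-ratio test; p-values are Benjamini-Hochberg corrected within
# each metric x comparison family across the four upstream scales.

#' Linear mixed model for group comparisons
#'
#' Fits `pct_per_year ~ [group +] latitude + longitude + ts_length +
#' (1 | provider)` by REML via `lme4`, and also records the ML log-likelihood
#' of the same specification for likelihood-ratio testing. With fewer than
#' two providers the random intercept is dropped and the model reduces to
#' ordinary least squares (provider variance 0).
#'
#' @param table data.frame with columns `pct_per_year`, `latitude`,
#'   `longitude`, `ts_length`, `provider`, and (if `include_group`) a logical
#'   or factor `group` column.
#' @param include_group include the group flag as a fixed term?
#' @return object of class `lmm_fit`: list with `fixed` (coefficient table),
#'   `provider_variance`, `residual_variance`, `loglik_ml`, `loglik_reml`,
#'   `n`, `n_fixed`, `vcov_fixed`, `model` (the lme4 or lm object), and
#'   `data`.
#' @export
fit_lmm <- function(table, include_group = TRUE) {
  req <- c("pct_per_year", "latitude", "longitude", "ts_length", "provider")
  if (include_group) req <- c(req, "group")
  miss <- setdiff(req, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(table[req])) stop("missing values in model columns")
  table$provider <- factor(table$provider)
  if (include_group && !is.factor(table$group))
    table$group <- factor(table$group, levels = c(FALSE, TRUE),
                          labels = c("no", "yes"))
  rhs <- paste(c(if (include_group) "group", "latitude", "longitude", "ts_length"),
               collapse = " + ")
  # rank check on the fixed design before fitting (lme4 would silently drop
  # aliased columns)
  Xf <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = table)
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf))
    stop("rank-deficient fixed design; aliased: ",
         paste(colnames(Xf)[qrX$pivot[(qrX$rank + 1L):ncol(Xf)]], collapse = ", "))
  if (nlevels(table$provider) >= 2L) {
    fml <- stats::as.formula(paste("pct_per_year ~", rhs, "+ (1 | provider)"))
    fit <- lme4::lmer(fml, data = table, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
    vc <- lme4::VarCorr(fit)
    prov_var <- as.numeric(vc$provider[1])
    res_var <- attr(vc, "sc")^2
    ll_ml <- as.numeric(stats::logLik(lme4::refitML(fit)))
    ll_reml <- as.numeric(stats::logLik(fit))
    cf <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
  } else {
    fml <- stats::as.formula(paste("pct_per_year ~", rhs))
    fit <- stats::lm(fml, data = table)
    if (any(is.na(stats::coef(fit))))
      stop("rank-deficient fixed design; aliased: ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
    prov_var <- 0
    res_var <- summary(fit)$sigma^2
    n <- nrow(table); p <- length(stats::coef(fit))
    rss <- sum(stats::residuals(fit)^2)
    ll_ml <- -0.5 * n * (log(2 * pi) + log(rss / n) + 1)
    ll_reml <- as.numeric(stats::logLik(fit, REML = TRUE))
    cf <- stats::coef(fit)
    V <- stats::vcov(fit)
  }
  fixed <- data.frame(term = names(cf), estimate = unname(cf),
                      se = sqrt(diag(V)), stringsAsFactors = FALSE)
  structure(list(fixed = fixed, provider_variance = prov_var,
                 residual_variance = res_var, loglik_ml = ll_ml,
                 loglik_reml = ll_reml, n = nrow(table),
                 n_fixed = nrow(fixed), vcov_fixed = V, model = fit,
                 include_group = include_group, data = table),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit: n %d, %d fixed terms, provider var %.4g, residual var %.4g>\n",
              x$n, x$n_fixed, x$provider_variance, x$residual_variance))
  print(x$fixed, row.names = FALSE)
  invisible(x)
}

#' Likelihood-ratio test of nested mixed models
#'
#' Compares maximum-likelihood fits of a full and a reduced specification on
#' the same data: statistic `2 * (llf - llr)` clipped at zero, degrees of
#' freedom equal to the difference in fixed-effect count, upper-tail
#' chi-squared p-value.
#'
#' @param full,reduced `lmm_fit` objects with the reduced model nested in the
#'   full one.
#' @return one-row data.frame with `statistic`, `df`, `p_raw`.
#' @export
lrt <- function(full, reduced) {
  if (full$n != reduced$n) stop("models were not fitted to the same data")
  df <- full$n_fixed - reduced$n_fixed
  if (df < 0L) stop("reduced model has more fixed terms than the full model")
  stat <- max(0, 2 * (full$loglik_ml - reduced$loglik_ml))
  p <- if (df == 0L) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  data.frame(statistic = stat, df = df, p_raw = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values for one family of tests, returned
#' in input order.
#'
#' @param p_values numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Predicted group means with 95% confidence intervals
#'
#' Predicted mean response per group level with all other fixed covariates
#' held at their sample means, with Wald intervals from the fixed-effect
#' covariance (the machine-readable form of a group-means figure).
#'
#' @param fit an `lmm_fit` fitted with a group term.
#' @param level confidence level.
#' @return data.frame with `group`, `mean`, `ci_low`, `ci_high`.
#' @export
group_mean_ci <- function(fit, level = 0.95) {
  if (!isTRUE(fit$include_group)) stop("model has no group term")
  dat <- fit$data
  lv <- levels(dat$group)
  terms_ <- fit$fixed$term
  X <- matrix(0, nrow = length(lv), ncol = length(terms_),
              dimnames = list(lv, terms_))
  X[, "(Intercept)"] <- 1
  for (cv in c("latitude", "longitude", "ts_length"))
    X[, cv] <- mean(dat[[cv]])
  for (k in seq_along(lv)[-1L]) {
    cn <- paste0("group", lv[k])
    if (cn %in% terms_) X[k, cn] <- 1
  }
  est <- as.numeric(X %*% fit$fixed$estimate)
  se <- sqrt(rowSums((X %*% fit$vcov_fixed) * X))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(group = lv, mean = est, ci_low = est - z * se,
             ci_high = est + z * se, stringsAsFactors = FALSE)
}

#' Group comparisons across the full metric x scale grid
#'
#' Runs the full analysis set 1: for each metric (abundance, richness, EQR),
#' scale, and comparison family (protected vs unprotected; gained vs no
#' gain), fits the full and reduced LMM, performs the LRT, and adjusts
#' p-values within each metric x family across the scales.
#'
#' @param trends trend table from [trend_table()].
#' @param cover cover table from [cover_table()].
#' @param covariates data.frame with `site_id`, `latitude`, `longitude`,
#'   `ts_length`, `provider`.
#' @param scales scales to analyse.
#' @param alpha significance threshold applied to adjusted p-values.
#' @return list with `tests` (one row per metric x scale x family:
#'   `statistic`, `df`, `p_raw`, `p_adjusted`, `significant`, group ns,
#'   estimated contrast) and `means` (group means and CIs per test).
#' @export
run_group_models <- function(trends, cover, covariates,
                             scales = c("1km", "10km", "100km", "full"),
                             alpha = 0.05) {
  tests <- list(); means <- list()
  for (metric_ in unique(trends$metric)) {
    tr <- trends[trends$metric == metric_, c("site_id", "pct_per_year")]
    for (family_ in c("protected", "gained")) {
      fam_rows <- list()
      for (scale_ in scales) {
        cv <- cover[cover$scale == scale_, c("site_id", "protected", "gained")]
        tab <- merge(merge(tr, cv, by = "site_id"), covariates, by = "site_id")
        tab$group <- tab[[family_]]
        if (length(unique(tab$group)) < 2L) {
          # one group empty at this scale: no contrast to test
          fam_rows[[scale_]] <- data.frame(
            metric = metric_, family = family_, scale = scale_,
            n = nrow(tab), n_group = sum(tab$group), n_ref = sum(!tab$group),
            contrast = NA_real_, statistic = NA_real_, df = NA_integer_,
            p_raw = NA_real_, stringsAsFactors = FALSE)
          next
        }
        full <- fit_lmm(tab, include_group = TRUE)
        red <- fit_lmm(tab, include_group = FALSE)
        tst <- lrt(full, red)
        gm <- group_mean_ci(full)
        gidx <- match("groupyes", full$fixed$term)
        fam_rows[[scale_]] <- data.frame(
          metric = metric_, family = family_, scale = scale_,
          n = full$n, n_group = sum(tab$group), n_ref = sum(!tab$group),
          contrast = full$fixed$estimate[gidx],
          statistic = tst$statistic, df = tst$df, p_raw = tst$p_raw,
          stringsAsFactors = FALSE)
        gm$metric <- metric_; gm$family <- family_; gm$scale <- scale_
        means[[paste(metric_, family_, scale_)]] <- gm
      }
      fam <- do.call(rbind, fam_rows)
      fam$p_adjusted <- bh_adjust(fam$p_raw)
      fam$significant <- fam$p_adjusted < alpha
      tests[[paste(metric_, family_)]] <- fam
    }
  }
  tests <- do.call(rbind, tests); rownames(tests) <- NULL
  means <- do.call(rbind, means); rownames(means) <- NULL
  list(tests = tests, means = means)
}
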