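# Analysis set 2: smooth (additive) models of the degree of protection.
#
# For sites with upstream protection (or gaining protection), the rate of
# biodiversity change is related to the square-root-transformed PA cover
# proportion (or gain-rate proportion) with penalized additive models:
# thin-plate main-effect smooths for the PA term, upstream catchment size
# (log10 km2) and initial EQR, pure-interaction tensor smooths between the
# PA term and each of size and initial EQR, linear controls for latitude,
# longitude and time-series length, and a provider random intercept realized
# as an identity-penalized coefficient block. Fitting and smoothing-parameter
# selection (REML by default) go through mgcv; interaction significance uses
# a Wald-type test on the term's coefficient block.

#' Square-root proportion transform
#'
#' Converts percent cover (or a percent-per-year gain rate) to a proportion
#' and takes the square root, evening out the skewed distribution of cover
#' values prior to smoothing.
#'
#' @param x percent values (>= 0).
#' @return `sqrt(x / 100)`.
#' @export
sqrt_prop <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("negative input to sqrt_prop")
  sqrt(x / 100)
}

#' Thin-plate regression spline basis
#'
#' Low-rank penalized spline basis with a wiggliness penalty whose null
#' space is the linear polynomial, centered for identifiability (a thin
#' wrapper over the mgcv smooth constructor).
#'
#' @param x covariate values.
#' @param k basis dimension (default 10); reduced with a warning when `x`
#'   has fewer distinct values.
#' @return object of class `smooth_basis`: list with `values` (n x k basis
#'   matrix), `penalty` (list of penalty matrices), `k`, and the mgcv smooth
#'   object in `spec`.
#' @export
spline_basis <- function(x, k = 10) {
  ux <- length(unique(x))
  if (ux < 2L) stop("constant x: cannot build a spline basis")
  if (ux < k) {
    warning("reducing basis dimension from ", k, " to ", ux)
    k <- ux
  }
  dat <- data.frame(x = x)
  sm <- mgcv::smoothCon(mgcv::s(x, bs = "tp", k = k), data = dat,
                        absorb.cons = FALSE)[[1]]
  structure(list(values = sm$X, penalty = sm$S, k = ncol(sm$X), spec = sm),
            class = "smooth_basis")
}

#' Tensor-product basis from two marginal bases
#'
#' Row-wise Kronecker product of two marginal smooth bases with one penalty
#' per margin (`S1 (x) I` and `I (x) S2`). When fitted alongside main-effect
#' smooths the main-effect space of the tensor is removed so the term
#' represents the pure interaction (the model-fitting layer uses the
#' pure-interaction construction).
#'
#' @param b1,b2 `smooth_basis` objects sharing the observation count.
#' @return a `smooth_basis` for the tensor term.
#' @export
tensor_basis <- function(b1, b2) {
  if (nrow(b1$values) != nrow(b2$values)) stop("mismatched observation counts")
  X1 <- b1$values; X2 <- b2$values
  n <- nrow(X1)
  X <- matrix(0, n, ncol(X1) * ncol(X2))
  for (j in seq_len(ncol(X2)))
    X[, ((j - 1L) * ncol(X1) + 1L):(j * ncol(X1))] <- X1 * X2[, j]
  I1 <- diag(ncol(X1)); I2 <- diag(ncol(X2))
  pen <- c(lapply(b1$penalty, function(S) I2 %x% S),
           lapply(b2$penalty, function(S) S %x% I1))
  structure(list(values = X, penalty = pen, k = ncol(X), spec = NULL),
            class = "smooth_basis")
}

#' Penalized additive model of biodiversity change against protection
#'
#' Gaussian identity-link fit of `pct_per_year` on `s(pa) + s(size) +
#' s(eqr0) + ti(pa, size) + ti(pa, eqr0) + latitude + longitude + ts_length
#' + provider random intercept`, with smoothing parameters selected by REML
#' (default) or GCV.
#'
#' @param table data.frame with columns `pct_per_year`, `pa` (transformed
#'   cover or gain via [sqrt_prop()]), `size` (log10 upstream area in km2),
#'   `eqr0` (initial EQR), `latitude`, `longitude`, `ts_length`, `provider`.
#' @param k basis dimension for main-effect smooths.
#' @param k_tensor per-margin basis dimension for tensor interactions.
#' @param method `"REML"` or `"GCV.Cp"`.
#' @param min_n minimum subset size; smaller inputs are refused.
#' @return object of class `gamm_fit`: list with the mgcv fit in `model`,
#'   per-term `edf`, `smoothing_parameters`, `criterion`, `n`, and the data.
#' @export
fit_gamm <- function(table, k = 10, k_tensor = 5, method = c("REML", "GCV.Cp"),
                     min_n = 30) {
  method <- match.arg(method)
  req <- c("pct_per_year", "pa", "size", "eqr0", "latitude", "longitude",
           "ts_length", "provider")
  miss <- setdiff(req, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(table) < min_n)
    stop("subset too small for smooth modeling (n = ", nrow(table),
         " < ", min_n, ")")
  table$provider <- factor(table$provider)
  # basis dimensions never exceed what the covariates can support
  k_pa <- min(k, length(unique(table$pa)))
  k_sz <- min(k, length(unique(table$size)))
  k_e0 <- min(k, length(unique(table$eqr0)))
  n_ps <- nrow(unique(table[, c("pa", "size")]))
  n_pe <- nrow(unique(table[, c("pa", "eqr0")]))
  kt_s <- max(3, min(k_tensor, floor(sqrt(n_ps)), k_pa, k_sz))
  kt_e <- max(3, min(k_tensor, floor(sqrt(n_pe)), k_pa, k_e0))
  re_term <- if (nlevels(table$provider) >= 2L) " + s(provider, bs = 're')" else ""
  fml <- stats::as.formula(sprintf(
    paste0("pct_per_year ~ s(pa, bs = 'tp', k = %d) + s(size, bs = 'tp', k = %d) +",
           " s(eqr0, bs = 'tp', k = %d) + ti(pa, size, k = %d) + ti(pa, eqr0, k = %d) +",
           " latitude + longitude + ts_length%s"),
    k_pa, k_sz, k_e0, kt_s, kt_e, re_term))
  fit <- mgcv::gam(fml, data = table, method = method, family = stats::gaussian())
  edf <- term_edf(fit)
  structure(list(model = fit, edf = edf,
                 smoothing_parameters = fit$sp,
                 criterion = as.numeric(fit$gcv.ubre), method = method,
                 n = nrow(table), data = table),
            class = "gamm_fit")
}

term_edf <- function(fit) {
  vapply(fit$smooth, function(sm) {
    sum(fit$edf[sm$first.para:sm$last.para])
  }, numeric(1)) -> e
  names(e) <- vapply(fit$smooth, function(sm) sm$label, character(1))
  e
}

#' @export
print.gamm_fit <- function(x, ...) {
  cat(sprintf("<gamm_fit (%s): n %d, criterion %.4f>\n", x$method, x$n, x$criterion))
  print(round(x$edf, 3))
  invisible(x)
}

#' Wald-type test of a smooth term
#'
#' Tests whether a smooth term's coefficient block differs from zero using
#' the reference Wald construction for penalized smooths (a rank-truncated
#' quadratic form in the term's coefficients and their covariance, with the
#' reference degrees of freedom tied to the term's effective degrees of
#' freedom; Wood 2013, as reported by `summary.gam`). A naive full-rank
#' quadratic form referred to chi-squared on the rounded EDF is markedly
#' anti-conservative and is not used.
#'
#' @param fit a `gamm_fit`.
#' @param term smooth label, e.g. `"ti(pa,eqr0)"` or `"s(pa)"`.
#' @return one-row data.frame with `term`, `edf`, `statistic`, `df`
#'   (reference df, possibly fractional), `p_raw`.
#' @export
wald_smooth <- function(fit, term) {
  g <- fit$model
  labs <- vapply(g$smooth, function(sm) sm$label, character(1))
  i <- match(term, labs)
  if (is.na(i)) stop("term not in fit: ", term, " (have: ",
                     paste(labs, collapse = ", "), ")")
  sm <- g$smooth[[i]]
  idx <- sm$first.para:sm$last.para
  b <- stats::coef(g)[idx]
  edf <- sum(g$edf[idx])
  if (edf < 0.01 || sum(b^2) < 1e-24) {
    return(data.frame(term = term, edf = edf, statistic = 0, df = 1,
                      p_raw = 1, note = "zero-edf term", stringsAsFactors = FALSE))
  }
  st <- summary(g)$s.table
  row <- st[rownames(st) == term, , drop = FALSE]
  if (nrow(row) != 1L) stop("no summary row for term ", term)
  stat_col <- intersect(c("F", "Chi.sq"), colnames(row))[1]
  data.frame(term = term, edf = unname(row[1, "edf"]),
             statistic = unname(row[1, stat_col]),
             df = unname(row[1, "Ref.df"]),
             p_raw = unname(row[1, "p-value"]),
             note = "", stringsAsFactors = FALSE)
}

#' Conditional effect curves of the protection term
#'
#' Pointwise predictions and 95% Wald bands for the PA term across a grid of
#' transformed cover values, conditioned on example initial EQR values with
#' the remaining covariates at their sample means and the provider effect
#' excluded. Grids beyond the observed transformed-PA range are clipped with
#' a warning.
#'
#' @param fit a `gamm_fit`.
#' @param eqr0_values conditioning initial EQR values.
#' @param pa_grid grid of transformed PA values (default: 50 points spanning
#'   the observed range).
#' @param size_fixed conditioning catchment size (log10 km2); defaults to the
#'   sample mean.
#' @return data.frame with `eqr0`, `pa`, `prediction`, `ci_low`, `ci_high`.
#' @export
predict_pa_effect <- function(fit, eqr0_values = c(0.2, 0.4, 0.6, 0.8),
                              pa_grid = NULL, size_fixed = NULL) {
  dat <- fit$data
  rng <- range(dat$pa)
  if (is.null(pa_grid)) {
    pa_grid <- seq(rng[1], rng[2], length.out = 50)
  } else if (any(pa_grid < rng[1] - 1e-9 | pa_grid > rng[2] + 1e-9)) {
    warning("pa_grid clipped to the observed transformed-PA range")
    pa_grid <- pmin(pmax(pa_grid, rng[1]), rng[2])
  }
  if (is.null(size_fixed)) size_fixed <- mean(dat$size)
  out <- list()
  for (e0 in eqr0_values) {
    nd <- data.frame(pa = pa_grid, size = size_fixed, eqr0 = e0,
                     latitude = mean(dat$latitude),
                     longitude = mean(dat$longitude),
                     ts_length = mean(dat$ts_length),
                     provider = factor(levels(factor(dat$provider))[1],
                                       levels = levels(factor(dat$provider))))
    labs <- vapply(fit$model$smooth, function(sm) sm$label, character(1))
    pr <- mgcv::predict.gam(fit$model, newdata = nd, se.fit = TRUE,
                            exclude = intersect("s(provider)", labs))
    out[[length(out) + 1L]] <- data.frame(
      eqr0 = e0, pa = pa_grid, prediction = as.numeric(pr$fit),
      ci_low = as.numeric(pr$fit - 1.96 * pr$se.fit),
      ci_high = as.numeric(pr$fit + 1.96 * pr$se.fit))
  }
  do.call(rbind, out)
}

#' Smooth models across the full metric x scale grid
#'
#' Runs analysis set 2: for each metric and scale, fits the cover model on
#' protected sites (PA term = transformed mean cover) and the gain model on
#' gaining sites (PA term = transformed gain rate), Wald-tests the tensor
#' interactions and the PA main effect, adjusts p-values within each metric
#' x family x term across scales, and extracts conditional effect curves.
#'
#' @inheritParams run_group_models
#' @param size_km2 data.frame with `site_id`, `size_km2` (full upstream area).
#' @param min_n minimum subset size per model (models on smaller subsets are
#'   skipped with a message).
#' @return list with `tests` (term-level results), `curves` (effect curves
#'   for the PA x initial-EQR interaction models), and `skipped`.
#' @export
run_smooth_models <- function(trends, cover, covariates, size_km2,
                              scales = c("1km", "10km", "100km", "full"),
                              alpha = 0.05, min_n = 30) {
  tests <- list(); curves <- list(); skipped <- list()
  eqr0 <- unique(trends[, c("site_id", "initial_eqr")])
  for (metric_ in unique(trends$metric)) {
    tr <- trends[trends$metric == metric_, c("site_id", "pct_per_year")]
    for (family_ in c("cover", "gain")) {
      fam_rows <- list()
      for (scale_ in scales) {
        cv <- cover[cover$scale == scale_, ]
        cv <- if (family_ == "cover") cv[cv$protected, ] else cv[cv$gained, ]
        tab <- Reduce(function(a, b) merge(a, b, by = "site_id"),
                      list(tr, cv[, c("site_id", "mean_pct", "gain_rate")],
                           covariates, size_km2, eqr0))
        if (nrow(tab) < min_n) {
          skipped[[paste(metric_, family_, scale_)]] <-
            data.frame(metric = metric_, family = family_, scale = scale_,
                       n = nrow(tab))
          next
        }
        tab$pa <- sqrt_prop(if (family_ == "cover") tab$mean_pct else tab$gain_rate)
        tab$size <- log10(pmax(tab$size_km2, 1e-3))
        tab$eqr0 <- tab$initial_eqr
        fit <- fit_gamm(tab, min_n = min_n)
        for (term in c("ti(pa,eqr0)", "ti(pa,size)", "s(pa)")) {
          w <- wald_smooth(fit, term)
          w$metric <- metric_; w$family <- family_; w$scale <- scale_
          w$n <- fit$n
          fam_rows[[paste(scale_, term)]] <- w
        }
        cu <- predict_pa_effect(fit)
        cu$metric <- metric_; cu$family <- family_; cu$scale <- scale_
        curves[[paste(metric_, family_, scale_)]] <- cu
      }
      if (!length(fam_rows)) next
      fam <- do.call(rbind, fam_rows)
      # BH within metric x family x term across scales
      for (term in unique(fam$term)) {
        sel <- fam$term == term
        fam$p_adjusted[sel] <- bh_adjust(fam$p_raw[sel])
      }
      fam$significant <- fam$p_adjusted < alpha
      tests[[paste(metric_, family_)]] <- fam
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else NULL
  curves <- if (length(curves)) do.call(rbind, curves) else NULL
  skipped <- if (length(skipped)) do.call(rbind, skipped) else NULL
  if (!is.null(tests)) rownames(tests) <- NULL
  if (!is.null(curves)) rownames(curves) <- NULL
  list(tests = tests, curves = curves, skipped = skipped)
}
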