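#' Range scaling to the unit interval
#'
#' `(x - min) / (max - min)`. Intended for joint visualisation of series on
#' different scales; modelling is done on unscaled data. A constant series
#' maps to all zeros and carries the attribute `constant = TRUE`.
#'
#' @param x Numeric vector (length >= 1, no NAs).
#' @return Vector in \[0, 1\], same length as `x`.
#' @export
range_scale <- function(x) {
  if (length(x) == 0) stop("empty series")
  if (anyNA(x)) stop("missing values")
  r <- range(x)
  if (r[1] == r[2]) {
    out <- rep(0, length(x))
    attr(out, "constant") <- TRUE
    return(out)
  }
  (x - r[1]) / (r[2] - r[1])
}

#' Spearman screen of descriptor-diversity pairs
#'
#' Rank correlation (average ranks for ties) between every hydrological
#' descriptor and every diversity index, within each antecedent window.
#' Exploratory: no p-values are attached.
#'
#' @param descriptors Output of [descriptor_table()].
#' @param diversity Output of [diversity_table()], one row per event in the
#'   same event order as the descriptor table.
#' @param indices Names of the diversity columns to screen.
#' @return Long data frame `window`, `descriptor`, `index`, `rho`; `rho` is
#'   NA (with no error) when either series is constant.
#' @export
spearman_screen <- function(descriptors, diversity,
                            indices = c("H", "E", "D", "Rao", "FAD1", "wFDc")) {
  desc_cols <- c("q_mean", "rb", "n_rise", "sum_rise", "sum_fall", "sum_abs")
  windows <- sort(unique(descriptors$window))
  out <- list()
  for (w in windows) {
    dw <- descriptors[descriptors$window == w, ]
    if (nrow(dw) != nrow(diversity)) {
      stop("descriptor and diversity tables disagree on event count")
    }
    if (nrow(dw) < 3) stop("need at least 3 paired observations")
    for (dc in desc_cols) {
      for (ix in indices) {
        x <- dw[[dc]]; y <- diversity[[ix]]
        rho <- if (stats::sd(x) == 0 || stats::sd(y) == 0 || anyNA(y)) {
          NA_real_
        } else {
          stats::cor(x, y, method = "spearman")
        }
        out[[length(out) + 1L]] <- data.frame(window = w, descriptor = dc,
                                              index = ix, rho = rho)
      }
    }
  }
  do.call(rbind, out)
}

#' Fit one penalised additive model of a diversity index on flow descriptors
#'
#' Fits `y ~ s(x1, k) + ... + s(x6, k)` with thin-plate smooths of basis
#' dimension `k` (default 3, so at most 2 effective df per term) over the
#' six antecedent descriptors of one window. For Gaussian responses an
#' AR(1) residual correlation over the event index is attempted first
#' (additive mixed model); if that fit fails or does not converge, the
#' fallback is a standard GAM with an additional smooth of the event index,
#' fitted with double-penalty shrinkage (`select = TRUE`, so a smooth can
#' be penalised away entirely). Beta responses (for proportion-bounded
#' indices) always use the fallback form with a logit-link beta family and
#' REML smoothness selection, after the boundary squeeze
#' `y' = (y (n - 1) + 0.5) / n`. Descriptors with fewer than `k` distinct
#' values enter as linear terms.
#'
#' @param y Response vector over events (a diversity index).
#' @param X Data frame of the six descriptors at one window (columns
#'   `q_mean`, `rb`, `n_rise`, `sum_rise`, `sum_fall`, `sum_abs`).
#' @param event_index Integer index of temporal order (default `1:n`).
#' @param family `"gaussian"` or `"beta"`.
#' @param k Basis dimension of each smooth.
#' @param ar1 Attempt the AR(1) structure first (Gaussian only)?
#' @param method Smoothness-selection criterion for the fallback Gaussian
#'   GAM: `"REML"` (default; more stable for the small samples typical
#'   here) or `"GCV.Cp"`. Beta fits always use REML.
#' @param drop Optional descriptor name to exclude (used by the drop-one
#'   importance stage).
#' @return An object of class `"flow_gam"`: a list with the fitted mgcv
#'   model (`model`), `fitted`, `residuals` (response scale), `r2_adj`,
#'   `rmse`, `shapiro_w`, `shapiro_p`, `normal_resid`, `edf_total`, and the
#'   flags `ar1_attempted`, `ar1_converged`, `fallback_event_smooth`.
#' @examples
#' \donttest{
#' st <- synth_memory_study(memory_scenario(n_events = 15), seed = 2)
#' X <- st$descriptors[st$descriptors$window == 9,
#'                     c("q_mean", "rb", "n_rise", "sum_rise", "sum_fall", "sum_abs")]
#' fit <- fit_flow_gam(st$diversity$H, X)
#' fit$r2_adj
#' }
#' @export
fit_flow_gam <- function(y, X, event_index = seq_along(y),
                         family = c("gaussian", "beta"), k = 3,
                         ar1 = TRUE, method = c("REML", "GCV.Cp"),
                         drop = NULL) {
  family <- match.arg(family)
  method <- match.arg(method)
  stopifnot(is.data.frame(X), nrow(X) == length(y),
            length(event_index) == length(y))
  n <- length(y)
  if (n < 10) stop("need at least 10 events to fit the additive model")
  if (anyNA(y) || anyNA(X)) stop("missing values in response or descriptors")

  preds <- names(X)
  if (!is.null(drop)) {
    if (!drop %in% preds) stop("unknown descriptor: ", drop)
    preds <- setdiff(preds, drop)
  }

  y_fit <- y
  if (family == "beta") {
    if (any(y < 0) || any(y > 1)) stop("beta family needs y in [0, 1]")
    y_fit <- (y * (n - 1) + 0.5) / n  # squeeze off the boundary
  }

  dat <- X
  dat$.y <- y_fit
  dat$.ev <- as.numeric(event_index)

  term_for <- function(v) {
    if (length(unique(dat[[v]])) >= k) sprintf("s(%s, k = %d)", v, k) else v
  }
  rhs <- paste(vapply(preds, term_for, character(1)), collapse = " + ")
  f_base <- stats::as.formula(paste(".y ~", rhs))
  f_fall <- stats::as.formula(paste(".y ~", rhs, "+ s(.ev, k =", k, ")"))

  ar1_attempted <- FALSE
  ar1_converged <- FALSE
  model <- NULL
  if (stats::var(y_fit) == 0) {
    # a constant response has nothing to model; REML cannot profile its
    # zero-variance likelihood, so fit the intercept alone
    f_base <- f_fall <- stats::as.formula(".y ~ 1")
    ar1 <- FALSE
    if (family == "gaussian") method <- "GCV.Cp"  # nothing for REML to profile
  }
  if (family == "gaussian" && ar1) {
    ar1_attempted <- TRUE
    g <- tryCatch(
      suppressWarnings(mgcv::gamm(f_base, data = dat,
                                  correlation = nlme::corAR1(form = ~.ev))),
      error = function(e) NULL)
    if (!is.null(g) && all(is.finite(stats::fitted(g$gam)))) {
      ar1_converged <- TRUE
      model <- g$gam
    }
  }
  fallback <- !ar1_converged
  if (fallback) {
    fam <- if (family == "beta") mgcv::betar(link = "logit") else stats::gaussian()
    if (family == "beta") method <- "REML"  # extended families need (RE)ML
    # double-penalty shrinkage: uninformative smooths can vanish entirely,
    # which keeps drop-one importance from crediting them by refit noise
    model <- mgcv::gam(f_fall, data = dat, family = fam, method = method,
                       select = TRUE)
  }

  fit_vals <- as.numeric(stats::fitted(model))
  resid_resp <- y_fit - fit_vals
  met <- model_metrics_internal(y_fit, fit_vals, model)
  sw <- residual_normality_values(resid_resp)

  structure(list(
    family = family, k = k, method = method, predictors = preds,
    dropped = drop,
    model = model, y = y_fit, fitted = fit_vals, residuals = resid_resp,
    r2_adj = met$r2_adj, r2 = met$r2, rmse = met$rmse,
    edf_total = met$p_eff, df_ok = met$df_ok,
    shapiro_w = sw$w, shapiro_p = sw$p,
    normal_resid = isTRUE(sw$p >= 0.05),
    ar1_attempted = ar1_attempted, ar1_converged = ar1_converged,
    fallback_event_smooth = fallback
  ), class = "flow_gam")
}

#' @export
print.flow_gam <- function(x, ...) {
  cat("Additive flow-diversity model (", x$family, " family)\n", sep = "")
  cat("  terms:", paste(x$predictors, collapse = ", "),
      if (x$fallback_event_smooth) "+ event smooth", "\n")
  cat(sprintf("  R2_adj = %.3f, RMSE = %.4g, Shapiro p = %.3f%s\n",
              x$r2_adj, x$rmse, x$shapiro_p,
              if (x$ar1_converged) " [AR(1)]" else ""))
  invisible(x)
}

#' Explanatory power and prediction error of a fitted model
#'
#' `R2 = 1 - SSE/SST` on the response scale, adjusted as
#' `R2_adj = 1 - (1 - R2) (n - 1) / (n - p_eff - 1)` with `p_eff` the total
#' effective degrees of freedom of the model terms (summed smooth edf plus
#' parametric terms, excluding the intercept), and `RMSE = sqrt(SSE / n)`.
#'
#' @param fit A `"flow_gam"` object.
#' @return Named list with `r2`, `r2_adj`, `rmse`, `p_eff` and `df_ok`
#'   (FALSE when the adjustment denominator is non-positive, making the
#'   adjusted value unreliable).
#' @export
model_metrics <- function(fit) {
  stopifnot(inherits(fit, "flow_gam"))
  model_metrics_internal(fit$y, fit$fitted, fit$model)
}

model_metrics_internal <- function(y, fitted_vals, model) {
  n <- length(y)
  sse <- sum((y - fitted_vals)^2)
  sst <- sum((y - mean(y))^2)
  # a constant response carries no explainable variance: R2 = 0 by
  # convention, so the adjustment drives R2_adj below zero
  r2 <- if (sst > 0) 1 - sse / sst else 0
  sm <- summary(model)
  p_eff <- sum(sm$edf) + max(0, length(stats::coef(model)[
    !grepl("^s\\(", names(stats::coef(model)))]) - 1L)
  denom <- n - p_eff - 1
  df_ok <- denom > 0
  r2_adj <- if (df_ok && !is.na(r2)) 1 - (1 - r2) * (n - 1) / denom else NA_real_
  list(r2 = r2, r2_adj = r2_adj, rmse = sqrt(sse / n), p_eff = p_eff,
       df_ok = df_ok)
}

#' Shapiro-Wilk residual diagnostic
#'
#' Shapiro-Wilk test of the response-scale residuals, used as a general
#' diagnostic of residual behaviour (a strict distributional test only for
#' Gaussian fits). `p >= 0.05` is read as approximately normal residuals.
#'
#' @param fit A `"flow_gam"` object.
#' @return Named list with `w`, `p` and `normal` (`p >= 0.05`).
#' @export
residual_normality <- function(fit) {
  stopifnot(inherits(fit, "flow_gam"))
  v <- residual_normality_values(fit$residuals)
  c(v, list(normal = isTRUE(v$p >= 0.05)))
}

residual_normality_values <- function(resid) {
  if (length(resid) < 3) stop("need at least 3 residuals")
  if (stats::sd(resid) == 0) {
    return(list(w = NA_real_, p = NA_real_))
  }
  sw <- stats::shapiro.test(resid)
  list(w = unname(sw$statistic), p = sw$p.value)
}
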