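#' Fit a random-intercept mixed model to well-level responses
#'
#' Fits one of the two model families used for flux responses: a Gaussian
#' linear mixed model on the log10-transformed response
#' (`family = "gaussian_log10"`) or a gamma generalized linear mixed model
#' with inverse link (`family = "gamma_inverse"`, Laplace approximation by
#' default). The grouping factor (experiment) enters as a random intercept,
#' which is what justifies treating each well as an observational unit. Both
#' families are fit by maximum likelihood (never REML) so that
#' likelihood-ratio tests between nested fixed-effect structures are valid.
#'
#' @param data A data frame of well-level responses.
#' @param response Name of the response column; all values must be positive.
#' @param fixed Character vector of fixed-effect terms, e.g.
#'   `c("condition", "treatment", "condition:treatment")`. Use `character(0)`
#'   or `"1"` for an intercept-only model.
#' @param random Name of the grouping column (default `"experiment_id"`);
#'   must have at least 2 levels.
#' @param family `"gaussian_log10"` or `"gamma_inverse"`.
#' @param nagq Number of adaptive Gauss-Hermite quadrature points for the
#'   gamma family; 1 (default) is the Laplace approximation.
#' @param alpha Significance level carried in the fit spec (default 0.05).
#'
#' @return A `flux_mm` object wrapping the lme4 fit, with [tidy()] and
#'   [glance()] methods.
#' @export
fit_mixed <- function(data, response, fixed,
                      random = "experiment_id",
                      family = c("gaussian_log10", "gamma_inverse"),
                      nagq = 1L, alpha = 0.05) {
  family <- match.arg(family)
  data <- as.data.frame(data)
  if (!response %in% names(data)) {
    usage_error(paste0("Response column not found: ", response))
  }
  if (!random %in% names(data)) {
    usage_error(paste0("Grouping column not found: ", random))
  }
  y <- data[[response]]
  if (anyNA(y)) {
    data <- data[!is.na(y), , drop = FALSE]
    y <- data[[response]]
  }
  if (any(y <= 0)) {
    validation_error(paste0(
      "All responses must be positive for both model families; ",
      sum(y <= 0), " non-positive value(s) found. Apply the exclusion ",
      "rules (see response_percent()) before fitting."
    ))
  }
  if (length(unique(data[[random]])) < 2) {
    validation_error("The random grouping factor needs at least 2 levels.")
  }
  data[[random]] <- factor(data[[random]])
  fixed <- fixed[fixed != "1"]
  fx <- if (length(fixed) == 0) "1" else paste(fixed, collapse = " + ")

  if (family == "gaussian_log10") {
    data$.log10_response <- log10(data[[response]])
    form <- as.formula(paste0(".log10_response ~ ", fx, " + (1 | ",
                              random, ")"))
    fit <- lme4::lmer(form, data = data, REML = FALSE)
    method <- "ML"
  } else {
    form <- as.formula(paste0(response, " ~ ", fx, " + (1 | ", random, ")"))
    fit <- suppressWarnings(
      lme4::glmer(form, data = data,
                  family = stats::Gamma(link = "inverse"), nAGQ = nagq)
    )
    method <- if (nagq <= 1) "Laplace" else paste0("AGQ-", nagq)
  }

  msgs <- fit@optinfo$conv$lme4$messages
  singular <- lme4::isSingular(fit, tol = 1e-5)
  converged <- isTRUE(all(fit@optinfo$conv$opt == 0)) &&
    (is.null(msgs) || all(grepl("boundary", msgs, ignore.case = TRUE)))
  if (singular) {
    rlang::warn("Random-intercept variance estimated at (or near) zero.",
                class = "fluxcap_singular_fit")
  }

  vc <- as.data.frame(lme4::VarCorr(fit))
  ri_var <- vc$vcov[vc$grp == random][1]
  resid_disp <- if (family == "gaussian_log10") stats::sigma(fit)^2
                else stats::sigma(fit)^2

  structure(
    list(
      model = fit, data = data, response = response, fixed = fixed,
      random = random, family = family, method = method, alpha = alpha,
      coefficients = lme4::fixef(fit),
      random_intercept_variance = ri_var,
      residual_dispersion = resid_disp,
      log_likelihood = as.numeric(logLik(fit)),
      n_obs = nrow(data),
      n_groups = length(unique(data[[random]])),
      converged = converged, singular = singular
    ),
    class = "flux_mm"
  )
}

#' @rdname fit_mixed
#' @param ... Passed to [fit_mixed()].
#' @export
fit_lmm_log10 <- function(data, response, fixed, ...) {
  fit_mixed(data, response, fixed, family = "gaussian_log10", ...)
}

#' @rdname fit_mixed
#' @export
fit_gamma_glmm <- function(data, response, fixed, ...) {
  fit_mixed(data, response, fixed, family = "gamma_inverse", ...)
}

#' @export
print.flux_mm <- function(x, ...) {
  cat("<flux_mm> ", x$family, " (", x$method, ")\n", sep = "")
  cat("  ", x$response, " ~ ",
      if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "1",
      " + (1 | ", x$random, ")\n", sep = "")
  cat("  n =", x$n_obs, "wells in", x$n_groups, "experiments;",
      "logLik =", format(x$log_likelihood, digits = 6), "\n")
  cat("  random-intercept variance =",
      format(x$random_intercept_variance, digits = 4),
      if (x$singular) "(singular)" else "", "\n")
  invisible(x)
}

#' @export
tidy.flux_mm <- function(x, ...) {
  cf <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std.error = cf[, "Std. Error"],
    statistic = cf[, 3]
  )
}

#' @export
glance.flux_mm <- function(x, ...) {
  tibble::tibble(
    family = x$family, method = x$method,
    logLik = x$log_likelihood,
    random_intercept_variance = x$random_intercept_variance,
    residual_dispersion = x$residual_dispersion,
    n_obs = x$n_obs, n_groups = x$n_groups,
    converged = x$converged, singular = x$singular
  )
}

n_fixed_params <- function(fit) length(fit$coefficients)

#' Likelihood-ratio test between nested mixed-model fits
#'
#' Twice the log-likelihood difference between a full and a nested reduced
#' fit (clamped at zero), referred to a chi-square distribution with degrees
#' of freedom equal to the difference in fixed-effect parameter count. Both
#' fits must be maximum-likelihood fits of the same family on the same data.
#'
#' @param full,reduced `flux_mm` fits; `reduced`'s fixed terms must nest in
#'   `full`'s.
#'
#' @return A one-row tibble: `term`, `chi2`, `df`, `p_value`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "flux_mm"), inherits(reduced, "flux_mm"))
  if (full$family != reduced$family) {
    usage_error("LRT requires the same model family in both fits.")
  }
  if (full$n_obs != reduced$n_obs || full$response != reduced$response) {
    usage_error("LRT requires the same data and response in both fits.")
  }
  if (!all(reduced$fixed %in% full$fixed)) {
    usage_error("The reduced model's fixed terms must nest in the full model's.")
  }
  df <- n_fixed_params(full) - n_fixed_params(reduced)
  if (df < 0) usage_error("The reduced model has more parameters than the full model.")
  chi2 <- max(0, 2 * (full$log_likelihood - reduced$log_likelihood))
  term <- setdiff(full$fixed, reduced$fixed)
  tibble::tibble(
    term = if (length(term)) paste(term, collapse = " + ") else "(none)",
    chi2 = chi2,
    df = df,
    p_value = if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE)
  )
}

#' Likelihood-ratio test for a single fixed-effect term
#'
#' Convenience wrapper: fits the full model and the model without `term`,
#' then calls [lrt()].
#'
#' @inheritParams fit_mixed
#' @param term The fixed-effect term to test (must be in `fixed`).
#' @return A one-row tibble as from [lrt()].
#' @export
lrt_term <- function(data, response, fixed, term,
                     random = "experiment_id",
                     family = c("gaussian_log10", "gamma_inverse"), ...) {
  family <- match.arg(family)
  if (!term %in% fixed) usage_error("`term` must be one of the fixed terms.")
  full <- fit_mixed(data, response, fixed, random, family, ...)
  reduced <- fit_mixed(data, response, setdiff(fixed, term), random,
                       family, ...)
  lrt(full, reduced)
}

#' Choose between the Gaussian-log10 and gamma-inverse families
#'
#' Fits both candidate families and keeps the one whose deviance residuals
#' look more Gaussian, using the Shapiro-Wilk W statistic as the concrete
#' criterion (higher is better). Deviance residuals are the residual type
#' that is approximately normal when a gamma model is correctly specified
#' (Pearson residuals of a gamma fit retain the response's skewness, which
#' would bias the choice toward the Gaussian family). Ties go to the
#' Gaussian-log10 family. Both fits and both statistics are returned so the
#' decision is auditable.
#'
#' @inheritParams fit_mixed
#'
#' @return A list of class `flux_family_choice`: `family` (the winner),
#'   `statistics` (named W values), `fits` (both `flux_mm` objects).
#' @export
choose_family <- function(data, response, fixed,
                          random = "experiment_id", ...) {
  fits <- list(
    gaussian_log10 = try(fit_mixed(data, response, fixed, random,
                                   "gaussian_log10", ...), silent = TRUE),
    gamma_inverse = try(fit_mixed(data, response, fixed, random,
                                  "gamma_inverse", ...), silent = TRUE)
  )
  ok <- !vapply(fits, inherits, logical(1), "try-error")
  if (!any(ok)) usage_error("Neither candidate family could be fitted.")
  w <- vapply(names(fits), function(nm) {
    if (!ok[[nm]]) return(-Inf)
    r <- residuals(fits[[nm]]$model, type = "deviance")
    if (length(r) < 3) return(-Inf)
    if (length(r) > 5000) r <- r[seq_len(5000)]
    suppressWarnings(shapiro.test(r)$statistic)
  }, numeric(1))
  names(w) <- names(fits)
  # >= : deterministic tie-break to the Gaussian family
  family <- if (w[["gaussian_log10"]] >= w[["gamma_inverse"]])
    "gaussian_log10" else "gamma_inverse"
  structure(list(family = family, statistics = w, fits = fits),
            class = "flux_family_choice")
}

#' @export
print.flux_family_choice <- function(x, ...) {
  cat("<flux_family_choice>", x$family, "\n")
  cat("  Shapiro-Wilk W on deviance residuals:\n")
  for (nm in names(x$statistics)) {
    cat("   ", nm, "=", format(x$statistics[[nm]], digits = 5), "\n")
  }
  invisible(x)
}

#' Pairwise marginal-means contrasts for a fixed factor
#'
#' Estimated marginal means on the link scale (log10 response for the
#' Gaussian family, inverse-mean for the gamma family), averaged over the
#' other fixed factors with equal weights, with all pairwise differences and
#' a Tukey-style multiplicity adjustment by default. Degrees of freedom:
#' Satterthwaite for the Gaussian LMM, asymptotic z for the gamma GLMM.
#'
#' @param fit A `flux_mm` object.
#' @param factor Name of a fixed factor in the fit.
#' @param adjust Multiplicity adjustment (`"tukey"` or `"none"`).
#'
#' @return A tibble with one row per level pair: `contrast`,
#'   `estimate_link_scale`, `std_error`, `df`, `statistic`, `p_adjusted`,
#'   `adjustment`. A single-level factor yields zero rows.
#' @export
emm_contrasts <- function(fit, factor, adjust = c("tukey", "none")) {
  stopifnot(inherits(fit, "flux_mm"))
  adjust <- match.arg(adjust)
  if (!factor %in% all.vars(as.formula(paste(
        "~", paste(c(fit$fixed, "1"), collapse = "+"))))) {
    usage_error(paste0("`", factor, "` is not a fixed factor of the fit."))
  }
  if (length(unique(fit$data[[factor]])) < 2) {
    return(tibble::tibble(
      contrast = character(0), estimate_link_scale = numeric(0),
      std_error = numeric(0), df = numeric(0), statistic = numeric(0),
      p_adjusted = numeric(0), adjustment = character(0)
    ))
  }
  lmer_df <- if (fit$family == "gaussian_log10" &&
                 requireNamespace("lmerTest", quietly = TRUE))
    "satterthwaite" else "asymptotic"
  emm <- emmeans::emmeans(fit$model, specs = factor, data = fit$data,
                          lmer.df = lmer_df)
  prs <- summary(emmeans::contrast(emm, method = "pairwise",
                                   adjust = adjust))
  stat_col <- intersect(c("t.ratio", "z.ratio"), names(prs))[1]
  tibble::tibble(
    contrast = as.character(prs$contrast),
    estimate_link_scale = prs$estimate,
    std_error = prs$SE,
    df = if ("df" %in% names(prs)) prs$df else Inf,
    statistic = prs[[stat_col]],
    p_adjusted = prs$p.value,
    adjustment = adjust
  )
}

#' Group summaries: mean, SD and 95% CI of the mean
#'
#' Cohort-style summary rows per group: mean, standard deviation (n-1
#' denominator), the half-width of the 95% t confidence interval of the
#' mean over wells, the number of wells, and `N`, the number of distinct
#' experiments. A half-width computed over experiment means
#' (`ci_experiment`) is also emitted, since well-level and experiment-level
#' precision can differ substantially in hierarchical data. Groups with a
#' single observation report `sd = 0` and are flagged.
#'
#' @param data A data frame of well-level values.
#' @param response Name of the value column.
#' @param ... Grouping columns (tidy-select style, passed to
#'   [dplyr::group_by()] via `dplyr::across`).
#' @param experiment Name of the experiment column (default
#'   `"experiment_id"`).
#'
#' @return A tibble with one row per group: the grouping columns, `N`,
#'   `n_wells`, `mean`, `sd`, `ci`, `ci_experiment`, `sd_undefined`.
#' @export
summarize_groups <- function(data, response, ...,
                             experiment = "experiment_id") {
  data <- tibble::as_tibble(data)
  vals <- data[[response]]
  data <- data[!is.na(vals), , drop = FALSE]
  grouped <- data |>
    dplyr::group_by(dplyr::across(c(...)))
  if (nrow(data) == 0) {
    rlang::warn("No non-missing observations; empty summary returned.")
  }
  ci_half <- function(x) {
    n <- length(x)
    if (n < 2) return(0)
    qt(0.975, n - 1) * sd(x) / sqrt(n)
  }
  grouped |>
    dplyr::summarise(
      N = dplyr::n_distinct(.data[[experiment]]),
      n_wells = dplyr::n(),
      mean = mean(.data[[response]]),
      sd = ifelse(dplyr::n() < 2, 0, sd(.data[[response]])),
      ci = ci_half(.data[[response]]),
      ci_experiment = ci_half(tapply(.data[[response]],
                                     .data[[experiment]], mean)),
      sd_undefined = dplyr::n() < 2,
      .groups = "drop"
    )
}
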