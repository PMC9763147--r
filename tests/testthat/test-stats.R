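# balanced two-group design: fixed effects of the ML fit equal the OLS
# (closed-form) solution for balanced data
sim_balanced <- function(seed = 101, n_exp = 3, n_wells = 4, effect = 0.15,
                         sd_exp = 0.3, sd_res = 0.2, mean_log10 = 2) {
  set.seed(seed)
  d <- expand.grid(experiment_id = sprintf("E%d", seq_len(n_exp)),
                   condition = c("non_capacitating", "capacitating"),
                   w = seq_len(n_wells), stringsAsFactors = FALSE)
  u <- rnorm(n_exp, 0, sd_exp)
  names(u) <- sprintf("E%d", seq_len(n_exp))
  d$response <- 10^(mean_log10 + effect * (d$condition == "capacitating") +
                      u[d$experiment_id] + rnorm(nrow(d), 0, sd_res))
  d
}

test_that("LMM fixed effects on balanced designs match the closed form", {
  d <- sim_balanced()
  fit <- fit_lmm_log10(d, "response", "condition")
  ref_level <- sort(unique(d$condition))[1] # "capacitating" alphabetically
  m_ref <- mean(log10(d$response[d$condition == ref_level]))
  m_other <- mean(log10(d$response[d$condition != ref_level]))
  expect_equal(unname(fit$coefficients[1]), m_ref, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[2]), m_other - m_ref,
               tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$n_groups, 3)
})

test_that("LMM inference is equivariant to response rescaling", {
  d <- sim_balanced(seed = 7)
  f1 <- fit_lmm_log10(d, "response", "condition")
  r1 <- fit_lmm_log10(d, "response", character(0))
  d2 <- d
  d2$response <- d2$response * 10
  f2 <- fit_lmm_log10(d2, "response", "condition")
  r2 <- fit_lmm_log10(d2, "response", character(0))
  expect_equal(unname(f2$coefficients[1]),
               unname(f1$coefficients[1]) + 1, tolerance = 1e-6)
  expect_equal(unname(f2$coefficients[2]), unname(f1$coefficients[2]),
               tolerance = 1e-6)
  expect_equal(lrt(f2, r2)$chi2, lrt(f1, r1)$chi2, tolerance = 1e-6)
})

test_that("zero between-experiment variability drives the random variance to zero", {
  d <- sim_balanced(seed = 13, sd_exp = 0, n_exp = 6, n_wells = 10)
  fit <- suppressWarnings(fit_lmm_log10(d, "response", "condition"))
  expect_lt(fit$random_intercept_variance,
            0.02 * fit$residual_dispersion)
})

test_that("responses must be positive and grouped in >= 2 experiments", {
  d <- sim_balanced()
  d$response[1] <- -1
  expect_error(fit_lmm_log10(d, "response", "condition"),
               class = "fluxcap_validation_error")
  d1 <- sim_balanced(n_exp = 1)
  expect_error(fit_lmm_log10(d1, "response", "condition"),
               class = "fluxcap_validation_error")
})

test_that("gamma GLMM at the no-random-effect boundary matches the gamma GLM", {
  set.seed(1)
  d <- expand.grid(experiment_id = sprintf("E%d", 1:6),
                   condition = c("a", "b"), w = 1:10,
                   stringsAsFactors = FALSE)
  mu <- 1 / (0.01 + 0.003 * (d$condition == "b"))
  d$response <- rgamma(nrow(d), shape = 20, rate = 20 / mu)
  fit <- suppressWarnings(fit_gamma_glmm(d, "response", "condition"))
  ref <- glm(response ~ condition, data = d,
             family = stats::Gamma(link = "inverse"))
  expect_true(fit$singular)
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
})

test_that("null-model gamma intercept is the inverse of the mean", {
  set.seed(5)
  d <- data.frame(
    experiment_id = rep(sprintf("E%d", 1:4), each = 15),
    response = rgamma(60, shape = 30, rate = 30 / 50)
  )
  fit <- suppressWarnings(fit_gamma_glmm(d, "response", character(0)))
  expect_equal(unname(fit$coefficients[1]), 1 / mean(d$response),
               tolerance = 0.02)
})

test_that("gamma GLMM recovers simulated fixed effects", {
  set.seed(99)
  b0 <- 0.010; b1 <- 0.004; shape <- 15
  d <- expand.grid(experiment_id = sprintf("E%d", 1:8),
                   condition = c("a", "b"), w = 1:12,
                   stringsAsFactors = FALSE)
  u <- rnorm(8, 0, 0.0015)
  names(u) <- sprintf("E%d", 1:8)
  eta <- b0 + b1 * (d$condition == "b") + u[d$experiment_id]
  d$response <- rgamma(nrow(d), shape = shape, rate = shape * eta)
  fit <- suppressWarnings(fit_gamma_glmm(d, "response", "condition"))
  td <- tidy(fit)
  expect_lt(abs(td$estimate[1] - b0), 3 * td$std.error[1])
  expect_lt(abs(td$estimate[2] - b1), 3 * td$std.error[2])
})

test_that("the likelihood-ratio test is exact on degenerate nestings", {
  d <- sim_balanced(seed = 3)
  f <- fit_lmm_log10(d, "response", "condition")
  self <- lrt(f, f)
  expect_equal(self$chi2, 0)
  expect_equal(self$df, 0)
  expect_equal(self$p_value, 1)

  r <- fit_lmm_log10(d, "response", character(0))
  out <- lrt(f, r)
  expect_equal(out$df, 1)
  expect_gte(out$chi2, 0)
  expect_identical(out$term, "condition")

  g <- suppressWarnings(fit_gamma_glmm(d, "response", "condition"))
  expect_error(lrt(g, r), class = "fluxcap_usage_error")
})

test_that("stronger effects and larger samples shrink the LRT p-value", {
  p_at <- function(n_wells, effect) {
    d <- sim_balanced(seed = 17, n_exp = 4, n_wells = n_wells,
                      effect = effect, sd_exp = 0.1)
    suppressWarnings(
      lrt_term(d, "response", "condition", "condition",
               family = "gaussian_log10")$p_value
    )
  }
  expect_lt(p_at(20, 0.3), p_at(4, 0.05))
})

test_that("family choice tracks the simulated error structure", {
  gen_lognormal <- function(i) {
    set.seed(1000 + i)
    u <- rnorm(4, 0, 0.3)
    d <- expand.grid(experiment_id = 1:4, condition = c("a", "b"), w = 1:15,
                     stringsAsFactors = FALSE)
    d$response <- exp(log(100) + 0.2 * (d$condition == "b") +
                        u[d$experiment_id] + rnorm(nrow(d), 0, 1.0))
    d
  }
  gen_gamma <- function(i) {
    set.seed(2000 + i)
    u <- rnorm(4, 0, 0.05)
    d <- expand.grid(experiment_id = 1:4, condition = c("a", "b"), w = 1:15,
                     stringsAsFactors = FALSE)
    mu <- 1 / (0.01 + 0.002 * (d$condition == "b") +
                 0.0005 * u[d$experiment_id])
    d$response <- rgamma(nrow(d), shape = 1.5, rate = 1.5 / mu)
    d
  }
  n_rep <- 20
  picks_ln <- vapply(seq_len(n_rep), function(i) {
    suppressWarnings(suppressMessages(
      choose_family(gen_lognormal(i), "response", "condition")))$family
  }, character(1))
  picks_gam <- vapply(seq_len(n_rep), function(i) {
    suppressWarnings(suppressMessages(
      choose_family(gen_gamma(i), "response", "condition")))$family
  }, character(1))
  expect_gte(mean(picks_ln == "gaussian_log10"), 0.9)
  expect_gte(mean(picks_gam == "gamma_inverse"), 0.9)

  # degenerate identical statistics tie-break deterministically to Gaussian
  ch <- suppressWarnings(choose_family(sim_balanced(), "response",
                                       "condition"))
  expect_true(ch$family %in% c("gaussian_log10", "gamma_inverse"))
  expect_named(ch$statistics, c("gaussian_log10", "gamma_inverse"))
})

test_that("marginal-means contrasts enumerate pairs and respect relabeling", {
  d <- sim_balanced(seed = 31, n_exp = 4, n_wells = 6)
  fit <- fit_lmm_log10(d, "response", "condition")
  ct <- emm_contrasts(fit, "condition")
  expect_equal(nrow(ct), 1) # C(2,2) = 1

  set.seed(41)
  d6 <- expand.grid(experiment_id = sprintf("E%d", 1:4),
                    treatment = sprintf("t%d", 1:6), w = 1:4,
                    stringsAsFactors = FALSE)
  d6$response <- rlnorm(nrow(d6), log(100), 0.3)
  f6 <- suppressWarnings(fit_lmm_log10(d6, "response", "treatment"))
  ct6 <- emm_contrasts(f6, "treatment")
  expect_equal(nrow(ct6), choose(6, 2)) # 15

  # relabeling levels permutes rows but not the set of adjusted p-values
  d6b <- d6
  d6b$treatment <- chartr("123456", "654321", d6b$treatment)
  f6b <- suppressWarnings(fit_lmm_log10(d6b, "response", "treatment"))
  ct6b <- emm_contrasts(f6b, "treatment")
  expect_equal(sort(ct6$p_adjusted), sort(ct6b$p_adjusted),
               tolerance = 1e-6)

  # single-level factor: no contrasts
  d1 <- d6[d6$treatment == "t1", ]
  d1$condition <- "only"
  f1 <- suppressWarnings(fit_lmm_log10(d1, "response", character(0)))
  f1$fixed <- "condition"
  f1$data <- d1
  expect_equal(nrow(emm_contrasts(f1, "condition")), 0)
})

test_that("group summaries report mean, SD and t-based CI half-widths", {
  d <- tibble::tibble(
    experiment_id = c("E1", "E1", "E2"),
    grp = "a",
    value = c(1, 2, 3)
  )
  s <- summarize_groups(d, "value", grp)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$N, 2)
  expect_equal(s$ci, qt(0.975, 2) * 1 / sqrt(3))

  s1 <- summarize_groups(d[1, ], "value", grp)
  expect_equal(s1$sd, 0)
  expect_true(s1$sd_undefined)
})

test_that("the t-based CI agrees with a bootstrap percentile interval", {
  set.seed(77)
  d <- tibble::tibble(
    experiment_id = rep(sprintf("E%d", 1:6), each = 10),
    grp = "a",
    value = rlnorm(60, log(100), 0.3)
  )
  s <- summarize_groups(d, "value", grp)
  boot_means <- replicate(4000, mean(sample(d$value, replace = TRUE)))
  boot_half <- diff(unname(quantile(boot_means, c(0.025, 0.975)))) / 2
  expect_lt(abs(s$ci - boot_half) / boot_half, 0.1)
})
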