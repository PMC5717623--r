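# Random-intercept mixed models for sequence-level analyses.
#
# Gesture-sequence observations are clustered within focal signallers, so
# fixed-effect inference uses a random intercept per focal individual.
# Random slopes are deliberately not offered: the scientific questions here
# concern population-level associations, not their between-subject
# variation.

#' Specify a random-intercept mixed model
#'
#' @param response name of the response column. Binary responses must be
#'   coded 0/1 for the binomial family.
#' @param fixed_effects character vector of fixed-effect column names.
#' @param group name of the grouping column (the focal individual's id),
#'   entered as a random intercept.
#' @param family `"binomial_logit"` (binary response, logit link) or
#'   `"gaussian_identity"` (continuous response).
#' @return a `glmm_spec` list.
#' @export
glmm_spec <- function(response, fixed_effects, group,
                      family = c("binomial_logit", "gaussian_identity")) {
  family <- match.arg(family)
  stopifnot(is.character(response), length(response) == 1,
            is.character(fixed_effects), length(fixed_effects) >= 1,
            is.character(group), length(group) == 1)
  structure(list(response = response, fixed_effects = fixed_effects,
                 group = group, family = family), class = "glmm_spec")
}

#' Fit a random-intercept mixed model
#'
#' Fits the model described by a [glmm_spec()] by maximum likelihood
#' (Laplace approximation for the binomial family via [lme4::glmer()]; REML
#' with Satterthwaite-based p-values via [lmerTest::lmer()] for the gaussian
#' family). Rows with missing values in any used column are dropped. When
#' the grouping factor has fewer than two levels the model degenerates to an
#' ordinary fixed-effects regression, which is fitted instead (random
#' intercept variance 0, noted in the diagnostics) — the mixed model with a
#' zero random-intercept variance reduces to exactly this fit.
#'
#' Non-convergence never fails silently: optimizer warnings are captured in
#' the result's `diagnostics` and flip `converged` to `FALSE`. A heuristic
#' separation check on binomial fits (absolute coefficient or standard error
#' above 15 on the logit scale) adds a warning to the diagnostics.
#'
#' @param data observation table.
#' @param spec a [glmm_spec()].
#' @return a `glmm_result`: `coefficients` (`data.frame` with `term`,
#'   `estimate`, `se`, `p`), `random_intercept_variance`, `n_obs`,
#'   `n_groups`, `converged`, `diagnostics`, `family`.
#' @export
fit_glmm <- function(data, spec) {
  stopifnot(inherits(spec, "glmm_spec"))
  used <- c(spec$response, spec$fixed_effects, spec$group)
  miss <- setdiff(used, names(data))
  if (length(miss)) {
    stop(sprintf("data is missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  df <- data[stats::complete.cases(data[, used, drop = FALSE]), used, drop = FALSE]
  if (nrow(df) < length(spec$fixed_effects) + 2) {
    stop("too few complete cases to fit the model", call. = FALSE)
  }
  if (spec$family == "binomial_logit") {
    yv <- df[[spec$response]]
    if (!all(yv %in% c(0, 1))) {
      stop("binomial responses must be coded 0/1", call. = FALSE)
    }
  }
  df[[spec$group]] <- factor(df[[spec$group]])
  n_groups <- nlevels(df[[spec$group]])
  diagnostics <- character(0)
  fe <- paste(spec$fixed_effects, collapse = " + ")

  if (n_groups < 2) {
    diagnostics <- c(diagnostics,
                     "single grouping level: fitted as fixed-effects regression")
    form <- stats::as.formula(paste(spec$response, "~", fe))
    if (spec$family == "binomial_logit") {
      fit <- stats::glm(form, data = df, family = stats::binomial())
    } else {
      fit <- stats::lm(form, data = df)
    }
    cf <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                        p = cf[, 4], row.names = NULL, stringsAsFactors = FALSE)
    re_var <- 0
    converged <- TRUE
  } else {
    form <- stats::as.formula(paste(spec$response, "~", fe, "+ (1 |", spec$group, ")"))
    warn <- character(0)
    fit <- tryCatch(
      withCallingHandlers(
        if (spec$family == "binomial_logit") {
          lme4::glmer(form, data = df, family = stats::binomial())
        } else {
          lmerTest::lmer(form, data = df)
        },
        warning = function(w) {
          warn <<- c(warn, conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) e)
    if (inherits(fit, "error")) {
      # numerical failure of the mixed fit; report the fixed-effects fit with
      # the failure on record rather than erroring or hiding it
      diagnostics <- c(diagnostics, warn,
                       sprintf("mixed-model fit failed (%s); reporting fixed-effects regression",
                               conditionMessage(fit)))
      form_fe <- stats::as.formula(paste(spec$response, "~", fe))
      fe_fit <- if (spec$family == "binomial_logit") {
        stats::glm(form_fe, data = df, family = stats::binomial())
      } else {
        stats::lm(form_fe, data = df)
      }
      cf <- summary(fe_fit)$coefficients
      coefs <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                          p = cf[, 4], row.names = NULL, stringsAsFactors = FALSE)
      re_var <- NA_real_
      converged <- FALSE
    } else {
      cf <- withCallingHandlers(
        summary(fit)$coefficients,
        warning = function(w) {
          warn <<- c(warn, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      diagnostics <- c(diagnostics, warn)
      pcol <- ncol(cf)  # Pr(>|z|) for glmer, Pr(>|t|) for lmerTest
      coefs <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                          p = cf[, pcol], row.names = NULL, stringsAsFactors = FALSE)
      vc <- as.data.frame(lme4::VarCorr(fit))
      re_var <- vc$vcov[vc$grp == spec$group][1]
      converged <- length(warn) == 0
    }
  }
  if (spec$family == "binomial_logit" &&
      any(abs(coefs$estimate) > 15 | coefs$se > 15)) {
    diagnostics <- c(diagnostics,
                     "possible separation: extreme coefficient or standard error on the logit scale")
  }
  structure(list(coefficients = coefs, random_intercept_variance = re_var,
                 n_obs = nrow(df), n_groups = n_groups, converged = converged,
                 diagnostics = diagnostics, family = spec$family,
                 spec = spec),
            class = "glmm_result")
}

#' @export
print.glmm_result <- function(x, ...) {
  cat(sprintf("<glmm_result> %s | %d obs, %d groups | random-intercept var %.4f%s\n",
              x$family, x$n_obs, x$n_groups, x$random_intercept_variance,
              if (x$converged) "" else " | NOT CONVERGED"))
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, 4)
  tab$se <- round(tab$se, 4)
  tab$p <- signif(tab$p, 3)
  print(tab)
  if (length(x$diagnostics)) {
    cat("diagnostics:\n")
    for (d in x$diagnostics) cat(" -", d, "\n")
  }
  invisible(x)
}
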