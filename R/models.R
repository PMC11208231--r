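## Multivariate two-level mixed models: stacked test outcomes with a
## subject random intercept and per-test group-difference (or association)
## contrasts from the Test x predictor interaction.

#' Stack a wide outcomes table into long model format
#'
#' One multivariate model analyzes the tests of a family together, so the
#' wide per-subject table is stacked into records of (subject, group, test,
#' value). Missing values are dropped, not imputed: the mixed model analyzes
#' all available rows by likelihood.
#'
#' @param outcomes data.frame with columns `subject`, `group`, and one
#'   column per test.
#' @param tests character vector of test column names forming the family.
#' @param family optional family name attached as an attribute.
#' @return long data.frame `subject`, `group`, `test`, `value` with `test`
#'   a factor in the order given; attribute `n_dropped` counts the missing
#'   records removed.
#' @export
stack_long <- function(outcomes, tests, family = NULL) {
  if (length(tests) == 0L) stop("empty test family", call. = FALSE)
  missing_cols <- setdiff(c("subject", "group", tests), names(outcomes))
  if (length(missing_cols) > 0L) {
    stop(sprintf("outcome column(s) not found: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  rows <- lapply(tests, function(tst) {
    data.frame(subject = outcomes$subject,
               group = outcomes$group,
               test = tst,
               value = outcomes[[tst]],
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  n0 <- nrow(long)
  long <- long[!is.na(long$value), , drop = FALSE]
  long$test <- factor(long$test, levels = tests)
  if (!is.factor(long$group)) {
    long$group <- factor(long$group, levels = c("control", "LBP"))
  }
  rownames(long) <- NULL
  attr(long, "n_dropped") <- n0 - nrow(long)
  attr(long, "family") <- family
  long
}

#' Fit a multivariate two-level mixed model
#'
#' Fits, by restricted maximum likelihood,
#' \deqn{value_{it} = \mu_t + \beta_t x_i + u_i + e_{it}}
#' where `t` indexes the stacked tests of one family, `x_i` is the
#' subject-level predictor on the right-hand side of `formula` (the group
#' indicator for case-control contrasts, or a clinical test score for
#' association models), `u_i ~ N(0, sigma_u^2)` is the subject random
#' intercept that absorbs the within-subject correlation of the test
#' outcomes, and `e_it` the residual. The per-test coefficients `beta_t`
#' come from the Test x predictor interaction (internal parametrization
#' `value ~ 0 + test + test:x + (1 | subject)`), with Wald standard errors,
#' normal 95% confidence intervals `beta +/- 1.96 SE` and normal-theory
#' p-values. No multiplicity adjustment is applied: all estimates derive
#' from the one model, and none beyond that is added.
#'
#' The residual variance is homogeneous across tests by default;
#' `var_by_test = TRUE` switches to a per-test residual variance
#' (`nlme::varIdent`), for families that stack tests on incommensurable
#' scales.
#'
#' @param formula `value ~ predictor`; both sides name columns of `data`.
#'   The predictor is a two-level factor (contrast = second minus first
#'   level) or a numeric score (contrast = slope).
#' @param data long data.frame with columns named by `formula`, `subject`
#'   and `test` (see [stack_long()]).
#' @param subject,test names of the subject and test columns.
#' @param var_by_test per-test residual variances via `nlme` (default
#'   FALSE = homogeneous, via `lme4`).
#' @param conf_level confidence level for the Wald intervals (default 0.95).
#' @return object of class `mvmm` with methods `print`, `summary`, `coef`,
#'   `confint`, `vcov`, `fitted`, `residuals`, `predict`, `plot` and the
#'   accessor [estimates()].
#' @examples
#' long <- simulate_outcome_table(10, c("a", "b"), effects = c(a = 0, b = 2),
#'                                seed = 7)
#' fit <- mvmm(value ~ group, long)
#' estimates(fit)
#' @export
mvmm <- function(formula, data, subject = "subject", test = "test",
                 var_by_test = FALSE, conf_level = 0.95) {
  stopifnot(inherits(formula, "formula"), length(formula) == 3L)
  response <- as.character(formula[[2]])
  pred <- all.vars(formula[[3]])
  if (length(pred) != 1L) {
    stop("the right-hand side must name exactly one predictor",
         call. = FALSE)
  }
  need <- c(response, pred, subject, test)
  if (!all(need %in% names(data))) {
    stop(sprintf("column(s) not found in data: %s",
                 paste(setdiff(need, names(data)), collapse = ", ")),
         call. = FALSE)
  }
  d <- data.frame(value = data[[response]],
                  x = data[[pred]],
                  subject = factor(data[[subject]]),
                  test = factor(data[[test]]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) == 0L) stop("no complete records to fit", call. = FALSE)
  if (is.character(d$x)) d$x <- factor(d$x)
  if (is.factor(d$x)) {
    d$x <- droplevels(d$x)
    if (nlevels(d$x) != 2L) {
      stop("a factor predictor must have exactly 2 observed levels",
           call. = FALSE)
    }
    per_level <- tapply(as.character(d$subject), d$x,
                        function(s) length(unique(s)))
    if (any(per_level < 2)) {
      stop("need at least 2 subjects per predictor level", call. = FALSE)
    }
  } else if (stats::var(d$x) == 0) {
    stop("predictor has no variance", call. = FALSE)
  }
  tests <- levels(droplevels(d$test))
  d$test <- droplevels(d$test)

  ## degenerate noiseless data (factor designs with zero within-cell
  ## variance): the mixed model is unidentified, so use the exact per-cell
  ## solution and flag the fit singular
  degenerate <- if (is.factor(d$x)) {
    cell_resid <- stats::ave(d$value, interaction(d$test, d$x),
                             FUN = function(v) v - mean(v))
    max(abs(cell_resid)) < 1e-12
  } else FALSE
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (degenerate) {
    beta <- vapply(tests, function(tst) {
      v <- d[d$test == tst, ]
      if (is.factor(v$x)) {
        mean(v$value[v$x == levels(v$x)[2]]) -
          mean(v$value[v$x == levels(v$x)[1]])
      } else {
        stats::coef(stats::lm(value ~ x, data = v))[["x"]]
      }
    }, numeric(1))
    contr <- data.frame(test = tests, beta = unname(beta), se = 0,
                        ci_low = unname(beta), ci_high = unname(beta),
                        p = NA_real_, stringsAsFactors = FALSE)
    out <- list(call = match.call(), formula = formula, predictor = pred,
                tests = tests, engine = "exact", fit = NULL,
                contrasts = contr, singular = TRUE,
                conf_level = conf_level, n_obs = nrow(d),
                n_subjects = nlevels(d$subject), data = d)
    class(out) <- "mvmm"
    return(out)
  }

  if (var_by_test && length(tests) > 1L) {
    lme_try <- function(opt, strict) {
      nlme::lme(value ~ 0 + test + test:x, random = ~ 1 | subject,
                weights = nlme::varIdent(form = ~ 1 | test),
                data = d, method = "REML",
                control = nlme::lmeControl(opt = opt, maxIter = 200,
                                           msMaxIter = 200,
                                           returnObject = !strict))
    }
    ## variance ratios across tests can be extreme; nlminb is the more
    ## robust optimizer here, optim the fallback, and a flagged
    ## non-strict fit the last resort
    fit <- tryCatch(lme_try("nlminb", strict = TRUE), error = function(e) {
      tryCatch(lme_try("optim", strict = TRUE), error = function(e2) {
        warning("mixed-model optimizer did not converge strictly; ",
                "estimates flagged (", conditionMessage(e), ")",
                call. = FALSE)
        suppressWarnings(lme_try("nlminb", strict = FALSE))
      })
    })
    fe <- nlme::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    singular <- as.numeric(nlme::VarCorr(fit)[1, "StdDev"]) < 1e-8
    engine <- "lme"
  } else {
    fit <- lme4::lmer(value ~ 0 + test + test:x + (1 | subject),
                      data = d, REML = TRUE)
    fe <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    singular <- lme4::isSingular(fit)
    engine <- "lmer"
  }
  if (singular) {
    warning("singular fit: a variance component is estimated at zero",
            call. = FALSE)
  }
  ia <- grepl(":x", names(fe), fixed = TRUE)
  beta <- fe[ia]
  se <- sqrt(diag(V)[ia])
  tlab <- sub(":x.*$", "", names(beta))
  tlab <- sub("^test", "", tlab)
  ord <- match(tests, tlab)
  beta <- unname(beta[ord]); se <- unname(se[ord])
  contr <- data.frame(test = tests, beta = beta, se = se,
                      ci_low = beta - z * se, ci_high = beta + z * se,
                      p = 2 * stats::pnorm(-abs(beta / se)),
                      stringsAsFactors = FALSE)
  out <- list(call = match.call(), formula = formula, predictor = pred,
              tests = tests, engine = engine, fit = fit,
              contrasts = contr, singular = singular,
              conf_level = conf_level, n_obs = nrow(d),
              n_subjects = nlevels(d$subject), data = d)
  class(out) <- "mvmm"
  out
}

#' Per-test coefficient estimates of a fitted model
#'
#' @param object a fitted `mvmm`.
#' @param ... unused.
#' @return data.frame with one row per test: `test`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `p`.
#' @export
estimates <- function(object, ...) UseMethod("estimates")

#' @rdname estimates
#' @export
estimates.mvmm <- function(object, ...) object$contrasts

#' @export
print.mvmm <- function(x, ...) {
  cat(sprintf("Multivariate mixed model: %s (engine %s%s)\n",
              deparse(x$formula), x$engine,
              if (x$singular) ", singular" else ""))
  cat(sprintf("  %d observations, %d subjects, %d tests\n",
              x$n_obs, x$n_subjects, length(x$tests)))
  print(x$contrasts, digits = 4)
  invisible(x)
}

#' @export
summary.mvmm <- function(object, ...) {
  vc <- if (object$engine == "lmer") {
    v <- as.data.frame(lme4::VarCorr(object$fit))
    c(subject_sd = v$sdcor[v$grp == "subject"],
      residual_sd = v$sdcor[v$grp == "Residual"])
  } else if (object$engine == "lme") {
    v <- nlme::VarCorr(object$fit)
    c(subject_sd = as.numeric(v["(Intercept)", "StdDev"]),
      residual_sd = as.numeric(v["Residual", "StdDev"]))
  } else {
    c(subject_sd = NA_real_, residual_sd = 0)
  }
  structure(list(model = object, varcomp = vc), class = "summary.mvmm")
}

#' @export
print.summary.mvmm <- function(x, ...) {
  print(x$model)
  cat(sprintf("  random intercept SD %.4g, residual SD %.4g\n",
              x$varcomp["subject_sd"], x$varcomp["residual_sd"]))
  invisible(x)
}

#' @export
coef.mvmm <- function(object, ...) {
  stats::setNames(object$contrasts$beta, object$contrasts$test)
}

#' @export
confint.mvmm <- function(object, parm, level = NULL, ...) {
  ci <- as.matrix(object$contrasts[, c("ci_low", "ci_high")])
  rownames(ci) <- object$contrasts$test
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
vcov.mvmm <- function(object, ...) {
  if (is.null(object$fit)) {
    matrix(0, 0, 0)
  } else {
    as.matrix(stats::vcov(object$fit))
  }
}

#' @export
fitted.mvmm <- function(object, ...) {
  if (is.null(object$fit)) return(object$data$value)
  as.numeric(stats::fitted(object$fit))
}

#' @export
residuals.mvmm <- function(object, ...) {
  if (is.null(object$fit)) return(rep(0, nrow(object$data)))
  as.numeric(stats::residuals(object$fit))
}

#' @export
predict.mvmm <- function(object, newdata = NULL, ...) {
  if (is.null(object$fit)) stop("no engine fit to predict from",
                                call. = FALSE)
  if (is.null(newdata)) return(fitted(object))
  nd <- data.frame(test = factor(newdata$test, levels = object$tests),
                   x = newdata[[object$predictor]])
  if (object$engine == "lmer") {
    as.numeric(stats::predict(object$fit, newdata = nd, re.form = NA))
  } else {
    as.numeric(stats::predict(object$fit, newdata = nd, level = 0))
  }
}

#' Residual diagnostics of an mvmm fit
#'
#' Residuals-versus-fitted and a normal Q-Q plot, the visual checks used to
#' judge normality and homoscedasticity of the stacked-model residuals.
#'
#' @param x fitted `mvmm`.
#' @param ... passed to the underlying plot calls.
#' @export
plot.mvmm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(fitted(x), residuals(x),
                 xlab = "fitted", ylab = "residual",
                 main = "Residuals vs fitted", ...)
  graphics::abline(h = 0, lty = 2)
  stats::qqnorm(residuals(x), main = "Normal Q-Q")
  stats::qqline(residuals(x))
  invisible(x)
}

#' Group-difference model for one test family
#'
#' Convenience front-end to [mvmm()] for the case-control contrast: per-test
#' LBP-minus-control differences with Wald inference.
#'
#' @param long long data.frame from [stack_long()] (columns `subject`,
#'   `group`, `test`, `value`).
#' @param var_by_test forwarded to [mvmm()].
#' @return fitted `mvmm`.
#' @export
fit_group_model <- function(long, var_by_test = FALSE) {
  mvmm(value ~ group, long, var_by_test = var_by_test)
}

#' Association model between map features and a clinical test
#'
#' The map family (one CoG axis across the four muscles, or the four areas)
#' is the multivariate outcome; the subject-level clinical score is the
#' predictor. Returns per-muscle association slopes.
#'
#' @param map_long long map outcomes (`subject`, `test` = muscle, `value`).
#' @param predictors data.frame with `subject` and the predictor column.
#' @param predictor name of the predictor column.
#' @param var_by_test forwarded to [mvmm()].
#' @return fitted `mvmm`.
#' @export
fit_association_model <- function(map_long, predictors, predictor,
                                  var_by_test = FALSE) {
  if (!predictor %in% names(predictors)) {
    stop(sprintf("predictor column '%s' not found", predictor),
         call. = FALSE)
  }
  idx <- match(map_long$subject, predictors$subject)
  if (anyNA(idx)) stop("predictor missing for some subjects", call. = FALSE)
  d <- map_long
  d[[predictor]] <- predictors[[predictor]][idx]
  mvmm(stats::as.formula(paste("value ~", predictor)), d,
       var_by_test = var_by_test)
}

#' Within-group refit of a significant association
#'
#' The stratified follow-up is only meaningful for associations already
#' flagged significant in the pooled model; the pipeline enforces that
#' gate and this function checks the subgroup is large enough.
#'
#' @param map_long,predictors,predictor as [fit_association_model()].
#' @param group_table data.frame with `subject` and `group`.
#' @param group subgroup level to refit in (`"LBP"` or `"control"`).
#' @param var_by_test forwarded.
#' @return fitted `mvmm` on the subgroup.
#' @export
stratified_association <- function(map_long, predictors, predictor,
                                   group_table, group,
                                   var_by_test = FALSE) {
  keep_subj <- group_table$subject[group_table$group == group]
  if (length(unique(keep_subj)) < 3L) {
    stop(sprintf("subgroup '%s' has fewer than 3 subjects", group),
         call. = FALSE)
  }
  sub <- map_long[map_long$subject %in% keep_subj, , drop = FALSE]
  fit_association_model(sub, predictors, predictor,
                        var_by_test = var_by_test)
}

#' Format estimate tables in the publication layout
#'
#' One row per test with `beta (SE)`, the 95% CI and the p-value;
#' significant rows (p below `alpha`) are wrapped in `**`. Coefficient
#' multipliers rescale selected rows, e.g. reporting two-point
#' discrimination associations per 5 mm step (the test's increment).
#'
#' @param est estimates data.frame (from [estimates()]), or a fitted
#'   `mvmm`.
#' @param alpha significance threshold for bolding (default 0.05).
#' @param multipliers named numeric vector of per-test coefficient
#'   multipliers applied to beta, SE and CI (default none).
#' @param digits digits for formatting (default 3).
#' @return data.frame of formatted strings: `test`, `beta_se`, `ci`, `p`.
#' @export
render_tables <- function(est, alpha = 0.05, multipliers = NULL,
                          digits = 3) {
  if (inherits(est, "mvmm")) est <- estimates(est)
  if (nrow(est) == 0L) {
    return(data.frame(test = character(0), beta_se = character(0),
                      ci = character(0), p = character(0)))
  }
  if (!is.null(multipliers)) {
    for (tst in names(multipliers)) {
      i <- est$test == tst
      m <- multipliers[[tst]]
      est$beta[i] <- est$beta[i] * m
      est$se[i] <- est$se[i] * m
      est$ci_low[i] <- est$ci_low[i] * m
      est$ci_high[i] <- est$ci_high[i] * m
    }
  }
  fmt <- function(x) formatC(x, digits = digits, format = "f")
  sig <- !is.na(est$p) & est$p < alpha
  emph <- function(s, yes) ifelse(yes, paste0("**", s, "**"), s)
  data.frame(
    test = est$test,
    beta_se = emph(sprintf("%s (%s)", fmt(est$beta), fmt(est$se)), sig),
    ci = emph(sprintf("%s to %s", fmt(est$ci_low), fmt(est$ci_high)), sig),
    p = emph(fmt(est$p), sig),
    stringsAsFactors = FALSE
  )
}
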