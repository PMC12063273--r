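# Shared REML fitting + extraction for all mixed models in the package.
# Fits with lmerTest so degrees of freedom can come from Satterthwaite or
# Kenward-Roger (pbkrtest); "none" skips df/p computation for speed when only
# the estimates are needed (e.g. Monte-Carlo recovery loops).
fit_lmm <- function(formula, data, df_method = c("satterthwaite", "kenward-roger", "none"),
                    not_reported = character(0)) {
  df_method <- match.arg(df_method)
  n_part <- length(unique(data$participant_id))
  if (n_part < 2L)
    parameter_error("mixed models need at least 2 participants (grouping levels)")
  ctrl <- lme4::lmerControl(optimizer = "bobyqa", calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  m <- suppressMessages(lmerTest::lmer(formula, data = data, REML = TRUE,
                                       control = ctrl))
  singular <- lme4::isSingular(m, tol = 1e-4)
  conv_msgs <- unlist(m@optinfo$conv$lme4$messages)
  converged <- is.null(conv_msgs)
  cs <- if (df_method == "none") {
    cf <- summary(m, ddf = "lme4")$coefficients
    cbind(cf[, 1:2, drop = FALSE], df = NA_real_,
          t = cf[, 1] / cf[, 2], p = NA_real_)
  } else {
    ddf <- if (df_method == "satterthwaite") "Satterthwaite" else "Kenward-Roger"
    summary(m, ddf = ddf)$coefficients[, c(1, 2, 3, 4, 5), drop = FALSE]
  }
  fixed <- data.frame(term = rownames(cs), estimate = cs[, 1], se = cs[, 2],
                      df = cs[, 3], t = cs[, 4], p = cs[, 5],
                      reported = !(rownames(cs) %in% not_reported),
                      row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(m))
  re <- vc[is.na(vc$var2) & vc$grp != "Residual", c("var1", "sdcor")]
  names(re) <- c("term", "sd")
  structure(list(
    model = m,
    formula = deparse(formula),
    fixed = fixed,
    ranef_sd = re,
    residual_sd = vc$sdcor[vc$grp == "Residual"],
    converged = converged,
    convergence_messages = conv_msgs,
    singular = singular,
    n_obs = nrow(data),
    n_participants = n_part,
    df_method = df_method), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s\n  n_obs = %d, participants = %d, df = %s%s%s\n",
              x$formula, x$n_obs, x$n_participants, x$df_method,
              if (x$singular) ", singular" else "",
              if (!x$converged) ", NOT CONVERGED" else ""))
  fx <- x$fixed
  for (i in seq_len(nrow(fx))) {
    cat(sprintf("  %-18s beta = %8.4g  SE = %.3g  t = %.3g(%.1f)  p = %.3g%s\n",
                fx$term[i], fx$estimate[i], fx$se[i], fx$t[i], fx$df[i],
                fx$p[i], if (!fx$reported[i]) "  [not reported]" else ""))
  }
  cat(sprintf("  random-effect SDs: %s; residual SD = %.3g\n",
              paste(sprintf("%s %.3g", x$ranef_sd$term, x$ranef_sd$sd),
                    collapse = ", "), x$residual_sd))
  invisible(x)
}

#' Fit the gait-speed model of propulsion symmetry
#'
#' For the stroke group: symmetry regressed on gait speed, symmetry at
#' comfortable walking speed (CWS), and their interaction, with random
#' intercept and speed slope per participant. The CWS-symmetry main effect is
#' estimated but marked not-reported (it carries no meaningful
#' interpretation, only the interaction does). For controls the reduced
#' model has speed as the only fixed effect with the same random structure.
#' Covariates enter uncentered, speed in m/s, symmetry as a fraction.
#'
#' @param obs observation table from [build_observation_table()].
#' @param metric `"peak"` or `"impulse"`.
#' @param group `"stroke"` or `"control"`.
#' @param df_method `"satterthwaite"`, `"kenward-roger"`, or `"none"`.
#' @return an `lmm_fit`.
#' @export
fit_symmetry_model <- function(obs, metric = c("peak", "impulse"),
                               group = c("stroke", "control"),
                               df_method = "kenward-roger") {
  metric <- match.arg(metric)
  group <- match.arg(group)
  ref <- if (group == "stroke") "paretic" else "left"
  d <- obs[obs$group == group & obs$leg == ref, , drop = FALSE]
  d$sym <- d[[paste0(metric, "_symmetry")]]
  d$sym_cws <- d[[paste0(metric, "_symmetry_at_cws")]]
  d <- d[complete.cases(d[, c("sym", "speed", "sym_cws")]), , drop = FALSE]
  if (!nrow(d)) parameter_error("no usable symmetry observations for this group")
  if (group == "stroke") {
    fit_lmm(sym ~ speed * sym_cws + (1 + speed | participant_id), d,
            df_method = df_method, not_reported = "sym_cws")
  } else {
    fit_lmm(sym ~ speed + (1 + speed | participant_id), d,
            df_method = df_method)
  }
}

#' Fit the per-leg propulsion model with a speed-by-leg interaction
#'
#' Absolute propulsion (peak or impulse, N/kg or N/kg.s) regressed on gait
#' speed, leg, and their interaction for the stroke group. Leg is an
#' indicator with the non-paretic leg as reference (0), so the leg effect is
#' the paretic deficit. Random effects: intercept, speed slope, leg, and
#' speed-by-leg per participant.
#'
#' @inheritParams fit_symmetry_model
#' @return an `lmm_fit`.
#' @export
fit_leg_model <- function(obs, metric = c("peak", "impulse"),
                          df_method = "kenward-roger") {
  metric <- match.arg(metric)
  d <- obs[obs$group == "stroke", , drop = FALSE]
  if (!all(c("paretic", "non_paretic") %in% unique(d$leg)))
    parameter_error("both paretic and non-paretic rows are required")
  d$y <- d[[metric]]
  d$leg_paretic <- as.numeric(d$leg == "paretic")
  d <- d[complete.cases(d[, c("y", "speed")]), , drop = FALSE]
  fit_lmm(y ~ speed * leg_paretic + (1 + speed * leg_paretic | participant_id),
          d, df_method = df_method)
}

#' Post-hoc single-leg gait-speed model
#'
#' The follow-up fit used when the speed-by-leg interaction is significant:
#' one leg's propulsion regressed on speed with random intercept and slope.
#'
#' @inheritParams fit_symmetry_model
#' @param leg `"paretic"` or `"non_paretic"`.
#' @return an `lmm_fit`.
#' @export
fit_per_leg_posthoc <- function(obs, metric = c("peak", "impulse"),
                                leg = c("non_paretic", "paretic"),
                                df_method = "kenward-roger") {
  metric <- match.arg(metric)
  leg <- match.arg(leg)
  d <- obs[obs$group == "stroke" & obs$leg == leg, , drop = FALSE]
  d$y <- d[[metric]]
  d <- d[complete.cases(d[, c("y", "speed")]), , drop = FALSE]
  if (!nrow(d)) parameter_error("no rows for the requested leg")
  fit_lmm(y ~ speed + (1 + speed | participant_id), d, df_method = df_method)
}

#' Control-group gait-speed model of absolute propulsion
#'
#' Speed as the only fixed effect, random intercept and slope per
#' participant, pooling both (exchangeable) legs.
#'
#' @inheritParams fit_symmetry_model
#' @return an `lmm_fit`.
#' @export
fit_control_metric_model <- function(obs, metric = c("peak", "impulse"),
                                     df_method = "kenward-roger") {
  metric <- match.arg(metric)
  d <- obs[obs$group == "control", , drop = FALSE]
  d$y <- d[[metric]]
  d <- d[complete.cases(d[, c("y", "speed")]), , drop = FALSE]
  if (!nrow(d)) parameter_error("no control rows available")
  fit_lmm(y ~ speed + (1 + speed | participant_id), d, df_method = df_method)
}

#' Residual diagnostics for a fitted mixed model
#'
#' The numerical material behind the three standard fit-assessment plots
#' (Q-Q plot, residual histogram, residuals vs fitted), plus a Shapiro-Wilk
#' normality summary of the residuals.
#'
#' @param fit an `lmm_fit`.
#' @return list with `residuals`, `fitted`, `qq` (data.frame of theoretical
#'   and sample quantiles of standardized residuals), `shapiro_w`,
#'   `shapiro_p`.
#' @export
compute_diagnostics <- function(fit) {
  r <- residuals(fit$model)
  f <- fitted(fit$model)
  z <- (r - mean(r)) / sd(r)
  qq <- data.frame(theoretical = qnorm(ppoints(length(z))), sample = sort(z))
  sw <- if (length(r) >= 3 && length(r) <= 5000) shapiro.test(r) else
    list(statistic = NA_real_, p.value = NA_real_)
  list(residuals = as.numeric(r), fitted = as.numeric(f), qq = qq,
       shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value)
}

#' Serialize a fitted model to a plain list (for JSON export)
#'
#' @param fit an `lmm_fit`.
#' @return list of estimates, SEs, df, p, random-effect SDs and fit status.
#' @export
lmm_fit_to_list <- function(fit) {
  list(formula = fit$formula, df_method = fit$df_method,
       fixed = fit$fixed, ranef_sd = fit$ranef_sd,
       residual_sd = fit$residual_sd, converged = fit$converged,
       singular = fit$singular, n_obs = fit$n_obs,
       n_participants = fit$n_participants)
}
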