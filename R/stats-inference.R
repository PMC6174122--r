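# Mixed-effects group inference: participant random intercepts,
# likelihood-ratio tests for fixed effects, Tukey-adjusted least-squares
# means, and per-subject percent-change summaries.

#' Fit a linear mixed model with a participant random intercept
#'
#' Fits `value ~ <fixed factors> + (1 | participant)` with lme4. When two
#' fixed factors are supplied and `interaction = TRUE`, their interaction is
#' included. Fits use maximum likelihood by default so nested models can be
#' compared by likelihood-ratio test; set `reml = TRUE` for variance
#' component estimates. A singular fit (zero between-participant variance)
#' is reported via a message, not an error.
#'
#' @param table Data frame with a `participant` column, the fixed-factor
#'   columns, and a response column.
#' @param fixed Character vector of fixed-factor column names (possibly
#'   empty, giving an intercept-only model).
#' @param response Response column name, default `"value"`.
#' @param participant Grouping column name, default `"participant"`.
#' @param interaction Include the interaction of two fixed factors.
#' @param reml Use REML (default `FALSE`, i.e. maximum likelihood).
#' @return A fitted `lmerMod`.
#' @export
fit_mixed_model <- function(table, fixed, response = "value",
                            participant = "participant",
                            interaction = TRUE, reml = FALSE) {
  stopifnot(is.data.frame(table))
  if (!participant %in% names(table))
    stop("`table` must contain a participant column")
  table[[participant]] <- factor(table[[participant]])
  if (nlevels(table[[participant]]) < 2L)
    stop("need at least 2 participants")
  for (f in fixed) {
    if (!f %in% names(table)) stop(sprintf("fixed factor '%s' not in table", f))
    table[[f]] <- factor(table[[f]])
    if (nlevels(table[[f]]) < 2L)
      stop(sprintf("fixed factor '%s' needs at least 2 levels", f))
  }
  rhs <- if (length(fixed) == 0L) "1"
         else paste(fixed, collapse = if (interaction && length(fixed) > 1L)
                                       " * " else " + ")
  fml <- as.formula(sprintf("%s ~ %s + (1 | %s)", response, rhs, participant))
  fit <- lme4::lmer(fml, data = table, REML = reml,
                    control = lme4::lmerControl(check.conv.singular =
                      lme4::.makeCC(action = "ignore", tol = 1e-4)))
  if (lme4::isSingular(fit))
    message("singular fit: between-participant variance estimated at zero")
  fit
}

#' Likelihood-ratio test between nested mixed models
#'
#' `statistic = 2 * (logLik(full) - logLik(reduced))`, referred to a
#' chi-square distribution with degrees of freedom equal to the parameter
#' difference. Both models must be fitted by maximum likelihood on the same
#' rows.
#'
#' @param full,reduced Fitted `lmerMod` objects, `reduced` nested in `full`.
#' @return One-row data frame: `statistic`, `df`, `p_value`.
#' @export
lrt_effect <- function(full, reduced) {
  if (stats::nobs(full) != stats::nobs(reduced))
    stop("models must be fitted on the same rows")
  if (isTRUE(lme4::isREML(full)) || isTRUE(lme4::isREML(reduced)))
    stop("likelihood-ratio tests require maximum-likelihood fits (REML = FALSE)")
  df_full <- attr(logLik(full), "df")
  df_red <- attr(logLik(reduced), "df")
  df <- df_full - df_red
  if (df < 0) stop("`reduced` must be nested in `full` (fewer parameters)")
  stat <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(reduced))))
  p <- if (df == 0) 1 else pchisq(stat, df = df, lower.tail = FALSE)
  data.frame(statistic = stat, df = df, p_value = p)
}

#' Likelihood-ratio test for one fixed effect of an endpoint table
#'
#' Convenience wrapper: fits the full model with all `fixed` factors and the
#' reduced model without `term` (dropping any interaction involving it) and
#' runs [lrt_effect()].
#'
#' @inheritParams fit_mixed_model
#' @param term The fixed factor to test.
#' @return One-row data frame: `term`, `statistic`, `df`, `p_value`.
#' @export
lrt_term <- function(table, term, fixed = term, response = "value",
                     participant = "participant", interaction = TRUE) {
  if (!term %in% fixed) stop("`term` must be one of the fixed factors")
  full <- fit_mixed_model(table, fixed, response, participant,
                          interaction = interaction, reml = FALSE)
  reduced <- fit_mixed_model(table, setdiff(fixed, term), response,
                             participant, interaction = FALSE, reml = FALSE)
  out <- lrt_effect(full, reduced)
  cbind(data.frame(term = term), out)
}

#' Tukey-adjusted pairwise contrasts of least-squares means
#'
#' Least-squares (model-adjusted) means for each level of `factor`, with
#' all pairwise contrasts adjusted by the Tukey (studentized-range) method.
#' Degrees of freedom use the Satterthwaite approximation.
#'
#' @param model A fitted `lmerMod`.
#' @param factor Name of the fixed factor (or `"a:b"` for cell means of an
#'   interaction).
#' @return List with `lsmeans` (data frame of level means and SEs) and
#'   `contrasts` (data frame with Tukey-adjusted p-values).
#' @export
tukey_contrasts <- function(model, factor) {
  spec <- as.formula(paste0("~ ", factor))
  em <- emmeans::emmeans(model, spec, lmer.df = "satterthwaite")
  ctr <- emmeans::contrast(em, method = "pairwise", adjust = "tukey")
  list(lsmeans = as.data.frame(em), contrasts = as.data.frame(ctr))
}

#' Per-subject percent change relative to a reference condition
#'
#' For each participant and non-reference condition,
#' `100 * (value_ref - value_cond) / value_ref`, then the mean and SD across
#' participants per condition (positive = decrease from reference).
#' Participants with a zero reference value are excluded with a warning.
#'
#' @param table Data frame with `participant`, `condition`, and a response
#'   column (one row per cell).
#' @param reference_condition Reference level, default `"0"`.
#' @param response Response column name, default `"value"`.
#' @return Data frame: `condition`, `mean_pct`, `sd_pct`, `n`.
#' @export
percent_change_summary <- function(table, reference_condition = "0",
                                   response = "value") {
  stopifnot(is.data.frame(table))
  table$condition <- as.character(table$condition)
  if (!reference_condition %in% table$condition)
    stop("reference condition not present in table")
  ref <- table[table$condition == reference_condition, ]
  ref_val <- setNames(ref[[response]], as.character(ref$participant))
  if (any(ref_val == 0)) {
    warning("participants with zero reference value excluded")
    ref_val <- ref_val[ref_val != 0]
  }
  conds <- setdiff(unique(table$condition), reference_condition)
  out <- lapply(conds, function(cc) {
    sub <- table[table$condition == cc, ]
    sub <- sub[as.character(sub$participant) %in% names(ref_val), ]
    pc <- 100 * (ref_val[as.character(sub$participant)] - sub[[response]]) /
      ref_val[as.character(sub$participant)]
    data.frame(condition = cc, mean_pct = mean(pc), sd_pct = sd(pc),
               n = length(pc))
  })
  do.call(rbind, out)
}
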