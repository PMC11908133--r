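#' Cox proportional-hazards survival stage
#'
#' Fits the survival model with the standard covariate set: maximum VAF,
#' maximum fitness, age at first observation (all z-scored), sex, and
#' MACS120 (z-scored on the log scale). Reports the log proportional
#' hazard (LPH) per covariate with 95% confidence intervals and the
#' concordance index. Optional stratified refits by age bin
#' (`[50,60) [60,70) [70,80) [80,Inf)`) or by cohort.
#'
#' @param metrics Metrics table with z-scored columns and `sex`
#'   ([cohort_metrics()] or [truth_metrics()]).
#' @param survival Data.frame `participant_id`, `followup_years`, `event`.
#' @param covariates Character vector of metric columns to include
#'   (default the five-covariate model).
#' @param by_age_bin,by_cohort Also fit per age bin / per cohort
#'   (default `FALSE`).
#' @return A list with `results` (one row per covariate and scope: `beta`
#'   i.e. LPH, `ci_lo`, `ci_hi`, `p`, `n`, `n_events`, `concordance`,
#'   `scope`, `flag`) and `fit` (the pooled [survival::coxph] object).
#' @export
fit_cox <- function(metrics, survival,
                    covariates = c("z_max_vaf", "z_max_fitness", "z_age",
                                   "sexM", "z_macs120"),
                    by_age_bin = FALSE, by_cohort = FALSE) {
  d <- merge(metrics, survival, by = "participant_id")
  d$sexM <- as.numeric(d$sex == "M")
  if (!sum(d$event, na.rm = TRUE))
    condition_error("no events in scope", "clonedyn_no_events_error")

  fit_one <- function(dd, scope) {
    flag <- NA_character_
    keep <- covariates[vapply(covariates, function(cv)
      stats::sd(dd[[cv]], na.rm = TRUE) > 0, logical(1))]
    dropped <- setdiff(covariates, keep)
    if (length(dropped)) {
      warning("dropping constant covariate(s): ", paste(dropped, collapse = ", "))
      flag <- paste0("dropped:", paste(dropped, collapse = ","))
    }
    if (!length(keep) || !sum(dd$event))
      return(NULL)
    form <- stats::as.formula(paste("survival::Surv(followup_years, event) ~",
                                    paste(keep, collapse = " + ")))
    fit <- withCallingHandlers(
      survival::coxph(form, data = dd),
      warning = function(w) {
        if (grepl("coefficient may be infinite|did not converge", conditionMessage(w))) {
          flag <<- "separation-penalized"
          invokeRestart("muffleWarning")
        }
      })
    if (identical(flag, "separation-penalized")) {
      # monotone likelihood: stabilize with a ridge penalty
      form <- stats::as.formula(paste("survival::Surv(followup_years, event) ~",
                                      "ridge(", paste(keep, collapse = ", "),
                                      ", theta = 1)"))
      fit <- survival::coxph(form, data = dd)
    }
    s <- summary(fit)
    co <- s$coefficients
    se_col <- if ("se(coef)" %in% colnames(co)) "se(coef)" else "se2"
    p_col <- ncol(co)   # "Pr(>|z|)" for plain fits, "p" for penalized ones
    rows <- data.frame(covariate = keep,
                       beta = co[seq_along(keep), "coef"],
                       ci_lo = co[seq_along(keep), "coef"] -
                         1.96 * co[seq_along(keep), se_col],
                       ci_hi = co[seq_along(keep), "coef"] +
                         1.96 * co[seq_along(keep), se_col],
                       p = co[seq_along(keep), p_col],
                       n = nrow(dd), n_events = sum(dd$event),
                       concordance = unname(s$concordance[1]),
                       scope = scope, flag = flag, stringsAsFactors = FALSE)
    list(rows = rows, fit = fit)
  }

  pooled <- fit_one(d, "pooled")
  res <- pooled$rows
  if (by_age_bin) {
    d$age_bin <- cut(d$age_first_obs, c(50, 60, 70, 80, Inf), right = FALSE,
                     labels = c("50-59", "60-69", "70-79", "80+"))
    for (b in levels(d$age_bin)) {
      sub <- d[!is.na(d$age_bin) & d$age_bin == b, ]
      if (nrow(sub) >= 20 && sum(sub$event) >= 5) {
        r <- tryCatch(fit_one(sub, paste0("age:", b)), error = function(e) NULL)
        if (!is.null(r)) res <- rbind(res, r$rows)
      }
    }
  }
  if (by_cohort) {
    for (co_name in unique(d$cohort)) {
      sub <- d[d$cohort == co_name, ]
      if (nrow(sub) >= 20 && sum(sub$event) >= 5) {
        r <- tryCatch(fit_one(sub, paste0("cohort:", co_name)),
                      error = function(e) NULL)
        if (!is.null(r)) res <- rbind(res, r$rows)
      }
    }
  }
  rownames(res) <- NULL
  list(results = res, fit = pooled$fit)
}
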