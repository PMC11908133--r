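# Blood-marker normalization and the longitudinal linear-mixed-model stage.

power_transforms <- list(
  identity = list(domain = function(v) TRUE, f = function(v, l) v),
  log = list(domain = function(v) all(v > 0), f = function(v, l) log(v)),
  sqrt = list(domain = function(v) all(v >= 0), f = function(v, l) sqrt(v)),
  boxcox = list(domain = function(v) all(v > 0),
                f = function(v, l) if (abs(l) < 1e-8) log(v) else (v^l - 1) / l),
  yeojohnson = list(domain = function(v) TRUE, f = function(v, l) {
    pos <- v >= 0
    out <- numeric(length(v))
    out[pos] <- if (abs(l) < 1e-8) log1p(v[pos]) else ((v[pos] + 1)^l - 1) / l
    out[!pos] <- if (abs(l - 2) < 1e-8) -log1p(-v[!pos])
                 else -((1 - v[!pos])^(2 - l) - 1) / (2 - l)
    out
  }))

shapiro_w <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) < 3 || stats::sd(v) == 0) return(NA_real_)
  if (length(v) > 5000) v <- v[round(seq(1, length(v), length.out = 5000))]
  tryCatch(stats::shapiro.test(v)$statistic, error = function(e) NA_real_)
}

#' Normalize one blood-marker series within a cohort
#'
#' The three-step standardization applied to each (marker, cohort) cell
#' before longitudinal modelling: (1) remove outliers beyond
#' `Q1 - 3 IQR` / `Q3 + 3 IQR`; (2) select, among identity, log, square
#' root, Box-Cox and Yeo-Johnson (log and square root only on valid
#' domains; power-transform lambdas chosen on a grid), the transform whose
#' output maximizes the Shapiro-Wilk normality statistic W; (3) z-score
#' the transformed values (cohort mean 0, SD 1 over retained values).
#' Binary markers (exactly two distinct values) are returned untouched with
#' `is_binary = TRUE`.
#'
#' @param values Numeric vector of marker measurements.
#' @param min_n Minimum number of non-missing values (default 8; below
#'   that the marker is skipped).
#' @param lambda_grid Lambda grid for Box-Cox / Yeo-Johnson (default
#'   `seq(-2, 2, 0.1)`).
#' @return A list: `values` (standardized, `NA` where removed or skipped),
#'   `kept` (logical), `transform`, `lambda`, `shapiro_w`, `is_binary`,
#'   `flag` (`NA`, `"too-few"`, or `"zero-variance"`).
#' @export
normalize_marker <- function(values, min_n = 8,
                             lambda_grid = seq(-2, 2, by = 0.1)) {
  out <- list(values = rep(NA_real_, length(values)), kept = !is.na(values),
              transform = NA_character_, lambda = NA_real_,
              shapiro_w = NA_real_, is_binary = FALSE, flag = NA_character_)
  v_ok <- values[!is.na(values)]
  if (length(unique(v_ok)) == 2L) {
    out$is_binary <- TRUE
    out$transform <- "none"
    out$values <- values
    return(out)
  }
  if (length(v_ok) < min_n) { out$flag <- "too-few"; out$kept[] <- FALSE; return(out) }
  qs <- stats::quantile(v_ok, c(0.25, 0.75), names = FALSE)
  iqr <- qs[2] - qs[1]
  lo <- qs[1] - 3 * iqr; hi <- qs[2] + 3 * iqr
  keep <- !is.na(values) & values >= lo & values <= hi
  v <- values[keep]
  if (stats::sd(v) == 0) { out$flag <- "zero-variance"; out$kept[] <- FALSE; return(out) }
  best <- list(w = -Inf)
  for (nm in names(power_transforms)) {
    tr <- power_transforms[[nm]]
    if (!tr$domain(v)) next
    lambdas <- if (nm %in% c("boxcox", "yeojohnson")) lambda_grid else NA_real_
    for (l in lambdas) {
      tv <- tr$f(v, l)
      if (any(!is.finite(tv))) next
      w <- shapiro_w(tv)
      if (!is.na(w) && w > best$w)
        best <- list(w = w, name = nm, lambda = l, tv = tv)
    }
  }
  if (!is.finite(best$w)) { out$flag <- "zero-variance"; out$kept[] <- FALSE; return(out) }
  z <- (best$tv - mean(best$tv)) / stats::sd(best$tv)
  out$values[keep] <- z
  out$kept <- keep
  out$transform <- best$name
  out$lambda <- best$lambda
  out$shapiro_w <- unname(best$w)
  out
}

#' Normalize a long marker table
#'
#' Applies [normalize_marker()] within each (cohort, marker) cell of a
#' long marker table.
#'
#' @param markers Data.frame from [read_marker_table()] /
#'   [simulate_markers()].
#' @return A list with `markers` (input plus a `value_std` column; removed
#'   or skipped rows are `NA`) and `report` (one row per cohort x marker:
#'   transform chosen, lambda, Shapiro-Wilk W, counts, flag).
#' @export
normalize_markers <- function(markers) {
  markers$value_std <- NA_real_
  rep_rows <- list()
  for (co in unique(markers$cohort)) for (mk in unique(markers$marker_name)) {
    idx <- which(markers$cohort == co & markers$marker_name == mk)
    if (!length(idx)) next
    nm <- normalize_marker(markers$value[idx])
    markers$value_std[idx] <- if (nm$is_binary) markers$value[idx] else nm$values
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      cohort = co, marker_name = mk, n = length(idx),
      n_removed = sum(!nm$kept & !is.na(markers$value[idx])),
      transform = nm$transform, lambda = nm$lambda, shapiro_w = nm$shapiro_w,
      is_binary = nm$is_binary, flag = nm$flag, stringsAsFactors = FALSE)
  }
  list(markers = markers, report = do.call(rbind, rep_rows))
}

#' Longitudinal marker associations via linear mixed models
#'
#' Fits, for each marker, the mixed model
#' `marker ~ age * maxVAF + maxFitness + MACS120` with a participant
#' random intercept (age centered on the scope mean; metric covariates
#' z-scored), and reports the coefficients of interest with Wald 95%
#' confidence intervals. The `age:maxVAF` interaction carries the
#' rate-of-change interpretation; interactions of age with maxFitness and
#' MACS120 can be added with `extra_interactions = TRUE`. P-values are
#' adjusted per predictor across the marker panel with the two-stage
#' Benjamini-Hochberg procedure ([bky_adjust()]).
#'
#' @param markers Standardized long marker table (needs `value_std`;
#'   output of [normalize_markers()]).
#' @param metrics Metrics table with z-scored columns ([cohort_metrics()]
#'   or [truth_metrics()]).
#' @param scope `"pooled"` (default) or `"cohort"` (fit each cohort
#'   separately).
#' @param fdr FDR level for the adaptive adjustment (default 0.05).
#' @param extra_interactions Also fit `age:maxFitness` and `age:MACS120`
#'   (default `FALSE`, the formula as printed).
#' @return Data.frame of association results: `outcome`, `predictor`,
#'   `beta`, `ci_lo`, `ci_hi`, `p`, `p_adj`, `n`, `scope`, `flag`.
#' @export
fit_marker_lmm <- function(markers, metrics, scope = c("pooled", "cohort"),
                           fdr = 0.05, extra_interactions = FALSE) {
  scope <- match.arg(scope)
  scopes <- if (scope == "pooled") list(pooled = markers) else
    split(markers, markers$cohort)
  out <- list()
  for (sc in names(scopes)) {
    mtab <- scopes[[sc]]
    for (mk in unique(mtab$marker_name)) {
      rows <- mtab[mtab$marker_name == mk & !is.na(mtab$value_std), ]
      nv <- table(rows$participant_id)
      rows <- rows[rows$participant_id %in% names(nv)[nv >= 2], ]
      res_flag <- NA_character_
      if (!nrow(rows) || length(unique(rows$participant_id)) < 10) {
        out[[length(out) + 1L]] <- data.frame(
          outcome = mk, predictor = NA_character_, beta = NA_real_,
          ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_, p_adj = NA_real_,
          n = length(unique(rows$participant_id)), scope = sc,
          flag = "skipped", stringsAsFactors = FALSE)
        next
      }
      d <- merge(rows, metrics, by = "participant_id")
      d$age_c <- d$age - mean(d$age)
      form <- value_std ~ age_c * z_max_vaf + z_max_fitness + z_macs120 +
        (1 | participant_id)
      if (extra_interactions)
        form <- stats::update(form, . ~ . + age_c:z_max_fitness + age_c:z_macs120)
      fit <- tryCatch(
        suppressMessages(lme4::lmer(form, data = d,
                                    control = lme4::lmerControl(calc.derivs = FALSE))),
        error = function(e) NULL)
      if (is.null(fit)) {
        res_flag <- "nonconvergence"
        co <- NULL
      } else {
        if (lme4::isSingular(fit, tol = 1e-5)) {
          # degenerate random intercept; fall back to the fixed-effect fit
          res_flag <- "singular-refit"
          lmfit <- stats::lm(lme4::nobars(form), data = d)
          co <- summary(lmfit)$coefficients[, 1:2, drop = FALSE]
        } else {
          co <- summary(fit)$coefficients[, 1:2, drop = FALSE]
        }
      }
      preds <- c("z_max_vaf", "age_c:z_max_vaf", "z_max_fitness", "z_macs120",
                 if (extra_interactions) c("age_c:z_max_fitness", "age_c:z_macs120"))
      for (pr in preds) {
        beta <- se <- NA_real_
        if (!is.null(co) && pr %in% rownames(co)) {
          beta <- co[pr, 1]; se <- co[pr, 2]
        }
        p <- if (is.na(beta)) NA_real_ else 2 * stats::pnorm(-abs(beta / se))
        out[[length(out) + 1L]] <- data.frame(
          outcome = mk, predictor = pr, beta = beta,
          ci_lo = beta - 1.96 * se, ci_hi = beta + 1.96 * se, p = p,
          p_adj = NA_real_, n = length(unique(d$participant_id)), scope = sc,
          flag = res_flag, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  # adaptive FDR per predictor across the marker panel, within scope;
  # flagged fits are excluded from the correction
  for (sc in unique(res$scope)) for (pr in unique(stats::na.omit(res$predictor))) {
    idx <- which(res$scope == sc & res$predictor == pr &
                   (is.na(res$flag) | res$flag == "singular-refit"))
    if (length(idx)) res$p_adj[idx] <- bky_adjust(res$p[idx], fdr)
  }
  rownames(res) <- NULL
  res
}
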