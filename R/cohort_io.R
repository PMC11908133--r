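#' Read a long-format longitudinal variant-call table
#'
#' Reads one row per (participant, variant, visit) from a TSV or CSV file
#' into the package's observation table. The VAF is recomputed as
#' `alt_reads / depth` whenever both are present; a `vaf` column is used
#' only as a fallback. Column names may be remapped through `aliases`.
#'
#' Canonical columns: `participant_id`, `cohort`, `gene`, `variant`, `age`,
#' `alt_reads`, `depth`; optional: `unique_alt_reads`, `vaf`, `gnomad_p`.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param aliases Named character vector mapping canonical names to the
#'   column names used in the file, e.g. `c(alt_reads = "AO")`.
#' @return A `data.frame` of validated mutation observations (one row per
#'   observation) with the canonical columns above.
#' @seealso [apply_variant_filters()], [build_trajectories()]
#' @export
read_variant_table <- function(path, dialect = c("tsv", "csv"), aliases = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    condition_error(paste0("file not found: ", path), "clonedyn_io_error")
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  nm <- names(raw)
  if (!is.null(aliases)) {
    for (canon in names(aliases)) nm[nm == aliases[[canon]]] <- canon
    names(raw) <- nm
  }
  required <- c("participant_id", "cohort", "gene", "variant", "age",
                "alt_reads", "depth")
  miss <- setdiff(required, nm)
  if (length(miss))
    condition_error(paste0("missing required column(s): ",
                           paste(miss, collapse = ", ")),
                    "clonedyn_schema_error")
  if (nrow(raw) == 0L)
    condition_error("variant table has a header but no data rows",
                    "clonedyn_empty_input_error")
  num_cols <- c("age", "alt_reads", "depth",
                intersect(c("unique_alt_reads", "vaf", "gnomad_p"), nm))
  out <- raw
  for (col in num_cols) {
    v <- raw[[col]]
    v[v %in% c("", "NA", ".")] <- NA
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad))
      condition_error(sprintf("unparsable numeric value '%s' in column '%s' at data row %d",
                              v[bad[1]], col, bad[1]),
                      "clonedyn_row_error")
    out[[col]] <- parsed
  }
  if (!"unique_alt_reads" %in% nm) out$unique_alt_reads <- NA_real_
  if (!"gnomad_p" %in% nm) out$gnomad_p <- NA_real_
  if (!"vaf" %in% nm) out$vaf <- NA_real_
  validate_observations(out)
}

# Row-level validation shared by readers and the simulator.
validate_observations <- function(obs) {
  bad_depth <- which(!is.na(obs$depth) & obs$depth <= 0)
  if (length(bad_depth))
    condition_error(sprintf("non-positive depth at data row %d", bad_depth[1]),
                    "clonedyn_row_error")
  bad_age <- which(is.na(obs$age) | obs$age <= 0)
  if (length(bad_age))
    condition_error(sprintf("missing or non-positive age at data row %d", bad_age[1]),
                    "clonedyn_row_error")
  bad_ao <- which(is.na(obs$alt_reads) | obs$alt_reads < 0 |
                    obs$alt_reads > obs$depth)
  if (length(bad_ao))
    condition_error(sprintf("alt_reads missing, negative, or exceeding depth at data row %d",
                            bad_ao[1]),
                    "clonedyn_row_error")
  # prefer exact recomputation over a reported VAF column
  obs$vaf <- ifelse(!is.na(obs$alt_reads) & !is.na(obs$depth),
                    obs$alt_reads / obs$depth, obs$vaf)
  keep <- c("participant_id", "cohort", "gene", "variant", "age",
            "alt_reads", "unique_alt_reads", "depth", "vaf", "gnomad_p")
  obs <- obs[, keep]
  rownames(obs) <- NULL
  obs
}

#' Write a variant table
#'
#' Inverse of [read_variant_table()]; full-precision round trip.
#'
#' @param obs Observation data.frame.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(obs, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  fmt <- obs
  for (col in names(fmt))
    if (is.numeric(fmt[[col]]))
      fmt[[col]] <- ifelse(is.na(fmt[[col]]), "NA",
                           format(fmt[[col]], digits = 17, trim = TRUE,
                                  scientific = FALSE))
  utils::write.table(fmt, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a covariate / survival table
#'
#' Columns: `participant_id`, `cohort`, `sex`, `age_first_obs`, and
#' optionally `followup_years` and `event` (0/1).
#'
#' @param path Path to a TSV file.
#' @return A `data.frame`.
#' @export
read_covariate_table <- function(path) {
  if (!file.exists(path))
    condition_error(paste0("file not found: ", path), "clonedyn_io_error")
  cov <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("participant_id", "sex", "age_first_obs")
  miss <- setdiff(need, names(cov))
  if (length(miss))
    condition_error(paste0("missing required column(s): ",
                           paste(miss, collapse = ", ")),
                    "clonedyn_schema_error")
  cov
}

#' Read a longitudinal blood-marker table
#'
#' Columns: `participant_id`, `cohort`, `age`, `marker_name`, `value`.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame`.
#' @export
read_marker_table <- function(path) {
  if (!file.exists(path))
    condition_error(paste0("file not found: ", path), "clonedyn_io_error")
  mk <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("participant_id", "cohort", "age", "marker_name", "value")
  miss <- setdiff(need, names(mk))
  if (length(miss))
    condition_error(paste0("missing required column(s): ",
                           paste(miss, collapse = ", ")),
                    "clonedyn_schema_error")
  mk
}

#' Filter somatic variant calls
#'
#' Applies the study-style call-level filters to an observation table. A
#' variant (one `participant_id` + `gene` + `variant` trajectory) passes if
#' at **any** visit it simultaneously satisfies: VAF >= `min_vaf`,
#' alt reads (AO) >= `min_ao`, unique-start alt reads (UAO) missing or
#' >= `min_uao`, and gnomAD p-value missing or <= `gnomad_alpha`
#' (significant under-representation in the population database argues
#' against a germline origin). Variants whose VAF sits inside a tolerance
#' band around 0.5 or 1.0 at *every* visit are rejected as stable germline
#' calls regardless of the other rules. Once a variant passes at any visit,
#' *all* of its participant-matched observations are kept, regardless of
#' their individual VAF, so trajectories retain their sub-threshold visits.
#'
#' Filtering never raises: rows that cannot be assessed are rejected with
#' reason `"malformed"`. Rejection reasons per observation are
#' `"germline-stable"`, `"denylisted"`, or the first failing rule among
#' `"VAF"`, `"AO"`, `"UAO"`, `"gnomad"`.
#'
#' @param obs Observation data.frame from [read_variant_table()].
#' @param min_vaf Minimum VAF at the qualifying visit (default 0.01; the
#'   study's alternative threshold 0.02 is also supported).
#' @param min_ao Minimum alt-read count (default 5).
#' @param min_uao Minimum unique-start alt-read count (default 3).
#' @param gnomad_alpha Maximum gnomAD p-value (default 0.05).
#' @param germline_tol Half-width of the germline VAF stability band
#'   around 0.5 and 1.0 (default 0.05).
#' @param denylist Optional character vector of `"gene:variant"` labels to
#'   reject (manual curation / artifact list); `allowlist` forces keeping.
#' @param allowlist Optional character vector of `"gene:variant"` labels
#'   exempt from all rules.
#' @return A list with `kept` (observation data.frame) and `rejected`
#'   (observation data.frame with an extra `reason` column).
#' @examples
#' obs <- data.frame(participant_id = "P1", cohort = "synthetic",
#'                   gene = "DNMT3A", variant = "R882H",
#'                   age = c(70, 76), alt_reads = c(30, 60),
#'                   unique_alt_reads = NA, depth = 2000,
#'                   vaf = c(0.015, 0.03), gnomad_p = NA)
#' apply_variant_filters(obs)$kept
#' @export
apply_variant_filters <- function(obs, min_vaf = 0.01, min_ao = 5,
                                  min_uao = 3, gnomad_alpha = 0.05,
                                  germline_tol = 0.05,
                                  denylist = NULL, allowlist = NULL) {
  if (nrow(obs) == 0L)
    return(list(kept = obs, rejected = cbind(obs, reason = character(0))))
  obs$vaf <- ifelse(!is.na(obs$alt_reads) & !is.na(obs$depth) & obs$depth > 0,
                    obs$alt_reads / obs$depth, obs$vaf)
  key <- paste(obs$participant_id, obs$gene, obs$variant, sep = "\r")
  lab <- paste(obs$gene, obs$variant, sep = ":")
  malformed <- is.na(obs$vaf) | is.na(obs$depth) | obs$depth <= 0 |
    is.na(obs$alt_reads) | obs$alt_reads < 0 | obs$alt_reads > obs$depth
  reason <- rep(NA_character_, nrow(obs))
  reason[malformed] <- "malformed"

  for (k in unique(key)) {
    idx <- which(key == k & !malformed)
    if (!length(idx)) next
    if (lab[idx[1]] %in% allowlist) next
    if (lab[idx[1]] %in% denylist) { reason[idx] <- "denylisted"; next }
    v <- obs$vaf[idx]
    germline <- all(abs(v - 0.5) <= germline_tol | abs(v - 1.0) <= germline_tol)
    if (germline) { reason[idx] <- "germline-stable"; next }
    ok_vaf <- v >= min_vaf
    ok_ao <- obs$alt_reads[idx] >= min_ao
    ok_uao <- is.na(obs$unique_alt_reads[idx]) | obs$unique_alt_reads[idx] >= min_uao
    ok_gno <- is.na(obs$gnomad_p[idx]) | obs$gnomad_p[idx] <= gnomad_alpha
    if (any(ok_vaf & ok_ao & ok_uao & ok_gno)) next  # variant passes; keep all visits
    first_fail <- function(i) {
      if (!ok_vaf[i]) "VAF" else if (!ok_ao[i]) "AO"
      else if (!ok_uao[i]) "UAO" else "gnomad"
    }
    reason[idx] <- vapply(seq_along(idx), first_fail, character(1))
  }
  rej <- !is.na(reason)
  rejected <- obs[rej, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[rej] else rejected$reason <- character(0)
  rownames(rejected) <- NULL
  kept <- obs[!rej, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Group filtered observations into per-participant trajectories
#'
#' Groups observations by (participant, gene, variant) into age-ordered
#' trajectories and assembles one record per participant. Participants
#' present in `covariates` but with no surviving variants are still
#' emitted with an empty trajectory list so that the survival and marker
#' stages see the whole roster.
#'
#' @param obs Filtered observation data.frame.
#' @param covariates Optional covariate/survival data.frame
#'   ([read_covariate_table()]).
#' @param markers Optional long marker data.frame ([read_marker_table()]).
#' @return A named list of `ch_participant` objects, each with fields
#'   `participant_id`, `cohort`, `sex`, `age_first_obs`, `trajectories`
#'   (named list of age-sorted observation data.frames), `survival`
#'   (`c(time, event)` or `NULL`) and `markers`.
#' @export
build_trajectories <- function(obs, covariates = NULL, markers = NULL) {
  key <- paste(obs$participant_id, obs$gene, obs$variant, sep = "\r")
  dup <- duplicated(paste(key, obs$age, sep = "\r"))
  if (any(dup)) {
    d <- which(dup)[1]
    condition_error(sprintf("duplicate record for participant '%s', variant '%s:%s', age %g",
                            obs$participant_id[d], obs$gene[d], obs$variant[d],
                            obs$age[d]),
                    "clonedyn_duplicate_error")
  }
  ids <- unique(c(obs$participant_id,
                  if (!is.null(covariates)) covariates$participant_id))
  out <- lapply(ids, function(pid) {
    rows <- obs[obs$participant_id == pid, , drop = FALSE]
    trajs <- list()
    if (nrow(rows)) {
      for (k in unique(paste(rows$gene, rows$variant, sep = ":"))) {
        tr <- rows[paste(rows$gene, rows$variant, sep = ":") == k, , drop = FALSE]
        tr <- tr[order(tr$age), , drop = FALSE]
        rownames(tr) <- NULL
        trajs[[k]] <- tr
      }
    }
    cv <- if (!is.null(covariates))
      covariates[covariates$participant_id == pid, , drop = FALSE]
    surv <- NULL
    if (!is.null(cv) && nrow(cv) && all(c("followup_years", "event") %in% names(cv)))
      surv <- c(time = cv$followup_years[1], event = cv$event[1])
    mk <- if (!is.null(markers))
      markers[markers$participant_id == pid, , drop = FALSE]
    structure(list(
      participant_id = pid,
      cohort = if (nrow(rows)) rows$cohort[1]
               else if (!is.null(cv) && nrow(cv) && "cohort" %in% names(cv)) cv$cohort[1]
               else NA_character_,
      sex = if (!is.null(cv) && nrow(cv)) cv$sex[1] else NA_character_,
      age_first_obs = if (nrow(rows)) min(rows$age)
                      else if (!is.null(cv) && nrow(cv)) cv$age_first_obs[1]
                      else NA_real_,
      trajectories = trajs,
      survival = surv,
      markers = mk), class = "ch_participant")
  })
  names(out) <- ids
  out
}

#' @exportS3Method base::print
print.ch_participant <- function(x, ...) {
  cat("Participant", x$participant_id, "(", x$cohort, "):",
      length(x$trajectories), "variant trajectory(ies)")
  if (length(x$trajectories)) {
    ages <- sort(unique(unlist(lapply(x$trajectories, `[[`, "age"))))
    cat("; visits at ages", paste(round(ages, 1), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}
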