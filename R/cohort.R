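# Cohort data model: one row per animal (wide layout), columns
#   animal_id, group ("therapy"/"control"),
#   ttl_baseline, ttl_followup,
#   mtv_baseline_mm3, mtv_followup_mm3,
#   adc_baseline_mm2s, adc_followup_mm2s,
#   vol_baseline_mm3, vol_followup_mm3,
#   cd31, ki67 (terminal IHC counts).
# ADC is carried in mm^2/s everywhere; the x10^-3 scale is applied only
# when reporting.

cohort_value_cols <- c("ttl_baseline", "ttl_followup",
                       "mtv_baseline_mm3", "mtv_followup_mm3",
                       "adc_baseline_mm2s", "adc_followup_mm2s",
                       "vol_baseline_mm3", "vol_followup_mm3",
                       "cd31", "ki67")

#' Paths to the packaged study tables
#'
#' Locations of the three plain-text fixtures transcribing the study's
#' per-animal tables: PET (TTL and metabolic tumor volume), MRI (ADC and
#' morphological tumor volume), and terminal immunohistochemistry (CD31,
#' Ki-67) for 12 therapy and 9 control animals.
#'
#' @return Named character vector of CSV paths (`pet`, `mri`, `ihc`).
#' @export
study_table_paths <- function() {
  c(pet = system.file("extdata", "table1_pet.csv", package = "petdwi"),
    mri = system.file("extdata", "table2_mri.csv", package = "petdwi"),
    ihc = system.file("extdata", "table3_ihc.csv", package = "petdwi"))
}

read_fixture_csv <- function(path, required, label) {
  if (!file.exists(path)) stop("cohort table not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse ", label, " (", path, "): ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L) stop(label, ": no data rows in ", path, call. = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(label, ": missing required column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(required, c("group", "timepoint"))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop(label, ": non-numeric value in column `", col, "`, row ", bad,
           call. = FALSE)
    }
  }
  bad_group <- which(!df$group %in% c("T", "C", "therapy", "control"))
  if (length(bad_group)) {
    stop(label, ": unknown group label `", df$group[bad_group[1L]],
         "` in row ", bad_group[1L], call. = FALSE)
  }
  df$group <- ifelse(df$group %in% c("T", "therapy"), "therapy", "control")
  df
}

#' Load a cohort from wide per-animal tables
#'
#' Reads the three-table wide layout (the canonical fixture layout: one row
#' per animal, paired baseline/follow-up columns) and merges on
#' `animal_id`. Group labels `T`/`C` are mapped to `therapy`/`control`.
#' Printed delta columns present in the fixtures are ignored: deltas are
#' always recomputed from the timepoint columns (see [compute_deltas()]).
#'
#' @param pet,mri,ihc CSV paths; default to the packaged study tables.
#' @return A `cohort_table` data frame.
#' @examples
#' coh <- load_cohort()
#' nrow(coh); table(coh$group)
#' @export
load_cohort <- function(pet = study_table_paths()[["pet"]],
                        mri = study_table_paths()[["mri"]],
                        ihc = study_table_paths()[["ihc"]]) {
  t_pet <- read_fixture_csv(pet, c("animal_id", "group", "ttl_baseline",
                                   "ttl_followup", "mtv_baseline_mm3",
                                   "mtv_followup_mm3"), "PET table")
  t_mri <- read_fixture_csv(mri, c("animal_id", "group", "adc_baseline_mm2s",
                                   "adc_followup_mm2s", "vol_baseline_mm3",
                                   "vol_followup_mm3"), "MRI table")
  t_ihc <- read_fixture_csv(ihc, c("animal_id", "group", "cd31", "ki67"),
                            "IHC table")
  keep <- function(df, cols) df[, c("animal_id", "group", cols)]
  out <- merge(keep(t_pet, c("ttl_baseline", "ttl_followup",
                             "mtv_baseline_mm3", "mtv_followup_mm3")),
               keep(t_mri, c("adc_baseline_mm2s", "adc_followup_mm2s",
                             "vol_baseline_mm3", "vol_followup_mm3")),
               by = c("animal_id", "group"))
  out <- merge(out, keep(t_ihc, c("cd31", "ki67")), by = c("animal_id", "group"))
  if (nrow(out) != nrow(t_pet)) {
    stop("load_cohort: tables do not describe the same animals ",
         "(merge on animal_id/group dropped rows)", call. = FALSE)
  }
  out <- out[order(out$animal_id), ]
  rownames(out) <- NULL
  validate_cohort(out)
}

#' Read / write a cohort in long (pipeline) layout
#'
#' The long layout is what the phantom pipeline writes: one row per animal
#' per timepoint with header
#' `animal_id,group,timepoint,ttl,mtv_mm3,adc_mm2s,vol_mm3,cd31,ki67`
#' (IHC counts are terminal-only and repeated on both rows).
#'
#' @param path CSV path.
#' @param cohort a `cohort_table` (for writing).
#' @return `load_cohort_long()` returns a `cohort_table`;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
load_cohort_long <- function(path) {
  df <- read_fixture_csv(path, c("animal_id", "group", "timepoint", "ttl",
                                 "mtv_mm3", "adc_mm2s", "vol_mm3",
                                 "cd31", "ki67"), "long cohort table")
  if (!all(df$timepoint %in% c("baseline", "followup"))) {
    stop("long cohort table: `timepoint` must be baseline/followup", call. = FALSE)
  }
  wide <- function(tp, col, new) {
    s <- df[df$timepoint == tp, c("animal_id", col)]
    names(s)[2L] <- new
    s
  }
  out <- unique(df[, c("animal_id", "group", "cd31", "ki67")])
  for (spec in list(c("baseline", "ttl", "ttl_baseline"),
                    c("followup", "ttl", "ttl_followup"),
                    c("baseline", "mtv_mm3", "mtv_baseline_mm3"),
                    c("followup", "mtv_mm3", "mtv_followup_mm3"),
                    c("baseline", "adc_mm2s", "adc_baseline_mm2s"),
                    c("followup", "adc_mm2s", "adc_followup_mm2s"),
                    c("baseline", "vol_mm3", "vol_baseline_mm3"),
                    c("followup", "vol_mm3", "vol_followup_mm3"))) {
    out <- merge(out, wide(spec[1], spec[2], spec[3]), by = "animal_id")
  }
  out <- out[order(out$animal_id),
             c("animal_id", "group", cohort_value_cols)]
  rownames(out) <- NULL
  validate_cohort(out)
}

#' @rdname load_cohort_long
#' @export
write_cohort_csv <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  long <- do.call(rbind, lapply(c("baseline", "followup"), function(tp) {
    data.frame(animal_id = cohort$animal_id, group = cohort$group,
               timepoint = tp,
               ttl = cohort[[paste0("ttl_", tp)]],
               mtv_mm3 = cohort[[paste0("mtv_", tp, "_mm3")]],
               adc_mm2s = cohort[[paste0("adc_", tp, "_mm2s")]],
               vol_mm3 = cohort[[paste0("vol_", tp, "_mm3")]],
               cd31 = cohort$cd31, ki67 = cohort$ki67)
  }))
  long <- long[order(long$animal_id, long$timepoint), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

validate_cohort <- function(cohort) {
  missing <- setdiff(c("animal_id", "group", cohort_value_cols), names(cohort))
  if (length(missing)) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(cohort$group %in% c("therapy", "control"))) {
    stop("cohort group labels must be therapy/control", call. = FALSE)
  }
  vols <- unlist(cohort[, grep("mm3$", cohort_value_cols, value = TRUE)])
  if (any(vols < 0)) stop("cohort volumes must be >= 0", call. = FALSE)
  adc <- unlist(cohort[, grep("mm2s$", cohort_value_cols, value = TRUE)])
  if (any(adc <= 0)) stop("cohort ADC values must be > 0", call. = FALSE)
  if (any(cohort$cd31 < 0) || any(cohort$ki67 < 0) ||
      any(cohort$cd31 != round(cohort$cd31)) || any(cohort$ki67 != round(cohort$ki67))) {
    stop("IHC counts must be non-negative integers", call. = FALSE)
  }
  if (!inherits(cohort, "cohort_table")) {
    class(cohort) <- c("cohort_table", class(cohort))
  }
  cohort
}

#' Per-animal delta-response metrics
#'
#' Computes follow-up minus baseline for every imaging biomarker. Deltas
#' are always recomputed from the timepoint columns rather than read from
#' any printed delta column: only the recomputed values reproduce the
#' published group means (the study tables contain one delta cell with a
#' typographical sign flip).
#'
#' @param cohort a `cohort_table`.
#' @return Data frame with `animal_id`, `group`, `d_ttl`, `d_mtv_mm3`,
#'   `d_adc_mm2s`, `d_vol_mm3`.
#' @export
compute_deltas <- function(cohort) {
  cohort <- validate_cohort(cohort)
  data.frame(animal_id = cohort$animal_id, group = cohort$group,
             d_ttl = cohort$ttl_followup - cohort$ttl_baseline,
             d_mtv_mm3 = cohort$mtv_followup_mm3 - cohort$mtv_baseline_mm3,
             d_adc_mm2s = cohort$adc_followup_mm2s - cohort$adc_baseline_mm2s,
             d_vol_mm3 = cohort$vol_followup_mm3 - cohort$vol_baseline_mm3)
}

#' Group summary: n, mean, sample SD
#'
#' The "mean +- SD" summary used throughout: arithmetic mean and sample
#' standard deviation (n - 1 denominator). Rounding happens only at report
#' time.
#'
#' @param values numeric vector of per-animal values (n >= 2).
#' @param group group label carried into the result.
#' @param biomarker biomarker name carried into the result.
#' @return A one-row data frame: `biomarker`, `group`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(values, group = NA_character_,
                          biomarker = NA_character_) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("group_summary: need n >= 2 for a mean +- SD summary", call. = FALSE)
  }
  if (anyNA(values)) stop("group_summary: NA in values", call. = FALSE)
  data.frame(biomarker = biomarker, group = group, n = length(values),
             mean = mean(values), sd = stats::sd(values))
}

#' All group summaries of a cohort
#'
#' Convenience wrapper over [group_summary()]: every biomarker at baseline,
#' follow-up, and delta (plus terminal IHC), per group.
#'
#' @param cohort a `cohort_table`.
#' @return Data frame of summaries, one row per biomarker x group.
#' @export
cohort_summaries <- function(cohort) {
  cohort <- validate_cohort(cohort)
  deltas <- compute_deltas(cohort)
  cols <- c(stats::setNames(cohort_value_cols, cohort_value_cols),
            d_ttl = "d_ttl", d_mtv_mm3 = "d_mtv_mm3",
            d_adc_mm2s = "d_adc_mm2s", d_vol_mm3 = "d_vol_mm3")
  rows <- list()
  for (nm in names(cols)) {
    src <- if (startsWith(nm, "d_")) deltas else cohort
    for (g in c("therapy", "control")) {
      rows[[paste(nm, g)]] <- group_summary(src[[nm]][src$group == g],
                                            group = g, biomarker = nm)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
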