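#' Subject-level cohort data
#'
#' A study cohort is a plain `data.frame` with class `"study_cohort"` and one
#' row per participant. Required columns: `id` (unique strings), `group`
#' (one of `"NC"`, `"NF"`, `"MILD"`, `"MAJOR"`), `age` (years), `education`
#' (years), `sex` (`"F"`/`"M"`), `moca_raw` and `mmse` (integers 0-30), and
#' `moca_z` (real, may be `NA`). The education-adjusted score `moca_adj` is
#' always recomputed with [education_adjust()] — never read from file — so the
#' +1-point education rule has a single source of truth.
#'
#' The patient pool is the union of the `MILD` and `MAJOR` groups; `MILD` is a
#' subgroup of that pool, not a disjoint diagnosis of its own.
#'
#' @param records data.frame with the columns above (without `moca_adj`).
#' @param provenance free-text origin of the data (file path, or simulation
#'   seed and parameter digest).
#' @return A `study_cohort` data.frame with `moca_adj` filled in and the
#'   provenance stored in `attr(, "provenance")`.
#' @seealso [read_cohort()], [simulate_study()], [validate_record()]
#' @export
study_cohort <- function(records, provenance = "unspecified") {
  required <- c("id", "group", "age", "education", "sex", "moca_raw", "mmse")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"moca_z" %in% names(records)) records$moca_z <- NA_real_

  df <- data.frame(
    id        = as.character(records$id),
    group     = toupper(as.character(records$group)),
    age       = as.numeric(records$age),
    education = as.integer(records$education),
    sex       = toupper(as.character(records$sex)),
    moca_raw  = as.integer(records$moca_raw),
    mmse      = as.integer(records$mmse),
    moca_z    = as.numeric(records$moca_z),
    stringsAsFactors = FALSE
  )
  df$moca_adj <- education_adjust(df$moca_raw, df$education)

  if (anyDuplicated(df$id)) stop("subject ids must be unique", call. = FALSE)
  bad_group <- setdiff(unique(df$group), GROUP_LEVELS)
  if (length(bad_group) > 0) {
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "),
         "; expected one of ", paste(GROUP_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("moca_raw", "mmse")) {
    v <- df[[col]]
    if (anyNA(v)) {
      stop("column '", col, "' contains missing/unparseable values (row ",
           which(is.na(v))[1], ")", call. = FALSE)
    }
    if (any(v < 0L | v > SCORE_MAX)) {
      stop("column '", col, "' outside score range [0,", SCORE_MAX, "] at row ",
           which(v < 0L | v > SCORE_MAX)[1], call. = FALSE)
    }
  }
  if (any(!df$sex %in% c("F", "M"))) {
    stop("sex must be 'F' or 'M' (row ", which(!df$sex %in% c("F", "M"))[1],
         ")", call. = FALSE)
  }

  structure(df, provenance = provenance,
            class = c("study_cohort", "data.frame"))
}

#' @export
print.study_cohort <- function(x, ...) {
  cat("study_cohort:", nrow(x), "subjects\n")
  tab <- table(factor(x$group, levels = GROUP_LEVELS))
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat("  provenance:", attr(x, "provenance"), "\n")
  invisible(x)
}

#' Read a cohort from a delimited text file
#'
#' Expects a header row with columns `id, group, age, education, sex,
#' moca_raw, mmse, moca_z` (`moca_z` optional; empty cells become `NA`).
#' Group labels are case-insensitive on read. Every row is validated against
#' the score-range invariants; a malformed file fails with an error naming the
#' offending column or row.
#'
#' @param path file path.
#' @param delim field delimiter, `","` (default) or `"\t"`.
#' @return A [study_cohort()] with the file path as provenance.
#' @export
read_cohort <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, sep = delim, stringsAsFactors = FALSE,
                  colClasses = "character")
  for (col in c("age", "education", "moca_raw", "mmse")) {
    if (col %in% names(raw)) {
      v <- suppressWarnings(as.numeric(raw[[col]]))
      if (any(is.na(v) & nzchar(trimws(raw[[col]])))) {
        bad <- which(is.na(v) & nzchar(trimws(raw[[col]])))[1]
        stop("unparseable value in column '", col, "' at data row ", bad,
             call. = FALSE)
      }
      raw[[col]] <- v
    }
  }
  if ("moca_z" %in% names(raw)) {
    raw$moca_z <- suppressWarnings(as.numeric(raw$moca_z))
  }
  raw$moca_adj <- NULL  # always recomputed
  study_cohort(raw, provenance = path)
}

#' Write a cohort to CSV
#'
#' Fixed column order (`id, group, age, education, sex, moca_raw, mmse,
#' moca_z`), canonical uppercase labels, deterministic byte-for-byte output for
#' identical input. `moca_adj` is deliberately not written: it is derived.
#'
#' @param ds a [study_cohort()].
#' @param path output path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(ds, path, delim = ",") {
  stopifnot(inherits(ds, "study_cohort"))
  cols <- c("id", "group", "age", "education", "sex", "moca_raw", "mmse",
            "moca_z")
  out <- as.data.frame(ds)[, cols]
  write.table(out, path, sep = delim, row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}

#' Check one subject record against range and inclusion rules
#'
#' Returns a character vector of violations (empty when the record is valid)
#' rather than raising: validation is total. Range invariants (scores in
#' 0-30, adjusted minus raw in \{0, 1\}, known group label) are always
#' checked; the study inclusion rules (age at least 65 years, education at
#' least 7 years) only when `inclusion = TRUE`, so cohorts outside that
#' demographic frame can still be analysed.
#'
#' @param r a list or one-row data.frame with the subject fields.
#' @param inclusion enforce the age/education inclusion rules?
#' @return character vector of violation messages, possibly empty.
#' @export
validate_record <- function(r, inclusion = FALSE) {
  v <- character(0)
  chk_score <- function(val, name) {
    if (is.null(val) || is.na(val)) return(paste0(name, " is missing"))
    if (val < 0 || val > SCORE_MAX)
      return(paste0(name, " outside [0,", SCORE_MAX, "]"))
    NULL
  }
  for (nm in c("moca_raw", "mmse")) {
    msg <- chk_score(r[[nm]], nm)
    if (!is.null(msg)) v <- c(v, msg)
  }
  if (!is.null(r$moca_adj) && !is.na(r$moca_adj)) {
    msg <- chk_score(r$moca_adj, "moca_adj")
    if (!is.null(msg)) v <- c(v, msg)
    if (!is.null(r$moca_raw) && !is.na(r$moca_raw) &&
        !(r$moca_adj - r$moca_raw) %in% c(0, 1)) {
      v <- c(v, "moca_adj - moca_raw must be 0 or 1")
    }
  }
  if (is.null(r$group) || !toupper(as.character(r$group)) %in% GROUP_LEVELS) {
    v <- c(v, paste0("group must be one of ",
                     paste(GROUP_LEVELS, collapse = ", ")))
  }
  if (inclusion) {
    if (!is.null(r$age) && !is.na(r$age) && r$age < 65)
      v <- c(v, "inclusion: age >= 65")
    if (!is.null(r$education) && !is.na(r$education) && r$education < 7)
      v <- c(v, "inclusion: education >= 7")
  }
  v
}

#' Extract a score vector for a set of groups
#'
#' @param ds a [study_cohort()].
#' @param groups character vector of group labels.
#' @param score_field one of `"moca_adj"`, `"moca_raw"`, `"moca_z"`, `"mmse"`.
#' @return numeric vector of scores for subjects in `groups`.
#' @export
group_scores <- function(ds, groups,
                         score_field = c("moca_adj", "moca_raw", "moca_z",
                                         "mmse")) {
  score_field <- match.arg(score_field)
  stopifnot(inherits(ds, "study_cohort"))
  groups <- toupper(groups)
  bad <- setdiff(groups, GROUP_LEVELS)
  if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
  ds[[score_field]][ds$group %in% groups]
}
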