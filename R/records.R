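# From coded diagnosis records to per-stratum binary disease matrices.
#
# Two lookup tables drive the reduction: a chronic-condition flag per code
# and a code-to-clinical-category grouping. The package ships only toy
# fixtures; real chronic-condition and category tables (e.g. AHRQ CCI/CCS
# for ICD-9-CM) are external resources supplied by the user in the same TSV
# schema.

#' Code lookup tables (chronic flag + clinical category)
#'
#' @param chronic Data frame with columns `code` and `chronic_flag`
#'   (`"chronic"` / `"not_chronic"`).
#' @param category Data frame with columns `code`, `category_id` (integer)
#'   and `category_label`. Every code present here must also appear in the
#'   chronic table; no code may map to two categories; the category ids must
#'   form a contiguous integer range.
#' @return A `code_lookup` object.
#' @export
code_lookup <- function(chronic, category) {
  req <- setdiff(c("code", "chronic_flag"), names(chronic))
  if (length(req)) stop("chronic table is missing column(s): ", paste(req, collapse = ", "))
  req <- setdiff(c("code", "category_id", "category_label"), names(category))
  if (length(req)) stop("category table is missing column(s): ", paste(req, collapse = ", "))
  if (!all(chronic$chronic_flag %in% c("chronic", "not_chronic"))) {
    stop("chronic_flag must be 'chronic' or 'not_chronic'")
  }
  if (anyDuplicated(chronic$code)) stop("duplicate codes in chronic table")
  if (anyDuplicated(category$code)) stop("a code maps to two categories")
  missing_codes <- setdiff(category$code, chronic$code)
  if (length(missing_codes)) {
    stop("codes in category table but not chronic table: ",
         paste(utils::head(missing_codes, 5), collapse = ", "))
  }
  ids <- sort(unique(category$category_id))
  if (!identical(ids, seq(min(ids), max(ids)))) {
    stop("category_ids must form a contiguous integer range")
  }
  lab <- unique(category[c("category_id", "category_label")])
  if (anyDuplicated(lab$category_id)) stop("a category_id carries two labels")
  structure(list(chronic = chronic, category = category), class = "code_lookup")
}

#' Read lookup tables from TSV files
#'
#' @param chronic_path TSV with columns `code`, `chronic_flag`.
#' @param category_path TSV with columns `code`, `category_id`,
#'   `category_label`.
#' @param sep Field delimiter.
#' @return A [code_lookup()].
#' @export
read_code_lookup <- function(chronic_path, category_path, sep = "\t") {
  code_lookup(
    utils::read.delim(chronic_path, sep = sep, colClasses = "character"),
    utils::read.delim(category_path, sep = sep,
                      colClasses = c(code = "character",
                                     category_id = "integer",
                                     category_label = "character")))
}

#' Read diagnosis records from delimited text
#'
#' Reads long-format diagnosis records (one coded diagnosis event per row)
#' and validates each row: `sex` must be `M`/`F`, `age_band` one of the five
#' canonical bands (en-dash variants tolerated), `coding_system` one of
#' `ICD9CM` / `ICPC1`, and no field empty. Malformed rows are collected into
#' a rejects report with the offending row number and reason; they are never
#' silently dropped. A missing required column is a hard error naming the
#' column.
#'
#' @param path Delimited text file with a header row.
#' @param sep Field delimiter.
#' @param columns Named character vector mapping the canonical names
#'   `patient_id`, `sex`, `age_band`, `code`, `coding_system` to the file's
#'   column names.
#' @return List with `records` (validated data frame in canonical columns)
#'   and `rejects` (data frame `row`, `reason`).
#' @export
read_records <- function(path, sep = "\t",
                         columns = c(patient_id = "patient_id", sex = "sex",
                                     age_band = "age_band", code = "code",
                                     coding_system = "coding_system")) {
  canon <- c("patient_id", "sex", "age_band", "code", "coding_system")
  columns <- columns[canon]
  if (any(is.na(columns))) {
    stop("`columns` must map all of: ", paste(canon, collapse = ", "))
  }
  raw <- utils::read.delim(path, sep = sep, colClasses = "character",
                           check.names = FALSE)
  miss <- setdiff(unname(columns), names(raw))
  if (length(miss)) stop("input is missing column(s): ", paste(miss, collapse = ", "))
  d <- stats::setNames(raw[, unname(columns), drop = FALSE], canon)
  d$age_band <- .norm_band(d$age_band)
  d$sex <- trimws(d$sex)

  reason <- rep(NA_character_, nrow(d))
  bad_sex <- !(d$sex %in% c("M", "F"))
  reason[bad_sex] <- paste("unknown sex token:", d$sex[bad_sex])
  bad_band <- is.na(reason) & !(d$age_band %in% age_bands())
  reason[bad_band] <- paste("unknown age band:", d$age_band[bad_band])
  bad_sys <- is.na(reason) & !(d$coding_system %in% c("ICD9CM", "ICPC1"))
  reason[bad_sys] <- paste("unknown coding system:", d$coding_system[bad_sys])
  bad_empty <- is.na(reason) & (d$patient_id == "" | d$code == "")
  reason[bad_empty] <- "empty patient_id or code"

  ok <- is.na(reason)
  list(records = d[ok, , drop = FALSE],
       rejects = data.frame(row = which(!ok), reason = reason[!ok],
                            stringsAsFactors = FALSE))
}

#' Keep only records whose code is flagged chronic
#'
#' Records whose code is absent from the chronic table are routed to an
#' `unmapped` report (code with record count) rather than silently dropped;
#' records mapped `not_chronic` are removed.
#'
#' @param records Data frame of diagnosis records (canonical columns).
#' @param lookup A [code_lookup()].
#' @return List with `records` (the chronic subset) and `unmapped`
#'   (data frame `code`, `n_records`).
#' @export
filter_chronic <- function(records, lookup) {
  stopifnot(inherits(lookup, "code_lookup"))
  flag <- lookup$chronic$chronic_flag[match(records$code, lookup$chronic$code)]
  unmapped_codes <- records$code[is.na(flag)]
  unmapped <- if (length(unmapped_codes)) {
    tab <- table(unmapped_codes)
    data.frame(code = names(tab), n_records = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    data.frame(code = character(), n_records = integer())
  }
  list(records = records[!is.na(flag) & flag == "chronic", , drop = FALSE],
       unmapped = unmapped)
}

#' Per-stratum binary disease matrix
#'
#' Container for one stratum's patient-by-disease-category indicator grid.
#' Prevalences are always recomputed from the indicators (see
#' [prevalence()]), so they can never drift out of sync.
#'
#' @param indicators Binary matrix, patients in rows (named), disease
#'   categories in columns (named).
#' @param sex,age_band The stratum label.
#' @return A `disease_matrix` object.
#' @export
disease_matrix <- function(indicators, sex, age_band) {
  stopifnot(is.matrix(indicators))
  if (!all(indicators %in% c(0L, 1L))) stop("indicators must be 0/1")
  if (nrow(indicators) > 0 && is.null(rownames(indicators))) {
    stop("indicators must carry patient names")
  }
  if (ncol(indicators) > 0 && is.null(colnames(indicators))) {
    stop("indicators must carry disease names")
  }
  if (ncol(indicators) == 0 && is.null(colnames(indicators))) {
    colnames(indicators) <- character(0)
  }
  structure(list(sex = sex, age_band = age_band,
                 indicators = indicators),
            class = "disease_matrix")
}

#' @export
print.disease_matrix <- function(x, ...) {
  cat(sprintf("Disease matrix, stratum %s %s: %d patients x %d diseases\n",
              x$sex, x$age_band, nrow(x$indicators), ncol(x$indicators)))
  invisible(x)
}

#' Per-disease prevalence of a stratum
#'
#' @param dm A [disease_matrix()].
#' @return Named vector of column means of the indicator grid.
#' @export
prevalence <- function(dm) {
  stopifnot(inherits(dm, "disease_matrix"))
  colMeans(dm$indicators)
}

#' Build per-stratum disease matrices from chronic diagnosis records
#'
#' Maps each record's code to its clinical category and marks the category
#' present for that patient; duplicate diagnoses of the same category are
#' idempotent. Strata are the observed (sex, age band) pairs; each patient
#' belongs to exactly one. A patient whose rows disagree on sex or age band
#' is a hard error (first-seen-wins is not allowed). Codes missing from the
#' category table are excluded and reported via the `unmapped_codes`
#' attribute of the result.
#'
#' @param records Chronic-filtered diagnosis records.
#' @param lookup A [code_lookup()].
#' @param exclude_categories Category labels to drop from every matrix
#'   (e.g. the index condition defining the cohort, which would otherwise be
#'   a degenerate 100%-prevalence node).
#' @return Named list (`"<sex>:<age_band>"`) of [disease_matrix()] objects,
#'   with attribute `unmapped_codes` (data frame `code`, `n_records`).
#' @export
build_matrix <- function(records, lookup, exclude_categories = NULL) {
  stopifnot(inherits(lookup, "code_lookup"))
  if (nrow(records) == 0) stop("no records to build matrices from")

  demo <- unique(records[c("patient_id", "sex", "age_band")])
  dup <- demo$patient_id[duplicated(demo$patient_id)]
  if (length(dup)) {
    stop("conflicting sex/age_band for patient(s): ",
         paste(utils::head(unique(dup), 5), collapse = ", "))
  }

  idx <- match(records$code, lookup$category$code)
  unmapped <- records$code[is.na(idx)]
  unmapped_report <- if (length(unmapped)) {
    tab <- table(unmapped)
    data.frame(code = names(tab), n_records = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    data.frame(code = character(), n_records = integer())
  }
  records <- records[!is.na(idx), , drop = FALSE]
  records$category <- lookup$category$category_label[idx[!is.na(idx)]]
  if (!is.null(exclude_categories)) {
    records <- records[!(records$category %in% exclude_categories), , drop = FALSE]
  }
  if (nrow(records) == 0) stop("no records remain after category mapping")

  key <- paste0(records$sex, ":", records$age_band)
  out <- lapply(split(records, key), function(d) {
    patients <- sort(unique(d$patient_id))
    cats <- sort(unique(d$category))
    ind <- matrix(0L, length(patients), length(cats),
                  dimnames = list(patients, cats))
    ind[cbind(match(d$patient_id, patients), match(d$category, cats))] <- 1L
    disease_matrix(ind, sex = d$sex[1], age_band = d$age_band[1])
  })
  out <- out[order(names(out))]
  attr(out, "unmapped_codes") <- unmapped_report
  out
}
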