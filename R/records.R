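#' Category levels used throughout the package
#'
#' Ethnicity is the study's seven-category coding with white British as the
#' reference group; diagnosis classes are the ICD-10 blocks F20-29
#' (non-affective) and F30-33 (affective).
#'
#' @name category-levels
#' @keywords internal
NULL

ethnicity_levels <- c("white British", "other white", "black Caribbean",
                      "black African", "Asian", "mixed", "other")
sex_levels <- c("female", "male")
diagnosis_levels <- c("nonaffective", "affective")

validate_records <- function(records, zero_dup = c("error", "offset")) {
  zero_dup <- match.arg(zero_dup)
  req <- c("ward_id", "dup_days", "age", "sex", "ethnicity")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  records$ward_id <- trimws(as.character(records$ward_id))
  records$sex <- trimws(as.character(records$sex))
  records$ethnicity <- trimws(as.character(records$ethnicity))

  drop <- is.na(records$ward_id) | !nzchar(records$ward_id)
  n_rejected <- sum(drop)
  if (n_rejected > 0L) {
    message(n_rejected, " record(s) rejected: no ward assignment (rows ",
            paste(which(drop), collapse = ", "), ")")
    records <- records[!drop, , drop = FALSE]
  }

  bad <- which(!(records$ethnicity %in% ethnicity_levels))
  if (length(bad))
    stop("unknown ethnicity \"", records$ethnicity[bad[1L]],
         "\" in row ", bad[1L])
  bad <- which(!(records$sex %in% sex_levels))
  if (length(bad))
    stop("unknown sex \"", records$sex[bad[1L]], "\" in row ", bad[1L])
  if (anyNA(records$dup_days) || anyNA(records$age))
    stop("missing dup_days or age value")

  zero <- which(records$dup_days == 0)
  if (length(zero)) {
    if (zero_dup == "offset") {
      message(length(zero), " zero-day DUP value(s) replaced by 0.5 days ",
              "(rows ", paste(zero, collapse = ", "), ")")
      records$dup_days[zero] <- 0.5
    } else {
      stop("dup_days is 0 in row ", zero[1L],
           " (use zero_dup = \"offset\" to substitute half a day)")
    }
  }
  neg <- which(records$dup_days < 0)
  if (length(neg)) stop("negative dup_days in row ", neg[1L])

  if ("diagnosis" %in% names(records)) {
    d <- trimws(as.character(records$diagnosis))
    ok <- is.na(d) | !nzchar(d) | d %in% diagnosis_levels
    if (!all(ok))
      stop("unknown diagnosis \"", d[which(!ok)[1L]], "\" in row ",
           which(!ok)[1L])
    records$diagnosis <- ifelse(nzchar(d) & !is.na(d), d, NA_character_)
  }
  rownames(records) <- NULL
  attr(records, "n_rejected") <- n_rejected
  records
}

#' Read individual-level case records
#'
#' Reads a delimited text file with header columns `ward_id`, `dup_days`
#' (duration of untreated psychosis in days), `age` (years), `sex`
#' (`male`/`female`), `ethnicity` (seven-category coding, see
#' [category-levels]) and optionally `diagnosis`
#' (`nonaffective`/`affective`). Rows without a ward assignment are
#' rejected with a reported count (mirroring the exclusion of cases whose
#' address could not be established); invalid category labels or
#' non-positive DUP values are errors naming the offending row.
#'
#' @param path file to read.
#' @param sep field separator (comma by default).
#' @param zero_dup `"error"` rejects zero-day DUP values; `"offset"`
#'   substitutes half a day (0.5) and logs the substitution.
#' @param encoding text encoding of the file.
#' @return Data frame of validated records; attribute `n_rejected` holds
#'   the number of rows dropped for missing ward assignment.
#' @export
read_individuals <- function(path, sep = ",",
                             zero_dup = c("error", "offset"),
                             encoding = "UTF-8") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, encoding = encoding,
                           na.strings = c("NA", ""), quote = "\"")
  validate_records(raw, zero_dup = match.arg(zero_dup))
}

#' Write individual-level case records
#' @param records data frame of records.
#' @param path output file.
#' @param sep field separator.
#' @export
write_individuals <- function(records, path, sep = ",") {
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = TRUE)
  invisible(path)
}

#' Natural-log transform of DUP
#'
#' The response analysed by every model is \eqn{T_{ij} = \log_e} DUP in
#' days; on this scale the heavily right-skewed raw durations are
#' approximately normal.
#'
#' @param x numeric vector of DUP values in days, or a record data frame
#'   with a `dup_days` column.
#' @return Numeric vector of log-DUP values, order preserved.
#' @export
log_transform <- function(x) {
  if (is.data.frame(x)) x <- x$dup_days
  if (!is.numeric(x)) stop("expected numeric dup_days")
  bad <- which(!is.na(x) & x <= 0)
  if (length(bad))
    stop("non-positive DUP in position ", bad[1L],
         "; the log transform requires dup_days > 0")
  log(x)
}
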