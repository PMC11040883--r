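#' Read a cohort file
#'
#' Reads a delimited cohort file (one row per patient encounter) into a
#' validated tibble. Cells that cannot be parsed, or whose values violate a
#' hard range invariant (e.g. a GCS outside 3--15), are treated as missing
#' and counted — erroneous registry entries are handled as missing data, not
#' as fatal errors. Unknown extra columns are kept untouched so auxiliary
#' variables can ride along into imputation.
#'
#' @param path Path to a delimited text file with one header row.
#' @param col_map Optional named character vector mapping canonical variable
#'   names to the file's column names, e.g. `c(sbp = "SYS_BP")`. Unmapped
#'   variables are looked up under their canonical names.
#' @param missing_tokens Strings read as missing. Default `c("", "NA")`.
#' @param delim Field delimiter. Default `","`.
#' @return A tibble with canonical column names and types. The attribute
#'   `"invalid_cells"` holds a named integer vector counting cells per
#'   variable that were set to missing because they violated an invariant; a
#'   warning summarises them.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path, col_map = NULL, missing_tokens = c("", "NA"),
                        delim = ",") {
  if (!file.exists(path)) {
    stop("cohort file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(
    path, header = TRUE, sep = delim, colClasses = "character",
    na.strings = missing_tokens, check.names = FALSE,
    stringsAsFactors = FALSE, quote = "\"", comment.char = ""
  )
  vars <- champ_variables()
  wanted <- vars$variable
  file_names <- wanted
  if (!is.null(col_map)) {
    idx <- match(names(col_map), wanted)
    if (anyNA(idx)) {
      stop("col_map names must be canonical variable names; unknown: ",
           paste(names(col_map)[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    file_names[idx] <- unname(col_map)
  }
  present <- file_names %in% names(raw)
  # Only the outcome and predictors present in the file are required as a
  # group; a cohort may legitimately omit screened-out candidates, but must
  # carry at least the outcome column.
  if (!present[wanted == "outcome"]) {
    stop("missing mandatory column: ",
         file_names[wanted == "outcome"], " (outcome)", call. = FALSE)
  }
  out <- tibble::as_tibble(raw)
  keep <- wanted[present]
  names(out)[match(file_names[present], names(out))] <- keep
  validate_cohort(out)
}

#' Validate and type a raw cohort tibble
#'
#' Coerces character columns to their canonical types and replaces values
#' violating hard invariants (range bounds, unknown categorical levels,
#' non-integer counts) with missing, counting each replacement.
#'
#' @param data A data frame whose columns use canonical variable names;
#'   non-canonical columns pass through unchanged.
#' @return A typed tibble with an `"invalid_cells"` attribute.
#' @export
validate_cohort <- function(data) {
  vars <- champ_variables()
  out <- tibble::as_tibble(data)
  invalid <- integer(0)
  for (i in seq_len(nrow(vars))) {
    v <- vars$variable[i]
    if (!v %in% names(out)) next
    col <- out[[v]]
    n_bad <- 0L
    if (vars$type[i] %in% c("continuous", "integer", "binary", "outcome")) {
      x <- suppressWarnings(as.numeric(col))
      n_bad <- n_bad + sum(is.na(x) & !is.na(col))
      lo <- vars$lower[i]; hi <- vars$upper[i]
      bad <- rep(FALSE, length(x))
      if (!is.na(lo)) bad <- bad | (!is.na(x) & x < lo)
      if (!is.na(hi)) bad <- bad | (!is.na(x) & x > hi)
      if (vars$type[i] %in% c("integer", "binary", "outcome")) {
        bad <- bad | (!is.na(x) & x != round(x))
      }
      n_bad <- n_bad + sum(bad)
      x[bad] <- NA_real_
      out[[v]] <- x
    } else { # categorical
      x <- as.character(col)
      lev <- vars$levels[[i]]
      bad <- !is.na(x) & !x %in% lev
      n_bad <- sum(bad)
      x[bad] <- NA_character_
      out[[v]] <- x
    }
    if (n_bad > 0) invalid[v] <- n_bad
  }
  if (length(invalid) > 0) {
    warning(sum(invalid), " cell(s) violated variable invariants and were ",
            "treated as missing (",
            paste(names(invalid), invalid, sep = "=", collapse = ", "), ")",
            call. = FALSE)
  }
  attr(out, "invalid_cells") <- invalid
  out
}

#' Write a cohort file
#'
#' Writes a cohort tibble as delimited text; missing cells are written as the
#' first missing token so that [read_cohort()] round-trips missingness
#' exactly.
#'
#' @param data Cohort tibble.
#' @param path Output path.
#' @param missing_token String written for missing cells. Default `""`.
#' @param delim Field delimiter. Default `","`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path, missing_token = "", delim = ",") {
  utils::write.table(
    data, path, sep = delim, na = missing_token, row.names = FALSE,
    quote = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}
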