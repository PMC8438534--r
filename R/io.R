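# Trait-table I/O and validation.
#
# CSV dialect: UTF-8, comma separator, "." decimal, empty cell = missing.
# Header: genotype,treatment,rep,<trait...>; treatment is exactly
# "control" or "deficient".

TREATMENT_LEVELS <- c("control", "deficient")

#' Read and validate a tidy trait table
#'
#' @param path CSV path with columns `genotype`, `treatment`, `rep` and one
#'   numeric column per trait.
#' @return Validated tibble.
#' @export
read_trait_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_trait_table(raw, source = path)
}

#' Validate an in-memory trait table
#'
#' Checks the key columns, the treatment labels, key uniqueness and that
#' every trait column is numeric; errors name the offending row.
#'
#' @param table Data frame to validate.
#' @param source Label used in error messages.
#' @return The table as a tibble, with `rep` as integer.
#' @export
validate_trait_table <- function(table, source = "trait table") {
  table <- tibble::as_tibble(table)
  need <- c("genotype", "treatment", "rep")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0L) {
    stop(source, ": missing required column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!table$treatment %in% TREATMENT_LEVELS)
  if (length(bad) > 0L) {
    stop(source, ": row ", bad[1L], " has treatment '",
         table$treatment[bad[1L]], "'; allowed labels are ",
         paste(sQuote(TREATMENT_LEVELS), collapse = " and "), call. = FALSE)
  }
  dup <- which(duplicated(table[need]))
  if (length(dup) > 0L) {
    stop(source, ": row ", dup[1L], " duplicates key (",
         paste(unlist(table[dup[1L], need]), collapse = ", "), ")", call. = FALSE)
  }
  traits <- setdiff(names(table), need)
  if (length(traits) == 0L) stop(source, ": no trait columns", call. = FALSE)
  for (tr in traits) {
    if (!is.numeric(table[[tr]])) {
      first_bad <- which(is.na(suppressWarnings(as.numeric(table[[tr]]))) &
                           !is.na(table[[tr]]))[1L]
      stop(source, ": trait column '", tr, "' is not numeric (see row ",
           ifelse(is.na(first_bad), 1L, first_bad), ")", call. = FALSE)
    }
  }
  table$rep <- as.integer(table$rep)
  table
}

#' Write a trait table to CSV
#'
#' Inverse of [read_trait_table()]: UTF-8 comma-separated values with an
#' empty cell for missing data, so a read/write round trip is
#' value-identical.
#'
#' @param table Trait table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  readr::write_csv(table, path, na = "")
  invisible(path)
}
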