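# Tabular readers/writers (UTF-8 CSV with headers) and bundle schema
# validation. Every writer's output is readable by its reader with value
# equality; Julian dates are stored as plain integers.

#' Read and write the pipeline's tables
#'
#' Plain UTF-8 CSV with a header row, decimal point, no thousands
#' separators. `write_bundle()` writes the four study tables (plus the truth
#' record as JSON for synthetic bundles) into a directory; `read_bundle()`
#' reads them back.
#'
#' @param path File path (or directory for bundle functions).
#' @param x Table to write.
#' @param bundle A `study_bundle` or compatible list of tables.
#' @name wrenlink_io
NULL

read_csv_strict <- function(path) {
  if (!file.exists(path)) {
    stop_wrenlink(sprintf("file not found: %s", path), "wrenlink_io_error")
  }
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  encoding = "UTF-8")
}

write_csv_plain <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname wrenlink_io
#' @export
read_nesting <- function(path) {
  d <- read_csv_strict(path)
  assert_columns(d, c("site", "territory", "first_egg_julian",
                      "nest_attempts", "successful_clutches", "total_eggs",
                      "fledglings"), "nesting table")
  d
}

#' @rdname wrenlink_io
#' @export
read_arthropods <- function(path) {
  d <- read_csv_strict(path)
  assert_columns(d, c("site", "territory", "block", "time_block",
                      "habitat_element", "stratum", "taxon", "count",
                      "body_length_mm"), "arthropod table")
  d
}

#' @rdname wrenlink_io
#' @export
read_cover <- function(path) {
  d <- read_csv_strict(path)
  assert_columns(d, c("territory", "habitat_element", "percent_cover"),
                 "cover table")
  d
}

#' @rdname wrenlink_io
#' @export
read_match_table <- function(path) {
  d <- read_csv_strict(path)
  assert_columns(d, c("otu_id", "order", "family", "genus", "species",
                      "percent_similarity"), "match table")
  d
}

#' @rdname wrenlink_io
#' @export
read_otu_table <- function(path) {
  d <- read_csv_strict(path)
  assert_columns(d, "sample_id", "OTU table")
  d
}

#' @rdname wrenlink_io
#' @export
write_bundle <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_csv_plain(bundle$otu_table, file.path(path, "otu_table.csv"))
  write_csv_plain(bundle$match_table, file.path(path, "match_table.csv"))
  write_csv_plain(bundle$arthropod_table,
                  file.path(path, "arthropod_table.csv"))
  write_csv_plain(bundle$cover_table, file.path(path, "cover_table.csv"))
  write_csv_plain(bundle$nesting_table, file.path(path, "nesting_table.csv"))
  if (!is.null(bundle$truth)) {
    jsonlite::write_json(bundle$truth, file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname wrenlink_io
#' @export
read_bundle <- function(path) {
  truth_path <- file.path(path, "truth.json")
  structure(list(
    otu_table = read_otu_table(file.path(path, "otu_table.csv")),
    match_table = read_match_table(file.path(path, "match_table.csv")),
    arthropod_table = read_arthropods(file.path(path,
                                                "arthropod_table.csv")),
    cover_table = read_cover(file.path(path, "cover_table.csv")),
    nesting_table = read_nesting(file.path(path, "nesting_table.csv")),
    truth = if (file.exists(truth_path)) {
      jsonlite::read_json(truth_path, simplifyVector = TRUE)
    }
  ), class = "study_bundle")
}

#' Validate a study bundle against the pipeline's schemas
#'
#' Checks every table for schema violations — unknown stratum labels,
#' non-positive counts or body lengths, cover rows not summing to 100 (+/- 1
#' for rounding), nesting invariants (successful clutches within attempts,
#' fledglings within eggs, Julian dates in 1..366), similarity values outside
#' 0..100 — and reports each violation with its table and row coordinates.
#' A clean bundle returns an empty report.
#'
#' @param bundle A `study_bundle` (in memory) or a directory path to read
#'   with [read_bundle()].
#' @param strata Allowed stratum labels.
#' @return Object of class `validation_report`: data.frame with columns
#'   `table`, `row`, `problem` (zero rows when clean).
#' @export
validate_tables <- function(bundle, strata = c("canopy", "ground")) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  bad <- list()
  note <- function(tab, rows, problem) {
    if (length(rows)) {
      bad[[length(bad) + 1L]] <<- data.frame(table = tab, row = rows,
                                             problem = problem,
                                             stringsAsFactors = FALSE)
    }
  }
  a <- bundle$arthropod_table
  if (!is.null(a)) {
    note("arthropod_table", which(a$count < 1), "count < 1")
    note("arthropod_table", which(a$body_length_mm <= 0),
         "body length <= 0")
    note("arthropod_table", which(!a$stratum %in% strata),
         "unknown stratum label")
  }
  cv <- bundle$cover_table
  if (!is.null(cv)) {
    note("cover_table", which(cv$percent_cover < 0 | cv$percent_cover > 100),
         "percent cover outside [0, 100]")
    sums <- tapply(cv$percent_cover, cv$territory, sum)
    off <- names(sums)[abs(sums - 100) > 1]
    note("cover_table",
         which(cv$territory %in% off & !duplicated(cv$territory)),
         "territory cover does not sum to 100 (+/- 1)")
  }
  nst <- bundle$nesting_table
  if (!is.null(nst)) {
    note("nesting_table",
         which(nst$successful_clutches > nst$nest_attempts),
         "successful clutches exceed nest attempts")
    note("nesting_table", which(nst$fledglings > nst$total_eggs),
         "fledglings exceed total eggs")
    note("nesting_table",
         which(nst$first_egg_julian < 1 | nst$first_egg_julian > 366),
         "first egg Julian day outside [1, 366]")
  }
  mt <- bundle$match_table
  if (!is.null(mt)) {
    note("match_table",
         which(mt$percent_similarity < 0 | mt$percent_similarity > 100),
         "percent similarity outside [0, 100]")
    note("match_table", which(is.na(mt$order) | mt$order == ""),
         "candidate missing order")
  }
  ot <- bundle$otu_table
  if (!is.null(ot) && ncol(ot) > 1L) {
    reads <- as.matrix(ot[-1])
    note("otu_table", which(apply(reads < 0, 1, any)),
         "negative read count")
  }
  report <- if (length(bad)) do.call(rbind, bad) else
    data.frame(table = character(), row = integer(), problem = character(),
               stringsAsFactors = FALSE)
  rownames(report) <- NULL
  structure(report, class = c("validation_report", "data.frame"))
}

#' @export
print.validation_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("Validation: clean (no schema violations)\n")
  } else {
    cat(sprintf("Validation: %d violation(s)\n", nrow(x)))
    print(as.data.frame(x), row.names = FALSE)
  }
  invisible(x)
}
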