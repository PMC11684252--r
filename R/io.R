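#' Read a claims bundle from delimited text files
#'
#' Reads the four comma-separated schema files (`enrollment.csv`,
#' `medical_claims.csv`, `pharmacy_claims.csv`, `demographics.csv`) and
#' returns a validated [claims_bundle()]. Dates must be ISO-8601
#' (`YYYY-MM-DD`); list-valued columns (`dx_codes`, `flags`) are
#' semicolon-joined. A missing column raises a schema error naming the
#' column; an unparseable date raises a row-level error.
#'
#' When `flag_map` is supplied, medical claims with an empty `flags` field
#' whose `proc_code` appears in the map receive the mapped flag — a small
#' code-to-flag table standing in for a drug/procedure code dictionary, so
#' bundles can be shipped without precomputed DMT/support flags.
#'
#' @param dir directory containing the four files under their standard
#'   names; ignored when `paths` is given.
#' @param paths optional named character vector with elements
#'   `enrollment`, `medical`, `pharmacy`, `demographics`.
#' @param dedupe drop exact duplicate claim rows (default `TRUE`).
#' @param flag_map optional data.frame with columns `code`, `flag`.
#' @return A validated [claims_bundle()].
#' @export
read_bundle <- function(dir = NULL, paths = NULL, dedupe = TRUE,
                        flag_map = NULL) {
  if (is.null(paths)) {
    stopifnot(!is.null(dir))
    paths <- c(enrollment = file.path(dir, "enrollment.csv"),
               medical = file.path(dir, "medical_claims.csv"),
               pharmacy = file.path(dir, "pharmacy_claims.csv"),
               demographics = file.path(dir, "demographics.csv"))
  }
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) {
    stop(sprintf("input file(s) not found: %s",
                 paste(missing_files, collapse = ", ")), call. = FALSE)
  }
  rd <- function(p) {
    fread(p, colClasses = "character", na.strings = NULL,
          encoding = "UTF-8", keepLeadingZeros = TRUE)
  }
  enrollment <- rd(paths[["enrollment"]])
  medical <- rd(paths[["medical"]])
  pharmacy <- rd(paths[["pharmacy"]])
  demographics <- rd(paths[["demographics"]])

  if (!is.null(flag_map) && nrow(medical)) {
    flag_map <- as.data.table(flag_map)
    stopifnot(all(c("code", "flag") %in% names(flag_map)))
    hit <- medical$flags == "" & medical$proc_code %in% flag_map$code
    if (any(hit)) {
      medical$flags[hit] <-
        flag_map$flag[match(medical$proc_code[hit], flag_map$code)]
    }
  }
  claims_bundle(enrollment, medical, pharmacy, demographics,
                dedupe = dedupe)
}

#' Write a claims bundle to delimited text files
#'
#' Writes the four schema files into `dir` (created if absent). Round-trip
#' property: `read_bundle()` of a written bundle is record-equal to the
#' original (after its constructor normalization, which has already been
#' applied to any valid bundle).
#'
#' @param bundle a [claims_bundle()].
#' @param dir output directory.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "claims_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create directory '%s'", dir),
                             call. = FALSE)
  paths <- c(enrollment = file.path(dir, "enrollment.csv"),
             medical = file.path(dir, "medical_claims.csv"),
             pharmacy = file.path(dir, "pharmacy_claims.csv"),
             demographics = file.path(dir, "demographics.csv"))
  fwrite(bundle$enrollment, paths[["enrollment"]], dateTimeAs = "ISO")
  fwrite(bundle$medical, paths[["medical"]], dateTimeAs = "ISO")
  fwrite(bundle$pharmacy, paths[["pharmacy"]], dateTimeAs = "ISO")
  fwrite(bundle$demographics, paths[["demographics"]], dateTimeAs = "ISO")
  invisible(paths)
}
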