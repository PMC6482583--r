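#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

# Subtype taxonomy: H healthy controls, BC HER2+ breast cancer, LC non-small
# cell lung cancer, ODminus severe obesity without T2DM, ODplus with T2DM.
cohort_subtypes <- function() c("H", "BC", "LC", "ODminus", "ODplus")

cohort_classes <- function() c("h", "c", "o")

#' Collapse sample subtypes into the merged three-class annotation
#'
#' Maps the five cohort subtypes onto the merged reference classes used by the
#' classifiers: healthy (`h`), cancer (`c` = BC or LC) and obesity
#' (`o` = ODminus or ODplus).
#'
#' @param subtype Character vector (or factor) of subtypes, each one of
#'   `"H"`, `"BC"`, `"LC"`, `"ODminus"`, `"ODplus"`.
#' @return A factor with levels `h`, `c`, `o`, same length as `subtype`.
#' @examples
#' merge_class(c("H", "BC", "ODplus"))
#' @export
merge_class <- function(subtype) {
  subtype <- as.character(subtype)
  bad <- setdiff(unique(subtype), cohort_subtypes())
  if (length(bad) > 0) {
    stop("unknown subtype(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(cohort_subtypes(), collapse = ", "), ")",
         call. = FALSE)
  }
  map <- c(H = "h", BC = "c", LC = "c", ODminus = "o", ODplus = "o")
  factor(unname(map[subtype]), levels = cohort_classes())
}

#' Default column-name schema for cohort files
#'
#' Named character vector mapping canonical field names (`sample_id`,
#' `subtype`, `formate`, `glucose`) to the column headers expected in a
#' delimited file. Columns are addressed by header name, never by position.
#'
#' @return Named character vector.
#' @export
default_schema <- function() {
  c(sample_id = "sample_id", subtype = "subtype",
    formate = "formate_mM", glucose = "glucose_area")
}

#' Validate and normalise a cohort table
#'
#' Checks the cohort invariants: unique sample ids, known subtypes, finite
#' nonnegative formate (mM) and glucose (peak area) on every row, nonnegative
#' extra metabolite intensities (missing values permitted there), and
#' (re)derives the merged `class` column from `subtype` so it can never drift.
#'
#' @param x A data frame with columns `sample_id`, `subtype`, `formate`,
#'   `glucose`; any further numeric columns are treated as extra metabolite
#'   intensities.
#' @return A tibble with `sample_id`, `subtype`, `class`, `formate`,
#'   `glucose`, then the extra metabolite columns.
#' @export
validate_cohort <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("sample_id", "subtype", "formate", "glucose")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x$sample_id <- as.character(x$sample_id)
  dup <- unique(x$sample_id[duplicated(x$sample_id)])
  if (length(dup) > 0) {
    stop("duplicate sample_id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  cls <- merge_class(x$subtype)
  x$subtype <- factor(as.character(x$subtype), levels = cohort_subtypes())

  for (col in c("formate", "glucose")) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(v))
    }
    bad <- !is.finite(v) | v < 0
    if (any(bad)) {
      stop("invalid ", col, " value (must be finite and nonnegative) for ",
           "sample_id(s): ", paste(x$sample_id[bad], collapse = ", "),
           call. = FALSE)
    }
    x[[col]] <- v
  }

  extra <- setdiff(names(x), c(required, "class"))
  for (col in extra) {
    v <- x[[col]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & (v < 0 | !is.finite(v))
    if (any(bad)) {
      stop("invalid intensity in column '", col, "' for sample_id(s): ",
           paste(x$sample_id[bad], collapse = ", "), call. = FALSE)
    }
    x[[col]] <- v
  }

  x$class <- cls
  dplyr::select(x, "sample_id", "subtype", "class", "formate", "glucose",
                dplyr::all_of(extra))
}

#' Read a cohort table from a delimited text file
#'
#' Reads a CSV with a header row (UTF-8, decimal point) holding one sample per
#' row, renames columns to canonical names via `schema`, and validates all
#' cohort invariants. Extra columns beyond the schema are kept as metabolite
#' intensities.
#'
#' @param path Path to a CSV file.
#' @param schema Named character vector mapping canonical names to file
#'   headers; see [default_schema()].
#' @return A validated cohort tibble (see [validate_cohort()]).
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write_cohort(generate_cohort(seed = 1), tf)
#' cohort <- read_cohort(tf)
#' @export
read_cohort <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # parse numerics via as.numeric (correctly rounded strtod) in
  # validate_cohort, so written values round-trip exactly
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_character()))
  required <- c("sample_id", "subtype", "formate", "glucose")
  schema <- schema[required]
  absent <- schema[!schema %in% names(raw)]
  if (length(absent) > 0) {
    stop("input file is missing column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  names(raw)[match(schema, names(raw))] <- names(schema)
  validate_cohort(raw)
}

#' Write a cohort table to CSV
#'
#' Writes the cohort with the schema's column headers. The derived `class`
#' column is not written (it is a pure function of `subtype`). Numeric values
#' are written at full round-trip precision, so
#' `read_cohort(write_cohort(x))` reproduces the numeric columns exactly.
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path.
#' @param schema Named character vector as in [read_cohort()].
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, schema = default_schema()) {
  cohort <- validate_cohort(cohort)
  out <- dplyr::select(cohort, -"class")
  names(out)[match(names(schema), names(out))] <- schema
  # 17 significant digits: exact binary64 round-trip through the text file
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric),
                                          ~ sprintf("%.17g", .x)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# internal: integer codes 1 = h, 2 = c, 3 = o for fast paths
class_codes <- function(cls) {
  match(as.character(cls), cohort_classes())
}
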