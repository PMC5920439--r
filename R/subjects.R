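#' Classify a tibial rotation angle into a pathology type
#'
#' Tibial rotation angles (degrees) are screened into three types:
#' Type 1 (pathological, angle of at most 20 degrees), Type 2 (normal,
#' between 20 and 65 degrees), and Type 3 (pathological, above 65 degrees).
#' The intervals are `[0, 20]`, `(20, 65]`, `(65, Inf)`: the 20-degree
#' boundary belongs to Type 1 and the 65-degree boundary to Type 2.
#'
#' @param angle Numeric vector of rotation angles in degrees; must be
#'   finite and non-negative.
#' @return A factor with levels `"TYPE1"`, `"TYPE2"`, `"TYPE3"`.
#' @examples
#' classify_rotation_type(c(15, 20, 45, 65, 70))
#' @seealso [assign_rule_cluster()]
#' @export
classify_rotation_type <- function(angle) {
  if (!is.numeric(angle)) stop("'angle' must be numeric", call. = FALSE)
  if (anyNA(angle) || any(!is.finite(angle))) {
    stop("rotation angles must be finite and non-missing", call. = FALSE)
  }
  if (any(angle < 0)) {
    stop("rotation angles must be >= 0 degrees", call. = FALSE)
  }
  lab <- ifelse(angle <= 20, "TYPE1", ifelse(angle <= 65, "TYPE2", "TYPE3"))
  factor(lab, levels = c("TYPE1", "TYPE2", "TYPE3"))
}

#' Assign a subject to an anthropometric rule cluster
#'
#' Deterministic reference grouping by physical characteristics: subjects
#' older than 30 years form Cluster 1; the remaining subjects are split by
#' body weight, at most 60 kg into Cluster 2 and above 60 kg into Cluster 3.
#' Height correlates with the weight split in the cohorts this rule was
#' designed for but does not enter the rule itself; it is validated only.
#'
#' @param age Age in years (strictly positive).
#' @param weight Body weight in kilograms (strictly positive).
#' @param height Standing height in meters (strictly positive).
#' @return A factor with levels `"C1"`, `"C2"`, `"C3"`.
#' @examples
#' assign_rule_cluster(35, 80, 1.80)  # C1
#' assign_rule_cluster(25, 55, 1.65)  # C2
#' assign_rule_cluster(25, 75, 1.78)  # C3
#' @export
assign_rule_cluster <- function(age, weight, height) {
  for (nm in c("age", "weight", "height")) {
    v <- get(nm)
    if (!is.numeric(v)) stop(sprintf("'%s' must be numeric", nm), call. = FALSE)
    if (anyNA(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("'%s' must be finite and strictly positive", nm), call. = FALSE)
    }
  }
  n <- max(length(age), length(weight), length(height))
  age <- rep_len(age, n); weight <- rep_len(weight, n)
  lab <- ifelse(age > 30, "C1", ifelse(weight <= 60, "C2", "C3"))
  factor(lab, levels = c("C1", "C2", "C3"))
}

subject_columns <- c("id", "age", "weight", "height",
                     "rter", "rtir", "lter", "ltir")

# Validate a subject table: required columns, numeric cells, positivity,
# non-negative angles, unique ids.  `where` names the source in messages.
validate_subjects <- function(df, where = "subject table") {
  missing <- setdiff(subject_columns, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing column(s): %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- df[, subject_columns, drop = FALSE]
  for (col in setdiff(subject_columns, "id")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop(sprintf("%s: column '%s' is not numeric (first bad row: %s)",
                   where, col, ifelse(is.na(bad), "?", bad)), call. = FALSE)
    }
    if (anyNA(v) || any(!is.finite(v))) {
      stop(sprintf("%s: column '%s' has missing/non-finite values (row %d)",
                   where, col, which(!is.finite(v) | is.na(v))[1]), call. = FALSE)
    }
  }
  for (col in c("age", "weight", "height")) {
    bad <- which(df[[col]] <= 0)
    if (length(bad)) {
      stop(sprintf("%s: column '%s' must be strictly positive (row %d, value %g)",
                   where, col, bad[1], df[[col]][bad[1]]), call. = FALSE)
    }
  }
  for (col in c("rter", "rtir", "lter", "ltir")) {
    bad <- which(df[[col]] < 0)
    if (length(bad)) {
      stop(sprintf("%s: column '%s' must be >= 0 (row %d, value %g)",
                   where, col, bad[1], df[[col]][bad[1]]), call. = FALSE)
    }
  }
  if (anyDuplicated(df$id)) {
    dup <- df$id[duplicated(df$id)][1]
    stop(sprintf("%s: duplicate subject id '%s'", where, dup), call. = FALSE)
  }
  df$id <- as.character(df$id)
  df
}

#' Read a subject table from CSV
#'
#' Expects a comma-separated UTF-8 file with header
#' `id,age,weight,height,rter,rtir,lter,ltir`: age in years, weight in kg,
#' height in meters, and the four tibial rotation angles (right/left
#' external/internal) in degrees. Row order is preserved. If the height
#' column's median exceeds 3 the file is assumed to be in centimeters and
#' is converted to meters with a warning.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with the eight subject columns, validated.
#' @seealso [write_subjects()], [simulate_cohort()]
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  where <- sprintf("'%s'", basename(path))
  missing <- setdiff(subject_columns, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing column(s): %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) > 0 && is.numeric(df$height) &&
      stats::median(df$height, na.rm = TRUE) > 3) {
    warning(sprintf("%s: height column looks like centimeters; converting to meters",
                    where), call. = FALSE)
    df$height <- df$height / 100
  }
  if (nrow(df) == 0) {
    df$id <- as.character(df$id)
    return(df[, subject_columns, drop = FALSE])
  }
  validate_subjects(df, where = where)
}

#' Write a subject table to CSV
#'
#' Inverse of [read_subjects()]: the written file round-trips field for
#' field at full double precision.
#'
#' @param subjects A validated subject `data.frame` (eight standard columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(subjects, path) {
  if (nrow(subjects) > 0) subjects <- validate_subjects(subjects)
  utils::write.csv(subjects[, subject_columns, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract the physical-feature matrix from a subject table
#'
#' @param subjects A subject `data.frame`.
#' @return A numeric matrix with columns `age`, `weight`, `height`, one row
#'   per subject — the feature space the clustering operates on.
#' @export
subject_features <- function(subjects) {
  as.matrix(subjects[, c("age", "weight", "height")])
}
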