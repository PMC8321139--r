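#' Long-format sector-lattice datasets
#'
#' The package's data model is a long-format data frame with one row per
#' observed (patient, eye, sector) cell. Required columns:
#'
#' * `patient_id` — patient identifier;
#' * `eye_id`     — eye identifier, unique across the dataset and nested
#'                  in `patient_id` (at most two eyes per patient);
#' * `sector_id`  — sector label, matching the grid in use;
#' * `thickness`  — response, retinal thickness in micrometres.
#'
#' Any further columns are patient- or eye-level covariates (e.g. `group`,
#' `age`, `gender`, `visual_acuity`, `laterality`). Missing responses are
#' represented by absent rows; rows with `NA` thickness are rejected.
#'
#' `as_long_data()` validates a data frame and returns it with class
#' `long_data`; modelling functions call it on their input.
#'
#' @param data A data frame in the layout above.
#' @param max_eyes_per_patient Maximum eyes per patient (default 2).
#' @return `data` with class `c("long_data", "data.frame")`.
#' @export
as_long_data <- function(data, max_eyes_per_patient = 2L) {
  if (!is.data.frame(data)) stop("'data' must be a data frame")
  need <- c("patient_id", "eye_id", "sector_id", "thickness")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  data <- as.data.frame(data)
  if (!is.numeric(data$thickness))
    stop("'thickness' must be numeric")
  if (anyNA(data$thickness))
    stop("NA responses are not allowed; omit the rows instead")
  key <- paste(data$patient_id, data$eye_id, data$sector_id, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- key[duplicated(key)][1]
    stop("duplicate (patient_id, eye_id, sector_id) key: ",
         gsub("\r", " / ", bad))
  }
  # nesting: each eye belongs to exactly one patient
  em <- unique(data[, c("patient_id", "eye_id")])
  if (anyDuplicated(em$eye_id))
    stop("eye_id values must be nested within a single patient_id")
  npe <- table(em$patient_id)
  if (any(npe > max_eyes_per_patient))
    stop("patient(s) with more than ", max_eyes_per_patient, " eyes: ",
         paste(utils::head(names(npe)[npe > max_eyes_per_patient], 3),
               collapse = ", "))
  nse <- table(data$eye_id)
  class(data) <- c("long_data", "data.frame")
  data
}

#' Read / write long-format sector data as CSV
#'
#' Thin wrappers around [utils::read.csv()] / [utils::write.csv()] that
#' validate the schema on read (see [as_long_data()]).
#'
#' @param path File path.
#' @param data A data frame in long format.
#' @return `read_long_data` returns a validated `long_data`;
#'   `write_long_data` returns `path` invisibly.
#' @export
read_long_data <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_long_data(df)
}

#' @rdname read_long_data
#' @export
write_long_data <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}
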