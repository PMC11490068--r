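#' Write reading records as CSV
#'
#' Dialect: header `exam_id,case_status,reader_id,decision,day,batch`, no row
#' names, plain unquoted fields.
#'
#' @param records Reading-record data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reading_records <- function(records, path) {
  need <- c("exam_id", "case_status", "reader_id", "decision")
  if (!all(need %in% names(records)))
    stop_invalid("records must have columns ", paste(need, collapse = ", "))
  if (!"day" %in% names(records)) records$day <- NA_integer_
  if (!"batch" %in% names(records)) records$batch <- NA_integer_
  utils::write.csv(records[, c(need, "day", "batch")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read reading records from CSV
#'
#' @param path CSV file written by [write_reading_records()] (or any file in
#'   the same dialect).
#' @return Reading-record data frame.
#' @export
read_reading_records <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(exam_id = "character",
                                        reader_id = "character"))
  need <- c("exam_id", "case_status", "reader_id", "decision")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop_malformed("records file is missing column(s): ", paste(miss, collapse = ", "))
  rec
}

#' Write model parameters (CSV + JSON sidecar)
#'
#' Reader effects go to `<path>` as CSV (`reader_id,r_neg,r_pos`); the scalar
#' parameters and any metadata go to `<path>.json`.
#'
#' @param params [model_parameters()].
#' @param path CSV path.
#' @param meta Optional named list merged into the sidecar (e.g. `nll`,
#'   seeds, fit settings).
#' @return `path`, invisibly.
#' @export
write_model_parameters <- function(params, path, meta = list()) {
  stopifnot(inherits(params, "model_parameters"))
  utils::write.csv(params$readers, path, row.names = FALSE, quote = FALSE)
  sidecar <- c(list(sigma_neg = params$sigma_neg, sigma_pos = params$sigma_pos),
               meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read model parameters written by [write_model_parameters()]
#'
#' @param path CSV path (`<path>.json` sidecar must exist).
#' @return A [model_parameters()] object with sidecar metadata attached as
#'   attribute `"meta"`.
#' @export
read_model_parameters <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) stop_invalid("sidecar not found: ", sidecar_path)
  readers <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(reader_id = "character"))
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  params <- model_parameters(readers, sigma_neg = sidecar$sigma_neg,
                             sigma_pos = sidecar$sigma_pos)
  attr(params, "meta") <- sidecar[setdiff(names(sidecar),
                                          c("sigma_neg", "sigma_pos"))]
  params
}

#' Write a strategy-comparison table as CSV
#'
#' @param results Data frame from [compare_pairing_strategies()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_strategy_results <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a strategy-comparison table
#'
#' @param path CSV written by [write_strategy_results()].
#' @return Data frame.
#' @export
read_strategy_results <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
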