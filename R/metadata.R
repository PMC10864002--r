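#' Construct and validate sample metadata
#'
#' Per-sample annotations used throughout cohort analyses: response group
#' (NR = non-responder, R = responder), dataset of origin, and sampling
#' timing relative to treatment (PRE / POST).
#'
#' @param sample_id character vector of unique sample ids.
#' @param group character vector, each `"NR"` or `"R"`.
#' @param dataset character vector of dataset ids.
#' @param timing character vector, each `"PRE"` or `"POST"`.
#' @return A `data.frame` of class `SampleMetadata`.
#' @export
sample_metadata <- function(sample_id, group, dataset = "dataset1",
                            timing = "PRE") {
  sample_id <- as.character(sample_id)
  n <- length(sample_id)
  group <- rep_len(as.character(group), n)
  dataset <- rep_len(as.character(dataset), n)
  timing <- rep_len(as.character(timing), n)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  if (!all(group %in% c("NR", "R"))) {
    stop("group must be one of NR, R", call. = FALSE)
  }
  if (!all(timing %in% c("PRE", "POST"))) {
    stop("timing must be one of PRE, POST", call. = FALSE)
  }
  structure(data.frame(sample_id = sample_id, group = group,
                       dataset = dataset, timing = timing,
                       stringsAsFactors = FALSE),
            class = c("SampleMetadata", "data.frame"))
}

#' Read sample metadata from CSV
#'
#' Expects columns `sample_id`, `group` and optionally `dataset`, `timing`.
#'
#' @param path CSV file path.
#' @return A [sample_metadata()] table.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "group")
  if (!all(required %in% names(df))) {
    stop("metadata must contain columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  sample_metadata(df$sample_id, df$group,
                  dataset = if ("dataset" %in% names(df)) df$dataset else "dataset1",
                  timing = if ("timing" %in% names(df)) df$timing else "PRE")
}
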