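#' Construct an APRQ transcript
#'
#' One participant's responses to the 17-item APRQ structured interview,
#' together with the group label. Responses may be empty strings but every
#' listed item must be one of 1..17.
#'
#' @param participant_id Character scalar.
#' @param group `"ASD"` or `"NT"`.
#' @param responses Named character vector or list; names are item ids
#'   (`"1"`..`"17"`), values are response texts.
#' @return An object of class `aprq_transcript`.
#' @export
aprq_transcript <- function(participant_id, group, responses) {
  group <- match.arg(group, c("ASD", "NT"))
  responses <- vapply(responses, function(x) {
    if (is.null(x) || (length(x) == 1L && is.na(x))) "" else as.character(x)
  }, "")
  items <- suppressWarnings(as.integer(names(responses)))
  if (length(responses) && (anyNA(items) || any(items < 1L | items > 17L))) {
    stop("response item ids must be integers in 1..17", call. = FALSE)
  }
  if (anyDuplicated(items)) stop("duplicate item ids", call. = FALSE)
  responses <- responses[order(items)]
  structure(list(participant_id = as.character(participant_id),
                 group = group, responses = responses),
            class = "aprq_transcript")
}

#' @export
print.aprq_transcript <- function(x, ...) {
  cat("APRQ transcript:", x$participant_id, "(", x$group, "),",
      length(x$responses), "items,",
      sum(nchar(x$responses) > 0), "non-empty\n")
  invisible(x)
}

#' Assemble a cohort
#'
#' Bundles transcripts with instrument responses (and optionally the
#' generator's ground truth) into the container the pipeline functions
#' consume.
#'
#' @param transcripts List of [aprq_transcript] objects.
#' @param instruments Data frame with columns `participant_id`, `tas_1` ..
#'   `tas_20`, `aq_1` .. `aq_10`, and optionally `age`; `NA` cells mark
#'   missing responses. May be `NULL`.
#' @param ground_truth Optional data frame of generating parameters (from
#'   [generate_cohort()]).
#' @return An object of class `aprq_cohort`.
#' @export
aprq_cohort <- function(transcripts, instruments = NULL, ground_truth = NULL) {
  stopifnot(all(vapply(transcripts, inherits, TRUE, "aprq_transcript")))
  ids <- vapply(transcripts, `[[`, "", "participant_id")
  if (anyDuplicated(ids)) stop("duplicate participant ids", call. = FALSE)
  if (!is.null(instruments)) {
    stopifnot(is.data.frame(instruments),
              "participant_id" %in% names(instruments))
    instruments$participant_id <- as.character(instruments$participant_id)
  }
  structure(list(transcripts = transcripts, instruments = instruments,
                 ground_truth = ground_truth),
            class = "aprq_cohort")
}

#' @export
print.aprq_cohort <- function(x, ...) {
  grp <- vapply(x$transcripts, `[[`, "", "group")
  cat("APRQ cohort:", length(x$transcripts), "participants (",
      sum(grp == "ASD"), "ASD /", sum(grp == "NT"), "NT );",
      if (is.null(x$instruments)) "no instrument data" else
        paste0("instrument rows: ", nrow(x$instruments)), "\n")
  invisible(x)
}

#' Read / write transcripts as JSONL
#'
#' One participant per line: a JSON object with fields `participant_id`,
#' `group` and `responses` (an object mapping item id to response text).
#'
#' @param path File path.
#' @return `read_transcripts_jsonl()` returns a list of [aprq_transcript]
#'   objects; the writer returns `path` invisibly.
#' @export
read_transcripts_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    if (!all(c("participant_id", "group", "responses") %in% names(obj))) {
      stop("JSONL transcript line missing required fields", call. = FALSE)
    }
    aprq_transcript(obj$participant_id, obj$group, unlist(obj$responses))
  })
}

#' @rdname read_transcripts_jsonl
#' @param transcripts List of [aprq_transcript] objects.
#' @export
write_transcripts_jsonl <- function(transcripts, path) {
  lines <- vapply(transcripts, function(t) {
    jsonlite::toJSON(list(participant_id = t$participant_id, group = t$group,
                          responses = as.list(t$responses)),
                     auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write transcripts as long-format CSV
#'
#' Columns `participant_id`, `group`, `item_id`, `response_text`; one row per
#' item response.
#'
#' @param path File path.
#' @return `read_transcripts_csv()` returns a list of [aprq_transcript]
#'   objects; the writer returns `path` invisibly.
#' @export
read_transcripts_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(participant_id = "character"))
  need <- c("participant_id", "group", "item_id", "response_text")
  if (!all(need %in% names(tab))) {
    stop("transcript CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(tab, tab$participant_id)[unique(tab$participant_id)],
         function(d) {
           aprq_transcript(d$participant_id[1L], d$group[1L],
                           stats::setNames(d$response_text,
                                           as.character(d$item_id)))
         })
}

#' @rdname read_transcripts_csv
#' @param transcripts List of [aprq_transcript] objects.
#' @export
write_transcripts_csv <- function(transcripts, path) {
  rows <- do.call(rbind, lapply(transcripts, function(t) {
    data.frame(participant_id = t$participant_id, group = t$group,
               item_id = as.integer(names(t$responses)),
               response_text = unname(t$responses),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read / write instrument responses as CSV
#'
#' One row per participant; columns `participant_id`, `tas_1`..`tas_20`,
#' `aq_1`..`aq_10` and optionally `age`. Empty cells become `NA` (missing
#' instruments are never imputed).
#'
#' @param path File path.
#' @return A data frame (reader) or `path` invisibly (writer).
#' @export
read_instruments_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(participant_id = "character"))
  if (!"participant_id" %in% names(tab)) {
    stop("instrument CSV must have a participant_id column", call. = FALSE)
  }
  tab
}

#' @rdname read_instruments_csv
#' @param instruments Data frame as described above.
#' @export
write_instruments_csv <- function(instruments, path) {
  utils::write.csv(instruments, path, row.names = FALSE, na = "")
  invisible(path)
}
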