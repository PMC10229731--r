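#' Load a LIWC-dialect category dictionary
#'
#' Parses the plain-text `.dic` dialect: a header block delimited by lines
#' containing only `%`, with `id<TAB>name` rows, followed by pattern rows
#' `pattern<TAB>id[<TAB>id...]`. A pattern is either a literal token or a
#' prefix wildcard ending in `*` (so `hate*` matches `hate`, `hated`,
#' `hatred`...). This is an open-format replacement for proprietary category
#' dictionaries: any word-category scheme expressible as literal/prefix
#' patterns can be supplied.
#'
#' @param source Path to a `.dic` file, or a character vector of its lines.
#' @return An object of class `category_dictionary` with elements `patterns`
#'   (character), `pattern_categories` (list of category-id integer vectors,
#'   parallel to `patterns`) and `category_names` (named character, names are
#'   ids).
#' @export
load_category_dictionary <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\n", source) &&
               file.exists(source)) {
    readLines(source, encoding = "UTF-8")
  } else {
    unlist(strsplit(as.character(source), "\n", fixed = TRUE))
  }
  delim <- which(trimws(lines) == "%")
  if (length(delim) < 2L) {
    stop("missing '%' header delimiters in category dictionary", call. = FALSE)
  }
  header <- lines[seq(delim[1] + 1L, delim[2] - 1L)]
  body <- if (delim[2] < length(lines)) lines[seq(delim[2] + 1L, length(lines))]
          else character()
  header <- header[trimws(header) != ""]
  body <- body[trimws(body) != ""]

  split_fields <- function(x) strsplit(trimws(x), "[\t ]+")
  hf <- split_fields(header)
  if (any(lengths(hf) < 2L)) {
    stop("malformed header row in category dictionary", call. = FALSE)
  }
  ids <- vapply(hf, `[[`, "", 1L)
  nms <- vapply(hf, function(f) paste(f[-1L], collapse = " "), "")
  if (anyDuplicated(ids)) stop("duplicate category ids", call. = FALSE)
  category_names <- stats::setNames(nms, ids)

  bf <- split_fields(body)
  patterns <- vapply(bf, `[[`, "", 1L)
  patterns <- tolower(patterns)
  if (anyDuplicated(patterns)) {
    stop("duplicate pattern(s): ",
         paste(unique(patterns[duplicated(patterns)]), collapse = ", "),
         call. = FALSE)
  }
  pattern_categories <- lapply(bf, function(f) {
    pid <- f[-1L]
    unknown <- setdiff(pid, ids)
    if (length(unknown)) {
      stop("pattern '", f[1L], "' references unknown category id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    match(pid, ids)
  })

  structure(list(patterns = patterns,
                 pattern_categories = pattern_categories,
                 category_names = category_names),
            class = "category_dictionary")
}

#' @export
print.category_dictionary <- function(x, ...) {
  cat("Category dictionary:", length(x$patterns), "patterns,",
      length(x$category_names), "categories (",
      paste(x$category_names, collapse = ", "), ")\n")
  invisible(x)
}

#' Categories matched by a single token
#'
#' A literal pattern matches on exact equality; a wildcard pattern `abc*`
#' matches any token whose prefix is `abc` (the full prefix must be present,
#' so `hat` does not match `hate*`). A token matching several patterns is
#' credited to the union of their categories; no match yields an empty set.
#'
#' @param token A nonempty lowercase token.
#' @param dictionary A `category_dictionary`.
#' @return Character vector of matched category names (possibly empty).
#' @export
match_categories <- function(token, dictionary) {
  stopifnot(inherits(dictionary, "category_dictionary"),
            is.character(token), length(token) == 1L, nzchar(token))
  hits <- token_pattern_hits(token, dictionary)
  ids <- sort(unique(unlist(dictionary$pattern_categories[hits])))
  unname(dictionary$category_names[ids])
}

# logical over patterns: does `token` match each pattern?
token_pattern_hits <- function(token, dictionary) {
  pats <- dictionary$patterns
  wild <- endsWith(pats, "*")
  hits <- logical(length(pats))
  hits[!wild] <- pats[!wild] == token
  if (any(wild)) {
    stems <- substr(pats[wild], 1L, nchar(pats[wild]) - 1L)
    hits[wild] <- startsWith(token, stems)
  }
  hits
}

# counts of tokens matching each category; internal workhorse for
# category_percentages(). O(patterns x tokens) via vectorised prefix tests.
category_token_matrix <- function(tokens, dictionary) {
  pats <- dictionary$patterns
  ncat <- length(dictionary$category_names)
  out <- matrix(FALSE, nrow = length(tokens), ncol = ncat,
                dimnames = list(NULL, unname(dictionary$category_names)))
  if (!length(tokens)) return(out)
  wild <- endsWith(pats, "*")
  stems <- substr(pats, 1L, nchar(pats) - wild)
  for (j in seq_along(pats)) {
    m <- if (wild[j]) startsWith(tokens, stems[j]) else tokens == pats[j]
    if (any(m)) {
      for (cid in dictionary$pattern_categories[[j]]) {
        out[m, cid] <- TRUE
      }
    }
  }
  out
}

#' Derive a category dictionary from an emotion lexicon
#'
#' Builds a literal-pattern `category_dictionary` whose categories mirror the
#' usual affect hierarchy: every lexicon term is credited to `affect`;
#' anger/anxiety/sadness terms additionally to `negative` and their specific
#' category; `positive` terms to `positive`; `negative` terms to `negative`.
#' This gives congruence analyses a dictionary consistent with the lexicon
#' without shipping a second word list.
#'
#' @param lexicon An `emotion_lexicon`.
#' @return A `category_dictionary` with categories `affect`, `positive`,
#'   `negative`, `anger`, `anxiety`, `sadness`.
#' @export
category_dictionary_from_lexicon <- function(lexicon) {
  stopifnot(inherits(lexicon, "emotion_lexicon"))
  ids <- c(affect = "1", positive = "2", negative = "3", anger = "4",
           anxiety = "5", sadness = "6")
  idx <- c(affect = 1L, positive = 2L, negative = 3L, anger = 4L,
           anxiety = 5L, sadness = 6L)
  cat_sets <- list(
    anger        = idx[c("affect", "negative", "anger")],
    anxiety      = idx[c("affect", "negative", "anxiety")],
    sadness      = idx[c("affect", "negative", "sadness")],
    positive     = idx[c("affect", "positive")],
    negative     = idx[c("affect", "negative")],
    other_affect = idx["affect"])
  terms <- names(lexicon$category_of)
  structure(list(
    patterns = unname(terms),
    pattern_categories = lapply(unname(lexicon$category_of[terms]),
                                function(cc) unname(cat_sets[[cc]])),
    category_names = stats::setNames(names(ids), unname(ids))),
    class = "category_dictionary")
}
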