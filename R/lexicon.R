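#' Affect lexicon categories
#'
#' Category labels an [emotion_lexicon] term may carry. Terms with no stated
#' category default to `"other_affect"`.
#' @keywords internal
LEXICON_CATEGORIES <- c("anger", "anxiety", "sadness", "positive",
                        "negative", "other_affect")

#' Load an emotion lexicon
#'
#' Reads a table of affect terms into an `emotion_lexicon` object. The lexicon
#' is an exact-match, lowercase word set: each row supplies a base term (e.g.
#' the adjectival form `"angry"`), optionally a comma-separated list of
#' syntactic variants with identical or near-identical meaning (`"anger"`,
#' `"angrily"`), and optionally an emotion category. Variant expansion is
#' data-driven rather than algorithmic stemming, which would over-match
#' (e.g. "moved" to "move").
#'
#' @param source Path to a UTF-8 TSV file with columns `term`, `variants`
#'   (optional, comma-separated) and `category` (optional), or a data frame
#'   with those columns.
#' @return An object of class `emotion_lexicon` with elements
#'   \describe{
#'     \item{terms}{character vector of all surface forms (bases + variants).}
#'     \item{base_terms}{the base terms only.}
#'     \item{base_to_variants}{named list mapping each base to its variants.}
#'     \item{base_of}{named character mapping every term to its base.}
#'     \item{category_of}{named character mapping every term to a category in
#'       `anger`, `anxiety`, `sadness`, `positive`, `negative`,
#'       `other_affect`.}
#'   }
#' @examples
#' lex <- load_emotion_lexicon(data.frame(
#'   term = c("angry", "sad"),
#'   variants = c("anger,angrily", ""),
#'   category = c("anger", "sadness")))
#' is_emotion_word(c("anger", "table"), lex)
#' @export
load_emotion_lexicon <- function(source) {
  tab <- if (is.character(source) && length(source) == 1L) {
    utils::read.delim(source, stringsAsFactors = FALSE, quote = "",
                      comment.char = "#", na.strings = character())
  } else {
    as.data.frame(source, stringsAsFactors = FALSE)
  }
  if (!"term" %in% names(tab)) {
    stop("lexicon source must have a 'term' column", call. = FALSE)
  }
  base <- tolower(trimws(as.character(tab$term)))
  if (any(base == "")) {
    stop("empty base term at row(s): ",
         paste(which(base == ""), collapse = ", "), call. = FALSE)
  }
  bad <- grepl("\\s", base)
  if (any(bad)) {
    stop("base terms must be single tokens (no whitespace); offending row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(base)) {
    dup <- which(base %in% base[duplicated(base)])
    stop("duplicate base terms at row(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }

  vcol <- if ("variants" %in% names(tab)) as.character(tab$variants) else
    rep("", length(base))
  vcol[is.na(vcol)] <- ""
  variants <- lapply(strsplit(tolower(vcol), ","), function(v) {
    v <- trimws(v)
    unique(v[v != ""])
  })
  names(variants) <- base
  vflat <- unlist(variants, use.names = FALSE)
  if (any(grepl("\\s", vflat))) {
    stop("variants must be single tokens (no whitespace)", call. = FALSE)
  }
  if (anyDuplicated(vflat)) {
    stop("variant(s) listed under more than one base term: ",
         paste(unique(vflat[duplicated(vflat)]), collapse = ", "),
         call. = FALSE)
  }
  clash <- intersect(vflat, base)
  if (length(clash)) {
    stop("variant(s) duplicate a base term: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }

  cat_raw <- if ("category" %in% names(tab)) {
    tolower(trimws(as.character(tab$category)))
  } else rep("", length(base))
  cat_raw[is.na(cat_raw) | cat_raw == ""] <- "other_affect"
  unknown <- setdiff(unique(cat_raw), LEXICON_CATEGORIES)
  if (length(unknown)) {
    stop("unknown lexicon categor(ies): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  base_of_variant <- rep(base, lengths(variants))
  terms <- c(base, vflat)
  base_of <- stats::setNames(c(base, base_of_variant), terms)
  category_of <- stats::setNames(cat_raw[match(base_of, base)], terms)

  structure(
    list(terms = terms, base_terms = base, base_to_variants = variants,
         base_of = base_of, category_of = category_of),
    class = "emotion_lexicon")
}

#' Write an emotion lexicon back to TSV
#'
#' Inverse of [load_emotion_lexicon()]: reloading the written file yields an
#' identical term set, variant map and category map.
#'
#' @param lexicon An `emotion_lexicon`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_emotion_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "emotion_lexicon"))
  tab <- data.frame(
    term = lexicon$base_terms,
    variants = vapply(lexicon$base_to_variants, paste, "", collapse = ","),
    category = unname(lexicon$category_of[lexicon$base_terms]),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged synthetic emotion lexicon
#'
#' Loads the lexicon shipped with the package:
#' `inst/extdata/emotion_lexicon_synthetic.tsv`, a curated set of English
#' affective-state adjectives with syntactic variants, organised in the five
#' working categories (anger, anxiety, sadness, positive, negative) plus
#' `other_affect`. It is a synthetic stand-in constructed for this package —
#' comparable in structure and scale to published affective taxonomies, but
#' not a reproduction of any proprietary or published word list. Pass your
#' own TSV to [load_emotion_lexicon()] to use a different lexicon.
#'
#' @return An `emotion_lexicon`.
#' @export
default_emotion_lexicon <- function() {
  load_emotion_lexicon(system.file("extdata", "emotion_lexicon_synthetic.tsv",
                                   package = "aprqtext", mustWork = TRUE))
}

#' @export
print.emotion_lexicon <- function(x, ...) {
  cat("Emotion lexicon:", length(x$base_terms), "base terms,",
      length(x$terms), "surface forms\n")
  tab <- table(x$category_of[x$base_terms])
  cat("Base terms by category:\n")
  for (nm in names(tab)) cat(sprintf("  %-12s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Test tokens for lexicon membership
#'
#' @param tokens Character vector of lowercase tokens.
#' @param lexicon An `emotion_lexicon`.
#' @return Logical vector: is each token an affect term (base or variant)?
#' @export
is_emotion_word <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "emotion_lexicon"))
  tokens %in% lexicon$terms
}

#' All surface forms of a lexicon category
#'
#' @param lexicon An `emotion_lexicon`.
#' @param category One of the lexicon categories.
#' @return Character vector of terms (bases and variants) in that category.
#' @export
emotion_sublexicon <- function(lexicon, category) {
  stopifnot(inherits(lexicon, "emotion_lexicon"))
  category <- match.arg(category, LEXICON_CATEGORIES)
  names(lexicon$category_of)[lexicon$category_of == category]
}

#' Build a stopword list
#'
#' Unions a base stopword list with custom additions such as transcribed
#' filler sounds; everything is lowercased. Interview transcripts carry
#' hesitation fillers ("hmm", "ahm", "ehm") that standard stopword lists
#' miss, so those three are the default custom set.
#'
#' @param base_list Character vector of stopwords.
#' @param custom_fillers Character vector of additions
#'   (default `c("hmm", "ahm", "ehm")`).
#' @return Sorted character vector of unique lowercase stopwords.
#' @export
build_stopwords <- function(base_list,
                            custom_fillers = c("hmm", "ahm", "ehm")) {
  words <- sort(unique(tolower(c(as.character(base_list),
                                 as.character(custom_fillers)))))
  words <- words[words != ""]
  if (!length(words)) stop("stopword list is empty", call. = FALSE)
  words
}

#' Packaged English stopword list with interview fillers
#'
#' Reads the packaged base list of English function words
#' (`inst/extdata/stopwords_en.txt`) and adds the transcription fillers via
#' [build_stopwords()]. The base list is a conventional function-word
#' inventory in the style of the snowball list; which list to use is a
#' configuration choice, so any character vector can be passed downstream
#' instead.
#'
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "aprqtext",
                      mustWork = TRUE)
  build_stopwords(readLines(path, encoding = "UTF-8"))
}
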