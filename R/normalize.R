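#' Text normalization configuration
#'
#' Holds the stop-word list and stemming scheme used to canonicalize free-text
#' ingredient mentions. The default stop words are a compact English list plus
#' food-label boilerplate ("contains", "ingredients", "may", "trace", ...),
#' read from `inst/extdata/stopwords.txt` so users can supply their own file.
#'
#' @param stopwords character vector of lowercase stop words, or a path to a
#'   plain-text file with one token per line.
#' @param stemmer stemming scheme; only `"porter"` is implemented.
#' @return an object of class `normalization_config`.
#' @examples
#' cfg <- normalization_config()
#' normalize_token("Contains Soy Lecithin", cfg)
#' @export
normalization_config <- function(stopwords = default_stopwords(),
                                 stemmer = "porter") {
  if (length(stopwords) == 1L && file.exists(stopwords)) {
    stopwords <- readLines(stopwords, warn = FALSE)
  }
  stemmer <- match.arg(stemmer, "porter")
  stopwords <- tolower(trimws(stopwords))
  stopwords <- stopwords[nzchar(stopwords)]
  structure(list(stopwords = stopwords, stemmer = stemmer),
            class = "normalization_config")
}

#' @rdname normalization_config
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords.txt", package = "foodgraph")
  if (nzchar(path)) return(readLines(path, warn = FALSE))
  # fallback when called from a source tree (e.g. pkgload)
  c("a", "an", "and", "are", "as", "at", "by", "for", "from", "in", "into",
    "is", "it", "of", "on", "or", "the", "to", "with",
    "contains", "contain", "ingredient", "ingredients", "may", "trace",
    "traces", "added", "include", "includes", "including", "less", "than")
}

#' Normalize a free-text ingredient mention to a canonical token
#'
#' Lowercases, strips punctuation, removes stop words and stems each remaining
#' word (to a fixed point, so normalization is idempotent). Multi-word
#' ingredients stay a single token with words joined by one space, so entity
#' matching is exact on the normalized string ("Soy Lecithin" -> "soy lecithin"
#' after stemming). Words containing digits are kept verbatim.
#'
#' @param raw character vector of raw mentions.
#' @param cfg a [normalization_config()].
#' @return character vector of normalized tokens; an element that is empty or
#'   reduced to nothing by stop-word removal raises an
#'   `"empty-after-normalization"` error unless `on_empty = "drop"` (then
#'   `NA_character_` is returned for it).
#' @param on_empty `"error"` (default) or `"drop"` (return `NA` for mentions
#'   that normalize to nothing).
#' @examples
#' normalize_token("Contains Soy", normalization_config())  # "soy"
#' normalize_token("peanuts", normalization_config())       # "peanut"
#' @export
normalize_token <- function(raw, cfg = normalization_config(),
                            on_empty = c("error", "drop")) {
  on_empty <- match.arg(on_empty)
  stopifnot(inherits(cfg, "normalization_config"))
  out <- vapply(as.character(raw), function(x) {
    if (is.na(x)) return(NA_character_)
    x <- tolower(x)
    x <- gsub("[^a-z0-9]+", " ", x)
    words <- strsplit(trimws(x), " +")[[1]]
    words <- setdiff(words, cfg$stopwords)
    words <- vapply(words, stem_fixpoint, character(1), USE.NAMES = FALSE)
    words <- words[nzchar(words)]
    if (length(words) == 0L) NA_character_ else paste(words, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
  if (on_empty == "error" && anyNA(out)) {
    stop_foodgraph("empty-after-normalization",
                   "input normalizes to an empty token")
  }
  out
}

# stemming to a fixed point keeps normalize_token idempotent
stem_fixpoint <- function(word) {
  repeat {
    stemmed <- porter_stem1(word)
    if (identical(stemmed, word)) return(word)
    word <- stemmed
  }
}

stop_foodgraph <- function(class, message, ...) {
  stop(structure(class = c(class, "foodgraph_error", "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}
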