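#' Porter suffix-stripping stemmer
#'
#' Reduces an English word to its stem by the Porter (1980) algorithm, the
#' standard suffix stripper used to improve entity matching between ingredient
#' mentions ("peanuts", "peanut" -> "peanut"). Words of length 1-2 and words
#' containing non-alphabetic characters are returned unchanged.
#'
#' @param words character vector of lowercase words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("peanuts", "flavoring", "sulphites"))
#' @export
porter_stem <- function(words) {
  stopifnot(is.character(words))
  vapply(words, porter_stem1, character(1), USE.NAMES = FALSE)
}

porter_stem1 <- function(word) {
  if (is.na(word) || nchar(word) <= 2L) return(word)
  if (grepl("[^a-z]", word)) return(word)
  w <- strsplit(word, "", fixed = TRUE)[[1]]
  w <- p_step1a(w)
  w <- p_step1b(w)
  w <- p_step1c(w)
  w <- p_step2(w)
  w <- p_step3(w)
  w <- p_step4(w)
  w <- p_step5a(w)
  w <- p_step5b(w)
  paste(w, collapse = "")
}

# consonant-ness of each position; 'y' is a vowel when preceded by a consonant
p_cons <- function(w) {
  n <- length(w)
  out <- logical(n)
  for (i in seq_len(n)) {
    ch <- w[i]
    out[i] <- if (ch %in% c("a", "e", "i", "o", "u")) {
      FALSE
    } else if (ch == "y") {
      if (i == 1L) TRUE else !out[i - 1L]
    } else TRUE
  }
  out
}

# the measure m: number of vowel->consonant transitions in [C](VC)^m[V]
p_measure <- function(w) {
  if (length(w) == 0L) return(0L)
  cons <- p_cons(w)
  rle_v <- rle(cons)
  vals <- rle_v$values
  sum(vals[-length(vals)] == FALSE & vals[-1L] == TRUE)
}

p_has_vowel <- function(w) length(w) > 0L && any(!p_cons(w))

p_ends <- function(w, suffix) {
  s <- strsplit(suffix, "", fixed = TRUE)[[1]]
  n <- length(w); k <- length(s)
  n >= k && all(w[(n - k + 1L):n] == s)
}

p_stem_before <- function(w, suffix) w[seq_len(length(w) - nchar(suffix))]

p_double_cons <- function(w) {
  n <- length(w)
  n >= 2L && w[n] == w[n - 1L] && p_cons(w)[n]
}

# ends consonant-vowel-consonant where the final consonant is not w, x or y
p_ends_cvc <- function(w) {
  n <- length(w)
  if (n < 3L) return(FALSE)
  cons <- p_cons(w)
  cons[n - 2L] && !cons[n - 1L] && cons[n] && !(w[n] %in% c("w", "x", "y"))
}

p_step1a <- function(w) {
  if (p_ends(w, "sses")) return(c(p_stem_before(w, "sses"), "s", "s"))
  if (p_ends(w, "ies")) return(c(p_stem_before(w, "ies"), "i"))
  if (p_ends(w, "ss")) return(w)
  if (p_ends(w, "s")) return(p_stem_before(w, "s"))
  w
}

p_step1b <- function(w) {
  if (p_ends(w, "eed")) {
    stem <- p_stem_before(w, "eed")
    if (p_measure(stem) > 0L) return(c(stem, "e", "e"))
    return(w)
  }
  stripped <- NULL
  if (p_ends(w, "ed") && p_has_vowel(p_stem_before(w, "ed"))) {
    stripped <- p_stem_before(w, "ed")
  } else if (p_ends(w, "ing") && p_has_vowel(p_stem_before(w, "ing"))) {
    stripped <- p_stem_before(w, "ing")
  }
  if (is.null(stripped)) return(w)
  if (p_ends(stripped, "at") || p_ends(stripped, "bl") || p_ends(stripped, "iz")) {
    return(c(stripped, "e"))
  }
  if (p_double_cons(stripped) && !(stripped[length(stripped)] %in% c("l", "s", "z"))) {
    return(stripped[-length(stripped)])
  }
  if (p_measure(stripped) == 1L && p_ends_cvc(stripped)) return(c(stripped, "e"))
  stripped
}

# y -> i only after a consonant (the standard refinement: "soy", "sky" and
# "enjoy" stay intact while "happy" -> "happi")
p_step1c <- function(w) {
  if (p_ends(w, "y")) {
    stem <- p_stem_before(w, "y")
    if (p_has_vowel(stem) && p_cons(stem)[length(stem)]) {
      return(c(stem, "i"))
    }
  }
  w
}

# rule tables: suffix -> replacement, applied to the longest matching suffix
p_rules2 <- list(
  ational = "ate", tional = "tion", enci = "ence", anci = "ance", izer = "ize",
  abli = "able", alli = "al", entli = "ent", eli = "e", ousli = "ous",
  ization = "ize", ation = "ate", ator = "ate", alism = "al", iveness = "ive",
  fulness = "ful", ousness = "ous", aliti = "al", iviti = "ive", biliti = "ble"
)
p_rules3 <- list(
  icate = "ic", ative = "", alize = "al", iciti = "ic",
  ical = "ic", ful = "", ness = ""
)
p_rules4 <- c(
  "ement", "ance", "ence", "able", "ible", "ment", "ion", "ant", "ent", "ism",
  "ate", "iti", "ous", "ive", "ize", "al", "er", "ic", "ou"
)

p_apply_rules <- function(w, rules, min_measure) {
  suffixes <- names(rules)
  suffixes <- suffixes[order(nchar(suffixes), decreasing = TRUE)]
  for (suf in suffixes) {
    if (p_ends(w, suf)) {
      stem <- p_stem_before(w, suf)
      if (p_measure(stem) > min_measure - 1L) {
        repl <- rules[[suf]]
        if (nzchar(repl)) stem <- c(stem, strsplit(repl, "", fixed = TRUE)[[1]])
        return(stem)
      }
      return(w)  # only the longest matching suffix is considered
    }
  }
  w
}

p_step2 <- function(w) p_apply_rules(w, p_rules2, 1L)
p_step3 <- function(w) p_apply_rules(w, p_rules3, 1L)

p_step4 <- function(w) {
  for (suf in p_rules4) {
    if (p_ends(w, suf)) {
      stem <- p_stem_before(w, suf)
      if (suf == "ion" && !(length(stem) > 0L && stem[length(stem)] %in% c("s", "t"))) {
        return(w)
      }
      if (p_measure(stem) > 1L) return(stem)
      return(w)
    }
  }
  w
}

p_step5a <- function(w) {
  if (!p_ends(w, "e")) return(w)
  stem <- p_stem_before(w, "e")
  m <- p_measure(stem)
  if (m > 1L || (m == 1L && !p_ends_cvc(stem))) return(stem)
  w
}

p_step5b <- function(w) {
  if (p_measure(w) > 1L && p_ends(w, "ll")) return(w[-length(w)])
  w
}
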