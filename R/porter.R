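# Classic Porter stemming algorithm (1980), operating on lowercase ASCII words.
# y counts as a vowel when preceded by a consonant; words of length <= 2 are
# returned unchanged, as in the original definition.

.pt_cons <- function(chs, i) {
  ch <- chs[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.pt_cons(chs, i - 1L))
  }
  TRUE
}

.pt_types <- function(word) {
  chs <- strsplit(word, "", fixed = TRUE)[[1L]]
  n <- length(chs)
  if (n == 0L) return(logical(0L))
  vapply(seq_len(n), function(i) .pt_cons(chs, i), logical(1L))
}

# measure m: number of VC sequences in [C](VC){m}[V]
.pt_m <- function(stem) {
  types <- .pt_types(stem)
  if (length(types) == 0L) return(0L)
  runs <- rle(types)$values
  if (length(runs) < 2L) return(0L)
  sum(!runs[-length(runs)] & runs[-1L])
}

.pt_has_vowel <- function(stem) {
  any(!.pt_types(stem))
}

# *d: ends with a double consonant
.pt_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L)
  b <- substr(word, n, n)
  if (a != b) return(FALSE)
  types <- .pt_types(word)
  types[n]
}

# *o: ends cvc where the final c is not w, x or y
.pt_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  types <- .pt_types(word)
  if (!(types[n - 2L] && !types[n - 1L] && types[n])) return(FALSE)
  !substr(word, n, n) %in% c("w", "x", "y")
}

.pt_ends <- function(word, suffix) {
  n <- nchar(word)
  s <- nchar(suffix)
  n >= s && substr(word, n - s + 1L, n) == suffix
}

.pt_chop <- function(word, k) substr(word, 1L, nchar(word) - k)

# apply the first (longest) matching rule of a step-2/3/4 style table;
# rules is a list of c(suffix, replacement), cond takes the stem
.pt_rule <- function(word, rules, cond) {
  ord <- order(vapply(rules, function(r) nchar(r[[1L]]), integer(1L)),
               decreasing = TRUE)
  for (r in rules[ord]) {
    if (.pt_ends(word, r[[1L]])) {
      stem <- .pt_chop(word, nchar(r[[1L]]))
      if (cond(stem)) return(paste0(stem, r[[2L]]))
      return(word)
    }
  }
  word
}

.pt_step1a <- function(w) {
  if (.pt_ends(w, "sses")) return(.pt_chop(w, 2L))
  if (.pt_ends(w, "ies")) return(.pt_chop(w, 2L))
  if (.pt_ends(w, "ss")) return(w)
  if (.pt_ends(w, "s")) return(.pt_chop(w, 1L))
  w
}

.pt_step1b <- function(w) {
  if (.pt_ends(w, "eed")) {
    stem <- .pt_chop(w, 3L)
    if (.pt_m(stem) > 0L) return(.pt_chop(w, 1L))
    return(w)
  }
  hit <- FALSE
  if (.pt_ends(w, "ed") && .pt_has_vowel(.pt_chop(w, 2L))) {
    w <- .pt_chop(w, 2L)
    hit <- TRUE
  } else if (.pt_ends(w, "ing") && .pt_has_vowel(.pt_chop(w, 3L))) {
    w <- .pt_chop(w, 3L)
    hit <- TRUE
  }
  if (hit) {
    if (.pt_ends(w, "at") || .pt_ends(w, "bl") || .pt_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.pt_double_cons(w) &&
               !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
      w <- .pt_chop(w, 1L)
    } else if (.pt_m(w) == 1L && .pt_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  w
}

.pt_step1c <- function(w) {
  if (.pt_ends(w, "y") && .pt_has_vowel(.pt_chop(w, 1L))) {
    return(paste0(.pt_chop(w, 1L), "i"))
  }
  w
}

.pt_step2_rules <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
  c("anci", "ance"), c("izer", "ize"), c("abli", "able"), c("alli", "al"),
  c("entli", "ent"), c("eli", "e"), c("ousli", "ous"), c("ization", "ize"),
  c("ation", "ate"), c("ator", "ate"), c("alism", "al"), c("iveness", "ive"),
  c("fulness", "ful"), c("ousness", "ous"), c("aliti", "al"),
  c("iviti", "ive"), c("biliti", "ble")
)

.pt_step3_rules <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", "")
)

.pt_step4_suffixes <- c(
  "al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
  "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize"
)

.pt_step4 <- function(w) {
  ord <- order(nchar(.pt_step4_suffixes), decreasing = TRUE)
  for (suf in .pt_step4_suffixes[ord]) {
    if (.pt_ends(w, suf)) {
      stem <- .pt_chop(w, nchar(suf))
      if (.pt_m(stem) > 1L) {
        if (suf == "ion" &&
            !substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")) {
          return(w)
        }
        return(stem)
      }
      return(w)
    }
  }
  w
}

.pt_step5a <- function(w) {
  if (.pt_ends(w, "e")) {
    stem <- .pt_chop(w, 1L)
    m <- .pt_m(stem)
    if (m > 1L || (m == 1L && !.pt_cvc(stem))) return(stem)
  }
  w
}

.pt_step5b <- function(w) {
  if (.pt_m(w) > 1L && .pt_double_cons(w) &&
      substr(w, nchar(w), nchar(w)) == "l") {
    return(.pt_chop(w, 1L))
  }
  w
}

.pt_stem_one <- function(word) {
  if (nchar(word) <= 2L) return(word)
  w <- .pt_step1a(word)
  w <- .pt_step1b(w)
  w <- .pt_step1c(w)
  w <- .pt_rule(w, .pt_step2_rules, function(s) .pt_m(s) > 0L)
  w <- .pt_rule(w, .pt_step3_rules, function(s) .pt_m(s) > 0L)
  w <- .pt_step4(w)
  w <- .pt_step5a(w)
  .pt_step5b(w)
}

#' Stem words with the Porter algorithm
#'
#' Applies the classic Porter suffix-stripping algorithm to each element of a
#' character vector. Inputs are expected to be lowercase tokens (the output of
#' [tokenize()]); uppercase letters are lowercased first. Stemming is
#' idempotent: `porter_stem(porter_stem(x))` equals `porter_stem(x)`.
#'
#' @param words character vector of tokens.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("abnormalities", "abnormality", "decreased", "depth"))
#' @export
porter_stem <- function(words) {
  if (length(words) == 0L) return(character(0L))
  stopifnot(is.character(words))
  vapply(tolower(words), .pt_stem_one, character(1L), USE.NAMES = FALSE)
}
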