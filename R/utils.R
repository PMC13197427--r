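# Internal helpers shared across modules.

pr_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "pr_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' Normalize text for keyword matching
#'
#' Applies Unicode NFKC normalization and lower-casing so that keyword
#' lexicons in different scripts (Japanese full-width/half-width variants,
#' Latin case variants) match consistently. All keyword matching in the
#' scoring module operates on text normalized by this function.
#'
#' @param x Character vector.
#' @return Character vector of the same length, NFKC-normalized and
#'   lower-cased.
#' @export
normalize_text <- function(x) {
  if (length(x) == 0) return(character(0))
  tolower(stringi::stri_trans_nfkc(as.character(x)))
}

# TRUE if any keyword occurs as a substring of the (already joined) text.
# Both sides are normalized; matching is fixed (no regex).
contains_any <- function(text, keywords) {
  if (length(keywords) == 0 || length(text) == 0) return(FALSE)
  txt <- paste(normalize_text(text), collapse = "   ")
  any(vapply(
    normalize_text(keywords),
    function(k) grepl(k, txt, fixed = TRUE),
    logical(1)
  ))
}

# Number of distinct keywords (types) present in the text.
count_matching_types <- function(text, keywords) {
  if (length(keywords) == 0 || length(text) == 0) return(0L)
  txt <- paste(normalize_text(text), collapse = "   ")
  sum(vapply(
    normalize_text(keywords),
    function(k) grepl(k, txt, fixed = TRUE),
    logical(1)
  ))
}

# Total keyword occurrences (tokens, not types) across a character vector.
count_occurrences <- function(text, keywords) {
  if (length(keywords) == 0 || length(text) == 0) return(0L)
  txt <- normalize_text(text)
  total <- 0L
  for (k in normalize_text(keywords)) {
    hits <- gregexpr(k, txt, fixed = TRUE)
    total <- total + sum(vapply(hits, function(m) {
      if (m[1] == -1L) 0L else length(m)
    }, integer(1)))
  }
  total
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up in magnitude (the convention used for
#' percent display in the summary tables), as opposed to [round()]'s
#' round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

is_scalar_chr <- function(x) is.character(x) && length(x) == 1 && !is.na(x)
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x)

# Run code under a local RNG substream without disturbing the caller's RNG.
with_substream <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic substream seed: fold the UTF-8 bytes of a key string into
# [1, 2^31 - 2] starting from the master seed. All intermediates stay well
# below 2^53 so the arithmetic is exact in doubles, and the seed for one
# record never depends on which other records exist.
substream_seed <- function(master_seed, key) {
  m <- 2147483647
  h <- as.numeric(master_seed) %% m
  for (b in as.integer(charToRaw(enc2utf8(key)))) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h %% (m - 1) + 1)
}
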