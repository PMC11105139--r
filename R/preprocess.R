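# Text normalization, tokenization and section detection.
#
# All public character offsets in this package are 0-based and half-open
# (a span [start, end) covers characters start .. end-1), measured in
# characters (not bytes) on the raw note text. Normalized-text offsets use
# the same convention on the normalized string.

# Explicit character mapping used by normalize_text(). A table (rather than
# a generic Unicode decomposition) keeps the normalized->raw offset map
# deterministic and auditable; ligatures expand to two characters, both of
# which trace back to the source character.
norm_char_table <- c(
  "à" = "a", "â" = "a", "ä" = "a", "á" = "a", "ã" = "a", "å" = "a",
  "À" = "a", "Â" = "a", "Ä" = "a", "Á" = "a", "Ã" = "a", "Å" = "a",
  "é" = "e", "è" = "e", "ê" = "e", "ë" = "e",
  "É" = "e", "È" = "e", "Ê" = "e", "Ë" = "e",
  "î" = "i", "ï" = "i", "í" = "i", "ì" = "i",
  "Î" = "i", "Ï" = "i", "Í" = "i", "Ì" = "i",
  "ô" = "o", "ö" = "o", "ó" = "o", "ò" = "o", "õ" = "o",
  "Ô" = "o", "Ö" = "o", "Ó" = "o", "Ò" = "o", "Õ" = "o",
  "ù" = "u", "û" = "u", "ü" = "u", "ú" = "u",
  "Ù" = "u", "Û" = "u", "Ü" = "u", "Ú" = "u",
  "ç" = "c", "Ç" = "c",
  "ÿ" = "y", "ý" = "y", "Ý" = "y",
  "ñ" = "n", "Ñ" = "n",
  "œ" = "oe", "Œ" = "oe",
  "æ" = "ae", "Æ" = "ae",
  # typographic quotes -> ASCII
  "«" = "\"", "»" = "\"", "“" = "\"", "”" = "\"", "„" = "\"",
  "‘" = "'", "’" = "'", "‚" = "'", "´" = "'", "`" = "'",
  # non-breaking / narrow spaces -> plain space
  " " = " ", " " = " "
)

#' Normalize clinical text while tracking raw offsets
#'
#' Lowercases the text, strips diacritics through an explicit per-character
#' table (ligatures expand: \code{"œ"} becomes \code{"oe"}), and maps
#' typographic quotes to their ASCII equivalents. Every character of the
#' normalized string traces back to the raw character that produced it, so
#' spans found on normalized text can be reported on the raw note.
#'
#' @param raw A single character string (the raw note text).
#'
#' @return An object of class `normalized_text`: a list with elements
#'   `norm` (the normalized string), `norm_to_raw` (an integer vector of
#'   length `nchar(norm)` giving, for each normalized character, the 0-based
#'   index of the raw character it came from), and `raw_len`.
#'
#' @examples
#' nt <- normalize_text("Diabète « sévère »")
#' nt$norm
#' @export
normalize_text <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L, !is.na(raw))
  raw <- enc2utf8(raw)
  if (nchar(raw) == 0L) {
    return(structure(
      list(norm = "", norm_to_raw = integer(0), raw_len = 0L),
      class = "normalized_text"
    ))
  }
  chars <- strsplit(raw, "", fixed = TRUE)[[1]]
  mapped <- unname(norm_char_table[chars])
  miss <- is.na(mapped)
  mapped[miss] <- tolower(chars[miss])
  lens <- nchar(mapped, type = "chars")
  structure(
    list(
      norm = paste(mapped, collapse = ""),
      norm_to_raw = rep(seq_along(chars) - 1L, times = lens),
      raw_len = length(chars)
    ),
    class = "normalized_text"
  )
}

#' @export
print.normalized_text <- function(x, ...) {
  cat("<normalized_text> ", x$raw_len, " raw chars -> ",
      nchar(x$norm), " normalized\n", sep = "")
  invisible(x)
}

# Map a 0-based half-open span on normalized text to the raw text.
norm_span_to_raw <- function(nt, start, end) {
  if (length(nt$norm_to_raw) == 0L || end <= start) {
    return(c(start = 0L, end = 0L))
  }
  c(start = nt$norm_to_raw[start + 1L], end = nt$norm_to_raw[end] + 1L)
}

# Extract a 0-based half-open span from a string (character units).
slice_chars <- function(text, start, end) {
  substr(text, start + 1L, end)
}

#' Tokenize normalized text
#'
#' Splits on whitespace, separates punctuation into single-character tokens,
#' and applies the French apostrophe-elision rule: `"l'asthme"` yields the
#' tokens `"l'"` and `"asthme"`. Every non-whitespace character belongs to
#' exactly one token.
#'
#' @param norm_text A `normalized_text` object, or a plain string (assumed
#'   already normalized).
#'
#' @return A tibble with one row per token: `idx` (1-based token index),
#'   `surface`, and 0-based half-open `start`/`end` offsets on the
#'   normalized text.
#' @examples
#' tokenize("pas de diabete.")
#' @export
tokenize <- function(norm_text) {
  norm <- if (inherits(norm_text, "normalized_text")) norm_text$norm else norm_text
  stopifnot(is.character(norm), length(norm) == 1L)
  if (nchar(norm) == 0L) {
    return(tibble::tibble(
      idx = integer(0), surface = character(0),
      start = integer(0), end = integer(0)
    ))
  }
  m <- gregexpr("[[:alnum:]]+'?|[^[:space:]]", norm, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(tibble::tibble(
      idx = integer(0), surface = character(0),
      start = integer(0), end = integer(0)
    ))
  }
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  tibble::tibble(
    idx = seq_along(starts),
    surface = substring(norm, starts + 1L, starts + lens),
    start = starts,
    end = starts + as.integer(lens)
  )
}

#' Detect titled sections in a normalized note
#'
#' Section titles are recognized from a configurable lexicon of title
#' patterns; a title must sit at the beginning of a line and be followed by
#' a colon. Each matched title opens a section that extends to the next
#' title (or the end of the note). Text before the first title forms one
#' implicit `relevant` section. When two title patterns match at the same
#' position the longest match wins.
#'
#' @param norm_text A `normalized_text` object or a normalized string.
#' @param section_lexicon A data frame with columns `pattern` (regex, matched
#'   on normalized text) and `relevance` (one of `"relevant"`,
#'   `"irrelevant"`, `"family_history"`). Defaults to the bundled French
#'   lexicon.
#'
#' @return A tibble with columns `title`, `start`, `end` (0-based half-open
#'   offsets on the normalized text) and `relevance`. Sections are ordered
#'   and non-overlapping and jointly cover the whole note.
#' @examples
#' detect_sections("antecedents familiaux :\npere diabetique\nconclusion :\nrien")
#' @export
detect_sections <- function(norm_text, section_lexicon = load_section_lexicon()) {
  norm <- if (inherits(norm_text, "normalized_text")) norm_text$norm else norm_text
  stopifnot(is.character(norm), length(norm) == 1L)
  n <- nchar(norm)
  empty <- tibble::tibble(
    title = character(0), start = integer(0),
    end = integer(0), relevance = character(0)
  )
  if (n == 0L) return(empty)

  hits <- purrr::pmap_dfr(
    list(section_lexicon$pattern, section_lexicon$relevance),
    function(pattern, relevance) {
      rx <- paste0("(?m)^[ \t]*(?:", pattern, ")[ \t]*:")
      m <- gregexpr(rx, norm, perl = TRUE)[[1]]
      if (m[1] == -1L) return(NULL)
      tibble::tibble(
        start = as.integer(m) - 1L,
        len = as.integer(attr(m, "match.length")),
        relevance = relevance
      )
    }
  )

  if (nrow(hits) == 0L) {
    return(tibble::tibble(
      title = NA_character_, start = 0L, end = as.integer(n),
      relevance = "relevant"
    ))
  }

  # longest match at each position, then drop titles nested in earlier ones
  hits <- hits |>
    dplyr::arrange(.data$start, dplyr::desc(.data$len)) |>
    dplyr::distinct(.data$start, .keep_all = TRUE)
  keep <- logical(nrow(hits))
  last_end <- -1L
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- hits$start[i] + hits$len[i]
    }
  }
  hits <- hits[keep, , drop = FALSE]

  bounds <- c(hits$start, as.integer(n))
  sections <- tibble::tibble(
    title = stringr::str_remove(
      substring(norm, hits$start + 1L, hits$start + hits$len), "[ \t]*:$"
    ),
    start = hits$start,
    end = bounds[-1],
    relevance = hits$relevance
  )
  if (hits$start[1] > 0L) {
    sections <- dplyr::bind_rows(
      tibble::tibble(
        title = NA_character_, start = 0L, end = hits$start[1],
        relevance = "relevant"
      ),
      sections
    )
  }
  sections
}
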