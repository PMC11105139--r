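# Per-condition NER: regex-dictionary matching on normalized text,
# identified-mechanism exclusions, section flags and context severity
# assignment. Mention spans are always reported on the raw note text; the
# internal `norm_start`/`norm_end` columns (normalized-text spans) are kept
# alongside while a mention table flows through the pipeline and are dropped
# by the writers.

#' Compile condition matchers
#'
#' Turns validated condition definitions into one matcher per condition
#' (inclusion patterns with optional status hints, exclusion patterns and
#' severity rules). Compilation cannot fail: regexes are validated when the
#' definitions are loaded.
#'
#' @param definitions A `condition_definitions` object.
#' @return A list of matchers (class `condition_matchers`), one per
#'   condition, in definition order.
#' @export
compile_matchers <- function(definitions) {
  matchers <- purrr::map(definitions, function(d) {
    list(
      condition_id = d$condition_id,
      statuses = d$statuses,
      window_tokens = d$window_tokens,
      patterns = d$patterns,
      exclusion_patterns = d$exclusion_patterns,
      severity_rules = d$severity_rules
    )
  })
  structure(matchers, class = "condition_matchers")
}

# All matches of one regex on a string, as parallel vectors of 0-based
# half-open spans (zero-length matches are dropped). A bare list keeps this
# hot path allocation-light.
regex_spans <- function(rx, text) {
  m <- gregexpr(rx, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(list(start = integer(0), end = integer(0)))
  }
  lens <- as.integer(attr(m, "match.length"))
  keep <- lens > 0L
  list(
    start = as.integer(m)[keep] - 1L,
    end = as.integer(m)[keep] - 1L + lens[keep]
  )
}

# Preprocess one note: normalization, tokens, sections.
preprocess_note <- function(text, section_lexicon = load_section_lexicon()) {
  nt <- normalize_text(text)
  list(
    nt = nt,
    tokens = tokenize(nt),
    sections = detect_sections(nt, section_lexicon)
  )
}

#' Extract condition mentions from notes
#'
#' Runs every condition's inclusion patterns over the normalized text of
#' each note. Overlapping matches of the same condition are merged, keeping
#' the longest (then leftmost) span; matches of different conditions may
#' overlap freely. Each mention's snippet is the context window of
#' `window_tokens` tokens on each side of the matched tokens (per-condition,
#' from the definitions). Spans are mapped back to the raw text.
#'
#' @param notes A notes tibble (columns `note_id`, `text`, ...).
#' @param definitions A `condition_definitions` object.
#' @param section_lexicon Section lexicon used downstream; kept here so the
#'   same preprocessing is reused.
#' @return A mentions tibble with `status` unset and all qualifier flags
#'   `FALSE`, plus internal `norm_start`/`norm_end`/`status_hint` columns.
#' @export
extract_mentions <- function(notes, definitions,
                             section_lexicon = load_section_lexicon()) {
  matchers <- compile_matchers(definitions)
  out <- purrr::map_dfr(seq_len(nrow(notes)), function(i) {
    pre <- preprocess_note(notes$text[i], section_lexicon)
    extract_mentions_one(notes$note_id[i], pre, matchers)
  })
  if (nrow(out) == 0L) {
    out <- empty_mentions()
    out$norm_start <- integer(0); out$norm_end <- integer(0)
    out$status_hint <- character(0)
  }
  out
}

extract_mentions_one <- function(note_id, pre, matchers) {
  nt <- pre$nt
  tokens <- pre$tokens
  out <- list()
  for (m in matchers) {
    starts <- integer(0); ends <- integer(0); hints <- character(0)
    for (p in seq_len(nrow(m$patterns))) {
      sp <- regex_spans(m$patterns$regex[p], nt$norm)
      if (length(sp$start) > 0L) {
        starts <- c(starts, sp$start)
        ends <- c(ends, sp$end)
        hints <- c(hints, rep(m$patterns$status_hint[p], length(sp$start)))
      }
    }
    if (length(starts) == 0L) next

    # merge overlapping same-condition hits: longest match, then leftmost
    o <- order(starts, -ends)
    starts <- starts[o]; ends <- ends[o]; hints <- hints[o]
    keep <- integer(0)
    best <- 1L; cluster_end <- ends[1]
    if (length(starts) > 1L) {
      for (j in 2:length(starts)) {
        if (starts[j] < cluster_end) {
          if (ends[j] - starts[j] > ends[best] - starts[best]) best <- j
          cluster_end <- max(cluster_end, ends[j])
        } else {
          keep <- c(keep, best)
          best <- j; cluster_end <- ends[j]
        }
      }
    }
    keep <- c(keep, best)
    ns <- starts[keep]; ne <- ends[keep]; hint <- hints[keep]
    k <- length(ns)

    raw_start <- nt$norm_to_raw[ns + 1L]
    raw_end <- nt$norm_to_raw[ne] + 1L
    snip_start <- integer(k); snip_end <- integer(k)
    for (j in seq_len(k)) {
      snip <- snippet_span(tokens, ns[j], ne[j], m$window_tokens)
      snip_raw <- norm_span_to_raw(nt, snip[1], snip[2])
      snip_start[j] <- snip_raw["start"]; snip_end[j] <- snip_raw["end"]
    }
    out[[m$condition_id]] <- tibble::tibble(
      mention_id = paste0(note_id, ":", m$condition_id, ":", seq_len(k)),
      note_id = note_id,
      condition_id = m$condition_id,
      status = NA_character_,
      start = raw_start, end = raw_end,
      snippet_start = snip_start, snippet_end = snip_end,
      negated = FALSE, hypothetical = FALSE, family = FALSE,
      generic_fp = FALSE, discarded = FALSE, score = NA_real_,
      norm_start = ns, norm_end = ne,
      status_hint = hint
    )
  }
  dplyr::bind_rows(out)
}

# Token index range [first, last] (1-based rows of `tokens`) overlapping a
# normalized span; NA when no token overlaps (shouldn't happen for pattern
# matches, which cover non-space characters).
token_range <- function(tokens, ns, ne) {
  hit <- which(tokens$start < ne & tokens$end > ns)
  if (length(hit) == 0L) return(c(NA_integer_, NA_integer_))
  c(min(hit), max(hit))
}

# Snippet normalized span: window_tokens tokens each side of the matched
# token range.
snippet_span <- function(tokens, ns, ne, window_tokens) {
  tr <- token_range(tokens, ns, ne)
  if (is.na(tr[1])) return(c(ns, ne))
  lo <- max(1L, tr[1] - window_tokens)
  hi <- min(nrow(tokens), tr[2] + window_tokens)
  c(min(tokens$start[lo], ns), max(tokens$end[hi], ne))
}

# Recompute normalized spans for mentions that lost them (eg, after a file
# round trip): the normalized span is the set of normalized characters that
# trace back into the raw span.
ensure_norm_spans <- function(mentions, notes) {
  if (all(c("norm_start", "norm_end") %in% names(mentions)) &&
      !anyNA(mentions$norm_start)) {
    return(mentions)
  }
  nts <- lapply(stats::setNames(notes$text, notes$note_id), normalize_text)
  spans <- purrr::map(seq_len(nrow(mentions)), function(i) {
    nt <- nts[[mentions$note_id[i]]]
    idx <- which(
      nt$norm_to_raw >= mentions$start[i] & nt$norm_to_raw < mentions$end[i]
    )
    if (length(idx) == 0L) c(0L, 0L) else c(min(idx) - 1L, max(idx))
  })
  mentions$norm_start <- purrr::map_int(spans, 1)
  mentions$norm_end <- purrr::map_int(spans, 2)
  mentions
}

#' Flag generic false positives and family-section mentions
#'
#' A mention overlapping an exclusion-pattern match (eg, a condition named
#' inside a care-site name) or lying inside an `irrelevant` section gains
#' the `generic_fp` qualifier and is discarded; a mention inside a
#' `family_history` section instead gains the `family` qualifier (and is
#' discarded, since a family-related mention is not asserted for the
#' patient).
#'
#' @param mentions A mentions tibble from [extract_mentions()].
#' @param notes The notes tibble.
#' @param definitions A `condition_definitions` object.
#' @param section_lexicon Section-title lexicon.
#' @return The mentions tibble with qualifier flags updated; spans,
#'   conditions and statuses are never altered.
#' @export
apply_exclusions <- function(mentions, notes, definitions,
                             section_lexicon = load_section_lexicon()) {
  if (nrow(mentions) == 0L) return(mentions)
  mentions <- ensure_norm_spans(mentions, notes)
  for (nid in unique(mentions$note_id)) {
    sel <- which(mentions$note_id == nid)
    text <- notes$text[notes$note_id == nid]
    nt <- normalize_text(text)
    sections <- detect_sections(nt, section_lexicon)
    irrelevant <- sections[sections$relevance == "irrelevant", , drop = FALSE]
    family_sec <- sections[sections$relevance == "family_history", , drop = FALSE]

    # exclusion spans computed once per (note, condition)
    excl_cache <- list()
    for (i in sel) {
      cid <- mentions$condition_id[i]
      if (is.null(excl_cache[[cid]])) {
        sps <- lapply(
          definitions[[cid]]$exclusion_patterns, regex_spans, text = nt$norm
        )
        excl_cache[[cid]] <- list(
          start = unlist(lapply(sps, `[[`, "start")),
          end = unlist(lapply(sps, `[[`, "end"))
        )
      }
      ns <- mentions$norm_start[i]; ne <- mentions$norm_end[i]
      spans <- excl_cache[[cid]]
      excluded <- length(spans$start) > 0L &&
        any(spans$start < ne & spans$end > ns)
      in_irrelevant <- nrow(irrelevant) > 0L &&
        any(irrelevant$start <= ns & irrelevant$end >= ne)
      in_family <- nrow(family_sec) > 0L &&
        any(family_sec$start <= ns & family_sec$end >= ne)
      if (excluded || in_irrelevant) {
        mentions$generic_fp[i] <- TRUE
        mentions$discarded[i] <- TRUE
      }
      if (in_family) {
        mentions$family[i] <- TRUE
        mentions$discarded[i] <- TRUE
      }
    }
  }
  mentions
}

# Sentence-terminator tokens bounding a severity-rule context window.
severity_terminators <- c(".", ";", "!", "?")

#' Assign severity statuses from the entity context
#'
#' For conditions with two statuses, inspects a context window of tokens
#' around each mention (per-rule `window_tokens`, truncated at sentence
#' terminators so severity cues do not leak across sentences). A matching
#' severity rule proposes its status, as does a status hint carried by the
#' inclusion pattern that produced the mention; when several statuses are
#' proposed the most severe wins. With no proposal the least severe
#' (present-unspecified) status is assigned. Mentions of binary conditions
#' are left untouched.
#'
#' @param mentions A mentions tibble from [extract_mentions()].
#' @param notes The notes tibble.
#' @param definitions A `condition_definitions` object.
#' @return The mentions tibble with `status` filled for statused conditions.
#' @export
assign_status <- function(mentions, notes, definitions) {
  if (nrow(mentions) == 0L) return(mentions)
  mentions <- ensure_norm_spans(mentions, notes)
  for (nid in unique(mentions$note_id)) {
    sel <- which(mentions$note_id == nid)
    text <- notes$text[notes$note_id == nid]
    nt <- normalize_text(text)
    tokens <- tokenize(nt)
    for (i in sel) {
      def <- definitions[[mentions$condition_id[i]]]
      if (length(def$statuses) == 0L) next
      candidates <- character(0)
      hint <- if ("status_hint" %in% names(mentions)) mentions$status_hint[i]
              else NA_character_
      if (!is.na(hint)) candidates <- hint
      tr <- token_range(tokens, mentions$norm_start[i], mentions$norm_end[i])
      if (!is.na(tr[1]) && nrow(def$severity_rules) > 0L) {
        for (r in seq_len(nrow(def$severity_rules))) {
          w <- def$severity_rules$window_tokens[r]
          win <- severity_window(tokens, tr, w)
          ctx <- slice_chars(nt$norm, win[1], win[2])
          if (grepl(def$severity_rules$regex[r], ctx, perl = TRUE)) {
            candidates <- c(candidates, def$severity_rules$status[r])
          }
        }
      }
      mentions$status[i] <- if (length(candidates) == 0L) {
        def$statuses[1]
      } else {
        def$statuses[max(match(candidates, def$statuses))]
      }
    }
  }
  mentions
}

# Normalized-text span of the severity context window: `w` tokens each side
# of the token range `tr`, truncated at sentence terminators.
severity_window <- function(tokens, tr, w) {
  lo <- max(1L, tr[1] - w)
  hi <- min(nrow(tokens), tr[2] + w)
  if (tr[1] > 1L) {
    before <- seq(tr[1] - 1L, lo)
    term <- before[tokens$surface[before] %in% severity_terminators]
    if (length(term) > 0L) lo <- max(term) + 1L
  }
  if (tr[2] < nrow(tokens)) {
    after <- seq(tr[2] + 1L, hi)
    term <- after[tokens$surface[after] %in% severity_terminators]
    if (length(term) > 0L) hi <- min(term) - 1L
  }
  c(tokens$start[lo], tokens$end[hi])
}
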