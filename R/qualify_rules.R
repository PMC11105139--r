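# Rule-based qualification: negation, hypothesis and family-relation
# detectors with NegEx-style cue scopes, and the mention-level driver that
# sets qualifier flags and the discard decision.

# Tokenize a cue phrase with the same token regex as note text (kept
# allocation-light: cue lookup runs once per note and cue class).
cue_token_seq <- function(cue) {
  regmatches(
    cue, gregexpr("[[:alnum:]]+'?|[^[:space:]]", cue, perl = TRUE)
  )[[1]]
}

# All occurrences of multi-token cue phrases in a token sequence, as
# parallel vectors of 1-based token index ranges [first, last].
find_cue_occurrences <- function(tokens, cues) {
  surf <- tokens$surface
  if (is.character(cues)) cues <- lapply(cues, cue_token_seq)
  first <- integer(0); last <- integer(0)
  for (ct in cues) {
    k <- length(ct)
    if (k == 0L || length(surf) < k) next
    starts <- which(surf == ct[1])
    if (k > 1L) {
      starts <- starts[starts + k - 1L <= length(surf)]
      if (length(starts) > 0L) {
        ok <- vapply(
          starts,
          function(s) all(surf[s:(s + k - 1L)] == ct),
          logical(1)
        )
        starts <- starts[ok]
      }
    }
    if (length(starts) > 0L) {
      first <- c(first, starts)
      last <- c(last, starts + k - 1L)
    }
  }
  list(first = first, last = last)
}

# TRUE when a cue occurrence governs the entity: the cue lies fully before
# (or after) the entity, within `window` tokens, with no scope terminator
# between cue and entity.
cue_in_scope <- function(tokens, occ, entity, window, terminators,
                         direction = c("preceding", "following")) {
  direction <- match.arg(direction)
  surf <- tokens$surface
  if (direction == "preceding") {
    if (occ$last >= entity[1]) return(FALSE)
    gap <- entity[1] - occ$last - 1L
    if (gap > window) return(FALSE)
    between <- if (gap > 0L) surf[(occ$last + 1L):(entity[1] - 1L)] else character(0)
  } else {
    if (occ$first <= entity[2]) return(FALSE)
    gap <- occ$first - entity[2] - 1L
    if (gap > window) return(FALSE)
    between <- if (gap > 0L) surf[(entity[2] + 1L):(occ$first - 1L)] else character(0)
  }
  !any(between %in% terminators)
}

scope_hit <- function(tokens, entity, cues, window, terminators, direction) {
  occs <- find_cue_occurrences(tokens, cues)
  for (i in seq_along(occs$first)) {
    occ <- list(first = occs$first[i], last = occs$last[i])
    if (cue_in_scope(tokens, occ, entity, window, terminators, direction)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Rule-based negation, hypothesis and family-relation detection
#'
#' NegEx-style semantics on a token sequence: a detector fires when a cue
#' phrase occurs within its scope window (in tokens) before the entity --
#' or, for following cues, after it -- with no scope terminator (sentence
#' punctuation, adversative conjunction) between the cue and the entity.
#' Hypothesis cues are tried in both directions. The family detector
#' additionally fires for any entity lying inside a `family_history`
#' section.
#'
#' @param tokens A token tibble from [tokenize()].
#' @param entity Integer vector `c(first, last)`: the 1-based token index
#'   range of the entity.
#' @param lexicon A `cue_lexicon` from [load_cue_lexicon()].
#' @param sections Optional section tibble from [detect_sections()]
#'   (family detector only); entity membership is judged on normalized
#'   offsets.
#' @return A logical scalar.
#' @export
detect_negation <- function(tokens, entity, lexicon = load_cue_lexicon()) {
  w <- lexicon$scope_window_tokens$negation
  term <- lexicon$scope_terminators
  scope_hit(tokens, entity, lexicon$negation_preceding, w, term, "preceding") ||
    scope_hit(tokens, entity, lexicon$negation_following, w, term, "following")
}

#' @rdname detect_negation
#' @export
detect_hypothesis <- function(tokens, entity, lexicon = load_cue_lexicon()) {
  w <- lexicon$scope_window_tokens$hypothesis
  term <- lexicon$scope_terminators
  scope_hit(tokens, entity, lexicon$hypothesis, w, term, "preceding") ||
    scope_hit(tokens, entity, lexicon$hypothesis, w, term, "following")
}

#' @rdname detect_negation
#' @export
detect_family <- function(tokens, entity, lexicon = load_cue_lexicon(),
                          sections = NULL) {
  w <- lexicon$scope_window_tokens$family
  term <- lexicon$scope_terminators
  inline <- scope_hit(tokens, entity, lexicon$family, w, term, "preceding") ||
    scope_hit(tokens, entity, lexicon$family, w, term, "following")
  if (inline) return(TRUE)
  if (!is.null(sections) && nrow(sections) > 0L && !anyNA(entity)) {
    ns <- tokens$start[entity[1]]; ne <- tokens$end[entity[2]]
    fam <- sections[sections$relevance == "family_history", , drop = FALSE]
    if (any(fam$start <= ns & fam$end >= ne)) return(TRUE)
  }
  FALSE
}

#' Rule-based qualification of extracted mentions
#'
#' Applies the three cue detectors to every mention and sets the qualifier
#' flags; a mention is discarded when it is negated, hypothetical,
#' family-related or a generic false positive (flag set upstream by
#' [apply_exclusions()]). Spans, conditions and statuses are never altered.
#'
#' @param mentions A mentions tibble.
#' @param notes The notes tibble.
#' @param lexicon A `cue_lexicon`.
#' @param section_lexicon Section-title lexicon (family-history sections).
#' @return The mentions tibble with `negated`, `hypothetical`, `family` and
#'   `discarded` updated.
#' @export
qualify_rule_based <- function(mentions, notes, lexicon = load_cue_lexicon(),
                               section_lexicon = load_section_lexicon()) {
  if (nrow(mentions) == 0L) return(mentions)
  mentions <- ensure_norm_spans(mentions, notes)
  cues_neg_pre <- lapply(lexicon$negation_preceding, cue_token_seq)
  cues_neg_fol <- lapply(lexicon$negation_following, cue_token_seq)
  cues_hyp <- lapply(lexicon$hypothesis, cue_token_seq)
  cues_fam <- lapply(lexicon$family, cue_token_seq)
  for (nid in unique(mentions$note_id)) {
    sel <- which(mentions$note_id == nid)
    text <- notes$text[notes$note_id == nid]
    nt <- normalize_text(text)
    tokens <- tokenize(nt)
    sections <- detect_sections(nt, section_lexicon)
    fam_sec <- sections[sections$relevance == "family_history", , drop = FALSE]

    # cue occurrences and terminator positions computed once per note
    occ_neg_pre <- find_cue_occurrences(tokens, cues_neg_pre)
    occ_neg_fol <- find_cue_occurrences(tokens, cues_neg_fol)
    occ_hyp <- find_cue_occurrences(tokens, cues_hyp)
    occ_fam <- find_cue_occurrences(tokens, cues_fam)
    term_idx <- which(tokens$surface %in% lexicon$scope_terminators)
    w <- lexicon$scope_window_tokens

    governs <- function(occs, entity, window) {
      if (length(occs$first) == 0L) return(FALSE)
      pre <- occs$last < entity[1] & (entity[1] - occs$last - 1L) <= window
      fol <- occs$first > entity[2] & (occs$first - entity[2] - 1L) <= window
      for (j in which(pre)) {
        if (!any(term_idx > occs$last[j] & term_idx < entity[1])) return(TRUE)
      }
      for (j in which(fol)) {
        if (!any(term_idx > entity[2] & term_idx < occs$first[j])) return(TRUE)
      }
      FALSE
    }
    governs_dir <- function(occs, entity, window, direction) {
      if (length(occs$first) == 0L) return(FALSE)
      if (direction == "preceding") {
        cand <- which(occs$last < entity[1] &
                        (entity[1] - occs$last - 1L) <= window)
        for (j in cand) {
          if (!any(term_idx > occs$last[j] & term_idx < entity[1])) return(TRUE)
        }
      } else {
        cand <- which(occs$first > entity[2] &
                        (occs$first - entity[2] - 1L) <= window)
        for (j in cand) {
          if (!any(term_idx > entity[2] & term_idx < occs$first[j])) return(TRUE)
        }
      }
      FALSE
    }

    for (i in sel) {
      tr <- token_range(tokens, mentions$norm_start[i], mentions$norm_end[i])
      if (is.na(tr[1])) next
      mentions$negated[i] <-
        governs_dir(occ_neg_pre, tr, w$negation, "preceding") ||
        governs_dir(occ_neg_fol, tr, w$negation, "following")
      mentions$hypothetical[i] <- governs(occ_hyp, tr, w$hypothesis)
      in_fam_sec <- nrow(fam_sec) > 0L && any(
        fam_sec$start <= tokens$start[tr[1]] & fam_sec$end >= tokens$end[tr[2]]
      )
      mentions$family[i] <- mentions$family[i] || in_fam_sec ||
        governs(occ_fam, tr, w$family)
    }
  }
  mentions$discarded <- mentions$negated | mentions$hypothetical |
    mentions$family | mentions$generic_fp
  mentions
}
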