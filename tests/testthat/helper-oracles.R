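# Independent oracles and small fixture builders shared across tests.
# Oracles are written as literal, loop-based transcriptions of the
# documented semantics, independent of the implementation paths they check.

# --- cue-scope oracle -------------------------------------------------------
# Literal enumeration of all (cue occurrence, entity) pairs: a cue governs
# the entity when it lies fully on the required side, the token gap is at
# most `window`, and no terminator token sits strictly between.
oracle_cue_scope <- function(surfaces, entity, cue_phrases, window,
                             terminators, direction) {
  token_of <- function(phrase) {
    regmatches(phrase,
               gregexpr("[[:alnum:]]+'?|[^[:space:]]", phrase, perl = TRUE))[[1]]
  }
  n <- length(surfaces)
  for (cue in cue_phrases) {
    ct <- token_of(cue)
    k <- length(ct)
    if (k == 0L || k > n) next
    for (s in 1:(n - k + 1L)) {
      if (!all(surfaces[s:(s + k - 1L)] == ct)) next
      first <- s; last <- s + k - 1L
      if (direction == "preceding" && last < entity[1]) {
        gap_tokens <- if (entity[1] - last > 1L) {
          surfaces[(last + 1L):(entity[1] - 1L)]
        } else character(0)
        if (length(gap_tokens) <= window &&
            !any(gap_tokens %in% terminators)) {
          return(TRUE)
        }
      }
      if (direction == "following" && first > entity[2]) {
        gap_tokens <- if (first - entity[2] > 1L) {
          surfaces[(entity[2] + 1L):(first - 1L)]
        } else character(0)
        if (length(gap_tokens) <= window &&
            !any(gap_tokens %in% terminators)) {
          return(TRUE)
        }
      }
    }
  }
  FALSE
}

oracle_negation <- function(surfaces, entity, lexicon) {
  oracle_cue_scope(surfaces, entity, lexicon$negation_preceding,
                   lexicon$scope_window_tokens$negation,
                   lexicon$scope_terminators, "preceding") ||
    oracle_cue_scope(surfaces, entity, lexicon$negation_following,
                     lexicon$scope_window_tokens$negation,
                     lexicon$scope_terminators, "following")
}

oracle_hypothesis <- function(surfaces, entity, lexicon) {
  oracle_cue_scope(surfaces, entity, lexicon$hypothesis,
                   lexicon$scope_window_tokens$hypothesis,
                   lexicon$scope_terminators, "preceding") ||
    oracle_cue_scope(surfaces, entity, lexicon$hypothesis,
                     lexicon$scope_window_tokens$hypothesis,
                     lexicon$scope_terminators, "following")
}

oracle_family <- function(surfaces, entity, lexicon) {
  oracle_cue_scope(surfaces, entity, lexicon$family,
                   lexicon$scope_window_tokens$family,
                   lexicon$scope_terminators, "preceding") ||
    oracle_cue_scope(surfaces, entity, lexicon$family,
                     lexicon$scope_window_tokens$family,
                     lexicon$scope_terminators, "following")
}

# Random cue/terminator/entity token sequences for the scope oracle.
random_snippet_case <- function(lexicon) {
  vocab <- c("le", "patient", "bilan", "stable", "examen", "note", "suivi",
             "chronique", "ancien", "traitement", "controle")
  cues <- c(
    sample(lexicon$negation_preceding, 2),
    sample(lexicon$negation_following, 1),
    sample(lexicon$hypothesis, 2),
    sample(lexicon$family, 2)
  )
  n_parts <- sample(4:10, 1)
  parts <- sample(
    c(sample(vocab, n_parts, replace = TRUE),
      sample(cues, sample(0:3, 1), replace = TRUE),
      sample(lexicon$scope_terminators, sample(0:2, 1), replace = TRUE))
  )
  surfaces <- unlist(lapply(parts, function(p) {
    regmatches(p, gregexpr("[[:alnum:]]+'?|[^[:space:]]", p, perl = TRUE))[[1]]
  }))
  pos <- sample(seq_along(surfaces), 1)
  surfaces <- append(surfaces, "diabete", after = pos - 1L)
  list(surfaces = surfaces, entity = c(pos, pos))
}

# --- metrics oracle ---------------------------------------------------------
# Direct transcription of the metric formulas.
oracle_metrics <- function(tp, fp, fn, tn = NA) {
  ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  se <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  sp <- if (!is.na(tn) && tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  f1 <- if (!is.na(ppv) && !is.na(se) && ppv + se > 0) {
    2 * ppv * se / (ppv + se)
  } else {
    NA_real_
  }
  c(ppv = ppv, sensitivity = se, specificity = sp, f1 = f1)
}

# --- entity-overlap oracle --------------------------------------------------
# Brute-force all-pairs overlap on kept mentions of one condition.
oracle_entity_counts <- function(pred, gold, condition, status = NULL) {
  filt <- function(m) {
    m <- m[!m$discarded & m$condition_id == condition, , drop = FALSE]
    if (!is.null(status)) {
      m <- m[!is.na(m$status) & m$status == status, , drop = FALSE]
    }
    m
  }
  p <- filt(pred); g <- filt(gold)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_len(nrow(p))) {
    hit <- FALSE
    for (j in seq_len(nrow(g))) {
      if (p$note_id[i] == g$note_id[j] &&
          p$start[i] < g$end[j] && p$end[i] > g$start[j]) {
        hit <- TRUE
      }
    }
    if (hit) tp <- tp + 1L else fp <- fp + 1L
  }
  for (j in seq_len(nrow(g))) {
    hit <- FALSE
    for (i in seq_len(nrow(p))) {
      if (p$note_id[i] == g$note_id[j] &&
          p$start[i] < g$end[j] && p$end[i] > g$start[j]) {
        hit <- TRUE
      }
    }
    if (!hit) fn <- fn + 1L
  }
  c(tp = tp, fp = fp, fn = fn)
}

# --- fixtures ---------------------------------------------------------------
defs_cached <- NULL
test_defs <- function() {
  if (is.null(defs_cached)) {
    defs_cached <<- load_condition_definitions()
  }
  defs_cached
}

test_lexicon <- function() load_cue_lexicon()

# Subset condition definitions, retaining the class.
defs_subset <- function(defs, ids) {
  structure(defs[ids], class = "condition_definitions")
}

# Mention columns carried by the standoff interchange round trip.
mention_standoff_cols <- function() comorbidr:::mention_cols

# A one-note corpus from raw text.
one_note <- function(text, note_id = "n1", stay_id = "s1",
                     stay_type = "inpatient") {
  tibble::tibble(
    note_id = note_id, stay_id = stay_id,
    note_class = if (stay_type == "inpatient") "discharge_summary" else
      "consultation_report",
    stay_type = stay_type, text = text
  )
}

# Random valid mention rows over a notes tibble (for round-trip tests).
random_mentions <- function(notes, n, seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      nid <- sample(notes$note_id, 1)
      len <- nchar(notes$text[notes$note_id == nid])
      start <- sample.int(max(1L, len - 5L), 1) - 1L
      end <- min(len, start + sample(1:5, 1))
      quals <- stats::runif(4) < 0.2
      tibble::tibble(
        mention_id = paste0("m", i), note_id = nid,
        condition_id = sample(condition_ids(), 1),
        status = sample(c(NA, "present", "uncomplicated"), 1),
        start = start, end = as.integer(end),
        snippet_start = max(0L, start - 10L),
        snippet_end = as.integer(min(len, end + 10L)),
        negated = quals[1], hypothetical = quals[2], family = quals[3],
        generic_fp = quals[4],
        discarded = any(quals),
        score = sample(c(NA_real_, round(stats::runif(1), 6)), 1)
      )
    })
    dplyr::bind_rows(rows)
  })
}
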