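# Deterministic synthetic-corpus generator: French-style clinical notes
# with condition mentions wrapped in negation/hypothesis/family cues,
# irrelevant care-site contexts, two-status conditions, section structure,
# stay labels and ICD-10 claim records with configurable undercoding.
#
# Mention sentences embed dictionary phrases verbatim, so NER misses are
# controlled solely by the out-of-vocabulary rate and test failures stay
# attributable. Gold spans are recorded at assembly time on the raw text.

#' Generator configuration
#'
#' Default rates emulate the composition of an annotated validation corpus
#' of discharge summaries and consultation reports: per-condition
#' prevalences follow the relative note-level frequencies of the 18
#' conditions in such cohorts, about a quarter of gold entities carry a
#' discard qualifier (negation being the most common), and claim records
#' suffer systemic undercoding.
#'
#' @param n_stays Number of stays (one note per stay).
#' @param inpatient_fraction Fraction of inpatient stays (discharge
#'   summaries; the rest are outpatient consultation reports).
#' @param prevalence Named list/vector of per-condition prevalences; names
#'   must be condition identifiers. Conditions omitted default to the
#'   built-in prevalence table; pass a short list to simulate a focused
#'   corpus.
#' @param mention_mean,mention_max Mean and cap of the number of mentions
#'   per positive (stay, condition); at least one mention is emitted.
#' @param negation_rate,hypothesis_rate,family_rate,generic_fp_rate
#'   Per-mention probabilities of wrapping the mention in each discard
#'   mechanism; the remainder are clean, kept mentions.
#' @param status_mix Probability that a statused condition takes its most
#'   severe status in a given stay.
#' @param oov_cue_rate Out-of-vocabulary realization rate: a discard-cued
#'   mention draws a cue phrasing outside the default cue lexicon (the
#'   rule-based qualifier will miss it), and a clean mention draws a
#'   surface form outside the regex dictionaries (the NER will miss it).
#' @param claim_undercoding_rate Probability that a truly present
#'   condition is missing from the stay's claim codes.
#' @param claim_overcoding_rate Probability that an absent condition gains
#'   a spurious claim code.
#' @param language `"fr"` (default) or `"en"` (demo templates).
#' @param seed Mandatory integer seed; the same configuration always
#'   produces a byte-identical corpus.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_stays = 100L,
                             inpatient_fraction = 0.5,
                             prevalence = NULL,
                             mention_mean = 2,
                             mention_max = 5L,
                             negation_rate = 0.12,
                             hypothesis_rate = 0.05,
                             family_rate = 0.04,
                             generic_fp_rate = 0.03,
                             status_mix = 0.4,
                             oov_cue_rate = 0.10,
                             claim_undercoding_rate = 0.30,
                             claim_overcoding_rate = 0,
                             language = c("fr", "en"),
                             seed = 1L) {
  language <- match.arg(language)
  default_prev <- c(
    myocardial_infarction = 0.14, congestive_heart_failure = 0.27,
    peripheral_vascular_disease = 0.41, cerebrovascular_disease = 0.11,
    dementia = 0.10, chronic_pulmonary_disease = 0.19,
    rheumatologic_disease = 0.11, peptic_ulcer_disease = 0.04,
    liver_disease = 0.04, diabetes = 0.20, hemiplegia = 0.02,
    renal_disease = 0.07, solid_tumor = 0.23, leukemia = 0.04,
    lymphoma = 0.07, aids = 0.01, alcohol_consumption = 0.06,
    tobacco_consumption = 0.18
  )
  if (is.null(prevalence)) {
    prevalence <- as.list(default_prev)
  } else {
    prevalence <- as.list(unlist(prevalence))
    unknown <- setdiff(names(prevalence), condition_ids())
    if (length(unknown) > 0L) {
      stop("prevalence map names unknown condition(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  rates <- c(
    inpatient_fraction, negation_rate, hypothesis_rate, family_rate,
    generic_fp_rate, status_mix, oov_cue_rate, claim_undercoding_rate,
    claim_overcoding_rate, unlist(prevalence)
  )
  stopifnot(all(rates >= 0 & rates <= 1), n_stays >= 0L, !is.null(seed))
  total_discard <- negation_rate + hypothesis_rate + family_rate +
    generic_fp_rate
  stopifnot(total_discard <= 1)
  structure(
    list(
      n_stays = as.integer(n_stays),
      inpatient_fraction = inpatient_fraction,
      prevalence = prevalence,
      mention_mean = mention_mean, mention_max = as.integer(mention_max),
      negation_rate = negation_rate, hypothesis_rate = hypothesis_rate,
      family_rate = family_rate, generic_fp_rate = generic_fp_rate,
      status_mix = status_mix, oov_cue_rate = oov_cue_rate,
      claim_undercoding_rate = claim_undercoding_rate,
      claim_overcoding_rate = claim_overcoding_rate,
      language = language, seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# Sentence templates; {X} is the mention slot. In-lexicon cue templates use
# cues from the bundled lexicon; "oov" variants deliberately avoid it.
sim_templates <- list(
  fr = list(
    clean = c("le patient presente {X}.", "on note {X}.",
              "suivi pour {X}.", "prise en charge de {X}.",
              "bilan de {X}."),
    neg = c("pas de {X}.", "absence de {X}.", "sans {X}.",
            "aucun {X}."),
    neg_oov = c("negativite pour {X}.", "on n'objective nullement {X}."),
    hyp = c("suspicion de {X}.", "possible {X}.", "probable {X}."),
    hyp_oov = c("interrogation quant a {X}.",
                "tableau compatible avec {X}."),
    fam = c("notion de {X} chez le pere.", "notion de {X} chez la mere.",
            "{X} chez le frere."),
    fam_oov = c("notion de {X} chez un apparente.",
                "contexte hereditaire de {X}."),
    fam_section = c("notion de {X}.", "{X} connu."),
    gfp = c("adresse par l'hopital {X} pour avis.",
            "transfert de la clinique {X}."),
    gfp_oov = c("vu au centre medical {X} de paris."),
    filler = c("L'examen clinique est sans particularité.",
               "Le bilan biologique est normal.",
               "La tension artérielle est correcte.",
               "Poursuite du traitement habituel.",
               "Évolution favorable pendant le séjour."),
    header_inpatient = "Compte rendu d'hospitalisation — Médecine interne",
    header_outpatient = "Compte rendu de consultation — Médecine interne",
    section_history = "antécédents personnels :",
    section_family = "antécédents familiaux :",
    section_conclusion = "conclusion :"
  ),
  en = list(
    clean = c("the patient has {X}.", "history of {X}.",
              "followed for {X}."),
    neg = c("no {X}.", "the patient has no {X}."),
    neg_oov = c("workup negative regarding {X}."),
    hyp = c("the patient may have {X}.", "possible {X}."),
    hyp_oov = c("picture compatible with {X}."),
    fam = c("the patient's father had {X}.", "mother with {X}."),
    fam_oov = c("relative with {X}."),
    fam_section = c("known {X}."),
    gfp = c("referred by hopital {X} for advice."),
    gfp_oov = c("seen at centre medical {X}."),
    filler = c("Examination is unremarkable.", "Labs are normal."),
    header_inpatient = "Discharge summary",
    header_outpatient = "Consultation report",
    section_history = "antécédents personnels :",
    section_family = "antécédents familiaux :",
    section_conclusion = "conclusion :"
  )
)

# Accented raw variants of a few dictionary phrases, to exercise the
# normalization/offset machinery on mention spans themselves.
sim_accented <- c(
  "diabete" = "diabète",
  "demence" = "démence",
  "ethylisme" = "éthylisme",
  "leucemie" = "leucémie",
  "hepatite chronique" = "hépatite chronique",
  "ulcere gastrique" = "ulcère gastrique",
  "ulcere duodenal" = "ulcère duodénal",
  "arteriopathie obliterante" = "artériopathie oblitérante"
)

#' Generate a synthetic corpus
#'
#' Assembles notes stay by stay: each positive (stay, condition) emits at
#' least one mention sentence built from templates (optional cue +
#' dictionary phrase + optional severity phrase); the cue class is recorded
#' as the gold qualifier. Family mentions may instead land in a generated
#' family-history section. Claim codes retain each truly present
#' condition's prefix with probability `1 - claim_undercoding_rate` (plus
#' optional overcoded noise), for inpatient stays only. Identical
#' configurations produce byte-identical corpora.
#'
#' @param config A `generator_config`.
#' @param definitions A `condition_definitions` object (phrases are drawn
#'   from its `generator` blocks).
#' @return A list of class `synthetic_corpus`: `notes`, `gold_mentions`,
#'   `stay_labels` (source `"gold"`), `claims`, and the `config`.
#' @export
generate_corpus <- function(config, definitions = load_condition_definitions()) {
  stopifnot(inherits(config, "generator_config"))
  tpl <- sim_templates[[config$language]]
  prev <- config$prevalence

  withr::with_seed(config$seed, {
    notes <- vector("list", config$n_stays)
    mentions <- vector("list", config$n_stays)
    claims <- vector("list", config$n_stays)

    for (s in seq_len(config$n_stays)) {
      stay_id <- sprintf("stay_%04d", s)
      note_id <- sprintf("note_%04d", s)
      inpatient <- stats::runif(1) < config$inpatient_fraction

      present <- names(prev)[stats::runif(length(prev)) < unlist(prev)]

      lines <- c(
        if (inpatient) tpl$header_inpatient else tpl$header_outpatient,
        "",
        tpl$section_history
      )
      stay_mentions <- list()
      family_lines <- character(0)
      family_mentions <- list()
      m_ctr <- 0L

      for (cid in present) {
        def <- definitions[[cid]]
        statused <- length(def$statuses) > 0L
        stay_status <- if (statused) {
          if (stats::runif(1) < config$status_mix) def$statuses[2] else def$statuses[1]
        } else {
          NA_character_
        }
        n_m <- min(config$mention_max,
                   1L + stats::rpois(1, max(0, config$mention_mean - 1)))
        cats <- sample(
          c("neg", "hyp", "fam", "gfp", "clean"), n_m, replace = TRUE,
          prob = c(config$negation_rate, config$hypothesis_rate,
                   config$family_rate, config$generic_fp_rate,
                   1 - config$negation_rate - config$hypothesis_rate -
                     config$family_rate - config$generic_fp_rate)
        )
        oov <- stats::runif(n_m) < config$oov_cue_rate
        clean_idx <- which(cats == "clean")
        sev_carrier <- if (length(clean_idx) > 0L) clean_idx[1] else 0L

        for (k in seq_len(n_m)) {
          m_ctr <- m_ctr + 1L
          cat_k <- cats[k]
          gen <- def$generator
          phrase <- if (cat_k == "clean" && oov[k] &&
                        length(gen$oov_phrases) > 0L) {
            sample(unlist(gen$oov_phrases), 1)
          } else {
            sample(unlist(gen$phrases), 1)
          }
          in_vocab <- !(cat_k == "clean" && oov[k] &&
                        length(gen$oov_phrases) > 0L)
          if (config$language == "fr" && phrase %in% names(sim_accented) &&
              stats::runif(1) < 0.5) {
            phrase <- sim_accented[[phrase]]
          }

          m_status <- NA_character_
          slot <- phrase
          if (statused && cat_k == "clean" && k == sev_carrier) {
            sp <- gen$status_phrases[[stay_status]]
            if (!is.null(sp)) slot <- paste(phrase, sp)
            m_status <- stay_status
          } else if (statused) {
            m_status <- def$statuses[1]
          }

          template <- switch(
            cat_k,
            clean = sample(tpl$clean, 1),
            neg = sample(if (oov[k]) tpl$neg_oov else tpl$neg, 1),
            hyp = sample(if (oov[k]) tpl$hyp_oov else tpl$hyp, 1),
            fam = if (oov[k]) sample(tpl$fam_oov, 1) else if (stats::runif(1) < 0.5) {
              sample(tpl$fam, 1)
            } else {
              "SECTION"
            },
            gfp = sample(if (oov[k]) tpl$gfp_oov else tpl$gfp, 1)
          )
          in_family_section <- identical(template, "SECTION")
          if (in_family_section) template <- sample(tpl$fam_section, 1)

          pre <- sub("\\{X\\}.*$", "", template)
          sentence <- sub("{X}", slot, template, fixed = TRUE)
          phrase_offset <- nchar(pre)

          mention <- tibble::tibble(
            mention_id = sprintf("%s:m%03d", note_id, m_ctr),
            note_id = note_id,
            condition_id = cid,
            status = m_status,
            phrase = phrase,
            sentence = sentence,
            phrase_offset = phrase_offset,
            negated = cat_k == "neg",
            hypothetical = cat_k == "hyp",
            family = cat_k == "fam",
            generic_fp = cat_k == "gfp",
            in_vocab = in_vocab,
            oov_realization = oov[k]
          )
          if (in_family_section) {
            family_lines <- c(family_lines, sentence)
            mention$line_rel <- length(family_lines)
            family_mentions[[length(family_mentions) + 1L]] <- mention
          } else {
            lines <- c(lines, sentence)
            mention$line_rel <- length(lines)
            stay_mentions[[length(stay_mentions) + 1L]] <- mention
            if (stats::runif(1) < 0.3) {
              lines <- c(lines, sample(tpl$filler, 1))
            }
          }
        }
      }

      fam_base <- length(lines) + 2L  # after "" and the family-section title
      if (length(family_lines) > 0L) {
        lines <- c(lines, "", tpl$section_family, family_lines)
      }
      lines <- c(lines, "", tpl$section_conclusion, sample(tpl$filler, 1))

      # lay out the note and resolve mention spans on the raw text
      text <- paste(lines, collapse = "\n")
      line_starts <- c(0L, cumsum(nchar(lines, type = "chars") + 1L))
      all_m <- c(
        stay_mentions,
        purrr::map(family_mentions, function(m) {
          m$line_rel <- m$line_rel + fam_base
          m
        })
      )
      if (length(all_m) > 0L) {
        m_tbl <- dplyr::bind_rows(all_m)
        line_of <- m_tbl$line_rel
        starts <- line_starts[line_of] + m_tbl$phrase_offset
        ends <- starts + nchar(m_tbl$phrase, type = "chars")
        sent_start <- line_starts[line_of]
        sent_end <- sent_start + nchar(m_tbl$sentence, type = "chars")
        mentions[[s]] <- tibble::tibble(
          mention_id = m_tbl$mention_id,
          note_id = m_tbl$note_id,
          condition_id = m_tbl$condition_id,
          status = m_tbl$status,
          start = as.integer(starts), end = as.integer(ends),
          snippet_start = as.integer(sent_start),
          snippet_end = as.integer(sent_end),
          negated = m_tbl$negated, hypothetical = m_tbl$hypothetical,
          family = m_tbl$family, generic_fp = m_tbl$generic_fp,
          discarded = m_tbl$negated | m_tbl$hypothetical | m_tbl$family |
            m_tbl$generic_fp,
          score = NA_real_,
          in_vocab = m_tbl$in_vocab,
          oov_realization = m_tbl$oov_realization
        )
      }

      notes[[s]] <- tibble::tibble(
        note_id = note_id, stay_id = stay_id,
        note_class = if (inpatient) "discharge_summary" else "consultation_report",
        stay_type = if (inpatient) "inpatient" else "outpatient",
        text = text
      )
    }

    notes <- dplyr::bind_rows(notes)
    gold_mentions <- dplyr::bind_rows(mentions)
    if (nrow(notes) == 0L) {
      notes <- tibble::tibble(
        note_id = character(0), stay_id = character(0),
        note_class = character(0), stay_type = character(0),
        text = character(0)
      )
    }
    if (is.null(gold_mentions) || nrow(gold_mentions) == 0L) {
      gold_mentions <- dplyr::bind_cols(
        empty_mentions(),
        tibble::tibble(in_vocab = logical(0), oov_realization = logical(0))
      )
    }

    stay_labels <- aggregate_stays(
      gold_mentions, notes, definitions, source = "gold"
    )

    claims <- sim_claims(stay_labels, notes, definitions, config)

    structure(
      list(
        notes = notes, gold_mentions = gold_mentions,
        stay_labels = stay_labels, claims = claims, config = config
      ),
      class = "synthetic_corpus"
    )
  })
}

# Claim codes for inpatient stays: truly present conditions keep a code
# with probability 1-u; overcoding adds spurious codes; a non-matching
# administrative noise code is always present.
sim_claims <- function(stay_labels, notes, definitions, config) {
  inpatient <- unique(notes$stay_id[notes$stay_type == "inpatient"])
  rows <- list()
  noise_codes <- c("Z515", "R51", "A09")
  for (sid in inpatient) {
    lab <- stay_labels[stay_labels$stay_id == sid, ]
    for (i in seq_len(nrow(lab))) {
      def <- definitions[[lab$condition_id[i]]]
      present <- lab$status[i] != "absent"
      if (present && stats::runif(1) >= config$claim_undercoding_rate) {
        key <- if (length(def$statuses) == 0L) "any" else lab$status[i]
        prefixes <- def$icd10[[key]]
        if (length(prefixes) > 0L) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            stay_id = sid, code = sim_pad_code(sample(prefixes, 1))
          )
        }
      } else if (!present && config$claim_overcoding_rate > 0 &&
                 stats::runif(1) < config$claim_overcoding_rate) {
        prefixes <- unlist(def$icd10, use.names = FALSE)
        if (length(prefixes) > 0L) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            stay_id = sid, code = sim_pad_code(sample(prefixes, 1))
          )
        }
      }
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      stay_id = sid, code = sample(noise_codes, 1)
    )
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(stay_id = character(0), code = character(0)))
  }
  dplyr::bind_rows(rows)
}

# Extend an ICD-10 prefix with digits up to a 4-character code.
sim_pad_code <- function(prefix) {
  while (nchar(prefix) < 4L) {
    prefix <- paste0(prefix, sample(0:9, 1))
  }
  prefix
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus> ", nrow(x$notes), " notes, ",
      nrow(x$gold_mentions), " gold mentions (",
      sum(x$gold_mentions$discarded), " discarded), ",
      nrow(x$claims), " claim rows [seed ", x$config$seed, "]\n", sep = "")
  invisible(x)
}

#' Labeled snippets from a synthetic corpus
#'
#' One snippet per gold mention, labeled `discard` when any qualifier is
#' set, for training and evaluating the learned qualifier.
#'
#' @param corpus A `synthetic_corpus`.
#' @param window Context window in tokens on each side of the entity.
#' @return A tibble with `mention_id`, `tokens` (list-column),
#'   `entity_start`, `entity_end`, `label`.
#' @export
make_labeled_snippets <- function(corpus, window = 8L) {
  snippets <- mention_snippets(corpus$gold_mentions, corpus$notes, window)
  snippets$label <- ifelse(corpus$gold_mentions$discarded, "discard", "keep")
  snippets
}

#' Upsampling note selection for annotation
#'
#' Ranks notes by an inverse-frequency-weighted pre-annotation score, so
#' notes carrying rare conditions surface first, and returns the top k.
#' The score of a note is the sum over conditions of its pre-annotation
#' mention count divided by the corpus-wide count of that condition; ties
#' are broken by a seeded shuffle.
#'
#' @param notes A notes tibble.
#' @param counts Pre-annotation counts: a tibble with `note_id`,
#'   `condition_id`, `n`.
#' @param k Number of notes to select.
#' @param seed Seed for the tie-breaking shuffle.
#' @return The selected rows of `notes`, in rank order.
#' @export
upsample_selection <- function(notes, counts, k, seed = 1L) {
  stopifnot(k >= 0L)
  freq <- counts |>
    dplyr::group_by(.data$condition_id) |>
    dplyr::summarise(freq = sum(.data$n), .groups = "drop")
  scores <- counts |>
    dplyr::left_join(freq, by = "condition_id") |>
    dplyr::mutate(w = ifelse(.data$freq > 0, .data$n / .data$freq, 0)) |>
    dplyr::group_by(.data$note_id) |>
    dplyr::summarise(score = sum(.data$w), .groups = "drop")
  ranked <- notes |>
    dplyr::left_join(scores, by = "note_id") |>
    dplyr::mutate(score = ifelse(is.na(.data$score), 0, .data$score))
  shuffle <- withr::with_seed(seed, sample.int(nrow(ranked)))
  ranked <- ranked[order(-ranked$score, shuffle), , drop = FALSE]
  utils::head(ranked[names(notes)], k)
}
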