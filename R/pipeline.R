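# End-to-end pipeline driver: preprocessing -> NER -> exclusions ->
# severity -> qualification -> stay aggregation.

#' Annotate notes with the full detection pipeline
#'
#' Runs the complete chain on a corpus: mention extraction with the 18
#' per-condition regex dictionaries, identified-mechanism exclusions and
#' section flags, context severity assignment, qualification (rule-based
#' cue detectors or the learned snippet classifier), and stay-level
#' aggregation.
#'
#' @param notes A notes tibble.
#' @param definitions A `condition_definitions` object.
#' @param mode `"rule_based"` (negation/hypothesis/family cue detectors) or
#'   `"learned"` (trained snippet classifier).
#' @param model A `qualifier_model`; required when `mode = "learned"`.
#' @param cue_lexicon Cue lexicon for the rule-based detectors.
#' @param section_lexicon Section-title lexicon.
#' @param window Snippet window (tokens each side) for the learned
#'   qualifier.
#' @return A list of class `annotation_result`: `mentions` (all extracted
#'   mentions with qualifier flags and discard decisions) and
#'   `stay_predictions` (source `"nlp"`).
#' @examples
#' \donttest{
#' corpus <- generate_corpus(generator_config(n_stays = 5, seed = 7))
#' res <- annotate_notes(corpus$notes)
#' res$stay_predictions
#' }
#' @export
annotate_notes <- function(notes,
                           definitions = load_condition_definitions(),
                           mode = c("rule_based", "learned"),
                           model = NULL,
                           cue_lexicon = load_cue_lexicon(),
                           section_lexicon = load_section_lexicon(),
                           window = 8L) {
  mode <- match.arg(mode)
  if (mode == "learned" && is.null(model)) {
    stop("mode = 'learned' requires a trained qualifier model", call. = FALSE)
  }
  mentions <- extract_mentions(notes, definitions, section_lexicon)
  mentions <- apply_exclusions(mentions, notes, definitions, section_lexicon)
  mentions <- assign_status(mentions, notes, definitions)
  mentions <- if (mode == "rule_based") {
    qualify_rule_based(mentions, notes, cue_lexicon, section_lexicon)
  } else {
    qualify_learned(mentions, notes, model, window)
  }
  stays <- aggregate_stays(mentions, notes, definitions, source = "nlp")
  structure(
    list(mentions = mentions, stay_predictions = stays, mode = mode),
    class = "annotation_result"
  )
}

#' @export
print.annotation_result <- function(x, ...) {
  kept <- sum(!x$mentions$discarded)
  cat("<annotation_result> mode=", x$mode, ": ", nrow(x$mentions),
      " mentions (", kept, " kept) over ",
      length(unique(x$stay_predictions$stay_id)), " stays\n", sep = "")
  invisible(x)
}
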