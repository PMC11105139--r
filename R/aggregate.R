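# Stay-level aggregation of qualified mentions, Charlson comorbidity index
# computation, and prevalence estimation.

#' Aggregate qualified mentions to stay-level predictions
#'
#' A condition is predicted present for a stay when at least one mention is
#' detected without being discarded; for statused conditions the stay takes
#' the status of the most severe kept mention (mentions with an unset
#' status count as least severe). Mentions from all of a stay's notes are
#' pooled. Aggregation is idempotent and order-independent, and adding a
#' kept mention can only turn a condition present or raise its status.
#'
#' @param mentions A qualified mentions tibble (discarded mentions are
#'   filtered out here).
#' @param notes The notes tibble (maps `note_id` to `stay_id`; defines the
#'   stay universe).
#' @param definitions A `condition_definitions` object.
#' @param source Label recorded in the `source` column (`"nlp"`, `"claim"`
#'   or `"gold"`).
#' @return A long tibble with one row per (stay, condition): columns
#'   `stay_id`, `source`, `condition_id`, `status` (`"absent"`,
#'   `"present"`, or a status label).
#' @export
aggregate_stays <- function(mentions, notes, definitions, source = "nlp") {
  stays <- unique(notes$stay_id)
  grid <- tidyr::expand_grid(
    stay_id = stays, condition_id = names(definitions)
  )
  kept <- mentions[!mentions$discarded, , drop = FALSE]
  kept <- dplyr::left_join(
    kept, notes[c("note_id", "stay_id")], by = "note_id"
  )
  hit <- kept |>
    dplyr::group_by(.data$stay_id, .data$condition_id) |>
    dplyr::summarise(
      status = most_severe_status(
        .data$status, definitions[[.data$condition_id[1]]]
      ),
      .groups = "drop"
    )
  out <- dplyr::left_join(grid, hit, by = c("stay_id", "condition_id"))
  out$status[is.na(out$status)] <- "absent"
  out$source <- source
  out[c("stay_id", "source", "condition_id", "status")]
}

# Stay status from kept mention statuses: "present" for binary conditions,
# else the most severe mention status (unset counts as least severe).
most_severe_status <- function(statuses, definition) {
  if (length(definition$statuses) == 0L) return("present")
  ranks <- ifelse(is.na(statuses), 1L, match(statuses, definition$statuses))
  definition$statuses[max(ranks)]
}

#' Compute the Charlson comorbidity index
#'
#' Weighted sum over the 16 index conditions present for each stay, using
#' the configured weight table; for statused conditions the status-specific
#' weight applies, and a bare `"present"` takes the least-severe weight.
#' Tobacco and alcohol consumption never contribute.
#'
#' @param stay_predictions A stay-prediction tibble from
#'   [aggregate_stays()] or [map_claim_codes()].
#' @param definitions A `condition_definitions` object carrying the weight
#'   table.
#' @return A tibble with columns `stay_id` and `cci`.
#' @export
compute_cci <- function(stay_predictions, definitions) {
  present <- stay_predictions[stay_predictions$status != "absent", , drop = FALSE]
  weights <- vapply(seq_len(nrow(present)), function(i) {
    cid <- present$condition_id[i]
    if (cid %in% non_cci_conditions()) return(0L)
    def <- definitions[[cid]]
    if (is.null(def)) stop("unknown condition: ", cid, call. = FALSE)
    wt <- def$cci_weight
    key <- if (length(def$statuses) == 0L) {
      "any"
    } else if (present$status[i] %in% def$statuses) {
      present$status[i]
    } else {
      def$statuses[1]
    }
    if (is.null(wt[[key]])) {
      stop(
        "CCI weight table does not cover condition '", cid, "' status '",
        key, "'", call. = FALSE
      )
    }
    wt[[key]]
  }, integer(1))
  present$weight <- weights
  all_stays <- tibble::tibble(stay_id = unique(stay_predictions$stay_id))
  scored <- present |>
    dplyr::group_by(.data$stay_id) |>
    dplyr::summarise(cci = sum(.data$weight), .groups = "drop")
  out <- dplyr::left_join(all_stays, scored, by = "stay_id")
  out$cci[is.na(out$cci)] <- 0L
  out$cci <- as.integer(out$cci)
  out
}

#' Estimate per-condition prevalence
#'
#' Fraction of stays with the condition present, per condition, for one
#' source of stay predictions.
#'
#' @param stay_predictions A stay-prediction tibble.
#' @return A tibble with columns `condition_id`, `n_stays`, `n_present`,
#'   `prevalence` (a fraction in `[0, 1]`).
#' @export
estimate_prevalence <- function(stay_predictions) {
  n_stays <- length(unique(stay_predictions$stay_id))
  if (n_stays == 0L) {
    stop("cannot estimate prevalence over an empty stay set", call. = FALSE)
  }
  stay_predictions |>
    dplyr::group_by(.data$condition_id) |>
    dplyr::summarise(
      n_stays = n_stays,
      n_present = sum(.data$status != "absent"),
      prevalence = .data$n_present / n_stays,
      .groups = "drop"
    )
}

#' Compare prevalence estimates between two sources
#'
#' @param pred_a,pred_b Stay-prediction tibbles (eg, NLP vs claim vs gold).
#' @return A list: `by_condition`, a tibble of per-condition prevalences
#'   and differences, and `mean_abs_gap`, the mean absolute prevalence gap
#'   (fraction).
#' @export
prevalence_gap <- function(pred_a, pred_b) {
  a <- estimate_prevalence(pred_a)[c("condition_id", "prevalence")]
  b <- estimate_prevalence(pred_b)[c("condition_id", "prevalence")]
  by_condition <- dplyr::inner_join(
    a, b, by = "condition_id", suffix = c("_a", "_b")
  ) |>
    dplyr::mutate(gap = .data$prevalence_a - .data$prevalence_b)
  list(
    by_condition = by_condition,
    mean_abs_gap = mean(abs(by_condition$gap))
  )
}
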