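# CLAIM comparator: derive stay-level predictions from ICD-10 claim codes.

#' Map ICD-10 claim codes to stay-level predictions
#'
#' A condition is present for a stay when any of the stay's codes starts
#' with any configured prefix for that condition; for statused conditions
#' the stay takes the most severe status whose prefix list matches.
#' Unmatched codes are ignored. Claim data only exists for inpatient
#' stays: when `notes` (or any tibble with `stay_id` and `stay_type`) is
#' supplied, the output is restricted to `stay_type == "inpatient"` stays
#' and covers all of them, including stays without any claim row.
#'
#' @param claims A claim-record tibble (`stay_id`, `code`), codes in
#'   normalized dot-free form (see [read_claim_records()]).
#' @param definitions A `condition_definitions` object with ICD-10 prefix
#'   lists.
#' @param stays Optional tibble with `stay_id` (and optionally
#'   `stay_type`) defining the stay universe; defaults to the stays seen
#'   in `claims`.
#' @return A stay-prediction tibble with `source = "claim"`.
#' @export
map_claim_codes <- function(claims, definitions, stays = NULL) {
  if (is.null(stays)) {
    universe <- unique(claims$stay_id)
  } else {
    stays <- dplyr::distinct(stays[intersect(
      c("stay_id", "stay_type"), names(stays)
    )])
    if ("stay_type" %in% names(stays)) {
      stays <- stays[stays$stay_type == "inpatient", , drop = FALSE]
    }
    universe <- unique(stays$stay_id)
  }
  claims <- claims[claims$stay_id %in% universe, , drop = FALSE]
  codes_by_stay <- split(normalize_icd10(claims$code), claims$stay_id)

  grid <- tidyr::expand_grid(
    stay_id = universe, condition_id = names(definitions)
  )
  grid$status <- purrr::map2_chr(
    grid$stay_id, grid$condition_id,
    function(sid, cid) {
      codes <- codes_by_stay[[sid]]
      if (is.null(codes) || length(codes) == 0L) return("absent")
      def <- definitions[[cid]]
      claim_status(codes, def)
    }
  )
  grid$source <- "claim"
  grid[c("stay_id", "source", "condition_id", "status")]
}

# Status implied by a stay's codes for one condition definition.
claim_status <- function(codes, def) {
  matches_any <- function(prefixes) {
    if (length(prefixes) == 0L) return(FALSE)
    any(vapply(
      prefixes,
      function(p) any(startsWith(codes, p)),
      logical(1)
    ))
  }
  if (length(def$statuses) == 0L) {
    if (matches_any(def$icd10[["any"]])) "present" else "absent"
  } else {
    hit <- vapply(
      def$statuses, function(s) matches_any(def$icd10[[s]]), logical(1)
    )
    if (matches_any(def$icd10[["any"]])) hit[1] <- TRUE
    if (!any(hit)) "absent" else def$statuses[max(which(hit))]
  }
}
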