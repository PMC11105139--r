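# Condition definitions and lexicons: loading, validation, helpers.

#' The 18 condition identifiers
#'
#' Snake-case identifiers of the 16 Charlson-index comorbidities plus
#' tobacco and alcohol consumption.
#'
#' @return A character vector of length 18.
#' @export
condition_ids <- function() {
  c(
    "myocardial_infarction", "congestive_heart_failure",
    "peripheral_vascular_disease", "cerebrovascular_disease", "dementia",
    "chronic_pulmonary_disease", "rheumatologic_disease",
    "peptic_ulcer_disease", "liver_disease", "diabetes", "hemiplegia",
    "renal_disease", "solid_tumor", "leukemia", "lymphoma", "aids",
    "alcohol_consumption", "tobacco_consumption"
  )
}

# Conditions that never enter the Charlson comorbidity index.
non_cci_conditions <- function() {
  c("alcohol_consumption", "tobacco_consumption")
}

#' Path to a bundled configuration file
#'
#' @param file File name under the package's `extdata` directory
#'   (`"conditions.yaml"` or `"lexicons.yaml"`).
#' @return Absolute path to the bundled file.
#' @export
comorbidr_config <- function(file = "conditions.yaml") {
  path <- system.file("extdata", file, package = "comorbidr")
  if (!nzchar(path)) stop("no bundled config file named ", file, call. = FALSE)
  path
}

icd10_code_rx <- "^[A-Z][0-9]{2}[0-9A-Z]{0,2}$"

check_regex <- function(rx, condition, what) {
  ok <- tryCatch(
    { grepl(rx, "", perl = TRUE); TRUE },
    error = function(e) FALSE,
    warning = function(w) FALSE
  )
  if (!ok) {
    stop(
      "condition '", condition, "': ", what, " does not compile: ", rx,
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Load and validate the condition-definition dictionaries
#'
#' Reads a structured YAML config describing, for each of the 18 conditions,
#' its regex synonym dictionary (with optional per-pattern status hints),
#' exclusion patterns, context severity rules, ICD-10 code prefixes,
#' Charlson weight and PPV-only flag. Every invariant is checked at load
#' time so that matcher compilation downstream cannot fail.
#'
#' @param path Path to a conditions YAML file; defaults to the bundled
#'   starter dictionaries.
#' @return An object of class `condition_definitions`: a named list (one
#'   element per condition, in canonical order) of definition lists.
#'
#' @details Validation enforces: all 18 conditions present; `statuses` empty
#'   or a 2-element least-to-most-severe list, with exactly the five
#'   statused conditions (diabetes, liver disease, solid tumor, tobacco and
#'   alcohol consumption) carrying statuses; every severity-rule status
#'   among the declared statuses; all regexes compile; ICD-10 prefixes
#'   normalized (uppercase, dot-free); a Charlson weight for every condition
#'   except tobacco and alcohol consumption, which must not carry one.
#' @export
load_condition_definitions <- function(path = comorbidr_config("conditions.yaml")) {
  raw <- yaml::read_yaml(path)

  missing <- setdiff(condition_ids(), names(raw))
  if (length(missing) > 0L) {
    stop(
      "config is missing condition definition(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  extra <- setdiff(names(raw), condition_ids())
  if (length(extra) > 0L) {
    stop(
      "config defines unknown condition(s): ", paste(extra, collapse = ", "),
      call. = FALSE
    )
  }

  expected_statused <- c(
    "diabetes", "liver_disease", "solid_tumor",
    "tobacco_consumption", "alcohol_consumption"
  )

  defs <- purrr::imap(raw[condition_ids()], function(def, id) {
    statuses <- as.character(def$statuses %||% character(0))
    if (!length(statuses) %in% c(0L, 2L)) {
      stop(
        "condition '", id, "': statuses must be empty or a 2-element list",
        call. = FALSE
      )
    }
    if (length(statuses) == 2L && !id %in% expected_statused) {
      stop("condition '", id, "' must not carry statuses", call. = FALSE)
    }
    if (length(statuses) == 0L && id %in% expected_statused) {
      stop("condition '", id, "' must carry 2 statuses", call. = FALSE)
    }

    patterns <- purrr::map_dfr(def$patterns, function(p) {
      if (is.character(p)) p <- list(regex = p)
      check_regex(p$regex, id, "inclusion pattern")
      hint <- p$status %||% NA_character_
      if (!is.na(hint) && !hint %in% statuses) {
        stop(
          "condition '", id, "': pattern status hint '", hint,
          "' not among declared statuses", call. = FALSE
        )
      }
      tibble::tibble(regex = p$regex, status_hint = hint)
    })
    if (nrow(patterns) == 0L) {
      stop("condition '", id, "': no inclusion patterns", call. = FALSE)
    }

    exclusions <- as.character(def$exclusion_patterns %||% character(0))
    purrr::walk(exclusions, check_regex, condition = id, what = "exclusion pattern")

    sev <- purrr::map_dfr(def$severity_rules %||% list(), function(r) {
      check_regex(r$regex, id, "severity rule")
      if (!r$status %in% statuses) {
        stop(
          "condition '", id, "': severity rule status '", r$status,
          "' not among declared statuses", call. = FALSE
        )
      }
      tibble::tibble(
        regex = r$regex, status = r$status,
        window_tokens = as.integer(r$window_tokens %||% def$window_tokens %||% 8L)
      )
    })

    icd10 <- purrr::map(def$icd10 %||% list(), function(codes) {
      codes <- normalize_icd10(as.character(codes))
      bad <- codes[!grepl("^[A-Z][0-9A-Z]*$", codes)]
      if (length(bad) > 0L) {
        stop(
          "condition '", id, "': malformed ICD-10 prefix(es): ",
          paste(bad, collapse = ", "), call. = FALSE
        )
      }
      codes
    })
    bad_keys <- setdiff(names(icd10), c("any", statuses))
    if (length(bad_keys) > 0L) {
      stop(
        "condition '", id, "': icd10 keyed by unknown status: ",
        paste(bad_keys, collapse = ", "), call. = FALSE
      )
    }

    weight <- def$cci_weight %||% list()
    if (id %in% non_cci_conditions()) {
      if (length(weight) > 0L) {
        stop(
          "condition '", id, "' must not carry a CCI weight (tobacco and ",
          "alcohol consumption are excluded from the index)", call. = FALSE
        )
      }
    } else {
      keys <- if (length(statuses) > 0L) statuses else "any"
      if (!all(keys %in% names(weight))) {
        stop("condition '", id, "': incomplete CCI weight table", call. = FALSE)
      }
      wvals <- unlist(weight[keys])
      if (any(wvals < 0) || any(wvals != round(wvals))) {
        stop("condition '", id, "': CCI weights must be nonnegative integers",
             call. = FALSE)
      }
    }

    list(
      condition_id = id,
      display_name = def$display_name %||% id,
      statuses = statuses,
      window_tokens = as.integer(def$window_tokens %||% 8L),
      patterns = patterns,
      exclusion_patterns = exclusions,
      severity_rules = sev,
      icd10 = icd10,
      cci_weight = purrr::map(weight, as.integer),
      ppv_only = isTRUE(def$ppv_only),
      generator = def$generator %||% list()
    )
  })

  structure(defs, class = "condition_definitions")
}

#' @export
print.condition_definitions <- function(x, ...) {
  n_statused <- sum(purrr::map_int(x, ~ length(.x$statuses)) > 0L)
  cat("<condition_definitions> ", length(x), " conditions (",
      n_statused, " with 2 statuses, ",
      sum(purrr::map_lgl(x, "ppv_only")), " PPV-only)\n", sep = "")
  invisible(x)
}

#' Summarize condition definitions as a tibble
#'
#' @param x A `condition_definitions` object.
#' @param ... Unused.
#' @return One row per condition with pattern/rule counts and flags.
#' @export
tidy.condition_definitions <- function(x, ...) {
  purrr::map_dfr(x, function(d) {
    tibble::tibble(
      condition_id = d$condition_id,
      display_name = d$display_name,
      n_statuses = length(d$statuses),
      n_patterns = nrow(d$patterns),
      n_exclusions = length(d$exclusion_patterns),
      n_severity_rules = nrow(d$severity_rules),
      ppv_only = d$ppv_only
    )
  })
}

# Severity rank of a status label: position in the least-to-most-severe
# statuses list; NA status (or binary condition) ranks 0.
status_rank <- function(status, definition) {
  if (length(definition$statuses) == 0L) return(0L)
  ifelse(is.na(status), 1L, match(status, definition$statuses))
}

#' Load the qualification cue lexicon
#'
#' Cue phrases (normalized form) for the negation, hypothesis and
#' family-relation detectors, together with per-class scope windows (in
#' tokens) and the scope terminators that cut a cue's reach.
#'
#' @param path Path to a lexicons YAML file; defaults to the bundled one.
#' @return A list of class `cue_lexicon` with elements `negation_preceding`,
#'   `negation_following`, `hypothesis`, `family`, `scope_window_tokens`,
#'   `scope_terminators`.
#' @export
load_cue_lexicon <- function(path = comorbidr_config("lexicons.yaml")) {
  raw <- yaml::read_yaml(path)$cues
  lex <- list(
    negation_preceding = as.character(raw$negation_preceding),
    negation_following = as.character(raw$negation_following),
    hypothesis = as.character(raw$hypothesis),
    family = as.character(raw$family),
    scope_window_tokens = purrr::map(raw$scope_window_tokens, as.integer),
    scope_terminators = as.character(raw$scope_terminators)
  )
  stopifnot(
    length(lex$negation_preceding) > 0L,
    length(lex$hypothesis) > 0L,
    length(lex$family) > 0L,
    length(lex$scope_terminators) > 0L
  )
  structure(lex, class = "cue_lexicon")
}

#' Load the section-title lexicon
#'
#' @param path Path to a lexicons YAML file; defaults to the bundled one.
#' @return A tibble with columns `pattern` and `relevance`.
#' @export
load_section_lexicon <- function(path = comorbidr_config("lexicons.yaml")) {
  raw <- yaml::read_yaml(path)$sections
  lex <- purrr::map_dfr(raw, ~ tibble::tibble(
    pattern = .x$pattern, relevance = .x$relevance
  ))
  bad <- setdiff(lex$relevance, c("relevant", "irrelevant", "family_history"))
  if (length(bad) > 0L) {
    stop("unknown section relevance class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lex
}

#' Normalize ICD-10 codes
#'
#' Uppercases and removes dots, the canonical dot-free form used for all
#' prefix matching (`"i21.4"` becomes `"I214"`).
#'
#' @param codes Character vector of ICD-10 codes or prefixes.
#' @return Character vector of normalized codes.
#' @export
normalize_icd10 <- function(codes) {
  gsub(".", "", toupper(trimws(codes)), fixed = TRUE)
}
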