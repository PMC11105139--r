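# Readers and writers for notes, mentions, standoff annotations, claim
# records and stay predictions. All tabular interchange is plain text
# (JSON-lines or CSV); readers skip lines starting with '#' so files may
# carry a provenance header comment.

mention_cols <- c(
  "mention_id", "note_id", "condition_id", "status", "start", "end",
  "snippet_start", "snippet_end", "negated", "hypothetical", "family",
  "generic_fp", "discarded", "score"
)

# Canonical empty mentions tibble; also used to coerce partial inputs.
empty_mentions <- function() {
  tibble::tibble(
    mention_id = character(0), note_id = character(0),
    condition_id = character(0), status = character(0),
    start = integer(0), end = integer(0),
    snippet_start = integer(0), snippet_end = integer(0),
    negated = logical(0), hypothetical = logical(0), family = logical(0),
    generic_fp = logical(0), discarded = logical(0), score = double(0)
  )
}

as_mentions <- function(x) {
  proto <- empty_mentions()
  for (col in setdiff(mention_cols, names(x))) {
    x[[col]] <- proto[[col]][NA_integer_][rep(1L, nrow(x))]
  }
  x <- x[mention_cols]
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  x$snippet_start <- as.integer(x$snippet_start)
  x$snippet_end <- as.integer(x$snippet_end)
  for (col in c("negated", "hypothetical", "family", "generic_fp", "discarded")) {
    x[[col]] <- ifelse(is.na(x[[col]]), FALSE, as.logical(x[[col]]))
  }
  x$score <- as.double(x$score)
  tibble::as_tibble(x)
}

provenance_line <- function(provenance) {
  if (is.null(provenance)) return(NULL)
  paste0(
    "# comorbidr ", as.character(utils::packageVersion("comorbidr")), " ",
    paste(names(provenance), unlist(provenance), sep = "=", collapse = " ")
  )
}

write_csv_with_header <- function(x, path, provenance = NULL) {
  hdr <- provenance_line(provenance)
  if (!is.null(hdr)) {
    writeLines(hdr, path)
    readr::write_csv(x, path, append = TRUE, col_names = TRUE, na = "")
  } else {
    readr::write_csv(x, path, na = "")
  }
  invisible(path)
}

#' Retrieve the rejected-record report of a reader
#'
#' Readers that tolerate malformed records ([read_notes()],
#' [read_claim_records()]) return the well-formed records and attach a
#' report of rejected ones.
#'
#' @param x An object returned by a reader.
#' @return A tibble with columns `line` and `reason` (zero rows when
#'   everything parsed).
#' @export
rejected_records <- function(x) {
  rej <- attr(x, "rejected")
  if (is.null(rej)) {
    rej <- tibble::tibble(line = integer(0), reason = character(0))
  }
  rej
}

#' Read a corpus of clinical notes
#'
#' The default interchange format is JSON-lines: one JSON object per line
#' with fields `note_id`, `stay_id`, `note_class`, `stay_type` and `text`.
#' A CSV dialect with the same columns is also supported. Malformed records
#' are rejected individually and reported via [rejected_records()]; a
#' duplicated `note_id` is a hard failure.
#'
#' @param path Path to the notes file.
#' @param dialect `"jsonl"` (default) or `"csv"`.
#' @return A tibble of notes (order preserved) with a `rejected` attribute.
#' @export
read_notes <- function(path, dialect = c("jsonl", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  required <- c("note_id", "stay_id", "note_class", "stay_type", "text")

  if (dialect == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    keep <- !grepl("^\\s*(#|$)", lines)
    idx <- which(keep)
    parsed <- purrr::map(lines[keep], function(l) {
      tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    })
    rejected <- list()
    rows <- list()
    for (i in seq_along(parsed)) {
      rec <- parsed[[i]]
      miss <- if (is.null(rec)) required else setdiff(required, names(rec))
      if (length(miss) > 0L) {
        rejected[[length(rejected) + 1L]] <- tibble::tibble(
          line = idx[i],
          reason = if (is.null(rec)) "unparsable JSON" else
            paste("missing field(s):", paste(miss, collapse = ", "))
        )
      } else {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          note_id = as.character(rec$note_id),
          stay_id = as.character(rec$stay_id),
          note_class = as.character(rec$note_class),
          stay_type = as.character(rec$stay_type),
          text = as.character(rec$text)
        )
      }
    }
    notes <- dplyr::bind_rows(rows)
    rejected <- dplyr::bind_rows(rejected)
  } else {
    notes <- readr::read_csv(
      path, comment = "#", show_col_types = FALSE,
      col_types = readr::cols(.default = readr::col_character())
    )
    miss <- setdiff(required, names(notes))
    if (length(miss) > 0L) {
      stop("notes CSV missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    rejected <- tibble::tibble(line = integer(0), reason = character(0))
  }

  if (nrow(notes) == 0L) {
    notes <- tibble::tibble(
      note_id = character(0), stay_id = character(0),
      note_class = character(0), stay_type = character(0), text = character(0)
    )
  }
  notes$text[is.na(notes$text)] <- ""
  dup <- notes$note_id[duplicated(notes$note_id)]
  if (length(dup) > 0L) {
    stop("duplicate note_id in corpus: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  attr(notes, "rejected") <- if (nrow(rejected)) rejected else
    tibble::tibble(line = integer(0), reason = character(0))
  notes
}

#' Write a corpus of notes as JSON-lines
#'
#' @param notes A notes tibble.
#' @param path Output path.
#' @param provenance Optional named list written as a `#` header comment.
#' @return The path, invisibly.
#' @export
write_notes <- function(notes, path, provenance = NULL) {
  lines <- purrr::pmap_chr(
    notes[c("note_id", "stay_id", "note_class", "stay_type", "text")],
    function(note_id, stay_id, note_class, stay_type, text) {
      jsonlite::toJSON(
        list(
          note_id = note_id, stay_id = stay_id, note_class = note_class,
          stay_type = stay_type, text = text
        ),
        auto_unbox = TRUE
      )
    }
  )
  writeLines(c(provenance_line(provenance), lines), path, useBytes = TRUE)
  invisible(path)
}

#' Write and read mention tables (CSV)
#'
#' The CSV dialect round-trips every mention field (spans, condition,
#' status, qualifier flags, discard flag, score).
#'
#' @param mentions A mentions tibble.
#' @param path File path.
#' @param provenance Optional named list written as a `#` header comment.
#' @return `write_mentions()` returns the path invisibly; `read_mentions()`
#'   returns a mentions tibble.
#' @export
write_mentions <- function(mentions, path, provenance = NULL) {
  write_csv_with_header(as_mentions(mentions), path, provenance)
}

#' @rdname write_mentions
#' @export
read_mentions <- function(path) {
  x <- readr::read_csv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      mention_id = readr::col_character(),
      note_id = readr::col_character(),
      condition_id = readr::col_character(),
      status = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      snippet_start = readr::col_integer(),
      snippet_end = readr::col_integer(),
      negated = readr::col_logical(),
      hypothetical = readr::col_logical(),
      family = readr::col_logical(),
      generic_fp = readr::col_logical(),
      discarded = readr::col_logical(),
      score = readr::col_double()
    )
  )
  dup <- x$mention_id[duplicated(x$mention_id)]
  if (length(dup) > 0L) {
    stop("duplicate mention_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  as_mentions(x)
}

#' Write mentions as BRAT standoff annotations
#'
#' One `.ann` file per note, named `<note_id>.ann`. Entity (`T`) lines carry
#' the condition label, the 0-based half-open raw-text span, and the exact
#' surface string; attribute (`A`) lines carry the status and qualifier
#' flags; `AnnotatorNotes` comment lines preserve the mention id and snippet
#' span so the round trip is lossless.
#'
#' @param mentions A mentions tibble.
#' @param notes The notes tibble the mentions refer to.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_standoff_annotations <- function(mentions, notes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mentions <- as_mentions(mentions)
  by_note <- split(mentions, mentions$note_id)
  for (nid in notes$note_id) {
    ms <- by_note[[nid]]
    lines <- character(0)
    if (!is.null(ms) && nrow(ms) > 0L) {
      text <- notes$text[notes$note_id == nid]
      a_ctr <- 0L
      for (i in seq_len(nrow(ms))) {
        surface <- gsub("\n", " ", slice_chars(text, ms$start[i], ms$end[i]))
        lines <- c(lines, sprintf(
          "T%d\t%s %d %d\t%s", i, ms$condition_id[i], ms$start[i], ms$end[i],
          surface
        ))
        meta <- jsonlite::toJSON(
          list(
            mention_id = ms$mention_id[i],
            snippet = c(ms$snippet_start[i], ms$snippet_end[i]),
            score = ms$score[i]
          ),
          auto_unbox = TRUE, null = "null", na = "null"
        )
        lines <- c(lines, sprintf("#%d\tAnnotatorNotes T%d\t%s", i, i, meta))
        if (!is.na(ms$status[i])) {
          a_ctr <- a_ctr + 1L
          lines <- c(lines, sprintf("A%d\tStatus T%d %s", a_ctr, i, ms$status[i]))
        }
        flags <- c(
          Negation = "negated", Hypothesis = "hypothetical",
          Family = "family", GenericFP = "generic_fp"
        )
        for (label in names(flags)) {
          if (isTRUE(ms[[flags[[label]]]][i])) {
            a_ctr <- a_ctr + 1L
            lines <- c(lines, sprintf("A%d\t%s T%d", a_ctr, label, i))
          }
        }
      }
    }
    writeLines(lines, file.path(dir, paste0(nid, ".ann")), useBytes = TRUE)
  }
  invisible(dir)
}

#' Read BRAT standoff annotations
#'
#' Reads one `.ann` file (note id taken from the file name) or a directory
#' of them. Entity spans are checked verbatim against the note text: a `T`
#' line whose quoted surface does not equal the corresponding text slice is
#' a hard failure naming the offending entity.
#'
#' @param path An `.ann` file or a directory containing `.ann` files.
#' @param notes The notes tibble the annotations refer to.
#' @return A mentions tibble. Mentions whose standoff carries a Negation,
#'   Hypothesis, Family or GenericFP attribute are flagged and marked
#'   discarded.
#' @export
read_standoff_annotations <- function(path, notes) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.ann$", full.names = TRUE)
  } else {
    path
  }
  purrr::map_dfr(files, function(f) {
    nid <- sub("\\.ann$", "", basename(f))
    if (!nid %in% notes$note_id) {
      stop("standoff file ", basename(f), " references unknown note '", nid,
           "'", call. = FALSE)
    }
    text <- notes$text[notes$note_id == nid]
    lines <- readLines(f, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    t_lines <- grep("^T", lines, value = TRUE)
    if (length(t_lines) == 0L) return(empty_mentions())

    ments <- purrr::map_dfr(t_lines, function(l) {
      parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 3L) {
        stop("malformed standoff T line in ", basename(f), ": ", l,
             call. = FALSE)
      }
      spec <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
      start <- as.integer(spec[2]); end <- as.integer(spec[3])
      surface <- parts[3]
      slice <- gsub("\n", " ", slice_chars(text, start, end))
      if (!identical(slice, surface)) {
        stop(
          "standoff span/surface mismatch for ", parts[1], " in ",
          basename(f), ": text slice '", slice, "' != '", surface, "'",
          call. = FALSE
        )
      }
      tibble::tibble(
        t_id = parts[1], note_id = nid, condition_id = spec[1],
        start = start, end = end
      )
    })

    ments$status <- NA_character_
    ments$negated <- FALSE; ments$hypothetical <- FALSE
    ments$family <- FALSE; ments$generic_fp <- FALSE
    ments$mention_id <- paste0(nid, ":", ments$t_id)
    ments$snippet_start <- NA_integer_; ments$snippet_end <- NA_integer_
    ments$score <- NA_real_

    for (l in grep("^A", lines, value = TRUE)) {
      parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
      spec <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
      j <- match(spec[2], ments$t_id)
      if (is.na(j)) next
      switch(
        spec[1],
        Status = { ments$status[j] <- spec[3] },
        Negation = { ments$negated[j] <- TRUE },
        Hypothesis = { ments$hypothetical[j] <- TRUE },
        Family = { ments$family[j] <- TRUE },
        GenericFP = { ments$generic_fp[j] <- TRUE }
      )
    }
    for (l in grep("^#", lines, value = TRUE)) {
      parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 3L || !grepl("^AnnotatorNotes", parts[2])) next
      t_ref <- strsplit(parts[2], " ", fixed = TRUE)[[1]][2]
      j <- match(t_ref, ments$t_id)
      if (is.na(j)) next
      meta <- tryCatch(jsonlite::fromJSON(parts[3]), error = function(e) NULL)
      if (is.null(meta)) next
      if (!is.null(meta$mention_id)) ments$mention_id[j] <- meta$mention_id
      if (!is.null(meta$snippet) && length(meta$snippet) == 2L &&
          !anyNA(meta$snippet)) {
        ments$snippet_start[j] <- as.integer(meta$snippet[1])
        ments$snippet_end[j] <- as.integer(meta$snippet[2])
      }
      if (!is.null(meta$score) && !is.na(meta$score)) {
        ments$score[j] <- as.numeric(meta$score)
      }
    }
    ments$discarded <- ments$negated | ments$hypothetical | ments$family |
      ments$generic_fp
    ments$t_id <- NULL
    as_mentions(ments)
  }) -> out
  if (nrow(out) == 0L) return(empty_mentions())
  dup <- out$mention_id[duplicated(out$mention_id)]
  if (length(dup) > 0L) {
    stop("duplicate mention_id in standoff corpus: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  out
}

#' Read and write claim records (CSV)
#'
#' Claim records are `stay_id, code` pairs of ICD-10 diagnosis codes. Codes
#' are normalized (uppercase, dot-free); rows whose normalized code does not
#' match the ICD-10 shape `[A-Z][0-9]{2}[0-9A-Z]{0,2}` are rejected and
#' reported via [rejected_records()].
#'
#' @param path File path.
#' @return A tibble with columns `stay_id` and `code`.
#' @export
read_claim_records <- function(path) {
  x <- readr::read_csv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      stay_id = readr::col_character(), code = readr::col_character()
    )
  )
  x$code <- normalize_icd10(x$code)
  ok <- grepl(icd10_code_rx, x$code)
  rejected <- tibble::tibble(
    line = which(!ok) + 1L,
    reason = paste0("malformed ICD-10 code: ", x$code[!ok])
  )
  out <- tibble::as_tibble(x[ok, , drop = FALSE])
  attr(out, "rejected") <- rejected
  out
}

#' @rdname read_claim_records
#' @param claims A claim-record tibble.
#' @param provenance Optional named list written as a `#` header comment.
#' @export
write_claim_records <- function(claims, path, provenance = NULL) {
  write_csv_with_header(claims[c("stay_id", "code")], path, provenance)
}

#' Write and read stay predictions (CSV)
#'
#' Stay predictions are long-format: one row per stay and condition, with
#' `status` equal to `"absent"`, `"present"` (binary conditions) or a status
#' label (statused conditions), plus the `source` that produced them
#' (`"nlp"`, `"claim"` or `"gold"`).
#'
#' @param stays A stay-prediction tibble.
#' @param path File path.
#' @param provenance Optional named list written as a `#` header comment.
#' @return `write_stay_predictions()` returns the path invisibly;
#'   `read_stay_predictions()` returns the tibble.
#' @export
write_stay_predictions <- function(stays, path, provenance = NULL) {
  write_csv_with_header(
    stays[c("stay_id", "source", "condition_id", "status")], path, provenance
  )
}

#' @rdname write_stay_predictions
#' @export
read_stay_predictions <- function(path) {
  readr::read_csv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      stay_id = readr::col_character(), source = readr::col_character(),
      condition_id = readr::col_character(), status = readr::col_character()
    )
  )
}
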