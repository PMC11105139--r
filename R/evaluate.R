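# Entity-level and stay-level scoring against gold standards: confusion
# counts, F1/PPV/sensitivity/specificity, micro/macro/weighted averages,
# bootstrap confidence intervals, PPV-only handling and pipeline
# comparison.

#' Entity-level confusion counts for one condition
#'
#' A predicted mention is a true positive when it overlaps (shares at least
#' one raw-text character with) a gold mention of the same condition in the
#' same note -- and of the same status when `status` is given. Predictions
#' are judged independently: a gold mention overlapped by k predictions
#' yields k true positives and no false negative. Gold mentions with no
#' overlapping prediction are false negatives. Discarded mentions on either
#' side are excluded first. There is no entity-level true-negative
#' universe, so `tn` is `NA`.
#'
#' @param pred,gold Mentions tibbles.
#' @param condition Condition identifier.
#' @param status Optional status label: restricts both sides to mentions
#'   carrying that status (the per-status binary task).
#' @return A one-row tibble with `tp`, `fp`, `fn`, `tn = NA`.
#' @export
match_entities <- function(pred, gold, condition, status = NULL) {
  per_stay <- entity_counts_by_note(pred, gold, condition, status)
  tibble::tibble(
    tp = sum(per_stay$tp), fp = sum(per_stay$fp), fn = sum(per_stay$fn),
    tn = NA_integer_
  )
}

# Per-note entity confusion contributions (additive; used for bootstrap).
entity_counts_by_note <- function(pred, gold, condition, status = NULL) {
  keep_task <- function(m) {
    m <- m[!m$discarded & m$condition_id == condition, , drop = FALSE]
    if (!is.null(status)) m <- m[!is.na(m$status) & m$status == status, , drop = FALSE]
    m
  }
  p <- keep_task(pred)
  g <- keep_task(gold)
  notes <- union(p$note_id, g$note_id)
  if (length(notes) == 0L) {
    return(tibble::tibble(
      note_id = character(0), tp = integer(0), fp = integer(0),
      fn = integer(0)
    ))
  }
  purrr::map_dfr(notes, function(nid) {
    pm <- p[p$note_id == nid, , drop = FALSE]
    gm <- g[g$note_id == nid, , drop = FALSE]
    if (nrow(pm) == 0L) {
      return(tibble::tibble(note_id = nid, tp = 0L, fp = 0L, fn = nrow(gm)))
    }
    if (nrow(gm) == 0L) {
      return(tibble::tibble(note_id = nid, tp = 0L, fp = nrow(pm), fn = 0L))
    }
    overlap <- outer(seq_len(nrow(pm)), seq_len(nrow(gm)), function(i, j) {
      pm$start[i] < gm$end[j] & pm$end[i] > gm$start[j]
    })
    pred_hit <- apply(overlap, 1, any)
    gold_hit <- apply(overlap, 2, any)
    tibble::tibble(
      note_id = nid,
      tp = sum(pred_hit), fp = sum(!pred_hit), fn = sum(!gold_hit)
    )
  })
}

#' Stay-level confusion counts for one condition
#'
#' Per stay: true positive when both prediction and gold are positive (and
#' agree on the status when `status` is given), false positive when only
#' the prediction is, false negative when only the gold is, true negative
#' when both are absent. The stay universe is the set of stays in `gold`;
#' stays missing from `pred` count as predicted absent.
#'
#' @param pred,gold Stay-prediction tibbles.
#' @param condition Condition identifier.
#' @param status Optional status label defining the per-status binary task;
#'   without it, any non-absent status counts as positive.
#' @return A one-row tibble with `tp`, `fp`, `fn`, `tn`.
#' @export
stay_confusion <- function(pred, gold, condition, status = NULL) {
  per_stay <- stay_counts_by_stay(pred, gold, condition, status)
  tibble::tibble(
    tp = sum(per_stay$tp), fp = sum(per_stay$fp),
    fn = sum(per_stay$fn), tn = sum(per_stay$tn)
  )
}

stay_counts_by_stay <- function(pred, gold, condition, status = NULL) {
  g <- gold[gold$condition_id == condition, c("stay_id", "status")]
  p <- pred[pred$condition_id == condition, c("stay_id", "status")]
  joined <- dplyr::left_join(g, p, by = "stay_id", suffix = c("_gold", "_pred"))
  joined$status_pred[is.na(joined$status_pred)] <- "absent"
  positive <- function(s) {
    if (is.null(status)) s != "absent" else s == status
  }
  gp <- positive(joined$status_gold)
  pp <- positive(joined$status_pred)
  tibble::tibble(
    stay_id = joined$stay_id,
    tp = as.integer(gp & pp), fp = as.integer(!gp & pp),
    fn = as.integer(gp & !pp), tn = as.integer(!gp & !pp)
  )
}

#' Confusion-derived metrics
#'
#' Positive predictive value, sensitivity, specificity and F1-score as
#' percentages, computed row-wise from confusion counts. A metric whose
#' denominator is zero (or whose counts are undefined, as specificity is at
#' the entity level) is `NA`, never 0.
#'
#' @param counts A tibble with columns `tp`, `fp`, `fn` and optionally `tn`.
#' @return The input with columns `ppv`, `sensitivity`, `specificity`, `f1`
#'   added (percentages in `[0, 100]` or `NA`).
#' @export
compute_metrics <- function(counts) {
  counts <- tibble::as_tibble(counts)
  if (!"tn" %in% names(counts)) counts$tn <- NA_integer_
  safe_div <- function(num, den) ifelse(!is.na(den) & den > 0, 100 * num / den, NA_real_)
  counts$ppv <- safe_div(counts$tp, counts$tp + counts$fp)
  counts$sensitivity <- safe_div(counts$tp, counts$tp + counts$fn)
  counts$specificity <- safe_div(counts$tn, counts$tn + counts$fp)
  counts$f1 <- ifelse(
    !is.na(counts$ppv) & !is.na(counts$sensitivity) &
      (counts$ppv + counts$sensitivity) > 0,
    2 * counts$ppv * counts$sensitivity / (counts$ppv + counts$sensitivity),
    NA_real_
  )
  counts
}

metric_names <- c("f1", "ppv", "sensitivity", "specificity")

#' Micro, macro and weighted averages of per-condition metrics
#'
#' Micro: metrics computed on the summed confusion counts. Macro:
#' unweighted mean of each metric over the rows where it is defined.
#' Weighted: support-weighted mean (support = gold positives, `tp + fn`).
#' Rows flagged `ppv_only` must be excluded by the caller before averaging.
#'
#' @param rows A tibble of per-condition rows with confusion counts (and
#'   metrics; recomputed if absent).
#' @return A three-row tibble (`average` = micro/macro/weighted) with the
#'   four metrics and the total support.
#' @export
average_metrics <- function(rows) {
  rows <- compute_metrics(rows[c("tp", "fp", "fn", "tn")])
  rows$support <- rows$tp + rows$fn

  micro_counts <- tibble::tibble(
    tp = sum(rows$tp), fp = sum(rows$fp), fn = sum(rows$fn),
    tn = if (anyNA(rows$tn)) NA_integer_ else sum(rows$tn)
  )
  micro <- compute_metrics(micro_counts)

  avg_row <- function(label, fun) {
    vals <- purrr::map_dbl(metric_names, function(m) fun(rows[[m]]))
    tibble::tibble(
      average = label,
      f1 = vals[1], ppv = vals[2], sensitivity = vals[3], specificity = vals[4],
      support = sum(rows$support)
    )
  }
  macro <- avg_row("macro", function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  weighted <- avg_row("weighted", function(x) {
    ok <- !is.na(x)
    if (!any(ok)) return(NA_real_)
    stats::weighted.mean(x[ok], rows$support[ok])
  })
  dplyr::bind_rows(
    tibble::tibble(
      average = "micro", f1 = micro$f1, ppv = micro$ppv,
      sensitivity = micro$sensitivity, specificity = micro$specificity,
      support = sum(rows$support)
    ),
    macro, weighted
  )
}

#' Percentile bootstrap confidence intervals over stays
#'
#' Resamples the independent sampling units (stays) with replacement and
#' recomputes the metric(s) on each resample; the interval is the
#' percentile interval at the requested level. Deterministic given the
#' seed. Resamples on which a metric is undefined are skipped for that
#' metric and counted.
#'
#' @param units A tibble with one or more rows per unit, keyed by the `by`
#'   column (default `"stay_id"`).
#' @param metric_fn A function taking a resampled tibble and returning a
#'   named numeric vector of metrics.
#' @param reps Number of bootstrap resamples (>= 1).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @param by Name of the unit-id column.
#' @return A tibble with one row per metric: `metric`, `estimate`, `low`,
#'   `high`, `n_degenerate`.
#' @export
bootstrap_ci <- function(units, metric_fn, reps = 1000L, seed = 1L,
                         level = 0.95, by = "stay_id") {
  stopifnot(reps >= 1L, by %in% names(units))
  ids <- unique(units[[by]])
  n <- length(ids)
  row_groups <- split(seq_len(nrow(units)), match(units[[by]], ids))
  point <- metric_fn(units)

  draws <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      pick <- sample.int(n, n, replace = TRUE)
      res <- units[unlist(row_groups[pick], use.names = FALSE), , drop = FALSE]
      as.numeric(metric_fn(res))[seq_along(point)]
    }, numeric(length(point)))
  })
  draws <- matrix(draws, nrow = length(point))

  alpha <- (1 - level) / 2
  purrr::map_dfr(seq_along(point), function(k) {
    x <- draws[k, ]
    deg <- sum(is.na(x))
    x <- x[!is.na(x)]
    tibble::tibble(
      metric = names(point)[k] %||% paste0("metric", k),
      estimate = unname(point[k]),
      low = if (length(x)) unname(stats::quantile(x, alpha)) else NA_real_,
      high = if (length(x)) unname(stats::quantile(x, 1 - alpha)) else NA_real_,
      n_degenerate = deg
    )
  })
}

# Per-stay confusion contributions for one evaluation task, at either level.
task_counts_by_stay <- function(pred, gold, condition, status, level, notes) {
  if (level == "stay") {
    stay_counts_by_stay(pred, gold, condition, status)
  } else {
    per_note <- entity_counts_by_note(pred, gold, condition, status)
    per_note$stay_id <- if (is.null(notes)) {
      per_note$note_id
    } else {
      notes$stay_id[match(per_note$note_id, notes$note_id)]
    }
    per_note |>
      dplyr::group_by(.data$stay_id) |>
      dplyr::summarise(
        tp = sum(.data$tp), fp = sum(.data$fp), fn = sum(.data$fn),
        .groups = "drop"
      ) |>
      dplyr::mutate(tn = NA_integer_)
  }
}

#' Evaluate a pipeline against a gold standard
#'
#' Builds the full metrics report: one row per condition (binary
#' conditions), and for statused conditions one row per status plus an
#' `"any"` row that collapses statuses to presence. PPV-only conditions
#' (by default hemiplegia and AIDS, validated only on positive
#' predictions) report only their PPV and are excluded from the micro,
#' macro and weighted averages. Optional bootstrap confidence intervals
#' resample stays.
#'
#' @param pred Predictions: a stay-prediction tibble (`level = "stay"`) or
#'   a mentions tibble (`level = "entity"`).
#' @param gold Gold standard of the same shape.
#' @param definitions A `condition_definitions` object.
#' @param level `"stay"` (the full pipeline) or `"entity"` (the pipeline
#'   minus aggregation).
#' @param notes Notes tibble; required at entity level (note-to-stay map
#'   for the bootstrap).
#' @param ci Compute bootstrap confidence intervals?
#' @param reps,seed,conf_level Bootstrap parameters.
#' @return A `metrics_report`: list with `rows` (per-condition metrics),
#'   `averages` (micro/macro/weighted), `excluded_conditions` and `level`.
#' @export
evaluate_pipeline <- function(pred, gold, definitions,
                              level = c("stay", "entity"), notes = NULL,
                              ci = FALSE, reps = 1000L, seed = 1L,
                              conf_level = 0.95) {
  level <- match.arg(level)
  if (level == "entity" && ci && is.null(notes)) {
    stop("entity-level bootstrap needs `notes` to map notes to stays",
         call. = FALSE)
  }

  tasks <- purrr::map_dfr(definitions, function(def) {
    if (length(def$statuses) == 0L) {
      tibble::tibble(
        condition_id = def$condition_id, scope = "condition",
        status = NA_character_, ppv_only = def$ppv_only
      )
    } else {
      dplyr::bind_rows(
        tibble::tibble(
          condition_id = def$condition_id, scope = "status",
          status = def$statuses, ppv_only = def$ppv_only
        ),
        tibble::tibble(
          condition_id = def$condition_id, scope = "any",
          status = NA_character_, ppv_only = def$ppv_only
        )
      )
    }
  })

  rows <- purrr::map_dfr(seq_len(nrow(tasks)), function(t) {
    status <- if (is.na(tasks$status[t])) NULL else tasks$status[t]
    per_stay <- task_counts_by_stay(
      pred, gold, tasks$condition_id[t], status, level, notes
    )
    counts <- tibble::tibble(
      tp = sum(per_stay$tp), fp = sum(per_stay$fp), fn = sum(per_stay$fn),
      tn = if (level == "stay") sum(per_stay$tn) else NA_integer_
    )
    row <- compute_metrics(counts)
    row <- dplyr::bind_cols(tasks[t, ], row)
    row$support <- row$tp + row$fn
    if (tasks$ppv_only[t]) {
      row$f1 <- NA_real_; row$sensitivity <- NA_real_
      row$specificity <- NA_real_
    }
    if (ci && !tasks$ppv_only[t]) {
      cis <- bootstrap_ci(
        per_stay,
        function(u) {
          m <- compute_metrics(tibble::tibble(
            tp = sum(u$tp), fp = sum(u$fp), fn = sum(u$fn),
            tn = if (level == "stay") sum(u$tn) else NA_integer_
          ))
          c(f1 = m$f1, ppv = m$ppv, sensitivity = m$sensitivity,
            specificity = m$specificity)
        },
        reps = reps, seed = seed, level = conf_level
      )
      for (m in metric_names) {
        row[[paste0(m, "_low")]] <- cis$low[cis$metric == m]
        row[[paste0(m, "_high")]] <- cis$high[cis$metric == m]
      }
    }
    row
  })

  excluded <- unique(rows$condition_id[rows$ppv_only])
  averages <- average_metrics(rows[!rows$ppv_only, , drop = FALSE])

  structure(
    list(
      rows = rows, averages = averages,
      excluded_conditions = excluded, level = level
    ),
    class = "metrics_report"
  )
}

# Display rounding: percentages round half-up to one decimal.
round_half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> level=", x$level, ", ", nrow(x$rows), " rows",
      if (length(x$excluded_conditions)) {
        paste0(" (PPV-only, excluded from averages: ",
               paste(x$excluded_conditions, collapse = ", "), ")")
      } else "",
      "\n", sep = "")
  shown <- x$rows[c("condition_id", "scope", "status", "support", metric_names)]
  for (m in metric_names) shown[[m]] <- round_half_up(shown[[m]])
  print(as.data.frame(shown), row.names = FALSE)
  cat("\n")
  avg <- x$averages
  for (m in metric_names) avg[[m]] <- round_half_up(avg[[m]])
  print(as.data.frame(avg), row.names = FALSE)
  invisible(x)
}

#' Tidy a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return The per-condition rows (raw, unrounded percentages).
#' @export
tidy.metrics_report <- function(x, ...) x$rows

#' @rdname tidy.metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  micro <- x$averages[x$averages$average == "micro", ]
  tibble::tibble(
    level = x$level,
    n_rows = nrow(x$rows),
    n_excluded = length(x$excluded_conditions),
    micro_f1 = micro$f1, micro_ppv = micro$ppv,
    micro_sensitivity = micro$sensitivity,
    micro_specificity = micro$specificity
  )
}

#' Write a metrics report to CSV and JSON
#'
#' @param report A `metrics_report`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @param provenance Optional named list written as a CSV header comment.
#' @return The report, invisibly.
#' @export
write_metrics_report <- function(report, csv_path = NULL, json_path = NULL,
                                 provenance = NULL) {
  if (!is.null(csv_path)) {
    write_csv_with_header(report$rows, csv_path, provenance)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(
        level = report$level,
        rows = report$rows,
        averages = report$averages,
        excluded_conditions = report$excluded_conditions
      ),
      json_path, auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  invisible(report)
}

#' Compare metrics reports across pipelines
#'
#' Stacks per-condition rows from several reports and flags, for every
#' (condition, scope, status, metric), the best-performing pipeline(s).
#'
#' @param reports A named list of `metrics_report` objects (names are
#'   pipeline labels).
#' @return A long tibble with columns `pipeline`, `condition_id`, `scope`,
#'   `status`, `metric`, `value`, `best`.
#' @export
compare_pipelines <- function(reports) {
  stopifnot(length(reports) >= 1L, !is.null(names(reports)))
  long <- purrr::imap_dfr(reports, function(rep, name) {
    rep$rows |>
      dplyr::select(dplyr::all_of(c(
        "condition_id", "scope", "status", metric_names
      ))) |>
      tidyr::pivot_longer(
        dplyr::all_of(metric_names),
        names_to = "metric", values_to = "value"
      ) |>
      dplyr::mutate(pipeline = name, .before = 1)
  })
  long |>
    dplyr::group_by(.data$condition_id, .data$scope, .data$status, .data$metric) |>
    dplyr::mutate(
      best = if (all(is.na(.data$value))) FALSE else {
        !is.na(.data$value) & .data$value == max(.data$value, na.rm = TRUE)
      }
    ) |>
    dplyr::ungroup()
}
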