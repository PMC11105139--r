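mk_span <- function(note_id, condition, start, end, status = NA_character_,
                    discarded = FALSE, id = NULL) {
  tibble::tibble(
    mention_id = id %||% paste0("m", start, "_", end, "_", note_id),
    note_id = note_id, condition_id = condition, status = status,
    start = as.integer(start), end = as.integer(end),
    snippet_start = as.integer(start), snippet_end = as.integer(end),
    negated = FALSE, hypothetical = FALSE, family = FALSE,
    generic_fp = FALSE, discarded = discarded, score = NA_real_
  )
}

test_that("entity matching uses character overlap, predictions judged independently", {
  g <- dplyr::bind_rows(
    mk_span("n1", "diabetes", 10, 20, id = "g1"),
    mk_span("n1", "diabetes", 40, 50, id = "g2")
  )
  # identical span sets
  c1 <- match_entities(g, g, "diabetes")
  expect_equal(c(c1$tp, c1$fp, c1$fn), c(2, 0, 0))
  expect_true(is.na(c1$tn))

  # one shared character suffices
  p2 <- mk_span("n1", "diabetes", 19, 30, id = "p1")
  c2 <- match_entities(p2, g, "diabetes")
  expect_equal(c(c2$tp, c2$fp, c2$fn), c(1, 0, 1))

  # 2 predictions over 1 gold + 1 unmatched gold -> tp=2, fp=0, fn=1
  p3 <- dplyr::bind_rows(
    mk_span("n1", "diabetes", 10, 15, id = "p1"),
    mk_span("n1", "diabetes", 15, 21, id = "p2")
  )
  c3 <- match_entities(p3, g, "diabetes")
  expect_equal(c(c3$tp, c3$fp, c3$fn), c(2, 0, 1))

  # same span in a different note never matches
  p4 <- mk_span("n2", "diabetes", 10, 20, id = "p4")
  c4 <- match_entities(p4, g, "diabetes")
  expect_equal(c(c4$tp, c4$fp, c4$fn), c(0, 1, 2))

  # randomized fixtures agree with the brute-force all-pairs oracle
  withr::with_seed(12, {
    for (i in 1:20) {
      rand_set <- function(tag) {
        n <- sample(0:8, 1)
        if (n == 0) return(mk_span("n1", "diabetes", 0, 1)[0, ])
        dplyr::bind_rows(lapply(seq_len(n), function(k) {
          s <- sample(0:60, 1)
          mk_span(sample(c("n1", "n2"), 1), "diabetes", s, s + sample(1:10, 1),
                  status = sample(c(NA, "uncomplicated"), 1),
                  discarded = stats::runif(1) < 0.2,
                  id = paste0(tag, k))
        }))
      }
      p <- rand_set("p"); gg <- rand_set("g")
      if (nrow(p) == 0 && nrow(gg) == 0) next
      got <- match_entities(p, gg, "diabetes")
      want <- oracle_entity_counts(p, gg, "diabetes")
      expect_equal(c(got$tp, got$fp, got$fn), unname(want))
    }
  })
})

stay_grid <- function(stays, condition, positive, status_lab = "present") {
  tibble::tibble(
    stay_id = stays, source = "x", condition_id = condition,
    status = ifelse(stays %in% positive, status_lab, "absent")
  )
}

test_that("stay confusion counts per-stay agreement", {
  stays <- sprintf("s%02d", 1:50)
  gold <- stay_grid(stays, "diabetes", stays[1:10])
  c1 <- stay_confusion(gold, gold, "diabetes")
  expect_equal(c(c1$tp, c1$fp, c1$fn, c1$tn), c(10, 0, 0, 40))

  none <- stay_grid(stays, "diabetes", character(0))
  c2 <- stay_confusion(none, gold, "diabetes")
  expect_equal(c(c2$tp, c2$fp, c2$fn, c2$tn), c(0, 0, 10, 40))

  # randomized fixture equals brute-force per-stay enumeration
  withr::with_seed(3, {
    for (i in 1:20) {
      st <- sprintf("s%02d", 1:20)
      gpos <- sample(st, sample(0:20, 1))
      ppos <- sample(st, sample(0:20, 1))
      g <- stay_grid(st, "dementia", gpos)
      p <- stay_grid(st, "dementia", ppos)
      got <- stay_confusion(p, g, "dementia")
      tp <- sum(st %in% gpos & st %in% ppos)
      fp <- sum(!(st %in% gpos) & st %in% ppos)
      fn <- sum(st %in% gpos & !(st %in% ppos))
      tn <- sum(!(st %in% gpos) & !(st %in% ppos))
      expect_equal(c(got$tp, got$fp, got$fn, got$tn), c(tp, fp, fn, tn))
    }
  })
})

test_that("metrics follow the closed forms, undefined never rendered as 0", {
  m <- compute_metrics(tibble::tibble(tp = 9, fp = 1, fn = 1, tn = 89))
  expect_equal(m$ppv, 90)
  expect_equal(m$sensitivity, 90)
  expect_equal(m$f1, 90)
  expect_equal(m$specificity, 100 * 89 / 90)

  z <- compute_metrics(tibble::tibble(tp = 0, fp = 0, fn = 0, tn = 5))
  expect_true(is.na(z$ppv) && is.na(z$sensitivity) && is.na(z$f1))
  expect_equal(z$specificity, 100)

  withr::with_seed(21, {
    for (i in 1:100) {
      tp <- sample(0:20, 1); fp <- sample(0:20, 1)
      fn <- sample(0:20, 1); tn <- sample(0:20, 1)
      got <- compute_metrics(tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn))
      want <- oracle_metrics(tp, fp, fn, tn)
      expect_equal(
        c(got$ppv, got$sensitivity, got$specificity, got$f1),
        unname(want[c("ppv", "sensitivity", "specificity", "f1")])
      )
    }
  })
})

test_that("micro/macro/weighted averages follow their definitions", {
  rows <- tibble::tibble(
    tp = c(5, 5, 5), fp = c(1, 1, 1), fn = c(2, 2, 2), tn = c(10, 10, 10)
  )
  avg <- average_metrics(rows)
  one <- compute_metrics(rows[1, ])
  for (a in c("micro", "macro", "weighted")) {
    expect_equal(avg$ppv[avg$average == a], one$ppv)
    expect_equal(avg$sensitivity[avg$average == a], one$sensitivity)
  }

  # weighted = support-weighted mean
  rows2 <- tibble::tibble(
    tp = c(1, 3), fp = c(0, 1), fn = c(0, 0), tn = c(5, 5)
  )
  m2 <- compute_metrics(rows2)
  supports <- rows2$tp + rows2$fn
  avg2 <- average_metrics(rows2)
  expect_equal(
    avg2$ppv[avg2$average == "weighted"],
    (supports[1] * m2$ppv[1] + supports[2] * m2$ppv[2]) / sum(supports)
  )

  # micro equals metrics of summed counts; invariance under permutation
  withr::with_seed(30, {
    rows3 <- tibble::tibble(
      tp = sample(0:9, 5, TRUE), fp = sample(0:9, 5, TRUE),
      fn = sample(0:9, 5, TRUE), tn = sample(0:9, 5, TRUE)
    )
    avg3 <- average_metrics(rows3)
    summed <- compute_metrics(tibble::tibble(
      tp = sum(rows3$tp), fp = sum(rows3$fp),
      fn = sum(rows3$fn), tn = sum(rows3$tn)
    ))
    expect_equal(avg3$ppv[1], summed$ppv)
    expect_equal(avg3$f1[1], summed$f1)
    avg3p <- average_metrics(rows3[sample(5), ])
    expect_equal(avg3, avg3p)
  })
})

test_that("bootstrap intervals are deterministic and degenerate-aware", {
  units <- tibble::tibble(
    stay_id = sprintf("s%02d", 1:30),
    tp = 1L, fp = 0L, fn = 0L, tn = 0L
  )
  se_fn <- function(u) c(sensitivity = 100 * sum(u$tp) / sum(u$tp + u$fn))
  ci <- bootstrap_ci(units, se_fn, reps = 200, seed = 4)
  expect_equal(ci$low, 100)
  expect_equal(ci$high, 100)
  expect_equal(ci$estimate, 100)

  ci2 <- bootstrap_ci(units, se_fn, reps = 200, seed = 4)
  expect_identical(ci, ci2)

  # degenerate resamples are skipped and counted
  units2 <- tibble::tibble(
    stay_id = c("a", "b"), tp = c(1L, 0L), fp = 0L, fn = 0L, tn = c(0L, 1L)
  )
  ppv_fn <- function(u) {
    den <- sum(u$tp + u$fp)
    c(ppv = if (den > 0) 100 * sum(u$tp) / den else NA_real_)
  }
  ci3 <- bootstrap_ci(units2, ppv_fn, reps = 500, seed = 9)
  expect_gt(ci3$n_degenerate, 0)
})

test_that("pipeline reports expand statuses and exclude PPV-only conditions", {
  defs <- test_defs()
  cfg <- generator_config(
    n_stays = 40, seed = 17,
    prevalence = list(diabetes = 0.8, hemiplegia = 0.3, renal_disease = 0.4),
    status_mix = 0.5, negation_rate = 0, hypothesis_rate = 0,
    family_rate = 0, generic_fp_rate = 0, oov_cue_rate = 0
  )
  corpus <- generate_corpus(cfg, defs)
  res <- annotate_notes(corpus$notes, defs)
  rep <- evaluate_pipeline(res$stay_predictions, corpus$stay_labels, defs,
                           level = "stay")

  dia <- rep$rows[rep$rows$condition_id == "diabetes", ]
  expect_equal(nrow(dia), 3)  # two statuses + any
  expect_setequal(dia$scope, c("status", "status", "any"))

  expect_setequal(rep$excluded_conditions, c("hemiplegia", "aids"))
  hemi <- rep$rows[rep$rows$condition_id == "hemiplegia", ]
  expect_true(is.na(hemi$f1) && is.na(hemi$sensitivity) && is.na(hemi$specificity))
  expect_false(is.na(hemi$ppv))

  # a perfect prediction scores 100 everywhere defined
  expect_true(all(rep$rows$f1[!rep$rows$ppv_only & !is.na(rep$rows$f1)] == 100))
  expect_equal(glance(rep)$micro_f1, 100)
})

test_that("pipeline comparison flags the best pipeline per metric", {
  defs <- test_defs()
  cfg <- generator_config(n_stays = 25, seed = 19)
  corpus <- generate_corpus(cfg, defs)
  res <- annotate_notes(corpus$notes, defs)
  rep <- evaluate_pipeline(res$stay_predictions, corpus$stay_labels, defs)

  single <- compare_pipelines(list(nlp = rep))
  expect_true(all(single$best | is.na(single$value)))

  # degrade a copy: the intact report dominates where they differ
  worse <- rep
  worse$rows$f1 <- worse$rows$f1 - 5
  both <- compare_pipelines(list(nlp = rep, worse = worse))
  f1_rows <- both[both$metric == "f1" & !is.na(both$value), ]
  expect_true(all(f1_rows$best[f1_rows$pipeline == "nlp"]))
  expect_false(any(f1_rows$best[f1_rows$pipeline == "worse"]))
})
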