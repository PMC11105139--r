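mk_mention <- function(note_id, condition_id, status = NA_character_,
                       discarded = FALSE, id = NULL) {
  tibble::tibble(
    mention_id = id %||% paste0("m", stats::runif(1)),
    note_id = note_id, condition_id = condition_id, status = status,
    start = 0L, end = 1L, snippet_start = 0L, snippet_end = 1L,
    negated = discarded, hypothetical = FALSE, family = FALSE,
    generic_fp = FALSE, discarded = discarded, score = NA_real_
  )
}

test_that("stay aggregation: presence iff a kept mention, most severe status", {
  defs <- test_defs()
  notes <- one_note("texte", note_id = "n1", stay_id = "s1")

  # no kept mentions -> absent
  agg0 <- aggregate_stays(
    mk_mention("n1", "diabetes", "uncomplicated", discarded = TRUE),
    notes, defs
  )
  expect_equal(agg0$status[agg0$condition_id == "diabetes"], "absent")

  # localized + metastatic -> metastatic
  ms <- dplyr::bind_rows(
    mk_mention("n1", "solid_tumor", "localized", id = "a"),
    mk_mention("n1", "solid_tumor", "metastatic", id = "b")
  )
  agg <- aggregate_stays(ms, notes, defs)
  expect_equal(agg$status[agg$condition_id == "solid_tumor"], "metastatic")

  # three identical statuses -> that status
  ms3 <- dplyr::bind_rows(lapply(1:3, function(i) {
    mk_mention("n1", "diabetes", "uncomplicated", id = paste0("d", i))
  }))
  agg3 <- aggregate_stays(ms3, notes, defs)
  expect_equal(agg3$status[agg3$condition_id == "diabetes"], "uncomplicated")

  # binary conditions report plain presence; unset statused counts least severe
  ms4 <- dplyr::bind_rows(
    mk_mention("n1", "renal_disease", id = "r1"),
    mk_mention("n1", "liver_disease", NA_character_, id = "l1")
  )
  agg4 <- aggregate_stays(ms4, notes, defs)
  expect_equal(agg4$status[agg4$condition_id == "renal_disease"], "present")
  expect_equal(agg4$status[agg4$condition_id == "liver_disease"], "mild")
})

test_that("aggregation is order-independent, idempotent and monotone", {
  defs <- test_defs()
  notes <- one_note("x", note_id = "n1", stay_id = "s1")
  statuses <- c(NA, "uncomplicated", "with_end_organ_damage")
  withr::with_seed(8, {
    for (i in 1:25) {
      n <- sample(1:6, 1)
      ms <- dplyr::bind_rows(lapply(seq_len(n), function(k) {
        mk_mention("n1", "diabetes", sample(statuses, 1),
                   discarded = stats::runif(1) < 0.4, id = paste0("m", k))
      }))
      a1 <- aggregate_stays(ms, notes, defs)
      a2 <- aggregate_stays(ms[sample(n), ], notes, defs)
      expect_equal(a1, a2)

      # adding a kept mention never removes presence nor lowers the status
      extra <- mk_mention("n1", "diabetes", sample(statuses, 1), id = "extra")
      a3 <- aggregate_stays(dplyr::bind_rows(ms, extra), notes, defs)
      s_before <- a1$status[a1$condition_id == "diabetes"]
      s_after <- a3$status[a3$condition_id == "diabetes"]
      rank_of <- function(s) {
        if (s == "absent") 0L else match(s, defs$diabetes$statuses)
      }
      expect_gte(rank_of(s_after), max(1L, rank_of(s_before)))
    }
  })
})

test_that("the Charlson index sums configured weights, skipping tobacco/alcohol", {
  defs <- test_defs()
  grid <- tidyr::expand_grid(
    stay_id = "s1", source = "gold", condition_id = condition_ids()
  )
  grid$status <- "absent"

  # all conditions absent -> 0
  expect_equal(compute_cci(grid, defs)$cci, 0L)

  # tobacco present alone -> still 0 (not part of the index)
  tob <- grid
  tob$status[tob$condition_id == "tobacco_consumption"] <- "present"
  expect_equal(compute_cci(tob, defs)$cci, 0L)
  alc <- grid
  alc$status[alc$condition_id == "alcohol_consumption"] <- "present"
  expect_equal(compute_cci(alc, defs)$cci, 0L)

  # hand-summed fixture against the shipped weight table:
  # myocardial infarction (1) + metastatic solid tumor (6) + mild liver (1)
  fx <- grid
  fx$status[fx$condition_id == "myocardial_infarction"] <- "present"
  fx$status[fx$condition_id == "solid_tumor"] <- "metastatic"
  fx$status[fx$condition_id == "liver_disease"] <- "mild"
  w <- defs$myocardial_infarction$cci_weight$any +
    defs$solid_tumor$cci_weight$metastatic +
    defs$liver_disease$cci_weight$mild
  expect_equal(compute_cci(fx, defs)$cci, as.integer(w))
  expect_equal(w, 8)

  # monotone: adding a present condition never decreases the score
  fx2 <- fx
  fx2$status[fx2$condition_id == "dementia"] <- "present"
  expect_gte(compute_cci(fx2, defs)$cci, compute_cci(fx, defs)$cci)

  # a weight table hole is an error
  defs2 <- test_defs()
  defs2$renal_disease$cci_weight <- list()
  bad <- grid
  bad$status[bad$condition_id == "renal_disease"] <- "present"
  expect_error(compute_cci(bad, defs2), "weight table")
})

test_that("prevalence estimates and gaps behave", {
  grid <- tidyr::expand_grid(
    stay_id = sprintf("s%02d", 1:50), source = "nlp",
    condition_id = "diabetes"
  )
  grid$status <- c(rep("present", 5), rep("absent", 45))
  prev <- estimate_prevalence(grid)
  expect_equal(prev$prevalence, 0.10)

  expect_error(estimate_prevalence(grid[0, ]), "empty")

  gap <- prevalence_gap(grid, grid)
  expect_equal(gap$mean_abs_gap, 0)
})
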