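test_that("inclusion patterns yield mentions with raw spans", {
  defs <- test_defs()
  note <- one_note("le patient presente un diabete de type 2 connu")
  ms <- extract_mentions(note, defs)
  ms <- ms[ms$condition_id == "diabetes", ]
  expect_equal(nrow(ms), 1)
  expect_equal(
    substr(note$text, ms$start + 1, ms$end),
    "diabete de type 2"
  )
  expect_true(is.na(ms$status))
  expect_false(any(ms$negated | ms$hypothetical | ms$family | ms$generic_fp))

  # no pattern hits -> no mentions
  expect_equal(nrow(extract_mentions(one_note("bilan strictement normal"), defs)), 0)

  # two distinct hits of the same condition stay separate
  ms2 <- extract_mentions(one_note("infarctus du myocarde ; idm confirme"), defs)
  ms2 <- ms2[ms2$condition_id == "myocardial_infarction", ]
  expect_equal(nrow(ms2), 2)

  # overlapping same-condition matches merge to the longest span
  ms3 <- extract_mentions(one_note("infection a vih connue"), defs)
  ms3 <- ms3[ms3$condition_id == "aids", ]
  expect_equal(nrow(ms3), 1)
  expect_equal(substr("infection a vih connue", ms3$start + 1, ms3$end),
               "infection a vih")
})

test_that("accented raw text maps spans back through normalization", {
  defs <- test_defs()
  note <- one_note("Le patient présente un Diabète évolué")
  ms <- extract_mentions(note, defs)
  ms <- ms[ms$condition_id == "diabetes", ]
  expect_equal(nrow(ms), 1)
  expect_equal(substr(note$text, ms$start + 1, ms$end), "Diabète")
})

test_that("exclusions and sections flag generic FPs and family mentions", {
  defs <- test_defs()
  # condition inside a care-site name -> generic FP, discarded
  note <- one_note("adresse par l'hopital marie lannelongue pour un avis ; insuffisance cardiaque")
  ms <- extract_mentions(note, defs)
  ms <- apply_exclusions(ms, note, defs)
  chf <- ms[ms$condition_id == "congestive_heart_failure", ]
  expect_equal(nrow(chf), 1)
  expect_false(chf$generic_fp)  # outside the care-site span: kept

  note2 <- one_note("transfert de l'hopital insuffisance cardiaque de paris")
  ms2 <- apply_exclusions(extract_mentions(note2, defs), note2, defs)
  chf2 <- ms2[ms2$condition_id == "congestive_heart_failure", ]
  expect_true(chf2$generic_fp)
  expect_true(chf2$discarded)

  # specific exclusion: diabete insipide is not the index condition
  note3 <- one_note("bilan d'un diabete insipide central")
  ms3 <- apply_exclusions(extract_mentions(note3, defs), note3, defs)
  expect_true(all(ms3$generic_fp[ms3$condition_id == "diabetes"]))

  # family-history section adds the family qualifier instead
  note4 <- one_note("antecedents familiaux :\ndiabete chez le pere\nconclusion :\nrien")
  ms4 <- apply_exclusions(extract_mentions(note4, defs), note4, defs)
  dia <- ms4[ms4$condition_id == "diabetes", ]
  expect_true(dia$family)
  expect_false(dia$generic_fp)

  # irrelevant section -> generic FP
  note5 <- one_note("signature :\ndr cancer service oncologie")
  ms5 <- apply_exclusions(extract_mentions(note5, defs), note5, defs)
  expect_true(all(ms5$generic_fp))

  # untouched mention in the implicit relevant section
  note6 <- one_note("suivi pour asthme ancien")
  ms6 <- apply_exclusions(extract_mentions(note6, defs), note6, defs)
  expect_false(any(ms6$discarded))
})

test_that("severity statuses come from context rules, most severe winning", {
  defs <- test_defs()
  run <- function(text) {
    note <- one_note(text)
    ms <- assign_status(extract_mentions(note, defs), note, defs)
    ms
  }
  ms <- run("diabete complique de retinopathie")
  expect_equal(ms$status[ms$condition_id == "diabetes"], "with_end_organ_damage")

  ms <- run("cancer du poumon avec metastases hepatiques")
  expect_equal(ms$status[ms$condition_id == "solid_tumor"], "metastatic")

  # both a stopped cue and an active cue in window: most severe wins
  ms <- run("tabagisme sevre puis repris actif")
  expect_equal(ms$status[ms$condition_id == "tobacco_consumption"], "present")

  # no severity cue: least severe (present-unspecified) status
  ms <- run("cirrhose connue")
  expect_equal(ms$status[ms$condition_id == "liver_disease"], "mild")

  # severity cues do not leak across sentence terminators
  ms <- run("cirrhose connue. par ailleurs ascite ancienne d'autre cause")
  expect_equal(ms$status[ms$condition_id == "liver_disease"], "mild")

  # binary conditions keep an unset status
  ms <- run("bpco severe")
  expect_true(is.na(ms$status[ms$condition_id == "chronic_pulmonary_disease"]))
})

test_that("matching is deterministic and monotone in the dictionaries", {
  defs <- test_defs()
  corpus <- generate_corpus(generator_config(n_stays = 6, seed = 31))
  a <- extract_mentions(corpus$notes, defs)
  b <- extract_mentions(corpus$notes, defs)
  expect_identical(a, b)

  # adding an inclusion pattern never removes coverage
  defs2 <- test_defs()
  defs2$diabetes$patterns <- dplyr::bind_rows(
    defs2$diabetes$patterns,
    tibble::tibble(regex = "glycemie elevee", status_hint = NA_character_)
  )
  a2 <- extract_mentions(corpus$notes, defs2)
  for (i in seq_len(nrow(a))) {
    same <- a2[a2$note_id == a$note_id[i] &
                 a2$condition_id == a$condition_id[i], ]
    expect_true(any(same$start < a$end[i] & same$end > a$start[i]))
  }

  # adding an exclusion pattern never adds a kept mention
  note <- one_note("suivi pour asthme et diabete")
  kept_before <- apply_exclusions(extract_mentions(note, defs), note, defs)
  defs3 <- test_defs()
  defs3$diabetes$exclusion_patterns <- c(
    defs3$diabetes$exclusion_patterns, "diabete"
  )
  kept_after <- apply_exclusions(extract_mentions(note, defs3), note, defs3)
  expect_true(all(
    kept_after$mention_id[!kept_after$discarded] %in%
      kept_before$mention_id[!kept_before$discarded]
  ))
})
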