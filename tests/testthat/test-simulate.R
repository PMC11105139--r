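test_that("degenerate configurations produce the expected corpora", {
  defs <- test_defs()

  cfg <- generator_config(
    n_stays = 10, seed = 1, prevalence = list(diabetes = 1),
    negation_rate = 0, hypothesis_rate = 0, family_rate = 0,
    generic_fp_rate = 0, oov_cue_rate = 0, claim_undercoding_rate = 0
  )
  corpus <- generate_corpus(cfg, defs)
  expect_equal(nrow(corpus$notes), 10)
  kept_dia <- corpus$gold_mentions[
    !corpus$gold_mentions$discarded &
      corpus$gold_mentions$condition_id == "diabetes",
  ]
  expect_true(all(corpus$notes$note_id %in% kept_dia$note_id))
  lab <- corpus$stay_labels
  expect_true(all(lab$status[lab$condition_id == "diabetes"] != "absent"))
  # every inpatient stay carries a diabetes claim code
  inpat <- corpus$notes$stay_id[corpus$notes$stay_type == "inpatient"]
  dia_prefixes <- unlist(defs$diabetes$icd10)
  for (sid in inpat) {
    codes <- corpus$claims$code[corpus$claims$stay_id == sid]
    expect_true(any(vapply(dia_prefixes,
                           function(p) any(startsWith(codes, p)),
                           logical(1))))
  }

  # n_stays = 0 -> empty corpus
  empty <- generate_corpus(generator_config(n_stays = 0, seed = 1), defs)
  expect_equal(nrow(empty$notes), 0)
  expect_equal(nrow(empty$gold_mentions), 0)

  # negation_rate = 1 -> every mention negated/discarded, all labels absent
  neg <- generate_corpus(generator_config(
    n_stays = 15, seed = 2, negation_rate = 1, hypothesis_rate = 0,
    family_rate = 0, generic_fp_rate = 0
  ), defs)
  expect_true(all(neg$gold_mentions$negated))
  expect_true(all(neg$gold_mentions$discarded))
  expect_true(all(neg$stay_labels$status == "absent"))

  # unknown condition in the prevalence map is rejected
  expect_error(generator_config(prevalence = list(gout = 0.5)), "unknown")
})

test_that("identical configurations give byte-identical corpora", {
  cfg <- generator_config(n_stays = 15, seed = 33)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$notes, b$notes)
  expect_identical(a$gold_mentions, b$gold_mentions)
  expect_identical(a$stay_labels, b$stay_labels)
  expect_identical(a$claims, b$claims)
})

test_that("gold spans slice to surfaces consistent with the dictionaries", {
  defs <- test_defs()
  corpus <- generate_corpus(generator_config(n_stays = 25, seed = 44))
  g <- corpus$gold_mentions
  for (i in seq_len(nrow(g))) {
    text <- corpus$notes$text[corpus$notes$note_id == g$note_id[i]]
    slice <- substr(text, g$start[i] + 1, g$end[i])
    expect_gt(nchar(slice), 0)
    norm_slice <- normalize_text(slice)$norm
    patterns <- defs[[g$condition_id[i]]]$patterns$regex
    hit <- any(vapply(patterns, function(rx) grepl(rx, norm_slice, perl = TRUE),
                      logical(1)))
    expect_equal(hit, g$in_vocab[i],
                 label = paste("dictionary hit for", g$mention_id[i]))
  }
})

test_that("empirical discard rates converge to the configured rates", {
  cfg <- generator_config(
    n_stays = 2000, seed = 55, prevalence = list(diabetes = 1),
    mention_mean = 1, negation_rate = 0.2, hypothesis_rate = 0.1,
    family_rate = 0.05, generic_fp_rate = 0.05
  )
  corpus <- generate_corpus(cfg)
  g <- corpus$gold_mentions
  expect_gt(nrow(g), 1500)
  expect_lt(abs(mean(g$negated) - 0.2), 0.03)
  expect_lt(abs(mean(g$hypothetical) - 0.1), 0.03)
  expect_lt(abs(mean(g$family) - 0.05), 0.03)
})

test_that("labeled snippets align with the note tokens", {
  corpus <- generate_corpus(generator_config(n_stays = 15, seed = 66))
  snips <- make_labeled_snippets(corpus, window = 8)
  expect_equal(nrow(snips), nrow(corpus$gold_mentions))
  expect_identical(
    snips$label == "discard",
    corpus$gold_mentions$discarded
  )
  # snippet token sequence equals the window slice of the note's tokens
  for (i in sample(nrow(snips), 10)) {
    mid <- snips$mention_id[i]
    m <- corpus$gold_mentions[corpus$gold_mentions$mention_id == mid, ]
    text <- corpus$notes$text[corpus$notes$note_id == m$note_id]
    toks <- tokenize(normalize_text(text))
    ent_surface <- snips$tokens[[i]][snips$entity_start[i]:snips$entity_end[i]]
    expect_true(all(ent_surface %in% toks$surface))
    # entity surfaces re-normalize from the gold span
    slice <- substr(text, m$start + 1, m$end)
    expect_equal(
      gsub("[[:space:]]", "", paste(ent_surface, collapse = "")),
      gsub("[[:space:]]", "", normalize_text(slice)$norm)
    )
  }
})

test_that("upsampling favors rare conditions with a documented score", {
  notes <- tibble::tibble(
    note_id = c("n1", "n2", "n3"), stay_id = c("s1", "s2", "s3"),
    note_class = "discharge_summary", stay_type = "inpatient", text = ""
  )
  counts <- tibble::tibble(
    note_id = c("n1", "n1", "n2", "n3"),
    condition_id = c("diabetes", "aids", "diabetes", "diabetes"),
    n = c(1L, 1L, 3L, 1L)
  )

  # k = corpus size -> all notes
  expect_equal(nrow(upsample_selection(notes, counts, 3)), 3)

  # the only note carrying the rarest condition ranks first
  top <- upsample_selection(notes, counts, 1)
  expect_equal(top$note_id, "n1")

  # random corpora match the brute-force argmax of the documented score
  withr::with_seed(10, {
    for (i in 1:10) {
      nn <- 6
      notes_r <- tibble::tibble(
        note_id = sprintf("n%d", 1:nn), stay_id = sprintf("s%d", 1:nn),
        note_class = "discharge_summary", stay_type = "inpatient", text = ""
      )
      counts_r <- tidyr::expand_grid(
        note_id = notes_r$note_id,
        condition_id = c("diabetes", "aids", "dementia")
      )
      counts_r$n <- sample(0:3, nrow(counts_r), replace = TRUE)
      freq <- tapply(counts_r$n, counts_r$condition_id, sum)
      score <- vapply(notes_r$note_id, function(nid) {
        sub <- counts_r[counts_r$note_id == nid, ]
        sum(ifelse(freq[sub$condition_id] > 0,
                   sub$n / freq[sub$condition_id], 0))
      }, numeric(1))
      top_r <- upsample_selection(notes_r, counts_r, 1, seed = i)
      expect_equal(
        unname(score[top_r$note_id]), max(score),
        label = paste("case", i)
      )
    }
  })
})
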