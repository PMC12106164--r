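test_that("generation is deterministic: same spec, identical bytes", {
  spec <- synthetic_page_spec(seed = 1, n_plant_entries = 4,
                              n_margin_annotations = 3,
                              handwritten_interruption_rate = 0.5,
                              char_noise_rate = 0.05, bleed_word_count = 2)
  j1 <- write_blocks(generate_page(spec)$page)
  j2 <- write_blocks(generate_page(spec)$page)
  expect_identical(as.character(j1), as.character(j2))
  # and a different seed genuinely differs
  spec2 <- synthetic_page_spec(seed = 2, n_plant_entries = 4,
                               n_margin_annotations = 3,
                               handwritten_interruption_rate = 0.5,
                               char_noise_rate = 0.05, bleed_word_count = 2)
  expect_false(identical(as.character(j1),
                         as.character(write_blocks(generate_page(spec2)$page))))
})

test_that("generated pages satisfy the block invariants and round-trip", {
  for (seed in c(4, 5)) {
    g <- generate_page(synthetic_page_spec(seed = seed, parity = "ODD",
                                           skew_inflation = 0.01,
                                           bleed_word_count = 2))
    pg <- g$page
    expect_false(anyDuplicated(pg$words$id) > 0)
    expect_true(all(pg$words$line_id %in% pg$lines$id))
    expect_true(all(pg$words$left >= 0 & pg$words$left + pg$words$width <= 1))
    expect_true(all(pg$words$top >= 0 & pg$words$top + pg$words$height <= 1))
    back <- parse_textract_json(write_blocks(pg))[[1]]
    expect_equal(page_signature(back), page_signature(pg))
  }
})

test_that("ground truth counts equal the spec parameters", {
  spec <- synthetic_page_spec(seed = 8, n_plant_entries = 5,
                              n_margin_annotations = 4,
                              n_header_annotations = 2,
                              n_footer_annotations = 1)
  tr <- generate_page(spec)$truth
  kinds <- vapply(tr$segments, function(s) s$kind, "")
  expect_equal(sum(kinds == "PLANT_NAME"), 5)
  expect_equal(sum(kinds == "PARAGRAPH"), 5)
  expect_equal(sum(kinds == "MARGIN"), 4)
  expect_equal(sum(kinds == "HEADER"), 2)
  expect_equal(sum(kinds == "FOOTER"), 1)
  expect_equal(nrow(tr$pairs), 4)
  # every ground-truth word exists on the page
  pg <- generate_page(spec)$page
  for (s in tr$segments) expect_true(all(s$word_ids %in% pg$words$id))
})

test_that("margin jitter never breaks the intended nearest-top pairing", {
  for (seed in 101:110) {
    g <- generate_page(synthetic_page_spec(seed = seed, n_plant_entries = 6,
                                           n_margin_annotations = 6))
    tr <- g$truth
    plants <- Filter(function(s) s$kind == "PLANT_NAME", tr$segments)
    tops <- vapply(plants, function(s) s$bbox[["top"]], numeric(1))
    ids <- vapply(plants, `[[`, "", "id")
    for (i in seq_len(nrow(tr$pairs))) {
      m <- tr$segments[[match(tr$pairs$margin_id[i],
                              vapply(tr$segments, `[[`, "", "id"))]]
      expect_equal(ids[brute_force_nearest(m$bbox[["top"]], tops)],
                   tr$pairs$plant_id[i])
    }
  }
})

test_that("character noise produces the nominal CER on average", {
  specs <- lapply(1:8, function(i) synthetic_page_spec(seed = 300 + i,
                                                       char_noise_rate = 0.1))
  vals <- unlist(lapply(specs, function(sp) {
    g <- generate_page(sp)
    ids <- vapply(g$truth$segments, `[[`, "", "id")
    noisy <- vapply(g$truth$segments, `[[`, "", "text")
    cer(g$truth$clean_texts[ids], noisy)
  }))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 10), 4 * se)
  # noise-free pages transcribe cleanly
  g0 <- generate_page(synthetic_page_spec(seed = 301))
  ids <- vapply(g0$truth$segments, `[[`, "", "id")
  expect_true(all(cer(g0$truth$clean_texts[ids],
                      vapply(g0$truth$segments, `[[`, "", "text")) == 0))
})

test_that("infeasible layouts fail with a generation error", {
  expect_error(generate_page(synthetic_page_spec(seed = 1, n_plant_entries = 40,
                                                 paragraph_length_range = c(6, 6))),
               "do not fit")
  expect_error(synthetic_page_spec(seed = 1, char_noise_rate = 1.5))
  expect_error(synthetic_page_spec(seed = 1, n_plant_entries = 0))
})

test_that("corpus generation writes pages, ground truth and manifest", {
  dir <- withr::local_tempdir()
  specs <- lapply(1:10, function(i) synthetic_page_spec(seed = 400 + i,
                                                        parity = if (i %% 2) "ODD" else "EVEN"))
  gc1 <- generate_corpus(specs, dir)
  expect_length(list.files(dir, pattern = "^syn-.*\\.json$"), 10)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # regenerating from the same specs is byte-identical
  dir2 <- withr::local_tempdir()
  generate_corpus(specs, dir2)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)),
                     label = f)
  }
  # per-kind ground-truth counts sum over specs
  gt <- read_records(file.path(dir, "ground_truth.json"))
  expect_equal(sum(vapply(gt, function(r) length(r$plants), numeric(1))),
               sum(vapply(specs, function(s) s$n_plant_entries, numeric(1))))
  expect_equal(sum(vapply(gt, function(r) length(r$margins), numeric(1))),
               sum(vapply(specs, function(s) s$n_margin_annotations, numeric(1))))
  # duplicate page ids are refused
  expect_error(generate_corpus(list(specs[[1]], specs[[1]])), "duplicate")
})
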