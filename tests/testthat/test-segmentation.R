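body_fixture <- function(tops_by_para, left = 0.1, text = "verba plura hic") {
  rows <- list(); ln <- 0
  for (tops in tops_by_para) {
    for (t in tops) {
      ln <- ln + 1
      rows[[ln]] <- text_line(text, left, t, ln)
    }
  }
  make_page(do.call(rbind, rows))
}

test_that("paragraphs split on gaps larger than the pitch multiple", {
  # three paragraphs of three lines at pitch 0.015, separated by 2x gaps
  paras <- list(c(0.10, 0.115, 0.13), c(0.16, 0.175, 0.19), c(0.22, 0.235, 0.25))
  pg <- body_fixture(paras)
  segs <- segment_paragraphs(pg, pg$lines$id)
  expect_length(segs, 3)
  for (i in 1:3) {
    expect_setequal(segs[[i]]$word_ids,
                    pg$words$id[pg$words$top %in% paras[[i]]])
  }
  # single line body: one single-line paragraph
  single <- make_page(text_line("unica linea", 0.1, 0.4, 1))
  segs1 <- segment_paragraphs(single, single$lines$id)
  expect_length(segs1, 1)
  expect_equal(segs1[[1]]$text, "unica linea")
  expect_length(segment_paragraphs(pg, character()), 0)
})

test_that("a handwritten interruption neither splits nor glues paragraphs", {
  rows <- rbind(
    text_line("prima linea paragraphi", 0.1, 0.100, 1),
    text_line("vide H.S. 12. 34.", 0.12, 0.1075, 2, "HANDWRITING"),
    text_line("secunda linea paragraphi", 0.1, 0.115, 3),
    text_line("altera paragraphus incipit", 0.1, 0.145, 4),
    text_line("et pergit adhuc", 0.1, 0.160, 5)
  )
  pg <- make_page(rows)
  segs <- segment_paragraphs(pg, pg$lines$id)
  expect_length(segs, 2)  # interruption stays inside paragraph one
  expect_true(all(pg$words$id[pg$words$text_type == "HANDWRITING"] %in%
                    segs[[1]]$word_ids))
  expect_setequal(segs[[1]]$handwritten_word_ids,
                  pg$words$id[pg$words$text_type == "HANDWRITING"])
})

test_that("paragraph count is non-increasing in the gap multiplier", {
  g <- generate_page(synthetic_page_spec(seed = 21, n_plant_entries = 5))
  lay <- detect_layout(g$page, classify_page_group(g$page))
  counts <- vapply(c(0.8, 1.2, 1.6, 2.4, 5), function(mult) {
    length(segment_paragraphs(g$page, lay,
                              mobilise_config(para_gap_mult = mult)))
  }, numeric(1))
  expect_false(is.unsorted(rev(counts)))
})

test_that("plant names are recognised by indent and by fallback features", {
  cfg <- mobilise_config()
  # 1-line indented capitalised entry
  pg <- make_page(rbind(
    text_line("Salvia latifolia serrata", 0.13, 0.10, 1),
    text_line("planta vulgaris foliis", 0.10, 0.13, 2),
    text_line("caule glabro minore", 0.10, 0.145, 3),
    text_line("flore albo odore gravi", 0.10, 0.16, 4)
  ))
  segs <- segment_paragraphs(pg, pg$lines$id)
  expect_length(segs, 2)
  expect_true(classify_plant_name(segs[[1]], 0.10, pg, cfg))
  expect_false(classify_plant_name(segs[[2]], 0.10, pg, cfg))
  # all-uppercase, non-indented
  up <- make_page(text_line("GRAMEN PANICULATUM", 0.10, 0.2, 1))
  seg_up <- segment_paragraphs(up, up$lines$id)[[1]]
  expect_true(classify_plant_name(seg_up, 0.10, up, cfg))
  # author-abbreviation opener, non-indented
  ab <- make_page(text_line("J.B. absinthium vulgare tertium", 0.10, 0.2, 1))
  seg_ab <- segment_paragraphs(ab, ab$lines$id)[[1]]
  expect_true(classify_plant_name(seg_ab, 0.10, ab, cfg))
  # 6-line, non-indented, lowercase paragraph is prose
  prose <- body_fixture(list(seq(0.1, by = 0.015, length.out = 6)))
  seg_pr <- segment_paragraphs(prose, prose$lines$id)[[1]]
  expect_false(classify_plant_name(seg_pr, 0.1, prose, cfg))
})

margin_page <- function(texts, tops, left = 0.85) {
  rows <- do.call(rbind, lapply(seq_along(texts), function(i) {
    text_line(texts[i], left, tops[i], i, "HANDWRITING", char_w = 0.003,
              space_w = 0.003)
  }))
  make_page(rows)
}

test_that("margin segments open on the H.S. initials or a wide gap", {
  pg <- margin_page(c("H.S. 114. p.29.1.", "229.5. 205.229", "H.S. 150.26."),
                    c(0.30, 0.315, 0.33))
  segs <- segment_margins(pg, pg$lines$id)
  expect_length(segs, 2)
  expect_equal(segs[[1]]$text, "H.S. 114. p.29.1. 229.5. 205.229")
  expect_equal(segs[[2]]$text, "H.S. 150.26.")

  expect_length(segment_margins(pg, character()), 0)
  one <- margin_page("H.S. 3 101", 0.4)
  segs1 <- segment_margins(one, one$lines$id)
  expect_length(segs1, 1)
  expect_length(segs1[[1]]$line_ids, 1)

  # no initials, but a wide gap still separates annotations: pitch from the
  # given lines is 0.015, the 0.075 gap exceeds 2 x pitch
  gap <- margin_page(c("150.26. 105.37", "229.5.", "12.7.", "105.37."),
                     c(0.30, 0.315, 0.33, 0.405))
  segs2 <- segment_margins(gap, gap$lines$id)
  expect_length(segs2, 2)
  expect_length(segs2[[1]]$line_ids, 3)
})

test_that("header/footer annotations group into per-band segments", {
  g <- generate_page(synthetic_page_spec(seed = 31, n_header_annotations = 2,
                                         n_footer_annotations = 1))
  lay <- detect_layout(g$page, classify_page_group(g$page))
  segs <- segment_headers_footers(g$page, lay)
  kinds <- vapply(segs, function(s) s$kind, "")
  expect_equal(sum(kinds == "HEADER"), 2)  # 3x-pitch gap separates the two
  expect_equal(sum(kinds == "FOOTER"), 1)

  # a band holding only the printed running title yields no segments
  g0 <- generate_page(synthetic_page_spec(seed = 32, n_header_annotations = 0,
                                          n_footer_annotations = 0))
  lay0 <- detect_layout(g0$page, classify_page_group(g0$page))
  expect_length(segment_headers_footers(g0$page, lay0), 0)
})

test_that("specimen references parse with volume, folio, optional specimen", {
  r <- parse_specimen_reference("H.S. 3 101")
  expect_equal(r$references$volume, 3L)
  expect_equal(r$references$folio, 101L)
  expect_true(is.na(r$references$specimen))
  expect_length(r$residue, 0)

  r2 <- parse_specimen_reference("H.S. 114. p.29. 1.")
  expect_equal(unlist(r2$references[1, ]), c(volume = 114L, folio = 29L,
                                             specimen = 1L))
  r3 <- parse_specimen_reference("")
  expect_equal(nrow(r3$references), 0)

  # multiple references in one transcription, plus residue
  r4 <- parse_specimen_reference("H.S. 150. 26. et H. S. 12 7 nota bene")
  expect_equal(r4$references$volume, c(150L, 12L))
  expect_equal(r4$references$folio, c(26L, 7L))
  expect_true("et" %in% r4$residue || any(grepl("et", r4$residue)))
  # unparseable spans never throw
  r5 <- parse_specimen_reference("229.5. 205.229")
  expect_equal(nrow(r5$references), 0)
  expect_true(length(r5$residue) > 0)
})

test_that("segmentation conserves words within each region", {
  for (seed in c(5, 6)) {
    g <- generate_page(synthetic_page_spec(seed = seed, parity = "EVEN",
                                           handwritten_interruption_rate = 0.5,
                                           n_header_annotations = 2))
    lay <- detect_layout(g$page, classify_page_group(g$page))
    for (cls in list(c("body", "PARAGRAPH"), c("margin", "MARGIN"))) {
      ids <- lay$assignment$line_id[lay$assignment$class == cls[1]]
      segs <- if (cls[1] == "body") segment_paragraphs(g$page, lay)
              else segment_margins(g$page, lay)
      seg_words <- unlist(lapply(segs, `[[`, "word_ids"))
      expect_false(anyDuplicated(seg_words) > 0)
      expect_setequal(seg_words, g$page$words$id[g$page$words$line_id %in% ids])
    }
    # segments are vertically ordered within a region
    segs <- segment_paragraphs(g$page, lay)
    tops <- vapply(segs, function(s) s$bbox[["top"]], numeric(1))
    expect_false(is.unsorted(tops))
  }
})
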