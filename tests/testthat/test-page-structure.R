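title_page <- function(text, text_type = "PRINTED", top = 0.03) {
  body <- rbind(text_line("planta foliis latis", 0.1, 0.2, 2),
                text_line("caule hirsuto minore", 0.1, 0.215, 3))
  make_page(rbind(text_line(text, 0.35, top, 1, text_type), body))
}

test_that("running titles decide page parity, tolerating OCR confusions", {
  cases <- list(
    list(text = "HISTORIA PLANTARUM", parity = "EVEN"),
    list(text = "H1STORIA PLANTARUM", parity = "EVEN"),
    list(text = "H IST OR1A", parity = "EVEN"),
    list(text = "H I S T O R I A", parity = "EVEN"),
    list(text = "Lib IV. De Herbis.", parity = "ODD"),
    list(text = "De Herbis", parity = "ODD")
  )
  for (cs in cases) {
    g <- classify_page_group(title_page(cs$text))
    expect_equal(g$value, cs$parity, label = cs$text)
    expect_true(length(g$evidence) > 0)
  }
})

test_that("pages without title evidence are UNKNOWN, not an error", {
  no_title <- make_page(text_line("planta foliis latis", 0.1, 0.5, 1))
  expect_equal(classify_page_group(no_title)$value, "UNKNOWN")
  # a title-like line in the page body (below the band) must not count
  low <- title_page("HISTORIA PLANTARUM", top = 0.5)
  expect_equal(classify_page_group(low)$value, "UNKNOWN")
  # handwritten look-alikes are not running titles
  hand <- title_page("HISTORIA PLANTARUM", text_type = "HANDWRITING")
  expect_equal(classify_page_group(hand)$value, "UNKNOWN")
})

margin_fixture <- function(margin_lefts = c(0.80, 0.85, 0.95), seed = 1) {
  set.seed(seed)
  body <- do.call(rbind, lapply(1:8, function(i) {
    text_line("verba corporis plura hic", runif(1, 0.10, 0.55), 0.1 + i * 0.02, i)
  }))
  marg <- do.call(rbind, lapply(seq_along(margin_lefts), function(j) {
    text_line("HS nota", margin_lefts[j], 0.12 + j * 0.05, 100 + j, "HANDWRITING")
  }))
  make_page(rbind(body, marg))
}

test_that("the margin boundary splits body and margin word clusters", {
  pg <- margin_fixture()
  mb <- detect_margin_boundary(pg, "ODD")
  expect_equal(mb$margin_side, "RIGHT")
  expect_true(mb$has_margin)
  # oracle: boundary must fall inside the largest gap between word intervals
  w <- pg$words
  gap <- brute_force_largest_gap(w$left, w$left + w$width)
  expect_gt(mb$margin_boundary_x, gap[["lo"]])
  expect_lt(mb$margin_boundary_x, gap[["hi"]])
  # body words reach ~0.66, margin starts at 0.80
  expect_gt(mb$margin_boundary_x, 0.66)
  expect_lt(mb$margin_boundary_x, 0.80)
})

test_that("a page without margin words collapses the boundary onto the body", {
  body <- do.call(rbind, lapply(1:6, function(i) {
    text_line("verba corporis plura", 0.10, 0.1 + i * 0.02, i)
  }))
  pg <- make_page(body)
  mb <- detect_margin_boundary(pg, "ODD")
  expect_false(mb$has_margin)
  expect_equal(mb$margin_boundary_x, mb$body_envelope[["right"]])
  lay <- detect_layout(pg, "ODD")
  expect_equal(sum(lay$assignment$class == "margin"), 0)
})

test_that("the boundary is invariant under permuting line order", {
  pg <- margin_fixture()
  ref <- detect_margin_boundary(pg, "ODD")$margin_boundary_x
  for (s in 1:5) {
    set.seed(s)
    perm <- pg
    ord <- sample(nrow(perm$lines))
    shuffled <- page_blocks(perm$page_id, perm$lines[ord, ], perm$words,
                            perm$width_px, perm$height_px)
    expect_equal(detect_margin_boundary(shuffled, "ODD")$margin_boundary_x, ref)
  }
})

test_that("every line lands in exactly one layout class", {
  for (seed in 1:6) {
    spec <- synthetic_page_spec(seed = seed,
                                parity = if (seed %% 2) "ODD" else "EVEN",
                                bleed_word_count = seed %% 3,
                                handwritten_interruption_rate = 0.4)
    g <- generate_page(spec)
    lay <- detect_layout(g$page, classify_page_group(g$page))
    expect_setequal(lay$assignment$line_id, g$page$lines$id)
    expect_false(anyDuplicated(lay$assignment$line_id) > 0)
    expect_true(all(lay$assignment$class %in%
                      c("header", "footer", "margin", "body", "discarded")))
  }
})

test_that("layout recovery on clean synthetic pages is exact", {
  for (seed in c(2, 9)) {
    g <- generate_page(synthetic_page_spec(seed = seed, parity = "EVEN",
                                           bleed_word_count = 3))
    lay <- detect_layout(g$page, classify_page_group(g$page))
    got <- setNames(lay$assignment$class, lay$assignment$line_id)
    want <- setNames(g$truth$layout$class, g$truth$layout$line_id)
    expect_equal(got[names(want)], want)
    # the three bleed lines are discarded, none lost
    expect_setequal(lay$discarded_line_ids,
                    g$truth$layout$line_id[g$truth$layout$class == "discarded"])
  }
})

test_that("a body-only page has empty bands and no discards", {
  body <- do.call(rbind, lapply(1:5, function(i) {
    text_line("verba corporis plura hic", 0.10, 0.3 + i * 0.015, i)
  }))
  pg <- make_page(body)
  lay <- detect_layout(pg, "UNKNOWN")
  expect_true(all(lay$assignment$class == "body"))
  expect_length(lay$discarded_line_ids, 0)
})

test_that("mirroring a page and flipping parity mirrors the layout", {
  g <- generate_page(synthetic_page_spec(seed = 11, parity = "EVEN",
                                         bleed_word_count = 2))
  pg <- g$page
  mirror <- pg
  mirror$words$left <- 1 - pg$words$left - pg$words$width
  mirror$lines$left <- 1 - pg$lines$left - pg$lines$width
  mirror <- page_blocks(pg$page_id, mirror$lines, mirror$words,
                        pg$width_px, pg$height_px)
  lay <- detect_layout(pg, "EVEN")
  lay_m <- detect_layout(mirror, "ODD")
  expect_equal(lay_m$margin_side, "RIGHT")
  expect_equal(lay$margin_side, "LEFT")
  a <- setNames(lay$assignment$class, lay$assignment$line_id)
  b <- setNames(lay_m$assignment$class, lay_m$assignment$line_id)
  expect_equal(b[names(a)], a)
  expect_equal(lay_m$margin_boundary_x, 1 - lay$margin_boundary_x,
               tolerance = 1e-9)
})
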