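## Seeded generator of Textract-dialect pages with exact ground truth.
## Emulates the structure of a two-page-parity herbal layout: running titles,
## body paragraphs, indented plant-name entries, side-margin "H.S." specimen
## references jittered around their entry, header/footer annotations, skewed
## line boxes, handwritten interruptions, adjacent-page bleed and
## per-character transcription noise.

## small bundled lexicons: content is irrelevant to the geometry-driven
## stages; only casing and indentation matter
.PLANT_PHRASES <- c(
  "Absinthium vulgare majus", "Corymbiferis flore albo",
  "Gramen paniculatum minus", "Salvia latifolia serrata",
  "Mentha aquatica rotundifolia", "Ranunculus pratensis repens",
  "Tithymalus characias amygdaloides", "Carduus stellatus luteus",
  "Eryngium maritimum caeruleum", "Polygonatum latifolium vulgare",
  "Anagallis flore phoeniceo", "Filix mas non ramosa",
  "Lychnis sylvestris alba", "Veronica mas supina",
  "Hieracium murorum laciniatum", "Scorzonera humilis angustifolia"
)
.BODY_WORDS <- c(
  "foliis", "caule", "radice", "flore", "semine", "ad", "in", "ex",
  "planta", "ramis", "minor", "major", "vulgaris", "sylvestris", "albo",
  "luteo", "purpureo", "angustis", "latioribus", "serratis", "hirsutis",
  "glabris", "odore", "sapore", "locis", "humidis", "siccis", "crescit",
  "floret", "junio", "julio", "passim", "copiose", "circa", "segetes"
)
.NOISE_POOL <- c(letters, LETTERS, as.character(0:9))

#' Specification of one synthetic page
#'
#' Captures the layout conditions a generated page emulates.  Defaults
#' describe a clean, well-separated page: four plant entries, three margin
#' annotations, a line pitch of 0.015 page heights and no noise; noise
#' features (skew-inflated line boxes, handwritten interruptions, bleed
#' words, character substitutions) are switched on per study.
#'
#' @param seed Integer seed; regenerating with the same spec is
#'   byte-identical.
#' @param parity `"ODD"` or `"EVEN"` — decides running title and margin side.
#' @param n_plant_entries Number of plant-name entries (each followed by a
#'   descriptive paragraph).
#' @param n_margin_annotations Number of `H.S.` margin annotations; at most
#'   one per entry when they fit, cycling otherwise.
#' @param n_header_annotations,n_footer_annotations Handwritten annotations
#'   in the top and bottom bands (0–2 each).
#' @param paragraph_length_range Inclusive range of printed lines per
#'   paragraph.
#' @param line_pitch Vertical distance between consecutive line tops, as a
#'   fraction of page height.
#' @param skew_inflation Extra height added to (a random half of) the
#'   provider *line* boxes, shifting their tops upward while word boxes stay
#'   tight — the skewed-scan failure mode the word-level segmenter defeats.
#' @param handwritten_interruption_rate Per-paragraph probability of a
#'   handwritten line interleaved between two of its printed lines.
#' @param bleed_word_count Words from the adjacent page placed beyond the
#'   non-margin edge.
#' @param char_noise_rate Per-character substitution probability applied to
#'   every transcription (ground truth keeps the clean text).
#' @param page_id Page identifier; defaults to `"syn-<seed>"`.
#' @return A `synthetic_page_spec` object.
#' @export
synthetic_page_spec <- function(seed = 1L, parity = c("EVEN", "ODD"),
                                n_plant_entries = 4L,
                                n_margin_annotations = 3L,
                                n_header_annotations = 1L,
                                n_footer_annotations = 1L,
                                paragraph_length_range = c(3L, 6L),
                                line_pitch = 0.015,
                                skew_inflation = 0,
                                handwritten_interruption_rate = 0,
                                bleed_word_count = 0L,
                                char_noise_rate = 0,
                                page_id = NULL) {
  parity <- match.arg(parity)
  spec <- list(seed = as.integer(seed), parity = parity,
               n_plant_entries = as.integer(n_plant_entries),
               n_margin_annotations = as.integer(n_margin_annotations),
               n_header_annotations = as.integer(n_header_annotations),
               n_footer_annotations = as.integer(n_footer_annotations),
               paragraph_length_range = as.integer(paragraph_length_range),
               line_pitch = line_pitch,
               skew_inflation = skew_inflation,
               handwritten_interruption_rate = handwritten_interruption_rate,
               bleed_word_count = as.integer(bleed_word_count),
               char_noise_rate = char_noise_rate,
               page_id = page_id %||% paste0("syn-", as.integer(seed)))
  stopifnot(spec$n_plant_entries >= 1,
            spec$n_margin_annotations >= 0,
            spec$n_header_annotations %in% 0:2,
            spec$n_footer_annotations %in% 0:2,
            length(spec$paragraph_length_range) == 2,
            spec$paragraph_length_range[1] >= 1,
            diff(spec$paragraph_length_range) >= 0,
            spec$line_pitch > 0,
            spec$skew_inflation >= 0, spec$skew_inflation <= 1,
            spec$handwritten_interruption_rate >= 0,
            spec$handwritten_interruption_rate <= 1,
            spec$bleed_word_count >= 0,
            spec$char_noise_rate >= 0, spec$char_noise_rate <= 1)
  structure(spec, class = "synthetic_page_spec")
}

.corrupt_text <- function(text, rate) {
  if (rate <= 0) return(text)
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  hit <- runif(length(ch)) < rate
  for (i in which(hit)) {
    ch[i] <- sample(setdiff(.NOISE_POOL, ch[i]), 1)
  }
  paste(ch, collapse = "")
}

#' Generate one synthetic page with exact ground truth
#'
#' Lays out a page according to its [synthetic_page_spec()]: a parity-
#' appropriate running title and page number, `n_plant_entries` blocks of an
#' indented printed plant-name line followed by a flush-left paragraph
#' (consecutive lines one pitch apart, paragraph boundaries two pitches
#' apart), handwritten `H.S. [volume]. [folio].` margin annotations whose
#' tops are jittered around their entry by at most 40% of the inter-entry
#' spacing (so nearest-top linking provably recovers the intended pairing),
#' and optional header/footer annotations, skew, interruptions, bleed and
#' character noise.  Everything is drawn from the seeded RNG, so identical
#' specs give byte-identical JSON.
#'
#' @param spec A [synthetic_page_spec()].
#' @return A list: `page` (a [page_blocks]), `truth` (a `ground_truth`:
#'   `segments` with true kinds and member lines, `pairs`, `layout`
#'   assignment, `clean_texts`, and a `record` projection in the pipeline's
#'   output schema).
#' @export
generate_page <- function(spec) {
  stopifnot(inherits(spec, "synthetic_page_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  pitch <- spec$line_pitch
  word_h <- 0.011
  char_w <- 0.0045
  space_w <- 0.0055
  pid <- spec$page_id
  even <- spec$parity == "EVEN"
  body_x <- if (even) c(0.22, 0.88) else c(0.10, 0.76)
  margin_x <- if (even) c(0.04, 0.16) else c(0.82, 0.94)
  bleed_x <- if (even) c(0.945, 0.985) else c(0.005, 0.055)
  indent <- 0.03
  body_top <- 0.085
  body_bottom <- 0.915

  words <- list(); lines <- list()
  n_line <- 0L; n_word <- 0L
  ## each entry: line ids + class + clean text, accumulated as we lay out
  line_meta <- list()

  add_line <- function(text, left, top, text_type, class, max_right = 1) {
    toks <- strsplit(text, " ", fixed = TRUE)[[1]]
    x <- left
    wrow <- list()
    for (tk in toks) {
      w <- nchar(tk) * char_w
      if (x + w > max_right) break
      n_word <<- n_word + 1L
      wrow[[length(wrow) + 1L]] <- data.frame(
        id = sprintf("%s-w%04d", pid, n_word), text = tk,
        text_type = text_type,
        left = round(x, 6), top = round(top, 6),
        width = round(w, 6), height = word_h,
        confidence = round(90 + runif(1) * 9.9, 2),
        line_id = NA_character_, stringsAsFactors = FALSE)
      x <- x + w + space_w
    }
    if (length(wrow) == 0) stop("generation error: line does not fit page",
                                call. = FALSE)
    wdf <- do.call(rbind, wrow)
    n_line <<- n_line + 1L
    lid <- sprintf("%s-l%03d", pid, n_line)
    wdf$line_id <- lid
    skew <- if (spec$skew_inflation > 0 && runif(1) < 0.5) spec$skew_inflation else 0
    lines[[length(lines) + 1L]] <<- data.frame(
      id = lid, text = paste(wdf$text, collapse = " "),
      left = min(wdf$left), top = round(max(top - skew, 0), 6),
      width = round(max(wdf$left + wdf$width) - min(wdf$left), 6),
      height = round(word_h + 0.001 + skew, 6), stringsAsFactors = FALSE)
    words[[length(words) + 1L]] <<- wdf
    line_meta[[lid]] <<- list(class = class, clean = paste(wdf$text, collapse = " "))
    lid
  }

  ## --- header furniture -------------------------------------------------
  title <- if (even) "HISTORIA PLANTARUM" else "Lib IV. De Herbis."
  title_lid <- add_line(title, 0.38, 0.030, "PRINTED", "header")
  page_no <- as.character(sample(100:999, 1))
  pno_left <- if (even) 0.08 else 0.90
  pno_lid <- add_line(page_no, pno_left, 0.030, "PRINTED", "header")

  ann_text <- function() {
    paste0(sample(.PLANT_PHRASES, 1), " H.S. ", sample(1:300, 1), ". ",
           sample(1:200, 1), ".")
  }
  header_lids <- character()
  for (i in seq_len(spec$n_header_annotations)) {
    header_lids[i] <- add_line(ann_text(), body_x[1], 0.004 + (i - 1) * 0.045,
                               "HANDWRITING", "header", body_x[2])
  }
  footer_lids <- character()
  for (i in seq_len(spec$n_footer_annotations)) {
    footer_lids[i] <- add_line(ann_text(), body_x[1], 0.930 + (i - 1) * 0.045,
                               "HANDWRITING", "footer", body_x[2])
  }

  ## --- body entries -----------------------------------------------------
  plant_lids <- character(spec$n_plant_entries)
  plant_tops <- numeric(spec$n_plant_entries)
  para_lids <- vector("list", spec$n_plant_entries)
  y <- body_top
  for (e in seq_len(spec$n_plant_entries)) {
    if (y + pitch > body_bottom) {
      stop("generation error: entries do not fit the page at this pitch",
           call. = FALSE)
    }
    plant_tops[e] <- y
    plant_lids[e] <- add_line(sample(.PLANT_PHRASES, 1), body_x[1] + indent, y,
                              "PRINTED", "body", body_x[2])
    y <- y + 2 * pitch
    k <- if (diff(spec$paragraph_length_range) == 0) spec$paragraph_length_range[1]
         else sample(seq(spec$paragraph_length_range[1],
                         spec$paragraph_length_range[2]), 1)
    lids <- character(k)
    ptops <- numeric(k)
    for (j in seq_len(k)) {
      txt <- paste(sample(.BODY_WORDS, sample(6:9, 1), replace = TRUE),
                   collapse = " ")
      lids[j] <- add_line(txt, body_x[1], y, "PRINTED", "body", body_x[2])
      ptops[j] <- y
      y <- y + pitch
    }
    ## handwritten interruption squeezed between two printed paragraph lines
    if (k >= 2 && runif(1) < spec$handwritten_interruption_rate) {
      j <- sample(seq_len(k - 1), 1)
      int_lid <- add_line(paste0("vide H.S. ", sample(1:300, 1), ". ",
                                 sample(1:200, 1), "."),
                          body_x[1] + 0.02, ptops[j] + pitch / 2,
                          "HANDWRITING", "body", body_x[2])
      lids <- c(lids, int_lid)
    }
    para_lids[[e]] <- lids
    y <- y + pitch  # one extra pitch: paragraph gap = 2 * pitch
  }
  if (y - pitch > body_bottom) {
    stop("generation error: entries do not fit the page at this pitch",
         call. = FALSE)
  }

  ## --- margin annotations ----------------------------------------------
  entry_gap <- if (spec$n_plant_entries > 1) min(diff(sort(plant_tops)))
               else 6 * pitch
  targets <- if (spec$n_margin_annotations == 0) integer()
    else if (spec$n_margin_annotations <= spec$n_plant_entries) {
      sort(sample(seq_len(spec$n_plant_entries), spec$n_margin_annotations))
    } else {
      sort(rep_len(seq_len(spec$n_plant_entries), spec$n_margin_annotations))
    }
  margin_segments <- list()
  for (t in targets) {
    jitter <- runif(1, -0.4, 0.4) * entry_gap
    mtop <- min(max(plant_tops[t] + jitter, body_top), body_bottom)
    ref <- paste0("H.S. ", sample(1:300, 1), ". ", sample(1:200, 1), ".")
    if (runif(1) < 0.3) ref <- paste0(ref, " ", sample(1:20, 1), ".")
    lids <- add_line(ref, margin_x[1], mtop, "HANDWRITING", "margin", margin_x[2])
    if (runif(1) < 0.3) {
      extra <- paste0(sample(1:300, 1), ".", sample(1:200, 1), ". ",
                      sample(1:300, 1), ".", sample(1:200, 1), ".")
      lids <- c(lids, add_line(extra, margin_x[1], mtop + pitch,
                               "HANDWRITING", "margin", margin_x[2]))
    }
    margin_segments[[length(margin_segments) + 1L]] <-
      list(line_ids = lids, top = mtop, plant = t)
  }

  ## --- adjacent-page bleed ----------------------------------------------
  short_words <- .BODY_WORDS[nchar(.BODY_WORDS) <= 7]  # must fit the bleed strip
  for (b in seq_len(spec$bleed_word_count)) {
    add_line(sample(short_words, 1), bleed_x[1],
             round(runif(1, body_top, body_bottom - pitch), 6),
             "PRINTED", "discarded", bleed_x[2])
  }

  words <- do.call(rbind, words)
  lines <- do.call(rbind, lines)

  ## --- character noise (geometry untouched: substitutions keep length) --
  if (spec$char_noise_rate > 0) {
    ## the rate is per character of the emitted transcription (spaces
    ## included); substitutions land on non-space characters, so scale the
    ## per-word-character rate by each line's space share
    for (i in seq_len(nrow(lines))) {
      sel <- which(words$line_id == lines$id[i])
      m <- sum(nchar(words$text[sel]))
      n <- m + length(sel) - 1L
      p_eff <- min(1, spec$char_noise_rate * n / m)
      words$text[sel] <- vapply(words$text[sel], .corrupt_text, "",
                                rate = p_eff, USE.NAMES = FALSE)
      lines$text[i] <- paste(words$text[sel], collapse = " ")
    }
  }

  page <- page_blocks(pid, lines = lines, words = words)

  ## --- ground truth -----------------------------------------------------
  clean_of <- function(lids) {
    paste(vapply(lids, function(l) line_meta[[l]]$clean, ""), collapse = " ")
  }
  segs <- list()
  add_seg <- function(kind, lids) {
    segs[[length(segs) + 1L]] <<- list(kind = kind, line_ids = lids,
                                       top = min(.line_tops(page, lids)),
                                       clean_text = clean_of(lids))
  }
  for (l in header_lids) add_seg("HEADER", l)
  for (l in footer_lids) add_seg("FOOTER", l)
  for (e in seq_len(spec$n_plant_entries)) add_seg("PLANT_NAME", plant_lids[e])
  for (e in seq_len(spec$n_plant_entries)) add_seg("PARAGRAPH", para_lids[[e]])
  margin_seg_idx <- integer()
  for (m in margin_segments) {
    add_seg("MARGIN", m$line_ids)
    margin_seg_idx <- c(margin_seg_idx, length(segs))
  }
  ## stable ids: <page>:<kind>:<ordinal>, ordinal by top within kind
  kind_token <- c(HEADER = "header", FOOTER = "footer", MARGIN = "margin",
                  PLANT_NAME = "plant", PARAGRAPH = "para")
  for (kind in names(kind_token)) {
    idx <- which(vapply(segs, function(s) s$kind, "") == kind)
    idx <- idx[order(vapply(segs[idx], function(s) s$top, numeric(1)))]
    for (o in seq_along(idx)) {
      segs[[idx[o]]]$id <- sprintf("%s:%s:%d", pid, kind_token[[kind]], o)
    }
  }
  full_seg <- function(s) {
    gs <- .new_segment(page, s$kind, s$line_ids)
    gs$id <- s$id
    gs
  }
  gt_segments <- lapply(segs, full_seg)
  clean_texts <- setNames(vapply(segs, function(s) s$clean_text, ""),
                          vapply(segs, function(s) s$id, ""))

  plant_ids_by_entry <- vapply(seq_len(spec$n_plant_entries), function(e) {
    i <- which(vapply(segs, function(s) identical(s$line_ids, plant_lids[e]), NA))
    segs[[i]]$id
  }, "")
  pairs <- if (length(margin_segments) == 0) {
    data.frame(margin_id = character(), plant_id = character(),
               distance = numeric(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(seq_along(margin_segments), function(i) {
      m <- margin_segments[[i]]
      s <- segs[[margin_seg_idx[i]]]
      data.frame(margin_id = s$id,
                 plant_id = plant_ids_by_entry[m$plant],
                 distance = abs(.seg_top(gt_segments[[margin_seg_idx[i]]]) -
                                  plant_tops[m$plant]),
                 stringsAsFactors = FALSE)
    }))
  }
  pairs <- pairs[order(match(pairs$margin_id,
                             vapply(gt_segments, `[[`, "", "id"))), , drop = FALSE]
  if (nrow(pairs) > 0) {
    ord <- order(vapply(pairs$margin_id, function(id) {
      gt_segments[[match(id, vapply(gt_segments, `[[`, "", "id"))]]$bbox[["top"]]
    }, numeric(1)))
    pairs <- pairs[ord, , drop = FALSE]
    rownames(pairs) <- NULL
  }

  assignment <- data.frame(
    line_id = lines$id,
    class = vapply(lines$id, function(l) line_meta[[l]]$class, ""),
    stringsAsFactors = FALSE)

  truth <- structure(
    list(page_id = pid, parity = spec$parity, spec = spec,
         segments = gt_segments, pairs = pairs,
         layout = assignment, clean_texts = clean_texts,
         record = .truth_record(pid, spec$parity, gt_segments, pairs,
                                clean_texts)),
    class = "ground_truth")
  list(page = page, truth = truth)
}

## project ground truth into the pipeline's page-record schema (clean texts)
.truth_record <- function(pid, parity, gt_segments, pairs, clean_texts) {
  entry <- function(s) {
    list(id = s$id, text = unname(clean_texts[[s$id]]), bbox = as.list(s$bbox))
  }
  of_kind <- function(kind) {
    lapply(Filter(function(s) s$kind == kind, gt_segments), entry)
  }
  list(page_id = pid, group = parity,
       header = of_kind("HEADER"), footer = of_kind("FOOTER"),
       plants = of_kind("PLANT_NAME"), margins = of_kind("MARGIN"),
       pairs = pairs, unlinked = character())
}

#' @export
print.ground_truth <- function(x, ...) {
  kinds <- table(vapply(x$segments, function(s) s$kind, ""))
  cat(sprintf("<ground_truth> %s (%s): %s; %d pair(s)\n", x$page_id, x$parity,
              paste(names(kinds), kinds, sep = " = ", collapse = ", "),
              nrow(x$pairs)))
  invisible(x)
}

#' Generate a corpus of synthetic pages
#'
#' Runs [generate_page()] over a list of specs and, when `dir` is given,
#' writes one Textract-dialect JSON per page, a `ground_truth.json` in the
#' pipeline record schema, and a `manifest.json` with the seeds, so the
#' corpus can be regenerated byte-for-byte.
#'
#' @param specs List of [synthetic_page_spec()] objects (or a single one).
#' @param dir Output directory, created if needed; `NULL` keeps the corpus
#'   in memory only.
#' @return Invisibly, a list with `pages`, `truths`, and `manifest`.
#' @export
generate_corpus <- function(specs, dir = NULL) {
  if (inherits(specs, "synthetic_page_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1)
  ids <- vapply(specs, function(s) s$page_id, "")
  if (anyDuplicated(ids)) stop("duplicate page ids in corpus specs", call. = FALSE)
  gen <- lapply(specs, generate_page)
  pages <- lapply(gen, `[[`, "page")
  truths <- lapply(gen, `[[`, "truth")
  manifest <- data.frame(
    page_id = ids,
    seed = vapply(specs, function(s) s$seed, integer(1)),
    parity = vapply(specs, function(s) s$parity, ""),
    file = paste0(ids, ".json"),
    stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_along(pages)) {
      write_blocks(pages[[i]], file.path(dir, manifest$file[i]))
    }
    write_records(lapply(truths, `[[`, "record"),
                  file.path(dir, "ground_truth.json"))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               file.path(dir, "manifest.json"), useBytes = TRUE)
  }
  invisible(list(pages = pages, truths = truths, manifest = manifest))
}
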