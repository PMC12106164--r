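## Segment detection: paragraphs from word-level spacing, plant-name
## classification, margin / header / footer annotation segments, and parsing
## of "H.S. [volume] [folio] [specimen]" herbarium references.

.new_segment <- function(page, kind, line_ids) {
  words <- page$words[page$words$line_id %in% line_ids, , drop = FALSE]
  words <- words[order(match(words$line_id, line_ids), words$left), , drop = FALSE]
  txt <- vapply(line_ids, function(lid) {
    paste(words$text[words$line_id == lid], collapse = " ")
  }, "")
  structure(
    list(id = NA_character_, kind = kind,
         bbox = .hull_box(words),
         text = paste(txt[nzchar(txt)], collapse = " "),
         word_ids = words$id, line_ids = line_ids,
         handwritten_word_ids = words$id[words$text_type == "HANDWRITING"]),
    class = "segment"
  )
}

#' @export
print.segment <- function(x, ...) {
  cat(sprintf("<segment %s> %s [%d line(s), top %.3f]: %s\n",
              x$kind, if (is.na(x$id)) "(unassigned)" else x$id,
              length(x$line_ids), x$bbox[["top"]],
              substr(x$text, 1, 60)))
  invisible(x)
}

## majority text type of a line's words
.line_printed <- function(page, lid) {
  w <- page$words[page$words$line_id == lid, ]
  nrow(w) == 0 || mean(w$text_type == "PRINTED") >= 0.5
}

.page_pitch <- function(page, line_ids, cfg) {
  p <- line_pitch(page, line_ids, source = cfg$line_top_source)
  if (is.na(p)) cfg$default_pitch else p
}

#' Split body lines into paragraph segments
#'
#' Paragraph boundaries come from the vertical spacing of *word* boxes, not
#' line boxes: skewed scans inflate the provider's line boxes, so each
#' line's top is taken as the median of its member word tops, and a new
#' paragraph starts whenever the gap between consecutive printed lines
#' exceeds `cfg$para_gap_mult` times the page's line pitch (default 1.6).
#' Handwritten lines interleaved with the printed text are excluded from the
#' gap computation entirely — an annotation squeezed between printed lines
#' must not split (or glue) a paragraph — but their words are retained as
#' members of the positionally-enclosing segment and flagged handwritten.
#'
#' @param page A [page_blocks] object.
#' @param layout A `page_layout` from [detect_layout()] (supplies the body
#'   lines), or a character vector of body line ids.
#' @param cfg A [mobilise_config()] list.
#' @return A list of `segment` objects of kind `"PARAGRAPH"`, top to bottom.
#' @export
segment_paragraphs <- function(page, layout, cfg = mobilise_config()) {
  line_ids <- if (inherits(layout, "page_layout")) .layout_lines(layout, "body")
              else as.character(layout)
  if (length(line_ids) == 0) return(list())
  tops <- .line_tops(page, line_ids, source = cfg$line_top_source)
  ord <- order(tops)
  line_ids <- line_ids[ord]; tops <- tops[ord]
  printed <- vapply(line_ids, .line_printed, logical(1), page = page)

  p_ids <- line_ids[printed]; p_tops <- tops[printed]
  pitch <- .page_pitch(page, p_ids, cfg)

  ## paragraph index per printed line
  if (length(p_ids) > 0) {
    brk <- c(FALSE, diff(p_tops) > cfg$para_gap_mult * pitch)
    para_of_printed <- cumsum(brk) + 1L
  } else {
    para_of_printed <- integer()
  }

  ## handwritten lines attach to the paragraph of the nearer printed line
  ## (ties toward the preceding one)
  para_of <- integer(length(line_ids))
  para_of[printed] <- para_of_printed
  for (i in which(!printed)) {
    if (length(p_ids) == 0) { para_of[i] <- 1L; next }
    before <- which(p_tops <= tops[i])
    after <- which(p_tops > tops[i])
    if (length(before) == 0) para_of[i] <- para_of_printed[min(after)]
    else if (length(after) == 0) para_of[i] <- para_of_printed[max(before)]
    else {
      d_prev <- tops[i] - p_tops[max(before)]
      d_next <- p_tops[min(after)] - tops[i]
      para_of[i] <- if (d_prev <= d_next) para_of_printed[max(before)]
                    else para_of_printed[min(after)]
    }
  }
  if (length(p_ids) == 0) para_of[] <- 1L

  lapply(sort(unique(para_of)), function(k) {
    .new_segment(page, "PARAGRAPH", line_ids[para_of == k])
  })
}

#' Is a paragraph segment a printed plant name?
#'
#' Plant-name entries are typically indented and spaced apart from the
#' surrounding paragraphs: the primary rule fires when the first printed
#' line is indented beyond the body's left edge by more than
#' `cfg$indent_frac` (default 0.015) and the segment has at most
#' `cfg$max_name_lines` printed lines (default 3).  Names set flush with the
#' text are caught by fallback features, any of which suffices: the first
#' token is a known author abbreviation (configurable lexicon), the first
#' character is an uppercase letter and the segment has at most two printed
#' lines, or every word is in uppercase.
#'
#' @param seg A `segment` of kind `"PARAGRAPH"`.
#' @param body_left Left edge (fraction) of the body text envelope.
#' @param page The owning [page_blocks] object.
#' @param cfg A [mobilise_config()] list.
#' @return `TRUE` or `FALSE`, deterministic given the configuration.
#' @export
classify_plant_name <- function(seg, body_left, page, cfg = mobilise_config()) {
  stopifnot(inherits(seg, "segment"))
  printed_lines <- seg$line_ids[vapply(seg$line_ids, .line_printed,
                                       logical(1), page = page)]
  if (length(printed_lines) == 0) return(FALSE)
  n_lines <- length(printed_lines)
  pw <- page$words[page$words$line_id %in% printed_lines &
                     page$words$text_type == "PRINTED", , drop = FALSE]
  first_line_left <- min(page$words$left[page$words$line_id == printed_lines[1]])

  indented <- (first_line_left - body_left) > cfg$indent_frac &&
    n_lines <= cfg$max_name_lines
  if (indented) return(TRUE)

  first_token <- if (nrow(pw) > 0) pw$text[1] else ""
  if (first_token %in% cfg$abbreviation_lexicon) return(TRUE)
  if (grepl("^[[:upper:]]", first_token) && n_lines <= 2) return(TRUE)
  has_letters <- grepl("[[:alpha:]]", pw$text)
  if (nrow(pw) > 0 && any(has_letters) &&
      all(pw$text[has_letters] == toupper(pw$text[has_letters]))) return(TRUE)
  FALSE
}

#' Segment side-margin annotations
#'
#' Handwritten specimen references are split into segments on two signals:
#' a line whose text opens with the herbarium initials (fuzzy `H.S.`
#' pattern, tolerating "H. S.", "HS", stray commas) always starts a new
#' segment, as does a vertical gap to the previous margin line exceeding
#' `cfg$margin_gap_mult` times the line pitch (default 2.0).
#'
#' @param page A [page_blocks] object.
#' @param layout A `page_layout` (supplies margin lines) or a character
#'   vector of margin line ids.
#' @param cfg A [mobilise_config()] list.
#' @return A list of `segment` objects of kind `"MARGIN"`, top to bottom.
#' @export
segment_margins <- function(page, layout, cfg = mobilise_config()) {
  line_ids <- if (inherits(layout, "page_layout")) .layout_lines(layout, "margin")
              else as.character(layout)
  if (length(line_ids) == 0) return(list())
  tops <- .line_tops(page, line_ids, source = cfg$line_top_source)
  ord <- order(tops)
  line_ids <- line_ids[ord]; tops <- tops[ord]
  pitch <- .page_pitch(page, .layout_body_or(layout, line_ids), cfg)

  texts <- page$lines$text[match(line_ids, page$lines$id)]
  starts_hs <- grepl(cfg$hs_pattern, texts)
  new_seg <- starts_hs | c(TRUE, diff(tops) > cfg$margin_gap_mult * pitch)
  new_seg[1] <- TRUE
  grp <- cumsum(new_seg)
  lapply(unique(grp), function(k) .new_segment(page, "MARGIN", line_ids[grp == k]))
}

## pitch is more stable when estimated from the body; fall back to the given
## lines when no layout is available
.layout_body_or <- function(layout, line_ids) {
  if (inherits(layout, "page_layout")) {
    b <- .layout_lines(layout, "body")
    if (length(b) >= 2) return(b)
  }
  line_ids
}

#' Segment header and footer annotations
#'
#' Within the header and footer bands, printed furniture (the running title,
#' page numbers) is set aside and the remaining *handwritten* lines are
#' grouped into segments with the same gap rule as the margins.  These
#' annotations carry their own plant names and herbarium references for
#' species missing from the printed list.
#'
#' @param page A [page_blocks] object.
#' @param layout A `page_layout` from [detect_layout()].
#' @param cfg A [mobilise_config()] list.
#' @return A list of `segment` objects of kind `"HEADER"` or `"FOOTER"`.
#' @export
segment_headers_footers <- function(page, layout, cfg = mobilise_config()) {
  out <- list()
  for (band in c("header", "footer")) {
    line_ids <- .layout_lines(layout, band)
    line_ids <- line_ids[!vapply(line_ids, .line_printed, logical(1), page = page)]
    if (length(line_ids) == 0) next
    tops <- .line_tops(page, line_ids, source = cfg$line_top_source)
    ord <- order(tops)
    line_ids <- line_ids[ord]; tops <- tops[ord]
    pitch <- .page_pitch(page, .layout_body_or(layout, line_ids), cfg)
    grp <- cumsum(c(TRUE, diff(tops) > cfg$margin_gap_mult * pitch))
    out <- c(out, lapply(unique(grp), function(k) {
      .new_segment(page, toupper(band), line_ids[grp == k])
    }))
  }
  out
}

#' Parse herbarium specimen references from annotation text
#'
#' Annotations reference specimens as `H.S. [volume] [folio]`, optionally
#' followed by a third number locating the specimen on the folio; transcribed
#' variants such as `H.S. 114. p.29. 1.` (a `p`-prefixed folio) are
#' accepted.  Extraction is best-effort by design: every parseable reference
#' is returned and the unparsed spans are reported as residue, never an
#' error — downstream curation decides what to do with them.
#'
#' @param text A segment transcription (single string).
#' @return A list with `references` (data frame: `volume`, `folio`,
#'   `specimen` — `NA` when absent) and `residue` (character vector of
#'   unparsed, non-empty spans).
#' @examples
#' parse_specimen_reference("H.S. 3 101")
#' parse_specimen_reference("H.S. 114. p.29. 1.")
#' @export
parse_specimen_reference <- function(text) {
  empty <- data.frame(volume = integer(), folio = integer(), specimen = integer())
  if (length(text) == 0 || is.na(text) || !nzchar(trimws(text))) {
    return(list(references = empty, residue = character()))
  }
  pat <- paste0("H\\s*[.,]?\\s*S\\s*[.,]?\\s*",      # the H.S. initials
                "(\\d+)\\s*[.,]?\\s*",               # Hortus siccus volume
                "(?:[pP]\\s*[.,]?\\s*)?(\\d+)",      # folio, optional p prefix
                "(?:\\s*[.,]?\\s*(\\d+))?")          # optional specimen number
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(list(references = empty, residue = trimws(text)))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
  grab <- function(i, j) {
    if (cs[i, j] == 0 || cl[i, j] == 0) NA_integer_
    else as.integer(substr(text, cs[i, j], cs[i, j] + cl[i, j] - 1))
  }
  refs <- data.frame(
    volume = vapply(seq_along(starts), grab, integer(1), j = 1),
    folio = vapply(seq_along(starts), grab, integer(1), j = 2),
    specimen = vapply(seq_along(starts), grab, integer(1), j = 3)
  )
  ## residue: the text outside all matched spans
  keep <- rep(TRUE, nchar(text))
  for (i in seq_along(starts)) keep[seq(starts[i], starts[i] + lens[i] - 1)] <- FALSE
  runs <- rle(keep)
  pos <- cumsum(c(1, runs$lengths))
  residue <- character()
  for (i in seq_along(runs$values)) {
    if (runs$values[i]) {
      span <- trimws(substr(text, pos[i], pos[i + 1] - 1))
      span <- gsub("^[.,[:space:]]+|[.,[:space:]]+$", "", span)
      if (nzchar(span)) residue <- c(residue, span)
    }
  }
  list(references = refs, residue = residue)
}
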