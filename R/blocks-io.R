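## OCR block model and reader/writer for the Textract "DetectDocumentText"
## JSON dialect: a Blocks[] array of PAGE / LINE / WORD objects with
## fractional Geometry.BoundingBox {Left, Top, Width, Height}, CHILD
## relationships, and WORD-level TextType (PRINTED | HANDWRITING).

.COORD_EPS <- 1e-6

## Default page pixel dimensions of the digitised volumes.
.DEFAULT_WIDTH_PX <- 4992L
.DEFAULT_HEIGHT_PX <- 6668L

.check_bbox <- function(left, top, width, height, what = "box") {
  ok <- is.finite(left) & is.finite(top) & is.finite(width) & is.finite(height) &
    left >= -.COORD_EPS & top >= -.COORD_EPS & width >= 0 & height >= 0 &
    left + width <= 1 + .COORD_EPS & top + height <= 1 + .COORD_EPS
  if (!all(ok)) {
    stop("invalid fractional bounding ", what, ": coordinates must lie in [0, 1]",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a fractional bounding box
#'
#' Boxes use the provider convention: origin at the top-left of the page,
#' `left`/`width` as fractions of page width and `top`/`height` as fractions
#' of page height, treated as closed rectangles.
#'
#' @param left,top,width,height Fractions in `[0, 1]` (a small epsilon is
#'   tolerated for provider rounding).
#' @return A named numeric vector `c(left, top, width, height)`.
#' @examples
#' bbox(0.1, 0.22, 0.3, 0.015)
#' @export
bbox <- function(left, top, width, height) {
  .check_bbox(left, top, width, height)
  c(left = as.numeric(left), top = as.numeric(top),
    width = as.numeric(width), height = as.numeric(height))
}

.as_box <- function(b) {
  if (is.list(b)) b <- unlist(b)
  if (is.null(names(b))) names(b) <- c("left", "top", "width", "height")
  b[c("left", "top", "width", "height")]
}

#' Construct a parsed page of OCR blocks
#'
#' The in-memory form of one provider page: a `lines` table, a `words` table
#' (each word belonging to exactly one line via `line_id`), and the page's
#' pixel dimensions.  Lines are stored top-to-bottom, words in reading order
#' within each line (left to right).
#'
#' @param page_id Opaque page identifier.
#' @param lines Data frame with columns `id`, `text`, `left`, `top`, `width`,
#'   `height`.
#' @param words Data frame with columns `id`, `text`, `text_type`
#'   (`"PRINTED"` or `"HANDWRITING"`), `left`, `top`, `width`, `height`,
#'   `confidence` (percentage), `line_id`.
#' @param width_px,height_px Page pixel dimensions; default 4992 x 6668.
#' @return An object of class `page_blocks`.
#' @export
page_blocks <- function(page_id, lines = NULL, words = NULL,
                        width_px = .DEFAULT_WIDTH_PX,
                        height_px = .DEFAULT_HEIGHT_PX) {
  empty_lines <- data.frame(id = character(), text = character(),
                            left = numeric(), top = numeric(),
                            width = numeric(), height = numeric(),
                            stringsAsFactors = FALSE)
  empty_words <- data.frame(id = character(), text = character(),
                            text_type = character(),
                            left = numeric(), top = numeric(),
                            width = numeric(), height = numeric(),
                            confidence = numeric(), line_id = character(),
                            stringsAsFactors = FALSE)
  if (is.null(lines)) lines <- empty_lines
  if (is.null(words)) words <- empty_words
  lines <- as.data.frame(lines, stringsAsFactors = FALSE)
  words <- as.data.frame(words, stringsAsFactors = FALSE)

  if (nrow(words) > 0) {
    stopifnot(!anyDuplicated(words$id), all(nzchar(words$text)))
    .check_bbox(words$left, words$top, words$width, words$height, "word box")
    if (!all(words$line_id %in% lines$id)) {
      stop("every word must be the child of a line on the same page", call. = FALSE)
    }
    stopifnot(all(words$text_type %in% c("PRINTED", "HANDWRITING")))
  }
  if (nrow(lines) > 0) {
    stopifnot(!anyDuplicated(lines$id))
    .check_bbox(lines$left, lines$top, lines$width, lines$height, "line box")
    lines <- lines[order(lines$top, lines$left), , drop = FALSE]
    rownames(lines) <- NULL
  }
  if (nrow(words) > 0) {
    words <- words[order(match(words$line_id, lines$id), words$left), , drop = FALSE]
    rownames(words) <- NULL
  }
  structure(
    list(page_id = as.character(page_id),
         width_px = as.integer(width_px), height_px = as.integer(height_px),
         lines = lines, words = words),
    class = "page_blocks"
  )
}

#' @export
print.page_blocks <- function(x, ...) {
  n_hw <- sum(x$words$text_type == "HANDWRITING")
  cat(sprintf("<page_blocks> %s: %d lines, %d words (%d handwritten), %d x %d px\n",
              x$page_id, nrow(x$lines), nrow(x$words), n_hw,
              x$width_px, x$height_px))
  invisible(x)
}

.block_box <- function(block) {
  g <- block$Geometry$BoundingBox
  if (is.null(g)) stop("block without Geometry.BoundingBox", call. = FALSE)
  c(left = as.numeric(g$Left), top = as.numeric(g$Top),
    width = as.numeric(g$Width), height = as.numeric(g$Height))
}

.child_ids <- function(block) {
  out <- character()
  for (rel in block$Relationships) {
    if (identical(rel$Type, "CHILD")) out <- c(out, unlist(rel$Ids))
  }
  out
}

#' Parse Textract-dialect block JSON
#'
#' Reads a `DetectDocumentText`-style document: a `Blocks` array of PAGE,
#' LINE and WORD objects with fractional bounding boxes, CHILD relationships
#' and WORD-level `TextType`.  Both single-page and multi-page arrays are
#' accepted; one [page_blocks] object is produced per PAGE block.  Unknown
#' block types are skipped with a warning.  A WORD referenced by no LINE is
#' kept by wrapping it in a synthetic one-word line (with a warning), so
#' degraded provider output still flows through.
#'
#' @param raw_json JSON text, or a path to a JSON file.
#' @return A list of [page_blocks] objects, named by page id.
#' @seealso [write_blocks()] for the inverse.
#' @export
parse_textract_json <- function(raw_json) {
  if (length(raw_json) == 1 && !grepl("[{[]", substr(raw_json, 1, 1)) &&
      file.exists(raw_json)) {
    raw_json <- paste(readLines(raw_json, warn = FALSE, encoding = "UTF-8"),
                      collapse = "\n")
  }
  doc <- jsonlite::fromJSON(raw_json, simplifyVector = FALSE)
  blocks <- doc$Blocks
  if (is.null(blocks)) stop("no Blocks array in document", call. = FALSE)
  if (length(blocks) == 0) {
    pg <- page_blocks("empty-page")
    return(setNames(list(pg), pg$page_id))
  }

  type <- vapply(blocks, function(b) as.character(b$BlockType %||% "?"), "")
  unknown <- setdiff(unique(type), c("PAGE", "LINE", "WORD"))
  if (length(unknown) > 0) {
    warning("ignoring unknown block types: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  by_id <- setNames(blocks, vapply(blocks, function(b) as.character(b$Id %||% ""), ""))

  ## optional dialect extension carrying pixel dimensions per page
  dims <- list()
  for (d in doc$PageDimensions) {
    dims[[as.character(d$PageId)]] <- c(as.integer(d$WidthPx), as.integer(d$HeightPx))
  }

  page_idx <- which(type == "PAGE")
  pages <- list()
  claimed_words <- character()

  parse_one <- function(page_block, line_blocks) {
    page_id <- as.character(page_block$Id)
    lines <- list(); words <- list()
    for (lb in line_blocks) {
      lbox <- .block_box(lb)
      lines[[length(lines) + 1L]] <- data.frame(
        id = as.character(lb$Id), text = as.character(lb$Text %||% ""),
        left = lbox[["left"]], top = lbox[["top"]],
        width = lbox[["width"]], height = lbox[["height"]],
        stringsAsFactors = FALSE)
      for (wid in .child_ids(lb)) {
        wb <- by_id[[wid]]
        if (is.null(wb) || !identical(wb$BlockType, "WORD")) next
        wbox <- .block_box(wb)
        words[[length(words) + 1L]] <- data.frame(
          id = as.character(wb$Id), text = as.character(wb$Text),
          text_type = as.character(wb$TextType %||% "PRINTED"),
          left = wbox[["left"]], top = wbox[["top"]],
          width = wbox[["width"]], height = wbox[["height"]],
          confidence = as.numeric(wb$Confidence %||% NA_real_),
          line_id = as.character(lb$Id), stringsAsFactors = FALSE)
        claimed_words <<- c(claimed_words, as.character(wb$Id))
      }
    }
    d <- dims[[page_id]]
    page_blocks(page_id,
                lines = if (length(lines)) do.call(rbind, lines),
                words = if (length(words)) do.call(rbind, words),
                width_px = if (!is.null(d)) d[1] else .DEFAULT_WIDTH_PX,
                height_px = if (!is.null(d)) d[2] else .DEFAULT_HEIGHT_PX)
  }

  for (i in page_idx) {
    pb <- blocks[[i]]
    line_ids <- .child_ids(pb)
    line_blocks <- Filter(function(b) !is.null(b) && identical(b$BlockType, "LINE"),
                          by_id[line_ids])
    pages[[as.character(pb$Id)]] <- parse_one(pb, line_blocks)
  }

  ## orphan WORDs: not claimed by any LINE of any page
  orphan_idx <- which(type == "WORD" &
                        !vapply(blocks, function(b) as.character(b$Id) %in% claimed_words,
                                logical(1)))
  if (length(orphan_idx) > 0) {
    warning(length(orphan_idx),
            " WORD block(s) referenced by no LINE; attached to synthetic lines",
            call. = FALSE)
    if (length(pages) == 0) {
      pages[["orphan-page"]] <- page_blocks("orphan-page")
    }
    host <- pages[[1]]
    for (k in orphan_idx) {
      wb <- blocks[[k]]
      wbox <- .block_box(wb)
      lid <- paste0("synthetic-line-", as.character(wb$Id))
      host$lines <- rbind(host$lines, data.frame(
        id = lid, text = as.character(wb$Text),
        left = wbox[["left"]], top = wbox[["top"]],
        width = wbox[["width"]], height = wbox[["height"]],
        stringsAsFactors = FALSE))
      host$words <- rbind(host$words, data.frame(
        id = as.character(wb$Id), text = as.character(wb$Text),
        text_type = as.character(wb$TextType %||% "PRINTED"),
        left = wbox[["left"]], top = wbox[["top"]],
        width = wbox[["width"]], height = wbox[["height"]],
        confidence = as.numeric(wb$Confidence %||% NA_real_),
        line_id = lid, stringsAsFactors = FALSE))
    }
    pages[[1]] <- page_blocks(host$page_id, host$lines, host$words,
                              host$width_px, host$height_px)
  }

  if (length(pages) == 0) stop("document contains no PAGE block", call. = FALSE)
  pages
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise pages back to Textract-dialect JSON
#'
#' Emits the same dialect consumed by [parse_textract_json()]; the round trip
#' `parse(write(p))` reproduces `p` structurally.  Page pixel dimensions are
#' carried in a top-level `PageDimensions` extension that the reader treats
#' as optional.
#'
#' @param pages A [page_blocks] object or a list of them.
#' @param path Optional file to write to.
#' @return JSON text (invisibly when `path` is given).
#' @export
write_blocks <- function(pages, path = NULL) {
  if (inherits(pages, "page_blocks")) pages <- list(pages)
  blocks <- list()
  dims <- list()
  for (pg in pages) {
    stopifnot(inherits(pg, "page_blocks"))
    geo <- function(left, top, width, height) {
      list(BoundingBox = list(Width = width, Height = height,
                              Left = left, Top = top))
    }
    rel <- function(ids) {
      if (length(ids) == 0) list() else list(list(Type = "CHILD", Ids = as.list(ids)))
    }
    blocks[[length(blocks) + 1L]] <- list(
      BlockType = "PAGE", Id = pg$page_id,
      Geometry = geo(0, 0, 1, 1), Relationships = rel(pg$lines$id))
    for (i in seq_len(nrow(pg$lines))) {
      ln <- pg$lines[i, ]
      wids <- pg$words$id[pg$words$line_id == ln$id]
      blocks[[length(blocks) + 1L]] <- list(
        BlockType = "LINE", Id = ln$id, Text = ln$text,
        Geometry = geo(ln$left, ln$top, ln$width, ln$height),
        Relationships = rel(wids))
    }
    for (i in seq_len(nrow(pg$words))) {
      w <- pg$words[i, ]
      blk <- list(
        BlockType = "WORD", Id = w$id, Text = w$text, TextType = w$text_type,
        Confidence = w$confidence,
        Geometry = geo(w$left, w$top, w$width, w$height))
      if (is.na(w$confidence)) blk$Confidence <- NULL
      blocks[[length(blocks) + 1L]] <- blk
    }
    dims[[length(dims) + 1L]] <- list(PageId = pg$page_id,
                                      WidthPx = pg$width_px,
                                      HeightPx = pg$height_px)
  }
  doc <- list(DocumentMetadata = list(Pages = length(pages)),
              Blocks = blocks, PageDimensions = dims)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Convert a pixel y-coordinate to a page-height fraction
#'
#' Provider geometry expresses every coordinate as a ratio of the page size;
#' for the digitised volumes the scans are 4992 x 6668 pixels, so a box top
#' at 1500 px has fractional top 1500/6668 = 0.22 (2 d.p.).
#'
#' @param pixel_top Pixel y-coordinate(s), `0 <= pixel_top <= page_height`.
#' @param page_height Page height in pixels; must be positive.
#' @return `pixel_top / page_height`.
#' @examples
#' top_fraction(1500, 6668)
#' @export
top_fraction <- function(pixel_top, page_height) {
  if (!is.numeric(page_height) || any(page_height <= 0)) {
    stop("page_height must be positive", call. = FALSE)
  }
  if (any(pixel_top < 0) || any(pixel_top > page_height)) {
    stop("pixel_top must lie within [0, page_height]", call. = FALSE)
  }
  pixel_top / page_height
}

## line top from member word boxes: median of printed-word tops, falling back
## to all words, then to the line box. Medians defeat skew-inflated line boxes.
.line_tops <- function(page, line_ids = page$lines$id,
                       source = c("word_median", "line_box")) {
  source <- match.arg(source)
  if (source == "line_box") {
    return(setNames(page$lines$top[match(line_ids, page$lines$id)], line_ids))
  }
  vapply(line_ids, function(lid) {
    w <- page$words[page$words$line_id == lid, ]
    wp <- w[w$text_type == "PRINTED", ]
    if (nrow(wp) > 0) median(wp$top)
    else if (nrow(w) > 0) median(w$top)
    else page$lines$top[match(lid, page$lines$id)]
  }, numeric(1))
}

#' Median inter-line pitch of a page
#'
#' Robust vertical scale estimate used by the spacing thresholds: the median
#' gap between consecutive line tops, where each line's top is the median of
#' its member word-box tops.  The median makes the estimate insensitive to
#' the occasional paragraph gap or outlier.
#'
#' @param page A [page_blocks] object.
#' @param line_ids Lines to use; defaults to all lines on the page.
#' @param source `"word_median"` (default) or `"line_box"` line tops.
#' @return The pitch as a fraction of page height, or `NA_real_` when fewer
#'   than two lines (callers fall back to a configured default).
#' @export
line_pitch <- function(page, line_ids = page$lines$id, source = "word_median") {
  if (length(line_ids) < 2) return(NA_real_)
  tops <- sort(.line_tops(page, line_ids, source))
  gaps <- diff(tops)
  gaps <- gaps[gaps > 1e-9]
  if (length(gaps) == 0) return(NA_real_)
  median(gaps)
}

## tight hull of a set of word boxes
.hull_box <- function(words) {
  c(left = min(words$left), top = min(words$top),
    width = max(words$left + words$width) - min(words$left),
    height = max(words$top + words$height) - min(words$top))
}
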