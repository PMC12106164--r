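# Small fixture builders, all programmatic.

# build a page_blocks from a compact word table; words sharing `line` go on
# one line whose box is their hull (optionally inflated, mimicking skew)
make_page <- function(words, page_id = "fix", line_inflate = 0) {
  words <- as.data.frame(words, stringsAsFactors = FALSE)
  if (is.null(words$text_type)) words$text_type <- "PRINTED"
  if (is.null(words$width)) words$width <- 0.02
  if (is.null(words$height)) words$height <- 0.011
  if (is.null(words$confidence)) words$confidence <- 99
  words$id <- sprintf("%s-w%03d", page_id, seq_len(nrow(words)))
  lines <- do.call(rbind, lapply(split(words, words$line), function(w) {
    data.frame(id = sprintf("%s-l%s", page_id, w$line[1]),
               text = paste(w$text[order(w$left)], collapse = " "),
               left = min(w$left), top = min(w$top) - line_inflate,
               width = max(w$left + w$width) - min(w$left),
               height = max(w$top + w$height) - min(w$top) + line_inflate,
               stringsAsFactors = FALSE)
  }))
  words$line_id <- sprintf("%s-l%s", page_id, words$line)
  words$line <- NULL
  page_blocks(page_id, lines = lines, words = words)
}

# word rows for a line of text laid out left-to-right
text_line <- function(text, left, top, line, text_type = "PRINTED",
                      char_w = 0.0045, space_w = 0.0055) {
  toks <- strsplit(text, " ", fixed = TRUE)[[1]]
  x <- left
  rows <- lapply(toks, function(tk) {
    r <- data.frame(text = tk, left = x, top = top, width = nchar(tk) * char_w,
                    text_type = text_type, line = line,
                    stringsAsFactors = FALSE)
    x <<- x + nchar(tk) * char_w + space_w
    r
  })
  do.call(rbind, rows)
}

# minimal raw Textract-dialect JSON with one page, one line, given words
textract_json_one_line <- function(words_text,
                                   text_type = rep("PRINTED", length(words_text))) {
  wids <- sprintf("word-%d", seq_along(words_text))
  blocks <- list(list(
    BlockType = "PAGE", Id = "page-1",
    Geometry = list(BoundingBox = list(Width = 1, Height = 1, Left = 0, Top = 0)),
    Relationships = list(list(Type = "CHILD", Ids = list("line-1")))
  ), list(
    BlockType = "LINE", Id = "line-1", Text = paste(words_text, collapse = " "),
    Geometry = list(BoundingBox = list(Width = 0.5, Height = 0.02,
                                       Left = 0.1, Top = 0.3)),
    Relationships = list(list(Type = "CHILD", Ids = as.list(wids)))
  ))
  for (i in seq_along(words_text)) {
    blocks[[length(blocks) + 1]] <- list(
      BlockType = "WORD", Id = wids[i], Text = words_text[i],
      TextType = text_type[i], Confidence = 98.5,
      Geometry = list(BoundingBox = list(Width = 0.05, Height = 0.02,
                                         Left = 0.1 + 0.06 * (i - 1), Top = 0.3)))
  }
  jsonlite::toJSON(list(Blocks = blocks), auto_unbox = TRUE, digits = NA)
}

# strip volatile pieces so two page_blocks can be compared structurally
page_signature <- function(p) {
  list(p$page_id, p$width_px, p$height_px,
       p$lines[order(p$lines$id), ],
       p$words[order(p$words$id), ])
}
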