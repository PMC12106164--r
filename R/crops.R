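## Crop corpus: convert fractional segment boxes to pixel boxes and, when a
## raster of the scanned page is available, cut out one image per segment
## plus an overview with all segments outlined.

#' Pixel crop boxes for a page record
#'
#' Converts every segment's fractional bounding box to an integer pixel box
#' on the page raster: floor for the left/top edge, ceiling for the
#' right/bottom edge, clipped to the page. Using floor/ceiling guarantees
#' the crop fully covers the fractional box.
#'
#' @param record A `page_record` from [mobilise_page()].
#' @param page The matching [page_blocks] (supplies pixel dimensions).
#' @return A data frame `segment_id`, `left`, `top`, `right`, `bottom`
#'   (pixels, right/bottom exclusive edges), with the page dimensions in
#'   attributes `width_px` / `height_px`.
#' @export
crop_manifest <- function(record, page) {
  W <- page$width_px; H <- page$height_px
  segs <- .record_segments(record)
  rows <- lapply(segs, function(s) {
    b <- s$bbox
    data.frame(
      segment_id = s$id,
      left = max(0L, min(W, as.integer(floor(b[["left"]] * W)))),
      top = max(0L, min(H, as.integer(floor(b[["top"]] * H)))),
      right = max(0L, min(W, as.integer(ceiling((b[["left"]] + b[["width"]]) * W)))),
      bottom = max(0L, min(H, as.integer(ceiling((b[["top"]] + b[["height"]]) * H)))),
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows) == 0) {
    data.frame(segment_id = character(), left = integer(), top = integer(),
               right = integer(), bottom = integer(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  attr(out, "width_px") <- W
  attr(out, "height_px") <- H
  out
}

#' Crop segment images from a page scan
#'
#' Optional step: given the raster of the scanned page (PNG), writes one
#' crop per segment plus an `overview` image with every segment outlined in
#' red.  With no image supplied this is a logged no-op, so the pipeline runs
#' unchanged on block JSON alone.
#'
#' @param manifest A [crop_manifest()] data frame.
#' @param image_path Path to the page raster (PNG), or `NULL` to skip.
#' @param out_dir Directory for the crops, created if needed.
#' @return Character vector of written files, invisibly.
#' @export
crop_images <- function(manifest, image_path = NULL, out_dir = ".") {
  if (is.null(image_path)) {
    message("no page image supplied; skipping crop generation")
    return(invisible(character()))
  }
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to crop images", call. = FALSE)
  }
  img <- png::readPNG(image_path)
  H <- dim(img)[1]; W <- dim(img)[2]
  eW <- attr(manifest, "width_px"); eH <- attr(manifest, "height_px")
  if (!is.null(eW) && (W != eW || H != eH)) {
    stop(sprintf("image dimensions %d x %d do not match page %d x %d",
                 W, H, eW, eH), call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (length(dim(img)) == 2) img <- array(img, c(dim(img), 1))
  written <- character()
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    crop <- img[(m$top + 1):m$bottom, (m$left + 1):m$right, , drop = FALSE]
    f <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9._-]", "_", m$segment_id),
                                   ".png"))
    png::writePNG(crop, f)
    written <- c(written, f)
  }
  ## overview: all segment boxes outlined
  over <- img
  if (dim(over)[3] == 1) over <- array(rep(over, 3), c(H, W, 3))
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    rows <- (m$top + 1):m$bottom; cols <- (m$left + 1):m$right
    edge_r <- unique(c(range(rows))); edge_c <- unique(c(range(cols)))
    over[edge_r, cols, 1] <- 1; over[edge_r, cols, 2:3] <- 0
    over[rows, edge_c, 1] <- 1; over[rows, edge_c, 2:3] <- 0
  }
  f <- file.path(out_dir, "overview.png")
  png::writePNG(over, f)
  invisible(c(written, f))
}
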