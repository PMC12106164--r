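## Association detection: each margin annotation is linked to the plant name
## whose bounding-box Top is vertically nearest its own — the annotations sit
## beside the printed entry they index, so the absolute shortest top-to-top
## distance recovers the intended specimen-to-name pairing.

.seg_top <- function(seg) {
  if (inherits(seg, "segment")) unname(seg$bbox[["top"]])
  else unname(.as_box(seg$bbox)[["top"]])
}

.seg_id <- function(seg) seg$id

#' Link one margin annotation to its plant name
#'
#' Computes `|top(margin) - top(plant)|` against every plant-name segment on
#' the page and links the annotation to the plant attaining the minimum.
#' Equidistant plants are resolved toward the one with the smaller top (the
#' earlier entry): annotations are usually written beside or just below
#' their entry.
#'
#' @param margin A `segment` of kind `"MARGIN"` (header/footer annotations
#'   are not distance-linked; they carry their own plant names).
#' @param plants Non-empty list of `"PLANT_NAME"` segments from the same
#'   page.
#' @param anchor `"top"` (the faithful default) or `"center"` of the boxes.
#' @return A `pair` object: `margin_id`, `plant_id`, `distance`, the index
#'   of the chosen plant, and the full `distances` vector in plant order.
#' @examples
#' # margin at top 0.43 against plant names at 0.22, 0.37, 0.45, 0.57:
#' # distances 0.21, 0.06, 0.02, 0.14 -> linked to the third plant
#' @export
link_margin_to_plant <- function(margin, plants, anchor = c("top", "center")) {
  anchor <- match.arg(anchor)
  if (length(plants) == 0) stop("no plant names to link against", call. = FALSE)
  pos <- function(seg) {
    if (anchor == "top") .seg_top(seg)
    else {
      b <- if (inherits(seg, "segment")) seg$bbox else .as_box(seg$bbox)
      unname(b[["top"]] + b[["height"]] / 2)
    }
  }
  x <- pos(margin)
  tops <- vapply(plants, pos, numeric(1))
  d <- abs(x - tops)
  ## ties are resolved toward the smaller top; equality is taken up to 1e-12
  ## so that floating-point noise cannot flip a genuine tie
  cand <- which(d - min(d) < 1e-12)
  best <- cand[which.min(tops[cand])]
  structure(
    list(margin_id = .seg_id(margin), plant_id = .seg_id(plants[[best]]),
         distance = d[best], plant_index = best, distances = d),
    class = "pair"
  )
}

#' @export
print.pair <- function(x, ...) {
  cat(sprintf("<pair> margin %s -> plant %s (|dTop| = %.3f)\n",
              x$margin_id, x$plant_id, x$distance))
  invisible(x)
}

#' Link every margin annotation on a page
#'
#' Applies [link_margin_to_plant()] independently to each margin segment —
#' several annotations may legitimately claim the same plant name (a folio
#' can hold many specimens of one species).  Output order is fixed by margin
#' top.  When the page has no plant names, every margin lands in the
#' `unlinked` list rather than failing.
#'
#' @param margins List of `"MARGIN"` segments from one page.
#' @param plants List of `"PLANT_NAME"` segments from the same page.
#' @param anchor See [link_margin_to_plant()].
#' @param tie_epsilon When positive, pairs whose two smallest distances
#'   differ by less than this are flagged `ambiguous` (intersecting
#'   annotations that humans also find hard); `0` disables the flag.
#' @return A list with `pairs` (data frame: `margin_id`, `plant_id`,
#'   `distance`, `ambiguous`) and `unlinked` (margin ids).
#' @export
link_page <- function(margins, plants, anchor = "top", tie_epsilon = 0) {
  margins <- margins[order(vapply(margins, .seg_top, numeric(1)))]
  if (length(margins) == 0 || length(plants) == 0) {
    return(list(
      pairs = data.frame(margin_id = character(), plant_id = character(),
                         distance = numeric(), ambiguous = logical(),
                         stringsAsFactors = FALSE),
      unlinked = vapply(margins, .seg_id, "")))
  }
  rows <- lapply(margins, function(m) {
    p <- link_margin_to_plant(m, plants, anchor = anchor)
    amb <- FALSE
    if (tie_epsilon > 0 && length(p$distances) > 1) {
      two <- sort(p$distances)[1:2]
      amb <- (two[2] - two[1]) < tie_epsilon
    }
    data.frame(margin_id = p$margin_id, plant_id = p$plant_id,
               distance = p$distance, ambiguous = amb,
               stringsAsFactors = FALSE)
  })
  list(pairs = do.call(rbind, rows), unlinked = character())
}
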