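## Page structure detection: parity from running titles, header/footer bands,
## side-margin boundary from the x-distribution of word boxes, and removal of
## text bleeding in from the adjacent page of the opening.

#' Built-in running-title patterns
#'
#' Odd-numbered pages of the digitised volumes carry "Lib IV." / "De Herbis"
#' running titles, even-numbered pages "HISTORIA PLANTARUM".  OCR renders
#' these with confusions such as "H1STORIA", "H IST OR1A" or
#' "H I S T O R I A", so matching is fuzzy: case-folded, `1 -> I` and
#' `0 -> O` mapped, spaces stripped, then a bounded edit distance.
#'
#' @return A list of `{parity, pattern, max_edits}` entries, first match wins.
#' @seealso [read_title_patterns()] for per-volume YAML variants.
#' @export
default_title_patterns <- function() {
  list(
    list(parity = "EVEN", pattern = "HISTORIA PLANTARUM", max_edits = 2),
    list(parity = "EVEN", pattern = "HISTORIA",           max_edits = 2),
    list(parity = "ODD",  pattern = "DE HERBIS",          max_edits = 2),
    list(parity = "ODD",  pattern = "LIB IV",             max_edits = 1)
  )
}

#' Read title patterns from a YAML file
#'
#' The file holds a list of `{parity, pattern, max_edits}` entries; volumes
#' and sections with different running titles get their own files.
#'
#' @param path Path to a YAML file.
#' @return A pattern list as produced by [default_title_patterns()].
#' @export
read_title_patterns <- function(path) {
  pats <- yaml::read_yaml(path)
  for (p in pats) {
    stopifnot(p$parity %in% c("ODD", "EVEN"), is.character(p$pattern))
  }
  lapply(pats, function(p) {
    list(parity = p$parity, pattern = p$pattern,
         max_edits = as.integer(p$max_edits %||% 2))
  })
}

## fold OCR confusions: uppercase, 1->I, 0->O, strip spaces
.fold_title <- function(x) {
  gsub("[[:space:]]+", "", chartr("10", "IO", toupper(x)))
}

#' Classify page parity from running titles
#'
#' Scans printed lines in the top band of the page (default 15% of page
#' height) for a fuzzy match against the per-parity running-title patterns
#' and returns the parity of the first match.  `UNKNOWN` is a value, not an
#' error: pages with no recognisable title flow through with the configured
#' fallback margin side.
#'
#' @param page A [page_blocks] object.
#' @param patterns Title patterns, see [default_title_patterns()].
#' @param cfg A [mobilise_config()] list (uses `title_band_frac`).
#' @return A `page_group` object: `value` one of `"ODD"`, `"EVEN"`,
#'   `"UNKNOWN"`, and `evidence` (matched line id and text, or empty).
#' @examples
#' pg <- generate_page(synthetic_page_spec(seed = 1, parity = "EVEN"))$page
#' classify_page_group(pg)$value
#' @export
classify_page_group <- function(page, patterns = default_title_patterns(),
                                cfg = mobilise_config()) {
  stopifnot(inherits(page, "page_blocks"))
  out <- function(value, evidence = list()) {
    structure(list(value = value, evidence = evidence), class = "page_group")
  }
  if (nrow(page$lines) == 0) return(out("UNKNOWN"))
  tops <- .line_tops(page, source = cfg$line_top_source)
  cand <- page$lines[tops <= cfg$title_band_frac, , drop = FALSE]
  if (nrow(cand) == 0) return(out("UNKNOWN"))
  printed <- vapply(cand$id, function(lid) {
    w <- page$words[page$words$line_id == lid, ]
    nrow(w) == 0 || mean(w$text_type == "PRINTED") >= 0.5
  }, logical(1))
  cand <- cand[printed, , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    folded <- .fold_title(cand$text[i])
    if (!nzchar(folded)) next
    for (p in patterns) {
      d <- adist(.fold_title(p$pattern), folded, partial = TRUE)[1, 1]
      if (d <= p$max_edits) {
        return(out(p$parity, list(line_id = cand$id[i], text = cand$text[i],
                                  pattern = p$pattern, edits = as.integer(d))))
      }
    }
  }
  out("UNKNOWN")
}

#' @export
print.page_group <- function(x, ...) {
  cat("<page_group>", x$value)
  if (length(x$evidence)) cat(sprintf(" (title %s, %d edit(s))",
                                      dQuote(x$evidence$text), x$evidence$edits))
  cat("\n")
  invisible(x)
}

.group_value <- function(group) {
  if (inherits(group, "page_group")) group$value else as.character(group)
}

.implied_margin_side <- function(group, cfg) {
  switch(.group_value(group),
         EVEN = cfg$margin_side_even,
         ODD = cfg$margin_side_odd,
         NA_character_)
}

## cluster word x-intervals: merge intervals closer than min_gap, return one
## row per cluster with its envelope and word count, ordered left to right
.x_clusters <- function(words, min_gap) {
  if (nrow(words) == 0) return(NULL)
  iv <- data.frame(left = words$left, right = words$left + words$width)
  iv <- iv[order(iv$left), ]
  cl_left <- iv$left[1]; cl_right <- iv$right[1]; cl_n <- 1L
  out <- NULL
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$left[i] - cl_right > min_gap) {
      out <- rbind(out, data.frame(left = cl_left, right = cl_right, n = cl_n))
      cl_left <- iv$left[i]; cl_right <- iv$right[i]; cl_n <- 1L
    } else {
      cl_right <- max(cl_right, iv$right[i]); cl_n <- cl_n + 1L
    }
  }
  rbind(out, data.frame(left = cl_left, right = cl_right, n = cl_n))
}

#' Locate the side-margin boundary from word x-coordinates
#'
#' Handwritten specimen references sit in the outer side margin, separated
#' from the printed body by white space.  The word x-intervals of the page
#' are merged into clusters; the cluster holding the most words is the body,
#' and on the margin side implied by page parity the boundary is placed at
#' the midpoint of the largest gap between the body envelope and the
#' outlying cluster(s).  When no cluster is separated by more than
#' `cfg$min_gap` (default 2% of page width) the boundary collapses onto the
#' body envelope edge and the page has no margin words.
#'
#' @param page A [page_blocks] object with at least one line.
#' @param group A `page_group` (or its value).  `UNKNOWN` pages use
#'   whichever side shows the larger separation.
#' @param cfg A [mobilise_config()] list.
#' @return A list: `margin_boundary_x`, `margin_side` (`"LEFT"`/`"RIGHT"`),
#'   `body_envelope` (`c(left, right)`), `has_margin`.
#' @export
detect_margin_boundary <- function(page, group = "UNKNOWN",
                                   cfg = mobilise_config()) {
  stopifnot(inherits(page, "page_blocks"))
  if (nrow(page$lines) == 0) stop("layout error: page has no lines", call. = FALSE)
  tops <- .line_tops(page, source = cfg$line_top_source)
  mid_ids <- page$lines$id[tops >= cfg$header_frac & tops <= cfg$footer_frac]
  words <- page$words[page$words$line_id %in% mid_ids, , drop = FALSE]
  if (nrow(words) == 0) words <- page$words
  if (nrow(words) == 0) stop("layout error: page has no words", call. = FALSE)

  cl <- .x_clusters(words, cfg$min_gap)
  body_i <- which.max(cl$n + cl$right - cl$left)  # most words, width breaks ties
  body <- cl[body_i, ]

  side_gap <- function(side) {
    ## largest inter-cluster gap on the given side of the body, with its span
    if (side == "LEFT") {
      idx <- which(cl$right < body$left)
      edges <- c(sort(c(cl$left[idx], cl$right[idx])), body$left)
    } else {
      idx <- which(cl$left > body$right)
      edges <- c(body$right, sort(c(cl$left[idx], cl$right[idx])))
    }
    if (length(idx) == 0) return(NULL)
    gaps <- diff(edges)
    ## keep only gaps between clusters, skipping each cluster's own width:
    ## LEFT edges run (c1.l, c1.r, ..., body.left) so between-gaps sit at even
    ## positions; RIGHT edges run (body.right, c1.l, c1.r, ...) so at odd ones
    between <- seq(if (side == "LEFT") 2 else 1, length(gaps), by = 2)
    g <- between[which.max(gaps[between])]
    list(size = gaps[g], lo = edges[g], hi = edges[g + 1])
  }

  side <- .implied_margin_side(group, cfg)
  if (is.na(side)) {
    gl <- side_gap("LEFT"); gr <- side_gap("RIGHT")
    side <- if (is.null(gl) && is.null(gr)) cfg$margin_side_odd
            else if (is.null(gr) || (!is.null(gl) && gl$size >= gr$size)) "LEFT"
            else "RIGHT"
  }
  g <- side_gap(side)
  if (is.null(g) || g$size <= cfg$min_gap) {
    boundary <- if (side == "LEFT") body$left else body$right
    has_margin <- FALSE
  } else {
    boundary <- (g$lo + g$hi) / 2
    has_margin <- TRUE
  }
  list(margin_boundary_x = boundary, margin_side = side,
       body_envelope = c(left = body$left, right = body$right),
       has_margin = has_margin)
}

#' Detect the full page layout
#'
#' Assigns every line of the page to exactly one of five classes:
#' \describe{
#'   \item{header}{lines at or above the running title, or with top above
#'     `cfg$header_frac` (default 0.06);}
#'   \item{footer}{lines with top below `cfg$footer_frac` (default 0.92);}
#'   \item{margin}{lines beyond the side-margin boundary on the parity-implied
#'     side;}
#'   \item{discarded}{bleed — lines whose whole box lies more than
#'     `cfg$bleed_frac` (default 0.02) outside the body envelope on the
#'     non-margin side, i.e. text showing through from the adjacent page;}
#'   \item{body}{everything else.}
#' }
#'
#' @param page A [page_blocks] object with at least one line.
#' @param group A `page_group` from [classify_page_group()]; `UNKNOWN` is
#'   allowed.
#' @param cfg A [mobilise_config()] list.
#' @return A `page_layout` object: bands, `margin_boundary_x`, `margin_side`,
#'   `body_region` box, `discarded_line_ids`, and an `assignment` table
#'   (`line_id`, `class`) partitioning the page's lines.
#' @export
detect_layout <- function(page, group = classify_page_group(page, cfg = cfg),
                          cfg = mobilise_config()) {
  stopifnot(inherits(page, "page_blocks"))
  if (nrow(page$lines) == 0) stop("layout error: page has no lines", call. = FALSE)
  tops <- .line_tops(page, source = cfg$line_top_source)
  ids <- page$lines$id
  cls <- rep(NA_character_, length(ids))

  title_top <- NA_real_
  if (inherits(group, "page_group") && length(group$evidence)) {
    title_top <- tops[match(group$evidence$line_id, ids)]
  }
  is_header <- tops < cfg$header_frac
  if (is.finite(title_top)) is_header <- is_header | tops <= title_top + 1e-9
  cls[is_header] <- "header"
  cls[is.na(cls) & tops > cfg$footer_frac] <- "footer"

  mb <- detect_margin_boundary(page, group, cfg)
  line_x <- vapply(ids, function(lid) {
    w <- page$words[page$words$line_id == lid, ]
    if (nrow(w) == 0) return(page$lines$left[match(lid, ids)])
    median(w$left + w$width / 2)
  }, numeric(1))
  in_margin <- if (mb$margin_side == "LEFT") line_x < mb$margin_boundary_x
               else line_x > mb$margin_boundary_x
  cls[is.na(cls) & mb$has_margin & in_margin] <- "margin"

  ## bleed: whole line box beyond the body envelope on the non-margin side
  line_l <- page$lines$left; line_r <- page$lines$left + page$lines$width
  bleed <- if (mb$margin_side == "LEFT") {
    line_l > mb$body_envelope[["right"]] + cfg$bleed_frac
  } else {
    line_r < mb$body_envelope[["left"]] - cfg$bleed_frac
  }
  cls[is.na(cls) & bleed] <- "discarded"
  cls[is.na(cls)] <- "body"

  body_ids <- ids[cls == "body"]
  body_region <- if (length(body_ids) > 0) {
    .hull_box(page$words[page$words$line_id %in% body_ids, , drop = FALSE])
  } else {
    c(left = NA_real_, top = NA_real_, width = NA_real_, height = NA_real_)
  }
  band <- function(which) {
    sel <- cls == which
    if (!any(sel)) {
      if (which == "header") c(0, cfg$header_frac) else c(cfg$footer_frac, 1)
    } else {
      ln <- page$lines[sel, , drop = FALSE]
      if (which == "header") c(0, max(ln$top + ln$height)) else c(min(ln$top), 1)
    }
  }
  structure(
    list(page_id = page$page_id,
         group = .group_value(group),
         header_band = band("header"), footer_band = band("footer"),
         margin_boundary_x = mb$margin_boundary_x, margin_side = mb$margin_side,
         body_envelope = mb$body_envelope, body_region = body_region,
         discarded_line_ids = ids[cls == "discarded"],
         assignment = data.frame(line_id = ids, class = cls,
                                 stringsAsFactors = FALSE)),
    class = "page_layout"
  )
}

#' @export
print.page_layout <- function(x, ...) {
  tab <- table(factor(x$assignment$class,
                      levels = c("header", "body", "margin", "footer", "discarded")))
  cat(sprintf("<page_layout> %s (%s): margin %s at x = %.3f\n",
              x$page_id, x$group, x$margin_side, x$margin_boundary_x))
  cat("  lines:", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

.layout_lines <- function(layout, class) {
  layout$assignment$line_id[layout$assignment$class == class]
}
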