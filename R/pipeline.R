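## Orchestration: configuration, per-page mobilisation into the JSON record
## schema, corpus runs with Table-1-style summaries, and record (de)serialisation.

#' Pipeline configuration
#'
#' Every threshold of the workflow in one place.  All lengths are fractions
#' of page size, so the settings are scale-free and tunable per corpus.
#'
#' @param header_frac Lines with top above this are header furniture
#'   (default 0.06).
#' @param footer_frac Lines with top below this are footer (default 0.92).
#' @param title_band_frac Band scanned for running titles (default 0.15).
#' @param min_gap Minimum horizontal white-space separating the margin word
#'   cluster from the body (default 0.02 of page width).
#' @param bleed_frac How far outside the body envelope (non-margin side) a
#'   line must lie to be discarded as adjacent-page bleed (default 0.02).
#' @param para_gap_mult New paragraph when the inter-line gap exceeds this
#'   multiple of the line pitch (default 1.6).
#' @param margin_gap_mult Same, for margin / header / footer segments
#'   (default 2.0).
#' @param indent_frac Minimum first-line indent marking a plant name
#'   (default 0.015).
#' @param max_name_lines Maximum printed lines of an indented plant name
#'   (default 3).
#' @param abbreviation_lexicon First tokens that mark a flush-left plant
#'   name (botanical author abbreviations).
#' @param hs_pattern Regex that opens a herbarium-reference margin segment.
#' @param default_pitch Fallback line pitch when a page has too few lines to
#'   estimate one (default 0.015).
#' @param line_top_source `"word_median"` (robust to skew-inflated line
#'   boxes; the default) or `"line_box"` (the ablation).
#' @param margin_side_even,margin_side_odd Which side the outer margin falls
#'   on per parity; default LEFT on even pages, RIGHT on odd.
#' @param iou_threshold Evaluation IoU threshold, strict `>` (default 0.7).
#' @param tie_epsilon Flag pairs whose two smallest distances differ by less
#'   than this as ambiguous; 0 (default) disables.
#' @param distance_anchor `"top"` (faithful default) or `"center"` boxes for
#'   association distances.
#' @param min_confidence Words below this confidence are flagged (never
#'   dropped); default 0 since the provider scores are not consumed by the
#'   geometry stages.
#' @return A `mobilise_config` list.
#' @export
mobilise_config <- function(header_frac = 0.06, footer_frac = 0.92,
                            title_band_frac = 0.15, min_gap = 0.02,
                            bleed_frac = 0.02, para_gap_mult = 1.6,
                            margin_gap_mult = 2.0, indent_frac = 0.015,
                            max_name_lines = 3,
                            abbreviation_lexicon = c("J.B.", "C.B.", "C.B.P.",
                                                     "Ger.", "Park.", "Matth.",
                                                     "Lob."),
                            hs_pattern = "^\\s*H\\s*[.,]?\\s*S\\s*[.,]?",
                            default_pitch = 0.015,
                            line_top_source = c("word_median", "line_box"),
                            margin_side_even = "LEFT",
                            margin_side_odd = "RIGHT",
                            iou_threshold = 0.7, tie_epsilon = 0,
                            distance_anchor = "top", min_confidence = 0) {
  structure(list(
    header_frac = header_frac, footer_frac = footer_frac,
    title_band_frac = title_band_frac, min_gap = min_gap,
    bleed_frac = bleed_frac, para_gap_mult = para_gap_mult,
    margin_gap_mult = margin_gap_mult, indent_frac = indent_frac,
    max_name_lines = max_name_lines,
    abbreviation_lexicon = abbreviation_lexicon, hs_pattern = hs_pattern,
    default_pitch = default_pitch,
    line_top_source = match.arg(line_top_source),
    margin_side_even = margin_side_even, margin_side_odd = margin_side_odd,
    iou_threshold = iou_threshold, tie_epsilon = tie_epsilon,
    distance_anchor = distance_anchor, min_confidence = min_confidence),
    class = "mobilise_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys missing from the file keep their [mobilise_config()] defaults.
#'
#' @param path Path to a YAML file of configuration keys.
#' @return A `mobilise_config` list.
#' @export
read_mobilise_config <- function(path) {
  vals <- yaml::read_yaml(path)
  base <- mobilise_config()
  unknown <- setdiff(names(vals), names(base))
  if (length(unknown) > 0) {
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "),
            call. = FALSE)
    vals <- vals[setdiff(names(vals), unknown)]
  }
  structure(modifyList(unclass(base), vals), class = "mobilise_config")
}

#' Mobilise one page into a structured record
#'
#' Runs the full per-page workflow — parity classification, layout
#' detection, paragraph / plant-name / margin / header / footer
#' segmentation, reference parsing and nearest-top association — and emits
#' the page record: `header`, `footer`, `plants` and `margins` elements with
#' unique ids and transcriptions, plus the `pairs` element holding the
#' margin-to-plant links.  Segment ids are `"<page_id>:<kind>:<ordinal>"`,
#' stable across reruns.  Deterministic given the configuration.
#'
#' @param page A [page_blocks] object.
#' @param cfg A [mobilise_config()] list.
#' @param patterns Running-title patterns; see [default_title_patterns()].
#' @return A `page_record` list.
#' @export
mobilise_page <- function(page, cfg = mobilise_config(),
                          patterns = default_title_patterns()) {
  stopifnot(inherits(page, "page_blocks"))
  empty_record <- function(group) {
    structure(list(page_id = page$page_id, group = group,
                   header = list(), footer = list(), plants = list(),
                   margins = list(),
                   pairs = data.frame(margin_id = character(),
                                      plant_id = character(),
                                      distance = numeric(),
                                      ambiguous = logical(),
                                      stringsAsFactors = FALSE),
                   unlinked = character()),
              class = "page_record")
  }
  if (nrow(page$lines) == 0) return(empty_record("UNKNOWN"))

  group <- classify_page_group(page, patterns, cfg)
  layout <- tryCatch(detect_layout(page, group, cfg),
                     error = function(e) {
                       stop("page ", page$page_id, ": ", conditionMessage(e),
                            call. = FALSE)
                     })

  paras <- segment_paragraphs(page, layout, cfg)
  body_left <- layout$body_envelope[["left"]]
  is_name <- vapply(paras, classify_plant_name, logical(1),
                    body_left = body_left, page = page, cfg = cfg)
  plants <- paras[is_name]
  for (i in seq_along(plants)) plants[[i]]$kind <- "PLANT_NAME"
  margins <- segment_margins(page, layout, cfg)
  bands <- segment_headers_footers(page, layout, cfg)
  headers <- Filter(function(s) s$kind == "HEADER", bands)
  footers <- Filter(function(s) s$kind == "FOOTER", bands)

  assign_ids <- function(segs, token) {
    segs <- segs[order(vapply(segs, .seg_top, numeric(1)))]
    for (i in seq_along(segs)) {
      segs[[i]]$id <- sprintf("%s:%s:%d", page$page_id, token, i)
    }
    segs
  }
  plants <- assign_ids(plants, "plant")
  margins <- assign_ids(margins, "margin")
  headers <- assign_ids(headers, "header")
  footers <- assign_ids(footers, "footer")

  links <- link_page(margins, plants, anchor = cfg$distance_anchor,
                     tie_epsilon = cfg$tie_epsilon)

  entry <- function(s, refs = FALSE) {
    e <- list(id = s$id, text = s$text, bbox = as.list(s$bbox))
    if (length(s$handwritten_word_ids) > 0) {
      e$handwritten_word_ids <- s$handwritten_word_ids
    }
    if (refs) e$parsed_references <- parse_specimen_reference(s$text)
    e
  }
  structure(
    list(page_id = page$page_id, group = .group_value(group),
         header = lapply(headers, entry), footer = lapply(footers, entry),
         plants = lapply(plants, entry),
         margins = lapply(margins, entry, refs = TRUE),
         pairs = links$pairs, unlinked = links$unlinked),
    class = "page_record")
}

#' @export
print.page_record <- function(x, ...) {
  cat(sprintf(
    "<page_record> %s (%s): %d plant(s), %d margin(s), %d header(s), %d footer(s), %d pair(s)\n",
    x$page_id, x$group, length(x$plants), length(x$margins),
    length(x$header), length(x$footer), nrow(.pairs_df(x))))
  invisible(x)
}

#' Summary counts for a corpus of page records
#'
#' The headline bookkeeping of a mobilisation run: pages, header / footer /
#' margin segments, printed plant names (plant-name segments in the page
#' body) and handwritten plant names (the annotation segments in headers and
#' footers, which name species missing from the printed list).  Each count
#' is an exact sum over the per-page records.
#'
#' @param records List of `page_record`s, or (alternatively) named counts
#'   passed directly via `...` to build a summary by hand.
#' @param ... Named counts (`pages`, `headers_segments`, `footers_segments`,
#'   `margins_segments`, `printed_plant_names`, `handwritten_plant_names`,
#'   `specimen_references`) when `records` is missing.
#' @return A `corpus_summary` object.
#' @seealso [aggregate_summaries()] to combine per-volume summaries.
#' @export
corpus_summary <- function(records, ...) {
  fields <- c("pages", "headers_segments", "footers_segments",
              "margins_segments", "printed_plant_names",
              "handwritten_plant_names", "specimen_references")
  if (missing(records)) {
    vals <- list(...)
    stopifnot(all(names(vals) %in% fields))
    out <- setNames(as.list(rep(0L, length(fields))), fields)
    out[names(vals)] <- lapply(vals, as.numeric)
    return(structure(out, class = "corpus_summary"))
  }
  if (inherits(records, "page_record")) records <- list(records)
  n_refs <- sum(vapply(records, function(r) {
    sum(vapply(r$margins, function(m) {
      refs <- m$parsed_references
      if (is.null(refs)) nrow(parse_specimen_reference(m$text)$references)
      else nrow(refs$references)
    }, numeric(1)))
  }, numeric(1)))
  structure(list(
    pages = length(records),
    headers_segments = sum(vapply(records, function(r) length(r$header), numeric(1))),
    footers_segments = sum(vapply(records, function(r) length(r$footer), numeric(1))),
    margins_segments = sum(vapply(records, function(r) length(r$margins), numeric(1))),
    printed_plant_names = sum(vapply(records, function(r) length(r$plants), numeric(1))),
    handwritten_plant_names = sum(vapply(records, function(r) {
      length(r$header) + length(r$footer)
    }, numeric(1))),
    specimen_references = n_refs),
    class = "corpus_summary")
}

#' Aggregate corpus summaries
#'
#' Sums every count across summaries — e.g. combining per-volume runs into
#' the totals for a whole work.
#'
#' @param ... `corpus_summary` objects, or a single list of them.
#' @return A combined `corpus_summary`.
#' @examples
#' v1 <- corpus_summary(printed_plant_names = 4130, handwritten_plant_names = 2968)
#' v2 <- corpus_summary(printed_plant_names = 3470, handwritten_plant_names = 1572)
#' aggregate_summaries(v1, v2)$printed_plant_names  # 7600
#' @export
aggregate_summaries <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "corpus_summary")) xs <- xs[[1]]
  stopifnot(length(xs) >= 1, all(vapply(xs, inherits, NA, "corpus_summary")))
  out <- xs[[1]]
  for (x in xs[-1]) {
    for (f in names(out)) out[[f]] <- out[[f]] + x[[f]]
  }
  out
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat("<corpus_summary>\n")
  for (f in names(x)) cat(sprintf("  %-24s %g\n", f, x[[f]]))
  invisible(x)
}

#' Mobilise a corpus of pages
#'
#' Runs [mobilise_page()] over every page; a failing page is logged (to
#' stderr), counted, and excluded from the summary while the run continues.
#'
#' @param pages List of [page_blocks] objects, or a directory of
#'   Textract-dialect JSON files (one document per file).
#' @param cfg A [mobilise_config()] list.
#' @param patterns Running-title patterns.
#' @param quiet Suppress per-page progress messages.
#' @return A list: `records` (per-page `page_record`s), `summary`
#'   (a [corpus_summary()]), `failed` (page ids with errors).
#' @export
mobilise_corpus <- function(pages, cfg = mobilise_config(),
                            patterns = default_title_patterns(),
                            quiet = TRUE) {
  if (is.character(pages) && length(pages) == 1 && dir.exists(pages)) {
    files <- sort(list.files(pages, pattern = "\\.json$", full.names = TRUE))
    files <- files[!basename(files) %in% c("ground_truth.json", "manifest.json")]
    pages <- unlist(lapply(files, parse_textract_json), recursive = FALSE)
  }
  if (inherits(pages, "page_blocks")) pages <- list(pages)
  if (length(pages) == 0) stop("empty corpus", call. = FALSE)
  records <- list(); failed <- character()
  for (pg in pages) {
    rec <- tryCatch(mobilise_page(pg, cfg, patterns), error = function(e) {
      message("page ", pg$page_id, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(rec)) failed <- c(failed, pg$page_id)
    else {
      records[[length(records) + 1L]] <- rec
      if (!quiet) {
        message(sprintf("page %s: %d plants, %d margins, %d pairs",
                        rec$page_id, length(rec$plants), length(rec$margins),
                        nrow(.pairs_df(rec))))
      }
    }
  }
  list(records = records, summary = corpus_summary(records), failed = failed)
}

#' Write page records to JSON
#'
#' One JSON array, one object per page, in the published output schema
#' (`header`, `footer`, `plants`, `margins`, `pairs`, `unlinked`, `group`).
#' Byte-stable across reruns of the same inputs.
#'
#' @param records List of `page_record`s (ground-truth records use the same
#'   schema).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_records <- function(records, path) {
  ser <- lapply(records, function(r) {
    r <- unclass(r)
    r$pairs <- if (nrow(.pairs_df(r)) == 0) list() else {
      df <- r$pairs
      lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
    }
    r$unlinked <- as.list(r$unlinked %||% character())
    r$margins <- lapply(r$margins, function(m) {
      if (!is.null(m$parsed_references)) {
        refs <- m$parsed_references$references
        m$parsed_references <- list(
          references = lapply(seq_len(nrow(refs)), function(i) {
            as.list(refs[i, , drop = FALSE])
          }),
          residue = as.list(m$parsed_references$residue))
      }
      m
    })
    r
  })
  writeLines(jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null", na = "null"),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read page records from JSON
#'
#' @param path A file written by [write_records()] (or ground truth in the
#'   same schema).
#' @return A list of `page_record`s.
#' @export
read_records <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    pairs <- if (length(r$pairs) == 0) {
      data.frame(margin_id = character(), plant_id = character(),
                 distance = numeric(), stringsAsFactors = FALSE)
    } else {
      ## keep whatever pair fields were written (distance, ambiguous, ...)
      do.call(rbind, lapply(r$pairs, function(p) {
        as.data.frame(p, stringsAsFactors = FALSE)
      }))
    }
    r$pairs <- pairs
    r$unlinked <- as.character(unlist(r$unlinked))
    for (field in c("header", "footer", "plants", "margins")) {
      r[[field]] <- lapply(r[[field]], function(e) {
        if (!is.null(e$handwritten_word_ids)) {
          e$handwritten_word_ids <- as.character(unlist(e$handwritten_word_ids))
        }
        e
      })
    }
    r$margins <- lapply(r$margins, function(m) {
      if (!is.null(m$parsed_references)) {
        refs <- m$parsed_references$references
        m$parsed_references <- list(
          references = if (length(refs) == 0) {
            data.frame(volume = integer(), folio = integer(),
                       specimen = integer())
          } else {
            do.call(rbind, lapply(refs, function(x) {
              data.frame(volume = as.integer(x$volume),
                         folio = as.integer(x$folio),
                         specimen = as.integer(x$specimen %||% NA_integer_),
                         stringsAsFactors = FALSE)
            }))
          },
          residue = as.character(unlist(m$parsed_references$residue)))
      }
      m
    })
    structure(r, class = "page_record")
  })
}
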