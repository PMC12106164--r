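## Evaluation protocol: character error rate for transcriptions, IoU-based
## one-to-one segment matching, and precision / recall / F1 per category and
## for the margin-to-plant relationships.

#' Character error rate (CER)
#'
#' `100 * Levenshtein(gt, hyp) / nchar(gt)`: the number of character
#' insertions, deletions and substitutions needed to turn the hypothesis
#' into the ground truth, divided by the ground-truth character count and
#' expressed as a percentage.  Values above 100 are possible with many
#' insertions.  Both strings are normalised to Unicode NFC before
#' comparison, so composed and decomposed encodings of the same text score
#' zero.  Edit costs are uniform (insert = delete = substitute = 1).
#'
#' @param ground_truth Reference transcription(s); must be non-empty.
#' @param hypothesis System transcription(s); recycled against
#'   `ground_truth`.
#' @return CER percentage(s), one per pair.
#' @examples
#' cer("150.26. 105.37", "156.26, 105.37")  # 2 substitutions / 14 chars
#' @export
cer <- function(ground_truth, hypothesis) {
  gt <- stringi::stri_trans_nfc(as.character(ground_truth))
  hyp <- stringi::stri_trans_nfc(as.character(hypothesis))
  n <- max(length(gt), length(hyp))
  gt <- rep_len(gt, n); hyp <- rep_len(hyp, n)
  if (any(is.na(gt)) || any(nchar(gt) == 0)) {
    stop("ground truth transcription must be non-empty", call. = FALSE)
  }
  dist <- vapply(seq_len(n), function(i) drop(adist(gt[i], hyp[i])), numeric(1))
  100 * dist / nchar(gt)
}

#' Intersection over union of two boxes
#'
#' @param a,b Fractional bounding boxes ([bbox()] vectors or
#'   `{left, top, width, height}` lists).
#' @return Overlap area / union area in `[0, 1]`; 0 for disjoint boxes and,
#'   by convention, for a zero-area union.
#' @export
iou <- function(a, b) {
  a <- .as_box(a); b <- .as_box(b)
  ix <- min(a[["left"]] + a[["width"]], b[["left"]] + b[["width"]]) -
    max(a[["left"]], b[["left"]])
  iy <- min(a[["top"]] + a[["height"]], b[["top"]] + b[["height"]]) -
    max(a[["top"]], b[["top"]])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  union <- a[["width"]] * a[["height"]] + b[["width"]] * b[["height"]] - inter
  if (union <= 0) return(0)
  inter / union
}

#' Match predicted segments to ground truth by IoU
#'
#' Greedy one-to-one matching: among all (prediction, ground truth) pairs
#' whose IoU strictly exceeds the threshold, repeatedly accept the pair with
#' the highest IoU and remove both segments from further consideration.
#' Unmatched predictions are false positives, unmatched ground-truth
#' segments false negatives.
#'
#' @param pred,gt Lists of segments (anything with `id` and `bbox`), from
#'   the same page and category.
#' @param threshold IoU threshold, strict `>`; default 0.7.
#' @return A list: `matches` (data frame `pred_id`, `gt_id`, `iou`),
#'   `unmatched_pred`, `unmatched_gt`, `mean_iou` over matched pairs
#'   (`NA` when none matched).
#' @export
match_segments <- function(pred, gt, threshold = 0.7) {
  np <- length(pred); ng <- length(gt)
  pid <- vapply(pred, .seg_id, ""); gid <- vapply(gt, .seg_id, "")
  matches <- data.frame(pred_id = character(), gt_id = character(),
                        iou = numeric(), stringsAsFactors = FALSE)
  if (np > 0 && ng > 0) {
    m <- matrix(0, np, ng)
    for (i in seq_len(np)) for (j in seq_len(ng)) {
      m[i, j] <- iou(if (inherits(pred[[i]], "segment")) pred[[i]]$bbox else pred[[i]]$bbox,
                     if (inherits(gt[[j]], "segment")) gt[[j]]$bbox else gt[[j]]$bbox)
    }
    repeat {
      best <- which.max(m)
      if (length(best) == 0 || m[best] <= threshold) break
      i <- (best - 1) %% np + 1; j <- (best - 1) %/% np + 1
      matches <- rbind(matches, data.frame(pred_id = pid[i], gt_id = gid[j],
                                           iou = m[best], stringsAsFactors = FALSE))
      m[i, ] <- -Inf; m[, j] <- -Inf
    }
  }
  list(matches = matches,
       unmatched_pred = setdiff(pid, matches$pred_id),
       unmatched_gt = setdiff(gid, matches$gt_id),
       mean_iou = if (nrow(matches) > 0) mean(matches$iou) else NA_real_)
}

#' F1 score from precision and recall
#'
#' `F1 = 2 * P * R / (P + R)`, defined as 0 when `P + R = 0`.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return The harmonic mean of precision and recall.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0, 2 * precision * recall / (precision + recall))
}

#' Precision, recall and F1 from match counts
#'
#' `P = tp / (tp + fp)`, `R = tp / (tp + fn)`, each defined as 0 when its
#' denominator is 0, combined into F1 by [f1_score()].
#'
#' @param tp,fp,fn Non-negative counts of true positives, false positives
#'   and false negatives.
#' @return Named vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  c(precision = p, recall = r, f1 = f1_score(p, r))
}

#' Evaluate margin-to-plant relationships
#'
#' A predicted pair counts as a true positive only when both of its
#' endpoints were IoU-matched to ground-truth segments *and* the ground
#' truth links those same two segments.  Precision is over predicted pairs,
#' recall over ground-truth pairs.
#'
#' @param pred_pairs,gt_pairs Data frames with `margin_id` and `plant_id`
#'   columns.
#' @param segment_map Named character vector mapping predicted segment ids
#'   to their matched ground-truth ids (from [match_segments()] matches).
#' @return Named vector `c(precision, recall, f1)`.
#' @export
evaluate_relationships <- function(pred_pairs, gt_pairs, segment_map) {
  gt_keys <- paste(gt_pairs$margin_id, gt_pairs$plant_id, sep = "\r")
  tp <- 0L
  for (i in seq_len(nrow(pred_pairs))) {
    gm <- segment_map[pred_pairs$margin_id[i]]
    gp <- segment_map[pred_pairs$plant_id[i]]
    if (!is.na(gm) && !is.na(gp) && paste(gm, gp, sep = "\r") %in% gt_keys) {
      tp <- tp + 1L
    }
  }
  precision_recall_f1(tp, nrow(pred_pairs) - tp, nrow(gt_pairs) - tp)
}

.record_segments <- function(record) {
  segs <- list()
  add <- function(entries, kind) {
    for (e in entries) {
      segs[[length(segs) + 1L]] <<- list(id = e$id, kind = kind,
                                         bbox = .as_box(e$bbox),
                                         text = e$text %||% "")
    }
  }
  add(record$header, "HEADER"); add(record$footer, "FOOTER")
  add(record$plants, "PLANT_NAME"); add(record$margins, "MARGIN")
  segs
}

.SEG_KINDS <- c("HEADER", "FOOTER", "MARGIN", "PLANT_NAME")

#' Evaluate mobilised page records against ground truth
#'
#' Runs the full evaluation protocol over a corpus: per category
#' (headers, footers, side margins, plant names) predicted segments are
#' IoU-matched one-to-one to ground truth within each page, precision /
#' recall / F1 and the mean IoU over matches are accumulated, relationships
#' are scored over matched endpoints with [evaluate_relationships()], and
#' CER is computed between the transcriptions of every matched segment pair,
#' reported per category.
#'
#' @param pred,gt Lists of page records (same shape as [mobilise_page()]
#'   output; ground truth uses the identical schema so pipeline outputs are
#'   directly evaluable).  Pages are aligned by `page_id`.
#' @param iou_threshold IoU match threshold, strict `>`; default 0.7.
#' @return An `eval_report`: `per_category` data frame (`category`,
#'   `total_gt`, `recall`, `precision`, `f1`, `mean_iou`, `mean_cer`),
#'   `relationships` row, overall `mean_iou`, and `cer_by_type`.
#' @export
evaluate_corpus <- function(pred, gt, iou_threshold = 0.7) {
  if (!is.null(pred$page_id)) pred <- list(pred)
  if (!is.null(gt$page_id)) gt <- list(gt)
  pid <- vapply(pred, function(r) r$page_id, "")
  gid <- vapply(gt, function(r) r$page_id, "")

  tp <- fp <- fn <- setNames(rep(0L, length(.SEG_KINDS)), .SEG_KINDS)
  ious <- setNames(rep(list(numeric()), length(.SEG_KINDS)), .SEG_KINDS)
  cers <- setNames(rep(list(numeric()), length(.SEG_KINDS)), .SEG_KINDS)
  rel_tp <- rel_pred <- rel_gt <- 0L

  for (pg in union(pid, gid)) {
    pr <- if (pg %in% pid) pred[[match(pg, pid)]] else NULL
    gr <- if (pg %in% gid) gt[[match(pg, gid)]] else NULL
    ps <- if (is.null(pr)) list() else .record_segments(pr)
    gs <- if (is.null(gr)) list() else .record_segments(gr)
    seg_map <- character()
    gt_texts <- setNames(vapply(gs, function(s) s$text, ""),
                         vapply(gs, function(s) s$id, ""))
    pr_texts <- setNames(vapply(ps, function(s) s$text, ""),
                         vapply(ps, function(s) s$id, ""))
    for (kind in .SEG_KINDS) {
      pk <- Filter(function(s) s$kind == kind, ps)
      gk <- Filter(function(s) s$kind == kind, gs)
      mm <- match_segments(pk, gk, threshold = iou_threshold)
      tp[kind] <- tp[kind] + nrow(mm$matches)
      fp[kind] <- fp[kind] + length(mm$unmatched_pred)
      fn[kind] <- fn[kind] + length(mm$unmatched_gt)
      ious[[kind]] <- c(ious[[kind]], mm$matches$iou)
      if (nrow(mm$matches) > 0) {
        seg_map[mm$matches$pred_id] <- mm$matches$gt_id
        ok <- nzchar(gt_texts[mm$matches$gt_id])
        if (any(ok)) {
          cers[[kind]] <- c(cers[[kind]],
                            cer(gt_texts[mm$matches$gt_id[ok]],
                                pr_texts[mm$matches$pred_id[ok]]))
        }
      }
    }
    pp <- .pairs_df(pr); gp <- .pairs_df(gr)
    if (nrow(pp) > 0 || nrow(gp) > 0) {
      r <- evaluate_relationships(pp, gp, seg_map)
      ## accumulate counts, not averaged ratios
      rel_tp <- rel_tp + round(r[["precision"]] * nrow(pp))
      rel_pred <- rel_pred + nrow(pp)
      rel_gt <- rel_gt + nrow(gp)
    }
  }

  per_cat <- do.call(rbind, lapply(.SEG_KINDS, function(kind) {
    prf <- precision_recall_f1(tp[kind], fp[kind], fn[kind])
    data.frame(category = kind, total_gt = tp[kind] + fn[kind],
               recall = prf[["recall"]], precision = prf[["precision"]],
               f1 = prf[["f1"]],
               mean_iou = if (length(ious[[kind]])) mean(ious[[kind]]) else NA_real_,
               mean_cer = if (length(cers[[kind]])) mean(cers[[kind]]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rel <- precision_recall_f1(rel_tp, rel_pred - rel_tp, rel_gt - rel_tp)
  all_ious <- unlist(ious)
  structure(
    list(per_category = per_cat,
         relationships = data.frame(total_gt = rel_gt,
                                    recall = rel[["recall"]],
                                    precision = rel[["precision"]],
                                    f1 = rel[["f1"]]),
         mean_iou = if (length(all_ious)) mean(all_ious) else NA_real_,
         cer_by_type = setNames(per_cat$mean_cer, per_cat$category),
         iou_threshold = iou_threshold),
    class = "eval_report"
  )
}

.pairs_df <- function(record) {
  if (is.null(record) || length(record$pairs) == 0) {
    return(data.frame(margin_id = character(), plant_id = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(record$pairs)) return(record$pairs)
  do.call(rbind, lapply(record$pairs, function(p) {
    data.frame(margin_id = p$margin_id, plant_id = p$plant_id,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> IoU threshold > %.2f, mean IoU %.2f\n",
              x$iou_threshold, x$mean_iou))
  tab <- x$per_category
  tab$recall <- round(tab$recall, 2)
  tab$precision <- round(tab$precision, 2)
  tab$f1 <- round(tab$f1, 2)
  tab$mean_iou <- round(tab$mean_iou, 2)
  tab$mean_cer <- round(tab$mean_cer, 1)
  print(tab, row.names = FALSE)
  with(x$relationships,
       cat(sprintf("Relationships: n = %d, R = %.2f, P = %.2f, F1 = %.2f\n",
                   total_gt, recall, precision, f1)))
  invisible(x)
}
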