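#' Intersection over union of two boxes
#'
#' Overlap area divided by union area under the 0-based half-open
#' convention; disjoint boxes score 0.
#'
#' @param a,b single-row box data.frames ([bbox()]).
#' @return numeric in `[0, 1]`.
#' @examples
#' iou(bbox(0, 0, 10, 10), bbox(5, 0, 15, 10))  # 50/150
#' @export
iou <- function(a, b) {
  validate_boxes(a); validate_boxes(b)
  iw <- max(0, min(a$xmax, b$xmax) - max(a$xmin, b$xmin))
  ih <- max(0, min(a$ymax, b$ymax) - max(a$ymin, b$ymin))
  inter <- iw * ih
  if (inter == 0) return(0)
  areas <- (a$xmax - a$xmin) * (a$ymax - a$ymin) +
           (b$xmax - b$xmin) * (b$ymax - b$ymin)
  inter / (areas - inter)
}

#' Detection records
#'
#' @param image_id,label character vectors.
#' @param confidence numeric in `[0, 1]`.
#' @param boxes box data.frame ([bbox()]), one row per detection (its
#'   `label` column is replaced by `label`).
#' @return data.frame with columns `image_id`, `label`, `confidence`,
#'   `xmin`, `ymin`, `xmax`, `ymax`.
#' @export
detections <- function(image_id, label, confidence, boxes) {
  validate_boxes(boxes)
  if (any(confidence < 0 | confidence > 1))
    stop("confidence must lie in [0, 1]")
  data.frame(image_id = as.character(image_id), label = as.character(label),
             confidence = as.numeric(confidence),
             boxes[c("xmin", "ymin", "xmax", "ymax")],
             stringsAsFactors = FALSE)
}

#' Read / write the detection exchange TSV
#'
#' Columns: `image_id`, `label`, `confidence`, `xmin`, `ymin`, `xmax`,
#' `ymax` (internal 0-based half-open coordinates).
#'
#' @param path TSV path.
#' @return `read_detections`: the detections data.frame.
#' @export
read_detections <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("image_id", "label", "confidence", "xmin", "ymin", "xmax", "ymax")
  if (!all(need %in% names(d)))
    stop("detection table must have columns: ", paste(need, collapse = ", "))
  b <- d[c("xmin", "ymin", "xmax", "ymax")]
  b$label <- d$label
  detections(d$image_id, d$label, d$confidence, b)
}

#' @rdname read_detections
#' @param dets detections data.frame.
#' @export
write_detections <- function(dets, path) {
  utils::write.table(dets, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Match detections to ground truth on one image and class
#'
#' The standard greedy protocol: detections are processed in descending
#' confidence; each claims the not-yet-matched ground truth of highest IoU,
#' provided that IoU reaches `iou_thr` (a true positive), otherwise it is a
#' false positive. Ground truths left unclaimed are false negatives.
#' Matching is one-to-one: a duplicate detection of an already-claimed seed
#' is a false positive.
#'
#' @param dets detections data.frame for a single image and class.
#' @param gts ground-truth box data.frame for the same image and class.
#' @param iou_thr IoU threshold (e.g. 0.5).
#' @return list of class `match_ledger`: `tp` (logical per detection, in
#'   the original row order), `confidence`, `matched_gt` (index or NA),
#'   `n_gt`, `fn`, `iou_thr`.
#' @export
match_detections <- function(dets, gts, iou_thr) {
  stopifnot(is.data.frame(dets), iou_thr >= 0, iou_thr <= 1)
  if (nrow(dets) > 0 && length(unique(dets$image_id)) > 1L)
    stop("match_detections expects a single image_id; got several")
  n_gt <- nrow(gts)
  ord <- order(-dets$confidence)
  tp <- logical(nrow(dets)); matched_gt <- rep(NA_integer_, nrow(dets))
  taken <- logical(n_gt)
  for (i in ord) {
    if (n_gt == 0) break
    ious <- vapply(seq_len(n_gt), function(j)
      iou(dets[i, , drop = FALSE], gts[j, , drop = FALSE]), numeric(1))
    ious[taken] <- -1
    j <- which.max(ious)
    if (length(j) && ious[j] >= iou_thr) {
      tp[i] <- TRUE; matched_gt[i] <- j; taken[j] <- TRUE
    }
  }
  structure(list(tp = tp, confidence = dets$confidence,
                 matched_gt = matched_gt, n_gt = n_gt,
                 fn = n_gt - sum(tp), iou_thr = iou_thr),
            class = "match_ledger")
}

#' Precision and recall of a match ledger
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`. An empty
#' denominator yields an explicit `NA` sentinel, never a silent 0, so
#' aggregate reports cannot absorb empty classes unnoticed.
#'
#' @param ledger a `match_ledger` ([match_detections()]).
#' @return named numeric `c(precision, recall)`, `NA` where undefined.
#' @export
precision_recall <- function(ledger) {
  stopifnot(inherits(ledger, "match_ledger"))
  tp <- sum(ledger$tp); fp <- sum(!ledger$tp); fn <- ledger$fn
  c(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Precision-recall curve over the confidence sweep
#'
#' Pools per-image match ledgers of one class, sorts detections by
#' descending confidence, and accumulates TP/FP to trace P(r).
#'
#' @param ledgers list of `match_ledger`s (one per image) for one class.
#' @return data.frame of class `pr_curve` with columns `confidence`,
#'   `recall`, `precision`; attribute `n_gt`.
#' @export
pr_curve <- function(ledgers) {
  stopifnot(length(ledgers) >= 1L)
  tp <- unlist(lapply(ledgers, `[[`, "tp"))
  conf <- unlist(lapply(ledgers, `[[`, "confidence"))
  n_gt <- sum(vapply(ledgers, `[[`, numeric(1), "n_gt"))
  o <- order(-conf)
  tp <- tp[o]; conf <- conf[o]
  cum_tp <- cumsum(tp); cum_fp <- cumsum(!tp)
  out <- data.frame(confidence = conf,
                    recall = if (n_gt > 0) cum_tp / n_gt
                             else rep(NA_real_, length(tp)),
                    precision = cum_tp / (cum_tp + cum_fp))
  structure(out, n_gt = n_gt, class = c("pr_curve", "data.frame"))
}

#' Average precision of one class
#'
#' Area under the precision envelope: precision at each recall is replaced
#' by the maximum precision at any greater-or-equal recall (making the
#' curve non-increasing), then integrated exactly over recall — the
#' all-points interpolation used across the YOLO ecosystem.
#'
#' @param curve a `pr_curve` ([pr_curve()]).
#' @return AP in `[0, 1]`; an empty curve (no detections) scores 0.
#' @export
average_precision <- function(curve) {
  stopifnot(inherits(curve, "pr_curve"))
  if (nrow(curve) == 0L || attr(curve, "n_gt") == 0) return(0)
  r <- c(0, curve$recall)
  p <- c(1, curve$precision)
  # envelope: running max from the right
  p <- rev(cummax(rev(p)))
  sum(diff(r) * p[-1])
}

#' Mean average precision
#'
#' `mean_ap` averages per-class APs at one IoU threshold.
#' `evaluate_detections` runs the whole protocol: per image and class
#' matching at each threshold of `iou_grid`, AP per class, mAP per
#' threshold, and their mean over the grid (mAP50-95 for the default grid
#' `seq(0.5, 0.95, 0.05)`).
#'
#' @param per_class_ap numeric vector of APs (one per class).
#' @return `mean_ap`: numeric scalar.
#' @export
mean_ap <- function(per_class_ap) {
  if (length(per_class_ap) == 0L) stop("empty class list")
  mean(per_class_ap)
}

#' @rdname mean_ap
#' @param dets detections data.frame (any number of images/classes).
#' @param gt_frames list of [annotated_frame()] ground truths.
#' @param iou_grid IoU thresholds; default `seq(0.5, 0.95, 0.05)`.
#' @return `evaluate_detections`: list with `ap` (class x threshold
#'   matrix), `map_per_iou` (named vector), `map` (mean over the grid),
#'   `precision`, `recall` (micro-averaged at the first threshold).
#' @export
evaluate_detections <- function(dets, gt_frames,
                                iou_grid = seq(0.5, 0.95, by = 0.05)) {
  stopifnot(length(gt_frames) >= 1L, length(iou_grid) >= 1L)
  gt_ids <- vapply(gt_frames, `[[`, character(1), "image_id")
  classes <- sort(unique(c(dets$label,
                           unlist(lapply(gt_frames,
                                         function(f) f$boxes$label)))))
  if (length(classes) == 0L) stop("no classes present in detections or truth")
  ap <- matrix(NA_real_, length(classes), length(iou_grid),
               dimnames = list(classes, sprintf("iou%.2f", iou_grid)))
  ledgers50 <- list()
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    for (ti in seq_along(iou_grid)) {
      ledgers <- lapply(seq_along(gt_frames), function(k) {
        f <- gt_frames[[k]]
        d <- dets[dets$image_id == f$image_id & dets$label == cl, ,
                  drop = FALSE]
        g <- f$boxes[f$boxes$label == cl, , drop = FALSE]
        match_detections(d, g, iou_grid[ti])
      })
      ap[ci, ti] <- average_precision(pr_curve(ledgers))
      if (ti == 1L) ledgers50 <- c(ledgers50, ledgers)
    }
  }
  map_per_iou <- apply(ap, 2, mean_ap)
  pooled <- list(tp = unlist(lapply(ledgers50, `[[`, "tp")),
                 confidence = unlist(lapply(ledgers50, `[[`, "confidence")),
                 matched_gt = NA,
                 n_gt = sum(vapply(ledgers50, `[[`, numeric(1), "n_gt")),
                 fn = sum(vapply(ledgers50, `[[`, numeric(1), "fn")),
                 iou_thr = iou_grid[1])
  class(pooled) <- "match_ledger"
  pr <- precision_recall(pooled)
  list(ap = ap, map_per_iou = map_per_iou, map = mean(map_per_iou),
       precision = unname(pr["precision"]), recall = unname(pr["recall"]))
}

# round half up to `digits` decimals (round() would round half to even)
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Germination rate
#'
#' Percentage of germinated seeds among all tested, rounded half up to one
#' decimal (2820 of 11858 gives 23.8; 3018 of 11858 gives 25.5).
#'
#' @param n_germinated,n_total non-negative counts, `n_total > 0`.
#' @return list of class `germination_rate`: `n_germinated`, `n_total`,
#'   `rate` (percent, one decimal).
#' @export
germination_rate <- function(n_germinated, n_total) {
  if (!is.numeric(n_total) || n_total <= 0)
    stop("n_total must be positive")
  if (n_germinated < 0) stop("n_germinated must be non-negative")
  structure(list(n_germinated = n_germinated, n_total = n_total,
                 rate = round_half_up(100 * n_germinated / n_total, 1)),
            class = "germination_rate")
}

#' @export
print.germination_rate <- function(x, ...) {
  cat(sprintf("germination rate: %d / %d = %.1f%%\n",
              x$n_germinated, x$n_total, x$rate))
  invisible(x)
}
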