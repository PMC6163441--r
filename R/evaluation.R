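# Pixel-level segmentation scoring against ground-truth masks.

#' Pixel confusion counts between a predicted and a ground-truth mask
#'
#' TP = foreground in both; FP = foreground predicted on true background;
#' FN = true foreground missed. True negatives are never computed.
#'
#' @param pred Predicted binary mask.
#' @param truth Ground-truth binary mask, same shape.
#' @return List with integer `tp`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  validate_mask(pred); validate_mask(truth)
  if (!identical(dim(pred), dim(truth))) {
    stop("prediction and ground truth have different shapes", call. = FALSE)
  }
  p <- pred != 0; g <- truth != 0
  list(tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g))
}

#' Precision, recall and F-score from confusion counts
#'
#' PC = TP/(TP+FP), RC = TP/(TP+FN), F = 2*PC*RC/(PC+RC). If a denominator
#' is zero (no predicted foreground, no true foreground, or PC = RC = 0) the
#' score is undefined and an error is raised rather than silently reporting
#' zero.
#'
#' @param counts List with `tp`, `fp`, `fn`.
#' @return List with `precision`, `recall`, `f_score`.
#' @export
seg_scores <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp + fp == 0) stop("precision undefined: no predicted foreground",
                         call. = FALSE)
  if (tp + fn == 0) stop("recall undefined: no ground-truth foreground",
                         call. = FALSE)
  pc <- tp / (tp + fp)
  rc <- tp / (tp + fn)
  if (pc + rc == 0) stop("F-score undefined: precision and recall both zero",
                         call. = FALSE)
  list(precision = pc, recall = rc, f_score = 2 * pc * rc / (pc + rc))
}

#' Score a set of segmentations
#'
#' Per-image precision/recall/F plus an overall row. With
#' `weighting = "pooled"` (default) the overall scores are computed from the
#' confusion counts summed across images, weighting images by pixel count;
#' `"per-image-mean"` averages the per-image scores instead.
#'
#' @param pairs List of `list(pred = mask, truth = mask)` pairs, optionally
#'   named (names become image ids).
#' @param weighting `"pooled"` or `"per-image-mean"`.
#' @return `data.frame` with one row per image plus an `"Overall"` row;
#'   columns `image_id`, `tp`, `fp`, `fn`, `precision`, `recall`, `f_score`
#'   (confusion counts are NA on a per-image-mean overall row).
#' @export
evaluate_set <- function(pairs, weighting = c("pooled", "per-image-mean")) {
  weighting <- match.arg(weighting)
  if (length(pairs) == 0) stop("empty evaluation set", call. = FALSE)
  ids <- names(pairs)
  if (is.null(ids)) ids <- sprintf("image%03d", seq_along(pairs))
  rows <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    cc <- tryCatch(confusion_counts(pairs[[i]]$pred, pairs[[i]]$truth),
                   error = function(e) {
                     stop(sprintf("pair '%s': %s", ids[i], conditionMessage(e)),
                          call. = FALSE)
                   })
    sc <- seg_scores(cc)
    rows[[i]] <- data.frame(image_id = ids[i], tp = cc$tp, fp = cc$fp,
                            fn = cc$fn, precision = sc$precision,
                            recall = sc$recall, f_score = sc$f_score,
                            stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  if (weighting == "pooled") {
    tot <- list(tp = sum(per$tp), fp = sum(per$fp), fn = sum(per$fn))
    sc <- seg_scores(tot)
    overall <- data.frame(image_id = "Overall", tp = tot$tp, fp = tot$fp,
                          fn = tot$fn, precision = sc$precision,
                          recall = sc$recall, f_score = sc$f_score,
                          stringsAsFactors = FALSE)
  } else {
    overall <- data.frame(image_id = "Overall", tp = NA_integer_,
                          fp = NA_integer_, fn = NA_integer_,
                          precision = mean(per$precision),
                          recall = mean(per$recall),
                          f_score = mean(per$f_score),
                          stringsAsFactors = FALSE)
  }
  rbind(per, overall)
}
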