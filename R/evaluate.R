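# Scoring recruited reads against ground truth: TP/FP/FN with boundary
# exclusion, recall / precision / F-measure, and ROC points over E-value
# cutoffs. Precision is TP/(TP+FP); undefined ratios are reported as NA,
# never coerced to 0 or 1.

#' Score recruited reads against ground truth
#'
#' Boundary-labeled reads contribute to no count. For each query q: TP are
#' homolog-of-q reads recruited to q, FP are recruited-to-q reads that are not
#' homolog-of-q (and not boundary), FN are homolog-of-q reads not recruited to
#' q. Pooled metrics are reported micro-averaged (pooled counts; the headline)
#' and macro-averaged (mean of per-query ratios).
#'
#' @param recruited data.frame with `read_id` and `query_id` (e.g. from
#'   [recruit()]).
#' @param truth data.frame with `read_id`, `label`, `query_id` (from
#'   [shred_reads()]).
#' @return a `grasp2_eval`: `per_query` data.frame (query_id, tp, fp, fn,
#'   recall, precision, f_measure), `micro` and `macro` lists.
#' @export
score_predictions <- function(recruited, truth) {
  if (nrow(recruited) > 0L && !all(recruited$read_id %in% truth$read_id)) {
    bad <- setdiff(recruited$read_id, truth$read_id)[1L]
    stop("prediction for unknown read id '", bad, "'")
  }
  boundary <- truth$read_id[truth$label == "boundary"]
  pred <- recruited[!(recruited$read_id %in% boundary), , drop = FALSE]
  queries <- sort(unique(c(truth$query_id[truth$label == "homolog"],
                           pred$query_id)))
  ratio <- function(num, den) if (den > 0L) num / den else NA_real_
  per <- lapply(queries, function(q) {
    truth_q <- truth$read_id[truth$label == "homolog" &
                               !is.na(truth$query_id) & truth$query_id == q]
    pred_q <- unique(pred$read_id[pred$query_id == q])
    tp <- length(intersect(pred_q, truth_q))
    fp <- length(setdiff(pred_q, truth_q))
    fn <- length(setdiff(truth_q, pred_q))
    data.frame(query_id = q, tp = tp, fp = fp, fn = fn)
  })
  per <- if (length(per) > 0L) do.call(rbind, per) else
    data.frame(query_id = character(0), tp = integer(0), fp = integer(0),
               fn = integer(0))
  per$recall <- mapply(ratio, per$tp, per$tp + per$fn)
  per$precision <- mapply(ratio, per$tp, per$tp + per$fp)
  per$f_measure <- ifelse(
    !is.na(per$recall) & !is.na(per$precision) &
      (per$recall + per$precision) > 0,
    2 * per$recall * per$precision / (per$recall + per$precision), NA_real_)
  pool <- function(tp, fp, fn) {
    r <- ratio(tp, tp + fn); p <- ratio(tp, tp + fp)
    f <- if (!is.na(r) && !is.na(p) && r + p > 0) 2 * r * p / (r + p)
         else NA_real_
    list(tp = tp, fp = fp, fn = fn, recall = r, precision = p, f_measure = f)
  }
  micro <- pool(sum(per$tp), sum(per$fp), sum(per$fn))
  macro <- list(recall = mean(per$recall, na.rm = TRUE),
                precision = mean(per$precision, na.rm = TRUE),
                f_measure = mean(per$f_measure, na.rm = TRUE))
  structure(list(per_query = per, micro = micro, macro = macro),
            class = "grasp2_eval")
}

#' @export
print.grasp2_eval <- function(x, ...) {
  cat(sprintf("pooled (micro): TP=%d FP=%d FN=%d recall=%.3f precision=%s\n",
              x$micro$tp, x$micro$fp, x$micro$fn, x$micro$recall,
              ifelse(is.na(x$micro$precision), "NA",
                     sprintf("%.3f", x$micro$precision))))
  invisible(x)
}

#' Precision/recall points over E-value cutoffs
#'
#' One point per cutoff, from the most permissive cutoff down; recall is
#' non-increasing as the cutoff tightens because the prediction sets are
#' nested.
#'
#' @param recruited recruited reads carrying an `evalue` column.
#' @param truth ground-truth labels.
#' @param cutoffs E-value cutoffs (default `10^(6..-10)`).
#' @return data.frame: cutoff, tp, fp, fn, recall, precision, f_measure
#'   (micro-averaged), ordered by decreasing cutoff.
#' @export
roc_over_cutoffs <- function(recruited, truth, cutoffs = 10^seq(6, -10)) {
  cutoffs <- sort(cutoffs, decreasing = TRUE)
  rows <- lapply(cutoffs, function(cut) {
    ev <- score_predictions(
      recruited[recruited$evalue <= cut, , drop = FALSE], truth)
    data.frame(cutoff = cut, tp = ev$micro$tp, fp = ev$micro$fp,
               fn = ev$micro$fn, recall = ev$micro$recall,
               precision = ev$micro$precision, f_measure = ev$micro$f_measure)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
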