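# Strict / relaxed span evaluation, micro-averaged over the corpus, in the
# four configurations used for GPRO scoring: {strict, relaxed} x
# {Type 1 only, Type 1 and 2 combined}.

check_side <- function(ments, side) {
  if (nrow(ments) < 2L) return(invisible(TRUE))
  key <- paste(ments$doc_id, ments$section)
  for (k in unique(key)) {
    g <- ments[key == k, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) > 1L && any(g$start[-1L] < g$end[-nrow(g)])) {
      stop(sprintf("overlapping mentions within %s side in %s", side, k))
    }
  }
  invisible(TRUE)
}

#' Score predicted mentions against gold
#'
#' Strict mode requires exact span equality; relaxed mode accepts any
#' overlap of at least one character. Scope `"type1"` drops `GPRO_TYPE_2`
#' mentions from both sides before scoring; scope `"combined"` keeps both
#' types and by default ignores the type label when matching (set
#' `respect_type = TRUE` to require type agreement). Matching is one-to-one
#' and greedy: gold mentions are scanned left to right and each takes the
#' leftmost unused matching prediction.
#'
#' @param gold,pred `gpro_mentions` data frames (non-overlapping within each
#'   document section on each side).
#' @param mode `"strict"` or `"relaxed"`.
#' @param scope `"type1"` or `"combined"`.
#' @param respect_type in combined scope, require predicted and gold types
#'   to agree.
#' @return An `eval_report` list: `mode`, `scope`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1` (percentages).
#' @export
score <- function(gold, pred, mode = c("strict", "relaxed"),
                  scope = c("combined", "type1"), respect_type = FALSE) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  check_side(gold, "gold")
  check_side(pred, "predicted")
  if (scope == "type1") {
    gold <- gold[gold$etype == "GPRO_TYPE_1", , drop = FALSE]
    pred <- pred[pred$etype == "GPRO_TYPE_1", , drop = FALSE]
  }
  tp <- 0L
  used <- rep(FALSE, nrow(pred))
  if (nrow(gold) > 0L) {
    gold <- gold[order(gold$doc_id, gold$section, gold$start), , drop = FALSE]
    for (i in seq_len(nrow(gold))) {
      same <- pred$doc_id == gold$doc_id[i] & pred$section == gold$section[i] & !used
      if (scope == "combined" && respect_type) {
        same <- same & pred$etype == gold$etype[i]
      }
      hit <- if (mode == "strict") {
        same & pred$start == gold$start[i] & pred$end == gold$end[i]
      } else {
        same & pred$start < gold$end[i] & pred$end > gold$start[i]
      }
      if (any(hit)) {
        j <- which(hit)[order(pred$start[hit])][1L]   # leftmost prediction
        used[j] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  fp <- nrow(pred) - tp
  fn <- nrow(gold) - tp
  precision <- if (tp + fp == 0L) 0 else 100 * tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else 100 * tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(mode = mode, scope = scope, tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, f1 = f1),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%s / %s: P %.2f%%  R %.2f%%  F1 %.2f%%  (tp %d, fp %d, fn %d)\n",
              x$mode, x$scope, x$precision, x$recall, x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}

#' All four GPRO evaluation configurations at once
#'
#' @inheritParams score
#' @return A data frame with one row per (mode, scope) combination.
#' @export
score_all <- function(gold, pred, respect_type = FALSE) {
  grid <- expand.grid(mode = c("strict", "relaxed"),
                      scope = c("type1", "combined"),
                      stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    r <- score(gold, pred, grid$mode[i], grid$scope[i], respect_type)
    data.frame(mode = r$mode, scope = r$scope, tp = r$tp, fp = r$fp,
               fn = r$fn, precision = r$precision, recall = r$recall,
               f1 = r$f1, stringsAsFactors = FALSE)
  }))
}
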