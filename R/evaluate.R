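#' Fraction of a ground-truth panel covered by a prediction
#'
#' Returns `area(pred intersect truth) / area(truth)` — the denominator is
#' always the ground-truth area, matching the convention that a predicted
#' sub-image is correct when it covers more than two-thirds of its
#' ground-truth panel.
#'
#' @param pred,truth Single-row panel-region data frames.
#' @return A fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(pred, truth) {
  stopifnot(nrow(pred) == 1, nrow(truth) == 1)
  rh <- min(pred$row_end, truth$row_end) - max(pred$row_start,
                                               truth$row_start)
  cw <- min(pred$col_end, truth$col_end) - max(pred$col_start,
                                               truth$col_start)
  if (rh <= 0 || cw <= 0) return(0)
  (rh * cw) / region_area(truth)
}

#' Match predicted panels to ground truth and score
#'
#' Greedy one-to-one matching: each ground-truth panel, in order, takes
#' the unmatched prediction with the largest overlap fraction (ties to
#' the earlier prediction). A match counts as correct (`Nc`) only when
#' the overlap strictly exceeds `overlap` (default 2/3). Precision is
#' `Nc / Ne` (0 when no panels were extracted), recall `Nc / Nt`, F1 the
#' harmonic mean (0 when both are 0).
#'
#' @param preds,truths Panel-region data frames (any number of rows).
#' @param overlap Correctness threshold on the overlap fraction,
#'   strictly-greater comparison. Default `2/3`.
#' @return An object of class `eval_report`: list with `Nc`, `Ne`, `Nt`,
#'   `precision`, `recall`, `f1`.
#' @examples
#' boxes <- panel_regions(c(0, 0), c(10, 10), c(0, 12), c(10, 22))
#' match_and_score(boxes, boxes)$f1 # 1
#' @export
match_and_score <- function(preds, truths, overlap = 2 / 3) {
  ne <- if (is.null(preds)) 0L else nrow(preds)
  nt <- if (is.null(truths)) 0L else nrow(truths)
  nc <- 0L
  used <- logical(ne)
  if (ne > 0 && nt > 0) {
    for (i in seq_len(nt)) {
      ov <- vapply(seq_len(ne), function(j)
        if (used[j]) -1 else overlap_fraction(preds[j, ], truths[i, ]),
        numeric(1))
      j <- which.max(ov) # first maximum: earlier prediction wins ties
      # sub-threshold best overlaps leave both sides unmatched
      if (ov[j] > overlap) {
        nc <- nc + 1L
        used[j] <- TRUE
      }
    }
  }
  precision <- if (ne == 0) 0 else nc / ne
  recall <- if (nt == 0) 0 else nc / nt
  f1 <- if (precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  structure(list(Nc = nc, Ne = ne, Nt = nt, precision = precision,
                 recall = recall, f1 = f1),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "panel evaluation: Nc=%d Ne=%d Nt=%d  P=%.4f R=%.4f F1=%.4f\n",
    x$Nc, x$Ne, x$Nt, x$precision, x$recall, x$f1))
  invisible(x)
}
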