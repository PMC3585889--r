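#' Segmentation quality metrics
#'
#' With `M` the reference (manual) mask, `A` the automatic mask and `W` the
#' whole frame:
#' sensitivity `SN = |M n A| / |M|`,
#' specificity `SP = |W - (M u A)| / |W - M|`,
#' positive predictive value `PPV = |M n A| / |A|`,
#' plus the Dice coefficient `2|M n A| / (|M| + |A|)` as a convenience.
#'
#' @param auto_mask automatic segmentation (binary matrix).
#' @param ref_mask reference segmentation; must be neither empty nor
#'   full-frame (SP is undefined otherwise).
#' @return list of class `seg_metrics` with `SN`, `SP`, `PPV`, `dice`; when
#'   `auto_mask` is empty, `PPV` is 0 with attribute `empty_auto = TRUE`.
#' @export
evaluate_segmentation <- function(auto_mask, ref_mask) {
  A <- as_mask(auto_mask)
  M <- as_mask(ref_mask)
  if (!all(dim(A) == dim(M)))
    stop("mask dimensions differ", call. = FALSE)
  nM <- sum(M)
  if (nM == 0L) stop("reference mask is empty", call. = FALSE)
  W <- length(M)
  if (nM == W) stop("reference mask covers the whole frame (SP undefined)",
                    call. = FALSE)
  nA <- sum(A)
  tp <- sum(A & M)
  ppv <- if (nA == 0L) structure(0, empty_auto = TRUE) else tp / nA
  structure(list(
    SN = tp / nM,
    SP = (W - sum(A | M)) / (W - nM),
    PPV = ppv,
    dice = if (nM + nA == 0L) 0 else 2 * tp / (nM + nA)
  ), class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("SN %.4f  SP %.4f  PPV %.4f  Dice %.4f\n",
              x$SN, x$SP, x$PPV, x$dice))
  invisible(x)
}

#' Quality gate for triggering shape absorption
#'
#' The segmentation fails the gate (absorption of a corrected shape is
#' recommended) when, in the default `"all"` mode, SN, SP and PPV are all
#' strictly below the threshold. `"any"` mode is a stricter variant failing
#' as soon as one metric drops below the threshold.
#'
#' @param metrics a [evaluate_segmentation()] result.
#' @param threshold gate threshold (default 0.90).
#' @param mode `"all"` (default) or `"any"`.
#' @return `TRUE` if the segmentation passes, `FALSE` if it fails.
#' @export
quality_gate <- function(metrics, threshold = 0.90, mode = c("all", "any")) {
  mode <- match.arg(mode)
  below <- c(metrics$SN, metrics$SP, metrics$PPV) < threshold
  fail <- if (mode == "all") all(below) else any(below)
  !fail
}
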