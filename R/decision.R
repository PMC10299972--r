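# Decision support: selection-efficiency evaluation of an HTFP-based
# overall-performance threshold on top of breeders' decisions, and the
# protein-per-area trade-off.

#' Efficiency of selection with and without an HTFP threshold
#'
#' Compares the breeders' selection with an enhanced selection that
#' additionally excludes lines whose predicted overall performance falls
#' below a threshold. A selected line counts as a success when its
#' observed performance reaches the threshold; efficiency is the ratio
#' of successes to selected lines (the ratio over all candidate lines is
#' reported as well). `threshold = "optimize"` scans the midpoints of
#' the sorted predictions and keeps the lowest threshold maximizing the
#' efficiency increase (enhanced minus baseline efficiency; the baseline
#' also depends on the threshold through the success criterion, so the
#' increase is the quantity with an interior maximum).
#'
#' @param predicted_op Named numeric vector: line -> predicted overall
#'   performance (t/ha).
#' @param breeder_selected Character vector of lines selected by the
#'   breeders (non-empty, subset of `names(predicted_op)`).
#' @param observed Named numeric vector: line -> observed performance of
#'   the evaluated generation (e.g. F8 yield), covering the selected
#'   lines.
#' @param threshold Numeric threshold on predicted OP, or `"optimize"`.
#' @return Object of class `"efficiency_report"`: `threshold`,
#'   `n_total`, `n_selected_base`, `n_selected_enhanced`,
#'   `efficiency_base`, `efficiency_enhanced`, `efficiency_increase`,
#'   `false_exclusions` (excluded lines whose observed performance
#'   reached the threshold), and per-line details.
#' @export
efficiency_analysis <- function(predicted_op, breeder_selected, observed,
                                threshold = "optimize") {
  stopifnot(is.numeric(predicted_op), !is.null(names(predicted_op)))
  breeder_selected <- as.character(breeder_selected)
  if (length(breeder_selected) == 0) stop("empty breeder selection set")
  if (!all(breeder_selected %in% names(predicted_op))) {
    stop("breeder-selected lines missing from predictions")
  }
  if (!all(breeder_selected %in% names(observed))) {
    stop("observed performance missing for some selected lines")
  }
  eval_at <- function(thr) {
    keep <- breeder_selected[predicted_op[breeder_selected] >= thr]
    succ_base <- sum(observed[breeder_selected] >= thr)
    succ_enh <- sum(observed[keep] >= thr)
    list(thr = thr, keep = keep,
         eff_base = succ_base / length(breeder_selected),
         eff_enh = if (length(keep)) succ_enh / length(keep) else 0)
  }
  if (identical(threshold, "optimize")) {
    # the increase changes at predicted values (selection cut) and at
    # observed values (success criterion): scan midpoints of both
    sp <- sort(unique(c(predicted_op[breeder_selected],
                        observed[breeder_selected])))
    cand <- if (length(sp) > 1) {
      c(sp[1] - 1, (sp[-length(sp)] + sp[-1]) / 2)
    } else {
      sp[1] - 1
    }
    effs <- vapply(cand, function(t) {
      e <- eval_at(t)
      e$eff_enh - e$eff_base
    }, 0)
    threshold <- cand[which.max(effs)] # which.max takes the first: lowest
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  res <- eval_at(threshold)
  excluded <- setdiff(breeder_selected, res$keep)
  false_exc <- excluded[observed[excluded] >= threshold]
  out <- list(threshold = threshold,
              n_total = length(predicted_op),
              n_selected_base = length(breeder_selected),
              n_selected_enhanced = length(res$keep),
              efficiency_base = res$eff_base,
              efficiency_enhanced = res$eff_enh,
              efficiency_increase = res$eff_enh - res$eff_base,
              efficiency_base_total = res$eff_base *
                length(breeder_selected) / length(predicted_op),
              false_exclusions = length(false_exc),
              false_excluded_lines = false_exc,
              enhanced_selection = res$keep)
  class(out) <- "efficiency_report"
  out
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf(
    "Selection efficiency at threshold %.3g: %.3f -> %.3f (increase %.3f)\n",
    x$threshold, x$efficiency_base, x$efficiency_enhanced,
    x$efficiency_increase))
  cat(sprintf("  selected %d -> %d of %d lines; false exclusions: %d\n",
              x$n_selected_base, x$n_selected_enhanced, x$n_total,
              x$false_exclusions))
  invisible(x)
}

#' Harvestable protein per area
#'
#' `yield (t/ha) * protein (%) / 100`, the level sets of which are the
#' iso-protein-per-hectare lines of the yield-protein trade-off.
#'
#' @param yield Non-negative yield in t/ha.
#' @param protein Grain protein content in percent (0-100).
#' @return Protein mass per area in t/ha.
#' @export
protein_per_area <- function(yield, protein) {
  if (any(yield < 0)) stop("yield must be non-negative")
  if (any(protein < 0 | protein > 100)) stop("protein must be in [0, 100] percent")
  yield * protein / 100
}
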