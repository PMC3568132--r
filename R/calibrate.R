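# Score-threshold calibration against database-member truth.
#
# The operating point of the score filters is chosen by grid search on
# calls from a control panel: retain as many known (database-member)
# variants as possible while minimizing the total number of variants
# retained. Known variants with undefined scores count as lost
# (conservative: their window membership cannot be certified).

#' Default calibration grids
#'
#' SNVs search a shared DS/QS window: lower bounds 0–50 in steps of 5,
#' upper bounds 100–300 in steps of 10. INDELs search the strict DS
#' ceiling over 50–300 in steps of 10 (the remaining INDEL criteria are
#' held at their configured values).
#'
#' @param vtype `"SNV"` or `"INDEL"`.
#' @return For SNVs, `list(lows, highs)`; for INDELs, `list(ds_max)`.
#' @export
default_grid <- function(vtype = c("SNV", "INDEL")) {
  vtype <- match.arg(vtype)
  if (vtype == "SNV") list(lows = seq(0, 50, by = 5), highs = seq(100, 300, by = 10))
  else list(ds_max = seq(50, 300, by = 10))
}

#' Calibrate score-filter thresholds against known-site truth
#'
#' Evaluates every grid combination on a variant set whose database
#' membership is known, computing the fraction of known variants
#' retained (`known_retention`) and the total number of variants
#' retained (`total_retained`). Among combinations meeting the retention
#' target, the one retaining the fewest variants overall wins; ties are
#' broken by higher known retention, then by lexicographically smallest
#' thresholds. If no combination meets the target, the maximum-retention
#' combination is returned with `target_met = FALSE` and a warning.
#'
#' @param vt variant table (all of one `vtype`).
#' @param known logical vector marking database-member variants; by
#'   default, rows whose `db_flags` contain `"dbsnp"`.
#' @param vtype `"SNV"` or `"INDEL"`.
#' @param target_retention required fraction of known variants retained
#'   (default 0.95).
#' @param grid grid specification as in [default_grid()].
#' @param config a [cascade_config()] supplying the non-searched INDEL
#'   criteria and the score orientation.
#' @return Object of class `calibration_result`: list with `chosen`
#'   (named thresholds), `known_retention`, `total_retained`,
#'   `target_met`, `vtype`, and the full `grid` data frame.
#' @export
calibrate_thresholds <- function(vt, known = NULL,
                                 vtype = c("SNV", "INDEL"),
                                 target_retention = 0.95,
                                 grid = NULL,
                                 config = cascade_config()) {
  vtype <- match.arg(vtype)
  if (nrow(vt) == 0) stop("empty variant set: nothing to calibrate on")
  if (is.null(known))
    known <- grepl("(^|,)dbsnp(,|$)", vt$db_flags)
  stopifnot(length(known) == nrow(vt))
  if (!any(known)) stop("no known (database-member) variants to calibrate on")
  if (is.null(grid)) grid <- default_grid(vtype)

  sc <- variant_scores(vt, config)
  n_known <- sum(known)

  if (vtype == "SNV") {
    combos <- expand.grid(low = grid$lows, high = grid$highs)
    combos <- combos[combos$low <= combos$high, , drop = FALSE]
    eval_one <- function(low, high) {
      keep <- !is.na(sc$ds) & !is.na(sc$qs) &
        sc$ds >= low & sc$ds <= high & sc$qs >= low & sc$qs <= high
      c(known_retention = sum(keep & known) / n_known,
        total_retained = sum(keep))
    }
    metrics <- t(mapply(eval_one, combos$low, combos$high))
  } else {
    combos <- data.frame(ds_max = grid$ds_max)
    eval_one <- function(ds_max) {
      keep <- !is.na(sc$ds) & sc$ds < ds_max &
        !is.na(vt$phred_alt) & vt$phred_alt > config$indel_phred_min &
        !is.na(vt$snp_quality) & vt$snp_quality > config$indel_snpq_min &
        !is.na(vt$depth_ref) & vt$depth_ref >= config$indel_min_reads_each &
        !is.na(vt$depth_alt) & vt$depth_alt >= config$indel_min_reads_each
      c(known_retention = sum(keep & known) / n_known,
        total_retained = sum(keep))
    }
    metrics <- t(vapply(combos$ds_max, eval_one,
                        c(known_retention = 0, total_retained = 0)))
  }
  gridtab <- cbind(combos, as.data.frame(metrics))
  rownames(gridtab) <- NULL

  feasible <- gridtab$known_retention >= target_retention
  target_met <- any(feasible)
  cand <- if (target_met) gridtab[feasible, , drop = FALSE] else gridtab
  ord <- if (vtype == "SNV")
    order(cand$total_retained, -cand$known_retention, cand$low, cand$high)
  else
    order(cand$total_retained, -cand$known_retention, cand$ds_max)
  if (!target_met) {
    ord <- if (vtype == "SNV")
      order(-cand$known_retention, cand$total_retained, cand$low, cand$high)
    else
      order(-cand$known_retention, cand$total_retained, cand$ds_max)
    warning("no grid combination reaches the retention target (",
            target_retention, "); returning the maximum-retention point")
  }
  best <- cand[ord[1], , drop = FALSE]
  chosen <- as.list(best[, setdiff(names(best),
                                   c("known_retention", "total_retained")),
                         drop = FALSE])
  structure(list(
    chosen = chosen,
    known_retention = best$known_retention,
    total_retained = best$total_retained,
    target_met = target_met,
    vtype = vtype,
    grid = gridtab
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> ", x$vtype, ": ", sep = "")
  cat(paste(names(x$chosen), unlist(x$chosen), sep = " = ", collapse = ", "))
  cat(sprintf("\n  known retention %.3f, total retained %d (%d grid points%s)\n",
              x$known_retention, x$total_retained, nrow(x$grid),
              if (x$target_met) "" else "; TARGET NOT MET"))
  invisible(x)
}
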