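# Funnel summarization: per-stage surviving-variant counts per family,
# with the averaged summary rows used in filtering-summary tables.

#' Summarize a filtering funnel over families
#'
#' The first ("detected") stage is counted per sequenced sample; later
#' stages are counted per family (the shared set for two-member
#' families, the single sample's set otherwise). A family's stage-1
#' value is the mean of its sample counts. The summary rows are:
#'
#' * `averages`: per-stage mean over families, rounded half-away-from-zero
#'   to the nearest integer;
#' * `percentages`: the reported (rounded) stage average divided by the
#'   reported stage-1 average, times 100, rounded to 2 decimals
#'   (stage 1 = 100). Percentages derive from the reported averages —
#'   the convention of typeset filtering-summary tables — so the two
#'   summary rows are mutually consistent to the printed precision.
#'
#' @param per_sample data frame with columns `family_id`, `member_id`,
#'   `count`: stage-1 counts for every sequenced sample.
#' @param per_family data frame whose first column is `family_id` and
#'   whose remaining columns are the per-family counts of stages
#'   2, 3, ... in funnel order.
#' @param stage_labels labels for all stages (stage 1 first); defaults to
#'   the first column name `"detected"` followed by the `per_family`
#'   stage column names.
#' @return Object of class `funnel_table`: list with `stage_labels`,
#'   `per_sample`, `per_family` (wide, stage-1 value = family mean),
#'   `averages`, `percentages` (rounded, named by stage) and their
#'   unrounded counterparts `averages_raw`, `percentages_raw`.
#' @export
summarize_funnel <- function(per_sample, per_family, stage_labels = NULL) {
  stopifnot(is.data.frame(per_sample), is.data.frame(per_family),
            all(c("family_id", "member_id", "count") %in% names(per_sample)),
            names(per_family)[1] == "family_id")
  if (is.null(stage_labels))
    stage_labels <- c("detected", names(per_family)[-1])
  n_stage <- ncol(per_family) # stage1 + (ncol-1) later stages
  if (length(stage_labels) != n_stage)
    stop("stage_labels must name all ", n_stage, " stages")

  fam_ids <- unique(per_sample$family_id)
  if (!setequal(fam_ids, per_family$family_id))
    stop("per_sample and per_family must cover the same families")
  per_family <- per_family[match(fam_ids, per_family$family_id), , drop = FALSE]

  stage1 <- vapply(fam_ids, function(f)
    mean(per_sample$count[per_sample$family_id == f]), 0)
  wide <- data.frame(family_id = fam_ids, stage1 = stage1,
                     per_family[, -1, drop = FALSE],
                     stringsAsFactors = FALSE, row.names = NULL)
  names(wide) <- c("family_id", stage_labels)

  vals <- as.matrix(wide[, -1, drop = FALSE])
  if (any(apply(vals, 1, function(r) any(diff(r) > 1e-9))))
    warning("funnel counts increase along stages for at least one family")

  avg_raw <- colMeans(vals)
  avg <- round_half_up(avg_raw)
  pct_raw <- if (avg[1] > 0) avg / avg[1] * 100 else rep(NA_real_, length(avg))
  structure(list(
    stage_labels = stage_labels,
    per_sample = per_sample,
    per_family = wide,
    averages = setNames(avg, stage_labels),
    percentages = setNames(round_half_up(pct_raw, 2), stage_labels),
    averages_raw = setNames(avg_raw, stage_labels),
    percentages_raw = setNames(pct_raw, stage_labels)
  ), class = "funnel_table")
}

#' @export
print.funnel_table <- function(x, ...) {
  m <- rbind(Average = x$averages, `Percentage remaining` =
               formatC(x$percentages, format = "f", digits = 2))
  tab <- x$per_family
  tab[, -1] <- lapply(tab[, -1, drop = FALSE],
                      function(v) formatC(v, format = "fg"))
  print(tab, row.names = FALSE)
  cat("---\n")
  print(m, quote = FALSE)
  invisible(x)
}

#' Write a funnel table as TSV
#'
#' Mirrors the layout of a filtering-summary table: one row per family
#' (stage-1 value = family mean of sample counts), then `Average` and
#' `Percentage remaining` rows.
#'
#' @param x a [funnel_table][summarize_funnel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_funnel_tsv <- function(x, path) {
  stopifnot(inherits(x, "funnel_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("family_id", x$stage_labels), collapse = "\t"), con)
  for (i in seq_len(nrow(x$per_family))) {
    writeLines(paste(unlist(x$per_family[i, ]), collapse = "\t"), con)
  }
  writeLines(paste(c("Average", x$averages), collapse = "\t"), con)
  writeLines(paste(c("Percentage remaining",
                     formatC(x$percentages, format = "f", digits = 2)),
                   collapse = "\t"), con)
  invisible(path)
}

#' Read worked-example funnel counts
#'
#' Reads a TSV of per-sample first-stage counts plus per-family counts
#' for the later stages (later-stage cells empty on all but one row per
#' family), as shipped in `inst/extdata/`, and splits it into the
#' `per_sample` / `per_family` inputs of [summarize_funnel()].
#'
#' @param path TSV with columns `family_id`, `member_id`, a first-stage
#'   count column, then one column per later stage.
#' @return List with elements `per_sample` and `per_family`.
#' @export
read_funnel_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(family_id = "character",
                                         member_id = "character"))
  stage_cols <- setdiff(names(df), c("family_id", "member_id"))
  per_sample <- data.frame(family_id = df$family_id, member_id = df$member_id,
                           count = df[[stage_cols[1]]], stringsAsFactors = FALSE)
  later <- df[!is.na(df[[stage_cols[2]]]), c("family_id", stage_cols[-1]),
              drop = FALSE]
  rownames(later) <- NULL
  list(per_sample = per_sample, per_family = later)
}
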