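# Rare-variant case-control statistics, MAF screening, segregation and
# candidate prioritization.

#' 2x2 allele-count contingency table
#'
#' @param a case variant alleles.
#' @param b case reference alleles.
#' @param c_ control variant alleles.
#' @param d control reference alleles.
#' @return Object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c_, d) {
  cells <- c(a = a, b = b, c = c_, d = d)
  if (any(is.na(cells)) || any(cells < 0))
    stop("contingency cells must be non-negative counts")
  structure(as.list(cells), class = "contingency_table")
}

#' Allele-count table from carrier counts
#'
#' Builds the 2x2 allele table for a rare variant from per-arm carrier
#' counts: each carrier contributes one variant allele (no homozygous
#' carriers assumed for rare variants), so the reference-allele cells are
#' `2 * n - carriers`.
#'
#' @param carriers_cases,n_cases carriers among cases / number of cases.
#' @param carriers_controls,n_controls same for controls.
#' @return A [contingency_table()] `(a, b, c, d)` =
#'   `(carriers_cases, 2*n_cases - carriers_cases, carriers_controls,
#'   2*n_controls - carriers_controls)`.
#' @examples
#' allele_table(10, 3409, 5, 3896)  # a=10, b=6808, c=5, d=7787
#' @export
allele_table <- function(carriers_cases, n_cases, carriers_controls, n_controls) {
  if (carriers_cases > n_cases || carriers_controls > n_controls)
    stop("carrier count exceeds sample count")
  contingency_table(carriers_cases, 2 * n_cases - carriers_cases,
                    carriers_controls, 2 * n_controls - carriers_controls)
}

#' Two-sided Fisher exact test p-value
#'
#' Computes the two-sided p-value by the point-probability rule: the sum
#' of hypergeometric probabilities of all tables with the observed
#' margins whose point probability does not exceed that of the observed
#' table (within relative tolerance 1e-7). This is the convention used
#' by standard genetic association software.
#'
#' @param tab a [contingency_table()].
#' @return p-value in `[0, 1]`.
#' @examples
#' fisher_exact_two_sided(contingency_table(10, 6808, 5, 7787))
#' @export
fisher_exact_two_sided <- function(tab) {
  stopifnot(inherits(tab, "contingency_table"))
  a <- tab$a; b <- tab$b; c_ <- tab$c; d <- tab$d
  m <- a + b          # row 1 margin
  n <- c_ + d         # row 2 margin
  k <- a + c_         # column 1 margin
  if (m == 0 || n == 0) stop("both row margins must be positive")
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- dens[support == a]
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = (a*d) / (b*c)`, with a 95% confidence interval on the log scale
#' (Woolf): `exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. A
#' table with any zero cell yields `NA`s under the `"na"` policy, or has
#' 0.5 added to every cell under `"haldane"`.
#'
#' @param tab a [contingency_table()].
#' @param zero_policy `"na"` or `"haldane"`.
#' @return List with `odds_ratio`, `ci_low`, `ci_high`.
#' @export
odds_ratio_ci <- function(tab, zero_policy = c("na", "haldane")) {
  stopifnot(inherits(tab, "contingency_table"))
  zero_policy <- match.arg(zero_policy)
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  if (any(cells == 0)) {
    if (zero_policy == "na")
      return(list(odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
    cells <- cells + 0.5
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  list(odds_ratio = or,
       ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se))
}

#' Case-control association for a rare variant
#'
#' Convenience wrapper assembling the allele table from carrier counts
#' and computing allele frequencies, the two-sided Fisher exact p-value
#' and the odds ratio with its Woolf 95% CI.
#'
#' @inheritParams allele_table
#' @inheritParams odds_ratio_ci
#' @return Object of class `association_result`: list with `table`,
#'   `freq_cases`, `freq_controls`, `p_value`, `odds_ratio`, `ci_low`,
#'   `ci_high`.
#' @examples
#' case_control_association(10, 3409, 5, 3896)
#' @export
case_control_association <- function(carriers_cases, n_cases,
                                     carriers_controls, n_controls,
                                     zero_policy = c("na", "haldane")) {
  tab <- allele_table(carriers_cases, n_cases, carriers_controls, n_controls)
  or <- odds_ratio_ci(tab, zero_policy)
  structure(list(
    table = tab,
    freq_cases = tab$a / (tab$a + tab$b),
    freq_controls = tab$c / (tab$c + tab$d),
    p_value = fisher_exact_two_sided(tab),
    odds_ratio = or$odds_ratio, ci_low = or$ci_low, ci_high = or$ci_high
  ), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "<association_result> allele freq cases %.5f, controls %.5f\n  OR = %s (95%% CI %s-%s), two-sided Fisher p = %.4g\n",
    x$freq_cases, x$freq_controls,
    ifelse(is.na(x$odds_ratio), "NA", sprintf("%.3f", x$odds_ratio)),
    ifelse(is.na(x$ci_low), "NA", sprintf("%.3f", x$ci_low)),
    ifelse(is.na(x$ci_high), "NA", sprintf("%.3f", x$ci_high)),
    x$p_value))
  invisible(x)
}

#' Control-population minor allele frequency screen
#'
#' `MAF = carriers / (2 * n_individuals)` for a rare heterozygous
#' variant; the variant is discarded when the MAF strictly exceeds the
#' threshold (default 1%).
#'
#' @param carriers carrier count in the control panel.
#' @param n_individuals panel size.
#' @param threshold MAF threshold (strict).
#' @return `"discard"` or `"retain"`.
#' @export
maf_screen <- function(carriers, n_individuals, threshold = 0.01) {
  if (carriers > n_individuals) stop("carrier count exceeds panel size")
  maf <- carriers / (2 * n_individuals)
  if (maf > threshold) "discard" else "retain"
}

#' Segregation of a candidate variant in a family
#'
#' Computes the fraction of available affected family members (with
#' known carrier status) who carry the variant; the variant segregates
#' when that fraction reaches 50%. Affected non-carriers diagnosed at or
#' above `age_threshold` are flagged as candidate phenocopies: late-onset
#' disease in a non-carrier is compatible with a sporadic case rather
#' than evidence against the variant.
#'
#' @param members data frame with columns `member_id`, `affected`
#'   (logical), `available` (logical), `carrier_status` (`"carrier"`,
#'   `"non-carrier"` or `"unknown"`), `diagnosis_age` (years, `NA`
#'   allowed).
#' @param age_threshold phenocopy age threshold in years (default 70).
#' @param rule `"geq"` (pass at exactly 50%, default) or `"gt"`
#'   (strictly over 50%).
#' @return Object of class `segregation_report`: list with
#'   `carriers_affected`, `available_affected`, `fraction`, `passes`,
#'   `phenocopy_flags` (member ids).
#' @export
segregation <- function(members, age_threshold = 70, rule = c("geq", "gt")) {
  rule <- match.arg(rule)
  req <- c("member_id", "affected", "available", "carrier_status")
  miss <- setdiff(req, names(members))
  if (length(miss)) stop("members lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(members$diagnosis_age)) members$diagnosis_age <- NA_real_
  eligible <- members$affected & members$available &
    members$carrier_status != "unknown"
  if (!any(eligible))
    stop("no available affected member with known carrier status")
  carriers <- sum(members$carrier_status[eligible] == "carrier")
  avail <- sum(eligible)
  fraction <- carriers / avail
  pheno <- members$member_id[
    members$affected & members$carrier_status == "non-carrier" &
      !is.na(members$diagnosis_age) & members$diagnosis_age >= age_threshold]
  structure(list(
    carriers_affected = carriers,
    available_affected = avail,
    fraction = fraction,
    passes = if (rule == "geq") fraction >= 0.5 else fraction > 0.5,
    phenocopy_flags = pheno
  ), class = "segregation_report")
}

#' @export
print.segregation_report <- function(x, ...) {
  cat(sprintf("<segregation_report> %d/%d available affected carriers (%.1f%%): %s\n",
              x$carriers_affected, x$available_affected, 100 * x$fraction,
              if (x$passes) "segregates" else "does not segregate"))
  if (length(x$phenocopy_flags))
    cat("  candidate phenocopies:", paste(x$phenocopy_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Prioritize candidate variants
#'
#' A candidate is selected iff (OR > 2 OR absent from controls) AND
#' predicted damaging by at least one predictor AND segregating (or
#' segregation not assessable, encoded as `NA`). Missing OR/control
#' counts or missing damaging flags count as non-passing for their
#' criterion. Output is ordered by selection status, then OR descending
#' with `NA` last.
#'
#' @param candidates data frame with columns `odds_ratio` (numeric, `NA`
#'   allowed), `control_carriers` (count, `NA` allowed), `damaging`
#'   (logical), `segregation_pass` (logical, `NA` = not assessable);
#'   other columns (ids, genes) are carried through.
#' @return `candidates` with a logical `selected` column, reordered.
#' @export
prioritize <- function(candidates) {
  stopifnot(is.data.frame(candidates),
            all(c("odds_ratio", "control_carriers", "damaging",
                  "segregation_pass") %in% names(candidates)))
  or_crit <- (!is.na(candidates$odds_ratio) & candidates$odds_ratio > 2) |
    (!is.na(candidates$control_carriers) & candidates$control_carriers == 0)
  dmg <- !is.na(candidates$damaging) & candidates$damaging
  seg <- is.na(candidates$segregation_pass) | candidates$segregation_pass
  candidates$selected <- or_crit & dmg & seg
  ord <- order(-candidates$selected,
               -ifelse(is.na(candidates$odds_ratio), -Inf, candidates$odds_ratio))
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
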