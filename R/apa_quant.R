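# qPCR quantification: 2^-ddCt relative expression, the long/total
# transcript ratio, and the OE-up / KD-down responsiveness classification.

#' Relative expression by the 2^-ddCt method
#'
#' Computes `base^-((ct_target - ct_reference) - (ct_target_cal -
#' ct_reference_cal))`: the expression of a target normalized to a
#' reference gene, relative to a calibrator sample. All arguments are
#' vectorized.
#'
#' @param ct_target,ct_reference Ct of the target and reference amplicon in
#'   the sample of interest.
#' @param ct_target_cal,ct_reference_cal the same in the calibrator sample.
#' @param base amplification base; 2 corresponds to perfect PCR efficiency.
#' @return relative expression (1 when all four Ct are equal).
#' @export
ddct_relative <- function(ct_target, ct_reference,
                          ct_target_cal, ct_reference_cal, base = 2) {
  vals <- c(ct_target, ct_reference, ct_target_cal, ct_reference_cal)
  if (!all(is.finite(vals))) stopf("all Ct values must be finite")
  if (base <= 1) stopf("base must exceed 1")
  ddct <- (ct_target - ct_reference) - (ct_target_cal - ct_reference_cal)
  base^-ddct
}

#' Long/total transcript ratio for one measurement pair
#'
#' Converts Ct values to abundances via `base^-Ct` when needed and returns
#' `abundance_long / abundance_total`. Ratios below 1 indicate that part of
#' the gene's transcripts end before the distal site (3'UTR shortening
#' lowers the ratio further).
#'
#' @param long,total measured values for the long-isoform-specific and the
#'   common (total) amplicon.
#' @param value_kind `"Ct"` or `"abundance"`.
#' @param base amplification base for Ct conversion.
#' @return the ratio (NA with a warning when total abundance is 0).
#' @export
long_total_ratio <- function(long, total, value_kind = c("Ct", "abundance"),
                             base = 2) {
  value_kind <- match.arg(value_kind)
  if (value_kind == "Ct") {
    if (!all(is.finite(c(long, total)))) stopf("Ct values must be finite")
    long <- base^-long
    total <- base^-total
  }
  if (any(long < 0 | total < 0)) stopf("abundances must be >= 0")
  out <- rep(NA_real_, length(long))
  zero <- total == 0
  if (any(zero)) warnf("total abundance is 0 for %d replicate(s); ratio undefined",
                       sum(zero))
  out[!zero] <- long[!zero] / total[!zero]
  out
}

#' Per-replicate long/total ratios from an expression table
#'
#' @param expr long-format table with columns `gene_id`, `condition`,
#'   `replicate`, `amplicon` (`long`/`total`), `value_kind` (`Ct` or
#'   `abundance`) and `value` — the layout written by
#'   [generate_expression()].
#' @param base amplification base for Ct conversion.
#' @return a data.frame `gene_id`, `condition`, `replicate`, `ratio`;
#'   replicates with zero total abundance are dropped with a warning.
#' @export
compute_ratios <- function(expr, base = 2) {
  need <- c("gene_id", "condition", "replicate", "amplicon", "value_kind",
            "value")
  if (!all(need %in% names(expr)))
    stopf("expression table must have columns: %s", paste(need, collapse = ", "))
  wide <- merge(
    expr[expr$amplicon == "long",
         c("gene_id", "condition", "replicate", "value_kind", "value")],
    expr[expr$amplicon == "total",
         c("gene_id", "condition", "replicate", "value_kind", "value")],
    by = c("gene_id", "condition", "replicate", "value_kind"),
    suffixes = c("_long", "_total"))
  if (nrow(wide) * 2 != nrow(expr))
    warnf("%d measurement(s) lacked a matching long/total partner and were dropped",
          nrow(expr) - nrow(wide) * 2)
  kinds <- unique(wide$value_kind)
  if (length(kinds) > 1) stopf("mixed value_kind in one table")
  wide$ratio <- long_total_ratio(wide$value_long, wide$value_total,
                                 value_kind = kinds, base = base)
  keep <- !is.na(wide$ratio)
  out <- wide[keep, c("gene_id", "condition", "replicate", "ratio")]
  out <- out[order(out$gene_id, out$condition, out$replicate), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Exact permutation p-value for small untied samples (combined n <= 12),
#' normal approximation with tie and continuity correction otherwise.
#' Returns 1 when every value is tied across both groups.
#'
#' @param group_a,group_b numeric vectors (each of length >= 3).
#' @return the two-sided p-value.
#' @export
rank_test <- function(group_a, group_b) {
  if (length(group_a) < 3 || length(group_b) < 3)
    stopf("each group must have >= 3 values")
  if (length(unique(c(group_a, group_b))) == 1) return(1)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- !ties && (length(group_a) + length(group_b)) <= 12
  p <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = exact, correct = TRUE)$p.value)
  min(p, 1)
}

#' Classify NUDT21 responsiveness from long/total ratios
#'
#' A gene is responsive when its mean ratio rises at least `min_fold`-fold
#' under overexpression and falls at least `min_fold`-fold under knockdown
#' (every knockdown by default): `mean R(OE) >= min_fold * mean R(control)`
#' and `mean R(KDi) <= mean R(control) / min_fold`. Rank-sum p-values for
#' each comparison are reported when both groups have >= 3 replicates but
#' do not gate the call.
#'
#' @param ratios output of [compute_ratios()]: `gene_id`, `condition`,
#'   `replicate`, `ratio`. Conditions must include `control`, `OE` and at
#'   least one condition matching `^KD`.
#' @param min_fold minimal fold change in both directions (default 1.2; 1
#'   reduces the rule to a pure direction check).
#' @param require_all_kd if `TRUE` (default) every knockdown must pass the
#'   down-fold; otherwise one suffices.
#' @return a data.frame, one row per gene: per-condition mean and sd
#'   ratios, `fold_oe`, `fold_kd` (worst-case knockdown fold under
#'   `require_all_kd`, best otherwise), `p_oe`, `p_kd` (smallest knockdown
#'   p), and `responsive`.
#' @export
classify_responsive <- function(ratios, min_fold = 1.2,
                                require_all_kd = TRUE) {
  if (min_fold < 1) stopf("min_fold must be >= 1")
  conds <- unique(ratios$condition)
  kd_conds <- sort(grep("^KD", conds, value = TRUE))
  if (!"control" %in% conds || !"OE" %in% conds || length(kd_conds) == 0)
    stopf("ratios must contain control, OE and at least one KD condition")
  rows <- lapply(split(ratios, ratios$gene_id), function(g) {
    by_cond <- split(g$ratio, g$condition)
    if (!all(c("control", "OE", kd_conds) %in% names(by_cond)))
      stopf("gene %s is missing a condition", g$gene_id[1])
    mu <- vapply(by_cond, mean, 1)
    sdv <- vapply(by_cond, function(x) if (length(x) > 1) stats::sd(x) else NA_real_, 1)
    # "increased"/"decreased" are strict: a fold of exactly 1 never passes,
    # even at min_fold = 1 (where the rule reduces to a direction check)
    up <- mu[["OE"]] > mu[["control"]] &&
      mu[["OE"]] >= min_fold * mu[["control"]]
    kd_folds <- mu[["control"]] / mu[kd_conds]   # >1 means ratio fell
    kd_pass <- kd_folds > 1 & kd_folds >= min_fold
    down <- if (require_all_kd) all(kd_pass) else any(kd_pass)
    ptest <- function(cond) {
      a <- by_cond[[cond]]; b <- by_cond[["control"]]
      if (length(a) >= 3 && length(b) >= 3) rank_test(a, b) else NA_real_
    }
    p_kd <- vapply(kd_conds, ptest, 1)
    out <- data.frame(gene_id = g$gene_id[1],
                      fold_oe = mu[["OE"]] / mu[["control"]],
                      fold_kd = if (require_all_kd) min(kd_folds) else max(kd_folds),
                      p_oe = ptest("OE"),
                      p_kd = if (all(is.na(p_kd))) NA_real_ else min(p_kd, na.rm = TRUE),
                      responsive = up && down,
                      stringsAsFactors = FALSE)
    for (cn in c("control", "OE", kd_conds)) {
      out[[paste0("mean_", cn)]] <- mu[[cn]]
      out[[paste0("sd_", cn)]] <- sdv[[cn]]
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quantify and classify in one step
#'
#' @param expr expression table (see [compute_ratios()]).
#' @param base amplification base for Ct conversion.
#' @inheritParams classify_responsive
#' @return the [classify_responsive()] table.
#' @export
quantify_responsiveness <- function(expr, base = 2, min_fold = 1.2,
                                    require_all_kd = TRUE) {
  classify_responsive(compute_ratios(expr, base = base),
                      min_fold = min_fold, require_all_kd = require_all_kd)
}
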