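# Carbon-source preference calls and final-ratio comparisons.

#' Classify carbon-source preference from monoculture CUEs
#'
#' Compares the replicate CUEs of the two monocultures on one carbon source
#' with a two-sample t-test (Welch by default). The carbon source is called
#' EC-preferred when p < alpha and the *E. coli* mean is higher, PP-preferred
#' when p < alpha and the *P. putida* mean is higher, and `"none"` otherwise.
#' No multiplicity adjustment is applied across carbon sources here.
#'
#' Degenerate inputs: if both replicate sets are constant with equal means,
#' p is taken as 1 and the call is `"none"`; constant sets with unequal
#' means are maximally separated and p is taken as 0.
#'
#' @param cue_ec replicate CUEs of the *E. coli* monoculture (>= 2 values).
#' @param cue_pp replicate CUEs of the *P. putida* monoculture (>= 2 values).
#' @param alpha significance level (default 0.05).
#' @param var_equal logical; `FALSE` (default) uses the Welch unequal-variance
#'   test, `TRUE` restores Student's pooled test.
#' @return one-row data frame: `preference` (`"EC"`, `"PP"` or `"none"`),
#'   `p_value`, `mean_cue_ec`, `mean_cue_pp`.
#' @export
classify_preference <- function(cue_ec, cue_pp, alpha = 0.05,
                                var_equal = FALSE) {
  if (length(cue_ec) < 2L || length(cue_pp) < 2L) {
    stop("at least 2 replicates per monoculture are required", call. = FALSE)
  }
  m_ec <- mean(cue_ec)
  m_pp <- mean(cue_pp)
  if (stats::sd(cue_ec) == 0 && stats::sd(cue_pp) == 0) {
    p <- if (m_ec == m_pp) 1 else 0
  } else {
    p <- stats::t.test(cue_ec, cue_pp, var.equal = var_equal)$p.value
  }
  preference <- if (p < alpha && m_ec > m_pp) "EC"
                else if (p < alpha && m_pp > m_ec) "PP"
                else "none"
  data.frame(preference = preference, p_value = p,
             mean_cue_ec = m_ec, mean_cue_pp = m_pp,
             stringsAsFactors = FALSE)
}

#' Preference calls for all carbon sources
#'
#' Applies [classify_preference()] to every carbon source of a CUE matrix,
#' using the two monoculture columns.
#'
#' @param cue a `cue_matrix` (see [extract_cue()]).
#' @param mono_ec,mono_pp culture labels of the two monocultures.
#' @inheritParams classify_preference
#' @return data frame with one row per carbon source: `carbon_id`,
#'   `preference`, `p_value`, `mean_cue_ec`, `mean_cue_pp`.
#' @export
preference_calls <- function(cue, mono_ec = "EC", mono_pp = "PP",
                             alpha = 0.05, var_equal = FALSE) {
  stopifnot(inherits(cue, "cue_matrix"))
  rows <- lapply(cue$carbons, function(cb) {
    ec <- cue_values(cue, mono_ec, cb)
    pp <- cue_values(cue, mono_pp, cb)
    cbind(data.frame(carbon_id = cb, stringsAsFactors = FALSE),
          classify_preference(ec, pp, alpha = alpha, var_equal = var_equal))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-carbon ANOVA of final ratios across cocultures
#'
#' For each carbon source, tests whether the final ratios of the cocultures
#' differ by one-way ANOVA on log10-transformed ratios, adjusts the ANOVA
#' p-values across all testable carbon sources by the Benjamini-Hochberg
#' method, and reports Tukey HSD post hoc pairs.
#'
#' Significance codes follow the adjusted p-value: `"**"` (< 0.01), `"*"`
#' (< 0.05), `"ns"` otherwise. A carbon source for which an entire coculture
#' group is missing (or any group has fewer than 2 usable replicates) is
#' flagged untestable and excluded from the BH family with a warning.
#'
#' @param ratios final-ratio table (see [final_ratios()]); only rows whose
#'   `culture` is one of `groups` are used.
#' @param groups the coculture groups to compare (default the three initial
#'   inoculum ratios).
#' @param log10_scale logical; test on log10 ratios (default `TRUE`, the
#'   transform applied before all ratio statistics) or raw ratios.
#' @return data frame with one row per carbon source: `carbon_id`,
#'   `anova_p`, `anova_p_adj`, `significance`, `untestable`; Tukey pairwise
#'   results are attached as a long data frame in `attr(, "pairwise")`
#'   (`carbon_id, group1, group2, p_adj, diff`).
#' @export
test_final_ratios <- function(ratios, groups = coculture_labels(),
                              log10_scale = TRUE) {
  ratios <- ratios[ratios$culture %in% groups & !is.na(ratios$ratio), ,
                   drop = FALSE]
  carbons <- unique(ratios$carbon_id)
  res <- data.frame(carbon_id = carbons, anova_p = NA_real_,
                    anova_p_adj = NA_real_, significance = NA_character_,
                    untestable = FALSE, stringsAsFactors = FALSE)
  pairwise <- list()
  for (i in seq_along(carbons)) {
    d <- ratios[ratios$carbon_id == carbons[i], , drop = FALSE]
    y <- if (log10_scale) d$log10_ratio else d$ratio
    g <- factor(d$culture, levels = groups)
    n_per <- table(g)
    if (length(n_per) < length(groups) || any(n_per < 2)) {
      res$untestable[i] <- TRUE
      next
    }
    fit <- stats::aov(y ~ g)
    res$anova_p[i] <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$g
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise[[length(pairwise) + 1L]] <- data.frame(
      carbon_id = carbons[i],
      group1 = vapply(pairs, `[`, "", 1L),
      group2 = vapply(pairs, `[`, "", 2L),
      diff = tk[, "diff"], p_adj = tk[, "p adj"],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (any(res$untestable)) {
    warning(sum(res$untestable), " carbon source(s) untestable (a coculture ",
            "group missing or with < 2 replicates); excluded from the BH ",
            "family", call. = FALSE)
  }
  testable <- !res$untestable
  res$anova_p_adj[testable] <- stats::p.adjust(res$anova_p[testable],
                                               method = "BH")
  res$significance[testable] <-
    ifelse(res$anova_p_adj[testable] < 0.01, "**",
           ifelse(res$anova_p_adj[testable] < 0.05, "*", "ns"))
  attr(res, "pairwise") <- if (length(pairwise)) do.call(rbind, pairwise)
                           else NULL
  res
}

#' Pairwise Wilcoxon rank-sum comparisons between groups
#'
#' Runs a Wilcoxon rank-sum test for every pair of groups, optionally
#' adjusting the p-values across the pairs by Benjamini-Hochberg (default,
#' matching the pairwise-comparison convention). Exact p-values are used for
#' small tie-free samples and a tie-corrected normal approximation
#' otherwise (the switching implemented by [stats::wilcox.test()]).
#'
#' @param values numeric observations.
#' @param groups grouping vector, same length as `values`.
#' @param adjust p-value adjustment across the pairs, any method of
#'   [stats::p.adjust()]; `"none"` disables it (default `"BH"`).
#' @return data frame with one row per pair: `group1`, `group2`, `n1`,
#'   `n2`, `p_value`, `p_adj`, `skipped` (pairs with a group of < 2 values
#'   are skipped and flagged).
#' @export
compare_groups <- function(values, groups, adjust = "BH") {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) < 2L) stop("need at least 2 groups", call. = FALSE)
  pairs <- utils::combn(lv, 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    n1 = NA_integer_, n2 = NA_integer_,
                    p_value = NA_real_, p_adj = NA_real_, skipped = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    x <- values[groups == pairs[1, k]]
    y <- values[groups == pairs[2, k]]
    out$n1[k] <- length(x)
    out$n2[k] <- length(y)
    if (length(x) < 2L || length(y) < 2L) {
      out$skipped[k] <- TRUE
      next
    }
    out$p_value[k] <- suppressWarnings(
      stats::wilcox.test(x, y)$p.value)
  }
  ok <- !out$skipped
  out$p_adj[ok] <- stats::p.adjust(out$p_value[ok], method = adjust)
  out
}
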