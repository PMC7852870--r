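# Abundance-weighted expected-CUE null model and the sequential one-sided
# interaction classifier: the core of the package.

#' Abundance-weighted expected (calculated) CUE
#'
#' The null expectation for a non-interacting coculture: the monoculture
#' CUEs weighted by the species' relative abundances in the coculture,
#' `mu2 = pA * mean(CUE_A) + pB * mean(CUE_B)`. Its dispersion `sd2` is
#' propagated assuming independence of the two monoculture measurements,
#' `sd2^2 = pA^2 var(CUE_A) + pB^2 var(CUE_B)` (default), or taken as the
#' unweighted pooled variance of the two replicate sets as a conservative
#' alternative (`variance_mode = "pooled"`).
#'
#' `n_effective` gives the replicate support behind the summary: the shared
#' monoculture replicate count when the two sets are of equal size,
#' otherwise a Welch-Satterthwaite effective count from the weighted
#' variance components.
#'
#' @param cue_a replicate CUEs of monoculture A (>= 2 values).
#' @param cue_b replicate CUEs of monoculture B (>= 2 values).
#' @param p_a relative abundance of species A in the coculture, in `[0, 1]`
#'   (the `ec_fraction` of the 24-h final ratio when A is *E. coli*).
#' @param p_b relative abundance of species B; defaults to `1 - p_a` and
#'   must satisfy `p_a + p_b = 1` within 1e-9.
#' @param variance_mode `"propagate"` (default) or `"pooled"`, see above.
#' @return An object of class `expected_cue`: list with `mu2`, `sd2`,
#'   `n_effective` and the `components` used (means, variances, replicate
#'   counts and fractions).
#' @examples
#' expected_cue(c(0.8, 0.8, 0.8), c(0.2, 0.2, 0.2), p_a = 0.0347)
#' @export
expected_cue <- function(cue_a, cue_b, p_a, p_b = 1 - p_a,
                         variance_mode = c("propagate", "pooled")) {
  variance_mode <- match.arg(variance_mode)
  if (length(cue_a) < 2L || length(cue_b) < 2L) {
    stop("each monoculture replicate set needs >= 2 values", call. = FALSE)
  }
  if (!is.finite(p_a) || !is.finite(p_b) ||
      p_a < 0 || p_a > 1 || p_b < 0 || p_b > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(p_a + p_b - 1) > 1e-9) {
    stop("p_a + p_b must equal 1 (tolerance 1e-9)", call. = FALSE)
  }
  n_a <- length(cue_a); n_b <- length(cue_b)
  m_a <- mean(cue_a); m_b <- mean(cue_b)
  v_a <- stats::var(cue_a); v_b <- stats::var(cue_b)
  mu2 <- p_a * m_a + p_b * m_b
  var2 <- switch(variance_mode,
    propagate = p_a^2 * v_a + p_b^2 * v_b,
    pooled = ((n_a - 1) * v_a + (n_b - 1) * v_b) / (n_a + n_b - 2)
  )
  if (n_a == n_b) {
    n_eff <- n_a
  } else {
    w_a <- p_a^2 * v_a; w_b <- p_b^2 * v_b
    if (w_a + w_b == 0) {
      n_eff <- min(n_a, n_b)
    } else {
      df_ws <- (w_a + w_b)^2 / (w_a^2 / (n_a - 1) + w_b^2 / (n_b - 1))
      n_eff <- floor(df_ws) + 1L
    }
  }
  structure(list(mu2 = mu2, sd2 = sqrt(var2), n_effective = n_eff,
                 components = list(mean_a = m_a, mean_b = m_b,
                                   var_a = v_a, var_b = v_b,
                                   n_a = n_a, n_b = n_b,
                                   p_a = p_a, p_b = p_b),
                 variance_mode = variance_mode),
            class = "expected_cue")
}

#' @export
print.expected_cue <- function(x, ...) {
  cat(sprintf("expected CUE: mu2 = %.4f, sd2 = %.4f (n_eff = %d, %s)\n",
              x$mu2, x$sd2, x$n_effective, x$variance_mode))
  with(x$components,
       cat(sprintf("  components: %.3f * %.4f + %.3f * %.4f\n",
                   p_a, mean_a, p_b, mean_b)))
  invisible(x)
}

# Welch summary-form t: sample 1 given as replicates, sample 2 as
# (mean, sd, n) summary. Returns t and Welch-Satterthwaite df.
.welch_summary <- function(m1, s1, n1, m2, s2, n2) {
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  se2 <- v1 + v2
  if (se2 == 0) {
    return(list(t = if (m1 == m2) 0 else sign(m1 - m2) * Inf, df = Inf))
  }
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = (m1 - m2) / sqrt(se2), df = df)
}

#' Classify one coculture interaction against its expected CUE
#'
#' Sequential one-sided Welch tests of the measured coculture CUE (mean
#' `mu1`) against the abundance-weighted expected CUE (`mu2`), both assumed
#' normally distributed:
#'
#' 1. Test the positive direction (alternative `mu1 > mu2`). If its p-value
#'    is below `alpha`, the interaction is **positive**.
#' 2. Otherwise test the negative direction (alternative `mu1 < mu2`). If
#'    its p-value is below `alpha`, the interaction is **negative**.
#' 3. Otherwise the interaction is **unresolved**.
#'
#' The expected CUE enters as a summary-form second sample
#' (`mu2`, `sd2`, `n_effective`); degrees of freedom follow
#' Welch-Satterthwaite. No multiplicity correction is applied across the two
#' branches. When both dispersions are zero and `mu1 == mu2`, both p-values
#' are set to 1 and the call is unresolved.
#'
#' @param measured replicate CUEs of the coculture (>= 2 values).
#' @param expected an `expected_cue` object.
#' @param alpha significance level (default 0.05).
#' @return one-row data frame: `mode` (`"positive"`, `"negative"`,
#'   `"unresolved"`), `mu1`, `mu2`, `p_pos` (first, positive-direction
#'   branch), `p_neg` (second branch; `NA` when not reached).
#' @seealso [bounds_precheck()] for the simple bounds rule this test
#'   refines, [classify_interactions()] for whole-experiment use.
#' @export
classify_interaction <- function(measured, expected, alpha = 0.05) {
  stopifnot(inherits(expected, "expected_cue"))
  if (length(measured) < 2L) {
    stop("at least 2 measured coculture replicates are required",
         call. = FALSE)
  }
  m1 <- mean(measured)
  s1 <- stats::sd(measured)
  w <- .welch_summary(m1, s1, length(measured),
                      expected$mu2, expected$sd2, expected$n_effective)
  if (is.infinite(w$df)) {
    # both dispersions zero: decisive unless the means coincide
    p_pos <- if (w$t > 0) 0 else 1
    p_neg <- if (w$t < 0) 0 else 1
  } else {
    p_pos <- stats::pt(w$t, w$df, lower.tail = FALSE)
    p_neg <- stats::pt(w$t, w$df, lower.tail = TRUE)
  }
  if (p_pos < alpha) {
    mode <- "positive"
    p_neg_out <- NA_real_
  } else if (p_neg < alpha) {
    mode <- "negative"
    p_neg_out <- p_neg
  } else {
    mode <- "unresolved"
    p_neg_out <- p_neg
  }
  data.frame(mode = mode, mu1 = m1, mu2 = expected$mu2,
             p_pos = p_pos, p_neg = p_neg_out, stringsAsFactors = FALSE)
}

#' Simple bounds rule for an interaction call
#'
#' The coarse legacy classification that the hypothesis-test model refines:
#' positive if the coculture CUE exceeds the larger monoculture mean,
#' negative if it falls below the smaller one, unresolved in between.
#'
#' @param measured_mean mean measured coculture CUE.
#' @param cue_a_mean,cue_b_mean monoculture mean CUEs (order irrelevant;
#'   they are sorted internally).
#' @return `"positive"`, `"negative"` or `"unresolved"` (vectorised over
#'   `measured_mean`).
#' @export
bounds_precheck <- function(measured_mean, cue_a_mean, cue_b_mean) {
  hi <- pmax(cue_a_mean, cue_b_mean)
  lo <- pmin(cue_a_mean, cue_b_mean)
  ifelse(measured_mean > hi, "positive",
         ifelse(measured_mean < lo, "negative", "unresolved"))
}

#' Classify all coculture interactions of an experiment
#'
#' Runs the abundance-weighted interaction classifier for every
#' (coculture, carbon source) pair: the species fractions come from the
#' coculture's 24-h final ratios (averaged over replicates by default), the
#' expected CUE from the two monocultures' replicate CUEs, and the call from
#' [classify_interaction()]. The simple bounds rule is reported alongside in
#' `bounds_mode`.
#'
#' @param cue a `cue_matrix` containing the monocultures and cocultures.
#' @param ratios final-ratio table (see [final_ratios()]).
#' @param alpha significance level (default 0.05).
#' @param variance_mode variance propagation for the expected CUE, see
#'   [expected_cue()].
#' @param cocultures coculture labels to classify.
#' @param mono_ec,mono_pp monoculture labels.
#' @return An object of class `interaction_calls`: a data frame with one
#'   row per (culture, carbon_id) holding `mode`, `mu1`, `mu2`, `p_pos`,
#'   `p_neg`, `ec_fraction` and `bounds_mode`. Pairs without any usable
#'   final ratio are flagged `mode = NA` with flag `"no_ratio"`.
#' @export
classify_interactions <- function(cue, ratios, alpha = 0.05,
                                  variance_mode = "propagate",
                                  cocultures = coculture_labels(),
                                  mono_ec = "EC", mono_pp = "PP") {
  stopifnot(inherits(cue, "cue_matrix"))
  cocultures <- intersect(cocultures, cue$cultures)
  rows <- vector("list", length(cocultures) * length(cue$carbons))
  k <- 0L
  for (cc in cocultures) {
    for (cb in cue$carbons) {
      k <- k + 1L
      measured <- cue_values(cue, cc, cb)
      ec <- cue_values(cue, mono_ec, cb)
      pp <- cue_values(cue, mono_pp, cb)
      fr <- ratios$ec_fraction[ratios$culture == cc &
                               ratios$carbon_id == cb &
                               !is.na(ratios$ec_fraction)]
      base <- data.frame(culture = cc, carbon_id = cb,
                         stringsAsFactors = FALSE)
      if (!length(fr) || length(measured) < 2L ||
          length(ec) < 2L || length(pp) < 2L) {
        rows[[k]] <- cbind(base, data.frame(
          mode = NA_character_, mu1 = NA_real_, mu2 = NA_real_,
          p_pos = NA_real_, p_neg = NA_real_, ec_fraction = NA_real_,
          bounds_mode = NA_character_, flag = "no_ratio",
          stringsAsFactors = FALSE))
        next
      }
      p_a <- mean(fr)
      exp_cue <- expected_cue(ec, pp, p_a = p_a,
                              variance_mode = variance_mode)
      call <- classify_interaction(measured, exp_cue, alpha = alpha)
      call$ec_fraction <- p_a
      call$bounds_mode <- bounds_precheck(call$mu1, mean(ec), mean(pp))
      call$flag <- ""
      rows[[k]] <- cbind(base, call)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("interaction_calls", "data.frame"),
            alpha = alpha, variance_mode = variance_mode)
}

#' @export
print.interaction_calls <- function(x, ...) {
  cat("Interaction calls (alpha = ", attr(x, "alpha"), ", variance mode '",
      attr(x, "variance_mode"), "')\n", sep = "")
  print(summarize_interactions(x))
  invisible(x)
}

#' Summarise interaction calls into mode proportions
#'
#' Tabulates the proportion of positive / negative / unresolved calls per
#' coculture, optionally stratified by a carbon annotation column
#' (`usage_group` or `preference`). Proportions in each row sum to 1 over
#' the three modes; stratified rows partition the same calls.
#'
#' @param calls an `interaction_calls` object (or data frame with `culture`,
#'   `carbon_id`, `mode`).
#' @param annotation optional carbon annotation data frame with `carbon_id`
#'   and the stratification column.
#' @param by `NULL` (no stratification), `"usage_group"` or `"preference"`.
#' @return data frame with columns `culture`, optionally the stratum, `n`,
#'   `positive`, `negative`, `unresolved` (proportions).
#' @export
summarize_interactions <- function(calls, annotation = NULL, by = NULL) {
  d <- as.data.frame(calls)
  d <- d[!is.na(d$mode), , drop = FALSE]
  if (!is.null(by)) {
    if (is.null(annotation) || !all(c("carbon_id", by) %in%
                                    names(annotation))) {
      stop("stratified summaries need an `annotation` with columns ",
           "'carbon_id' and '", by, "'", call. = FALSE)
    }
    d$stratum <- annotation[[by]][match(d$carbon_id, annotation$carbon_id)]
    keys <- unique(d[, c("culture", "stratum")])
  } else {
    keys <- unique(d[, "culture", drop = FALSE])
  }
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- d$culture == keys$culture[i]
    if (!is.null(by)) sel <- sel & d$stratum == keys$stratum[i]
    sub <- d[sel, , drop = FALSE]
    n <- nrow(sub)
    out <- data.frame(culture = keys$culture[i], stringsAsFactors = FALSE)
    if (!is.null(by)) out[[by]] <- keys$stratum[i]
    out$n <- n
    out$positive <- mean(sub$mode == "positive")
    out$negative <- mean(sub$mode == "negative")
    out$unresolved <- mean(sub$mode == "unresolved")
    out
  })
  out <- do.call(rbind, rows)
  ord <- order(match(out$culture, culture_labels()))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
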