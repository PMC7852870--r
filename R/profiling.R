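# Usage-group clustering, ordination and CUE regression.

#' Cluster carbon sources into usage groups
#'
#' Agglomerative hierarchical clustering (complete linkage by default,
#' Euclidean distance) of the replicate-level CUE matrix (carbons x
#' culture-replicate columns), cut into `k` groups. Group labels are made
#' deterministic by ordering clusters on ascending within-group mean CUE:
#' the lowest-CUE cluster is `U1` (in the study design, carbon sources that
#' are difficult for every culture), the next `U2`, and so on. The
#' culture-replicate side (columns) is clustered analogously and returned as
#' a second dendrogram.
#'
#' @param cue a `cue_matrix`, complete for the clustered cells (missing
#'   entries are imputed by the carbon's mean CUE, with a warning).
#' @param k number of usage groups (default 3).
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"complete"`).
#' @param distance distance metric for [stats::dist()] (default
#'   `"euclidean"`).
#' @return An object of class `usage_groups`: list with `assignments`
#'   (data frame `carbon_id, usage_group`), `sizes`, `carbon_hclust`,
#'   `culture_hclust` and `k`.
#' @export
cluster_usage_groups <- function(cue, k = 3, linkage = "complete",
                                 distance = "euclidean") {
  stopifnot(inherits(cue, "cue_matrix"))
  m <- as.matrix(cue)
  if (k < 1 || k > nrow(m)) {
    stop("`k` must be between 1 and the number of carbon sources",
         call. = FALSE)
  }
  if (anyNA(m)) {
    warning("missing CUE entries imputed by the carbon's mean CUE",
            call. = FALSE)
    for (i in which(rowSums(is.na(m)) > 0)) {
      m[i, is.na(m[i, ])] <- mean(m[i, ], na.rm = TRUE)
    }
  }
  hc <- stats::hclust(stats::dist(m, method = distance), method = linkage)
  raw <- if (k == 1L) rep(1L, nrow(m)) else stats::cutree(hc, k = k)
  group_mean <- tapply(rowMeans(m), raw, mean)
  relabel <- match(names(sort(group_mean)), names(group_mean))
  labels <- paste0("U", match(raw, relabel))
  hc_cult <- stats::hclust(stats::dist(t(m), method = distance),
                           method = linkage)
  assignments <- data.frame(carbon_id = rownames(m), usage_group = labels,
                            stringsAsFactors = FALSE)
  structure(list(assignments = assignments,
                 sizes = table(factor(labels, levels = paste0("U", 1:k))),
                 carbon_hclust = hc, culture_hclust = hc_cult, k = k),
            class = "usage_groups")
}

#' @export
print.usage_groups <- function(x, ...) {
  cat("Carbon usage groups (complete-linkage clustering, k = ", x$k, ")\n",
      sep = "")
  print(x$sizes)
  invisible(x)
}

#' @export
plot.usage_groups <- function(x, side = c("carbon", "culture"), ...) {
  side <- match.arg(side)
  hc <- if (side == "carbon") x$carbon_hclust else x$culture_hclust
  plot(hc, main = paste("Usage-group dendrogram:", side, "side"),
       xlab = "", sub = "", ...)
  invisible(x)
}

#' Principal component analysis of CUE profiles
#'
#' Centred (by default unscaled, since all CUE values share one scale) PCA
#' of the replicate-level CUE matrix with carbon sources as observations.
#' Component signs are fixed by a deterministic convention: within each
#' component the loading of largest magnitude is made positive.
#'
#' @param cue a `cue_matrix`.
#' @param center,scale. passed to [stats::prcomp()] (defaults: centring on,
#'   scaling off).
#' @return An object of class `cue_pca`: list with `scores` (carbons x
#'   components), `loadings` (columns x components), `var_explained`
#'   (proportions summing to 1) and `sdev`. A constant matrix yields a
#'   zero-variance warning and empty components.
#' @export
pca_profiles <- function(cue, center = TRUE, scale. = FALSE) {
  stopifnot(inherits(cue, "cue_matrix"))
  m <- as.matrix(cue)
  if (anyNA(m)) stop("PCA requires a complete CUE matrix", call. = FALSE)
  if (all(apply(m, 2, stats::var) == 0)) {
    warning("CUE matrix has zero variance; no components returned",
            call. = FALSE)
    return(structure(list(scores = m[, 0, drop = FALSE],
                          loadings = matrix(nrow = ncol(m), ncol = 0),
                          var_explained = numeric(0), sdev = numeric(0)),
                     class = "cue_pca"))
  }
  p <- stats::prcomp(m, center = center, scale. = scale.)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    lo <- p$rotation[, j]
    sign(lo[which.max(abs(lo))])
  }, numeric(1))
  scores <- sweep(p$x, 2, flip, `*`)
  loadings <- sweep(p$rotation, 2, flip, `*`)
  structure(list(scores = scores, loadings = loadings,
                 var_explained = p$sdev^2 / sum(p$sdev^2), sdev = p$sdev,
                 center = p$center, scale = p$scale),
            class = "cue_pca")
}

#' @export
print.cue_pca <- function(x, ...) {
  cat("PCA of CUE profiles:", length(x$var_explained), "components\n")
  ve <- utils::head(x$var_explained, 5)
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_along(ve), 100 * ve),
            collapse = ", "), "\n")
  invisible(x)
}

#' Build the regression table for CUE modelling
#'
#' Joins coculture CUE observations with the per-carbon annotations into
#' the table consumed by [regress_cue()]. Monocultures are excluded: no
#' initial inoculum ratio is defined for them.
#'
#' @param cue a `cue_matrix`.
#' @param annotation data frame with `carbon_id`, `preference`,
#'   `usage_group` (see [annotate_carbons()]).
#' @param cocultures coculture labels to keep.
#' @return data frame with columns `cue`, `usage_group`, `initial_ratio`,
#'   `preference`, `carbon_id`, `replicate`.
#' @export
regression_table <- function(cue, annotation,
                             cocultures = coculture_labels()) {
  stopifnot(inherits(cue, "cue_matrix"))
  d <- cue$data[cue$data$culture %in% cocultures, , drop = FALSE]
  i <- match(d$carbon_id, annotation$carbon_id)
  data.frame(cue = d$cue,
             usage_group = annotation$usage_group[i],
             initial_ratio = d$culture,
             preference = annotation$preference[i],
             carbon_id = d$carbon_id,
             replicate = d$replicate,
             stringsAsFactors = FALSE)
}

#' Combine preference calls and usage groups into a carbon annotation
#'
#' @param preferences preference table from [preference_calls()].
#' @param groups a `usage_groups` object or its `assignments` data frame.
#' @return data frame `carbon_id, preference, usage_group`.
#' @export
annotate_carbons <- function(preferences, groups) {
  if (inherits(groups, "usage_groups")) groups <- groups$assignments
  out <- merge(preferences[, c("carbon_id", "preference")], groups,
               by = "carbon_id", all = TRUE, sort = TRUE)
  out
}

#' Multiple linear regression of CUE on experimental factors
#'
#' Ordinary least squares of CUE on treatment-coded categorical factors:
#' carbon usage group (reference `U1`), initial inoculum ratio (reference
#' `1:1`) and carbon preference (reference `none`). Reports per-term
#' coefficients, adjusted R^2, the overall F-test p-value, and the terms
#' ranked by influence (partial sum of squares from a type-II drop-one
#' analysis).
#'
#' @param table data frame with columns `cue`, `usage_group`,
#'   `initial_ratio`, `preference` (see [regression_table()]).
#' @return An object of class `cue_regression`: list with `fit` (the `lm`),
#'   `coefficients` (estimate, std. error, t, p per coefficient),
#'   `r_squared`, `adj_r_squared`, `overall_p`, `term_order` and
#'   `term_ss` (partial sums of squares).
#' @export
regress_cue <- function(table) {
  need <- c("cue", "usage_group", "initial_ratio", "preference")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop("regression table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  relev <- function(x, ref) {
    f <- factor(x)
    if (ref %in% levels(f)) stats::relevel(f, ref = ref) else f
  }
  d <- data.frame(cue = table$cue,
                  usage_group = relev(table$usage_group, "U1"),
                  initial_ratio = relev(table$initial_ratio, "1:1"),
                  preference = relev(table$preference, "none"))
  terms_used <- c("usage_group", "initial_ratio", "preference")
  terms_used <- terms_used[vapply(d[terms_used], nlevels, 1L) >= 2L]
  if (!length(terms_used)) {
    stop("no factor with >= 2 levels to regress on", call. = FALSE)
  }
  form <- stats::as.formula(paste("cue ~", paste(terms_used, collapse = " + ")))
  fit <- stats::lm(form, data = d)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design; aliased coefficient(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  }
  sm <- .quiet_perfect_fit(summary(fit))
  fstat <- sm$fstatistic
  overall_p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  dr <- .quiet_perfect_fit(stats::drop1(fit, test = "F"))
  term_ss <- dr[["Sum of Sq"]][-1]
  names(term_ss) <- rownames(dr)[-1]
  term_order <- names(sort(term_ss, decreasing = TRUE))
  structure(list(fit = fit, coefficients = sm$coefficients,
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 overall_p = unname(overall_p),
                 term_ss = term_ss, term_order = term_order),
            class = "cue_regression")
}

#' @export
print.cue_regression <- function(x, ...) {
  cat("CUE regression (OLS, treatment coding)\n")
  cat(sprintf("  adjusted R^2 = %.4f (R^2 = %.4f), overall p = %.3g\n",
              x$adj_r_squared, x$r_squared, x$overall_p))
  cat("  influence order:", paste(x$term_order, collapse = " > "), "\n\n")
  stats::printCoefmat(x$coefficients, digits = 4, signif.stars = FALSE)
  invisible(x)
}

#' @export
summary.cue_regression <- function(object, ...) summary(object$fit, ...)
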