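# qPCR standard curves, template quantification and final species ratios.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(template concentration) over a
#' serial dilution series (the study design: 4-fold dilutions from a maximum
#' of 10 ng/uL, standards run in triplicate and fitted as individual points
#' so residual degrees of freedom are preserved for R^2).
#'
#' A warning is emitted when R^2 < 0.98 or when the fitted slope is
#' non-negative (Ct must decrease with template concentration for a valid
#' amplification).
#'
#' @param concentration template concentrations in ng/uL, strictly positive.
#' @param ct observed Ct values (cycles), same length.
#' @return An object of class `standard_curve` with elements `slope`
#'   (Ct per log10 concentration), `intercept` (Ct at 1 ng/uL),
#'   `r_squared`, `n_points`, `conc_range` and `efficiency` (the implied
#'   amplification efficiency `10^(-1/slope)`).
#' @examples
#' conc <- 10 / 4^(0:5)
#' ct <- 20 - log2(conc / 10)        # ideal efficiency-2 amplifier
#' fit_standard_curve(conc, ct)
#' @export
fit_standard_curve <- function(concentration, ct) {
  concentration <- as.numeric(concentration)
  ct <- as.numeric(ct)
  if (length(concentration) != length(ct)) {
    stop("`concentration` and `ct` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  if (length(unique(concentration)) < 3L) {
    stop("at least 3 distinct concentrations are required to fit a ",
         "standard curve", call. = FALSE)
  }
  logc <- log10(concentration)
  fit <- stats::lm(ct ~ logc)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  # exact synthetic series fit perfectly; that is not worth a warning
  r2 <- .quiet_perfect_fit(summary(fit))$r.squared
  if (slope >= 0) {
    warning("fitted slope is non-negative; Ct should decrease with ",
            "concentration", call. = FALSE)
  }
  if (r2 < 0.98) {
    warning(sprintf("standard curve R^2 = %.3f is below 0.98", r2),
            call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 n_points = length(ct),
                 conc_range = range(concentration),
                 efficiency = 10^(-1 / slope), fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("qPCR standard curve: Ct = ",
      sprintf("%.4f %+.4f", x$intercept, x$slope),
      " * log10(conc)\n", sep = "")
  cat(sprintf("  R^2 = %.4f over %d points (%.3g-%.3g ng/uL), efficiency = %.3f\n",
              x$r_squared, x$n_points, x$conc_range[1], x$conc_range[2],
              x$efficiency))
  invisible(x)
}

#' Predict Ct from a template quantity
#'
#' The forward direction of the standard curve; [quantify()] is its inverse.
#'
#' @param curve a `standard_curve`.
#' @param quantity template quantity in ng/uL, strictly positive.
#' @return predicted Ct values (cycles).
#' @export
predict_ct <- function(curve, quantity) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(quantity <= 0)) {
    stop("quantities must be strictly positive", call. = FALSE)
  }
  curve$intercept + curve$slope * log10(quantity)
}

#' Quantify template DNA from a Ct value
#'
#' Inverts the standard curve: `quantity = 10^((ct - intercept) / slope)`.
#' Strictly decreasing in Ct for a valid (negative-slope) curve.
#'
#' @param ct Ct values (cycles); `NA` propagates.
#' @param curve a `standard_curve`.
#' @return template quantities in ng/uL.
#' @export
quantify <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) {
    stop("standard curve slope is zero; cannot quantify", call. = FALSE)
  }
  10^((ct - curve$intercept) / curve$slope)
}

#' Final ratio and species fractions from paired quantities
#'
#' Computes the final *E. coli* : *P. putida* ratio and the species
#' fractions `EC% = ratio / (1 + ratio)` and `PP% = 1 / (1 + ratio)` from
#' the two template quantities. Fractions always sum to exactly 1.
#'
#' @param ec_quantity *E. coli* template quantity, ng/uL, > 0.
#' @param pp_quantity *P. putida* template quantity, ng/uL, > 0.
#' @return data frame with columns `ratio`, `log10_ratio`, `ec_fraction`,
#'   `pp_fraction`.
#' @examples
#' compute_final_ratio(1, 1)       # ratio 1, fractions 0.5/0.5
#' compute_final_ratio(0.036, 1)   # the study's median final ratio
#' @export
compute_final_ratio <- function(ec_quantity, pp_quantity) {
  n <- max(length(ec_quantity), length(pp_quantity))
  ec_quantity <- rep_len(as.numeric(ec_quantity), n)
  pp_quantity <- rep_len(as.numeric(pp_quantity), n)
  ok_ec <- is.na(ec_quantity) | ec_quantity > 0
  ok_pp <- is.na(pp_quantity) | pp_quantity > 0
  if (!all(ok_ec)) {
    stop("non-positive E. coli (EC) quantity", call. = FALSE)
  }
  if (!all(ok_pp)) {
    stop("non-positive P. putida (PP) quantity", call. = FALSE)
  }
  ratio <- ec_quantity / pp_quantity
  ec_fraction <- ratio / (1 + ratio)
  # complement rather than 1/(1+ratio): identical to within one ulp and
  # guarantees the fractions sum to exactly 1 in floating point
  data.frame(ratio = ratio,
             log10_ratio = log10(ratio),
             ec_fraction = ec_fraction,
             pp_fraction = 1 - ec_fraction)
}

#' Read a qPCR Ct table
#'
#' CSV schema `culture,carbon_id,replicate,species,ct` with species in
#' \{EC, PP\}. Empty or `NA` Ct marks an undetermined reaction (no
#' amplification) and propagates as a missing ratio.
#'
#' @param path file path or a data frame in the same shape.
#' @return validated data frame.
#' @export
read_qpcr <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("culture", "carbon_id", "replicate", "species", "ct")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("qPCR table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(df$species %in% c("EC", "PP"))) {
    stop("species must be 'EC' or 'PP'", call. = FALSE)
  }
  df$ct <- as.numeric(df$ct)
  df[, need]
}

#' Read a qPCR standards table
#'
#' CSV schema `species,concentration,ct`.
#'
#' @param path file path or a data frame in the same shape.
#' @return validated data frame.
#' @export
read_standards <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "concentration", "ct")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("standards table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df[, need]
}

#' Final ratios for a whole experiment
#'
#' Quantifies every species-specific Ct against its standard curve and pairs
#' the two species of each (culture, carbon source, replicate) into a final
#' ratio with species fractions. Separate per-species curves are supported;
#' by default one shared curve is used for both primer sets (the two assays
#' were designed to have similar amplification efficiencies).
#'
#' Flags (`;`-separated in the `flags` column):
#' \describe{
#'   \item{`missing`}{one or both Ct values undetermined; the ratio is `NA`
#'     rather than infinite.}
#'   \item{`below_range`}{a quantity extrapolated below the lowest fitted
#'     standard.}
#' }
#'
#' @param qpcr Ct table (see [read_qpcr()]).
#' @param curve_ec standard curve for the *E. coli* assay.
#' @param curve_pp standard curve for the *P. putida* assay; defaults to
#'   `curve_ec` (shared standard).
#' @return data frame with one row per (culture, carbon_id, replicate):
#'   quantities, `ratio`, `log10_ratio`, `ec_fraction`, `pp_fraction`,
#'   `flags`.
#' @export
final_ratios <- function(qpcr, curve_ec, curve_pp = curve_ec) {
  qpcr <- read_qpcr(qpcr)
  key <- paste(qpcr$culture, qpcr$carbon_id, qpcr$replicate, sep = "\r")
  if (anyDuplicated(paste(key, qpcr$species, sep = "\r"))) {
    stop("duplicate Ct for the same (culture, carbon, replicate, species)",
         call. = FALSE)
  }
  qpcr$quantity <- ifelse(qpcr$species == "EC",
                          quantify(qpcr$ct, curve_ec),
                          quantify(qpcr$ct, curve_pp))
  lo <- ifelse(qpcr$species == "EC", curve_ec$conc_range[1],
               curve_pp$conc_range[1])
  qpcr$below_range <- !is.na(qpcr$quantity) & qpcr$quantity < lo

  split_key <- unique(key)
  idx <- match(key, split_key)
  out <- data.frame(
    culture = qpcr$culture[!duplicated(key)],
    carbon_id = qpcr$carbon_id[!duplicated(key)],
    replicate = qpcr$replicate[!duplicated(key)],
    ec_quantity = NA_real_, pp_quantity = NA_real_,
    stringsAsFactors = FALSE
  )
  below <- logical(length(split_key))
  for (s in c("EC", "PP")) {
    rows <- qpcr$species == s
    col <- if (s == "EC") "ec_quantity" else "pp_quantity"
    out[[col]][idx[rows]] <- qpcr$quantity[rows]
    below[idx[rows]] <- below[idx[rows]] | qpcr$below_range[rows]
  }
  miss <- is.na(out$ec_quantity) | is.na(out$pp_quantity)
  fr <- compute_final_ratio(ifelse(miss, NA_real_, out$ec_quantity),
                            ifelse(miss, NA_real_, out$pp_quantity))
  out <- cbind(out, fr)
  out$flags <- ifelse(miss, "missing", "")
  out$flags <- ifelse(below & !miss,
                      paste0(out$flags,
                             ifelse(nzchar(out$flags), ";", ""),
                             "below_range"),
                      out$flags)
  ord <- order(match(out$culture, culture_labels()), out$carbon_id,
               out$replicate)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
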