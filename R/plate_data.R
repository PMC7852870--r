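# Plate I/O and normalisation: raw well readings -> A1-zeroed CUE matrix.

#' Default GEN III plate layout
#'
#' Returns the well layout of a Biolog GEN III microtiter plate as used here:
#' well A1 is the negative control, the remaining 71 wells of columns 1--9
#' carry one carbon source each, and the 24 wells of columns 10--12 are
#' chemical-sensitivity wells that are parsed but excluded from analysis.
#'
#' Carbon identifiers default to `"C01" .. "C71"` in row-major order
#' (A2..A9, B1..B9, ..., H1..H9); supply `carbon_ids` to use real substrate
#' names.
#'
#' @param carbon_ids optional character vector of length 71 with carbon
#'   source identifiers, in row-major well order.
#' @param n_carbons number of carbon wells to keep (default all 71); smaller
#'   values truncate the layout for reduced designs and mark the remaining
#'   carbon wells as excluded.
#' @return A data frame with columns `well`, `carbon_id` (`NA` for
#'   non-carbon wells) and `role` (`"carbon"`, `"negative_control"` or
#'   `"excluded"`).
#' @examples
#' layout <- gen3_layout()
#' table(layout$role)
#' @export
gen3_layout <- function(carbon_ids = NULL, n_carbons = 71L) {
  rows <- LETTERS[1:8]
  wells <- as.vector(t(outer(rows, 1:12, paste0)))
  col_of <- rep(1:12, times = 8)
  layout <- data.frame(well = wells, carbon_id = NA_character_,
                       role = "excluded", stringsAsFactors = FALSE)
  carbon_wells <- wells[col_of <= 9 & wells != "A1"]
  stopifnot(length(carbon_wells) == 71L)
  if (is.null(carbon_ids)) {
    carbon_ids <- sprintf("C%02d", seq_len(71L))
  }
  if (length(carbon_ids) != 71L || anyDuplicated(carbon_ids)) {
    stop("`carbon_ids` must be 71 unique identifiers", call. = FALSE)
  }
  n_carbons <- as.integer(n_carbons)
  if (n_carbons < 1L || n_carbons > 71L) {
    stop("`n_carbons` must be between 1 and 71", call. = FALSE)
  }
  keep <- seq_len(n_carbons)
  idx <- match(carbon_wells[keep], layout$well)
  layout$carbon_id[idx] <- carbon_ids[keep]
  layout$role[idx] <- "carbon"
  layout$role[layout$well == "A1"] <- "negative_control"
  layout
}

#' Normalise well coordinates
#'
#' Well coordinates are treated case-insensitively and stored as uppercase
#' row letter plus unpadded column number (`"a01"` becomes `"A1"`).
#'
#' @param well character vector of well coordinates.
#' @return normalised character vector; invalid coordinates are returned as
#'   `NA`.
#' @examples
#' normalize_well(c("a01", "H12", "b9", "Z9"))
#' @export
normalize_well <- function(well) {
  w <- toupper(trimws(as.character(well)))
  m <- regmatches(w, regexec("^([A-H])0*([1-9][0-9]?)$", w))
  vapply(m, function(g) {
    if (length(g) != 3L) return(NA_character_)
    col <- as.integer(g[3])
    if (col < 1L || col > 12L) return(NA_character_)
    paste0(g[2], col)
  }, character(1))
}

.reading_cols <- c("plate_id", "culture", "replicate", "well",
                   "wavelength_nm", "time_h", "absorbance")

#' Read and validate plate readings
#'
#' Reads a long-format CSV of raw absorbance readings (one reading per row,
#' header `plate_id,culture,replicate,well,wavelength_nm,time_h,absorbance`)
#' and validates it against a plate layout.
#'
#' Validation enforces: known well coordinates present in the layout,
#' non-negative raw absorbance, wavelength in \{590, 750\} nm, and at most
#' one reading per (plate, well, wavelength, time). Malformed rows are
#' reported with their line number in the file.
#'
#' @param path path to the readings CSV, or a data frame already in that
#'   shape.
#' @param layout plate layout as returned by [gen3_layout()].
#' @return A validated data frame of readings sorted by
#'   (plate, time, well), with normalised well coordinates.
#' @seealso [a1_zero()], [extract_cue()], [write_readings()]
#' @export
load_readings <- function(path, layout = gen3_layout()) {
  df <- if (is.data.frame(path)) {
    path
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(.reading_cols, names(df))
  if (length(missing_cols)) {
    stop("readings table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, .reading_cols]
  # line numbers in the source file: header is line 1
  line <- seq_len(nrow(df)) + 1L

  well <- normalize_well(df$well)
  if (anyNA(well)) {
    bad <- line[is.na(well)]
    stop("malformed well coordinate at line(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ...", call. = FALSE)
  }
  unknown <- !well %in% layout$well
  if (any(unknown)) {
    stop("well(s) not in plate layout at line(s) ",
         paste(utils::head(line[unknown], 5), collapse = ", "),
         call. = FALSE)
  }
  df$well <- well

  num_bad <- !is.finite(df$absorbance)
  if (any(num_bad)) {
    stop("non-numeric or missing absorbance at line(s) ",
         paste(utils::head(line[num_bad], 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$absorbance < 0)) {
    stop("negative raw absorbance at line(s) ",
         paste(utils::head(line[df$absorbance < 0], 5), collapse = ", "),
         "; raw readings must be >= 0 (zeroing happens in a1_zero())",
         call. = FALSE)
  }
  if (!all(df$wavelength_nm %in% c(590, 750))) {
    bad <- line[!df$wavelength_nm %in% c(590, 750)]
    stop("wavelength must be 590 or 750 nm; offending line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(df$plate_id, df$well, df$wavelength_nm, df$time_h, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- line[duplicated(key)]
    stop("duplicate reading for the same (plate, well, wavelength, time) ",
         "at line(s) ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  df[order(df$plate_id, df$time_h, df$well), , drop = FALSE]
}

#' Write plate readings
#'
#' Writes readings in the long CSV schema read back by [load_readings()].
#'
#' @param readings data frame of readings.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_readings <- function(readings, path) {
  utils::write.csv(readings[, .reading_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' A1-zero plate readings
#'
#' Normalises raw readings by subtracting the negative-control well (A1) of
#' the same plate, wavelength and timepoint from every well. The A1 wells
#' themselves map to exactly 0. Values that become negative after zeroing
#' are retained (optionally clamped at 0) and flagged in the logical column
#' `negative_cue`.
#'
#' The operation is idempotent: once A1 is 0, applying it again subtracts 0.
#'
#' @param readings validated readings data frame (see [load_readings()]).
#' @param clamp_negative_cue logical; if `TRUE`, post-zeroing negative values
#'   are clamped to 0 (default `FALSE`: they are kept, so downstream tests
#'   see the true variance).
#' @return The readings with `absorbance` replaced by its A1-zeroed value
#'   and an added logical column `negative_cue`.
#' @export
a1_zero <- function(readings, clamp_negative_cue = FALSE) {
  group <- paste(readings$plate_id, readings$wavelength_nm, readings$time_h,
                 sep = "\r")
  is_a1 <- readings$well == "A1"
  a1_val <- readings$absorbance[is_a1]
  names(a1_val) <- group[is_a1]
  ref <- a1_val[group]
  if (anyNA(ref)) {
    missing_groups <- unique(group[is.na(ref)])
    stop("no A1 negative-control reading for (plate, wavelength, time) ",
         "group(s): ",
         paste(gsub("\r", " / ", utils::head(missing_groups, 3)),
               collapse = "; "),
         call. = FALSE)
  }
  readings$absorbance <- readings$absorbance - unname(ref)
  readings$negative_cue <- readings$absorbance < 0
  if (clamp_negative_cue) {
    readings$absorbance[readings$negative_cue] <- 0
  }
  readings
}

#' Extract the CUE matrix at one timepoint
#'
#' Slices A1-zeroed readings at one wavelength and timepoint into the carbon
#' usage efficiency (CUE) matrix indexed by carbon source, culture and
#' replicate. By default this is the 590 nm absorbance at 24 h, the CUE
#' definition used throughout; 750 nm (turbidity) values can be extracted
#' through the same interface for side analyses but are never used as CUE by
#' default.
#'
#' Only wells with layout role `"carbon"` enter the matrix. Missing entries
#' of the full carbon x culture x replicate grid are flagged in the
#' `missing` element, never silently dropped.
#'
#' @param readings A1-zeroed readings (see [a1_zero()]).
#' @param layout plate layout, see [gen3_layout()].
#' @param time_h extraction timepoint in hours (default 24).
#' @param wavelength wavelength in nm, 590 (default, CUE) or 750 (turbidity).
#' @return An object of class `cue_matrix`: a list with elements
#'   `data` (long data frame `carbon_id, culture, replicate, cue,
#'   negative_cue`), `missing` (data frame of flagged grid gaps), `time_h`
#'   and `wavelength`. `as.matrix()` yields the carbons x (culture,
#'   replicate) wide matrix.
#' @export
extract_cue <- function(readings, layout = gen3_layout(), time_h = 24,
                        wavelength = 590) {
  if (!any(readings$time_h == time_h)) {
    stop("no readings at timepoint ", time_h, " h", call. = FALSE)
  }
  sel <- readings$time_h == time_h & readings$wavelength_nm == wavelength
  if (!any(sel)) {
    stop("no readings at ", wavelength, " nm for timepoint ", time_h, " h",
         call. = FALSE)
  }
  sub <- readings[sel, , drop = FALSE]
  carbon_map <- layout$carbon_id[match(sub$well, layout$well)]
  keep <- layout$role[match(sub$well, layout$well)] == "carbon"
  sub <- sub[keep, , drop = FALSE]
  data <- data.frame(
    carbon_id = carbon_map[keep],
    culture = as.character(sub$culture),
    replicate = as.integer(sub$replicate),
    cue = sub$absorbance,
    negative_cue = if ("negative_cue" %in% names(sub)) sub$negative_cue
                   else sub$absorbance < 0,
    stringsAsFactors = FALSE
  )
  carbons <- layout$carbon_id[layout$role == "carbon"]
  cultures <- unique(data$culture)
  known <- culture_labels()
  cultures <- c(intersect(known, cultures), setdiff(sort(cultures), known))
  replicates <- sort(unique(data$replicate))
  grid <- expand.grid(carbon_id = carbons, culture = cultures,
                      replicate = replicates, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  gkey <- paste(grid$carbon_id, grid$culture, grid$replicate, sep = "\r")
  dkey <- paste(data$carbon_id, data$culture, data$replicate, sep = "\r")
  if (anyDuplicated(dkey)) {
    stop("more than one CUE value for the same (carbon, culture, replicate)",
         call. = FALSE)
  }
  missing <- grid[!gkey %in% dkey, , drop = FALSE]
  rownames(missing) <- NULL
  ord <- order(match(data$carbon_id, carbons), match(data$culture, cultures),
               data$replicate)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  structure(list(data = data, missing = missing, time_h = time_h,
                 wavelength = wavelength, carbons = carbons,
                 cultures = cultures, replicates = replicates),
            class = "cue_matrix")
}

#' @export
print.cue_matrix <- function(x, ...) {
  cat("CUE matrix (", x$wavelength, " nm, A1-zeroed, t = ", x$time_h,
      " h)\n", sep = "")
  cat("  ", length(x$carbons), " carbon sources x ", length(x$cultures),
      " cultures x ", length(x$replicates), " replicates\n", sep = "")
  if (nrow(x$missing)) {
    cat("  ", nrow(x$missing), " missing entries (see $missing)\n", sep = "")
  }
  n_neg <- sum(x$data$negative_cue)
  if (n_neg) cat("  ", n_neg, " negative CUE values flagged\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.cue_matrix <- function(x, ...) {
  cols <- as.vector(t(outer(x$cultures, x$replicates,
                            function(cu, r) paste0(cu, "_r", r))))
  m <- matrix(NA_real_, nrow = length(x$carbons), ncol = length(cols),
              dimnames = list(x$carbons, cols))
  j <- paste0(x$data$culture, "_r", x$data$replicate)
  m[cbind(match(x$data$carbon_id, x$carbons), match(j, cols))] <- x$data$cue
  m
}

#' Replicate CUE values for one culture and carbon source
#'
#' @param cue a `cue_matrix`.
#' @param culture culture label.
#' @param carbon_id carbon source identifier.
#' @return numeric vector of replicate CUE values (may be length 0 if all
#'   replicates are missing).
#' @export
cue_values <- function(cue, culture, carbon_id) {
  d <- cue$data
  d$cue[d$culture == culture & d$carbon_id == carbon_id]
}
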