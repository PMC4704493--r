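# Screen processing: row-median plate normalization, replicate
# aggregation, z-score standardization, hit calling, responsiveness and
# seed-family variance summaries.

#' Row-median normalize a screen plate
#'
#' Each well's luminescence is divided by the median luminescence of its
#' plate row, removing row/position gain artifacts; afterwards every row
#' has median exactly 1. Optionally the plate can additionally be centered
#' by its overall median (a per-plate batch correction), applied after the
#' row step and recorded in the returned plate.
#'
#' @param plate A \code{\link{screen_plate}} with raw luminescence values.
#' @param batch_center Logical; also divide by the plate-wide median of
#'   the row-normalized values (default \code{FALSE}; row medians of 1
#'   already imply a plate median of 1 for full plates, so this matters
#'   only for unbalanced layouts).
#' @return The plate with \code{value} replaced by normalized relative
#'   viability and \code{normalized = TRUE}.
#' @export
normalize_row_median <- function(plate, batch_center = FALSE) {
  stopifnot(inherits(plate, "screen_plate"))
  if (plate$normalized) {
    ms_validation_error(sprintf("plate '%s' is already normalized",
                                plate$plate_id))
  }
  w <- plate$wells
  med <- tapply(w$value, w$row, stats::median)
  zero <- names(med)[!is.finite(med) | med == 0]
  if (length(zero) > 0L) {
    ms_degenerate_error(sprintf(
      "plate '%s': row median is zero/undefined for row(s) %s",
      plate$plate_id, paste(zero, collapse = ", ")),
      plate_id = plate$plate_id, rows = zero)
  }
  w$value <- w$value / as.numeric(med[w$row])
  if (isTRUE(batch_center)) {
    w$value <- w$value / stats::median(w$value)
  }
  plate$wells <- w
  plate$normalized <- TRUE
  plate
}

#' Aggregate normalized replicates to per-(mimic, line) summaries
#'
#' Wells are first averaged within each replicate (relevant only for
#' mimics plated in several wells per plate, e.g. controls), then the
#' replicate means are summarized by their mean and sample standard
#' deviation. Mimics missing from some replicates are summarized over the
#' replicates that carry them; the contributing count is reported and the
#' SD is left missing (never fabricated) when fewer than two replicates
#' contribute.
#'
#' @param plates List of normalized \code{\link{screen_plate}} objects
#'   covering one screen (all lines, all replicates).
#' @param drop_controls Drop the negative-control mimic
#'   (\code{\link{negative_control_id}}) after aggregation (default
#'   \code{TRUE}; its normalization job is done).
#' @return A list with matrices \code{mean}, \code{sd} and \code{n}
#'   (replicate counts), mimics in rows and cell lines in columns.
#' @export
aggregate_replicates <- function(plates, drop_controls = TRUE) {
  if (length(plates) == 0L) ms_empty_error("no plates supplied")
  ok <- vapply(plates, function(p)
    inherits(p, "screen_plate") && p$normalized, logical(1L))
  if (!all(ok)) {
    ms_validation_error("all plates must be normalized screen_plate objects")
  }
  per_rep <- do.call(rbind, lapply(plates, function(p) {
    agg <- tapply(p$wells$value, p$wells$mimic_id, mean)
    data.frame(mimic_id = names(agg), cell_line = p$cell_line,
               replicate = p$replicate, value = as.numeric(agg),
               stringsAsFactors = FALSE)
  }))
  if (isTRUE(drop_controls)) {
    per_rep <- per_rep[per_rep$mimic_id != negative_control_id(), ,
                       drop = FALSE]
    if (nrow(per_rep) == 0L) ms_empty_error("only control wells present")
  }
  mimics <- sort(unique(per_rep$mimic_id))
  lines <- sort(unique(per_rep$cell_line))
  shape <- list(mimics, lines)
  mk <- function() matrix(NA_real_, length(mimics), length(lines),
                          dimnames = shape)
  m_mean <- mk(); m_sd <- mk()
  m_n <- matrix(0L, length(mimics), length(lines), dimnames = shape)
  grp <- interaction(factor(per_rep$mimic_id, mimics),
                     factor(per_rep$cell_line, lines), drop = FALSE)
  idx <- split(per_rep$value, grp)
  for (key in names(idx)) {
    vals <- idx[[key]]
    if (length(vals) == 0L) next
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    i <- parts[1L]; j <- paste(parts[-1L], collapse = ".")
    m_mean[i, j] <- mean(vals)
    m_sd[i, j] <- if (length(vals) >= 2L) stats::sd(vals) else NA_real_
    m_n[i, j] <- length(vals)
  }
  list(mean = m_mean, sd = m_sd, n = m_n)
}

#' Standardize mean viabilities to z-scores
#'
#' z = (x - mean) / SD (sample SD, divisor n-1) within the chosen scoping
#' population. The default scope standardizes each cell line over all
#' mimics screened in that line, which is what makes hit calls comparable
#' across lines.
#'
#' @param mean_viability Numeric matrix, mimics x cell lines.
#' @param scope \code{"per_line"} (default: each column standardized over
#'   its mimics) or \code{"per_plate"} (standardize within plate groups;
#'   requires \code{plate_map}).
#' @param plate_map Named character vector mapping mimic ids to plate ids;
#'   required for \code{scope = "per_plate"}.
#' @return A \code{\link{zscore_matrix}} with the input attached as its
#'   \code{mean_viability} attribute. Each scoping group has mean 0 and
#'   sample SD 1 to within 1e-9.
#' @export
compute_zscores <- function(mean_viability,
                            scope = c("per_line", "per_plate"),
                            plate_map = NULL) {
  scope <- match.arg(scope)
  x <- as.matrix(mean_viability)
  if (!is.numeric(x)) ms_validation_error("mean_viability must be numeric")
  standardize <- function(v, label) {
    obs <- v[!is.na(v)]
    if (length(obs) < 3L) {
      ms_degenerate_error(sprintf(
        "scope group '%s' has fewer than 3 values", label))
    }
    s <- stats::sd(obs)
    if (!is.finite(s) || s == 0) {
      ms_degenerate_error(sprintf(
        "scope group '%s' has zero standard deviation", label))
    }
    (v - mean(obs)) / s
  }
  z <- x
  if (scope == "per_line") {
    for (j in seq_len(ncol(x))) {
      z[, j] <- standardize(x[, j], colnames(x)[j] %||% as.character(j))
    }
  } else {
    if (is.null(plate_map)) {
      ms_config_error("scope = 'per_plate' requires a plate_map")
    }
    unmapped <- setdiff(rownames(x), names(plate_map))
    if (length(unmapped) > 0L) {
      ms_config_error(sprintf("plate_map missing mimics: %s",
                              paste(utils::head(unmapped, 5L),
                                    collapse = ", ")))
    }
    groups <- split(rownames(x), plate_map[rownames(x)])
    for (j in seq_len(ncol(x))) {
      for (g in names(groups)) {
        rows <- groups[[g]]
        z[rows, j] <- standardize(x[rows, j],
                                  sprintf("%s/%s", g, colnames(x)[j]))
      }
    }
  }
  zscore_matrix(z, mean_viability = x)
}

#' Call viability hits from a z-score matrix
#'
#' A (mimic, line) cell is a hit when its z-score is at or below the
#' threshold (inclusive boundary: z = -2 is a hit at the default
#' threshold). Negative-control entries, if present, are never reported.
#'
#' @param z A \code{\link{zscore_matrix}} (or labeled numeric matrix).
#' @param threshold Hit threshold, must be negative (default \code{-2}:
#'   two standard deviations below the mean).
#' @param inclusive Treat z equal to the threshold as a hit (default
#'   \code{TRUE}).
#' @return A data frame of class \code{"hit_table"} with columns
#'   \code{mimic_id}, \code{cell_line}, \code{z}, carrying the threshold
#'   and the panel's line count as attributes.
#' @export
call_hits <- function(z, threshold = -2, inclusive = TRUE) {
  if (!is.matrix(z)) ms_validation_error("z must be a matrix")
  if (!is_scalar_number(threshold) || threshold >= 0) {
    ms_config_error("threshold must be a negative number")
  }
  hit <- if (isTRUE(inclusive)) z <= threshold else z < threshold
  hit[is.na(hit)] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  out <- data.frame(
    mimic_id = rownames(z)[idx[, 1L]],
    cell_line = colnames(z)[idx[, 2L]],
    z = z[idx],
    stringsAsFactors = FALSE
  )
  out <- out[out$mimic_id != negative_control_id(), , drop = FALSE]
  out <- out[order(out$mimic_id, out$cell_line), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, threshold = threshold, inclusive = isTRUE(inclusive),
            n_lines = ncol(z),
            class = c("hit_table", class(out)))
}

#' Summarize hit responsiveness across the panel
#'
#' Bins the distinct hit mimics by their number of responsive cell lines,
#' and reports the fraction of "private" hits (responsive in only 1 or 2
#' lines) and the maximum responsiveness observed.
#'
#' @param hits A \code{\link{call_hits}} result.
#' @param n_lines Number of cell lines in the panel (defaults to the
#'   value recorded on the hit table).
#' @return A list with \code{histogram} (named integer vector over
#'   1..n_lines summing to the number of distinct hit mimics),
#'   \code{fraction_private}, \code{max_lines} and \code{n_hit_mimics}.
#'   With an empty hit table the histogram is all zero and
#'   \code{fraction_private} is \code{NA} with a signaled warning (it is
#'   undefined, not zero).
#' @export
responsiveness_summary <- function(hits, n_lines = attr(hits, "n_lines")) {
  if (is.null(n_lines) || !is_scalar_number(n_lines) || n_lines < 1) {
    ms_config_error("n_lines must be a positive integer")
  }
  n_lines <- as.integer(n_lines)
  counts <- table(hits$mimic_id)
  histogram <- setNames(integer(n_lines), as.character(seq_len(n_lines)))
  if (length(counts) == 0L) {
    warning(structure(
      class = c("mimicscreen_undefined_warning", "warning", "condition"),
      list(message = "empty hit table: fraction_private is undefined",
           call = sys.call(-1))))
    return(list(histogram = histogram, fraction_private = NA_real_,
                max_lines = 0L, n_hit_mimics = 0L))
  }
  if (max(counts) > n_lines) {
    ms_integrity_error("a mimic is responsive in more lines than n_lines")
  }
  tab <- table(factor(as.integer(counts), levels = seq_len(n_lines)))
  histogram[] <- as.integer(tab)
  list(
    histogram = histogram,
    fraction_private = sum(histogram[1:min(2L, n_lines)]) / sum(histogram),
    max_lines = max(as.integer(counts)),
    n_hit_mimics = length(counts)
  )
}

#' Count unique mature sequences among hit mimics
#'
#' Mimic libraries built from successive database releases can contain
#' distinct reagent ids carrying the same mature sequence; this collapses
#' the hit list to the distinct sequences.
#'
#' @param hits A \code{\link{call_hits}} result.
#' @param ann A \code{\link{mimic_annotations}} table covering every hit
#'   mimic.
#' @return Integer count of distinct mature sequences among hit mimics.
#' @export
collapse_unique_mature <- function(hits, ann) {
  ids <- unique(hits$mimic_id)
  missing_ids <- setdiff(ids, ann$mimic_id)
  if (length(missing_ids) > 0L) {
    ms_annotation_error(sprintf(
      "hit mimic(s) lack annotation: %s",
      paste(utils::head(missing_ids, 10L), collapse = ", ")),
      mimic_ids = missing_ids)
  }
  seqs <- ann$mature_sequence[match(ids, ann$mimic_id)]
  length(unique(seqs))
}

# Gaussian KDE on a 512-point grid spanning the data +/- 4 bandwidths
# (Silverman's rule), wide enough that the grid carries essentially all
# the mass. Degenerate all-equal inputs take a tiny positive bandwidth so
# the density mass concentrates at the common value.
kde_curve <- function(x, n_grid = 512L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NULL)
  bw <- if (length(x) >= 2L && stats::sd(x) > 0) {
    stats::bw.nrd0(x)
  } else {
    1e-9 * max(1, abs(x[1L]))
  }
  d <- stats::density(x, bw = bw, n = n_grid,
                      from = min(x) - 4 * bw, to = max(x) + 4 * bw)
  list(grid = d$x, density = d$y, bw = bw)
}

#' Decompose screen variance into panel, seed-family and replicate scales
#'
#' Computes three standard-deviation distributions: per mimic across the
#' cell-line panel (total phenotypic variation), within seed family per
#' line (pooled over lines; families need at least two members), and
#' within replicate (technical reproducibility), each summarized by a
#' Gaussian kernel density estimate.
#'
#' @param mean_viability Mimic x line matrix of mean viabilities.
#' @param within_rep_sd Mimic x line matrix of within-replicate sample
#'   SDs (from \code{\link{aggregate_replicates}}).
#' @param ann A \code{\link{mimic_annotations}} table (family ids).
#' @return An object of class \code{"variance_profile"}: lists
#'   \code{across_panel}, \code{family}, \code{within_replicate} each with
#'   the SD values and a \code{kde} (grid/density/bw). When every family
#'   is a singleton the family distribution is empty and a warning is
#'   signaled.
#' @export
variance_profile <- function(mean_viability, within_rep_sd, ann) {
  x <- as.matrix(mean_viability)
  across <- apply(x, 1L, stats::sd, na.rm = TRUE)
  fam <- ann$family_id[match(rownames(x), ann$mimic_id)]
  fam_sizes <- table(fam[!is.na(fam)])
  multi <- names(fam_sizes)[fam_sizes >= 2L]
  family_sds <- numeric(0)
  if (length(multi) > 0L) {
    for (f in multi) {
      rows <- which(!is.na(fam) & fam == f)
      # within-family SD at each line, pooled over lines
      family_sds <- c(family_sds, apply(x[rows, , drop = FALSE], 2L,
                                        stats::sd, na.rm = TRUE))
    }
    family_sds <- family_sds[is.finite(family_sds)]
  } else {
    warning(structure(
      class = c("mimicscreen_undefined_warning", "warning", "condition"),
      list(message = "all seed families are singletons: family SD distribution is empty",
           call = sys.call(-1))))
  }
  rep_sds <- as.numeric(within_rep_sd)
  rep_sds <- rep_sds[is.finite(rep_sds)]
  structure(
    list(
      across_panel = list(sd = across, kde = kde_curve(across)),
      family = list(sd = family_sds, kde = kde_curve(family_sds)),
      within_replicate = list(sd = rep_sds, kde = kde_curve(rep_sds))
    ),
    class = "variance_profile"
  )
}

#' @export
print.variance_profile <- function(x, ...) {
  fmt <- function(el, label) {
    if (length(el$sd) == 0L) {
      cat(sprintf("  %-18s (empty)\n", label))
    } else {
      cat(sprintf("  %-18s n=%d  median SD=%.4f\n", label, length(el$sd),
                  stats::median(el$sd)))
    }
  }
  cat("<variance_profile>\n")
  fmt(x$across_panel, "across panel:")
  fmt(x$family, "within family:")
  fmt(x$within_replicate, "within replicate:")
  invisible(x)
}
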