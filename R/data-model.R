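# Domain types shared across the pipeline stages. All containers are plain
# base-R structures (data frames, matrices, lists) carrying an S3 class for
# validation and printing.

WELL_COLUMNS <- c("plate_id", "cell_line", "replicate", "row", "column",
                  "mimic_id", "raw_lum")

#' Negative-control mimic identifier
#'
#' Wells carrying the negative-control mimic are excluded from hit calling
#' and annotation checks but participate in row-median normalization. The
#' identifier is a package option so libraries using a different control
#' naming scheme can be accommodated.
#'
#' @return The current negative-control mimic id (default \code{"miR-NC"}).
#' @export
negative_control_id <- function() {
  getOption("mimicscreen.negative_control", "miR-NC")
}

#' Validate a table of per-well screen measurements
#'
#' A well table holds one row per physical well: plate and grid coordinates,
#' the cell line and replicate the plate belongs to, the mimic transfected
#' into the well, and the raw luminescence readout. The combination
#' (plate_id, row, column, replicate) must be unique and luminescence must
#' be non-negative.
#'
#' @param df A data frame with columns \code{plate_id}, \code{cell_line},
#'   \code{replicate}, \code{row}, \code{column}, \code{mimic_id},
#'   \code{raw_lum}.
#' @return The validated data frame (invisibly classed
#'   \code{"ms_well_table"}).
#' @export
validate_well_table <- function(df) {
  missing_cols <- setdiff(WELL_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    ms_schema_error(
      sprintf("well table is missing column(s): %s",
              paste(missing_cols, collapse = ", ")),
      columns = missing_cols
    )
  }
  df$plate_id <- as.character(df$plate_id)
  df$cell_line <- as.character(df$cell_line)
  df$row <- as.character(df$row)
  df$mimic_id <- as.character(df$mimic_id)
  df$replicate <- as.integer(df$replicate)
  df$column <- as.integer(df$column)
  df$raw_lum <- as.numeric(df$raw_lum)
  if (anyNA(df$replicate) || any(df$replicate < 1L)) {
    ms_validation_error("replicate must be an integer >= 1")
  }
  if (anyNA(df$column) || any(df$column < 1L)) {
    ms_validation_error("column must be an integer >= 1")
  }
  if (anyNA(df$raw_lum) || any(df$raw_lum < 0)) {
    ms_validation_error("raw_lum must be non-negative and non-missing")
  }
  key <- paste(df$plate_id, df$row, df$column, df$replicate, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    offenders <- unique(paste0(df$plate_id[dup], ":", df$row[dup],
                               df$column[dup], " rep ", df$replicate[dup]))
    ms_integrity_error(
      sprintf("duplicate well coordinate(s): %s",
              paste(utils::head(offenders, 5L), collapse = ", ")),
      wells = offenders
    )
  }
  class(df) <- unique(c("ms_well_table", class(df)))
  df
}

#' Construct a single screen plate
#'
#' A screen plate is the unit the normalizer operates on: all wells of one
#' physical plate (one cell line, one replicate) with their grid geometry.
#' Row labels must form a rectangular grid (every row label paired with the
#' same set of columns).
#'
#' @param plate_id,cell_line,replicate Plate identity.
#' @param wells Data frame with columns \code{row}, \code{column},
#'   \code{mimic_id}, \code{value} (raw luminescence or, after
#'   normalization, relative viability).
#' @param normalized Logical; whether \code{value} has been row-median
#'   normalized.
#' @return An object of class \code{"screen_plate"}.
#' @export
screen_plate <- function(plate_id, cell_line, replicate, wells,
                         normalized = FALSE) {
  stopifnot(is_scalar_string(plate_id), is_scalar_string(cell_line))
  replicate <- as.integer(replicate)
  stopifnot(length(replicate) == 1L, !is.na(replicate), replicate >= 1L)
  needed <- c("row", "column", "mimic_id", "value")
  if (!all(needed %in% names(wells))) {
    ms_schema_error(sprintf(
      "plate wells need columns %s", paste(needed, collapse = ", ")))
  }
  wells <- wells[needed]
  wells$row <- as.character(wells$row)
  wells$column <- as.integer(wells$column)
  wells$mimic_id <- as.character(wells$mimic_id)
  wells$value <- as.numeric(wells$value)
  # rectangular geometry: identical column set in every row
  cols_by_row <- tapply(wells$column, wells$row,
                        function(v) paste(sort(v), collapse = ","))
  if (length(unique(cols_by_row)) > 1L) {
    ms_integrity_error(sprintf(
      "plate '%s': row labels do not form a rectangular grid", plate_id))
  }
  structure(
    list(plate_id = plate_id, cell_line = cell_line, replicate = replicate,
         wells = wells, normalized = isTRUE(normalized)),
    class = "screen_plate"
  )
}

#' @export
print.screen_plate <- function(x, ...) {
  cat(sprintf(
    "<screen_plate> %s | line %s | replicate %d | %d wells (%d rows x %d cols)%s\n",
    x$plate_id, x$cell_line, x$replicate, nrow(x$wells),
    length(unique(x$wells$row)), length(unique(x$wells$column)),
    if (x$normalized) " | normalized" else ""))
  invisible(x)
}

#' Split a well table into screen plates
#'
#' @param df A validated well table (see \code{\link{validate_well_table}}).
#' @param normalized Logical; mark the plates as already row-median
#'   normalized (used when re-reading normalized tables).
#' @return A named list of \code{\link{screen_plate}} objects, one per
#'   (plate_id, replicate) combination.
#' @export
as_screen_plates <- function(df, normalized = FALSE) {
  df <- validate_well_table(df)
  key <- paste(df$plate_id, df$replicate, sep = "\r")
  split_idx <- split(seq_len(nrow(df)), key)
  plates <- lapply(split_idx, function(idx) {
    sub <- df[idx, , drop = FALSE]
    line <- unique(sub$cell_line)
    if (length(line) != 1L) {
      ms_integrity_error(sprintf(
        "plate '%s' replicate %d mixes cell lines: %s",
        sub$plate_id[1L], sub$replicate[1L], paste(line, collapse = ", ")))
    }
    screen_plate(
      plate_id = sub$plate_id[1L], cell_line = line,
      replicate = sub$replicate[1L],
      wells = data.frame(row = sub$row, column = sub$column,
                         mimic_id = sub$mimic_id, value = sub$raw_lum,
                         stringsAsFactors = FALSE),
      normalized = normalized
    )
  })
  names(plates) <- vapply(plates, function(p)
    sprintf("%s.rep%d", p$plate_id, p$replicate), character(1L))
  plates[order(names(plates))]
}

#' Flatten screen plates back to a well table
#'
#' Inverse of \code{\link{as_screen_plates}} for raw (non-normalized)
#' plates; for normalized plates the \code{raw_lum} column carries the
#' normalized viability values.
#'
#' @param plates List of \code{\link{screen_plate}} objects.
#' @return A well table data frame.
#' @export
as_well_table <- function(plates) {
  if (length(plates) == 0L) ms_empty_error("no plates supplied")
  out <- do.call(rbind, lapply(plates, function(p) {
    data.frame(plate_id = p$plate_id, cell_line = p$cell_line,
               replicate = p$replicate, row = p$wells$row,
               column = p$wells$column, mimic_id = p$wells$mimic_id,
               raw_lum = p$wells$value, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  validate_well_table(out)
}

#' Annotate a mimic library with seeds and seed families
#'
#' Seeds are extracted from the mature sequence over a configurable window
#' (default positions 2-8, the canonical 7-mer) and mimics sharing a seed
#' are assigned to the same family.
#'
#' @param df Data frame with columns \code{mimic_id} and
#'   \code{mature_sequence} (RNA alphabet A/C/G/U); optional \code{seed}
#'   and \code{family_id} columns are validated/regenerated.
#' @param seed_window Integer vector of length 2, first and last mature
#'   position of the seed (default \code{c(2, 8)}; \code{c(2, 7)} selects
#'   the 6-mer core).
#' @return A data frame of class \code{"mimic_annotations"} with columns
#'   \code{mimic_id}, \code{mature_sequence}, \code{seed},
#'   \code{family_id}.
#' @export
mimic_annotations <- function(df, seed_window = c(2L, 8L)) {
  if (!all(c("mimic_id", "mature_sequence") %in% names(df))) {
    ms_schema_error("annotations need columns mimic_id, mature_sequence")
  }
  stopifnot(length(seed_window) == 2L, seed_window[1L] >= 1L,
            seed_window[2L] >= seed_window[1L])
  df$mimic_id <- as.character(df$mimic_id)
  df$mature_sequence <- toupper(as.character(df$mature_sequence))
  if (anyDuplicated(df$mimic_id)) {
    ms_integrity_error("duplicate mimic_id in annotations")
  }
  bad <- grepl("[^ACGU]", df$mature_sequence)
  if (any(bad)) {
    ms_validation_error(sprintf(
      "mature_sequence not over {A,C,G,U} for: %s",
      paste(utils::head(df$mimic_id[bad], 5L), collapse = ", ")))
  }
  if (any(nchar(df$mature_sequence) < seed_window[2L])) {
    ms_validation_error("mature sequence shorter than the seed window")
  }
  df$seed <- substr(df$mature_sequence, seed_window[1L], seed_window[2L])
  df$family_id <- paste0("fam_", df$seed)
  df <- df[c("mimic_id", "mature_sequence", "seed", "family_id")]
  attr(df, "seed_window") <- as.integer(seed_window)
  class(df) <- unique(c("mimic_annotations", class(df)))
  df
}

#' Construct a standardized z-score matrix
#'
#' The screen's central object: mimics in rows, cell lines in columns,
#' entries the standardized mean viability of that mimic in that line.
#'
#' @param z Numeric matrix with unique, non-empty row names (mimic ids) and
#'   column names (cell lines).
#' @param mean_viability Optional matrix of the same shape carrying the
#'   pre-standardization mean viabilities.
#' @return An object of class \code{"zscore_matrix"} (a matrix).
#' @export
zscore_matrix <- function(z, mean_viability = NULL) {
  if (!is.matrix(z) || !is.numeric(z)) {
    ms_validation_error("z must be a numeric matrix")
  }
  if (is.null(rownames(z)) || is.null(colnames(z)) ||
      any(!nzchar(rownames(z))) || any(!nzchar(colnames(z)))) {
    ms_validation_error("z needs complete mimic and cell-line labels")
  }
  if (anyDuplicated(rownames(z)) || anyDuplicated(colnames(z))) {
    ms_integrity_error("duplicate mimic or cell-line labels")
  }
  if (!is.null(mean_viability)) {
    if (!identical(dim(mean_viability), dim(z))) {
      ms_validation_error("mean_viability must match the shape of z")
    }
    dimnames(mean_viability) <- dimnames(z)
  }
  structure(z, mean_viability = mean_viability,
            class = c("zscore_matrix", class(z)))
}

#' @export
print.zscore_matrix <- function(x, ...) {
  cat(sprintf("<zscore_matrix> %d mimics x %d cell lines\n",
              nrow(x), ncol(x)))
  cat(sprintf("  z range: [%.3f, %.3f]%s\n",
              min(x, na.rm = TRUE), max(x, na.rm = TRUE),
              if (is.null(attr(x, "mean_viability"))) "" else
                " | mean viability attached"))
  invisible(x)
}

#' Validate a survival cohort table
#'
#' @param df Data frame with columns \code{sample_id}, \code{time}
#'   (non-negative, months), \code{event} (0/1 or logical; 1 = death
#'   observed) and \code{expression} (miRNA abundance, platform units).
#' @return The validated data frame, classed \code{"survival_cohort"}.
#' @export
survival_cohort <- function(df) {
  needed <- c("sample_id", "time", "event", "expression")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    ms_schema_error(sprintf("survival cohort missing column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }
  df$sample_id <- as.character(df$sample_id)
  df$time <- as.numeric(df$time)
  df$event <- as.integer(as.logical(df$event))
  df$expression <- as.numeric(df$expression)
  if (anyNA(df$time) || any(df$time < 0)) {
    ms_validation_error("survival time must be non-negative")
  }
  if (anyNA(df$event)) ms_validation_error("event indicator must be 0/1")
  class(df) <- unique(c("survival_cohort", class(df)))
  df
}

#' Construct a phenocopy panel
#'
#' Holds one mimic's toxicity profile across a cell-line panel together
#' with per-gene siRNA toxicity profiles measured with two independent
#' reagent pools, plus the per-gene viability from the original
#' genome-wide siRNA screen in the index line (used by the stage-1
#' activity filter).
#'
#' @param cell_lines Character vector of panel line names.
#' @param mimic_profile Numeric vector (length = number of lines) of the
#'   mimic's relative-viability (or z-score) profile.
#' @param gene_profiles Named list, one element per gene, each a 2 x
#'   n_lines numeric matrix with rows \code{pool1}, \code{pool2}.
#' @param index_line The sensitive line in which stage-1 activity was
#'   screened; must be one of \code{cell_lines}.
#' @param screen_viability Optional named numeric vector (per gene) of
#'   relative viability upon depletion in the index line from the original
#'   genome-wide screen. When absent, the pool-1 profile value at the
#'   index line is used by the filter.
#' @return An object of class \code{"phenocopy_panel"}.
#' @export
phenocopy_panel <- function(cell_lines, mimic_profile, gene_profiles,
                            index_line, screen_viability = NULL) {
  cell_lines <- as.character(cell_lines)
  n <- length(cell_lines)
  if (n < 3L) ms_config_error("phenocopy panel needs at least 3 cell lines")
  if (anyDuplicated(cell_lines)) ms_integrity_error("duplicate cell lines")
  if (length(mimic_profile) != n) {
    ms_validation_error("mimic_profile length must match cell_lines")
  }
  if (!is_scalar_string(index_line) || !(index_line %in% cell_lines)) {
    ms_validation_error("index_line must be one of cell_lines")
  }
  if (length(gene_profiles) == 0L || is.null(names(gene_profiles)) ||
      any(!nzchar(names(gene_profiles)))) {
    ms_validation_error("gene_profiles must be a non-empty named list")
  }
  gene_profiles <- lapply(gene_profiles, function(m) {
    if (!is.matrix(m) || nrow(m) != 2L || ncol(m) != n) {
      ms_validation_error("each gene profile must be a 2 x n_lines matrix")
    }
    rownames(m) <- c("pool1", "pool2")
    colnames(m) <- cell_lines
    m
  })
  if (!is.null(screen_viability)) {
    if (is.null(names(screen_viability)) ||
        !setequal(names(screen_viability), names(gene_profiles))) {
      ms_validation_error(
        "screen_viability must be named for exactly the panel genes")
    }
    screen_viability <- screen_viability[names(gene_profiles)]
  }
  structure(
    list(cell_lines = cell_lines,
         mimic_profile = setNames(as.numeric(mimic_profile), cell_lines),
         gene_profiles = gene_profiles, index_line = index_line,
         screen_viability = screen_viability),
    class = "phenocopy_panel"
  )
}

#' Validate a target-prediction table
#'
#' One record per predicted target gene of a given miRNA, with the
#' prediction engine's total context score (more negative = stronger
#' predicted repression) and a caller-supplied expression flag.
#'
#' @param df Data frame with columns \code{gene_id}, \code{context_score},
#'   \code{is_expressed}.
#' @return The validated data frame, classed \code{"target_predictions"}.
#' @export
target_predictions <- function(df) {
  needed <- c("gene_id", "context_score", "is_expressed")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    ms_schema_error(sprintf("target predictions missing column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }
  df$gene_id <- as.character(df$gene_id)
  df$context_score <- as.numeric(df$context_score)
  df$is_expressed <- as.logical(df$is_expressed)
  if (anyDuplicated(df$gene_id)) {
    ms_integrity_error("one record per gene: duplicate gene_id")
  }
  class(df) <- unique(c("target_predictions", class(df)))
  df
}
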