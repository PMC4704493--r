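# Feature-preparation rules for expression clustering and read-depth
# copy-number classification.

#' Keep the most variable genes of an expression matrix
#'
#' Retains exactly \code{round(fraction * n_genes)} genes with the
#' largest per-gene sample variance across samples (no transform is
#' applied internally; callers wanting log-scale variance transform
#' first). Ties at the boundary are broken deterministically toward the
#' lexicographically smaller gene id.
#'
#' @param expr Numeric gene-by-sample matrix with gene row names.
#' @param fraction Fraction of genes to keep, in (0, 1] (default 0.2).
#' @return The filtered matrix (original gene order preserved).
#' @export
top_variant_filter <- function(expr, fraction = 0.2) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L) {
    ms_degenerate_error("variance undefined with fewer than 2 samples")
  }
  if (!is_scalar_number(fraction) || fraction <= 0 || fraction > 1) {
    ms_config_error("fraction must be in (0, 1]")
  }
  if (is.null(rownames(expr))) {
    rownames(expr) <- paste0("gene", seq_len(nrow(expr)))
  }
  n_keep <- round(fraction * nrow(expr))
  if (n_keep < 1L) ms_config_error("fraction keeps no genes")
  v <- apply(expr, 1L, stats::var)
  ord <- order(-v, rownames(expr))
  keep <- sort(ord[seq_len(n_keep)])
  expr[keep, , drop = FALSE]
}

#' Classify gene copy number from read-depth ratios
#'
#' Gene-level copy-number state from the ratio of exon read depth in the
#' sample to a reference: gain at ratio >= \code{gain_min}, loss at
#' ratio <= \code{loss_max} (both boundaries inclusive), neutral
#' otherwise.
#'
#' @param ratios Named non-negative numeric vector (gene id to depth
#'   ratio).
#' @param gain_min Minimum ratio called a gain (default 1.5).
#' @param loss_max Maximum ratio called a loss (default 0.5).
#' @return Data frame of class \code{"cnv_calls"} with columns
#'   \code{gene_id}, \code{depth_ratio}, \code{call} (factor
#'   gain/neutral/loss).
#' @export
classify_copy_number <- function(ratios, gain_min = 1.5, loss_max = 0.5) {
  r <- as.numeric(ratios)
  if (anyNA(r) || any(r < 0)) {
    ms_validation_error("depth ratios must be non-negative and non-missing")
  }
  if (!is_scalar_number(gain_min) || !is_scalar_number(loss_max) ||
      loss_max >= gain_min) {
    ms_config_error("need loss_max < gain_min")
  }
  ids <- names(ratios) %||% paste0("gene", seq_along(r))
  call <- ifelse(r >= gain_min, "gain",
                 ifelse(r <= loss_max, "loss", "neutral"))
  structure(
    data.frame(gene_id = ids, depth_ratio = r,
               call = factor(call, levels = c("gain", "neutral", "loss")),
               stringsAsFactors = FALSE),
    gain_min = gain_min, loss_max = loss_max,
    class = c("cnv_calls", "data.frame"))
}
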