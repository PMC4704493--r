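# Set-overlap enrichment, context-score response curves, and the
# dual-pool siRNA phenocopy filter for nominating functional miRNA
# targets.

#' Exact hypergeometric overlap test
#'
#' Upper-tail probability of observing at least the seen overlap between
#' two sets drawn from a common universe: with N = |universe|,
#' K = |set_a|, n = |set_b| and k = |intersection|, p = P(X >= k) for X
#' hypergeometric(N, K, n). The tail is computed exactly (no normal
#' approximation). One-sided, enrichment direction only.
#'
#' @param set_a,set_b Vectors of element ids, both subsets of
#'   \code{universe}.
#' @param universe Vector of all eligible element ids.
#' @return An object of class \code{"overlap_result"}: list with
#'   \code{universe_size}, \code{set_a_size}, \code{set_b_size},
#'   \code{overlap} and \code{p_value}.
#' @export
hypergeom_overlap <- function(set_a, set_b, universe) {
  universe <- unique(as.character(universe))
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  out_a <- setdiff(set_a, universe)
  out_b <- setdiff(set_b, universe)
  if (length(out_a) + length(out_b) > 0L) {
    ms_membership_error(sprintf(
      "element(s) outside the universe: %s",
      paste(utils::head(c(out_a, out_b), 10L), collapse = ", ")),
      offenders = c(out_a, out_b))
  }
  N <- length(universe)
  K <- length(set_a)
  n <- length(set_b)
  k <- length(intersect(set_a, set_b))
  # exact upper tail P(X >= k)
  p <- if (k == 0L) 1 else stats::phyper(k - 1L, K, N - K, n,
                                         lower.tail = FALSE)
  structure(list(universe_size = N, set_a_size = K, set_b_size = n,
                 overlap = k, p_value = min(1, p)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> overlap %d (sets %d & %d of universe %d) | p = %.4g\n",
    x$overlap, x$set_a_size, x$set_b_size, x$universe_size, x$p_value))
  invisible(x)
}

#' Enrichment of predicted targets among responsive genes
#'
#' Tests whether the genes responding to a mimic are enriched for its
#' predicted targets, within the expressed-gene universe.
#'
#' @param responsive_genes Genes with altered expression upon mimic
#'   transfection.
#' @param predicted_targets Predicted target genes of the mimic.
#' @param expressed_universe All expressed (detection-positive) genes.
#' @return An \code{\link{hypergeom_overlap}} result.
#' @export
target_enrichment <- function(responsive_genes, predicted_targets,
                              expressed_universe) {
  hypergeom_overlap(responsive_genes, predicted_targets,
                    expressed_universe)
}

#' Probability of target down-regulation by context-score bin
#'
#' Bins expressed predicted targets by the prediction engine's total
#' context score and, per bin, estimates the probability that a target
#' shows at least a \code{fold_threshold}-fold decrease in expression
#' (log2 ratio at or below \code{-log2(fold_threshold)}).
#'
#' @param predictions A \code{\link{target_predictions}} table.
#' @param log2_ratios Named numeric vector (gene id to log2 expression
#'   ratio, treatment over control) covering every expressed predicted
#'   target.
#' @param fold_threshold Fold-decrease defining "down" (default 2; must
#'   exceed 1).
#' @param bin_edges Strictly decreasing score edges; bin j holds scores in
#'   (edge[j+1], edge[j]]. Default \code{c(0, -0.1, -0.2, -0.3, -0.4,
#'   -Inf)}.
#' @return An object of class \code{"context_score_curve"}: data frame
#'   with per-bin \code{score_max}, \code{score_min}, \code{n_targets},
#'   \code{n_down}, \code{probability_down} (NA, with a signaled warning,
#'   for empty bins).
#' @export
context_score_curve <- function(predictions, log2_ratios,
                                fold_threshold = 2,
                                bin_edges = c(0, -0.1, -0.2, -0.3, -0.4,
                                              -Inf)) {
  predictions <- target_predictions(predictions)
  if (!is_scalar_number(fold_threshold) || fold_threshold <= 1) {
    ms_config_error("fold_threshold must be > 1")
  }
  if (length(bin_edges) < 2L || any(diff(bin_edges) >= 0)) {
    ms_config_error("bin_edges must be strictly decreasing")
  }
  expressed <- predictions[predictions$is_expressed, , drop = FALSE]
  missing_ids <- setdiff(expressed$gene_id, names(log2_ratios))
  if (length(missing_ids) > 0L) {
    ms_validation_error(sprintf(
      "no log2 ratio for expressed predicted target(s): %s",
      paste(utils::head(missing_ids, 10L), collapse = ", ")))
  }
  down_cut <- -log2(fold_threshold)
  down <- log2_ratios[expressed$gene_id] <= down_cut
  n_bins <- length(bin_edges) - 1L
  out <- data.frame(score_max = bin_edges[-length(bin_edges)],
                    score_min = bin_edges[-1L],
                    n_targets = 0L, n_down = 0L,
                    probability_down = NA_real_)
  for (j in seq_len(n_bins)) {
    in_bin <- expressed$context_score <= out$score_max[j] &
      expressed$context_score > out$score_min[j]
    out$n_targets[j] <- sum(in_bin)
    out$n_down[j] <- sum(down[in_bin])
    out$probability_down[j] <- if (out$n_targets[j] > 0L) {
      out$n_down[j] / out$n_targets[j]
    } else NA_real_
  }
  if (any(out$n_targets == 0L)) {
    warning(structure(
      class = c("mimicscreen_undefined_warning", "warning", "condition"),
      list(message = sprintf(
        "%d empty bin(s): probability undefined there",
        sum(out$n_targets == 0L)), call = sys.call(-1))))
  }
  structure(out, fold_threshold = fold_threshold,
            class = c("context_score_curve", class(out)))
}

#' Dual-pool siRNA phenocopy screen for functional target nomination
#'
#' Two-stage filter identifying which predicted targets of a mimic
#' phenocopy its toxicity. Stage 1 keeps genes whose depletion was active
#' in the index line (relative viability strictly below
#' \code{viability_cutoff} in the genome-wide screen). Stage 2 nominates
#' the stage-1 genes whose siRNA toxicity profile across the panel is
#' positively correlated with the mimic profile (Pearson r > 0 and
#' r^2 strictly above \code{r2_cutoff}) with both independent reagent
#' pools.
#'
#' @param panel A \code{\link{phenocopy_panel}}.
#' @param viability_cutoff Stage-1 activity cutoff on relative viability
#'   (default 0.5).
#' @param r2_cutoff Stage-2 squared-correlation cutoff (default 0.35).
#' @return An object of class \code{"phenocopy_result"}: data frame with
#'   per-gene \code{passes_viability_filter}, \code{r_pool1},
#'   \code{r_pool2}, \code{r2_pool1}, \code{r2_pool2}, \code{nominated},
#'   and an \code{excluded} attribute listing genes whose correlation was
#'   undefined (constant profile) with the reason.
#' @export
phenocopy_screen <- function(panel, viability_cutoff = 0.5,
                             r2_cutoff = 0.35) {
  stopifnot(inherits(panel, "phenocopy_panel"))
  if (!is_scalar_number(viability_cutoff) || viability_cutoff <= 0) {
    ms_config_error("viability_cutoff must be positive")
  }
  if (!is_scalar_number(r2_cutoff) || r2_cutoff < 0 || r2_cutoff >= 1) {
    ms_config_error("r2_cutoff must be in [0, 1)")
  }
  if (length(panel$cell_lines) < 3L) {
    ms_config_error("need at least 3 shared cell lines per correlation")
  }
  genes <- names(panel$gene_profiles)
  mimic <- panel$mimic_profile
  if (stats::sd(mimic) == 0) {
    ms_degenerate_error("mimic profile is constant: correlations undefined")
  }
  idx <- panel$index_line
  excluded <- character(0)
  res <- data.frame(gene_id = genes, passes_viability_filter = NA,
                    r_pool1 = NA_real_, r_pool2 = NA_real_,
                    r2_pool1 = NA_real_, r2_pool2 = NA_real_,
                    nominated = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    prof <- panel$gene_profiles[[genes[i]]]
    stage1_value <- if (!is.null(panel$screen_viability)) {
      panel$screen_viability[[genes[i]]]
    } else {
      prof["pool1", idx]
    }
    res$passes_viability_filter[i] <- stage1_value < viability_cutoff
    if (stats::sd(prof["pool1", ]) == 0 || stats::sd(prof["pool2", ]) == 0) {
      excluded <- c(excluded, sprintf(
        "%s: constant siRNA profile, correlation undefined", genes[i]))
      next
    }
    r1 <- stats::cor(prof["pool1", ], mimic)
    r2 <- stats::cor(prof["pool2", ], mimic)
    res$r_pool1[i] <- r1
    res$r_pool2[i] <- r2
    res$r2_pool1[i] <- r1^2
    res$r2_pool2[i] <- r2^2
    res$nominated[i] <- res$passes_viability_filter[i] &&
      r1 > 0 && r1^2 > r2_cutoff &&
      r2 > 0 && r2^2 > r2_cutoff
  }
  structure(res, viability_cutoff = viability_cutoff,
            r2_cutoff = r2_cutoff, excluded = excluded,
            class = c("phenocopy_result", class(res)))
}

#' Benjamini-Hochberg adjustment utility
#'
#' Provided for callers running many overlap tests; the screen-analysis
#' operations themselves report unadjusted p-values.
#'
#' @param p Vector of p-values.
#' @return BH-adjusted p-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
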