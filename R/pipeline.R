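# Stage orchestration: a configuration object covering every stage
# parameter, file-based stage runners with atomic outputs and run
# manifests, and a one-command synthetic end-to-end demo.

PIPELINE_STAGES <- c("simulate", "normalize", "zscore", "hits", "cluster",
                     "enrich", "survival", "phenocopy", "cnv", "report")

#' Pipeline configuration
#'
#' Collects every stage parameter with the module defaults, plus the
#' output directory, table dialect and master seed. Configurations
#' round-trip losslessly through YAML via \code{\link{write_config}} /
#' \code{\link{read_config}}.
#'
#' @param out_dir Directory stage outputs are written to.
#' @param seed Master seed for every stochastic stage.
#' @param hit_threshold,zscore_scope Hit-calling z threshold and z-score
#'   scoping population.
#' @param ap_metric,ap_preference,ap_damping,ap_max_iter,ap_convergence_window
#'   Affinity propagation parameters for the cluster stage.
#' @param percentile_range,alpha Survival cutoff-scan parameters.
#' @param viability_cutoff,r2_cutoff Phenocopy filter parameters.
#' @param fold_threshold,bin_edges Context-score curve parameters.
#' @param cnv_gain_min,cnv_loss_max Copy-number call thresholds.
#' @param dialect Table dialect, \code{"tsv"} or \code{"csv"}.
#' @return A list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(out_dir = "mimicscreen_run", seed = 1L,
                            hit_threshold = -2,
                            zscore_scope = "per_line",
                            ap_metric = "neg_euclidean",
                            ap_preference = "median",
                            ap_damping = 0.9, ap_max_iter = 1000L,
                            ap_convergence_window = 50L,
                            percentile_range = c(25, 75), alpha = 0.05,
                            viability_cutoff = 0.5, r2_cutoff = 0.35,
                            fold_threshold = 2,
                            bin_edges = c(0, -0.1, -0.2, -0.3, -0.4, -Inf),
                            cnv_gain_min = 1.5, cnv_loss_max = 0.5,
                            dialect = "tsv") {
  if (!dialect %in% c("tsv", "csv")) {
    ms_config_error("dialect must be 'tsv' or 'csv'")
  }
  if (!is_scalar_number(hit_threshold) || hit_threshold >= 0) {
    ms_config_error("hit_threshold must be negative")
  }
  if (!zscore_scope %in% c("per_line", "per_plate")) {
    ms_config_error("zscore_scope must be 'per_line' or 'per_plate'")
  }
  structure(list(
    out_dir = out_dir, seed = as.integer(seed),
    hit_threshold = hit_threshold, zscore_scope = zscore_scope,
    ap_metric = ap_metric, ap_preference = ap_preference,
    ap_damping = ap_damping, ap_max_iter = as.integer(ap_max_iter),
    ap_convergence_window = as.integer(ap_convergence_window),
    percentile_range = percentile_range, alpha = alpha,
    viability_cutoff = viability_cutoff, r2_cutoff = r2_cutoff,
    fold_threshold = fold_threshold, bin_edges = bin_edges,
    cnv_gain_min = cnv_gain_min, cnv_loss_max = cnv_loss_max,
    dialect = dialect), class = "pipeline_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' @param cfg A \code{\link{pipeline_config}}.
#' @param path YAML file path.
#' @return \code{write_config}: the path, invisibly; \code{read_config}:
#'   the configuration.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    ms_config_error(sprintf("config file does not exist: %s", path))
  }
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

# write a table atomically: temp file in the target dir, then rename
atomic_write <- function(df, path, dialect) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  old <- options(digits = 17); on.exit(options(old), add = TRUE)
  write_delim_dialect(df, tmp, dialect)
  file.rename(tmp, path)
  invisible(path)
}

stage_path <- function(cfg, name) {
  ext <- if (cfg$dialect == "tsv") ".tsv" else ".csv"
  file.path(cfg$out_dir, paste0(name, ext))
}

require_input <- function(path) {
  if (!file.exists(path)) {
    ms_validation_error(sprintf("required input is missing: %s", path),
                        path = path)
  }
  path
}

write_manifest <- function(cfg, stage, inputs, outputs) {
  manifest <- list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("mimicscreen")),
    seed = cfg$seed,
    parameters = unclass(cfg)[setdiff(names(cfg), "out_dir")],
    input_digests = if (length(inputs)) {
      as.list(tools::md5sum(inputs))
    } else list(),
    outputs = as.list(outputs)
  )
  path <- file.path(cfg$out_dir, sprintf("manifest_%s.json", stage))
  tmp <- tempfile(tmpdir = cfg$out_dir, fileext = ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Run one pipeline stage
#'
#' File-based orchestration of the analysis stages on the configured
#' output directory. Stages consume the outputs of their upstream stages
#' (simulated stand-ins are generated for the enrich/survival/phenocopy/
#' cnv stages when no input file is present, so the synthetic demo runs
#' end to end), write their outputs atomically, and record a run
#' manifest (parameters, input digests, seed, package version).
#'
#' @param name One of \code{"simulate"}, \code{"normalize"},
#'   \code{"zscore"}, \code{"hits"}, \code{"cluster"}, \code{"enrich"},
#'   \code{"survival"}, \code{"phenocopy"}, \code{"cnv"},
#'   \code{"report"}.
#' @param cfg A \code{\link{pipeline_config}}.
#' @return Invisibly, a character vector of the files the stage wrote.
#' @export
run_stage <- function(name, cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is_scalar_string(name) || !(name %in% PIPELINE_STAGES)) {
    ms_config_error(sprintf(
      "unknown stage '%s'; stages are: %s", as.character(name)[1L],
      paste(PIPELINE_STAGES, collapse = ", ")))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  dialect <- cfg$dialect
  inputs <- character(0)
  outputs <- character(0)
  emit <- function(df, stem) {
    p <- stage_path(cfg, stem)
    atomic_write(df, p, dialect)
    outputs <<- c(outputs, p)
    p
  }

  if (name == "simulate") {
    sim <- simulate_screen(screen_sim_config(), seed = cfg$seed)
    emit(as.data.frame(as_well_table(sim$plates)), "wells")
    emit(as.data.frame(sim$annotations), "annotations")
    eff <- sim$truth$effects
    emit(data.frame(mimic_id = rownames(eff), eff, check.names = FALSE),
         "truth_effects")
    emit(data.frame(cell_line = names(sim$truth$line_clusters),
                    cluster = as.integer(sim$truth$line_clusters)),
         "truth_line_clusters")
  } else if (name == "normalize") {
    inputs <- require_input(stage_path(cfg, "wells"))
    plates <- read_well_table(inputs, dialect)
    plates <- lapply(plates, normalize_row_median)
    emit(as.data.frame(as_well_table(plates)), "normalized_wells")
  } else if (name == "zscore") {
    inputs <- require_input(stage_path(cfg, "normalized_wells"))
    plates <- read_well_table(inputs, dialect, normalized = TRUE)
    agg <- aggregate_replicates(plates)
    z <- compute_zscores(agg$mean, scope = cfg$zscore_scope)
    p <- stage_path(cfg, "zscores")
    write_zscore_matrix(z, p, dialect); outputs <- c(outputs, p)
    p2 <- stage_path(cfg, "mean_viability")
    write_zscore_matrix(agg$mean, p2, dialect); outputs <- c(outputs, p2)
    p3 <- stage_path(cfg, "replicate_sd")
    write_zscore_matrix(agg$sd, p3, dialect); outputs <- c(outputs, p3)
  } else if (name == "hits") {
    inputs <- require_input(stage_path(cfg, "zscores"))
    z <- read_zscore_matrix(inputs, dialect)
    hits <- call_hits(z, threshold = cfg$hit_threshold)
    emit(as.data.frame(hits), "hits")
    rs <- responsiveness_summary(hits, n_lines = ncol(z))
    emit(data.frame(responsive_lines = as.integer(names(rs$histogram)),
                    n_mimics = as.integer(rs$histogram)),
         "responsiveness_histogram")
  } else if (name == "cluster") {
    inputs <- require_input(stage_path(cfg, "zscores"))
    z <- read_zscore_matrix(inputs, dialect)
    h_lines <- hierarchical_ap(t(unclass(z)), metric = cfg$ap_metric,
                               preference = cfg$ap_preference,
                               damping = cfg$ap_damping,
                               max_iter = cfg$ap_max_iter,
                               convergence_window =
                                 cfg$ap_convergence_window)
    memb <- h_lines$membership
    emit(data.frame(item = rownames(memb), memb, check.names = FALSE),
         "cluster_lines_membership")
    gp <- file.path(cfg$out_dir, "cluster_lines.graphml")
    export_cluster_network(h_lines, gp)
    outputs <- c(outputs, gp)
  } else if (name == "enrich") {
    pred_path <- stage_path(cfg, "target_predictions")
    lr_path <- stage_path(cfg, "log2_ratios")
    if (!file.exists(pred_path) || !file.exists(lr_path)) {
      sim <- simulate_expression_response(seed = cfg$seed)
      atomic_write(as.data.frame(sim$predictions), pred_path, dialect)
      atomic_write(data.frame(gene_id = names(sim$log2_ratios),
                              log2_ratio = as.numeric(sim$log2_ratios)),
                   lr_path, dialect)
    }
    inputs <- c(require_input(pred_path), require_input(lr_path))
    pred <- target_predictions(read_delim_dialect(pred_path, dialect))
    lr_df <- read_delim_dialect(lr_path, dialect)
    lr <- setNames(lr_df$log2_ratio, lr_df$gene_id)
    responsive <- names(lr)[lr <= -log2(cfg$fold_threshold)]
    enr <- target_enrichment(responsive,
                             pred$gene_id[pred$is_expressed],
                             names(lr))
    emit(data.frame(universe = enr$universe_size,
                    responsive = enr$set_a_size,
                    predicted = enr$set_b_size, overlap = enr$overlap,
                    p_value = enr$p_value), "enrichment")
    curve <- suppressWarnings(
      context_score_curve(pred, lr, fold_threshold = cfg$fold_threshold,
                          bin_edges = cfg$bin_edges))
    emit(as.data.frame(curve), "context_curve")
  } else if (name == "survival") {
    coh_path <- stage_path(cfg, "survival_cohort")
    if (!file.exists(coh_path)) {
      sim <- simulate_survival_cohort(survival_sim_config(),
                                      seed = cfg$seed)
      atomic_write(as.data.frame(sim$cohort), coh_path, dialect)
    }
    inputs <- require_input(coh_path)
    cohort <- survival_cohort(read_delim_dialect(coh_path, dialect))
    sp <- split_cohort(cohort, seed = cfg$seed)
    scan <- cutoff_scan(sp$training,
                        percentile_range = cfg$percentile_range,
                        alpha = cfg$alpha)
    emit(scan$candidates, "cutoff_scan")
    sel <- scan$candidates[scan$candidates$selected, , drop = FALSE]
    val <- do.call(rbind, lapply(seq_len(nrow(sel)), function(i) {
      v <- tryCatch(validate_cutoff(sp$validation, sel$cutoff_value[i],
                                    alpha = cfg$alpha),
                    mimicscreen_degenerate_error = function(e) NULL)
      if (is.null(v)) return(NULL)
      data.frame(percentile = sel$percentile[i],
                 cutoff_value = sel$cutoff_value[i],
                 training_p = sel$p[i], validation_p = v$p,
                 median_low = v$median_low, median_high = v$median_high,
                 primary = FALSE)
    }))
    if (!is.null(val) && nrow(val) > 0L) {
      val$primary <- seq_len(nrow(val)) == which.min(val$training_p)
    } else {
      val <- data.frame(percentile = numeric(0), cutoff_value = numeric(0),
                        training_p = numeric(0), validation_p = numeric(0),
                        median_low = numeric(0), median_high = numeric(0),
                        primary = logical(0))
    }
    emit(val, "cutoff_validation")
  } else if (name == "phenocopy") {
    panel_rds <- stage_path(cfg, "phenocopy_profiles")
    if (!file.exists(panel_rds)) {
      sim <- simulate_phenocopy_panel(seed = cfg$seed)
      flat <- do.call(rbind, lapply(names(sim$panel$gene_profiles),
        function(g) {
          m <- sim$panel$gene_profiles[[g]]
          data.frame(gene_id = g,
                     pool = rep(c(1L, 2L), each = ncol(m)),
                     cell_line = rep(colnames(m), 2L),
                     viability = c(m["pool1", ], m["pool2", ]))
        }))
      atomic_write(flat, panel_rds, dialect)
      atomic_write(data.frame(cell_line = sim$panel$cell_lines,
                              mimic_value = sim$panel$mimic_profile,
                              index_line = sim$panel$index_line,
                              stringsAsFactors = FALSE),
                   stage_path(cfg, "phenocopy_mimic"), dialect)
      atomic_write(data.frame(gene_id = names(sim$panel$screen_viability),
                              screen_viability =
                                as.numeric(sim$panel$screen_viability)),
                   stage_path(cfg, "phenocopy_screen_viability"), dialect)
    }
    inputs <- c(require_input(panel_rds),
                require_input(stage_path(cfg, "phenocopy_mimic")))
    flat <- read_delim_dialect(panel_rds, dialect)
    mi <- read_delim_dialect(stage_path(cfg, "phenocopy_mimic"), dialect)
    sv_path <- stage_path(cfg, "phenocopy_screen_viability")
    sv <- if (file.exists(sv_path)) {
      df <- read_delim_dialect(sv_path, dialect)
      setNames(df$screen_viability, df$gene_id)
    } else NULL
    genes <- unique(flat$gene_id)
    profiles <- setNames(lapply(genes, function(g) {
      sub <- flat[flat$gene_id == g, ]
      m <- rbind(
        pool1 = sub$viability[sub$pool == 1L][match(mi$cell_line,
                 sub$cell_line[sub$pool == 1L])],
        pool2 = sub$viability[sub$pool == 2L][match(mi$cell_line,
                 sub$cell_line[sub$pool == 2L])])
      colnames(m) <- mi$cell_line
      m
    }), genes)
    panel <- phenocopy_panel(mi$cell_line,
                             setNames(mi$mimic_value, mi$cell_line),
                             profiles, index_line = mi$index_line[1L],
                             screen_viability = sv)
    res <- phenocopy_screen(panel, viability_cutoff = cfg$viability_cutoff,
                            r2_cutoff = cfg$r2_cutoff)
    emit(as.data.frame(res), "phenocopy_result")
  } else if (name == "cnv") {
    dr_path <- stage_path(cfg, "depth_ratios")
    if (!file.exists(dr_path)) {
      ratios <- with_seed(cfg$seed,
        stats::rlnorm(500L, meanlog = 0, sdlog = 0.4))
      atomic_write(data.frame(gene_id = sprintf("gene_%04d", 1:500),
                              depth_ratio = ratios), dr_path, dialect)
    }
    inputs <- require_input(dr_path)
    dr <- read_delim_dialect(dr_path, dialect)
    calls <- classify_copy_number(setNames(dr$depth_ratio, dr$gene_id),
                                  gain_min = cfg$cnv_gain_min,
                                  loss_max = cfg$cnv_loss_max)
    emit(as.data.frame(calls), "cnv_calls")
  } else if (name == "report") {
    inputs <- c(require_input(stage_path(cfg, "hits")),
                require_input(stage_path(cfg, "responsiveness_histogram")))
    hits_df <- read_delim_dialect(inputs[1L], dialect)
    hist_df <- read_delim_dialect(inputs[2L], dialect)
    counts <- table(factor(table(hits_df$mimic_id),
                           levels = hist_df$responsive_lines))
    report <- data.frame(
      responsive_lines = hist_df$responsive_lines,
      n_mimics = hist_df$n_mimics,
      n_mimics_recomputed = as.integer(counts))
    report_totals <- data.frame(
      metric = c("n_hit_mimics", "n_hit_cells", "max_responsive_lines"),
      value = c(length(unique(hits_df$mimic_id)), nrow(hits_df),
                if (nrow(hits_df)) max(table(hits_df$mimic_id)) else 0))
    emit(report, "report_histogram")
    emit(report_totals, "report_summary")
  }
  write_manifest(cfg, name, inputs, outputs)
  invisible(outputs)
}

#' Run the full synthetic demo pipeline
#'
#' Executes every stage in order on the configured output directory.
#'
#' @param cfg A \code{\link{pipeline_config}}.
#' @param stages Stages to run (default all, in pipeline order).
#' @return Invisibly, a named list of the files written per stage.
#' @export
run_pipeline <- function(cfg = pipeline_config(),
                         stages = PIPELINE_STAGES) {
  out <- lapply(stages, run_stage, cfg = cfg)
  names(out) <- stages
  invisible(out)
}
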