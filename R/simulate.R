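# Seeded generators producing synthetic inputs with the statistical
# structure every pipeline stage assumes: a plate-based mimic toxicity
# screen with position/batch effects and planted sensitivities, survival
# cohorts with threshold-dependent hazards, dual-pool phenocopy panels,
# and context-score-dependent expression responses. Every generator is a
# pure function of (config, seed).

#' Configuration for the synthetic mimic screen
#'
#' Defaults emulate a genome-scale screen: 400 mimics against a 16-line
#' panel in biological triplicate on 96-well (8 x 12) plates, one
#' negative-control well per row, multiplicative lognormal row/batch/
#' replicate noise on luminescence, seed-family-correlated phenotypes,
#' and a planted hit architecture of 108 sensitive mimics of which 86
#' are "private" (responsive in only 1-2 lines; about 80 percent, the
#' hallmark of idiosyncratic mimic toxicity) with a responsiveness tail
#' reaching 9 lines. Cell lines belong to latent response clusters that
#' shape both the shared phenotype component and where public hits land.
#'
#' @param n_mimics,n_lines,n_replicates Library and panel dimensions.
#' @param plate_rows,plate_cols Plate geometry (default 8 x 12; the last
#'   column of every row carries the negative control).
#' @param baseline_lum Baseline luminescence of a fully viable well.
#' @param row_effect_sd,batch_effect_sd,noise_sd Lognormal sdlog of the
#'   per-(plate, replicate, row) position effect, the per-(plate,
#'   replicate) batch effect, and per-well replicate noise.
#' @param phenotype_sd Lognormal sdlog of the line-specific (non-toxic)
#'   phenotype component of each mimic.
#' @param line_cluster_sd Lognormal sdlog of the phenotype component
#'   shared by all lines of a response cluster.
#' @param family_rho Intra-seed-family phenotype correlation in [0, 1].
#' @param family_sizes Integer vector of seed-family sizes summing to
#'   \code{n_mimics}.
#' @param n_duplicate_pairs Number of two-member families whose members
#'   carry the identical mature sequence (library-redundancy emulation).
#' @param hit_line_counts Integer vector, one entry per planted sensitive
#'   mimic, giving its number of responsive lines (empty vector = no
#'   planted hits).
#' @param effect_range Range of the planted fractional viability
#'   reduction, within [0, 1].
#' @param n_line_clusters Number of latent cell-line response clusters.
#' @return A validated list of class \code{"screen_sim_config"}.
#' @export
screen_sim_config <- function(n_mimics = 400L, n_lines = 16L,
                              n_replicates = 3L, plate_rows = 8L,
                              plate_cols = 12L, baseline_lum = 1e6,
                              row_effect_sd = 0.1, batch_effect_sd = 0.1,
                              noise_sd = 0.02, phenotype_sd = 0.03,
                              line_cluster_sd = 0.05, family_rho = 0.8,
                              family_sizes = NULL,
                              n_duplicate_pairs = NULL,
                              hit_line_counts = NULL,
                              effect_range = c(0.4, 0.7),
                              n_line_clusters = NULL) {
  n_mimics <- as.integer(n_mimics); n_lines <- as.integer(n_lines)
  n_replicates <- as.integer(n_replicates)
  plate_rows <- as.integer(plate_rows); plate_cols <- as.integer(plate_cols)
  if (n_mimics < 1L || n_lines < 1L || n_replicates < 1L) {
    ms_config_error("n_mimics, n_lines, n_replicates must be >= 1")
  }
  if (plate_rows < 1L || plate_cols < 2L) {
    ms_config_error(
      "plate geometry needs >= 1 row and >= 2 columns (one is the control)")
  }
  if (is.null(n_duplicate_pairs)) {
    n_duplicate_pairs <- min(14L, floor(n_mimics * 0.035))
  }
  n_duplicate_pairs <- as.integer(n_duplicate_pairs)
  if (is.null(n_line_clusters)) n_line_clusters <- min(5L, n_lines)
  if (is.null(family_sizes)) {
    n2 <- max(n_duplicate_pairs, floor(n_mimics * 0.225 / 2))
    n3 <- floor(n_mimics * 0.15 / 3)
    n1 <- n_mimics - 2L * n2 - 3L * n3
    if (n1 < 0L) ms_config_error("default family sizes overflow n_mimics")
    family_sizes <- c(rep(1L, n1), rep(2L, n2), rep(3L, n3))
  }
  family_sizes <- as.integer(family_sizes)
  if (sum(family_sizes) != n_mimics || any(family_sizes < 1L)) {
    ms_config_error("family_sizes must be positive and sum to n_mimics")
  }
  if (n_duplicate_pairs > sum(family_sizes == 2L)) {
    ms_config_error("n_duplicate_pairs exceeds the two-member families")
  }
  if (is.null(hit_line_counts)) {
    hit_line_counts <- if (n_mimics >= 108L && n_lines >= 9L) {
      c(rep(1L, 60L), rep(2L, 26L), rep(3L, 5L), rep(4L, 4L),
        rep(5L, 3L), rep(6L, 3L), rep(7L, 3L), rep(8L, 2L), rep(9L, 2L))
    } else {
      integer(0)
    }
  }
  hit_line_counts <- as.integer(hit_line_counts)
  if (length(hit_line_counts) > n_mimics ||
      (length(hit_line_counts) > 0L && max(hit_line_counts) > n_lines)) {
    ms_config_error("hit_line_counts exceed the library or panel size")
  }
  if (!is_scalar_number(family_rho) || family_rho < 0 || family_rho > 1) {
    ms_config_error("family_rho must be in [0, 1]")
  }
  if (length(effect_range) != 2L || any(effect_range < 0) ||
      any(effect_range > 1) || effect_range[1L] > effect_range[2L]) {
    ms_config_error("effect_range must be an increasing range within [0, 1]")
  }
  n_line_clusters <- as.integer(n_line_clusters)
  if (n_line_clusters < 1L || n_line_clusters > n_lines) {
    ms_config_error("n_line_clusters must be in [1, n_lines]")
  }
  # capacity: one control column per plate row
  mimic_wells_per_plate <- plate_rows * (plate_cols - 1L)
  n_plates <- ceiling(n_mimics / mimic_wells_per_plate)
  structure(
    list(n_mimics = n_mimics, n_lines = n_lines,
         n_replicates = n_replicates, plate_rows = plate_rows,
         plate_cols = plate_cols, baseline_lum = baseline_lum,
         row_effect_sd = row_effect_sd, batch_effect_sd = batch_effect_sd,
         noise_sd = noise_sd, phenotype_sd = phenotype_sd,
         line_cluster_sd = line_cluster_sd, family_rho = family_rho,
         family_sizes = family_sizes,
         n_duplicate_pairs = as.integer(n_duplicate_pairs),
         hit_line_counts = hit_line_counts, effect_range = effect_range,
         n_line_clusters = n_line_clusters, n_plates = n_plates),
    class = "screen_sim_config")
}

rand_rna <- function(n, len = 22L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
          collapse = ""), character(1L))
}

#' Simulate a plate-based miRNA mimic toxicity screen
#'
#' Generates raw luminescence plates for every cell line and replicate
#' under the model
#' \code{lum = baseline x row effect x batch effect x (1 - planted
#' effect) x phenotype x noise}, where the phenotype component is shared
#' within seed families (correlation \code{family_rho}) and within
#' latent cell-line response clusters, and planted sensitivities follow
#' the configured hit architecture (public hits land inside line
#' clusters).
#'
#' @param cfg A \code{\link{screen_sim_config}}.
#' @param seed Integer seed; output is a pure function of (cfg, seed).
#' @return A list: \code{plates} (raw \code{\link{screen_plate}}s),
#'   \code{annotations} (\code{\link{mimic_annotations}}),
#'   \code{truth} with \code{effects} (mimic x line matrix of planted
#'   fractional reductions), \code{sensitive} (logical matrix),
#'   \code{line_clusters} (named vector), \code{family} (mimic to family
#'   id), \code{n_unique_mature_hits} and the per-mimic
#'   \code{responsive_line_counts}.
#' @export
simulate_screen <- function(cfg = screen_sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  with_seed(seed, {
    n_m <- cfg$n_mimics; n_l <- cfg$n_lines
    mimics <- sprintf("mimic_%03d", seq_len(n_m))
    lines <- sprintf("line_%02d", seq_len(n_l))

    # seed families and mature sequences
    n_fam <- length(cfg$family_sizes)
    fam_of <- rep(seq_len(n_fam), cfg$family_sizes)
    fam_seeds <- rand_rna(n_fam, 7L)
    while (anyDuplicated(fam_seeds)) {          # families must differ
      dup <- which(duplicated(fam_seeds))
      fam_seeds[dup] <- rand_rna(length(dup), 7L)
    }
    flank5 <- substr(rand_rna(n_m, 1L), 1L, 1L)
    flank3 <- rand_rna(n_m, 14L)
    mature <- paste0(flank5, fam_seeds[fam_of], flank3)
    two_member <- which(cfg$family_sizes == 2L)
    dup_fams <- two_member[seq_len(cfg$n_duplicate_pairs)]
    for (f in dup_fams) {                        # identical mature pair
      members <- which(fam_of == f)
      mature[members[2L]] <- mature[members[1L]]
    }
    ann <- mimic_annotations(data.frame(
      mimic_id = mimics, mature_sequence = mature,
      stringsAsFactors = FALSE))

    # latent cell-line response clusters (near-equal sizes)
    cl_sizes <- diff(round(seq(0, n_l, length.out = cfg$n_line_clusters + 1)))
    line_cluster <- setNames(rep(seq_len(cfg$n_line_clusters), cl_sizes),
                             lines)

    # planted sensitivity map: sensitive mimics get responsive lines
    # drawn inside a home cluster (spilling into a neighbor when the
    # requested count exceeds the cluster)
    effects <- matrix(0, n_m, n_l, dimnames = list(mimics, lines))
    counts <- cfg$hit_line_counts
    sensitive_mimics <- if (length(counts) > 0L) {
      sample(seq_len(n_m), length(counts))
    } else integer(0)
    for (j in seq_along(sensitive_mimics)) {
      m <- sensitive_mimics[j]; k <- counts[j]
      home <- sample.int(cfg$n_line_clusters, 1L)
      pool <- which(line_cluster == home)
      if (k > length(pool)) {
        others <- sample(setdiff(seq_len(cfg$n_line_clusters), home))
        for (o in others) {
          pool <- c(pool, which(line_cluster == o))
          if (length(pool) >= k) break
        }
      }
      hit_lines <- pool[seq_len(min(k, length(pool)))]
      if (k <= length(pool)) hit_lines <- sample(pool, k)
      effects[m, hit_lines] <- runif(length(hit_lines),
                                     cfg$effect_range[1L],
                                     cfg$effect_range[2L])
    }

    # phenotype component: family latent + own, each built from a
    # cluster-shared and a line-specific lognormal piece
    structured <- function(n_units) {
      cl <- matrix(rnorm(n_units * cfg$n_line_clusters,
                         sd = cfg$line_cluster_sd),
                   n_units, cfg$n_line_clusters)
      cl[, line_cluster, drop = FALSE] +
        matrix(rnorm(n_units * n_l, sd = cfg$phenotype_sd), n_units, n_l)
    }
    fam_latent <- structured(n_fam)
    own_latent <- structured(n_m)
    log_pheno <- sqrt(cfg$family_rho) * fam_latent[fam_of, , drop = FALSE] +
      sqrt(1 - cfg$family_rho) * own_latent
    pheno <- exp(log_pheno)

    # plate layout: identical mimic placement for every line/replicate;
    # last column of each row holds the negative control, leftover wells
    # on the final plate are filled with extra controls
    rows <- LETTERS[seq_len(cfg$plate_rows)]
    mimic_cols <- seq_len(cfg$plate_cols - 1L)
    layout <- expand.grid(column = mimic_cols, row = rows,
                          plate = seq_len(cfg$n_plates),
                          KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
    layout <- layout[order(layout$plate, layout$row, layout$column), ]
    layout$mimic_id <- c(mimics,
                         rep(negative_control_id(),
                             nrow(layout) - n_m))
    control_wells <- expand.grid(column = cfg$plate_cols, row = rows,
                                 plate = seq_len(cfg$n_plates),
                                 KEEP.OUT.ATTRS = FALSE,
                                 stringsAsFactors = FALSE)
    control_wells$mimic_id <- negative_control_id()
    layout <- rbind(layout, control_wells)
    layout <- layout[order(layout$plate, layout$row, layout$column), ]

    viab_of <- function(mimic_id, l) {
      v <- rep(1, length(mimic_id))
      is_m <- mimic_id != negative_control_id()
      idx <- match(mimic_id[is_m], mimics)
      at <- cbind(idx, rep.int(l, length(idx)))
      v[is_m] <- (1 - effects[at]) * pheno[at]
      v
    }

    plates <- list()
    for (l in seq_len(n_l)) {
      for (r in seq_len(cfg$n_replicates)) {
        for (p in seq_len(cfg$n_plates)) {
          wl <- layout[layout$plate == p, , drop = FALSE]
          plate_id <- sprintf("%s_p%02d", lines[l], p)
          batch <- rlnorm(1L, sdlog = cfg$batch_effect_sd)
          row_eff <- setNames(rlnorm(length(rows),
                                     sdlog = cfg$row_effect_sd), rows)
          noise <- rlnorm(nrow(wl), sdlog = cfg$noise_sd)
          lum <- cfg$baseline_lum * batch * row_eff[wl$row] *
            viab_of(wl$mimic_id, l) * noise
          plates[[sprintf("%s.rep%d", plate_id, r)]] <- screen_plate(
            plate_id = plate_id, cell_line = lines[l], replicate = r,
            wells = data.frame(row = wl$row, column = wl$column,
                               mimic_id = wl$mimic_id, value = lum,
                               stringsAsFactors = FALSE))
        }
      }
    }

    resp_counts <- setNames(rowSums(effects > 0), mimics)
    hit_ids <- mimics[resp_counts > 0]
    truth <- list(
      effects = effects,
      sensitive = effects > 0,
      line_clusters = line_cluster,
      family = setNames(ann$family_id, ann$mimic_id),
      responsive_line_counts = resp_counts[resp_counts > 0],
      n_unique_mature_hits = length(unique(
        ann$mature_sequence[match(hit_ids, ann$mimic_id)]))
    )
    list(plates = plates, annotations = ann, truth = truth, config = cfg)
  })
}

#' Configuration for the synthetic survival cohort
#'
#' @param n_patients Cohort size (default 300).
#' @param censoring_rate Hazard of the independent exponential censoring
#'   process (per month; 0 = no censoring; default 0.02).
#' @param baseline_hazard Event hazard below the threshold (per month;
#'   default 0.05, i.e. median survival about 14 months).
#' @param threshold_percentile Expression percentile above which the
#'   hazard changes (default 60).
#' @param hazard_ratio Multiplicative hazard for patients above the
#'   threshold (default 3; must be positive).
#' @param expression_dist Function(n) drawing expression values (default
#'   standard normal).
#' @return A validated list of class \code{"survival_sim_config"}.
#' @export
survival_sim_config <- function(n_patients = 300L, censoring_rate = 0.02,
                                baseline_hazard = 0.05,
                                threshold_percentile = 60,
                                hazard_ratio = 3,
                                expression_dist = stats::rnorm) {
  if (!is_scalar_number(hazard_ratio) || hazard_ratio <= 0) {
    ms_config_error("hazard_ratio must be positive")
  }
  if (!is_scalar_number(threshold_percentile) ||
      threshold_percentile <= 0 || threshold_percentile >= 100) {
    ms_config_error("threshold_percentile must be in (0, 100)")
  }
  if (!is_scalar_number(censoring_rate) || censoring_rate < 0) {
    ms_config_error("censoring_rate must be non-negative")
  }
  if (!is_scalar_number(baseline_hazard) || baseline_hazard <= 0) {
    ms_config_error("baseline_hazard must be positive")
  }
  structure(list(n_patients = as.integer(n_patients),
                 censoring_rate = censoring_rate,
                 baseline_hazard = baseline_hazard,
                 threshold_percentile = threshold_percentile,
                 hazard_ratio = hazard_ratio,
                 expression_dist = expression_dist),
            class = "survival_sim_config")
}

#' Simulate a survival cohort with a threshold-dependent hazard
#'
#' Exponential survival with the hazard multiplied by
#' \code{hazard_ratio} for patients whose expression lies strictly above
#' the configured percentile of the cohort's expression values;
#' independent exponential censoring at \code{censoring_rate}.
#'
#' @param cfg A \code{\link{survival_sim_config}}.
#' @param seed Integer seed.
#' @return List with \code{cohort} (a \code{\link{survival_cohort}}) and
#'   \code{truth} (threshold percentile and value, per-patient group,
#'   true group median survivals).
#' @export
simulate_survival_cohort <- function(cfg = survival_sim_config(),
                                     seed = 1L) {
  stopifnot(inherits(cfg, "survival_sim_config"))
  with_seed(seed, {
    n <- cfg$n_patients
    expr <- cfg$expression_dist(n)
    thr <- as.numeric(stats::quantile(expr, cfg$threshold_percentile / 100,
                                      type = 7))
    high <- expr > thr
    hazard <- cfg$baseline_hazard * ifelse(high, cfg$hazard_ratio, 1)
    t_event <- rexp(n, rate = hazard)
    t_cens <- if (cfg$censoring_rate > 0) {
      rexp(n, rate = cfg$censoring_rate)
    } else rep(Inf, n)
    cohort <- survival_cohort(data.frame(
      sample_id = sprintf("pt_%04d", seq_len(n)),
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      expression = expr, stringsAsFactors = FALSE))
    truth <- list(threshold_percentile = cfg$threshold_percentile,
                  threshold_value = thr, high = high,
                  median_low = log(2) / cfg$baseline_hazard,
                  median_high = log(2) /
                    (cfg$baseline_hazard * cfg$hazard_ratio))
    list(cohort = cohort, truth = truth)
  })
}

#' Simulate a dual-pool phenocopy panel
#'
#' The mimic toxicity profile is drawn standard normal across lines. The
#' planted gene's two siRNA pool profiles are constructed to have
#' exactly the requested sample correlation with the mimic profile
#' (Gram-Schmidt mixture of the mimic profile with an orthogonalized
#' noise vector, one independent noise vector per pool); the remaining
#' genes are independent noise. Every gene is given a passing stage-1
#' screen viability in the index line, mirroring a pre-filtered
#' candidate panel.
#'
#' @param n_lines Panel size (default 13; at least 3).
#' @param n_genes Number of candidate genes (default 10).
#' @param planted_gene Index (1-based) of the gene carrying the planted
#'   correlation.
#' @param planted_r Planted Pearson correlation in [0, 1].
#' @param seed Integer seed.
#' @return List with \code{panel} (a \code{\link{phenocopy_panel}}) and
#'   \code{truth} (planted gene id and correlation).
#' @export
simulate_phenocopy_panel <- function(n_lines = 13L, n_genes = 10L,
                                     planted_gene = 1L, planted_r = 0.8,
                                     seed = 1L) {
  n_lines <- as.integer(n_lines); n_genes <- as.integer(n_genes)
  if (n_lines < 3L) ms_config_error("n_lines must be at least 3")
  if (n_genes < 1L) ms_config_error("n_genes must be at least 1")
  if (!is_scalar_number(planted_r) || planted_r < 0 || planted_r > 1) {
    ms_config_error("planted_r must be in [0, 1]")
  }
  planted_gene <- as.integer(planted_gene)
  if (planted_gene < 1L || planted_gene > n_genes) {
    ms_config_error("planted_gene must index one of the genes")
  }
  with_seed(seed, {
    lines <- sprintf("line_%02d", seq_len(n_lines))
    genes <- sprintf("gene_%02d", seq_len(n_genes))
    mimic <- rnorm(n_lines)
    m_std <- as.numeric(scale(mimic))
    correlated_profile <- function(r) {
      z <- rnorm(n_lines)
      e <- z - m_std * sum(z * m_std) / sum(m_std^2)  # orthogonal residual
      if (sum(e^2) == 0) e <- rep(0, n_lines) else
        e <- as.numeric(scale(e))
      r * m_std + sqrt(max(0, 1 - r^2)) * e
    }
    gene_profiles <- setNames(vector("list", n_genes), genes)
    for (g in seq_len(n_genes)) {
      prof <- if (g == planted_gene) {
        rbind(correlated_profile(planted_r), correlated_profile(planted_r))
      } else {
        rbind(as.numeric(scale(rnorm(n_lines))),
              as.numeric(scale(rnorm(n_lines))))
      }
      # map to a relative-viability scale (correlation-preserving)
      gene_profiles[[g]] <- 0.8 + 0.2 * prof
    }
    panel <- phenocopy_panel(
      cell_lines = lines, mimic_profile = mimic,
      gene_profiles = gene_profiles, index_line = lines[1L],
      screen_viability = setNames(runif(n_genes, 0.15, 0.45), genes))
    list(panel = panel,
         truth = list(planted_gene = genes[planted_gene],
                      planted_r = planted_r))
  })
}

#' Simulate an expression response with score-dependent knockdown
#'
#' Predicted targets receive context scores from \code{score_dist}; each
#' target is down-regulated (log2 ratio at or below -1) with probability
#' \code{down_rate_by_score(score)}, non-targets at
#' \code{background_rate}.
#'
#' @param n_genes Total expressed genes (default 2000).
#' @param target_fraction Fraction that are predicted targets (default
#'   0.25).
#' @param score_dist Function(n) drawing context scores (default uniform
#'   on [-0.6, 0]).
#' @param down_rate_by_score Function(score) giving the per-target
#'   down-regulation probability (default 0.41 at scores <= -0.2, 0.15
#'   above).
#' @param background_rate Down-regulation rate of non-targets (default
#'   0.05).
#' @param seed Integer seed.
#' @return List with \code{predictions} (a
#'   \code{\link{target_predictions}} table for the target genes),
#'   \code{log2_ratios} (named vector over all genes), \code{universe}
#'   (all gene ids) and \code{truth} (per-gene target/down flags and the
#'   rate function used).
#' @export
simulate_expression_response <- function(n_genes = 2000L,
                                         target_fraction = 0.25,
                                         score_dist = function(n)
                                           -runif(n, 0, 0.6),
                                         down_rate_by_score = function(s)
                                           ifelse(s <= -0.2, 0.41, 0.15),
                                         background_rate = 0.05,
                                         seed = 1L) {
  n_genes <- as.integer(n_genes)
  if (!is_scalar_number(target_fraction) || target_fraction <= 0 ||
      target_fraction > 1) {
    ms_config_error("target_fraction must be in (0, 1]")
  }
  if (!is_scalar_number(background_rate) || background_rate < 0 ||
      background_rate > 1) {
    ms_config_error("background_rate must be in [0, 1]")
  }
  with_seed(seed, {
    genes <- sprintf("gene_%05d", seq_len(n_genes))
    n_targets <- round(target_fraction * n_genes)
    target_idx <- sample.int(n_genes, n_targets)
    scores <- score_dist(n_targets)
    if (any(scores > 0)) {
      ms_validation_error("context scores must be <= 0")
    }
    p_down <- rep(background_rate, n_genes)
    p_down[target_idx] <- down_rate_by_score(scores)
    if (any(p_down < 0 | p_down > 1)) {
      ms_validation_error("down rates must be probabilities")
    }
    down <- rbinom(n_genes, 1L, p_down) == 1L
    lr <- rnorm(n_genes, 0, 0.3)
    lr[lr <= -1] <- -0.99                    # keep non-down strictly above
    lr[down] <- -1 - rexp(sum(down), rate = 2)
    names(lr) <- genes
    predictions <- target_predictions(data.frame(
      gene_id = genes[target_idx], context_score = scores,
      is_expressed = TRUE, stringsAsFactors = FALSE))
    list(predictions = predictions, log2_ratios = lr, universe = genes,
         truth = list(targets = genes[target_idx], down = setNames(down, genes),
                      down_rate_by_score = down_rate_by_score,
                      background_rate = background_rate))
  })
}
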