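test_that("row-median normalization removes planted per-row gains", {
  plate <- make_gain_plate()
  norm <- normalize_row_median(plate)
  # spreadsheet-style recomputation: value / median of its row
  w <- plate$wells
  expected <- w$value / ave(w$value, w$row, FUN = median)
  expect_equal(norm$wells$value, expected)
  med_by_row <- tapply(norm$wells$value, norm$wells$row, median)
  expect_equal(as.numeric(med_by_row), rep(1, 8))
  # gains are gone: identical mimic columns agree across rows
  by_mimic <- split(norm$wells$value, norm$wells$mimic_id)
  expect_true(all(vapply(by_mimic, function(v) diff(range(v)) < 1e-12,
                         logical(1))))
})

test_that("row normalization handles constant and simple rows by inspection", {
  wells <- data.frame(row = rep(c("A", "B"), each = 3), column = rep(1:3, 2),
                      mimic_id = paste0("m", 1:6),
                      value = c(4, 4, 4, 2, 4, 6))
  p <- normalize_row_median(screen_plate("P", "L", 1L, wells))
  expect_equal(p$wells$value, c(1, 1, 1, 0.5, 1, 1.5))
})

test_that("normalization is invariant to per-row scaling and rejects zero rows", {
  plate <- make_gain_plate()
  scaled <- plate
  scaled$wells$value <- plate$wells$value *
    ifelse(plate$wells$row == "C", 7.3, 1)
  expect_equal(normalize_row_median(scaled)$wells$value,
               normalize_row_median(plate)$wells$value)
  zero <- plate
  zero$wells$value[zero$wells$row == "B"] <- 0
  err <- tryCatch(normalize_row_median(zero), error = identity)
  expect_s3_class(err, "mimicscreen_degenerate_error")
  expect_match(conditionMessage(err), "B")
})

test_that("replicate aggregation gives hand-computed means and sample SDs", {
  wells <- function(v, rep) data.frame(row = "A", column = 1:2,
                                       mimic_id = c("m1", negative_control_id()),
                                       value = c(v, 1))
  plates <- lapply(1:3, function(r) {
    p <- screen_plate("P", "L", r, wells(c(0.8, 1.0, 1.2)[r], r))
    p$normalized <- TRUE
    p
  })
  agg <- aggregate_replicates(plates)
  expect_equal(agg$mean["m1", "L"], 1.0)
  expect_equal(agg$sd["m1", "L"], 0.2)   # sample SD of (0.8, 1.0, 1.2)
  expect_equal(agg$n["m1", "L"], 3L)

  # constant replicates
  plates_const <- lapply(1:3, function(r) {
    p <- screen_plate("P", "L", r, wells(1.0, r)); p$normalized <- TRUE; p
  })
  expect_equal(aggregate_replicates(plates_const)$sd["m1", "L"], 0)

  # a mimic missing from one replicate: mean/SD over 2, count 2, never
  # fabricated
  p3 <- plates
  p3[[3]]$wells <- p3[[3]]$wells[p3[[3]]$wells$mimic_id != "m1", ]
  agg2 <- aggregate_replicates(p3)
  expect_equal(agg2$n["m1", "L"], 2L)
  expect_equal(agg2$mean["m1", "L"], 0.9)
  expect_equal(agg2$sd["m1", "L"], sd(c(0.8, 1.0)))
})

test_that("z-scores standardize each line and match a two-pass oracle", {
  m <- matrix(c(1, 2, 3, 10, 20, 60), 3, 2,
              dimnames = list(c("a", "b", "c"), c("L1", "L2")))
  z <- compute_zscores(m)
  expect_equal(unname(unclass(z)[, "L1"]), c(-1, 0, 1))
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-9)

  # independent two-pass mean/SD oracle on the default synthetic screen
  pl <- default_screen_pipeline()
  oracle <- apply(pl$agg$mean, 2, function(v) (v - mean(v)) / sd(v))
  expect_lt(max(abs(unclass(pl$z) - oracle)), 1e-10)

  const <- m
  const[, 2] <- 5
  expect_error(compute_zscores(const),
               class = "mimicscreen_degenerate_error")
})

test_that("z-scores are invariant to positive affine transforms of a line", {
  pl <- default_screen_pipeline()
  m <- pl$agg$mean
  m2 <- m
  m2[, 3] <- 2.5 * m2[, 3] + 7
  expect_equal(unclass(compute_zscores(m2)), unclass(pl$z),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("hit calling uses an inclusive boundary and is monotone in the threshold", {
  z <- zscore_matrix(matrix(c(-2.0, -1.99, -2.01, 0), 2, 2,
                            dimnames = list(c("m1", "m2"),
                                            c("L1", "L2"))))
  hits <- call_hits(z, threshold = -2)
  expect_setequal(paste(hits$mimic_id, hits$cell_line),
                  c("m1 L1", "m1 L2"))   # -2.0 is a hit, -1.99 is not
  strict <- call_hits(z, threshold = -2, inclusive = FALSE)
  expect_equal(nrow(strict), 1L)

  pl <- default_screen_pipeline()
  for (pair in list(c(-3, -2), c(-2.5, -1.5), c(-4, -0.5))) {
    h1 <- call_hits(pl$z, pair[1])
    h2 <- call_hits(pl$z, pair[2])
    expect_true(all(paste(h1$mimic_id, h1$cell_line) %in%
                      paste(h2$mimic_id, h2$cell_line)))
  }
  expect_error(call_hits(z, threshold = 1),
               class = "mimicscreen_config_error")
})

test_that("hit calling is deterministic and recovers planted cells exactly", {
  pl <- default_screen_pipeline()
  expect_identical(call_hits(pl$z), call_hits(pl$z))
  # planted-truth oracle at the exact threshold of the z matrix itself
  k <- sum(unclass(pl$z) <= -2 &
             rownames(pl$z) != negative_control_id())
  expect_equal(nrow(pl$hits), k)
})

test_that("responsiveness summary matches the planted architecture", {
  # direct construction: 1 mimic hitting 1 line
  h1 <- structure(data.frame(mimic_id = "m1", cell_line = "L1", z = -3),
                  n_lines = 4L, class = c("hit_table", "data.frame"))
  rs1 <- responsiveness_summary(h1)
  expect_equal(unname(rs1$histogram), c(1, 0, 0, 0))
  expect_equal(rs1$fraction_private, 1.0)
  expect_equal(rs1$max_lines, 1L)

  # empty table: zero histogram, undefined fraction signaled
  h0 <- structure(data.frame(mimic_id = character(0),
                             cell_line = character(0), z = numeric(0)),
                  n_lines = 4L, class = c("hit_table", "data.frame"))
  expect_warning(rs0 <- responsiveness_summary(h0),
                 class = "mimicscreen_undefined_warning")
  expect_true(all(rs0$histogram == 0))
  expect_true(is.na(rs0$fraction_private))

  # planted design: 60 private-of-1, 26 private-of-2, 22 spread 3..9
  counts <- c(rep(1, 60), rep(2, 26), rep(3, 5), rep(4, 4), rep(5, 3),
              rep(6, 3), rep(7, 3), rep(8, 2), rep(9, 2))
  rows <- do.call(rbind, lapply(seq_along(counts), function(i)
    data.frame(mimic_id = sprintf("m%03d", i),
               cell_line = sprintf("L%02d", seq_len(counts[i])),
               z = -3)))
  hp <- structure(rows, n_lines = 16L,
                  class = c("hit_table", "data.frame"))
  rsp <- responsiveness_summary(hp)
  expect_equal(sum(rsp$histogram), 108L)
  expect_equal(rsp$fraction_private, 86 / 108)
  expect_equal(rsp$max_lines, 9L)
})

test_that("unique mature sequence collapse honors the duplication map", {
  ann <- mimic_annotations(data.frame(
    mimic_id = c("m1", "m2", "m3"),
    mature_sequence = c("UGAGGUAGUAGGUUGUAUAGUU",
                        "UGAGGUAGUAGGUUGUAUAGUU",
                        "CCCGGUAGUAGGUUGUAUAGUU")))
  mk_hits <- function(ids) structure(
    data.frame(mimic_id = ids, cell_line = "L1", z = -3),
    n_lines = 1L, class = c("hit_table", "data.frame"))
  expect_equal(collapse_unique_mature(mk_hits(c("m1", "m2")), ann), 1L)
  expect_equal(collapse_unique_mature(mk_hits(c("m1", "m3")), ann), 2L)
  err <- tryCatch(collapse_unique_mature(mk_hits(c("m1", "zz")), ann),
                  error = identity)
  expect_s3_class(err, "mimicscreen_annotation_error")
  expect_match(conditionMessage(err), "zz")

  # synthetic library with a known duplication map
  pl <- default_screen_pipeline()
  got <- collapse_unique_mature(pl$hits, pl$sim$annotations)
  oracle <- length(unique(pl$sim$annotations$mature_sequence[
    match(unique(pl$hits$mimic_id), pl$sim$annotations$mimic_id)]))
  expect_equal(got, oracle)
  expect_lt(got, length(unique(pl$hits$mimic_id)))  # duplicates collapse
})

test_that("variance decomposition orders family below panel variation", {
  pl <- default_screen_pipeline()
  vp <- variance_profile(pl$agg$mean, pl$agg$sd, pl$sim$annotations)
  expect_true(all(vp$across_panel$sd >= 0))
  expect_true(all(vp$family$sd >= 0))
  # planted intra-family correlation 0.8 compresses family spread
  expect_lt(median(vp$family$sd), median(vp$across_panel$sd))
  # each KDE integrates to ~1 on its grid (trapezoidal rule)
  for (el in vp[c("across_panel", "family", "within_replicate")]) {
    dx <- diff(el$kde$grid)
    y <- el$kde$density
    integral <- sum(dx * (y[-1] + y[-length(y)]) / 2)
    expect_equal(integral, 1, tolerance = 1e-3)
  }
})

test_that("degenerate variance inputs are handled explicitly", {
  ann <- mimic_annotations(data.frame(
    mimic_id = c("m1", "m2"),
    mature_sequence = c("UGAGGUAGUAGGUUGUAUAGUU",
                        "UGAGGUAGUAGGUUGUAUAGUU")))
  # identical phenotypes: all across-panel SDs zero, KDE mass at zero
  m <- matrix(1, 2, 3, dimnames = list(c("m1", "m2"), c("a", "b", "c")))
  vp <- variance_profile(m, m * 0, ann)
  expect_true(all(vp$across_panel$sd == 0))
  expect_true(all(vp$family$sd == 0))   # two-member family, same profile
  expect_lt(max(abs(vp$across_panel$kde$grid)), 1e-6)
  # all-singleton families signal an empty family distribution
  ann2 <- mimic_annotations(data.frame(
    mimic_id = c("m1", "m2"),
    mature_sequence = c("UGAGGUAGUAGGUUGUAUAGUU",
                        "CCCGGUAGUAGGUUGUAUAGUU")))
  expect_warning(vp2 <- variance_profile(m, m * 0, ann2),
                 class = "mimicscreen_undefined_warning")
  expect_length(vp2$family$sd, 0L)
})
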