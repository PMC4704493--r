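# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; no stored data.

# A hand-constructed 8 x 12 plate with known per-row gain factors.
make_gain_plate <- function(gains = NULL, base = 100) {
  rows <- LETTERS[1:8]
  if (is.null(gains)) gains <- seq(0.5, 2.25, length.out = 8)
  names(gains) <- rows
  wells <- expand.grid(column = 1:12, row = rows,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # deterministic "biology": well value depends only on its column
  wells$mimic_id <- sprintf("m%02d", wells$column)
  wells$value <- base * (1 + wells$column / 20) * gains[wells$row]
  screen_plate("P1", "lineA", 1L, wells)
}

# Small well table covering several plates/replicates.
make_well_table <- function(n_rows = 2L, n_cols = 4L, n_reps = 2L,
                            lines = c("L1", "L2")) {
  out <- do.call(rbind, lapply(lines, function(ln) {
    do.call(rbind, lapply(seq_len(n_reps), function(r) {
      g <- expand.grid(row = LETTERS[seq_len(n_rows)],
                       column = seq_len(n_cols),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      g$plate_id <- paste0(ln, "_p1")
      g$cell_line <- ln
      g$replicate <- r
      g$mimic_id <- ifelse(g$column == n_cols, negative_control_id(),
                           sprintf("m%s%d", g$row, g$column))
      g$raw_lum <- 100 + 10 * g$column + seq_len(nrow(g)) + 3 * r
      g
    }))
  }))
  out[c("plate_id", "cell_line", "replicate", "row", "column",
        "mimic_id", "raw_lum")]
}

# The default synthetic screen, simulated once per test run.
default_sim <- local({
  cache <- NULL
  function(seed = 42) {
    if (is.null(cache)) {
      cache <<- simulate_screen(screen_sim_config(), seed = seed)
    }
    cache
  }
})

default_screen_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- default_sim()
      plates <- lapply(sim$plates, normalize_row_median)
      agg <- aggregate_replicates(plates)
      z <- compute_zscores(agg$mean)
      cache <<- list(sim = sim, agg = agg, z = z, hits = call_hits(z))
    }
    cache
  }
})

# --- independent oracles -------------------------------------------------

# Exhaustive search over exemplar subsets maximizing net similarity.
brute_force_ap <- function(S) {
  n <- nrow(S)
  best <- NULL
  best_val <- -Inf
  for (mask in 1:(2^n - 1)) {
    ex <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    val <- sum(diag(S)[ex])
    for (i in setdiff(seq_len(n), ex)) val <- val + max(S[i, ex])
    if (val > best_val) {
      best_val <- val
      best <- ex
    }
  }
  partition <- vapply(seq_len(n), function(i) {
    if (i %in% best) i else best[which.max(S[i, best])]
  }, integer(1L))
  list(value = best_val, exemplars = best, partition = partition)
}

# Straight loop transcription of the message update equations.
transcribe_messages <- function(S, R, A) {
  n <- nrow(S)
  Rn <- R
  An <- A
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      Rn[i, k] <- S[i, k] - max((A[i, ] + S[i, ])[-k])
    }
  }
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      if (i == k) {
        An[k, k] <- sum(pmax(0, Rn[-k, k]))
      } else {
        An[i, k] <- min(0, Rn[k, k] +
                          sum(pmax(0, Rn[setdiff(seq_len(n), c(i, k)), k])))
      }
    }
  }
  list(R = Rn, A = An)
}

# Exact hypergeometric upper tail by explicit combinatorial summation.
enumerate_hyper_tail <- function(N, K, n, k) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Hand-tabulated two-group log-rank chi-square via per-event-time
# 2x2 observed/expected/variance tables.
tabulate_logrank <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  O1 <- E1 <- V <- 0
  for (tt in times) {
    n1 <- sum(t1 >= tt)
    n2 <- sum(t2 >= tt)
    d1 <- sum(t1 == tt & e1 == 1)
    d2 <- sum(t2 == tt & e2 == 1)
    nn <- n1 + n2
    dd <- d1 + d2
    O1 <- O1 + d1
    E1 <- E1 + dd * n1 / nn
    if (nn > 1) V <- V + dd * (n1 / nn) * (n2 / nn) * (nn - dd) / (nn - 1)
  }
  (O1 - E1)^2 / V
}

# Hand product-limit tabulation.
tabulate_km <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(times))
  for (i in seq_along(times)) {
    at_risk <- sum(time >= times[i])
    d <- sum(time == times[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = times, surv = surv)
}

recovery_rates <- function(z, hits, truth_sensitive) {
  called <- matrix(FALSE, nrow(z), ncol(z), dimnames = dimnames(z))
  if (nrow(hits) > 0) {
    called[cbind(match(hits$mimic_id, rownames(z)),
                 match(hits$cell_line, colnames(z)))] <- TRUE
  }
  truth <- truth_sensitive[rownames(z), colnames(z)]
  list(sensitivity = sum(called & truth) / sum(truth),
       specificity = sum(!called & !truth) / sum(!truth))
}
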