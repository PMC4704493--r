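# Affinity propagation clustering, implemented from the
# responsibility/availability message-passing update rules and iterated
# hierarchically over exemplars.
#
# Updates (all messages initialized to zero; s(i,k) the input similarity,
# diagonal = preference):
#   r(i,k) <- s(i,k) - max_{k' != k} { a(i,k') + s(i,k') }
#   a(i,k) <- min{ 0, r(k,k) + sum_{i' not in {i,k}} max(0, r(i',k)) }   (i != k)
#   a(k,k) <- sum_{i' != k} max(0, r(i',k))
# damped as  msg <- damping * old + (1 - damping) * new.
# Exemplars are the points with r(k,k) + a(k,k) > 0.

#' Build a pairwise similarity matrix
#'
#' @param x Numeric item-by-feature matrix with row names (the items).
#' @param metric \code{"neg_euclidean"} (negative Euclidean distance,
#'   default) or \code{"pearson"} (correlation between item feature
#'   vectors, used directly as the similarity).
#' @param preference Diagonal self-similarity controlling how many
#'   exemplars emerge: \code{"median"} (median of the off-diagonal
#'   similarities, the standard data-driven choice), \code{"quantile"}
#'   (the \code{preference_q} quantile of the off-diagonal similarities)
#'   or an explicit number.
#' @param preference_q Quantile in (0, 1) used when
#'   \code{preference = "quantile"}.
#' @param pairwise_complete For \code{metric = "pearson"} only: tolerate
#'   missing features via pairwise-complete correlations.
#' @return A square matrix of class \code{"similarity_matrix"} with
#'   attributes \code{metric} and \code{preference}; its diagonal is
#'   uniformly the preference.
#' @export
build_similarity <- function(x, metric = c("neg_euclidean", "pearson"),
                             preference = "median", preference_q = NULL,
                             pairwise_complete = FALSE) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (nrow(x) < 2L) ms_config_error("need at least 2 items to cluster")
  if (is.null(rownames(x))) rownames(x) <- paste0("item", seq_len(nrow(x)))
  if (anyNA(x) && !(metric == "pearson" && isTRUE(pairwise_complete))) {
    ms_validation_error(
      "missing features; use pearson with pairwise_complete = TRUE")
  }
  if (metric == "neg_euclidean") {
    s <- -as.matrix(stats::dist(x, method = "euclidean"))
  } else {
    sds <- apply(x, 1L, stats::sd, na.rm = TRUE)
    if (any(!is.finite(sds) | sds == 0)) {
      bad <- rownames(x)[!is.finite(sds) | sds == 0]
      ms_degenerate_error(sprintf(
        "constant feature vector(s): correlation undefined for %s",
        paste(utils::head(bad, 5L), collapse = ", ")), items = bad)
    }
    use <- if (isTRUE(pairwise_complete)) "pairwise.complete.obs" else
      "everything"
    s <- stats::cor(t(x), use = use)
  }
  dimnames(s) <- list(rownames(x), rownames(x))
  off <- s[row(s) != col(s)]
  pref <- if (identical(preference, "median")) {
    stats::median(off)
  } else if (identical(preference, "quantile")) {
    if (!is_scalar_number(preference_q) || preference_q <= 0 ||
        preference_q >= 1) {
      ms_config_error("preference_q must be in (0, 1)")
    }
    as.numeric(stats::quantile(off, preference_q))
  } else if (is_scalar_number(preference)) {
    preference
  } else {
    ms_config_error("preference must be 'median', 'quantile' or a number")
  }
  diag(s) <- pref
  structure(s, metric = metric, preference = pref,
            class = c("similarity_matrix", class(s)))
}

# One exact (undamped) message-passing sweep; exported for verification of
# the update rules against independent transcriptions. Returns new R, A.
ap_message_sweep <- function(S, R, A) {
  n <- nrow(S)
  AS <- A + S
  i1 <- max.col(AS, ties.method = "first")
  m1 <- AS[cbind(seq_len(n), i1)]
  AS2 <- AS
  AS2[cbind(seq_len(n), i1)] <- -Inf
  m2 <- AS2[cbind(seq_len(n), max.col(AS2, ties.method = "first"))]
  Rnew <- S - m1
  Rnew[cbind(seq_len(n), i1)] <- S[cbind(seq_len(n), i1)] - m2
  Rpos <- pmax(Rnew, 0)
  diag(Rpos) <- 0                        # sums run over i' != k
  cs <- colSums(Rpos)
  Anew <- pmin(matrix(diag(Rnew) + cs, n, n, byrow = TRUE) - Rpos, 0)
  diag(Anew) <- cs
  list(R = Rnew, A = Anew)
}

#' Affinity propagation clustering
#'
#' Iterates the responsibility/availability message updates with damping
#' until the exemplar set is stable, then assigns every item to its most
#' similar exemplar (exemplars to themselves). All tie-breaks are
#' deterministic lowest-index rules, so repeated runs are identical.
#'
#' @param S A \code{\link{build_similarity}} matrix (square; finite
#'   off-diagonal entries; diagonal = preference).
#' @param damping Message damping factor in [0, 1); the update keeps
#'   \code{damping} of the old message (default 0.9).
#' @param max_iter Maximum message-passing iterations (default 1000).
#' @param convergence_window Number of consecutive iterations the
#'   exemplar set must stay unchanged to declare convergence (default
#'   50).
#' @return An object of class \code{"cluster_result"}: \code{exemplars}
#'   (character vector), \code{assignment} (named character vector, item
#'   to exemplar), \code{n_iterations}, \code{converged}.
#' @details If the messages reach a numerical fixed point with no point
#'   accumulating positive exemplar evidence (possible for exactly
#'   duplicated items under the median preference), the configuration is
#'   treated as a single cluster exemplified by the lowest-index item.
#'   If \code{max_iter} is reached with no exemplar and no fixed point, a
#'   convergence error carrying the last message state is raised.
#' @export
ap_cluster <- function(S, damping = 0.9, max_iter = 1000L,
                       convergence_window = 50L) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    ms_validation_error("S must be a square matrix")
  }
  if (!is_scalar_number(damping) || damping < 0 || damping >= 1) {
    ms_config_error("damping must be in [0, 1)")
  }
  n <- nrow(S)
  items <- rownames(S) %||% paste0("item", seq_len(n))
  S <- unclass(S)
  dimnames(S) <- list(items, items)
  if (n == 1L) {
    return(structure(list(
      exemplars = items, assignment = setNames(items, items),
      n_iterations = 0L, converged = TRUE), class = "cluster_result"))
  }
  if (any(!is.finite(S[row(S) != col(S)]))) {
    ms_validation_error("off-diagonal similarities must be finite")
  }
  # Exactly symmetric similarity configurations put exemplar evidence on a
  # knife edge (message dynamics preserve the symmetry and the evidence
  # stays pinned at zero). Break such degeneracies with a tiny
  # deterministic perturbation -- a fixed internal stream, so identical
  # inputs still give bit-identical results, and it is invariant under
  # translation of the similarities (depends only on n and the range).
  spread <- diff(range(S))
  if (spread > 0) {
    jitter <- with_seed(20150406L, matrix(runif(n * n) - 0.5, n, n))
    S <- S + jitter * 1e-9 * spread
  }
  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  stable_count <- 0L
  prev_ex <- integer(0)
  fixed_point <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    new <- ap_message_sweep(S, R, A)
    Rn <- damping * R + (1 - damping) * new$R
    An <- damping * A + (1 - damping) * new$A
    delta <- max(abs(Rn - R), abs(An - A))
    R <- Rn; A <- An
    ex <- which(diag(R) + diag(A) > 0)
    if (length(ex) > 0L && identical(ex, prev_ex)) {
      stable_count <- stable_count + 1L
    } else {
      stable_count <- 0L
    }
    prev_ex <- ex
    if (length(ex) > 0L && stable_count >= convergence_window) break
    if (delta < 1e-12) { fixed_point <- TRUE; break }
  }
  ex <- which(diag(R) + diag(A) > 0)
  converged <- (length(ex) > 0L && stable_count >= convergence_window) ||
    fixed_point
  if (length(ex) == 0L) {
    if (fixed_point) {
      # degenerate symmetric configuration: single cluster, lowest index
      ex <- 1L
    } else {
      ms_convergence_error(
        sprintf("no exemplar emerged after %d iterations", it),
        responsibility = R, availability = A, n_iterations = it)
    }
  }
  # final clean assignment pass: similarity argmax over the exemplar set,
  # lowest-index tie-break; exemplars are assigned to themselves
  Sx <- S[, ex, drop = FALSE]
  best <- max.col(Sx, ties.method = "first")
  assignment <- items[ex[best]]
  assignment[ex] <- items[ex]
  names(assignment) <- items
  structure(list(
    exemplars = items[ex], assignment = assignment,
    n_iterations = it, converged = converged),
    class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d items, %d exemplar(s): %s\n",
              length(x$assignment), length(x$exemplars),
              paste(utils::head(x$exemplars, 8L), collapse = ", ")))
  cat(sprintf("  iterations: %d | converged: %s\n", x$n_iterations,
              x$converged))
  invisible(x)
}

#' Net similarity of a clustering configuration
#'
#' The objective affinity propagation approximately maximizes: the sum of
#' each non-exemplar item's similarity to its exemplar plus the
#' preference for each exemplar.
#'
#' @param S The similarity matrix used for clustering.
#' @param result A \code{\link{ap_cluster}} result (or any list with
#'   \code{exemplars} and \code{assignment} in the same format).
#' @return The net similarity (a number).
#' @export
net_similarity <- function(S, result) {
  items <- rownames(S) %||% paste0("item", seq_len(nrow(S)))
  assignment <- result$assignment
  if (!all(assignment %in% result$exemplars)) {
    ms_integrity_error("assignment maps to a non-exemplar item")
  }
  if (!all(result$exemplars %in% items) ||
      !setequal(names(assignment), items)) {
    ms_integrity_error("result does not match the similarity matrix items")
  }
  if (!all(assignment[result$exemplars] == result$exemplars)) {
    ms_integrity_error("an exemplar is not assigned to itself")
  }
  idx_i <- match(names(assignment), items)
  idx_k <- match(assignment, items)
  sum(S[cbind(idx_i, idx_k)])   # diagonal entries are the preference
}

#' Hierarchical affinity propagation
#'
#' Runs \code{\link{ap_cluster}} on all items, then re-clusters the
#' resulting exemplars (using their original feature vectors), repeating
#' until a single cluster remains or no further merging occurs. Full-item
#' memberships at each level are obtained by composing the per-level
#' assignments.
#'
#' @param x Numeric item-by-feature matrix with row names.
#' @param metric,preference,preference_q Passed to
#'   \code{\link{build_similarity}} at every level.
#' @param damping,max_iter,convergence_window Passed to
#'   \code{\link{ap_cluster}}.
#' @return An object of class \code{"cluster_hierarchy"}: \code{levels}
#'   (list of per-level \code{cluster_result}s over that level's items)
#'   and \code{membership} (items x levels character matrix of composed
#'   exemplar labels).
#' @export
hierarchical_ap <- function(x, metric = c("neg_euclidean", "pearson"),
                            preference = "median", preference_q = NULL,
                            damping = 0.9, max_iter = 1000L,
                            convergence_window = 50L) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (nrow(x) < 2L) ms_config_error("need at least 2 items to cluster")
  if (is.null(rownames(x))) rownames(x) <- paste0("item", seq_len(nrow(x)))
  items <- rownames(x)
  levels <- list()
  membership <- NULL
  current <- items   # items clustered at the current level
  compose <- setNames(items, items)  # item -> current-level representative
  level <- 0L
  repeat {
    level <- level + 1L
    S <- build_similarity(x[current, , drop = FALSE], metric = metric,
                          preference = preference,
                          preference_q = preference_q)
    res <- tryCatch(
      ap_cluster(S, damping = damping, max_iter = max_iter,
                 convergence_window = convergence_window),
      mimicscreen_convergence_error = function(e) {
        ms_convergence_error(sprintf("level %d: %s", level,
                                     conditionMessage(e)), level = level)
      })
    exemplars <- res$exemplars
    if (level > 1L && length(exemplars) >= length(current)) {
      break   # no further merging: previous level is the top
    }
    levels[[level]] <- res
    compose <- setNames(res$assignment[compose], names(compose))
    membership <- cbind(membership, compose)
    if (length(exemplars) <= 1L) break
    current <- exemplars
  }
  colnames(membership) <- paste0("level", seq_len(ncol(membership)))
  structure(list(levels = levels, membership = membership,
                 metric = metric),
            class = "cluster_hierarchy")
}

#' @export
print.cluster_hierarchy <- function(x, ...) {
  counts <- vapply(x$levels, function(l) length(l$exemplars), integer(1L))
  cat(sprintf("<cluster_hierarchy> %d items | %d level(s) | clusters: %s\n",
              nrow(x$membership), length(x$levels),
              paste(counts, collapse = " -> ")))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    ms_validation_error("partitions must have equal length")
  }
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
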