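# Shape-based K = 2 clustering of SCG beats: dynamic time warping (DTW)
# dissimilarity with medoid updates. DTW absorbs the nonlinear stretching
# of beats caused by heart-rate variability (e.g. respiratory sinus
# arrhythmia), which would corrupt a Euclidean comparison of beats of
# unequal length.

#' Dynamic time warping distance
#'
#' Dynamic-programming alignment cost between two sequences of possibly
#' unequal length: local cost `|x_i - y_j|`, symmetric unit-weight steps
#' (diagonal, up, right), boundary-to-boundary path; the distance is the
#' sum of local costs along the optimal path. Runs in `Theta(l^2)` time in
#' compiled code.
#'
#' @param x,y nonempty numeric vectors.
#' @param window optional Sakoe-Chiba band half-width in samples on the
#'   slope-corrected index difference; `NULL` (default) imposes no global
#'   constraint.
#' @return nonnegative alignment cost; 0 iff a perfect warping alignment
#'   exists (in particular `dtw_distance(x, x) == 0`).
#' @examples
#' dtw_distance(c(0, 1, 0), c(0, 1, 1, 0))  # 0: the plateau is absorbed
#' dtw_distance(c(0, 0, 0), c(1, 1, 1))     # 3: diagonal path, unit costs
#' @export
dtw_distance <- function(x, y, window = NULL) {
  if (!length(x) || !length(y)) stopf("DTW inputs must be nonempty")
  w <- if (is.null(window)) -1L else as.integer(window)
  .dtw_cost_cpp(as.numeric(x), as.numeric(y), w)
}

#' Pairwise DTW distance matrix
#'
#' @param waveforms list of nonempty numeric vectors.
#' @inheritParams dtw_distance
#' @return symmetric matrix of DTW distances with zero diagonal.
#' @export
dtw_pairwise <- function(waveforms, window = NULL) {
  if (!length(waveforms) || any(lengths(waveforms) == 0)) {
    stopf("`waveforms` must be a nonempty list of nonempty vectors")
  }
  w <- if (is.null(window)) -1L else as.integer(window)
  .dtw_pairwise_cpp(lapply(waveforms, as.numeric), w)
}

# One full k-medoid run on a precomputed distance matrix: alternate
# nearest-medoid assignment (ties to the lower cluster index; a medoid
# stays in its own cluster, which only matters under exact ties) and the
# argmin-of-summed-distance medoid update, until labels stop changing.
kmedoid_sweep <- function(D, medoids, K, max_iter) {
  n <- nrow(D)
  labels <- rep(NA_integer_, n)
  objective_trace <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    new_labels <- apply(D[, medoids, drop = FALSE], 1, which.min)
    new_labels[medoids] <- seq_len(K)
    for (j in seq_len(K)) {
      if (!any(new_labels == j)) {
        # re-seed an emptied cluster with the beat farthest from the others
        others <- medoids[-j]
        far <- which.max(apply(D[, others, drop = FALSE], 1, min))
        message(sprintf("cluster %d emptied; re-seeded with beat %d", j, far))
        medoids[j] <- far
        new_labels[far] <- j
      }
    }
    changed <- !identical(new_labels, labels)
    labels <- new_labels
    for (j in seq_len(K)) {
      members <- which(labels == j)
      sums <- rowSums(D[members, members, drop = FALSE])
      medoids[j] <- members[which.min(sums)]
    }
    objective_trace <- c(objective_trace,
                         sum(D[cbind(seq_len(n), medoids[labels])]))
    if (!changed) { converged <- TRUE; break }
    if (iterations >= max_iter) break
  }
  list(labels = labels, medoids = medoids, iterations = iterations,
       converged = converged, objective_trace = objective_trace)
}

#' K-medoid clustering of SCG beats under DTW
#'
#' Alternates (a) assignment of every beat to its nearest medoid by DTW
#' and (b) a medoid update that sets each cluster's medoid to the member
#' minimizing the summed DTW distance to all members, until no assignment
#' changes (a label fixpoint) or `max_iter` sweeps. Both steps can only
#' decrease the objective (summed within-cluster distance to the medoid),
#' so the objective trace is non-increasing. Assignment ties go to the
#' lower cluster index.
#'
#' Distances are computed on the normalized beats (shape, not amplitude).
#' The full pairwise matrix is computed once up front, so the iterations
#' are cheap.
#'
#' With `K = 2`, clusters are relabelled after convergence so that cluster
#' 1 is the one with the higher mean heart rate; in respiration-clustered
#' SCG data the faster cluster is the one riding the inspiratory rise of
#' the RSA cycle, and pinning the convention makes labels comparable
#' across runs and subjects.
#'
#' @param bs a normalized `beat_set` (see [normalize_beats()]).
#' @param K number of clusters (default 2).
#' @param max_iter iteration cap (default 50).
#' @param seed integer seed for the random initialization.
#' @param init `"random"` (seeded choice of K distinct beats) or
#'   `"farthest"` (deterministic: the two beats at maximal DTW distance,
#'   then successive farthest beats for K > 2).
#' @param n_restarts number of random restarts (default 3); the run with
#'   the lowest final objective wins. Random initialization of k-medoids
#'   can land in a poor local optimum, and restarts are the standard
#'   remedy. Ignored for `init = "farthest"`, which is deterministic.
#' @param window optional Sakoe-Chiba half-width passed to the DTW kernel.
#' @return a `cluster_result`: `labels` (1..K per beat), `medoid_index`
#'   (per cluster), `C1`/`C2` (medoid waveforms, normalized and raw, for
#'   K = 2), `n1`/`n2`, `iterations`, `converged`, `objective_trace`,
#'   `distance_matrix`, `seed`.
#' @export
k_medoids_dtw <- function(bs, K = 2, max_iter = 50, seed = 1L,
                          init = c("random", "farthest"), n_restarts = 3,
                          window = NULL) {
  stopifnot(inherits(bs, "beat_set"))
  init <- match.arg(init)
  if (!isTRUE(bs$normalized)) {
    stopf("beats must be normalized before clustering (see normalize_beats)")
  }
  n <- length(bs$beats)
  if (K > n) stopf("K = %d exceeds the number of beats (%d)", K, n)
  D <- dtw_pairwise(beat_waveforms(bs), window = window)

  starts <- if (init == "farthest") {
    m <- as.integer(arrayInd(which.max(D), dim(D))[1, ])
    while (length(m) < K) {
      rest <- setdiff(seq_len(n), m)
      m <- c(m, rest[which.max(apply(D[rest, m, drop = FALSE], 1, min))])
    }
    list(m[seq_len(K)])
  } else {
    with_local_seed(seed, lapply(seq_len(max(1, n_restarts)),
                                 function(r) sample.int(n, K)))
  }

  best <- NULL
  for (medoids in starts) {
    run <- kmedoid_sweep(D, medoids, K, max_iter)
    if (is.null(best) ||
        utils::tail(run$objective_trace, 1) <
          utils::tail(best$objective_trace, 1)) {
      best <- run
    }
  }
  labels <- best$labels
  medoids <- best$medoids
  iterations <- best$iterations
  converged <- best$converged
  objective_trace <- best$objective_trace
  if (K == 2) {
    hr <- 60 / beat_rr(bs)
    if (mean(hr[labels == 2]) > mean(hr[labels == 1])) {
      labels <- 3L - labels
      medoids <- rev(medoids)
    }
  }

  wf_n <- beat_waveforms(bs)
  wf_r <- beat_waveforms(bs, raw = TRUE)
  structure(list(
    labels = as.integer(labels),
    medoid_index = medoids,
    C1 = if (K >= 1) list(normalized = wf_n[[medoids[1]]],
                          raw = wf_r[[medoids[1]]]),
    C2 = if (K >= 2) list(normalized = wf_n[[medoids[2]]],
                          raw = wf_r[[medoids[2]]]),
    n1 = sum(labels == 1L), n2 = sum(labels == 2L),
    iterations = iterations, converged = converged,
    objective_trace = objective_trace,
    distance_matrix = D, seed = as.integer(seed)
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> n1=%d n2=%d, medoids (%s), %d iteration(s)%s\n",
    x$n1, x$n2, paste(x$medoid_index, collapse = ", "), x$iterations,
    if (x$converged) ", converged" else " (max_iter reached)"))
  invisible(x)
}

#' Cross-tabulate clusters against respiratory phase
#'
#' Builds the 2 x 4 contingency of cluster label by respiratory phase and
#' scores the association as the fraction of beats consistent with the
#' expected regime mapping - cluster 1 occupying the high-lung-volume arc
#' (`HLV-INS`, `HLV-EXP`) - maximized over the label permutation (cluster
#' identities are arbitrary up to relabelling).
#'
#' @param cr a `cluster_result` (K = 2).
#' @param gt_phases per-beat respiratory phase factor/character, aligned
#'   with the clustered beats.
#' @return list with `table` (2 x 4 counts) and `association` in [0, 1]
#'   (0.5 is chance for balanced clusters).
#' @export
cross_tabulate_phase <- function(cr, gt_phases) {
  stopifnot(inherits(cr, "cluster_result"))
  if (length(gt_phases) != length(cr$labels)) {
    stopf("phase labels (%d) and cluster labels (%d) differ in length",
          length(gt_phases), length(cr$labels))
  }
  ph <- factor(as.character(gt_phases), levels = resp_phase_levels())
  tab <- table(cluster = factor(cr$labels, levels = 1:2), phase = ph)
  hlv <- ph %in% c("HLV-INS", "HLV-EXP")
  match1 <- mean((cr$labels == 1L) == hlv)
  list(table = tab, association = max(match1, 1 - match1))
}

#' Serialize a clustering result
#'
#' Writes labels, medoid indices, iteration count and seed as JSON, and
#' the medoid waveforms as CSV (`<prefix>_medoids.csv`).
#'
#' @param cr a `cluster_result`.
#' @param path_prefix output path prefix.
#' @export
write_cluster_result <- function(cr, path_prefix) {
  stopifnot(inherits(cr, "cluster_result"))
  jsonlite::write_json(
    list(labels = cr$labels, medoid_index = cr$medoid_index,
         n1 = cr$n1, n2 = cr$n2, iterations = cr$iterations,
         converged = cr$converged, seed = cr$seed),
    paste0(path_prefix, ".json"), auto_unbox = TRUE, digits = NA)
  m1 <- cr$C1$raw
  m2 <- cr$C2$raw
  len <- max(length(m1), length(m2))
  pad <- function(v) c(v, rep(NA_real_, len - length(v)))
  write.csv(data.frame(C1 = pad(m1), C2 = pad(m2)),
            paste0(path_prefix, "_medoids.csv"), row.names = FALSE)
  invisible(path_prefix)
}
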