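#' Pool participant time series into a feature matrix
#'
#' Concatenates parcel-level BOLD matrices (parcels x volumes) column-wise in
#' participant order, producing the `n_parcels x sum(T_i)` feature matrix on
#' which co-activation-pattern clustering operates, plus an index mapping each
#' pooled column back to (participant, time).
#'
#' @param series Named list of numeric matrices, one per participant, each
#'   `n_parcels x T_i` with identical row count. Unnamed lists are indexed
#'   by position.
#' @return List with `features` (matrix) and `index` (`data.frame` with
#'   columns `participant`, `time`, `column`).
#' @export
build_feature_matrix <- function(series) {
  stop_if(!is.list(series) || length(series) == 0L,
          "`series` must be a non-empty list of matrices")
  p <- nrow(series[[1]])
  ok <- vapply(series, function(m) is.matrix(m) && nrow(m) == p, logical(1))
  stop_if(!all(ok), "all series must be matrices over the same parcellation")
  tt <- vapply(series, ncol, integer(1))
  stop_if(any(tt < 1L), "each participant needs at least one volume")
  ids <- names(series)
  if (is.null(ids)) ids <- as.character(seq_along(series))
  features <- do.call(cbind, series)
  index <- data.frame(participant = rep(ids, tt),
                      time = sequence(tt),
                      column = seq_len(sum(tt)),
                      stringsAsFactors = FALSE)
  list(features = features, index = index)
}

#' Correlation distance between two vectors
#'
#' `1 - r(x, y)` with `r` the sample Pearson correlation; ranges over
#' `[0, 2]`. Constant (zero-variance) vectors are rejected.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return The correlation distance.
#' @export
corr_distance <- function(x, y) {
  stop_if(length(x) != length(y) || length(x) < 2L,
          "`x` and `y` must have equal length >= 2")
  stop_if(stats::sd(x) == 0 || stats::sd(y) == 0,
          "correlation distance undefined for zero-variance vectors")
  1 - stats::cor(x, y)
}

# Standardize columns to zero mean and unit Euclidean norm, so that
# ||x - y||^2 / 2 = 1 - r(x, y) for any two columns.
standardize_cols <- function(x) {
  x <- sweep(x, 2, colMeans(x), `-`)
  nrm <- sqrt(colSums(x^2))
  bad <- which(nrm == 0)
  stop_if(length(bad) > 0,
          "zero-variance volume(s) at column(s) ",
          paste(utils::head(bad, 5), collapse = ", "),
          "; remove flat volumes before clustering")
  sweep(x, 2, nrm, `/`)
}

#' K-means clustering under correlation distance
#'
#' Lloyd's algorithm with the distance `1 - r(x, y)`, implemented through the
#' identity `1 - r(x, y) = ||x - y||^2 / 2` for vectors standardized to zero
#' mean and unit norm: all volumes are standardized once, cluster means are
#' re-standardized after every update, and assignment maximizes the inner
#' product with the (unit-norm) centroids. The best of `n_restarts`
#' uniformly-seeded runs by total within-cluster distance (inertia) is
#' returned. Ties in assignment go to the lowest state index; an emptied
#' cluster is re-seeded from the volume farthest (in correlation distance)
#' from its current centroid.
#'
#' @param points Numeric matrix `n_parcels x n_volumes`; columns are the
#'   observations (pooled BOLD volumes).
#' @param k Number of states (default 5).
#' @param n_restarts Random restarts (default 20).
#' @param max_iter Maximum Lloyd iterations per restart (default 300).
#' @param tol Convergence tolerance on the inertia decrease (default 1e-6).
#' @param seed Integer seed for the restarts; `NULL` uses the current stream.
#' @return Object of class `brain_state_model`: `k`, `centroids`
#'   (`k x n_parcels`, standardized rows), `assignments` (integer per
#'   column), `inertia`, `iterations`, `converged`, `n_restarts`, `seed`.
#' @export
kmeans_corr <- function(points, k = 5, n_restarts = 20, max_iter = 300,
                        tol = 1e-6, seed = NULL) {
  stop_if(!is.matrix(points) || nrow(points) < 2L, "`points` must be a matrix")
  stop_if(!is_count(k), "`k` must be a positive integer")
  n <- ncol(points)
  stop_if(k > n, "`k` exceeds the number of volumes")
  xs <- standardize_cols(points)

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      fit <- kmeans_corr_once(xs, k, max_iter, tol)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  centroids <- t(best$centroids)
  rownames(centroids) <- paste0("state_", seq_len(k))
  structure(list(k = as.integer(k), centroids = centroids,
                 assignments = best$assign, inertia = best$inertia,
                 iterations = best$iter, converged = best$converged,
                 n_restarts = n_restarts, seed = seed),
            class = "brain_state_model")
}

# One Lloyd run on pre-standardized columns `xs` (parcels x n).
kmeans_corr_once <- function(xs, k, max_iter, tol) {
  n <- ncol(xs)
  cent <- xs[, sample.int(n, k), drop = FALSE]
  inertia <- Inf
  assign <- integer(n)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    sim <- crossprod(cent, xs)                   # k x n inner products
    new_assign <- max.col(t(sim), ties.method = "first")
    sim_assigned <- sim[cbind(new_assign, seq_len(n))]
    # re-seed empty clusters from the worst-fitting volume
    empty <- setdiff(seq_len(k), unique(new_assign))
    for (j in empty) {
      far <- which.min(sim_assigned)
      cent[, j] <- xs[, far]
      new_assign[far] <- j
      sim_assigned[far] <- 1
    }
    new_inertia <- sum(1 - sim_assigned)
    moved <- !identical(new_assign, assign)
    assign <- new_assign
    if ((!moved || abs(inertia - new_inertia) < tol) && iter > 1L) {
      inertia <- new_inertia
      converged <- TRUE
      break
    }
    inertia <- new_inertia
    if (iter >= max_iter) break
    for (j in seq_len(k)) {
      m <- rowMeans(xs[, assign == j, drop = FALSE])
      m <- m - mean(m)
      nrm <- sqrt(sum(m^2))
      cent[, j] <- if (nrm > 0) m / nrm else xs[, which.min(sim_assigned)]
    }
  }
  list(centroids = cent, assign = assign, inertia = inertia, iter = iter,
       converged = converged)
}

#' @export
print.brain_state_model <- function(x, ...) {
  cat(sprintf("Brain-state model: k = %d, %d volumes, inertia %.4f (%s, %d iter)\n",
              x$k, length(x$assignments), x$inertia,
              if (x$converged) "converged" else "not converged", x$iterations))
  cat("  volumes per state:", tabulate(x$assignments, x$k), "\n")
  invisible(x)
}

#' Estimate brain states from a set of participant time series
#'
#' Convenience wrapper: builds the pooled feature matrix, clusters it with
#' [kmeans_corr()], and attaches the participant index to the model so
#' occupancies can be computed directly.
#'
#' @inheritParams build_feature_matrix
#' @inheritParams kmeans_corr
#' @return A `brain_state_model` with an `index` element.
#' @export
estimate_brain_states <- function(series, k = 5, n_restarts = 20,
                                  max_iter = 300, tol = 1e-6, seed = NULL) {
  fm <- build_feature_matrix(series)
  model <- kmeans_corr(fm$features, k = k, n_restarts = n_restarts,
                       max_iter = max_iter, tol = tol, seed = seed)
  model$index <- fm$index
  model
}

#' Per-participant fractional occupancies
#'
#' `FO[i, s]` is the proportion of participant `i`'s retained volumes
#' assigned to state `s`; each row sums to 1.
#'
#' @param assignments Integer state label per pooled volume (or a
#'   `brain_state_model`, in which case its stored index is used).
#' @param index Participant index from [build_feature_matrix()].
#' @param k Number of states.
#' @return Numeric matrix `n_participants x k` (rows named by participant,
#'   columns `fo_1..fo_k`), participants in order of first appearance.
#' @export
fractional_occupancy <- function(assignments, index = NULL, k = NULL) {
  if (inherits(assignments, "brain_state_model")) {
    model <- assignments
    stop_if(is.null(model$index), "model carries no participant index")
    index <- if (is.null(index)) model$index else index
    k <- if (is.null(k)) model$k else k
    assignments <- model$assignments
  }
  stop_if(is.null(index) || is.null(k), "`index` and `k` are required")
  stop_if(length(assignments) != nrow(index),
          "one assignment per pooled volume required")
  stop_if(any(assignments < 1 | assignments > k), "labels outside 1..k")
  ids <- unique(index$participant)
  fo <- t(vapply(ids, function(id) {
    lab <- assignments[index$participant == id]
    stop_if(length(lab) == 0L, "participant with zero volumes: ", id)
    tabulate(lab, nbins = k) / length(lab)
  }, numeric(k)))
  dimnames(fo) <- list(ids, paste0("fo_", seq_len(k)))
  fo
}

#' Identify the high-occupancy states
#'
#' Ranks states by their cohort *mean* fractional occupancy (medians are also
#' reported), selects the top two, and computes each participant's
#' high-occupancy summary `fo_high`: by default the arithmetic mean of the two
#' top-state occupancies (an option to use the sum is provided). Exact ties in
#' the ranking are broken by the lower state index.
#'
#' @param fo Occupancy matrix from [fractional_occupancy()].
#' @param method `"mean"` (default) or `"sum"` for the per-participant
#'   high-occupancy summary.
#' @return List of class `high_occupancy`: `ranking` (states by descending
#'   mean FO), `top` (the two selected states, ascending), `mean_fo`,
#'   `median_fo`, `fo_high` (named numeric per participant), `method`.
#' @export
select_high_occupancy <- function(fo, method = c("mean", "sum")) {
  method <- match.arg(method)
  stop_if(!is.matrix(fo) || ncol(fo) < 2L, "`fo` must be a matrix with k >= 2")
  mean_fo <- colMeans(fo)
  ranking <- order(-mean_fo, seq_len(ncol(fo)))
  top <- sort(ranking[1:2])
  fo_high <- if (method == "mean") rowMeans(fo[, top, drop = FALSE])
             else rowSums(fo[, top, drop = FALSE])
  structure(list(ranking = ranking, top = top, mean_fo = mean_fo,
                 median_fo = apply(fo, 2, stats::median), fo_high = fo_high,
                 method = method),
            class = "high_occupancy")
}

#' @export
print.high_occupancy <- function(x, ...) {
  cat("High-occupancy state selection (", x$method, " of top two)\n", sep = "")
  cat("  ranking by mean FO:", x$ranking, "\n")
  cat(sprintf("  top states: {%s}; cohort mean fo_high %.4f\n",
              paste(x$top, collapse = ", "), mean(x$fo_high)))
  invisible(x)
}

#' Network activation profile of the state centroids
#'
#' For each state, the cosine similarity between the positive part (and,
#' separately, the negative part) of its centroid and the binary
#' parcel-membership indicator of each large-scale network. All-zero parts
#' yield similarity 0.
#'
#' @param model A `brain_state_model` (or a plain `k x n_parcels` centroid
#'   matrix).
#' @param network_labels Character vector assigning each parcel to a network.
#' @return `data.frame` with columns `state`, `network`, `sim_pos`,
#'   `sim_neg`; similarities lie in `[0, 1]`.
#' @export
network_profile <- function(model, network_labels) {
  cent <- if (inherits(model, "brain_state_model")) model$centroids else model
  stop_if(!is.matrix(cent), "`model` must be a brain_state_model or matrix")
  stop_if(length(network_labels) != ncol(cent),
          "one network label per parcel required")
  nets <- unique(network_labels)
  cos_sim <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
  }
  out <- expand.grid(state = seq_len(nrow(cent)), network = nets,
                     stringsAsFactors = FALSE)
  out$sim_pos <- NA_real_
  out$sim_neg <- NA_real_
  for (r in seq_len(nrow(out))) {
    c_s <- cent[out$state[r], ]
    ind <- as.numeric(network_labels == out$network[r])
    out$sim_pos[r] <- cos_sim(pmax(c_s, 0), ind)
    out$sim_neg[r] <- cos_sim(pmax(-c_s, 0), ind)
  }
  out
}
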