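# Lloyd's k-means with careful (k-means++-style) seeding.
#
# Written out rather than delegated so that the estimator matches the
# segmentation procedure exactly: squared-Euclidean assignment with
# lowest-index tie-breaking, convergence on centroid movement < tol,
# empty clusters re-seeded at the point currently farthest from its
# centroid, and a recorded inertia trace.

.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k)[-1L]) {
    i <- if (all(d2 <= 0)) sample.int(n, 1L) else sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

.lloyd <- function(x, centers, max_iter = 300L, tol = 1e-6) {
  k <- nrow(centers)
  n <- nrow(x)
  trace <- numeric(0)
  iter <- 0L
  for (it in seq_len(max_iter)) {
    iter <- it
    d2 <- .pairwise_sqdist(x, centers)
    labels <- max.col(-d2, ties.method = "first")
    own <- d2[cbind(seq_len(n), labels)]
    trace <- c(trace, sum(own))
    counts <- tabulate(labels, k)
    new_centers <- centers
    filled <- sort(unique(labels))
    sums <- rowsum(x, labels) # rows in sorted label order
    new_centers[filled, ] <- sums / counts[filled]
    for (j in which(counts == 0L)) {
      # standard remedy: hand the empty cluster the worst-served point
      far <- which.max(own)
      new_centers[j, ] <- x[far, ]
      own[far] <- 0
    }
    movement <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (movement < tol) break
  }
  d2 <- .pairwise_sqdist(x, centers)
  labels <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(n), labels)])
  list(centers = centers, labels = labels, inertia = inertia,
       iterations = iter, inertia_trace = c(trace, inertia))
}

# Best-of-n_init restarts by final inertia. RNG use is confined to the caller's
# .with_seed() block so a fixed seed reproduces the fit bit for bit.
.kmeans_restarts <- function(x, k, n_init, max_iter = 300L, tol = 1e-6) {
  best <- NULL
  for (r in seq_len(n_init)) {
    fit <- .lloyd(x, .kmeanspp_init(x, k), max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  best
}
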