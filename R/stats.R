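# Group-level inference on representation maps: paired t-tests and
# cluster-based permutation tests over time-time maps, with the null
# built by per-participant condition sign flips (full enumeration for
# small groups) and family-wise control via the maximum cluster mass.

#' Paired t-test
#'
#' Standard paired t over participants, df = n - 1, two-sided p.
#'
#' @param a,b Numeric vectors of equal length >= 2, one value per
#'   participant per condition.
#' @return List with `t`, `df`, `p`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    stop_validation("need equal-length vectors with >= 2 participants")
  }
  if (anyNA(a) || anyNA(b)) stop_validation("missing values not allowed")
  d <- a - b
  if (stats::sd(d) == 0) stop_degenerate("zero-variance differences")
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

# Label 4-connected components of a logical matrix; returns an integer
# matrix (0 = background) via union-find with path compression.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  parent <- seq_along(idx)
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(idx)) {
    cell <- idx[k]
    r <- (cell - 1L) %% nr + 1L
    c <- (cell - 1L) %/% nr + 1L
    if (r > 1L && mask[cell - 1L]) {
      a <- find(k); b <- find(pos[cell - 1L])
      if (a != b) parent[a] <- b
    }
    if (c > 1L && mask[cell - nr]) {
      a <- find(k); b <- find(pos[cell - nr])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  lab[idx] <- match(roots, unique(roots))
  lab
}

# Pointwise paired t statistics over participants for a n x p matrix of
# per-participant differences.
t_map <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  s <- sqrt((colSums(D^2) - n * m^2) / (n - 1))
  s[s == 0] <- NA
  m / (s / sqrt(n))
}

# Max |cluster mass| over positive and negative exceedance clusters.
max_cluster_mass <- function(tv, nr, nc, tcrit) {
  tm <- matrix(tv, nr, nc)
  best <- 0
  for (sgn in c(1, -1)) {
    mask <- !is.na(tm) & sgn * tm > tcrit
    if (!any(mask)) next
    lab <- label_components(mask)
    sums <- tapply(tm[mask], lab[lab > 0], sum)
    best <- max(best, abs(sums))
  }
  best
}

#' Cluster-based permutation test for paired map comparison
#'
#' Pointwise paired t statistics over participants are thresholded at
#' two-sided pointwise `p_point`; suprathreshold points are grouped into
#' 4-connected clusters separately for positive and negative exceedances
#' and each cluster's mass is the sum of its t-values. The null
#' distribution of the maximum absolute cluster mass is built by
#' randomly sign-flipping each participant's condition difference
#' (full enumeration of the 2^n flips when n <= 12, Monte Carlo
#' otherwise); cluster p-values use +1 smoothing.
#'
#' @param mapsA,mapsB Arrays participants x rows x cols (matched
#'   conditions), or lists of equal-dimension matrices.
#' @param n_perm Permutations when sampling (default 1000).
#' @param p_point Pointwise two-sided threshold (default 0.05).
#' @param seed RNG seed.
#' @return A `wm_clusters` with the cluster label matrix, per-cluster
#'   mass and p-value, the observed t-map and the thresholds used.
#' @export
cluster_permutation_paired <- function(mapsA, mapsB, n_perm = 1000,
                                       p_point = 0.05, seed = 1L) {
  if (is.list(mapsA)) mapsA <- simplify2array_first(mapsA)
  if (is.list(mapsB)) mapsB <- simplify2array_first(mapsB)
  if (!all(dim(mapsA) == dim(mapsB))) {
    stop_validation("map arrays must have identical dimensions")
  }
  n <- dim(mapsA)[1]
  if (n < 2) stop_validation("need >= 2 participants")
  nr <- dim(mapsA)[2]; nc <- dim(mapsA)[3]
  D <- matrix(aperm(mapsA - mapsB, c(1, 2, 3)), n, nr * nc)
  tcrit <- stats::qt(1 - p_point / 2, df = n - 1)
  tv <- t_map(D)
  tm <- matrix(tv, nr, nc)
  labels <- matrix(0L, nr, nc)
  masses <- numeric(0)
  next_id <- 0L
  for (sgn in c(1, -1)) {
    mask <- !is.na(tm) & sgn * tm > tcrit
    if (!any(mask)) next
    lab <- label_components(mask)
    for (cl in seq_len(max(lab))) {
      next_id <- next_id + 1L
      labels[lab == cl] <- next_id
      masses[next_id] <- sum(tm[lab == cl])
    }
  }
  # sign-flip null of the maximum cluster mass
  if (n <= 12) {
    flips <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    n_used <- nrow(flips)
  } else {
    flips <- with_seed(seed, {
      matrix(sample(c(1, -1), n_perm * n, replace = TRUE), n_perm, n)
    })
    n_used <- n_perm
  }
  null_max <- vapply(seq_len(n_used), function(i) {
    max_cluster_mass(t_map(flips[i, ] * D), nr, nc, tcrit)
  }, numeric(1))
  p <- vapply(masses, function(m) {
    (sum(null_max >= abs(m)) + 1) / (n_used + 1)
  }, numeric(1))
  structure(list(labels = labels, masses = masses, p = p, t_map = tm,
                 t_crit = tcrit, n_perm = n_used, p_point = p_point,
                 null_max = null_max),
            class = "wm_clusters")
}

simplify2array_first <- function(lst) {
  aperm(simplify2array(lst), c(3, 1, 2))
}

#' @export
print.wm_clusters <- function(x, ...) {
  if (!length(x$masses)) {
    cat("<wm_clusters> no suprathreshold clusters\n")
  } else {
    cat(sprintf("<wm_clusters> %d cluster(s):\n", length(x$masses)))
    for (i in seq_along(x$masses)) {
      cat(sprintf("  #%d mass %.2f, p = %.4g\n", i, x$masses[i], x$p[i]))
    }
  }
  invisible(x)
}
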