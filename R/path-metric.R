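## Song path length: shortest open Hamiltonian path over syllable-cluster
## centroids. Exhaustive enumeration (with reversal symmetry) for k <= 8,
## Held-Karp dynamic programming for 9 <= k <= 15.

#' Pairwise distance between two 2-D points
#'
#' @param a,b finite numeric 2-vectors.
#' @param metric one of \code{"euclidean"}, \code{"cosine"},
#'   \code{"manhattan"}, \code{"chebyshev"}. Cosine distance is
#'   \code{1 - cosine similarity} and requires both points to be nonzero.
#' @return a nonnegative length.
#' @examples
#' pairwiseDistance(c(0, 0), c(3, 4), "euclidean")  # 5
#' @export
pairwiseDistance <- function(a, b,
                             metric = c("euclidean", "cosine", "manhattan",
                                        "chebyshev")) {
  metric <- match.arg(metric)
  stopifnot(length(a) == 2L, length(b) == 2L, all(is.finite(c(a, b))))
  switch(metric,
    euclidean = sqrt(sum((a - b)^2)),
    manhattan = sum(abs(a - b)),
    chebyshev = max(abs(a - b)),
    cosine = {
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na == 0 || nb == 0)
        stop("cosine distance is undefined for a zero vector")
      1 - sum(a * b) / (na * nb)
    })
}

centroidDistMatrix <- function(cs, metric) {
  pts <- centroidCoords(cs)
  k <- nrow(pts)
  d <- matrix(0, k, k)
  for (i in seq_len(k))
    for (j in seq_len(k))
      if (i < j)
        d[i, j] <- d[j, i] <- pairwiseDistance(pts[i, ], pts[j, ], metric)
  d
}

#' Path length of one cluster ordering
#'
#' Sums centroid-to-centroid distances along a given ordering of all
#' clusters: \eqn{\sum_{i=1}^{k-1} d(c_{o_i}, c_{o_{i+1}})}. For a single
#' cluster the sum is empty and the length is 0.
#'
#' @param cs a [CentroidSet-class].
#' @param order integer permutation of the 0-based cluster ids
#'   \code{0:(k-1)}.
#' @inheritParams pairwiseDistance
#' @return the path length.
#' @export
pathLengthForOrder <- function(cs, order, metric = "euclidean") {
  stopifnot(is(cs, "CentroidSet"))
  k <- nrow(centroidCoords(cs))
  order <- as.integer(order)
  if (!setequal(order, seq_len(k) - 1L) || length(order) != k)
    stop("order must be a permutation of 0:(k-1) with no repeats")
  if (k == 1L) return(0)
  d <- centroidDistMatrix(cs, match.arg(metric, c("euclidean", "cosine",
                                                  "manhattan", "chebyshev")))
  idx <- order + 1L
  sum(d[cbind(idx[-k], idx[-1L])])
}

# All permutations of 1..k as a k! x k integer matrix, in lexicographic order.
allPermutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(k - 1L)
  out <- matrix(0L, k * nrow(sub), k)
  row <- 1L
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(first,
      matrix(rest[sub], nrow(sub), k - 1L))
    row <- row + nrow(sub)
  }
  out
}

#' Minimum path length over all cluster orderings
#'
#' Computes the song path length: the minimum, over all orderings of the k
#' cluster centroids, of the summed consecutive distances (the shortest open
#' Hamiltonian path; for k clusters there are k! orderings, k!/2 distinct
#' paths by reversal symmetry). Orderings are enumerated exhaustively for
#' k <= 8; for 9 <= k <= 15 a Held-Karp dynamic program over subsets is
#' used, which returns the identical minimum. Ties are broken by the
#' lexicographically smallest optimal ordering (considering both traversal
#' directions). k > 15 is rejected: the exact subset dynamic program needs
#' 2^k * k memory, so reduce the cluster count first.
#'
#' @param cs a [CentroidSet-class] with 1 <= k <= 15 clusters.
#' @inheritParams pairwiseDistance
#' @param all_orders keep the full per-order length table (k <= 8 only;
#'   default TRUE for k <= 8). The table lists each of the k!/2
#'   reversal-deduplicated orderings (the representative with the smaller
#'   first-vs-last cluster id) and its length.
#' @return a [PathLengthResult-class].
#' @examples
#' cs <- new("CentroidSet",
#'   centroids = rbind(c(0, 0), c(1, 0), c(2, 0)),
#'   cluster_sizes = c(1L, 1L, 1L), aggregation = "arithmetic")
#' pathLength(minPathLength(cs))  # 2: end-to-end traversal
#' @export
minPathLength <- function(cs, metric = c("euclidean", "cosine", "manhattan",
                                         "chebyshev"),
                          all_orders = NULL) {
  stopifnot(is(cs, "CentroidSet"))
  metric <- match.arg(metric)
  k <- nrow(centroidCoords(cs))
  if (k > 15L)
    stop("exact minimum-path computation is limited to k <= 15 clusters ",
         "(2^k subset dynamic program); got k = ", k,
         ". Reduce the number of clusters (e.g. larger min_cluster_size).")
  if (is.null(all_orders)) all_orders <- k <= 8L
  empty <- data.frame(order = character(), length = numeric())
  if (k == 1L)
    return(new("PathLengthResult", k = 1L, metric = metric, min_path = 0,
               argmin_order = 0L, per_order_lengths = empty,
               n_orders_considered = 1))
  d <- centroidDistMatrix(cs, metric)
  n_orders <- factorial(k) / 2
  if (k <= 8L) {
    perms <- allPermutations(k)
    perms <- perms[perms[, 1L] < perms[, k], , drop = FALSE]  # reversal dedup
    lens <- numeric(nrow(perms))
    for (s in seq_len(k - 1L))
      lens <- lens + d[cbind(perms[, s], perms[, s + 1L])]
    best <- min(lens)
    tol <- 1e-9 * (1 + abs(best))
    cand <- perms[lens <= best + tol, , drop = FALSE]
    cand <- rbind(cand, cand[, k:1, drop = FALSE])  # both directions
    ord <- cand[do.call(order, as.data.frame(cand))[1L], ] - 1L
    tab <- if (all_orders)
      data.frame(order = apply(perms - 1L, 1L, paste, collapse = "-"),
                 length = lens)
    else empty
    return(new("PathLengthResult", k = as.integer(k), metric = metric,
               min_path = best, argmin_order = as.integer(ord),
               per_order_lengths = tab, n_orders_considered = n_orders))
  }
  hk <- heldKarpMinPath(d)
  new("PathLengthResult", k = as.integer(k), metric = metric,
      min_path = hk$min, argmin_order = as.integer(hk$order - 1L),
      per_order_lengths = empty, n_orders_considered = n_orders)
}

# Held-Karp for the shortest open Hamiltonian path.
# C[mask, j] = minimal cost of a path that starts at j and visits exactly the
# vertices in mask (j included). Reconstruction greedily picks the smallest
# feasible vertex at each step, yielding the lexicographically smallest
# optimal order.
heldKarpMinPath <- function(d) {
  k <- nrow(d)
  full <- bitwShiftL(1L, k) - 1L
  C <- matrix(Inf, full, k)
  bit <- bitwShiftL(1L, seq_len(k) - 1L)
  for (j in seq_len(k)) C[bit[j], j] <- 0
  for (mask in seq_len(full)) {
    members <- which(bitwAnd(mask, bit) != 0L)
    if (length(members) < 2L) next
    for (j in members) {
      rest <- mask - bit[j]
      ls <- members[members != j]
      C[mask, j] <- min(d[j, ls] + C[rest, ls])
    }
  }
  best <- min(C[full, ])
  tol <- 1e-9 * (1 + abs(best))
  # forward greedy reconstruction, smallest vertex first on ties
  order <- integer(k)
  mask <- full
  j <- which(C[full, ] <= best + tol)[1L]
  order[1L] <- j
  for (step in 2:k) {
    rest <- mask - bit[j]
    members <- which(bitwAnd(rest, bit) != 0L)
    feas <- members[d[j, members] + C[rest, members] <= C[mask, j] + tol]
    nxt <- feas[1L]
    order[step] <- nxt
    mask <- rest
    j <- nxt
  }
  list(min = best, order = order)
}

#' Contrast between two path lengths
#'
#' Signed difference \code{long - short} of the minimal path lengths of two
#' results computed under the same metric; used to characterize stimulus
#' pairs by how far apart their song complexities are.
#'
#' @param long,short [PathLengthResult-class] objects with matching metrics.
#' @return the signed difference of min-path values.
#' @export
pathContrast <- function(long, short) {
  stopifnot(is(long, "PathLengthResult"), is(short, "PathLengthResult"))
  if (long@metric != short@metric)
    stop("cannot contrast path lengths computed under different metrics (",
         long@metric, " vs ", short@metric, ")")
  pathLength(long) - pathLength(short)
}
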