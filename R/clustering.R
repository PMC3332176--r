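# K-means and fuzzy C-means on per-pixel feature vectors. Both are written
# out from their defining update equations because the segmentation contract
# requires fully deterministic behavior: farthest-point seeding, lowest-index
# tie-breaks, and a fixed empty-cluster re-seeding rule.

as_pointset <- function(points) {
  X <- if (is.matrix(points)) points else matrix(as.numeric(points), ncol = 1L)
  if (!all(is.finite(X))) stop("points must be finite", call. = FALSE)
  if (nrow(X) == 0L) stop("empty point set", call. = FALSE)
  X
}

# squared Euclidean distances, N x C
dist2_to_centers <- function(X, centers) {
  cc <- rowSums(centers^2)
  d2 <- outer(rowSums(X^2), cc, "+") - 2 * X %*% t(centers)
  d2[d2 < 0] <- 0
  d2
}

# deterministic farthest-point seeding: start at the point nearest the
# global mean, then repeatedly add the point maximizing the distance to the
# nearest chosen centroid (lowest index on ties)
farthest_point_seeds <- function(X, K) {
  gm <- matrix(colMeans(X), 1L)
  chosen <- which.min(dist2_to_centers(X, gm)[, 1L])
  mind2 <- dist2_to_centers(X, X[chosen, , drop = FALSE])[, 1L]
  while (length(chosen) < K) {
    nxt <- which.max(mind2)
    chosen <- c(chosen, nxt)
    mind2 <- pmin(mind2, dist2_to_centers(X, X[nxt, , drop = FALSE])[, 1L])
  }
  X[chosen, , drop = FALSE]
}

#' K-means clustering
#'
#' Lloyd iterations: each point is assigned to the nearest centroid by
#' squared Euclidean distance (lowest cluster index on ties) and centroids
#' are recomputed as the means of their assigned points, until no centroid
#' moves by more than `tol` or `max_iter` is reached. With no
#' `init_centroids` the seeding is deterministic farthest-point (see
#' Details), so repeated runs are identical; `n_restart > 1` adds seeded
#' random restarts and returns the lowest within-cluster sum of squares.
#'
#' An emptied cluster is re-seeded at the point currently farthest from its
#' assigned centroid, keeping all `K` clusters alive deterministically.
#'
#' @param points Numeric matrix `N x d`, or a vector (treated as `d = 1`).
#' @param K Number of clusters, `1 <= K <= N`.
#' @param init_centroids Optional `K x d` matrix of starting centroids.
#' @param seed Integer seed used only when `n_restart > 1`.
#' @param tol Convergence threshold on the largest centroid displacement.
#' @param max_iter Iteration cap.
#' @param n_restart Number of additional random restarts.
#' @return Object of class `kmeans_result`: list with `centroids` (`K x d`),
#'   `assignment` (length `N`, values in `1..K`), `withinss` (total
#'   within-cluster sum of squares) and `iterations`.
#' @export
kmeans_cluster <- function(points, K, init_centroids = NULL, seed = 0L,
                           tol = 1e-8, max_iter = 100L, n_restart = 1L) {
  X <- as_pointset(points)
  N <- nrow(X)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (K > N) stop("K = ", K, " exceeds the number of points N = ", N,
                  call. = FALSE)
  run_once <- function(cent) {
    it <- 0L
    assign <- rep(1L, N)
    repeat {
      it <- it + 1L
      d2 <- dist2_to_centers(X, cent)
      assign <- max.col(-d2, ties.method = "first")
      newcent <- cent
      for (kk in seq_len(K)) {
        idx <- assign == kk
        if (any(idx)) {
          newcent[kk, ] <- colMeans(X[idx, , drop = FALSE])
        } else {
          far <- which.max(d2[cbind(seq_len(N), assign)])
          newcent[kk, ] <- X[far, ]
          assign[far] <- kk
        }
      }
      moved <- max(sqrt(rowSums((newcent - cent)^2)))
      cent <- newcent
      if (moved <= tol || it >= max_iter) break
    }
    d2 <- dist2_to_centers(X, cent)
    assign <- max.col(-d2, ties.method = "first")
    list(centroids = cent, assignment = assign,
         withinss = sum(d2[cbind(seq_len(N), assign)]), iterations = it)
  }
  if (!is.null(init_centroids)) {
    cent0 <- matrix(as.numeric(init_centroids), nrow = K)
    best <- run_once(cent0)
  } else {
    best <- run_once(farthest_point_seeds(X, K))
    if (n_restart > 1L) {
      rs <- local({
        old <- globalenv()$.Random.seed
        on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                          envir = globalenv()))
        set.seed(seed)
        lapply(seq_len(n_restart - 1L), function(i)
          X[sample.int(N, K), , drop = FALSE])
      })
      for (cent0 in rs) {
        cand <- run_once(cent0)
        if (cand$withinss < best$withinss) best <- cand
      }
    }
  }
  structure(best, class = "kmeans_result")
}

#' Fuzzy C-means membership update
#'
#' Each membership is the inverse-distance-ratio weight
#' `1 / sum_m (||x_i - c_j|| / ||x_i - c_m||)^(2/(k-1))`, so every column
#' (point) sums to one. A point coinciding with one or more centers takes
#' the limiting memberships: uniform over the coinciding centers, zero
#' elsewhere.
#'
#' @param points `N x d` matrix or vector.
#' @param centers `C x d` matrix or vector.
#' @param k Fuzziness exponent, `> 1`.
#' @return `C x N` membership matrix with unit column sums.
#' @export
fcm_membership <- function(points, centers, k = 2) {
  X <- as_pointset(points)
  cen <- if (is.matrix(centers)) centers else matrix(centers, ncol = ncol(X))
  stopifnot(k > 1)
  d2 <- dist2_to_centers(X, cen)            # N x C
  zero <- d2 == 0
  hit <- rowSums(zero) > 0
  w <- d2^(-1 / (k - 1))
  u <- w / rowSums(w)
  if (any(hit)) {
    u[hit, ] <- zero[hit, , drop = FALSE] /
      rowSums(zero[hit, , drop = FALSE])
  }
  t(u)
}

#' Fuzzy C-means center update
#'
#' Each center is the mean of all points weighted by the `k`-th power of
#' its memberships. A cluster whose memberships are identically zero is
#' re-seeded at the point farthest from the current global weighted mean.
#'
#' @param points `N x d` matrix or vector.
#' @param memberships `C x N` matrix.
#' @param k Fuzziness exponent.
#' @return `C x d` matrix of centers.
#' @export
fcm_centers <- function(points, memberships, k = 2) {
  X <- as_pointset(points)
  u <- as.matrix(memberships)
  uk <- u^k
  wsum <- rowSums(uk)
  cen <- (uk %*% X) / wsum
  dead <- wsum == 0
  if (any(dead)) {
    gm <- matrix(colMeans(X), 1L)
    far <- which.max(dist2_to_centers(X, gm)[, 1L])
    cen[dead, ] <- matrix(X[far, ], sum(dead), ncol(X), byrow = TRUE)
  }
  cen
}

#' Fuzzy C-means objective
#'
#' The membership-weighted sum of squared distances
#' `E = sum_j sum_i u_ij^k ||x_i - c_j||^2`.
#'
#' @inheritParams fcm_centers
#' @param centers `C x d` matrix.
#' @return Nonnegative scalar.
#' @export
fcm_objective <- function(points, memberships, centers, k = 2) {
  X <- as_pointset(points)
  cen <- if (is.matrix(centers)) centers else matrix(centers, ncol = ncol(X))
  u <- as.matrix(memberships)
  sum(t(u^k) * dist2_to_centers(X, cen))
}

#' Fuzzy C-means clustering
#'
#' Alternates the membership and center updates until the objective changes
#' by at most `tol` or `max_iter` is reached. With no `init_centers`, the
#' starting centers are equidistant over the data's per-dimension range
#' (`c_j = min + j * range / C`), which makes the whole run deterministic.
#'
#' @param points `N x d` matrix or vector.
#' @param C Number of clusters (`>= 1`; `C = 1` degenerates to the global
#'   mean).
#' @param k Fuzziness exponent, `> 1`; larger is softer.
#' @param init_centers Optional `C x d` starting centers.
#' @param tol Convergence threshold on `|delta E|`.
#' @param max_iter Iteration cap.
#' @return Object of class `fcm_state`: list with `memberships` (`C x N`),
#'   `centers` (`C x d`), `k`, `objective`, `objective_trace` (one value per
#'   iteration), and `iterations`.
#' @export
fcm_cluster <- function(points, C, k = 2, init_centers = NULL,
                        tol = 1e-5, max_iter = 300L) {
  X <- as_pointset(points)
  C <- as.integer(C)
  stopifnot(C >= 1L, k > 1)
  if (C > nrow(X)) stop("C = ", C, " exceeds the number of points", call. = FALSE)
  if (is.null(init_centers)) {
    lo <- apply(X, 2L, min)
    hi <- apply(X, 2L, max)
    cen <- t(vapply(seq_len(C), function(j) lo + j * (hi - lo) / C,
                    numeric(ncol(X))))
    cen <- matrix(cen, nrow = C)
  } else {
    cen <- matrix(as.numeric(init_centers), nrow = C)
  }
  E_prev <- Inf
  trace <- numeric(0)
  it <- 0L
  repeat {
    it <- it + 1L
    u <- fcm_membership(X, cen, k)
    cen <- fcm_centers(X, u, k)
    E <- fcm_objective(X, u, cen, k)
    trace <- c(trace, E)
    if (is.finite(E_prev) && abs(E_prev - E) <= tol) break
    if (it >= max_iter) break
    E_prev <- E
  }
  structure(list(memberships = u, centers = cen, k = k, objective = E,
                 objective_trace = trace, iterations = it),
            class = "fcm_state")
}

#' @export
print.fcm_state <- function(x, ...) {
  cat("<fcm_state> C = ", nrow(x$centers), ", k = ", x$k, ", ",
      x$iterations, " iteration(s), E = ", format(x$objective), "\n",
      sep = "")
  invisible(x)
}

#' Hard labels from a membership matrix
#'
#' @param memberships `C x N` matrix.
#' @return Integer vector of length `N` (argmax membership, lowest index on
#'   ties).
#' @export
hard_labels <- function(memberships) {
  max.col(t(as.matrix(memberships)), ties.method = "first")
}
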