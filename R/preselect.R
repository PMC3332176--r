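# Automatic cluster-count preselection for FCM: a Mamdani fuzzy inference
# system maps the intensity range D = Vmax - Vmin of a fused grayscale
# image and the image size (pixel count) to a number of clusters, which is
# then seeded with equidistant centers and refined by ordinary FCM.

#' Gaussian fuzzy set
#'
#' @param label Set name.
#' @param center Location of unit membership.
#' @param spread Gaussian spread (sigma), `> 0`.
#' @return Object of class `fuzzy_set`.
#' @export
fuzzy_set <- function(label, center, spread) {
  stopifnot(is.character(label), length(label) == 1L, spread > 0)
  structure(list(label = label, center = as.numeric(center),
                 spread = as.numeric(spread)), class = "fuzzy_set")
}

#' Gaussian membership value
#'
#' `exp(-(x - center)^2 / (2 * spread^2))`: one at the center, strictly
#' positive everywhere.
#'
#' @param x Numeric (vectorized).
#' @param set A [fuzzy_set()].
#' @return Membership in `(0, 1]`.
#' @export
gauss_membership <- function(x, set) {
  exp(-(x - set$center)^2 / (2 * set$spread^2))
}

make_sets <- function(labels, centers, spreads) {
  stats::setNames(
    mapply(fuzzy_set, labels, centers, spreads, SIMPLIFY = FALSE),
    labels)
}

# linguistic variables: six Distance sets on the 0-255 intensity-range
# universe, five Size sets on the pixel-count universe (up to ~1200^2),
# five Cluster sets on the cluster-count universe
default_distance_sets <- function() {
  make_sets(c("minimum", "shorter", "short", "regular", "large", "maximum"),
            c(15, 53, 105, 150, 222, 255),
            c(16, 24, 30, 30, 45, 15))
}

default_size_sets <- function() {
  make_sets(c("min", "small", "medium", "big", "max"),
            c(9000, 3.015e5, 6.53e5, 9.728e5, 1.44e6),
            c(1.789e5, 1.626e5, 1.968e5, 2.236e5, 2.862e5))
}

default_cluster_sets <- function() {
  make_sets(c("very_few", "few", "some", "many", "too_many"),
            c(2, 7, 16, 23, 33),
            c(3, 3, 5, 5, 7))
}

#' Fuzzy rule base for cluster-count preselection
#'
#' Assembles the three linguistic variables (Distance, Size, Cluster) and
#' the 30 rules — one per (distance, size) antecedent pair. The default
#' rules follow a monotone grid: the consequent rank is
#' `clamp(floor((i + j) / 2), 1, 5)` for distance rank `i` and size rank
#' `j`, so small range and small image map to "very few" clusters and
#' maximal range and size to "too many".
#'
#' @param distance_sets,size_sets,cluster_sets Named lists of
#'   [fuzzy_set()]s; defaults are the built-in tables.
#' @param rules Data frame with character columns `distance`, `size`,
#'   `cluster`; default the monotone grid.
#' @return Object of class `fuzzy_rulebase`.
#' @export
default_rulebase <- function(distance_sets = default_distance_sets(),
                             size_sets = default_size_sets(),
                             cluster_sets = default_cluster_sets(),
                             rules = NULL) {
  if (is.null(rules)) {
    grid <- expand.grid(i = seq_along(distance_sets),
                        j = seq_along(size_sets))
    rank <- pmin(pmax(floor((grid$i + grid$j) / 2), 1L),
                 length(cluster_sets))
    rules <- data.frame(distance = names(distance_sets)[grid$i],
                        size = names(size_sets)[grid$j],
                        cluster = names(cluster_sets)[rank],
                        stringsAsFactors = FALSE)
  }
  rb <- structure(list(distance_sets = distance_sets, size_sets = size_sets,
                       cluster_sets = cluster_sets, rules = rules),
                  class = "fuzzy_rulebase")
  validate_rulebase(rb)
}

validate_rulebase <- function(rb) {
  r <- rb$rules
  stopifnot(all(c("distance", "size", "cluster") %in% names(r)))
  if (nrow(r) != length(rb$distance_sets) * length(rb$size_sets))
    stop("rule base must contain exactly one rule per antecedent pair (",
         length(rb$distance_sets) * length(rb$size_sets), " rules), got ",
         nrow(r), call. = FALSE)
  if (anyDuplicated(r[c("distance", "size")]))
    stop("duplicate antecedent pair in rule base", call. = FALSE)
  bad <- setdiff(unique(r$distance), names(rb$distance_sets))
  bad <- c(bad, setdiff(unique(r$size), names(rb$size_sets)))
  bad <- c(bad, setdiff(unique(r$cluster), names(rb$cluster_sets)))
  if (length(bad))
    stop("rule labels not defined as fuzzy sets: ",
         paste(bad, collapse = ", "), call. = FALSE)
  rb
}

#' @export
print.fuzzy_rulebase <- function(x, ...) {
  cat("<fuzzy_rulebase> ", length(x$distance_sets), " distance x ",
      length(x$size_sets), " size sets, ", nrow(x$rules), " rules, ",
      length(x$cluster_sets), " cluster sets\n", sep = "")
  invisible(x)
}

#' Read fuzzy sets from a plain-text file
#'
#' One set per line, `label, center, spread`; blank lines and `#` comments
#' ignored.
#'
#' @param path File path.
#' @return Named list of [fuzzy_set()]s in file order.
#' @export
read_fuzzy_sets <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sets <- lapply(lines, function(ln) {
    parts <- trimws(strsplit(ln, ",")[[1L]])
    if (length(parts) != 3L)
      stop("fuzzy-set line must be 'label, center, spread': '", ln, "'",
           call. = FALSE)
    fuzzy_set(parts[1L], as.numeric(parts[2L]), as.numeric(parts[3L]))
  })
  stats::setNames(sets, vapply(sets, `[[`, character(1L), "label"))
}

#' Read fuzzy rules from a plain-text file
#'
#' One rule per line, `distance_label, size_label -> cluster_label`;
#' blank lines and `#` comments ignored.
#'
#' @param path File path.
#' @return Data frame with columns `distance`, `size`, `cluster`, usable as
#'   the `rules` argument of [default_rulebase()].
#' @export
read_rules <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(lines, function(ln) {
    halves <- trimws(strsplit(ln, "->", fixed = TRUE)[[1L]])
    if (length(halves) != 2L)
      stop("rule line must be 'distance, size -> cluster': '", ln, "'",
           call. = FALSE)
    ante <- trimws(strsplit(halves[1L], ",")[[1L]])
    if (length(ante) != 2L)
      stop("rule antecedent must be 'distance, size': '", ln, "'",
           call. = FALSE)
    data.frame(distance = ante[1L], size = ante[2L], cluster = halves[2L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise color-channel distances
#'
#' Sums of squared per-pixel differences between the R/B, R/G and G/B
#' channels (no square root; comparisons between these values order the
#' pairs exactly as true Euclidean distances would).
#'
#' @param image `H x W x 3` array, channel order R, G, B.
#' @return Named numeric vector `c(RB = , RG = , GB = )`.
#' @export
channel_pair_distances <- function(image) {
  ch <- split_channels(image)
  c(RB = sum((ch$R - ch$B)^2),
    RG = sum((ch$R - ch$G)^2),
    GB = sum((ch$G - ch$B)^2))
}

#' Fuse the two most similar color channels
#'
#' Finds the channel pair with the smallest pairwise distance and returns
#' their per-pixel arithmetic mean as one grayscale image.
#'
#' @param image `H x W x 3` array, channel order R, G, B.
#' @return `H x W` matrix.
#' @export
fuse_similar_channels <- function(image) {
  d <- channel_pair_distances(image)
  ch <- split_channels(image)
  pair <- list(RB = c("R", "B"), RG = c("R", "G"), GB = c("G", "B"))[[
    names(d)[which.min(d)]]]
  (ch[[pair[1L]]] + ch[[pair[2L]]]) / 2
}

#' Infer the number of clusters by Mamdani max-min inference
#'
#' For each candidate integer cluster count `c`, the system output is
#' `Q(c) = max over rules of min(firing, consequent membership at c)`,
#' where the firing strength is the min of the two antecedent memberships
#' at `(D, size)`. The inferred count is the argmax of `Q` over the
#' candidate range (smallest on ties), never below 2.
#'
#' @param D Intensity range `Vmax - Vmin` of the fused grayscale image, in
#'   `[0, 255]`.
#' @param size Image size in pixels.
#' @param rulebase A [default_rulebase()]-style rule base.
#' @param candidates Integer candidate cluster counts (default `2:40`).
#' @return Integer cluster count.
#' @export
infer_cluster_count <- function(D, size, rulebase = default_rulebase(),
                                candidates = 2:40) {
  stopifnot(is.finite(D), is.finite(size), size > 0)
  r <- rulebase$rules
  firing <- vapply(seq_len(nrow(r)), function(i) {
    min(gauss_membership(D, rulebase$distance_sets[[r$distance[i]]]),
        gauss_membership(size, rulebase$size_sets[[r$size[i]]]))
  }, numeric(1L))
  Q <- vapply(candidates, function(cc) {
    max(vapply(seq_len(nrow(r)), function(i) {
      min(firing[i],
          gauss_membership(cc, rulebase$cluster_sets[[r$cluster[i]]]))
    }, numeric(1L)))
  }, numeric(1L))
  n <- candidates[which.max(Q)]
  max(2L, as.integer(n))
}

#' Equidistant initial cluster centers
#'
#' `c_j = v_min + j * D / N` for `j = 1..N`: `N` equally spaced centers
#' spanning the upper part of the intensity range, anchored at the image's
#' minimum so they lie inside the data.
#'
#' @param v_min Minimum intensity.
#' @param D Intensity range.
#' @param N Number of centers.
#' @return Strictly increasing numeric vector of length `N` (constant when
#'   `D = 0`).
#' @export
initial_centers <- function(v_min, D, N) {
  stopifnot(N >= 1L, D >= 0)
  v_min + seq_len(N) * D / N
}

#' Cluster-preselection fuzzy C-means on a color image
#'
#' The full automatic procedure: (1) split the RGB image and fuse the two
#' most similar channels into a grayscale image; (2) compute its intensity
#' range `D` and the pixel count; (3) infer the cluster count by fuzzy
#' inference; (4) seed equidistant centers; (5-7) run FCM to convergence.
#' A constant image (`D = 0`) yields a single-cluster segmentation with a
#' warning.
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param rulebase Rule base for the inference step.
#' @param k,tol,max_iter FCM parameters (see [fcm_cluster()]).
#' @return List with the `fcm_state` (`NULL` for a constant image), the
#'   inferred count `N`, range `D`, the fused `gray` image and the `H x W`
#'   integer `labels` map.
#' @export
cpsfcm <- function(image, rulebase = default_rulebase(), k = 2,
                   tol = 1e-5, max_iter = 300L) {
  gray <- fuse_similar_channels(image)
  v <- range(gray)
  D <- v[2L] - v[1L]
  if (D == 0) {
    warning("constant image: returning a single-cluster segmentation")
    return(list(state = NULL, N = 1L, D = 0, gray = gray,
                labels = matrix(1L, nrow(gray), ncol(gray))))
  }
  N <- infer_cluster_count(D, length(gray), rulebase)
  cen <- initial_centers(v[1L], D, N)
  st <- fcm_cluster(as.numeric(gray), N, k = k, init_centers = cen,
                    tol = tol, max_iter = max_iter)
  labels <- matrix(hard_labels(st$memberships), nrow(gray), ncol(gray))
  list(state = st, N = N, D = D, gray = gray, labels = labels)
}
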