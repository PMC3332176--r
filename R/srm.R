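# Statistical region merging baseline. Adjacent pixel pairs are visited in
# order of increasing color difference; two regions merge when, for every
# channel, the gap between their observed averages is within a statistical
# bound b derived from the number of hypothetical independent intensity
# variables Q per channel.

#' Statistical merging bound
#'
#' `b(R) = g * sqrt(ln(2/delta) / (2 * Q * |R|))` with
#' `delta = 1 / (6 * n_pixels^2)` by default: the deviation bound on a
#' region's observed channel average.
#'
#' @param count Region pixel count `|R|`.
#' @param Q Statistical complexity (hypothetical independent variables per
#'   channel).
#' @param n_pixels Image pixel count (sets the default `delta`).
#' @param g Gray-level count (256).
#' @param delta Confidence parameter; default `1 / (6 * n_pixels^2)`.
#' @return Nonnegative bound (vectorized over `count`).
#' @export
srm_bound <- function(count, Q, n_pixels, g = 256,
                      delta = 1 / (6 * n_pixels^2)) {
  g * sqrt(log(2 / delta) / (2 * Q * count))
}

#' SRM merge predicate
#'
#' Two regions merge when for every color channel the absolute difference
#' of observed averages is at most the combined bound. The default combines
#' the per-region bounds as `sqrt(b(R)^2 + b(R')^2)`; the `"as_printed"`
#' form compares against `b(R)^2 + b(R')^2` without the square root.
#'
#' @param r1,r2 Regions: lists with `count` (pixels) and `means` (length-3
#'   channel averages).
#' @param Q Statistical complexity.
#' @param n_pixels Image pixel count.
#' @param predicate `"canonical"` or `"as_printed"`.
#' @param g,delta See [srm_bound()].
#' @return Logical.
#' @export
merge_predicate <- function(r1, r2, Q, n_pixels,
                            predicate = c("canonical", "as_printed"),
                            g = 256, delta = 1 / (6 * n_pixels^2)) {
  predicate <- match.arg(predicate)
  b1 <- srm_bound(r1$count, Q, n_pixels, g, delta)
  b2 <- srm_bound(r2$count, Q, n_pixels, g, delta)
  bound <- if (predicate == "canonical") sqrt(b1^2 + b2^2) else b1^2 + b2^2
  all(abs(r1$means - r2$means) <= bound)
}

#' Statistical region merging segmentation
#'
#' 4-connected pixel pairs are sorted by the maximum over channels of the
#' absolute intensity difference (pixel index breaking ties) and processed
#' once each through a union-find structure, merging the two incident
#' regions whenever [merge_predicate()] holds on their current statistics.
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param Q Statistical complexity; larger `Q` tightens the bound and
#'   yields at least as many regions.
#' @param predicate Bound form, see [merge_predicate()].
#' @param g,delta See [srm_bound()].
#' @return Object of class `srm_result`: list with `labels` (`H x W`
#'   integers `1..n_regions`, renumbered in raster order of first
#'   occurrence), `regions` (data frame: `label`, `count`, `R`, `G`, `B`)
#'   and `n_regions`.
#' @export
srm_segment <- function(image, Q = 256L,
                        predicate = c("canonical", "as_printed"),
                        g = 256, delta = NULL) {
  predicate <- match.arg(predicate)
  ch <- split_channels(image)
  H <- nrow(ch$R); W <- ncol(ch$R)
  n <- H * W
  if (is.null(delta)) delta <- 1 / (6 * n^2)
  chm <- cbind(as.numeric(ch$R), as.numeric(ch$G), as.numeric(ch$B))
  # 4-connectivity edges in column-major pixel indexing
  idx <- matrix(seq_len(n), H, W)
  e_v <- cbind(as.vector(idx[-H, , drop = FALSE]),
               as.vector(idx[-1L, , drop = FALSE]))
  e_h <- cbind(as.vector(idx[, -W, drop = FALSE]),
               as.vector(idx[, -1L, drop = FALSE]))
  edges <- rbind(e_v, e_h)
  wgt <- pmax(abs(chm[edges[, 1L], 1L] - chm[edges[, 2L], 1L]),
              abs(chm[edges[, 1L], 2L] - chm[edges[, 2L], 2L]),
              abs(chm[edges[, 1L], 3L] - chm[edges[, 2L], 3L]))
  ord <- order(wgt, edges[, 1L], edges[, 2L])
  parent <- seq_len(n)
  count <- rep(1L, n)
  sums <- chm
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  lnfac <- log(2 / delta)
  bcoef <- g^2 * lnfac / (2 * Q)       # b^2(R) = bcoef / |R|
  for (e in ord) {
    a <- find(edges[e, 1L])
    b <- find(edges[e, 2L])
    if (a == b) next
    b2a <- bcoef / count[a]
    b2b <- bcoef / count[b]
    bound <- if (predicate == "canonical") sqrt(b2a + b2b) else b2a + b2b
    if (all(abs(sums[a, ] / count[a] - sums[b, ] / count[b]) <= bound)) {
      # union by size, lower index as root on ties
      if (count[a] < count[b] || (count[a] == count[b] && b < a)) {
        tmp <- a; a <- b; b <- tmp
      }
      parent[b] <- a
      count[a] <- count[a] + count[b]
      sums[a, ] <- sums[a, ] + sums[b, ]
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  labels <- match(roots, unique(roots))
  uroots <- unique(roots)
  regions <- data.frame(label = seq_along(uroots),
                        count = count[uroots],
                        R = sums[uroots, 1L] / count[uroots],
                        G = sums[uroots, 2L] / count[uroots],
                        B = sums[uroots, 3L] / count[uroots])
  structure(list(labels = matrix(labels, H, W), regions = regions,
                 n_regions = length(uroots)),
            class = "srm_result")
}

#' @export
print.srm_result <- function(x, ...) {
  cat("<srm_result> ", nrow(x$labels), "x", ncol(x$labels), ", ",
      x$n_regions, " region(s)\n", sep = "")
  invisible(x)
}

#' Lesion score map from an SRM segmentation
#'
#' Maps each region's mean gray intensity through an inverted min-max
#' rescaling, so the darkest region scores 1 and the lightest 0 (flipped
#' under `polarity = "light"`), giving SRM a continuous output comparable
#' with the clustering methods.
#'
#' @param srm An `srm_result`.
#' @param polarity `"dark"` or `"light"`.
#' @return `H x W` matrix in `[0, 1]`.
#' @export
srm_score_map <- function(srm, polarity = c("dark", "light")) {
  polarity <- match.arg(polarity)
  gray <- rowMeans(srm$regions[, c("R", "G", "B")])
  rng <- range(gray)
  s <- if (rng[2L] == rng[1L]) rep(0.5, length(gray))
       else (gray - rng[1L]) / (rng[2L] - rng[1L])
  if (polarity == "dark") s <- 1 - s
  matrix(s[srm$labels], nrow(srm$labels), ncol(srm$labels))
}
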