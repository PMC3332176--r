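# End-to-end segmentation: channel split -> (optional) wavelet feature
# image per channel -> per-channel clustering into a continuous lesion
# score -> nearest-neighbor fusion of R with G, then with B -> score map
# and thresholded binary mask.

#' Split an RGB image into channels
#'
#' @param image `H x W x 3` numeric array, channel order R, G, B, values in
#'   `[0, 255]`.
#' @return Named list of `H x W` matrices `R`, `G`, `B`.
#' @export
split_channels <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("expected an H x W x 3 RGB array, got dimensions ",
         paste(dim(image), collapse = "x"), call. = FALSE)
  if (!all(is.finite(image))) stop("image values must be finite", call. = FALSE)
  shp <- dim(image)[1:2]
  list(R = matrix(image[, , 1L], shp[1L], shp[2L]),
       G = matrix(image[, , 2L], shp[1L], shp[2L]),
       B = matrix(image[, , 3L], shp[1L], shp[2L]))
}

#' Recombine three channels into an RGB array
#'
#' @param R,G,B `H x W` matrices.
#' @return `H x W x 3` array.
#' @export
combine_channels <- function(R, G, B) {
  stopifnot(all(dim(R) == dim(G)), all(dim(G) == dim(B)))
  array(c(R, G, B), dim = c(dim(R), 3L))
}

# which clusters count as lesion, given 1-D cluster centers:
# two clusters -> the extreme one on the lesion side; more -> all clusters
# on the lesion side of the size-weighted global mean
lesion_cluster_set <- function(centers, weights, polarity) {
  cen <- as.numeric(centers)
  if (polarity == "light") cen <- -cen
  if (length(cen) == 1L) return(1L)
  if (length(cen) == 2L) return(which.min(cen))
  gm <- sum(cen * weights) / sum(weights)
  les <- which(cen < gm)
  if (length(les) == 0L) les <- which.min(cen)
  if (length(les) == length(cen)) les <- setdiff(les, which.max(cen))
  les
}

#' Segment one (feature) channel into a lesion score
#'
#' Clusters the channel's pixel intensities and converts the result into a
#' continuous per-pixel lesion score in `[0, 1]`. The lesion cluster is the
#' one with the lowest center (lesions are darker than the surrounding skin;
#' set `polarity = "light"` to invert). For the fuzzy methods the score is
#' the membership to the lesion cluster(s); for K-means it is the soft
#' ratio `1 - d_lesion / (d_lesion + d_nearest_other)`. With more than two
#' clusters, all clusters whose centers fall on the lesion side of the
#' weighted global mean intensity contribute.
#'
#' @param feature `H x W` numeric matrix.
#' @param method `"kmeans"`, `"fcm"` or `"cpsfcm"` (the latter infers the
#'   cluster count from this channel's intensity range and size).
#' @param C Number of clusters (ignored by `"cpsfcm"`).
#' @param k Fuzziness exponent for the fuzzy methods.
#' @param polarity `"dark"` (default) or `"light"`: which intensity extreme
#'   is lesion.
#' @param rulebase Rule base for `"cpsfcm"`.
#' @param tol,max_iter Convergence controls passed to the clusterer.
#' @return Object of class `channel_segmentation`: list with `labels`
#'   (`H x W` integer), `score` (`H x W` in `[0, 1]`), `centers`, and
#'   `lesion_clusters`.
#' @export
segment_channel <- function(feature, method = c("fcm", "kmeans", "cpsfcm"),
                            C = 3L, k = 2, polarity = c("dark", "light"),
                            rulebase = default_rulebase(),
                            tol = NULL, max_iter = NULL) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  feature <- as.matrix(feature)
  stopifnot(all(is.finite(feature)))
  x <- as.numeric(feature)
  shp <- dim(feature)
  if (max(x) == min(x)) {
    warning("constant feature image: uniform score")
    return(structure(list(labels = matrix(1L, shp[1L], shp[2L]),
                          score = matrix(0.5, shp[1L], shp[2L]),
                          centers = x[1L], lesion_clusters = 1L),
                     class = "channel_segmentation"))
  }
  if (method == "kmeans") {
    res <- kmeans_cluster(x, C,
                          tol = if (is.null(tol)) 1e-8 else tol,
                          max_iter = if (is.null(max_iter)) 100L else max_iter)
    cen <- as.numeric(res$centroids)
    sizes <- tabulate(res$assignment, nbins = C)
    les <- lesion_cluster_set(cen, sizes, polarity)
    d2 <- dist2_to_centers(matrix(x, ncol = 1L), res$centroids)
    d_les <- sqrt(apply(d2[, les, drop = FALSE], 1L, min))
    oth <- setdiff(seq_len(nrow(res$centroids)), les)
    if (length(oth) == 0L) {
      score <- rep(1, length(x))
    } else {
      d_oth <- sqrt(apply(d2[, oth, drop = FALSE], 1L, min))
      score <- 1 - d_les / (d_les + d_oth)
      score[d_les + d_oth == 0] <- 0.5
    }
    labels <- res$assignment
  } else {
    st <- if (method == "fcm") {
      fcm_cluster(x, C, k = k,
                  tol = if (is.null(tol)) 1e-5 else tol,
                  max_iter = if (is.null(max_iter)) 300L else max_iter)
    } else {
      v <- range(x)
      N <- infer_cluster_count(v[2L] - v[1L], length(x), rulebase)
      fcm_cluster(x, N, k = k,
                  init_centers = initial_centers(v[1L], v[2L] - v[1L], N),
                  tol = if (is.null(tol)) 1e-5 else tol,
                  max_iter = if (is.null(max_iter)) 300L else max_iter)
    }
    cen <- as.numeric(st$centers)
    weights <- rowSums(st$memberships)
    les <- lesion_cluster_set(cen, weights, polarity)
    score <- colSums(st$memberships[les, , drop = FALSE])
    labels <- hard_labels(st$memberships)
  }
  structure(list(labels = matrix(labels, shp[1L], shp[2L]),
                 score = matrix(pmin(1, pmax(0, score)), shp[1L], shp[2L]),
                 centers = cen, lesion_clusters = les),
            class = "channel_segmentation")
}

#' Fuse two score maps
#'
#' Per-pixel arithmetic mean of two score maps on a common shape
#' (commutative and idempotent; resample first with [nni_resample()] if the
#' shapes differ).
#'
#' @param a,b Numeric matrices in `[0, 1]` of equal shape.
#' @return Matrix of the same shape.
#' @export
fuse_two <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop("score maps must share a shape after resampling; got ",
         paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  (a + b) / 2
}

#' Segment a dermoscopic RGB image
#'
#' The full framework: the image is split into R, G and B channels; each
#' channel is (for the `w*` methods) replaced by its wavelet feature image;
#' each channel is clustered into a continuous lesion score; the red score
#' is fused with the green by nearest-neighbor alignment and per-pixel
#' averaging, then the result with the blue; the fused score is thresholded
#' into the binary mask.
#'
#' @param image `H x W x 3` array, values in `[0, 255]`.
#' @param method One of `"wfcm"`, `"wkmeans"`, `"wcpsfcm"` (wavelet-domain)
#'   or `"fcm"`, `"kmeans"`, `"cpsfcm"` (raw channels).
#' @param family,levels,wavelet_mode,boundary,sqrt_magnitude Wavelet feature
#'   controls (see [feature_image()]); ignored by the non-wavelet methods.
#' @param C,k,polarity,rulebase,tol,max_iter Passed to [segment_channel()].
#' @param threshold Score threshold for the default binary mask.
#' @return Object of class `segmentation`: list with `score` (`H x W` in
#'   `[0, 1]`), `mask` (`H x W` in `{0, 1}`), `channels` (the three
#'   `channel_segmentation`s), `method` and `threshold`.
#' @examples
#' fix <- generate_lesion(lesion_spec(size = 48L, seed = 1L))
#' seg <- segment_image(fix$image, method = "wfcm", C = 2L)
#' mean(seg$mask == fix$mask)
#' @export
segment_image <- function(image,
                          method = c("wfcm", "wkmeans", "wcpsfcm",
                                     "fcm", "kmeans", "cpsfcm"),
                          family = "db4", levels = 1L,
                          wavelet_mode = c("approximation", "magnitude"),
                          boundary = c("symmetric", "periodic"),
                          sqrt_magnitude = FALSE,
                          C = 3L, k = 2, polarity = c("dark", "light"),
                          rulebase = default_rulebase(),
                          tol = NULL, max_iter = NULL, threshold = 0.5) {
  method <- match.arg(method)
  wavelet_mode <- match.arg(wavelet_mode)
  boundary <- match.arg(boundary)
  polarity <- match.arg(polarity)
  ch <- split_channels(image)
  use_wavelet <- startsWith(method, "w")
  base_method <- sub("^w", "", method)
  feats <- lapply(ch, function(x) {
    if (use_wavelet)
      feature_image(x, family = family, levels = levels, mode = wavelet_mode,
                    boundary = boundary, sqrt_magnitude = sqrt_magnitude)
    else x
  })
  segs <- lapply(feats, segment_channel, method = base_method, C = C, k = k,
                 polarity = polarity, rulebase = rulebase, tol = tol,
                 max_iter = max_iter)
  shp <- dim(image)[1:2]
  sc <- lapply(segs, function(s) nni_resample(s$score, shp))
  fused <- fuse_two(fuse_two(sc$R, sc$G), sc$B)
  if (max(fused) == min(fused))
    warning("uniform fused score: mask is empty or full")
  structure(list(score = fused,
                 mask = (fused >= threshold) * 1L,
                 channels = segs, method = method, threshold = threshold),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat("<segmentation> method ", x$method, ", ", nrow(x$score), "x",
      ncol(x$score), ", lesion fraction ",
      format(mean(x$mask), digits = 3), "\n", sep = "")
  invisible(x)
}
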