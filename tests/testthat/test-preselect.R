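test_that("gaussian membership matches its closed form", {
  dmin <- default_distance_sets()$minimum
  expect_equal(gauss_membership(15, dmin), 1.0)
  expect_equal(gauss_membership(31, dmin), exp(-0.5))
  expect_lt(gauss_membership(1e6, dmin), 1e-12)
  expect_error(fuzzy_set("bad", 0, 0))
})

test_that("the built-in linguistic variables carry the standard parameters", {
  d <- default_distance_sets(); s <- default_size_sets(); k <- default_cluster_sets()
  expect_length(d, 6L); expect_length(s, 5L); expect_length(k, 5L)
  expect_equal(d$short$center, 105); expect_equal(d$short$spread, 30)
  expect_equal(s$medium$center, 6.53e5); expect_equal(s$medium$spread, 1.968e5)
  expect_equal(k$some$center, 16); expect_equal(k$some$spread, 5)
  expect_equal(k$very_few$center, 2); expect_equal(k$too_many$center, 33)
})

test_that("the default rule base covers every antecedent pair exactly once", {
  rb <- default_rulebase()
  expect_equal(nrow(rb$rules), 30L)
  expect_equal(anyDuplicated(rb$rules[c("distance", "size")]), 0L)
  # monotone corners: small/small -> very few, large/large -> too many
  r <- rb$rules
  expect_equal(r$cluster[r$distance == "minimum" & r$size == "min"], "very_few")
  expect_equal(r$cluster[r$distance == "maximum" & r$size == "max"], "too_many")
  # malformed rule bases are rejected
  expect_error(default_rulebase(rules = r[-1, ]), "exactly one rule")
  bad <- r; bad$cluster[1] <- "plenty"
  expect_error(default_rulebase(rules = bad), "not defined")
})

test_that("rules and fuzzy sets round-trip through their text formats", {
  rb <- default_rulebase()
  rpath <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# rules", sprintf("%s, %s -> %s", rb$rules$distance,
                                  rb$rules$size, rb$rules$cluster)), rpath)
  expect_equal(read_rules(rpath), rb$rules)
  spath <- withr::local_tempfile(fileext = ".txt")
  writeLines(sprintf("%s, %g, %g",
                     names(rb$cluster_sets),
                     vapply(rb$cluster_sets, `[[`, numeric(1), "center"),
                     vapply(rb$cluster_sets, `[[`, numeric(1), "spread")),
             spath)
  got <- read_fuzzy_sets(spath)
  expect_equal(got$some$center, 16)
  expect_equal(got$too_many$spread, 7)
})

test_that("channel distances are squared-difference sums with full symmetry", {
  img <- array(0, c(2, 2, 3))
  expect_equal(unname(channel_pair_distances(img)), c(0, 0, 0))
  img[, , 2] <- 1                          # G differs by 1 at P = 4 pixels
  d <- channel_pair_distances(img)
  expect_equal(unname(d), c(0, 4, 4))      # RB, RG, GB
  # permuting two channels swaps the corresponding distances
  swapped <- img[, , c(2, 1, 3)]
  d2 <- channel_pair_distances(swapped)
  expect_equal(unname(d2[c("RG", "RB", "GB")]), unname(d[c("RG", "GB", "RB")]))
})

test_that("the most similar channel pair is fused by averaging", {
  img <- array(0, c(1, 2, 3))
  img[, , 2] <- c(3, 4)                    # G far from identical R and B
  expect_equal(fuse_similar_channels(img), matrix(0, 1, 2))
  img2 <- array(7, c(2, 2, 3))
  expect_equal(fuse_similar_channels(img2), matrix(7, 2, 2))
})

test_that("fuzzy inference hits the tabulated peaks and stays in range", {
  expect_identical(infer_cluster_count(15, 9000), 2L)
  expect_identical(infer_cluster_count(255, 1.44e6), 33L)
  set.seed(31)
  for (i in 1:20) {
    n <- infer_cluster_count(runif(1, 0, 255), runif(1, 1, 2e6))
    expect_gte(n, 2L); expect_lte(n, 40L)
  }
})

test_that("inference equals the brute-force max-min oracle on a grid", {
  rb <- default_rulebase()
  for (D in seq(0, 255, length.out = 6)) {
    for (s in seq(5000, 1.5e6, length.out = 6)) {
      expect_identical(infer_cluster_count(D, s, rb),
                       brute_force_infer(D, s, rb))
    }
  }
})

test_that("equidistant seeding spans the intensity range", {
  expect_equal(initial_centers(0, 250, 5), c(50, 100, 150, 200, 250))
  expect_equal(initial_centers(10, 100, 2), c(60, 110))
  expect_equal(initial_centers(3, 7, 1), 10)
  cen <- initial_centers(12, 130, 7)
  expect_equal(diff(cen), rep(130 / 7, 6))
})

test_that("cpsfcm segments a two-intensity image into two coherent labels", {
  m <- matrix(200, 16, 16); m[5:12, 5:12] <- 50
  img <- array(rep(m, 3), c(16, 16, 3))
  res <- cpsfcm(img)
  expect_gte(res$N, 2L)
  expect_equal(res$D, 150)
  lab_dark <- unique(res$labels[m == 50])
  lab_light <- unique(res$labels[m == 200])
  expect_length(lab_dark, 1L)
  expect_length(lab_light, 1L)
  expect_false(lab_dark == lab_light)
  # deterministic: same image, same rule base -> identical output
  expect_identical(res$labels, cpsfcm(img)$labels)
})

test_that("a constant image degenerates to one cluster with a warning", {
  img <- array(99, c(8, 8, 3))
  expect_warning(res <- cpsfcm(img), "constant image")
  expect_true(all(res$labels == 1L))
  expect_identical(res$N, 1L)
})
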