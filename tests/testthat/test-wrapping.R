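test_that("outline is the 1-px inner boundary", {
  sq <- matrix(FALSE, 5, 5); sq[2:4, 2:4] <- TRUE
  ol <- region_outline(sq)
  expect_equal(sum(ol), 8)            # centre pixel survives erosion
  expect_false(ol[3, 3])

  px <- matrix(FALSE, 5, 5); px[3, 3] <- TRUE
  expect_identical(region_outline(px), px)  # a single pixel is its own outline

  disc <- rasterize_disc(c(21, 21), c(11, 11), 6)
  ol <- region_outline(disc)
  expect_identical(ol, brute_outline(disc))  # every outline pixel has a background 8-neighbour
  expect_error(region_outline(matrix(FALSE, 4, 4)), "empty")
})

test_that("outline matches the brute-force boundary on random blobs", {
  set.seed(21)
  for (i in 1:25) {
    m <- matrix(runif(15 * 15) < 0.45, 15, 15)
    if (!any(m)) next
    expect_identical(region_outline(m), brute_outline(m))
  }
})

test_that("overlap mask encodes myelin-positive outline pixels as 255, others 0", {
  disc <- rasterize_disc(c(21, 21), c(11, 11), 6)
  ol <- region_outline(disc)
  full <- matrix(TRUE, 21, 21)
  om <- overlap_mask(ol, full)
  expect_true(all(om[ol] == 255))
  expect_true(all(is.na(om[!ol])))
  empty <- matrix(FALSE, 21, 21)
  expect_true(all(overlap_mask(ol, empty)[ol] == 0))

  half <- matrix(FALSE, 21, 21); half[, 1:11] <- TRUE  # half-plane through the centre
  omh <- overlap_mask(ol, half)
  ratio <- sum(omh == 255, na.rm = TRUE) / sum(ol)
  expect_lt(abs(ratio - 0.5), 0.05)
})

test_that("wrap fraction is the outline myelin-positive share", {
  # a 100-px outline with 80 myelin-positive pixels
  ol <- matrix(TRUE, 10, 10)
  my <- matrix(FALSE, 10, 10); my[1:8, ] <- TRUE
  expect_equal(wrap_fraction(ol, my), 0.8)
  expect_equal(wrap_fraction(ol, matrix(TRUE, 10, 10)), 1.0)
  expect_error(wrap_fraction(matrix(FALSE, 5, 5), my), "outline")
})

test_that("wrap fraction equals the brute-force pixel count on random masks", {
  set.seed(33)
  for (i in 1:50) {
    m <- matrix(runif(12 * 12) < 0.5, 12, 12)
    if (!any(m)) next
    ol <- region_outline(m)
    my <- matrix(runif(12 * 12) < 0.5, 12, 12)
    expect_identical(wrap_fraction(ol, my), brute_wrap_fraction(ol, my))
    expect_identical(wrap_fraction(ol, my),
                     sum(overlap_mask(ol, my) == 255, na.rm = TRUE) / sum(ol))
  }
})

test_that("wrap fraction is monotone in myelin and blind to off-outline pixels", {
  set.seed(8)
  disc <- rasterize_disc(c(25, 25), c(13, 13), 7)
  ol <- region_outline(disc)
  my <- matrix(runif(25 * 25) < 0.3, 25, 25)
  f0 <- wrap_fraction(ol, my)
  my_more <- my | matrix(runif(25 * 25) < 0.3, 25, 25)
  expect_gte(wrap_fraction(ol, my_more), f0)
  my_off <- my; my_off[!ol] <- TRUE
  expect_identical(wrap_fraction(ol, my_off), f0)
})

test_that("profiles aggregate z-runs into segments with physical lengths", {
  p <- make_profile(c(0.9, 0.9, 0.9))
  expect_equal(nrow(p$segments), 1)
  expect_equal(p$segments$length_um, 6)
  expect_true(p$fully_wrapped)

  p <- make_profile(c(0.9, 0.7, 0.9))
  expect_equal(p$segments$length_um, c(2, 2))
  expect_false(p$fully_wrapped)

  p <- make_profile(rep(0.85, 5))
  expect_equal(p$segments$length_um, 10)
  expect_true(p$fully_wrapped)

  # absent slices break contiguity even when flanked by wrapped slices
  p <- make_profile(c(0.9, NA, 0.9, 0.9))
  expect_equal(sort(p$segments$length_um), c(2, 4))
  expect_false(p$fully_wrapped)
  expect_true(is.na(p$wrap_fraction[2]))
})

test_that("the per-slice threshold is strictly greater than 0.8", {
  # a square region has a 40-px outline, so exactly 0.8 = 32/40 is realizable
  dims <- c(21L, 21L)
  sq <- matrix(FALSE, dims[1], dims[2]); sq[6:16, 6:16] <- TRUE
  region <- structure(list(axon_id = 1L,
                           pixels = replicate(3, which(sq), simplify = FALSE),
                           centroid = c(11, 11), border_touching = FALSE,
                           dims = dims), class = "axon_region")
  ol <- which(region_outline(sq))
  expect_equal(length(ol), 40)
  paint <- function(k) {
    m <- matrix(FALSE, dims[1], dims[2]); m[ol[seq_len(k)]] <- TRUE; m
  }
  exact08 <- make_mask_stack(replicate(3, paint(32), simplify = FALSE))
  p <- build_profile(region, exact08, z_step = 2)
  expect_equal(p$wrap_fraction, rep(0.8, 3))
  expect_equal(nrow(p$segments), 0)     # exactly 0.8 must not open a segment
  expect_false(p$fully_wrapped)

  above <- make_mask_stack(replicate(3, paint(33), simplify = FALSE))
  p2 <- build_profile(region, above, z_step = 2)
  expect_equal(nrow(p2$segments), 1)
  expect_true(p2$fully_wrapped)
})

test_that("categories bin the maximum per-slice fraction exclusively", {
  expect_equal(as.character(wrap_category(0.1)), "0-20%")
  expect_equal(as.character(wrap_category(0.2)), "0-20%")
  expect_equal(as.character(wrap_category(0.35)), "20-50%")
  expect_equal(as.character(wrap_category(0.8)), "50-80%")
  expect_equal(as.character(wrap_category(0.95)), "80-100%")
})

test_that("field metrics count categories over engaged axons and divide by nuclei", {
  full <- replicate(5, make_profile(c(0.9, 0.9, 0.9)), simplify = FALSE)
  fm <- field_metrics(full, 20)
  expect_equal(fm$wrapping_index, 0.25)
  expect_equal(fm$n_fully_wrapped, 5)
  expect_equal(fm$cat_80_100, 5)

  none <- list(make_profile(c(0.1, 0, 0)), make_profile(c(0, 0, 0)))
  fm0 <- field_metrics(none, 10)
  expect_equal(fm0$wrapping_index, 0)
  # the all-zero axon is not myelin-engaged and joins no category
  expect_equal(fm0$cat_0_20, 1)
  expect_equal(fm0$n_axons, 2)

  expect_warning(fmz <- field_metrics(full, 0), "zero nuclei")
  expect_false(fmz$valid)
  expect_true(is.na(fmz$wrapping_index))
})

test_that("border-touching axons never enter field metrics", {
  a <- make_profile(c(0.9, 0.9, 0.9))
  b <- make_profile(c(0.9, 0.9, 0.9), border_touching = TRUE)
  fm <- field_metrics(list(a, b), 10)
  expect_equal(fm$n_axons, 1)
  expect_equal(fm$n_fully_wrapped, 1)
})

test_that("fully wrapped axons always sit in the 80-100% category", {
  set.seed(14)
  for (i in 1:20) {
    fr <- runif(6)
    p <- make_profile(fr)
    if (p$fully_wrapped)
      expect_equal(as.character(p$category), "80-100%")
    fm <- field_metrics(list(p), 5)
    expect_lte(fm$n_fully_wrapped, fm$cat_80_100)
  }
})

test_that("wrapping index scales exactly as 1/n_nuclei", {
  ps <- replicate(3, make_profile(c(0.9, 0.9, 0.9)), simplify = FALSE)
  f1 <- field_metrics(ps, 6)
  f2 <- field_metrics(ps, 12)
  expect_identical(f1$wrapping_index, 2 * f2$wrapping_index)
  expect_identical(f1$wrapping_index, 3 / 6)
})

test_that("noiseless fields recover ground-truth full-wrap labels exactly", {
  cfg <- tiny_config(seed = 5L)
  np <- n_pillars(cfg)
  set.seed(5)
  cov <- do.call(rbind, lapply(runif(np) < 0.4, function(fl)
    axonwrap:::sample_axon_coverage(cfg$n_slices, fl)))
  fld <- generate_field(cfg, cov)
  q <- quantify_stack(fld$stack)
  expect_equal(length(q$profiles), np)
  got <- vapply(q$profiles, `[[`, logical(1), "fully_wrapped")
  truth <- fld$axons$true_fully_wrapped
  expect_equal(sum(got), sum(truth))
  expect_equal(q$field$n_fully_wrapped, sum(truth))
})
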