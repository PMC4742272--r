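cfg_small <- threshold_config(min_interior_area = 50)

test_that("thresholding recovers a synthetic annulus exactly", {
  fx <- make_ring_image(10, 14, ring_dn = 200, bg_dn = 50)
  roi <- matrix(TRUE, nrow(fx$ring), ncol(fx$ring))
  ring <- extract_perinuclear_ring(fx$image, roi, cfg_small)
  expect_identical(ring, fx$ring)
})

test_that("an ROI entirely below t_peri raises NoPerinuclearSignal", {
  img <- gray_image(matrix(120L, 30, 30))
  expect_error(extract_perinuclear_ring(img, matrix(TRUE, 30, 30), cfg_small),
               "NoPerinuclearSignal")
})

test_that("the largest of several bright components is kept (8-connectivity oracle)", {
  px <- matrix(50L, 120, 120)
  px[10:39, 10:39] <- 200L     # 900 px blob
  px[60:109, 50:109] <- 200L   # larger blob
  px[40, 40] <- 200L           # diagonal bridge pixel off the first blob
  roi <- matrix(TRUE, 120, 120)
  ring <- extract_perinuclear_ring(gray_image(px), roi,
                                   threshold_config(closing_radius = 0,
                                                    min_interior_area = 50))
  lab <- oracle_label(px >= 145, connectivity = 8)
  sizes <- tabulate(lab[lab > 0])
  expect_identical(ring, lab == which.max(sizes))
  expect_equal(sum(ring), 50 * 60)
})

test_that("label_components agrees with the brute-force BFS oracle", {
  set.seed(31)
  for (i in 1:6) {
    m <- matrix(runif(24 * 24) < 0.35, 24, 24)
    for (conn in c(8L, 4L)) {
      got <- label_components(m, conn)
      want <- oracle_label(m, conn)
      # same partition up to label names
      expect_equal(max(got), max(want))
      expect_true(all(tapply(want[m], got[m], function(v) length(unique(v))) == 1))
    }
  }
})

test_that("continuity is enclosure: closed ring yes, 15-degree gap no", {
  closed <- make_annulus(15, 19)
  res <- assess_continuity(closed, cfg_small)
  expect_true(res$continuous)
  expect_identical(res$interior, oracle_unreachable_background(closed))

  gapped <- make_annulus(15, 19, gap_deg = 30, gap_width_deg = 15)
  res2 <- assess_continuity(gapped, cfg_small)
  expect_false(res2$continuous)
  expect_false(any(res2$interior))
  expect_equal(res2$interior, gapped & FALSE)
})

test_that("a 1-px crack is bridged by closing during ring extraction", {
  fx <- make_ring_image(12, 16, ring_dn = 200, bg_dn = 50)
  px <- fx$image$pixels
  ctr <- (nrow(px) + 1) / 2
  px[ctr, (ctr + 12):(ctr + 16)] <- 50L            # radial crack, 1 px wide
  roi <- matrix(TRUE, nrow(px), ncol(px))
  ring <- extract_perinuclear_ring(gray_image(px), roi, cfg_small)
  res <- assess_continuity(ring, cfg_small)
  expect_true(res$continuous)
  # without closing the crack stays open
  ring0 <- extract_perinuclear_ring(gray_image(px), roi,
                                    threshold_config(closing_radius = 0,
                                                     min_interior_area = 50))
  expect_false(assess_continuity(ring0, cfg_small)$continuous)
})

test_that("speck enclosures are rejected by min_interior_area", {
  tiny <- make_annulus(4, 7)
  expect_false(assess_continuity(tiny, threshold_config())$continuous)
  expect_true(assess_continuity(tiny, threshold_config(min_interior_area = 10))$continuous)
})

test_that("nucleolus detection follows the size-fraction rule", {
  interior <- make_disk(30)                       # 2821 px
  px <- matrix(100L, nrow(interior), ncol(interior))
  ctr <- (nrow(px) + 1) / 2
  # one dense blob ~8% of interior
  blob <- (row(px) - ctr)^2 + (col(px) - ctr)^2 <= 8.5^2
  px[blob] <- 220L
  got <- detect_nucleolus(gray_image(px), interior, threshold_config())
  expect_identical(got, blob & interior)

  # scattered specks only: none qualifies
  px2 <- matrix(100L, nrow(interior), ncol(interior))
  px2[cbind(c(10, 20, 30), c(10, 20, 30))] <- 220L
  expect_false(any(detect_nucleolus(gray_image(px2), interior, threshold_config())))

  # two blobs at ~6% and ~9%: only the larger is the nucleolus
  px3 <- matrix(100L, nrow(interior), ncol(interior))
  b1 <- (row(px3) - 20)^2 + (col(px3) - 20)^2 <= 7.3^2   # ~167 px ~ 6%
  b2 <- (row(px3) - 48)^2 + (col(px3) - 48)^2 <= 9^2     # ~253 px ~ 9%
  px3[b1 | b2] <- 220L
  got3 <- detect_nucleolus(gray_image(px3), interior, threshold_config())
  expect_identical(got3, b2 & interior)

  # an externally supplied mask overrides detection
  ext <- b1 & interior
  expect_identical(detect_nucleolus(gray_image(px3), interior, threshold_config(),
                                    nucleolus_mask = b1), ext)
})

test_that("inner perimeter matches closed forms within 2%", {
  sq <- matrix(FALSE, 60, 60); sq[6:55, 6:55] <- TRUE    # side 50
  expect_lt(abs(inner_perimeter_length(sq) - 200) / 200, 0.02)
  disk <- make_disk(100)
  expect_lt(abs(inner_perimeter_length(disk) - 2 * pi * 100) / (2 * pi * 100), 0.02)
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  p <- inner_perimeter_length(single)
  expect_gt(p, 0); expect_lt(p, 4)
  expect_error(inner_perimeter_length(matrix(FALSE, 5, 5)), "empty")
  two <- matrix(FALSE, 9, 9); two[2, 2] <- TRUE; two[8, 8] <- TRUE
  expect_error(inner_perimeter_length(two), "single connected")
})

test_that("segment_nucleus composes the stages and keeps its invariants", {
  gen <- generate_nucleus(nucleus_spec(seed = 3))
  seg <- segment_nucleus(gen$image, gen$truth$roi)
  expect_true(seg$continuous)
  expect_true(all(!(seg$interior_mask & seg$ring_mask)))
  expect_true(all(!seg$nucleolus_mask | seg$interior_mask))
  expect_gt(seg$inner_perimeter, 0)
  iou <- function(a, b) sum(a & b) / sum(a | b)
  expect_gte(iou(seg$ring_mask, gen$truth$ring), 0.95)
  expect_gte(iou(seg$interior_mask, gen$truth$interior), 0.95)

  gen2 <- generate_nucleus(nucleus_spec(gap_arcs = list(c(120, 25)), seed = 4))
  seg2 <- segment_nucleus(gen2$image, gen2$truth$roi)
  expect_false(seg2$continuous)
  expect_false(any(seg2$interior_mask))
  expect_equal(seg2$inner_perimeter, 0)
})

test_that("verdict and measurements are invariant under translation and rotation", {
  base <- nucleus_spec(seed = 9)
  gen <- generate_nucleus(base)
  seg <- segment_nucleus(gen$image, gen$truth$roi)
  shifted <- generate_nucleus(nucleus_spec(center = c(70, 90), seed = 9))
  seg_s <- segment_nucleus(shifted$image, shifted$truth$roi)
  expect_equal(seg_s$continuous, seg$continuous)
  expect_equal(sum(seg_s$interior_mask), sum(seg$interior_mask), tolerance = 0.01)
  # 90-degree rotation of the identical image
  rot <- t(gen$image$pixels)[, nrow(gen$image$pixels):1]
  roi_rot <- t(gen$truth$roi)[, nrow(gen$truth$roi):1]
  seg_r <- segment_nucleus(gray_image(rot), roi_rot)
  expect_equal(seg_r$continuous, seg$continuous)
  expect_equal(sum(seg_r$ring_mask), sum(seg$ring_mask))
  expect_equal(sum(seg_r$interior_mask), sum(seg$interior_mask))
  expect_equal(seg_r$inner_perimeter, seg$inner_perimeter, tolerance = 1e-6)
})

test_that("continuity verdict equals the border flood-fill oracle on random rings", {
  set.seed(17)
  for (i in 1:10) {
    gap <- if (i %% 2 == 0) list(c(runif(1, 0, 360), runif(1, 5, 40))) else list()
    gen <- generate_nucleus(nucleus_spec(gap_arcs = gap, seed = 100 + i))
    ring <- extract_perinuclear_ring(gen$image, gen$truth$roi)
    verdict <- assess_continuity(ring)$continuous
    oracle_interior <- oracle_unreachable_background(ring)
    expect_equal(verdict, sum(oracle_interior) >= 500)
    expect_equal(verdict, gen$truth$continuous)
  }
})
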