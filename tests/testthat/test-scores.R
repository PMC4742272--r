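# direct-formula checks use a hand-built segmentation record
fake_seg <- function(ring, interior, nucleolus, perim = 1) {
  structure(list(ring_mask = ring, interior_mask = interior,
                 nucleolus_mask = nucleolus, continuous = TRUE,
                 inner_perimeter = perim, nucleus_id = "fake"),
            class = "nucleus_segmentation")
}

test_that("Nuc-CS is the condensed fraction of interior minus nucleolus", {
  n <- 120
  interior <- matrix(FALSE, n, n); interior[11:110, 11:110] <- TRUE  # 10,000 px
  nucleolus <- matrix(FALSE, n, n); nucleolus[11:60, 11:30] <- TRUE  # 1,000 px
  px <- matrix(100L, n, n)
  outside <- which(interior & !nucleolus)
  px[outside[1:450]] <- 200L                                        # 450 condensed px
  seg <- fake_seg(matrix(FALSE, n, n), interior, nucleolus)
  expect_equal(compute_nuc_cs(gray_image(px), seg), 450 / 9000 * 100)

  px0 <- matrix(100L, n, n)
  expect_equal(compute_nuc_cs(gray_image(px0), seg), 0)
  px1 <- matrix(100L, n, n); px1[interior & !nucleolus] <- 255L
  expect_equal(compute_nuc_cs(gray_image(px1), seg), 100)
})

test_that("Nuc-CS errors on discontinuous nuclei and empty denominators", {
  n <- 20
  seg <- fake_seg(matrix(FALSE, n, n), matrix(TRUE, n, n), matrix(TRUE, n, n))
  expect_error(compute_nuc_cs(gray_image(matrix(0L, n, n)), seg), "denominator")
  seg2 <- fake_seg(matrix(FALSE, n, n), matrix(TRUE, n, n), matrix(FALSE, n, n))
  seg2$continuous <- FALSE
  expect_error(compute_nuc_cs(gray_image(matrix(0L, n, n)), seg2), "continuous")
})

test_that("Per-CS is condensed ring area over inner perimeter", {
  n <- 80
  ring <- matrix(FALSE, n, n); ring[1:40, 1:60] <- TRUE   # 2400 px
  px <- matrix(100L, n, n); px[ring] <- 200L
  seg <- fake_seg(ring, matrix(FALSE, n, n), matrix(FALSE, n, n), perim = 800)
  expect_equal(compute_per_cs(gray_image(px), seg), 3.0)
  px_cold <- matrix(100L, n, n); px_cold[ring] <- 150L    # above t_peri, below t_cond
  expect_equal(compute_per_cs(gray_image(px_cold), seg), 0)
})

test_that("Per-CS on a rasterized annulus matches the analytic value within 5%", {
  fx <- make_ring_image(100, 103, ring_dn = 200, bg_dn = 50)
  roi <- matrix(TRUE, nrow(fx$ring), ncol(fx$ring))
  cfg <- threshold_config()
  seg <- segment_nucleus(fx$image, roi, cfg)
  expect_true(seg$continuous)
  analytic <- pi * (103^2 - 100^2) / (2 * pi * 100)
  expect_lt(abs(compute_per_cs(fx$image, seg, cfg) - analytic) / analytic, 0.05)
})

test_that("patient classification follows unanimity then majority with a flag", {
  expect_equal(classify_patient(rep(FALSE, 10)), list(group = "A", consistent = TRUE))
  expect_equal(classify_patient(rep(TRUE, 10)), list(group = "N", consistent = TRUE))
  expect_warning(mixed <- classify_patient(c(rep(TRUE, 7), rep(FALSE, 3))), "mixed")
  expect_equal(mixed, list(group = "N", consistent = FALSE))
  expect_error(classify_patient(logical(0)), "no nuclei")
})

test_that("patient aggregation is the mean plus a percentile dispersion report", {
  one <- aggregate_patient(4.0, 2.0)
  expect_equal(one$patient_nuc_cs, 4.0)
  three <- aggregate_patient(c(2, 4, 6), c(1, 2, 3))
  expect_equal(three$patient_nuc_cs, 4.0)
  expect_equal(three$patient_per_cs, 2.0)

  set.seed(41)
  x <- runif(50, 0, 10); y <- runif(50, 0, 8)
  agg <- aggregate_patient(x, y)
  # sort-based oracle for the linear-interpolation quantile at p
  oq <- function(v, p) {
    s <- sort(v); h <- (length(v) - 1) * p + 1
    lo <- floor(h); s[lo] + (h - lo) * (s[min(lo + 1, length(v))] - s[lo])
  }
  for (j in seq_along(c(0.1, 0.25, 0.5, 0.75, 0.9))) {
    p <- c(0.1, 0.25, 0.5, 0.75, 0.9)[j]
    expect_equal(agg$dispersion["nuc_cs", j], oq(x, p))
    expect_equal(agg$dispersion["per_cs", j], oq(y, p))
  }
  expect_equal(agg$patient_nuc_cs, sum(x) / 50)
})

test_that("two-step stratification follows the decision branches", {
  expect_equal(two_step_evaluate("A", 0.5, 0.5, 3, 3), "high-risk")
  expect_equal(two_step_evaluate("A"), "high-risk")
  expect_equal(two_step_evaluate("N", 8.0, 6.0, 3.0, 3.0), "low-risk")
  expect_equal(two_step_evaluate("N", 2.0, 5.0, 3.0, 3.0), "elevated-risk")
  expect_equal(two_step_evaluate("N", 5.0, 2.0, 3.0, 3.0), "elevated-risk")
  expect_equal(two_step_evaluate("N", 8.0, 6.0), "low-risk")   # report-only default
  expect_error(two_step_evaluate("N", NULL, NULL, 3.0, 3.0), "missing")
})

test_that("scores recover generator expectations (noiseless)", {
  set.seed(99)
  for (s in 1:12) {
    spec <- nucleus_spec(particle_density = runif(1, 1, 6),
                         ring_thickness = runif(1, 2.5, 5.5),
                         nucleolus_radius = sample(c(0, 15, 18), 1),
                         seed = 200 + s)
    gen <- generate_nucleus(spec)
    seg <- segment_nucleus(gen$image, gen$truth$roi)
    expect_true(seg$continuous)
    expect_lt(abs(compute_nuc_cs(gen$image, seg) - gen$truth$expected_nuc_cs), 1.0)
    expect_lt(abs(compute_per_cs(gen$image, seg) - gen$truth$expected_per_cs), 0.2)
  }
})

test_that("Nuc-CS rises with particle density, Per-CS with rim thickness", {
  dens_levels <- seq(1, 6, length.out = 6)
  mean_nuc <- vapply(seq_along(dens_levels), function(i) {
    vals <- vapply(1:4, function(j) {
      gen <- generate_nucleus(nucleus_spec(particle_density = dens_levels[i],
                                           seed = 1000 + 10 * i + j))
      seg <- segment_nucleus(gen$image, gen$truth$roi)
      compute_nuc_cs(gen$image, seg)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_gt(cor(dens_levels, mean_nuc, method = "spearman"), 0.95)

  thick_levels <- seq(2.5, 5.5, length.out = 6)
  per <- vapply(seq_along(thick_levels), function(i) {
    gen <- generate_nucleus(nucleus_spec(ring_thickness = thick_levels[i],
                                         seed = 2000 + i))
    seg <- segment_nucleus(gen$image, gen$truth$roi)
    compute_per_cs(gen$image, seg)
  }, numeric(1))
  expect_gt(cor(thick_levels, per, method = "spearman"), 0.95)
})

test_that("Nuc-CS is invariant to nucleolus size when no condensed pixels sit inside it", {
  # same particle field, nucleolus below detection threshold vs absent:
  # both numerator and denominator exclude it consistently
  g_with <- generate_nucleus(nucleus_spec(nucleolus_radius = 15, particle_density = 4,
                                          seed = 77))
  g_without <- generate_nucleus(nucleus_spec(nucleolus_radius = 0, particle_density = 4,
                                             seed = 77))
  s_with <- segment_nucleus(g_with$image, g_with$truth$roi)
  s_without <- segment_nucleus(g_without$image, g_without$truth$roi)
  expect_lt(abs(compute_nuc_cs(g_with$image, s_with) - g_with$truth$expected_nuc_cs), 1)
  expect_lt(abs(compute_nuc_cs(g_without$image, s_without) -
                  g_without$truth$expected_nuc_cs), 1)
})
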