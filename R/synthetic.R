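# Synthetic EM-nucleus, cohort and trichrome generators with analytic
# ground truth. The default nucleus emulates a cardiomyocyte nucleus
# photographed at 10,000x on the 8-bit scale: a dense perinuclear rim
# (optionally gapped, the Group A phenotype), granular condensed-chromatin
# particles in the nucleoplasm, a central nucleolus, Z-disk reference
# stripes outside the nucleus, and optional truncated Gaussian noise.

#' Specification of one synthetic nucleus
#'
#' DN levels are chosen so the noiseless phantom is already Z-disk
#' calibrated (stripes at the 159 target) and each structure falls on the
#' intended side of the method's thresholds: rim and particles above the
#' condensed band (>= 193 on the 1-256 scale), nucleoplasm and background
#' well below the perinuclear band.
#'
#' @param image_size side of the square image (px).
#' @param center nucleus center `c(row, col)`, 1-based; default image center.
#' @param inner_radius inner rim radius (px).
#' @param ring_thickness radial rim thickness (px).
#' @param gap_arcs list/matrix of `(start_deg, extent_deg)` rim gaps; empty
#'   means a continuous rim.
#' @param ring_dn,particle_dn,nucleolus_dn,nucleoplasm_dn,background_dn DN
#'   levels of the structures.
#' @param particle_density expected particles per 1,000 interior px.
#' @param particle_radius particle radius (px).
#' @param nucleolus_radius nucleolus radius (px); 0 = none.
#' @param zdisk_stripes number of vertical Z-disk reference stripes.
#' @param zdisk_dn stripe DN (default 159, the calibration target).
#' @param noise_sigma additive truncated-Gaussian noise SD (DN).
#' @param seed RNG seed for particle placement and noise.
#' @return A `synthetic_nucleus_spec` list.
#' @export
nucleus_spec <- function(image_size = 160L, center = NULL,
                         inner_radius = 60, ring_thickness = 4,
                         gap_arcs = list(),
                         ring_dn = 210L, particle_dn = 230L,
                         nucleolus_dn = 220L, nucleoplasm_dn = 100L,
                         background_dn = 50L,
                         particle_density = 3, particle_radius = 2L,
                         nucleolus_radius = 15, zdisk_stripes = 2L,
                         zdisk_dn = 159L, noise_sigma = 0, seed = 1L) {
  if (is.null(center)) center <- c((image_size + 1) / 2, (image_size + 1) / 2)
  if (inner_radius + ring_thickness >= image_size / 2)
    stop("nucleus does not fit: inner_radius + ring_thickness must be < image_size / 2")
  dns <- c(ring_dn, particle_dn, nucleolus_dn, nucleoplasm_dn, background_dn, zdisk_dn)
  if (any(dns < 0) || any(dns > 255)) stop("DN levels must be in [0, 255]")
  if (is.matrix(gap_arcs)) gap_arcs <- asplit(gap_arcs, 1)
  structure(list(image_size = as.integer(image_size), center = center,
                 inner_radius = inner_radius, ring_thickness = ring_thickness,
                 gap_arcs = gap_arcs, ring_dn = ring_dn,
                 particle_dn = particle_dn, nucleolus_dn = nucleolus_dn,
                 nucleoplasm_dn = nucleoplasm_dn, background_dn = background_dn,
                 particle_density = particle_density,
                 particle_radius = as.integer(particle_radius),
                 nucleolus_radius = nucleolus_radius,
                 zdisk_stripes = as.integer(zdisk_stripes),
                 zdisk_dn = zdisk_dn, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "synthetic_nucleus_spec")
}

#' Render a synthetic nucleus with its ground truth
#'
#' Deterministic for a fixed seed (base R Mersenne-Twister, restored on
#' exit). Particles are placed by dart throwing with rejection (at most
#' 10,000 attempts), kept clear of the rim and the nucleolus so structures
#' never merge; the realized count is recorded. Ground-truth masks are the
#' noiseless geometry. Analytic expectations: the nucleoplasmic score uses
#' the realized rasterized particle area,
#' `expected_nuc_cs = 100 * particle_px / (interior_px - nucleolus_px)`;
#' the perinuclear score is fully analytic,
#' `expected_per_cs = pi ((r+t)^2 - r^2) / (2 pi r) = t (1 + t / (2 r))`
#' (continuous rims only; rasterization error is what recovery tolerances
#' absorb).
#'
#' @param spec a [nucleus_spec()].
#' @return A list with `image` (a [gray_image()]) and `truth`, a list of
#'   `ring`, `interior`, `nucleolus`, `particles`, `roi`, `zdisk` masks plus
#'   `continuous`, `expected_nuc_cs`, `expected_per_cs` (NA when gapped),
#'   `n_particles`, `realized_density`.
#' @export
generate_nucleus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_nucleus_spec"))
  n <- spec$image_size
  withr_seed(spec$seed, {
    rr <- matrix(rep(seq_len(n), n), n, n)
    cc <- t(rr)
    d <- sqrt((rr - spec$center[1])^2 + (cc - spec$center[2])^2)
    theta <- (atan2(cc - spec$center[2], rr - spec$center[1]) * 180 / pi) %% 360

    in_gap <- matrix(FALSE, n, n)
    for (g in spec$gap_arcs) {
      lo <- g[1] %% 360; span <- g[2]
      rel <- (theta - lo) %% 360
      in_gap <- in_gap | rel < span
    }
    r_in <- spec$inner_radius; r_out <- r_in + spec$ring_thickness
    ring <- d >= r_in & d < r_out & !in_gap
    interior <- d < r_in
    nucleolus <- if (spec$nucleolus_radius > 0) d <= spec$nucleolus_radius
                 else interior & FALSE

    # dart-throwing particle placement inside the nucleoplasm, clear of the
    # rim (>= 6 px, beyond the reach of the ring-extraction closing), the
    # nucleolus (>= 2 px) and other particles
    pr <- spec$particle_radius
    n_target <- stats::rpois(1, spec$particle_density * sum(interior) / 1000)
    max_r <- r_in - pr - 6
    centers <- matrix(numeric(0), 0, 2)
    attempts <- 0L
    while (nrow(centers) < n_target && attempts < 10000L) {
      attempts <- attempts + 1L
      a <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * max_r
      p <- spec$center + rad * c(cos(a), sin(a))
      d_nuc <- sqrt(sum((p - spec$center)^2))
      if (spec$nucleolus_radius > 0 &&
          d_nuc < spec$nucleolus_radius + pr + 2) next
      if (nrow(centers) > 0 &&
          min(sqrt(colSums((t(centers) - p)^2))) < 2 * pr + 1) next
      centers <- rbind(centers, p)
    }
    particles <- matrix(FALSE, n, n)
    for (i in seq_len(nrow(centers)))
      particles <- particles |
        ((rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= pr^2)
    particles <- particles & interior

    # Z-disk reference stripes in the background margin (left edge outward)
    zdisk <- matrix(FALSE, n, n)
    stripe_cols <- 3:5
    for (s in seq_len(spec$zdisk_stripes))
      zdisk[, stripe_cols + (s - 1L) * 5L] <- TRUE
    zdisk <- zdisk & d > r_out + 4   # never touch the nucleus

    img <- matrix(spec$background_dn, n, n)
    img[zdisk] <- spec$zdisk_dn
    img[interior] <- spec$nucleoplasm_dn
    img[d >= r_in & d < r_out & in_gap] <- spec$nucleoplasm_dn
    img[nucleolus] <- spec$nucleolus_dn
    img[particles] <- spec$particle_dn
    img[ring] <- spec$ring_dn
    if (spec$noise_sigma > 0)
      img <- pmin(pmax(round(img + stats::rnorm(n * n, 0, spec$noise_sigma)), 0), 255)

    # ground-truth ROI: an annular neighborhood of the nuclear envelope, the
    # way an annotator outlines the nuclear border; it deliberately excludes
    # the deep nucleoplasm so the (equally electron-dense) nucleolus can
    # never compete with the rim for the largest thresholded component
    roi <- d <= r_out + 6 & d >= r_in - 10
    interior_px <- sum(interior); nucleolus_px <- sum(nucleolus & interior)
    particle_px <- sum(particles & !nucleolus)
    continuous <- length(spec$gap_arcs) == 0L
    truth <- list(
      ring = ring, interior = interior, nucleolus = nucleolus & interior,
      particles = particles, roi = roi, zdisk = zdisk,
      continuous = continuous,
      expected_nuc_cs = 100 * particle_px / (interior_px - nucleolus_px),
      expected_per_cs = if (continuous)
        spec$ring_thickness * (1 + spec$ring_thickness / (2 * r_in)) else NA_real_,
      n_particles = nrow(centers),
      realized_density = 1000 * nrow(centers) / interior_px)
    list(image = gray_image(img, source_id = sprintf("synthetic-seed%d", spec$seed)),
         truth = truth)
  })
}

# evaluate expr under a seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic patient cohort with linked outcomes
#'
#' Mirrors the study design this method was developed on: `n_a` patients
#' with gapped (discontinuous, Group A) rims who all meet the 12-month
#' event, and `n_n` patients with continuous rims whose generative score
#' levels are drawn from an event and a non-event stratum
#' (`score_event_link`); with the default non-overlapping strata the
#' score-event link is perfectly separated. Each patient contributes
#' ~`nuclei_mean` nuclei (Poisson, minimum 3). Clinical covariates (age,
#' LVEF, LVEDD, BNP, percent fibrosis) are drawn from group-specific
#' distributions typical of a severe-DCM biopsy cohort.
#'
#' @param n_a,n_n patients per group (defaults 11 and 52).
#' @param n_events_n Group N patients assigned an event (default 7).
#' @param score_event_link list with uniform ranges
#'   `density_event`, `density_noevent` (particles / 1,000 px) and
#'   `thickness_event`, `thickness_noevent` (px).
#' @param nuclei_mean mean nuclei per patient (default 10).
#' @param noise_sigma per-image noise SD (DN; default 0).
#' @param seed RNG seed.
#' @return A list with `patients` (per patient: `patient_id`, `group_true`,
#'   `event`, `specs`, a list of [nucleus_spec()]s) and `table`, the cohort
#'   data frame (patient_id, group_true, age, lvef, lvedd, bnp, fibrosis,
#'   event).
#' @export
generate_cohort <- function(n_a = 11L, n_n = 52L, n_events_n = 7L,
                            score_event_link = list(
                              density_event = c(0.9, 2.0),
                              density_noevent = c(2.6, 6.5),
                              thickness_event = c(2.3, 2.8),
                              thickness_noevent = c(3.4, 6.0)),
                            nuclei_mean = 10, noise_sigma = 0, seed = 1L) {
  if (n_events_n > n_n) stop("n_events_n cannot exceed n_n")
  withr_seed(seed, {
    patients <- list()
    tab <- list()
    nucleus_seed <- (as.integer(seed) %% 1000000L) * 1000L
    mk_covariates <- function(group) {
      if (group == "A")
        c(age = max(18, round(stats::rnorm(1, 36.8, 10.3))),
          lvef = round(max(5, stats::rnorm(1, 21.0, 7.9)), 1),
          lvedd = round(stats::rnorm(1, 74.5, 13.9), 1),
          bnp = round(stats::rlnorm(1, log(341), 0.5)),
          fibrosis = round(max(0, stats::rnorm(1, 23.7, 18.9)), 1))
      else
        c(age = max(18, round(stats::rnorm(1, 50.9, 12.8))),
          lvef = round(max(5, stats::rnorm(1, 25.8, 6.5)), 1),
          lvedd = round(stats::rnorm(1, 64.3, 10.2), 1),
          bnp = round(stats::rlnorm(1, log(259), 0.6)),
          fibrosis = round(max(0, stats::rnorm(1, 18.7, 11.6)), 1))
    }
    idx <- 0L
    for (i in seq_len(n_a)) {
      idx <- idx + 1L
      pid <- sprintf("A%02d", i)
      n_nuc <- max(3L, stats::rpois(1, nuclei_mean))
      specs <- lapply(seq_len(n_nuc), function(j) {
        nucleus_seed <<- nucleus_seed + 1L
        nucleus_spec(gap_arcs = list(c(stats::runif(1, 0, 360),
                                       stats::runif(1, 10, 40))),
                     particle_density = stats::runif(1, 2, 6),
                     ring_thickness = stats::runif(1, 2.5, 5),
                     noise_sigma = noise_sigma, seed = nucleus_seed)
      })
      cov <- mk_covariates("A")
      event <- if (i <= ceiling(n_a * 9 / 11)) "VAD" else "death"
      patients[[idx]] <- list(patient_id = pid, group_true = "A",
                              event = event, specs = specs)
      tab[[idx]] <- data.frame(patient_id = pid, group_true = "A",
                               t(cov), event = event)
    }
    event_n <- sample(c(rep(TRUE, n_events_n), rep(FALSE, n_n - n_events_n)))
    for (i in seq_len(n_n)) {
      idx <- idx + 1L
      pid <- sprintf("N%02d", i)
      link <- score_event_link
      dens_rng <- if (event_n[i]) link$density_event else link$density_noevent
      thk_rng <- if (event_n[i]) link$thickness_event else link$thickness_noevent
      dens <- stats::runif(1, dens_rng[1], dens_rng[2])
      thk <- stats::runif(1, thk_rng[1], thk_rng[2])
      n_nuc <- max(3L, stats::rpois(1, nuclei_mean))
      specs <- lapply(seq_len(n_nuc), function(j) {
        nucleus_seed <<- nucleus_seed + 1L
        nucleus_spec(particle_density = dens * stats::runif(1, 0.95, 1.05),
                     ring_thickness = thk,
                     noise_sigma = noise_sigma, seed = nucleus_seed)
      })
      cov <- mk_covariates("N")
      event <- if (event_n[i]) "VAD" else "none"
      patients[[idx]] <- list(patient_id = pid, group_true = "N",
                              event = event, specs = specs)
      tab[[idx]] <- data.frame(patient_id = pid, group_true = "N",
                               t(cov), event = event)
    }
    list(patients = patients, table = do.call(rbind, tab))
  })
}

#' Generate a synthetic Masson-trichrome slide
#'
#' A tissue disc of muscle-red pixels on a near-white background, with blue
#' collagen blobs grown to a target fraction of the tissue and a final
#' per-pixel adjustment so the realized fraction is within 0.005 of the
#' target. Colors are drawn with small jitter well inside (blue) or outside
#' (muscle, background) the default HSV detection band.
#'
#' @param blue_fraction target fibrotic fraction of the tissue, in \[0, 1\].
#' @param size image side (px).
#' @param seed RNG seed.
#' @return A list with `image` (a `trichrome_image` whose tissue mask is
#'   the disc) and `true_fraction`, the exact realized blue fraction.
#' @export
generate_trichrome <- function(blue_fraction, size = 160L, seed = 1L) {
  if (blue_fraction < 0 || blue_fraction > 1) stop("blue_fraction must be in [0, 1]")
  withr_seed(seed, {
    n <- as.integer(size)
    rr <- matrix(rep(seq_len(n), n), n, n); cc <- t(rr)
    ctr <- (n + 1) / 2
    tissue <- (rr - ctr)^2 + (cc - ctr)^2 <= (0.45 * n)^2
    n_tissue <- sum(tissue)
    blue <- matrix(FALSE, n, n)
    target_px <- round(blue_fraction * n_tissue)
    # grow random blobs until just below target, then top up pixelwise
    guard <- 0L
    while (sum(blue & tissue) < target_px && guard < 5000L) {
      guard <- guard + 1L
      rad <- stats::runif(1, 2, max(3, n / 20))
      p <- c(stats::runif(1, 1, n), stats::runif(1, 1, n))
      blob <- (rr - p[1])^2 + (cc - p[2])^2 <= rad^2
      if (sum((blue | blob) & tissue) > target_px) next
      blue <- blue | blob
    }
    deficit <- target_px - sum(blue & tissue)
    if (deficit > 0) {
      avail <- which(tissue & !blue)
      blue[sample(avail, deficit)] <- TRUE
    }
    blue <- blue & tissue
    jit <- function(mu, s) pmin(pmax(round(mu + stats::rnorm(n * n, 0, s)), 0), 255)
    rgb <- array(0, dim = c(n, n, 3))
    rgb[, , 1] <- jit(240, 3); rgb[, , 2] <- jit(240, 3); rgb[, , 3] <- jit(240, 3)
    muscle <- tissue & !blue
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[muscle] <- jit(c(185, 70, 95)[ch], 8)[muscle]
      plane[blue] <- jit(c(60, 90, 180)[ch], 8)[blue]
      rgb[, , ch] <- plane
    }
    list(image = trichrome_image(rgb, tissue_mask = tissue),
         true_fraction = sum(blue) / n_tissue)
  })
}
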