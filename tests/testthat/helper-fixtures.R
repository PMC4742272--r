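# Geometric fixture builders used across the suite. All coordinates follow
# the package convention: row-major matrices, pixel centers at integer
# positions.

# logical disk of radius r centered in a (2*(r+pad)+1)^2 grid
make_disk <- function(r, pad = 5) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  rr <- matrix(rep(seq_len(n), n), n, n); cc <- t(rr)
  (rr - ctr)^2 + (cc - ctr)^2 <= r^2
}

# logical annulus r_in <= d < r_out, optionally with an angular gap
make_annulus <- function(r_in, r_out, size = 2 * r_out + 11,
                         gap_deg = NULL, gap_width_deg = 0) {
  ctr <- (size + 1) / 2
  rr <- matrix(rep(seq_len(size), size), size, size); cc <- t(rr)
  d <- sqrt((rr - ctr)^2 + (cc - ctr)^2)
  m <- d >= r_in & d < r_out
  if (!is.null(gap_deg)) {
    theta <- (atan2(cc - ctr, rr - ctr) * 180 / pi) %% 360
    m <- m & !(((theta - gap_deg) %% 360) < gap_width_deg)
  }
  m
}

# gray image with an annulus at ring_dn over a flat background
make_ring_image <- function(r_in, r_out, ring_dn = 200, bg_dn = 50, ...) {
  ring <- make_annulus(r_in, r_out, ...)
  px <- matrix(bg_dn, nrow(ring), ncol(ring))
  px[ring] <- ring_dn
  list(image = gray_image(px), ring = ring)
}

# brute-force connected-component labeling by BFS (test oracle)
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  shifts <- if (connectivity == 8)
    rbind(c(-1,-1),c(-1,0),c(-1,1),c(0,-1),c(0,1),c(1,-1),c(1,0),c(1,1))
  else rbind(c(-1,0),c(1,0),c(0,-1),c(0,1))
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pr <- (p - 1L) %% nr + 1L; pc <- (p - 1L) %/% nr + 1L
      for (s in seq_len(nrow(shifts))) {
        qr <- pr + shifts[s, 1]; qc <- pc + shifts[s, 2]
        if (qr < 1 || qr > nr || qc < 1 || qc > nc) next
        q <- (qc - 1L) * nr + qr
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  lab
}

# brute-force even-odd point-in-polygon at pixel centers (test oracle)
oracle_point_in_polygon <- function(vertices, shape) {
  out <- matrix(FALSE, shape[1], shape[2])
  n <- nrow(vertices)
  for (r in 0:(shape[1] - 1)) for (c in 0:(shape[2] - 1)) {
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      yi <- vertices[i, 1]; xi <- vertices[i, 2]
      yj <- vertices[j, 1]; xj <- vertices[j, 2]
      if ((yi > r) != (yj > r) &&
          c < xi + (r - yi) * (xj - xi) / (yj - yi)) inside <- !inside
      j <- i
    }
    out[r + 1, c + 1] <- inside
  }
  out
}

# flood fill of FALSE pixels 4-connectedly from the border (test oracle for
# the continuity rule: interior = unreachable background)
oracle_unreachable_background <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  reach <- matrix(FALSE, nr, nc)
  queue <- integer(0)
  for (p in which(!mask)) {
    pr <- (p - 1L) %% nr + 1L; pc <- (p - 1L) %/% nr + 1L
    if (pr == 1 || pr == nr || pc == 1 || pc == nc) { reach[p] <- TRUE; queue <- c(queue, p) }
  }
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    pr <- (p - 1L) %% nr + 1L; pc <- (p - 1L) %/% nr + 1L
    for (s in list(c(-1,0), c(1,0), c(0,-1), c(0,1))) {
      qr <- pr + s[1]; qc <- pc + s[2]
      if (qr < 1 || qr > nr || qc < 1 || qc > nc) next
      q <- (qc - 1L) * nr + qr
      if (!mask[q] && !reach[q]) { reach[q] <- TRUE; queue <- c(queue, q) }
    }
  }
  !mask & !reach
}
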