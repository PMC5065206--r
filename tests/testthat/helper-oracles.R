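# Independent brute-force reimplementations of the scoring formulas and
# geometry primitives, used as oracles. Deliberately written with explicit
# loops and no shared code with the package internals.

oracle_centroid <- function(contour) {
  n <- nrow(contour)
  sx <- 0; sy <- 0
  for (i in seq_len(n)) {
    sx <- sx + contour[i, 1]
    sy <- sy + contour[i, 2]
  }
  c(sx / n, sy / n)
}

oracle_radial <- function(contour) {
  ctr <- oracle_centroid(contour)
  n <- nrow(contour)
  d <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- sqrt((ctr[1] - contour[i, 1])^2 + (ctr[2] - contour[i, 2])^2)
  }
  d
}

oracle_smooth <- function(profile, span, boundary = "wrap") {
  n <- length(profile)
  h <- (span - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (boundary == "wrap") {
      s <- 0
      for (j in (i - h):(i + h)) {
        jj <- ((j - 1) %% n) + 1
        s <- s + profile[jj]
      }
      out[i] <- s / span
    } else {
      lo <- max(1, i - h); hi <- min(n, i + h)
      out[i] <- sum(profile[lo:hi]) / (hi - lo + 1)
    }
  }
  out
}

oracle_pd <- function(contour, span, penalties, edges = c(0.1, 0.2, 0.3),
                      boundary = "wrap") {
  d <- oracle_radial(contour)
  ds <- oracle_smooth(d, span, boundary)
  n <- length(d)
  dif <- numeric(n)
  for (i in seq_len(n)) dif[i] <- abs(d[i] - ds[i])
  mu <- sum(dif) / n
  rat <- if (mu > 0) dif / mu else rep(0, n)
  counts <- c(sum(rat < edges[1]),
              sum(rat >= edges[1] & rat < edges[2]),
              sum(rat >= edges[2] & rat < edges[3]),
              sum(rat >= edges[3]))
  p <- counts / n
  list(d = d, d_s = ds, diff = dif, mu_pd = mu, rat = rat, partitions = p,
       pd = penalties[1] * p[1] + penalties[2] * p[2] +
            penalties[3] * p[3] + penalties[4] * p[4])
}

oracle_residual <- function(profile, type) {
  n <- length(profile)
  center <- if (type == "mean") {
    sum(profile) / n
  } else {
    s <- sort(profile)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  resi <- numeric(n)
  for (i in seq_len(n)) resi[i] <- abs(profile[i] - center)
  mu <- sum(resi) / n
  ss <- 0
  for (i in seq_len(n)) ss <- ss + (resi[i] - mu)^2
  list(center = center, resi = resi, mu = mu, sigma = sqrt(ss / (n - 1)))
}

# Boundary pixel sets for the contour point-set sandwich: every foreground
# pixel with a background 4-neighbour must be traced; traced points must all
# have a background 8-neighbour. Returns 0-based (x, y) pairs as "x,y" keys.
oracle_boundary_keys <- function(mask, connectivity = 4) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  nb <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  keys <- character(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    for (dd in nb) {
      if (!pad[r + 1 + dd[1], c + 1 + dd[2]]) {
        keys <- c(keys, paste(c - 1, r - 1, sep = ","))
        break
      }
    }
  }
  keys
}

contour_keys <- function(contour) {
  unique(paste(contour[, 1], contour[, 2], sep = ","))
}

# Fixture builders ------------------------------------------------------------

disk_mask <- function(r, frac = 0.74) {
  n <- round(sqrt(pi * r^2 / frac))
  if (n %% 2 == 0) n <- n + 1  # odd canvas: integer-centered disk
  cx <- (n + 1) / 2
  outer(1:n, 1:n, function(rr, cc) (cc - cx)^2 + (rr - cx)^2 <= r^2)
}

# Analytic (non-rasterized) circle contour, fine sampling.
circle_contour <- function(r = 50, n = 360, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

# Analytic star-shaped contour r(theta) = base + amp * cos(freq * theta).
star_contour <- function(base = 50, amp = 8, freq = 12, n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- base + amp * cos(freq * th)
  cbind(x = r * cos(th), y = r * sin(th))
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# A pool of rasterized pixel-chain contours from random shape specs, for
# oracle-equivalence sweeps. Seeded, so test expectations are stable.
random_contours <- function(n, seed = 42, classes = c("NILM", "LSIL", "HSIL")) {
  set.seed(seed)
  seeds <- sample.int(1e6, n)
  lapply(seq_len(n), function(i) {
    cl <- classes[(i - 1) %% length(classes) + 1]
    make_contour(random_shape_spec(cl, seed = seeds[i]))$contour
  })
}
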