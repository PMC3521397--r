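# Geometric fixtures built in code: rasterized disks, ellipses and bars on
# zero-padded canvases, used across the unit tests.

diskMask <- function(r, pad = 10L) {
  n <- 2L * r + 2L * pad + 1L
  ctr <- (n + 1) / 2
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- t(xs)
  matrix(as.integer((xs - ctr)^2 + (ys - ctr)^2 <= r^2), n, n)
}

ellipseMask <- function(a, b, angleDeg = 0, pad = 10L) {
  n <- 2L * ceiling(max(a, b)) + 2L * pad + 1L
  ctr <- (n + 1) / 2
  xs <- matrix(rep(seq_len(n), each = n), n, n) - ctr
  ys <- t(matrix(rep(seq_len(n), each = n), n, n)) - ctr
  th <- angleDeg * pi / 180
  xr <- xs * cos(th) + ys * sin(th)
  yr <- -xs * sin(th) + ys * cos(th)
  matrix(as.integer((xr / a)^2 + (yr / b)^2 <= 1), n, n)
}

barMask <- function(h, w, pad = 5L) {
  m <- matrix(0L, h + 2L * pad, w + 2L * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- 1L
  m
}

# Flat-background image with a darker filled disk, for edge-detection tests.
diskImage <- function(r, n = 2L * r + 41L, bg = 0.85, fg = 0.2) {
  ctr <- (n + 1) / 2
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- t(xs)
  img <- matrix(bg, n, n)
  img[(xs - ctr)^2 + (ys - ctr)^2 <= r^2] <- fg
  img
}

# Independent brute-force longest-chord oracle: exhaustive all-pairs search
# over boundary pixels with the documented tie policy (pairs within half a
# pixel of the maximum length count as tied; resolved by shortest |theta|,
# then lexicographically smallest endpoints by (row, col)).
bruteChord <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  bp <- NULL
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (mask[r, c] == 0) next
    nb <- c(
      if (r > 1) mask[r - 1, c] else 0L, if (r < h) mask[r + 1, c] else 0L,
      if (c > 1) mask[r, c - 1] else 0L, if (c < w) mask[r, c + 1] else 0L)
    if (any(nb == 0) || r == 1 || r == h || c == 1 || c == w)
      bp <- rbind(bp, c(x = c, y = r))
  }
  cand <- NULL
  for (i in seq_len(nrow(bp) - 1)) for (j in (i + 1):nrow(bp)) {
    a <- bp[i, ]; b <- bp[j, ]
    if (b["y"] < a["y"] || (b["y"] == a["y"] && b["x"] < a["x"])) {
      tmp <- a; a <- b; b <- tmp
    }
    dx <- unname(b["x"] - a["x"]); dy <- unname(b["y"] - a["y"])
    d2 <- dx^2 + dy^2
    th <- if (dx == 0) 90 else atan(dy / dx) * 180 / pi
    cand <- rbind(cand, data.frame(d2 = d2, th = th,
                                   y1 = unname(a["y"]), x1 = unname(a["x"]),
                                   y2 = unname(b["y"]), x2 = unname(b["x"])))
  }
  near <- cand[sqrt(cand$d2) >= sqrt(max(cand$d2)) - 0.5, ]
  th2 <- near$th * pi / 90
  thetaHat <- atan2(mean(sin(th2)), mean(cos(th2))) * 90 / pi
  if (thetaHat <= -90) thetaHat <- thetaHat + 180
  near <- near[order(abs(near$th), near$y1, near$x1, near$y2, near$x2), ]
  list(d2 = max(cand$d2), th = thetaHat,
       p1 = c(near$x1[1], near$y1[1]), p2 = c(near$x2[1], near$y2[1]))
}

# Put a drawn archetype patch into a SegmentedObject.
drawAsObject <- function(label, ...) {
  d <- drawObject(label, ...)
  SegmentedObject(1L, d$mask, colorCrop = d$color)
}
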