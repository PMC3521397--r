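# Internal pixel-grid helpers. Images are numeric matrices (gray, [0,1]) or
# H x W x 3 arrays (rgb); masks are integer 0/1 matrices. Rows are y
# (increasing downward), columns are x. EBImage stores images transposed
# relative to this convention, but every EBImage operation used here
# (labeling, isotropic morphology, hole filling, distance map, watershed)
# is invariant under transposition, so matrices are passed through directly.

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

asMask <- function(m) matrix(as.integer(m != 0), nrow(m), ncol(m))

stopifnotGray <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("expected a grayscale image (numeric matrix)")
}

stopifnotRGB <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected an RGB image (H x W x 3 array)")
}

# Replicate-pad a matrix by `k` pixels on every side.
padReplicate <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  m[c(rep(1L, k), 1:h, rep(h, k)), c(rep(1L, k), 1:w, rep(w, k)), drop = FALSE]
}

# Shifted view of a k-padded matrix: offset (dr, dc) in \[-k, k\].
shiftView <- function(mp, k, dr, dc, h, w) {
  mp[(1 + k + dr):(h + k + dr), (1 + k + dc):(w + k + dc), drop = FALSE]
}

# Separable convolution with a symmetric 1-D kernel, replicate borders.
sepConvolve <- function(m, kernel) {
  k <- (length(kernel) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  mp <- padReplicate(m, k)
  rowpass <- matrix(0, h, w)
  for (i in seq_along(kernel))
    rowpass <- rowpass + kernel[i] * mp[(i):(i + h - 1L), (k + 1L):(k + w), drop = FALSE]
  rp <- padReplicate(rowpass, k)
  out <- matrix(0, h, w)
  for (i in seq_along(kernel))
    out <- out + kernel[i] * rp[(k + 1L):(k + h), (i):(i + w - 1L), drop = FALSE]
  out
}

# 8-connected component labeling. EBImage::bwlabel is 4-connected; diagonal
# adjacencies between its labels are merged through a label-graph union-find.
label8 <- function(mask) {
  l <- EBImage::bwlabel(asMask(mask))
  n <- max(l)
  if (n <= 1L) return(matrix(as.integer(l), nrow(l), ncol(l)))
  h <- nrow(l); w <- ncol(l)
  pairs <- rbind(
    cbind(as.vector(l[-h, -w]), as.vector(l[-1, -1])),   # \ diagonal
    cbind(as.vector(l[-h, -1]), as.vector(l[-1, -w]))    # / diagonal
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
  if (nrow(pairs) > 0) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  out <- matrix(0L, h, w)
  fg <- l > 0
  out[fg] <- relabel[l[fg]]
  out
}

# Bounding box of a 0/1 matrix, 0-based half-open (r0, c0, r1, c1).
maskBBox <- function(mask) {
  fg <- which(mask != 0, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("empty mask has no bounding box")
  c(min(fg[, 1]) - 1L, min(fg[, 2]) - 1L, max(fg[, 1]), max(fg[, 2]))
}

# Coordinates (col = x, row = y) of foreground pixels that touch the
# background 4-connectedly or the matrix edge.
boundaryPixels <- function(mask) {
  mask <- asMask(mask)
  h <- nrow(mask); w <- ncol(mask)
  mp <- matrix(0L, h + 2L, w + 2L)
  mp[2:(h + 1), 2:(w + 1)] <- mask
  core <- mp[2:(h + 1), 2:(w + 1)]
  nb <- mp[1:h, 2:(w + 1)] & mp[3:(h + 2), 2:(w + 1)] &
        mp[2:(h + 1), 1:w] & mp[2:(h + 1), 3:(w + 2)]
  idx <- which(core == 1L & !nb, arr.ind = TRUE)
  cbind(x = idx[, 2], y = idx[, 1])
}

# Intersection-over-union of two same-sized 0/1 matrices.
maskIoU <- function(a, b) {
  inter <- sum(a != 0 & b != 0)
  uni <- sum(a != 0 | b != 0)
  if (uni == 0) return(0)
  inter / uni
}

# Paste a cropped mask back onto a full-size zero canvas at bbox.
uncropMask <- function(mask, bbox, h, w) {
  full <- matrix(0L, h, w)
  full[(bbox[1] + 1):bbox[3], (bbox[2] + 1):bbox[4]] <- asMask(mask)
  full
}
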