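# Internal vision helpers shared by the detection pipelines.
# All operate on plain numeric matrices (rows = y, cols = x); coordinates
# handed back are 0-based pixel-centre coordinates.

smooth_gauss <- function(m, sigma) {
  if (sigma <= 0) return(m)
  EBImage::gblur(m, sigma = sigma)
}

# Otsu threshold on a 0-255 matrix; returns the threshold on the same scale
otsu_level <- function(m) {
  EBImage::otsu(m / 255, range = c(0, 1)) * 255
}

# 1-D Otsu on a numeric vector (256 bins over the observed range)
otsu_1d <- function(v, nbins = 256) {
  r <- range(v)
  if (diff(r) < 1e-9) return(r[1])
  h <- tabulate(pmin(nbins, 1L + floor((v - r[1]) / diff(r) * nbins)), nbins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
  w0 <- cumsum(p); m0 <- cumsum(p * mids)
  mt <- m0[nbins]
  sb <- (mt * w0 - m0)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  mids[which.max(sb)]
}

# dark wall mask: global Otsu, recursing into the dark class when it is the
# majority (bright cells in frame push the first threshold above background)
wall_mask <- function(sm) {
  t1 <- otsu_level(sm)
  mask <- sm < t1
  if (mean(mask) > 0.5) {
    t2 <- otsu_1d(sm[mask])
    mask <- sm < t2
  }
  mask
}

label_components <- function(mask) {
  EBImage::bwlabel(mask)
}

fill_mask_holes <- function(mask) {
  EBImage::fillHull(mask) > 0
}

morph_close <- function(mask, radius) {
  EBImage::closing(mask, EBImage::makeBrush(2L * radius + 1L, "disc")) > 0
}

morph_open_square <- function(mask, size = 3L, iterations = 1L) {
  k <- EBImage::makeBrush(size, "box")
  for (i in seq_len(iterations)) mask <- EBImage::erode(mask, k)
  for (i in seq_len(iterations)) mask <- EBImage::dilate(mask, k)
  mask > 0
}

# boundary pixels of every labelled component in one pass: pixels with a
# 4-neighbour of a different label (or on the frame edge); returns a list
# mapping label id -> data.frame(x, y), 0-based
component_boundaries <- function(labels) {
  m <- labels > 0
  h <- nrow(m); w <- ncol(m)
  pad <- function(dy, dx) {
    out <- matrix(FALSE, h, w)
    ys <- seq_len(h) + dy; xs <- seq_len(w) + dx
    ok_y <- ys >= 1 & ys <= h; ok_x <- xs >= 1 & xs <= w
    out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
    out
  }
  interior <- pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
  b <- m & !interior
  idx <- which(b, arr.ind = TRUE)
  ids <- labels[b]
  xs <- idx[, 2] - 1; ys <- idx[, 1] - 1
  out <- vector("list", max(labels, 1))
  for (k in split(seq_along(ids), ids)) {
    out[[ids[k[1]]]] <- data.frame(x = xs[k], y = ys[k])
  }
  out
}

component_boundary <- function(labels, id) {
  component_boundaries(labels)[[id]]
}

component_stats <- function(labels) {
  n <- max(labels)
  if (n == 0) {
    return(data.frame(id = integer(), area = numeric(), xmin = numeric(),
                      xmax = numeric(), ymin = numeric(), ymax = numeric(),
                      cx = numeric(), cy = numeric()))
  }
  idx <- which(labels > 0, arr.ind = TRUE)
  ids <- labels[labels > 0]
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  data.frame(id = seq_len(n),
             area = as.numeric(tabulate(ids, n)),
             xmin = tapply(x, ids, min)[as.character(seq_len(n))],
             xmax = tapply(x, ids, max)[as.character(seq_len(n))],
             ymin = tapply(y, ids, min)[as.character(seq_len(n))],
             ymax = tapply(y, ids, max)[as.character(seq_len(n))],
             cx = tapply(x, ids, mean)[as.character(seq_len(n))],
             cy = tapply(y, ids, mean)[as.character(seq_len(n))],
             row.names = NULL)
}
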