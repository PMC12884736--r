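# Shared fixtures, built in code at test time.

# unit square in the z = 0 plane, two facets
unit_square_mesh <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
               rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
}

# noisy checkerboard texture used by the fusion tests
checkerboard_image <- function(n = 128, period = 8, lo = 30, hi = 230,
                               noise = 3, seed = 11) {
  img <- matrix(lo, n, n)
  sel <- (floor((row(img) - 1) / period) + floor((col(img) - 1) / period)) %% 2 == 1
  img[sel] <- hi
  img + musescan:::with_seed(seed, matrix(rnorm(n * n, 0, noise), n))
}

# disks of known radius on a flat background; returns image + exact mask
disk_image <- function(centers, radius = 10, n = 128, fg = 200, bg = 50) {
  img <- matrix(bg, n, n)
  mask <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(centers))) {
    dd <- outer((seq_len(n) - centers[k, 1])^2,
                (seq_len(n) - centers[k, 2])^2, "+")
    mask <- mask | dd <= radius^2
  }
  img[mask] <- fg
  list(image = img, mask = mask)
}

# brute-force area-weighted facet-centroid average (centroid oracle)
brute_force_centroid <- function(mesh) {
  acc <- c(0, 0, 0); wsum <- 0
  for (i in seq_len(nrow(mesh$faces))) {
    tri <- mesh$vertices[mesh$faces[i, ], ]
    w <- musescan:::vnorm(musescan:::cross3(tri[2, ] - tri[1, ],
                                            tri[3, ] - tri[1, ])) / 2
    acc <- acc + w * colMeans(tri)
    wsum <- wsum + w
  }
  acc / wsum
}

# brute-force Mann-Whitney AUC (pairwise comparison oracle)
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

path_cost <- function(poses, idx) {
  if (length(idx) < 2) return(0)
  sum(vapply(seq_len(length(idx) - 1), function(i) {
    a <- poses[[idx[i]]]; b <- poses[[idx[i + 1]]]
    abs(a$rx - b$rx) + abs(a$ry - b$ry) +
      0.01 * sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  }, numeric(1)))
}
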