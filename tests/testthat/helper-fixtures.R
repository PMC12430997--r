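# shared fixture builders and brute-force oracles

unitImage <- function(px, id = "img") RGBImage(px, scale = "unit", id = id)

# image with every pixel the same (r, g, b)
flatImage <- function(r, g, b, H = 8, W = 8, id = "flat") {
  px <- array(0, c(H, W, 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  unitImage(px, id)
}

# rasterized disc mask: pixel centers within radius r of the center
discMask <- function(r, pad = 3L) {
  n <- 2L * (ceiling(r) + pad) + 1L
  c0 <- (n + 1) / 2
  d <- outer(seq_len(n) - c0, seq_len(n) - c0,
             function(a, b) sqrt(a^2 + b^2))
  d <= r
}

# rasterized filled ellipse, semi-axes (a, b), rotated by theta
ellipseMask <- function(a, b, theta = 0, pad = 3L) {
  n <- 2L * (ceiling(a) + pad) + 1L
  c0 <- (n + 1) / 2
  rr <- matrix(seq_len(n) - c0, n, n)
  cc <- t(rr)
  x <- rr * cos(theta) + cc * sin(theta)
  y <- -rr * sin(theta) + cc * cos(theta)
  (x / a)^2 + (y / b)^2 <= 1
}

squareMask <- function(s, pad = 3L) {
  n <- s + 2L * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1):(pad + s), (pad + 1):(pad + s)] <- TRUE
  m
}

# wrap an n x 15 matrix as a raw FeatureTable (for anomaly-module tests)
matrixFeatureTable <- function(X) {
  df <- as.data.frame(X)
  names(df) <- featureNames()
  df <- cbind(instance_id = seq_len(nrow(X)), df,
              flag_circularity = FALSE, flag_correlation = FALSE,
              flag_constant = FALSE)
  new("FeatureTable", table = df, scalingState = "raw",
      glcmConfig = glcmConfig())
}

# brute-force O(n^2) silhouette with the singleton-0 convention
bruteSilhouette <- function(X, labels) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    oth <- which(labels != labels[i])
    if (length(own) == 0L) { s[i] <- 0; next }
    a <- mean(D[i, own]); b <- mean(D[i, oth])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# exhaustive single-threshold Otsu on a histogram (between-class variance)
bruteOtsu1 <- function(counts) {
  n <- length(counts)
  p <- counts / sum(counts)
  best <- -Inf; bestT <- NA
  for (t in 1:(n - 1)) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(p[1:t] * (1:t)) / w0
    m1 <- sum(p[(t + 1):n] * ((t + 1):n)) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; bestT <- t }
  }
  bestT
}

# exhaustive two-threshold search maximizing sum of class w * mu^2
bruteOtsu2 <- function(counts) {
  n <- length(counts)
  p <- counts / sum(counts)
  sc <- function(a, b) {  # class over bins (a, b]
    w <- sum(p[(a + 1):b])
    if (w == 0) return(0)
    (sum(p[(a + 1):b] * ((a + 1):b)))^2 / w
  }
  best <- -Inf; bestT <- NULL
  for (t1 in 1:(n - 2)) for (t2 in (t1 + 1):(n - 1)) {
    v <- sc(0, t1) + sc(t1, t2) + sc(t2, n)
    if (v > best) { best <- v; bestT <- c(t1, t2) }
  }
  bestT
}

# an IndexMap whose 256-bin histogram equals `counts` exactly: one pixel
# per count at the bin center
histIndexMap <- function(counts) {
  v <- rep(seq_along(counts) - 0.5, counts)  # bin centers on a 0..n grid
  # pad to rectangle
  H <- ceiling(sqrt(length(v)))
  v <- c(v, rep(v[1], H * H - length(v)))
  new("IndexMap", values = matrix(v, H), indexName = "ExGR",
      sourceId = "hist")
}
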