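# Shared fixtures and independent reference implementations (oracles).

# The 2 x 2, B = 2 worked example:
#   X1 = [[1,2],[3,4]], X2 = [[5,6],[7,8]]
#   C1 = [[1,0],[1,1]], C2 = [[0,1],[1,0]]
#   Y  = [[1,6],[10,4]], coverage = [[1,1],[2,1]], Ybar = [[1,6],[5,4]]
worked_example <- function() {
  X1 <- matrix(c(1, 3, 2, 4), 2, 2)
  X2 <- matrix(c(5, 7, 6, 8), 2, 2)
  C1 <- matrix(c(1, 1, 0, 1), 2, 2)
  C2 <- matrix(c(0, 1, 1, 0), 2, 2)
  list(video = tcs_video(array(c(X1, X2), c(2, 2, 2)), pixel_peak = 255),
       masks = tcsem:::new_tcs_masks(array(c(C1, C2), c(2, 2, 2)), 7L, 0.5),
       Y = matrix(c(1, 10, 6, 4), 2, 2),
       Ybar = matrix(c(1, 5, 6, 4), 2, 2))
}

# Brute-force windowed SSIM: explicit loop over every valid window position.
ssim_reference <- function(a, b, peak, window = 11, sigma = 1.5,
                           K = c(0.01, 0.03)) {
  g1 <- exp(-(seq_len(window) - (window + 1) / 2)^2 / (2 * sigma^2))
  g1 <- g1 / sum(g1)
  w <- outer(g1, g1)
  C1 <- (K[1] * peak)^2
  C2 <- (K[2] * peak)^2
  nx <- nrow(a); ny <- ncol(a)
  vals <- c()
  for (i in seq_len(nx - window + 1)) {
    for (j in seq_len(ny - window + 1)) {
      wa <- a[i:(i + window - 1), j:(j + window - 1)]
      wb <- b[i:(i + window - 1), j:(j + window - 1)]
      mu1 <- sum(w * wa); mu2 <- sum(w * wb)
      s11 <- sum(w * wa^2) - mu1^2
      s22 <- sum(w * wb^2) - mu2^2
      s12 <- sum(w * wa * wb) - mu1 * mu2
      vals <- c(vals, ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
                  ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)))
    }
  }
  mean(vals)
}

# Direct same-padding convolution by quadruple loop (channels-last matrix
# in, channels-last matrix out), independent of the compiled path.
conv2d_reference <- function(xmat, wmat, bias, H, W, N, k) {
  Cin <- ncol(xmat); Cout <- ncol(wmat)
  p <- (k - 1) / 2
  x4 <- array(xmat, c(H, W, N, Cin))
  out <- array(0, c(H, W, N, Cout))
  for (co in seq_len(Cout)) {
    for (n in seq_len(N)) {
      for (i in seq_len(H)) {
        for (j in seq_len(W)) {
          acc <- bias[co]
          off <- 0
          for (dj in seq_len(k)) {
            for (di in seq_len(k)) {
              off <- off + 1
              si <- i + di - 1 - p; sj <- j + dj - 1 - p
              if (si >= 1 && si <= H && sj >= 1 && sj <= W) {
                for (ci in seq_len(Cin)) {
                  acc <- acc + x4[si, sj, n, ci] * wmat[(off - 1) * Cin + ci, co]
                }
              }
            }
          }
          out[i, j, n, co] <- acc
        }
      }
    }
  }
  matrix(out, H * W * N, Cout)
}

# Tiny deterministic lattice clip for decoder tests.
tiny_clip <- function(B = 3, nx = 8, ny = 8, seed = 3) {
  sc <- scene_config("lattice", B = B, nx = nx, ny = ny, seed = seed,
                     dose = Inf, gaussian_sigma = 0, drift = c(0.5, 0.25))
  lattice_video(sc)$clean
}
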