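# Independent brute-force FRC oracle: loops over every Fourier sample,
# assigns it to a ring by rounded Euclidean radius, and accumulates the
# numerator and the two denominators directly. Shares no code with the
# package's vectorized ring binning.
frc_brute_force <- function(m1, m2) {
  n <- nrow(m1)
  F1 <- stats::fft(m1 - mean(m1))
  F2 <- stats::fft(m2 - mean(m2))
  rmax <- n %/% 2
  num <- den1 <- den2 <- cnt <- numeric(rmax)
  for (i in 0:(n - 1)) {
    fi <- if (i > n / 2) i - n else i
    for (j in 0:(n - 1)) {
      fj <- if (j > n / 2) j - n else j
      r <- round(sqrt(fi^2 + fj^2))
      if (r >= 1 && r <= rmax) {
        v1 <- F1[i + 1, j + 1]
        v2 <- F2[i + 1, j + 1]
        num[r] <- num[r] + Re(v1 * Conj(v2))
        den1[r] <- den1[r] + Mod(v1)^2
        den2[r] <- den2[r] + Mod(v2)^2
        cnt[r] <- cnt[r] + 1
      }
    }
  }
  keep <- cnt > 0
  den <- sqrt(den1 * den2)
  list(ring = which(keep),
       corr = ifelse(den[keep] > 0, num[keep] / den[keep], 0),
       n = cnt[keep])
}

# Square ROI polygon covering [0, s] x [0, s].
square_roi <- function(s) cbind(c(0, s, s, 0), c(0, 0, s, s))

roi_all_slices <- function(s, n_slices) {
  roi_set(stats::setNames(rep(list(square_roi(s)), n_slices),
                          0:(n_slices - 1)))
}

random_plane <- function(n, pixel_size = 0.1) {
  image_plane(matrix(stats::runif(n * n, 0, 100), n, n), pixel_size)
}
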