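# Independent oracles, deliberately coded differently from the package:
# homogeneous-transform forward kinematics and a direct-DFT spectral arc
# length.

# 4x4 homogeneous transforms, degrees
Hrx <- function(d) { a <- d * pi / 180
  rbind(c(1, 0, 0, 0), c(0, cos(a), -sin(a), 0),
        c(0, sin(a), cos(a), 0), c(0, 0, 0, 1)) }
Hry <- function(d) { a <- d * pi / 180
  rbind(c(cos(a), 0, sin(a), 0), c(0, 1, 0, 0),
        c(-sin(a), 0, cos(a), 0), c(0, 0, 0, 1)) }
Hrz <- function(d) { a <- d * pi / 180
  rbind(c(cos(a), -sin(a), 0, 0), c(sin(a), cos(a), 0, 0),
        c(0, 0, 1, 0), c(0, 0, 0, 1)) }
Htr <- function(v) { m <- diag(4); m[1:3, 4] <- v; m }

# full-chain composition: shoulder (x/z/y axes), translate to elbow,
# elbow (x), forearm (y), translate to wrist, wrist (z, x), translate to
# grasp point; flexion-type joints negated as in the package convention
fk_oracle <- function(geometry, angles) {
  angles <- as_joint_angles(angles)
  H <- Hrx(-angles[["sfe"]]) %*% Hrz(angles[["saa"]]) %*%
    Hry(angles[["hr"]]) %*% Htr(c(0, -geometry$upper_arm, 0)) %*%
    Hrx(-angles[["efe"]]) %*% Hry(angles[["fps"]]) %*%
    Htr(c(0, -geometry$forearm, 0)) %*%
    Hrz(angles[["wru"]]) %*% Hrx(-angles[["wfe"]]) %*%
    Htr(c(0, -geometry$hand, 0))
  list(position = as.numeric(H[1:3, 4]),
       axis = as.numeric(H[1:3, 1:3] %*% c(0, -1, 0)))
}

# spectral arc length by explicit DFT sums (no fft())
sal_oracle <- function(positions, timestamps, cutoff = 20, pad_factor = 4) {
  dt <- diff(timestamps)
  fs <- 1 / stats::median(dt)
  v <- sqrt(rowSums(diff(as.matrix(positions))^2)) / dt
  nfft <- 2^(ceiling(log2(length(v))) + pad_factor)
  j <- seq_along(v) - 1
  ks <- 0:(nfft - 1)
  f <- ks * fs / nfft
  keep <- f <= cutoff
  V <- vapply(ks[keep], function(k)
    Mod(sum(v * exp(-2i * pi * j * k / nfft))), numeric(1))
  # endpoint interpolated onto the exact cutoff, as in the package
  kn <- sum(keep)
  if (f[kn] < cutoff && kn < nfft) {
    k2 <- ks[kn + 1]
    V2 <- Mod(sum(v * exp(-2i * pi * j * k2 / nfft)))
    w <- (cutoff - f[kn]) / (f[kn + 1] - f[kn])
    V <- c(V, (1 - w) * V[kn] + w * V2)
    fn <- c(f[keep] / cutoff, 1)
  } else fn <- f[keep] / cutoff
  Vn <- V / V[1]
  -sum(sqrt(diff(fn)^2 + diff(Vn)^2))
}

axis_angle_deg <- function(u, v) {
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}
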