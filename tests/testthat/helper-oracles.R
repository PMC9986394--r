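# Independent oracles used against the package's implementations.

# Median by explicit sorting (no call to stats::median).
bruteMedian <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Robust Z-scores from first principles.
bruteRobustZ <- function(x, k = 0.6745) {
  m <- bruteMedian(x)
  madRaw <- bruteMedian(abs(x - m))
  list(xMedian = m, mad = madRaw,
       rz = if (madRaw == 0) rep(NA_real_, length(x))
            else k * (x - m) / madRaw)
}

# Upper normal tail P(Z > z) by composite Simpson integration of the
# density, independent of pnorm.
simpsonNormalTail <- function(z, upper = 40, n = 20000L) {
  if (n %% 2 == 1) n <- n + 1L
  xs <- seq(z, upper, length.out = n + 1L)
  h <- xs[2] - xs[1]
  fx <- exp(-xs^2 / 2) / sqrt(2 * pi)
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  sum(w * fx) * h / 3
}

# Render one Gaussian-profiled disc directly into a matrix (for hand-built
# fields that the generator's min-separation rule would refuse).
addBlob <- function(mat, center, radius, amp) {
  sig <- radius / 2
  rr <- seq_len(nrow(mat)); cc <- seq_len(ncol(mat))
  d2 <- outer((rr - center[1])^2, (cc - center[2])^2, "+")
  mat + amp * exp(-d2 / (2 * sig^2))
}
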