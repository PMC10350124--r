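# Butterworth filter design as cascaded second-order sections (biquads).
#
# Band-pass filters for narrow high-frequency channels are numerically fragile
# as a single transfer function; the cascade form keeps pole clusters separate.
# Design route: analog Butterworth prototype -> lowpass/bandpass frequency
# transform -> bilinear transform -> conjugate-pair grouping into biquads.

butter_prototype_poles <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

bilinear_zpk <- function(z, p, k, fs) {
  fs2 <- 2 * fs
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  kd <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  # analog zeros at infinity map to z = -1
  zd <- c(zd, rep(-1 + 0i, length(p) - length(z)))
  list(z = zd, p = pd, k = kd)
}

# Split a set of roots (closed under conjugation) into conjugate pairs and reals
split_conjugates <- function(r, tol = 1e-8) {
  is_real <- abs(Im(r)) < tol * pmax(1, abs(r))
  reals <- sort(Re(r[is_real]))
  cplx <- r[!is_real]
  cplx <- cplx[Im(cplx) > 0] # keep one of each conjugate pair
  list(pairs = cplx, reals = reals)
}

# Build biquad coefficient matrix [b0 b1 b2 a0 a1 a2] per row from digital zpk
zpk_to_sos <- function(z, p, k) {
  pz <- split_conjugates(p)
  zz <- split_conjugates(z)

  pole_sections <- list()
  for (pp in pz$pairs) {
    pole_sections[[length(pole_sections) + 1]] <- c(-2 * Re(pp), abs(pp)^2)
  }
  reals <- pz$reals
  while (length(reals) >= 2) {
    pole_sections[[length(pole_sections) + 1]] <-
      c(-(reals[1] + reals[2]), reals[1] * reals[2])
    reals <- reals[-(1:2)]
  }
  if (length(reals) == 1) {
    pole_sections[[length(pole_sections) + 1]] <- c(-reals[1], 0)
  }

  # flatten zeros into a queue of real roots (complex pairs expanded lazily)
  zero_queue <- list()
  for (zp in zz$pairs) zero_queue[[length(zero_queue) + 1]] <- c(-2 * Re(zp), abs(zp)^2)
  zreals <- zz$reals
  while (length(zreals) >= 2) {
    zero_queue[[length(zero_queue) + 1]] <- c(-(zreals[1] + zreals[2]), zreals[1] * zreals[2])
    zreals <- zreals[-(1:2)]
  }
  if (length(zreals) == 1) zero_queue[[length(zero_queue) + 1]] <- c(-zreals[1], 0)

  n_sec <- length(pole_sections)
  sos <- matrix(0, n_sec, 6)
  for (i in seq_len(n_sec)) {
    a <- pole_sections[[i]]
    b <- if (i <= length(zero_queue)) c(1, zero_queue[[i]]) else c(1, 0, 0)
    sos[i, ] <- c(b, 1, a)
  }
  sos[1, 1:3] <- sos[1, 1:3] * k
  sos
}

#' @keywords internal
butter_lowpass_sos <- function(order, fc, fs) {
  stopifnot(order >= 1, fc > 0, fc < fs / 2)
  wc <- 2 * fs * tan(pi * fc / fs)
  p <- butter_prototype_poles(order) * wc
  d <- bilinear_zpk(complex(0), p, wc^order, fs)
  zpk_to_sos(d$z, d$p, Re(d$k))
}

#' @keywords internal
butter_bandpass_sos <- function(n_poles, f_lo, f_hi, fs) {
  stopifnot(n_poles >= 2, n_poles %% 2 == 0, f_lo > 0, f_lo < f_hi, f_hi < fs / 2)
  m <- n_poles / 2 # analog prototype order; the band transform doubles it
  w1 <- 2 * fs * tan(pi * f_lo / fs)
  w2 <- 2 * fs * tan(pi * f_hi / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  proto <- butter_prototype_poles(m)
  # lowpass-to-bandpass: each prototype pole yields the roots of
  # s^2 - (p*bw) s + w0^2
  p <- unlist(lapply(proto, function(pp) {
    disc <- sqrt(as.complex((pp * bw)^2 - 4 * w0^2))
    c((pp * bw + disc) / 2, (pp * bw - disc) / 2)
  }))
  z <- rep(0 + 0i, m)
  d <- bilinear_zpk(z, p, bw^m, fs)
  zpk_to_sos(d$z, d$p, Re(d$k))
}

# Causal cascade filtering through the biquads
sos_filter <- function(sos, x) {
  for (i in seq_len(nrow(sos))) {
    x <- signal::filter(sos[i, 1:3], sos[i, 4:6], x)
  }
  as.numeric(x)
}

# Complex frequency response of the cascade at frequencies f (Hz)
sos_response <- function(sos, f, fs) {
  z1 <- exp(-2i * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (i in seq_len(nrow(sos))) {
    b <- sos[i, 1:3]
    a <- sos[i, 4:6]
    h <- h * (b[1] + b[2] * z1 + b[3] * z1^2) / (a[1] + a[2] * z1 + a[3] * z1^2)
  }
  h
}
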