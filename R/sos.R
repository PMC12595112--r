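# Butterworth design as cascaded second-order sections (biquads).
#
# High-order transfer-function polynomials are numerically fragile at the
# extremes the clinical parameter grid allows (e.g. order 10 band-pass with a
# 0.1 kHz lower edge at 44.1 kHz), so filters are designed from the analog
# prototype poles and bilinear-transformed pole by pole; each biquad is
# applied separately. Each section is order <= 2 and unconditionally stable
# in double precision.

# analog Butterworth prototype poles (left half plane, |p| = 1)
butter_prototype_poles <- function(order) {
  k <- seq_len(order)
  exp(1i * pi * (2 * k + order - 1) / (2 * order))
}

# Design a Butterworth filter as second-order sections.
# cutoff_hz: one edge for low/high, c(lower, upper) for pass.
# Returns list(sections = list(list(b = c(b0,b1,b2), a = c(1,a1,a2))), gain).
butter_sos <- function(order, cutoff_hz, rate, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  stopifnot(order >= 1, order == round(order))
  nyq <- rate / 2
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= nyq)) {
    stop(sprintf("cutoff must lie strictly inside (0, %g) Hz", nyq), call. = FALSE)
  }
  p <- butter_prototype_poles(order)

  if (type == "low") {
    wc <- tan(pi * cutoff_hz[1] / rate)
    s_poles <- wc * p
    zero_at <- -1        # digital zeros all at z = -1
    ref_z <- 1 + 0i      # unity gain at DC
  } else if (type == "high") {
    wc <- tan(pi * cutoff_hz[1] / rate)
    s_poles <- wc / p
    zero_at <- 1         # digital zeros all at z = +1
    ref_z <- -1 + 0i     # unity gain at Nyquist
  } else {
    if (length(cutoff_hz) != 2 || cutoff_hz[1] >= cutoff_hz[2]) {
      stop("band-pass needs cutoff_hz = c(lower, upper) with lower < upper",
           call. = FALSE)
    }
    w1 <- tan(pi * cutoff_hz[1] / rate)
    w2 <- tan(pi * cutoff_hz[2] / rate)
    bw <- w2 - w1
    w0sq <- w1 * w2
    # s_lp -> (s^2 + w0^2) / (bw * s): each prototype pole becomes two poles
    s_poles <- unlist(lapply(p, function(pk) {
      disc <- sqrt((bw * pk)^2 - 4 * w0sq + 0i)
      c((bw * pk + disc) / 2, (bw * pk - disc) / 2)
    }))
    zero_at <- NA        # n zeros at z = 1 and n at z = -1: one (1 - z^-2) each
    ref_z <- exp(2i * atan(sqrt(w0sq)))  # unity gain at warped center
  }

  z_poles <- (1 + s_poles) / (1 - s_poles)  # bilinear transform

  tol <- 1e-10
  cplx <- z_poles[Im(z_poles) > tol]
  real_p <- Re(z_poles[abs(Im(z_poles)) <= tol])

  sections <- list()
  for (zp in cplx) {
    sections[[length(sections) + 1L]] <-
      list(a = c(1, -2 * Re(zp), Mod(zp)^2))
  }
  while (length(real_p) >= 2) {
    sections[[length(sections) + 1L]] <-
      list(a = c(1, -(real_p[1] + real_p[2]), real_p[1] * real_p[2]))
    real_p <- real_p[-(1:2)]
  }
  first_order <- length(real_p) == 1

  if (is.na(zero_at)) {
    numer <- c(1, 0, -1)                      # (1 - z^-1)(1 + z^-1)
  } else {
    numer <- c(1, -2 * zero_at, 1)            # (1 -/+ z^-1)^2
  }
  for (i in seq_along(sections)) sections[[i]]$b <- numer
  if (first_order) {
    sections[[length(sections) + 1L]] <- list(
      a = c(1, -real_p[1], 0),
      b = if (is.na(zero_at)) c(1, 0, -1) else c(1, -zero_at, 0)
    )
  }

  sos <- list(sections = sections, gain = 1)
  g <- abs(sos_response(sos, ref_z = ref_z))
  sos$gain <- 1 / g
  sos
}

# complex response at digital frequencies (freq_hz at `rate`), or at a raw z
sos_response <- function(sos, freq_hz = NULL, rate = NULL, ref_z = NULL) {
  z <- if (is.null(ref_z)) exp(2i * pi * freq_hz / rate) else ref_z
  h <- rep(sos$gain + 0i, length(z))
  zi1 <- 1 / z
  zi2 <- zi1^2
  for (s in sos$sections) {
    h <- h * (s$b[1] + s$b[2] * zi1 + s$b[3] * zi2) /
      (s$a[1] + s$a[2] * zi1 + s$a[3] * zi2)
  }
  h
}

# causal (single-pass) application of an SOS cascade
sos_filter <- function(x, sos) {
  for (s in sos$sections) {
    x <- as.numeric(signal::filter(s$b, s$a, x))
  }
  x * sos$gain
}
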