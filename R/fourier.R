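# Shared Fourier conventions (used by the simulator, phase retrieval and the
# gridding reconstructor):
#   - spatial frequency u is measured in cycles per meter;
#   - the Laplacian maps to -4*pi^2*|u|^2;
#   - Fourier-domain filters act on frames mirror-padded to twice their size
#     (half-sample symmetric extension) and are cropped back afterwards, so a
#     filter and its exact inverse compose to the identity on the frame.

# DFT sample frequencies, numpy-style: 0, 1, ..., ceil(n/2)-1, -floor(n/2), ..., -1
# divided by n*d.
fft_freq <- function(n, d = 1) {
  k <- c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

# Half-sample symmetric (mirror) extension of a matrix to twice each dimension.
mirror_pad <- function(x) {
  x <- rbind(x, x[nrow(x):1, , drop = FALSE])
  cbind(x, x[, ncol(x):1, drop = FALSE])
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Apply a Fourier-domain transfer function H(|u|^2) to a frame (matrix; a
# vector is treated as an n x 1 frame).  `transfer` receives |u|^2 in
# (cycles/m)^2 and must return a (possibly complex) multiplier of the same
# shape.  With pad = TRUE the frame is mirror-padded to twice its size first;
# real input yields real output.
fourier_filter <- function(frame, transfer, pixel_m, pad = TRUE) {
  vec <- is.null(dim(frame))
  if (vec) frame <- matrix(frame, ncol = 1)
  n1 <- nrow(frame); n2 <- ncol(frame)
  f <- if (pad) mirror_pad(frame) else frame
  u1 <- fft_freq(nrow(f), pixel_m)
  u2 <- if (ncol(f) > 1) fft_freq(ncol(f), pixel_m) else 0
  usq <- outer(u1^2, u2^2, `+`)
  H <- transfer(usq)
  out <- ifft2(fft2(f) * H)
  out <- out[seq_len(n1), seq_len(n2), drop = FALSE]
  if (is.double(frame)) out <- Re(out)
  if (vec) out <- drop(out)
  out
}

# Deterministic per-frame substream seed derived from one master seed, so that
# frame i's noise does not depend on how many frames are simulated.
frame_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) %% 2147480000 + 100003 * i) %% 2147483629)
}
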