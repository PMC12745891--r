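# Regridding reconstruction: Kaiser-Bessel convolution gridding with ramp
# density compensation, oversampled FFT and deapodization.

# Kaiser-Bessel parameters: kernel width 4 grid samples, oversampling 1.5,
# shape parameter from the standard minimum-aliasing-error prescription.
kb_params <- function(width = 4, osf = 1.5) {
  beta <- pi * sqrt((width / osf)^2 * (osf - 0.5)^2 - 0.8)
  list(width = width, osf = osf, beta = beta)
}

# Fourier transform of the (unnormalised) KB kernel at frequency f in
# cycles per grid sample; used for deapodization.
kb_ft <- function(f, kb) {
  z2 <- kb$beta^2 - (pi * kb$width * f)^2
  out <- numeric(length(z2))
  pos <- z2 > 0
  zp <- sqrt(z2[pos])
  out[pos] <- sinh(zp) / zp
  zn <- sqrt(-z2[!pos])
  out[!pos] <- ifelse(zn == 0, 1, sin(zn) / zn)
  kb$width * out
}

fftshift2 <- function(m) {
  G <- nrow(m)
  h <- G %/% 2
  m[c((h + 1):G, 1:h), c((h + 1):G, 1:h)]
}

# Reconstruct one 2D image plane from radial k-space samples.
#
# kr: readout offsets in cycles/mm (length nr, uniform, centred on 0)
# theta: spoke angles (length na)
# smat: complex samples, nr x na
# N: output matrix size; fov: mm
# Returns an N x N complex image in object units (voxel centres at
# (i - 0.5) * vox - fov/2).
recon_plane_radial <- function(smat, kr, theta, N, fov, kb = kb_params()) {
  na <- length(theta)
  nr <- length(kr)
  dk <- 1 / fov
  G <- as.integer(round(N * kb$osf))
  dkg <- 1 / (fov * kb$osf)
  # ramp density compensation: annular area element per sample; the DC
  # samples (one per spoke) share the central disk of radius dk/2
  w <- abs(kr) * dk * pi / na
  w[abs(kr) < dk / 4] <- pi * (dk / 2)^2 / (4 * na)
  sw <- smat * w
  kx <- outer(kr, cos(theta)) / dkg
  ky <- outer(kr, sin(theta)) / dkg
  g <- grid_radial_cpp(as.numeric(kx), as.numeric(ky), as.complex(sw),
                       G, kb$width, kb$beta)
  img <- fftshift2(stats::fft(g, inverse = TRUE))
  # image lattice x = n * vox, n centred; callers align voxel centres
  # ((i - 0.5) * vox - fov/2) by pre-multiplying samples with a half-voxel
  # phase ramp
  crop <- (G - N) %/% 2
  img <- img[(crop + 1):(crop + N), (crop + 1):(crop + N)]
  nidx <- seq_len(N) - (N %/% 2 + 1L)
  deap <- kb_ft(nidx / G, kb)
  img <- img / outer(deap, deap)
  img
}
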