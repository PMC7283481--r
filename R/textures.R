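# Procedural texture constants for the synthetic-slide generator.
#
# Every tissue class is rendered as a mean RGB colour plus two shared
# zero-mean Gaussian noise fields: a fine field (wavelength ~3 px) that
# gives within-tile texture, and a coarse field (wavelength ~96 px) that
# varies slowly across the slide and therefore moves whole-tile colour
# statistics -- emulating staining / fixation variation. Both amplitudes
# scale with the cohort's `texture_noise_sd`.
#
# The confounder (necrosis/inflammation) mean colour deliberately sits close
# to the carcinoma mean, at a distance comparable to the coarse-field sd: at
# the default noise level the two tissues overlap partially in appearance.
# Necrotic and inflamed tissue resembling carcinoma stroma is precisely the
# label-noise mechanism that motivates weak supervision, and without the
# overlap a region-supervised baseline would not degrade. The same
# confounder parameters are used inside carcinoma polygons and on
# non-neoplastic slides, so its marginal pixel distribution is identical in
# the two contexts.

.texture_class_codes <- c(background = 0L, normal_tissue = 1L,
                          carcinoma_tissue = 2L, confounder_tissue = 3L)

.texture_params <- list(
  background = list(mean = c(0.965, 0.960, 0.970), fine = 0.15, coarse = 0),
  normal     = list(mean = c(0.850, 0.660, 0.800), fine = 1.00, coarse = 1),
  carcinoma  = list(mean = c(0.460, 0.300, 0.560), fine = 1.00, coarse = 1),
  confounder = list(mean = c(0.600, 0.440, 0.504), fine = 1.00, coarse = 1)
)

# Coarse-field amplitude relative to texture_noise_sd, wavelength (px), and
# the downscaling factor at which the coarse field is synthesised before
# block upscaling (pure speed: the field is smooth at this scale).
# stain_gain scales a per-slide, per-channel constant offset applied to all
# tissue pixels, emulating slide-to-slide staining variation.
.texture_coarse_gain <- 1.2
.texture_coarse_wavelength <- 96
.texture_coarse_res <- 8L
.texture_stain_gain <- 0.6

# Heatmap rendering constants (see render_heatmap).
.heatmap_colours <- c("#0571b0", "#92c5de", "#f7f7f7", "#f4a582", "#ca0020")
.heatmap_alpha <- 0.55

# Unit-sd smooth Gaussian random field via FFT low-pass filtering of white
# noise. `wavelength` is the e-folding scale of the Gaussian transfer
# function in pixels. Draws from the current RNG stream.
gaussian_field <- function(height, width, wavelength) {
  z <- matrix(stats::rnorm(height * width), nrow = height)
  if (wavelength <= 1) return(z)
  fy <- c(seq(0, floor(height / 2)), seq(-ceiling(height / 2) + 1, -1)) / height
  fx <- c(seq(0, floor(width / 2)), seq(-ceiling(width / 2) + 1, -1)) / width
  w <- exp(-2 * pi^2 * wavelength^2 * outer(fy^2, fx^2, `+`))
  w[1, 1] <- 0  # drop the DC mode: the field is zero-mean by construction
  f <- Re(stats::fft(stats::fft(z) * w, inverse = TRUE)) / (height * width)
  s <- stats::sd(f)
  if (s < .Machine$double.eps) return(matrix(0, height, width))
  f / s
}

# Coarse field synthesised at 1/.texture_coarse_res scale, block-upscaled;
# the 96-px-wavelength field is smooth at that scale so the replication
# step is invisible relative to tile-level statistics.
coarse_field <- function(height, width) {
  f <- .texture_coarse_res
  hs <- ceiling(height / f); ws <- ceiling(width / f)
  small <- gaussian_field(hs, ws, .texture_coarse_wavelength / f)
  small[rep(seq_len(hs), each = f)[seq_len(height)],
        rep(seq_len(ws), each = f)[seq_len(width)], drop = FALSE]
}
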