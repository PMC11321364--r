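#' Light source specification
#'
#' Gaussian beam entering the proximal face along +z. The `radius` is the
#' 1/e^2 intensity radius, so the Gaussian position SD is `radius / 2`.
#'
#' @param radius Beam 1/e^2 radius in mm.
#' @return A `source_spec` list.
#' @export
source_spec <- function(radius = 1.0) {
  stopifnot(radius > 0)
  structure(list(radius = radius, sigma = radius / 2), class = "source_spec")
}

#' Detector specification
#'
#' Circular aperture on the distal face, coaxial with the source. The
#' default 90 degree acceptance half-angle accepts every forward exit within
#' the radius.
#'
#' @param radius Detector radius in mm (`Inf` accepts the whole face).
#' @param acceptance_half_angle Acceptance half-angle in degrees, in (0, 90].
#' @return A `detector_spec` list.
#' @export
detector_spec <- function(radius = 1.0, acceptance_half_angle = 90) {
  stopifnot(radius > 0, acceptance_half_angle > 0,
            acceptance_half_angle <= 90)
  structure(list(radius = radius,
                 acceptance_half_angle = acceptance_half_angle,
                 cos_min = cos(acceptance_half_angle * pi / 180)),
            class = "detector_spec")
}

#' Transport run configuration
#'
#' @param target_detected Stop once this many photon packets have been
#'   detected (checked at batch boundaries).
#' @param max_launched Hard cap on launched packets; exceeding it before the
#'   target is reached raises a budget-exhausted error carrying the partial
#'   tally.
#' @param roulette_threshold Weight below which Russian roulette is played.
#' @param roulette_survival Survival probability of the roulette.
#' @param seed Integer seed for the counter-based generator.
#' @param batch_size Packets per RNG substream; the tally is reproducible
#'   for a fixed `(seed, batch_size)` regardless of scheduling.
#' @param importance_spacing Spacing (mm) of importance planes for
#'   split/roulette variance reduction towards the detector; `Inf` (the
#'   default) disables it. Estimates stay unbiased either way; splitting
#'   raises the rate at which detection events accumulate in thick,
#'   strongly attenuating stacks.
#' @return A `run_config` list.
#' @export
run_config <- function(target_detected = 1e6, max_launched = 1e9,
                       roulette_threshold = 1e-4, roulette_survival = 0.1,
                       seed = 1, batch_size = 1e4,
                       importance_spacing = Inf) {
  stopifnot(target_detected >= 1, roulette_survival > 0,
            roulette_survival <= 1, batch_size >= 1,
            max_launched >= batch_size, importance_spacing > 0)
  structure(list(target_detected = target_detected,
                 max_launched = max_launched,
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival,
                 seed = seed, batch_size = batch_size,
                 importance_spacing = importance_spacing),
            class = "run_config")
}

#' Specular reflectance at normal incidence
#'
#' `((n1 - n2) / (n1 + n2))^2`; the initial packet weight is one minus this.
#'
#' @param n_ambient,n_tissue Refractive indices on either side.
#' @return Reflected fraction.
#' @export
#' @examples
#' specular_reflectance(1.0, 1.4)  # 0.027778
specular_reflectance <- function(n_ambient, n_tissue) {
  stopifnot(n_ambient >= 1, n_tissue >= 1)
  cpp_specular_reflectance(n_ambient, n_tissue)
}

#' Unpolarized Fresnel reflectance
#'
#' Average of the s- and p-polarized Fresnel power reflectances; returns 1
#' beyond the critical angle.
#'
#' @param n_in,n_out Refractive indices of the incident and far media.
#' @param cos_i Cosine of the incidence angle.
#' @return Reflected fraction in `[0, 1]`.
#' @export
fresnel_reflectance <- function(n_in, n_out, cos_i) {
  stopifnot(cos_i >= -1, cos_i <= 1)
  cpp_fresnel_unpolarized(n_in, n_out, cos_i)
}

#' Sample exponential free paths
#'
#' `s = -log(u) / mu_t` with `u ~ U(0, 1]`, the hop length of weighted
#' transport.
#'
#' @param mu_t Total attenuation coefficient (mm^-1), positive.
#' @param n Number of draws.
#' @param seed,stream RNG substream selectors.
#' @return Numeric vector of path lengths (mm).
#' @export
sample_free_path <- function(mu_t, n = 1, seed = 1, stream = 0) {
  stopifnot(mu_t > 0, n >= 1)
  cpp_sample_free_path(mu_t, as.integer(n), seed, stream)
}

#' Sample Henyey-Greenstein deflection cosines
#'
#' Inverse-CDF sampling of the Henyey-Greenstein phase function; the mean of
#' the draws converges to the anisotropy `g`.
#'
#' @param g Anisotropy factor in `[-1, 1]`.
#' @param n Number of draws.
#' @param seed,stream RNG substream selectors.
#' @return Numeric vector of deflection cosines.
#' @export
sample_hg_deflection <- function(g, n = 1, seed = 1, stream = 0) {
  stopifnot(abs(g) <= 1, n >= 1)
  cpp_sample_hg(g, as.integer(n), seed, stream)
}

#' Rotate a direction by a scattering deflection
#'
#' @param direction Unit 3-vector.
#' @param cos_theta Deflection cosine.
#' @param phi Azimuthal angle (radians).
#' @return Rotated unit 3-vector.
#' @export
update_direction <- function(direction, cos_theta, phi) {
  stopifnot(length(direction) == 3,
            abs(sqrt(sum(direction^2)) - 1) < 1e-9,
            abs(cos_theta) <= 1)
  cpp_update_direction(as.numeric(direction), cos_theta, phi)
}

#' Sample Gaussian source entry positions
#'
#' @param source A [source_spec()].
#' @param n Number of draws.
#' @param seed,stream RNG substream selectors.
#' @return An `n x 2` matrix of transverse (x, y) positions in mm.
#' @export
sample_source_positions <- function(source = source_spec(), n = 1,
                                    seed = 1, stream = 0) {
  cpp_sample_gaussian_source(source$sigma, as.integer(n), seed, stream)
}

# internal: pull the per-layer coefficient vectors of one wavelength
stack_arrays <- function(stack, wavelength) {
  rows <- stack[stack$wavelength == wavelength, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("stack has no optical properties at ", wavelength, " nm",
         call. = FALSE)
  }
  rows <- rows[order(rows$index), , drop = FALSE]
  list(
    z_bounds = c(0, cumsum(rows$thickness)),
    mu_a = rows$mu_a, mu_s = rows$mu_s, g = rows$g
  )
}

#' Run the photon-transport simulation
#'
#' Launches seeded batches of weighted photon packets through a
#' [build_finger_model()] stack (or phantom) until the target number of
#' detected packets is reached, and returns the weight bookkeeping. The
#' tally satisfies exact conservation: specular + absorbed + detected +
#' escaped + residual = launched.
#'
#' @param stack A `tissue_stack`.
#' @param source A [source_spec()].
#' @param detector A [detector_spec()].
#' @param config A [run_config()].
#' @param wavelength Which wavelength of the stack to transport (nm);
#'   default the first one present.
#' @param stream_base First RNG substream index; condition grids give each
#'   condition a disjoint base so streams never collide.
#' @return An `mc_tally` list: `launched`, `specular_weight`,
#'   `absorbed_weight`, `detected_weight`, `detected_count`,
#'   `escaped_weight`, `residual_weight`, `batches`, plus run metadata.
#' @export
#' @examples
#' ph <- make_homogeneous_phantom(1, 0, 0, 1)
#' tl <- run_simulation(ph, detector = detector_spec(radius = 1e6),
#'                      config = run_config(target_detected = 100, seed = 7))
#' transmittance(tl)  # ~ exp(-1)
run_simulation <- function(stack, source = source_spec(),
                           detector = detector_spec(),
                           config = run_config(),
                           wavelength = NULL,
                           stream_base = 0) {
  stopifnot(inherits(stack, "tissue_stack"),
            inherits(source, "source_spec"),
            inherits(detector, "detector_spec"),
            inherits(config, "run_config"))
  if (is.null(wavelength)) wavelength <- stack$wavelength[1]
  arr <- stack_arrays(stack, wavelength)
  bone <- attr(stack, "bone")
  has_bone <- !is.null(bone)
  wl_key <- as.character(wavelength)
  bone_layer <- if (has_bone) {
    rows <- stack[stack$wavelength == wavelength, ]
    which(rows$layer[order(rows$index)] == bone$layer)[1] - 1L
  } else -1L

  det_radius <- if (is.infinite(detector$radius)) 1e12 else detector$radius
  z_max <- attr(stack, "total_thickness")
  planes <- if (is.finite(config$importance_spacing) &&
                config$importance_spacing < z_max) {
    seq(config$importance_spacing, z_max - config$importance_spacing / 2,
        by = config$importance_spacing)
  } else numeric()
  res <- cpp_run_mc(
    arr$z_bounds, arr$mu_a, arr$mu_s, arr$g,
    has_bone, as.integer(bone_layer),
    if (has_bone) bone$center_z else 0,
    if (has_bone) bone$radius else 0,
    if (has_bone) unname(bone$mu_a[wl_key]) else 0,
    if (has_bone) unname(bone$mu_s[wl_key]) else 0,
    if (has_bone) unname(bone$g[wl_key]) else 0,
    attr(stack, "refractive_index"), attr(stack, "ambient_index"),
    source$sigma, det_radius,
    # 90 degrees accepts the full forward hemisphere
    if (detector$acceptance_half_angle >= 90) 0 else detector$cos_min,
    attr(stack, "lateral_halfwidth") %||% Inf,
    planes,
    config$target_detected, config$max_launched, config$batch_size,
    config$roulette_threshold, config$roulette_survival,
    config$seed, stream_base)

  tally <- structure(
    c(res[setdiff(names(res), "budget_exhausted")],
      list(wavelength = wavelength, seed = config$seed,
           stream_base = stream_base, batch_size = config$batch_size)),
    class = "mc_tally")

  if (isTRUE(res$budget_exhausted)) {
    cnd <- structure(
      class = c("pulseoxmc_budget_exhausted", "error", "condition"),
      list(message = sprintf(
        "photon budget exhausted: %d detected of %d target after %d launched",
        as.integer(res$detected_count), as.integer(config$target_detected),
        as.integer(res$launched)),
        call = sys.call(-1), tally = tally))
    stop(cnd)
  }
  tally
}

#' Transmittance of a tally
#'
#' Ratio of detected output intensity to incident intensity (launched
#' packets times unit initial weight).
#'
#' @param tally An `mc_tally` from [run_simulation()].
#' @return Transmitted fraction.
#' @export
transmittance <- function(tally) {
  stopifnot(inherits(tally, "mc_tally"))
  if (tally$launched <= 0) stop("no photons launched", call. = FALSE)
  tally$detected_weight / tally$launched
}

#' @export
print.mc_tally <- function(x, ...) {
  cat("<mc_tally>", x$launched, "launched,",
      x$detected_count, "detected; transmittance",
      signif(x$detected_weight / x$launched, 4), "\n")
  invisible(x)
}

#' Weight-conservation residual of a tally
#'
#' Relative gap between launched weight and the sum of all tallied sinks;
#' zero up to floating-point accumulation for a correct transport run.
#'
#' @param tally An `mc_tally`.
#' @return Signed relative conservation error.
#' @export
conservation_error <- function(tally) {
  total <- tally$specular_weight + tally$absorbed_weight +
    tally$detected_weight + tally$escaped_weight + tally$residual_weight
  (total - tally$launched) / tally$launched
}
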