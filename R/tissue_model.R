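#' Epidermal absorption coefficient from melanosome content
#'
#' Absorption of the melanin-bearing epidermis: a melanin power law weighted
#' by the melanosome volume fraction, plus water, plus the pigment-free
#' tissue baseline for the remaining volume,
#' \deqn{\mu_a = v_{mel}\,6.6\times10^{10}\lambda^{-3.33}
#'       + \mu_{a,w} v_w + (1 - v_{mel} - v_w)\,7.84\times10^{7}
#'       \lambda^{-3.255}.}
#'
#' @param vmel Melanosome volume fraction of the epidermis.
#' @param vw Water volume fraction.
#' @param wavelength Wavelength in nm (vectorised).
#' @param constants A [chromophore_constants()] object.
#' @return Absorption coefficient in mm^-1.
#' @export
#' @examples
#' epidermis_mu_a(0.0255, 0.20, 660)  # light skin, red
epidermis_mu_a <- function(vmel, vw, wavelength,
                           constants = chromophore_constants()) {
  if (any(vmel < 0) || any(vw < 0) || any(vmel + vw > 1)) {
    stop("volume fractions must be nonnegative with vmel + vw <= 1",
         call. = FALSE)
  }
  stopifnot(all(wavelength > 0))
  key <- as.character(wavelength)
  mu_w <- unname(constants$mu_a_water[key])
  if (anyNA(mu_w)) stop("water absorption undefined at this wavelength",
                        call. = FALSE)
  vmel * constants$melanin_prefactor * wavelength^constants$melanin_exponent +
    mu_w * vw +
    (1 - vmel - vw) * constants$baseline_prefactor *
      wavelength^constants$baseline_exponent
}

#' Dermal absorption coefficient with arterial and venous blood
#'
#' Four-term absorption of a dermal sublayer: arterial blood at saturation
#' `sat_a`, venous blood at `sat_v`, water, and the baseline power law for
#' the residual volume,
#' \deqn{\mu_a = v_A(s_A \mu_{HbO_2} + (1-s_A)\mu_{HHb})
#'   + v_V(s_V \mu_{HbO_2} + (1-s_V)\mu_{HHb})
#'   + \mu_{a,w} v_w + (1 - v_A - v_V - v_w)\,7.84\times10^{7}
#'   \lambda^{-3.255}.}
#'
#' When the pulsatile doubling drives `v_A + v_V + v_w` above one (the
#' systolic upper blood net), the baseline term is clamped at zero rather
#' than contributing negative absorption.
#'
#' @param state A [hemodynamic_state()] (supplies `sat_a`, `sat_v`).
#' @param v_arterial,v_venous Arterial and venous blood volume fractions.
#' @param vw Water volume fraction.
#' @param wavelength Wavelength in nm.
#' @param constants A [chromophore_constants()].
#' @return Absorption coefficient in mm^-1.
#' @export
dermis_mu_a <- function(state, v_arterial, v_venous, vw, wavelength,
                        constants = chromophore_constants()) {
  if (any(v_arterial < 0) || any(v_venous < 0) || any(vw < 0) ||
      any(v_arterial + v_venous > 1) || any(vw > 1)) {
    stop("volume fractions must be nonnegative fractions", call. = FALSE)
  }
  stopifnot(state$sat_a >= 0, state$sat_a <= 1, state$sat_v >= 0,
            state$sat_v <= 1)
  key <- as.character(wavelength)
  hbo <- unname(constants$mu_a_hbo2[key])
  hhb <- unname(constants$mu_a_hhb[key])
  mu_w <- unname(constants$mu_a_water[key])
  if (anyNA(c(hbo, hhb, mu_w))) {
    stop("chromophore constants undefined at this wavelength", call. = FALSE)
  }
  # the systolic upper blood net reaches vA + vV + vw = 1.2; the baseline
  # term covers only whatever volume is actually left, never negative
  residual <- pmax(0, 1 - v_arterial - v_venous - vw)
  v_arterial * (state$sat_a * hbo + (1 - state$sat_a) * hhb) +
    v_venous * (state$sat_v * hbo + (1 - state$sat_v) * hhb) +
    mu_w * vw +
    residual * constants$baseline_prefactor *
      wavelength^constants$baseline_exponent
}

#' Split pulsatile blood volume between compartments
#'
#' The diastolic blood volume of a dermal sublayer is divided equally between
#' arterial and venous blood; systole doubles the total volume, again split
#' equally.
#'
#' @param vb_diastolic Diastolic total blood volume fraction.
#' @param phase `"diastole"` or `"systole"`.
#' @return Named numeric `c(v_arterial = , v_venous = )`.
#' @export
#' @examples
#' pulsatile_blood_volumes(0.30, "systole")   # doubled, split equally
pulsatile_blood_volumes <- function(vb_diastolic,
                                    phase = c("diastole", "systole")) {
  phase <- match.arg(phase)
  if (vb_diastolic < 0 || vb_diastolic > 0.5) {
    stop("vb_diastolic must lie in [0, 0.5]", call. = FALSE)
  }
  total <- if (phase == "systole") 2 * vb_diastolic else vb_diastolic
  if (total > 1) stop("systolic blood volume exceeds unity", call. = FALSE)
  c(v_arterial = total / 2, v_venous = total / 2)
}

#' Build the layered finger model
#'
#' Assembles the 15-region transmittance-mode finger: six skin sublayers,
#' fat, muscle with an embedded bone cylinder, fat, and the six skin
#' sublayers mirrored on the detector side. Both skin stacks receive the same
#' pigmentation. Epidermal absorption comes from [epidermis_mu_a()], the four
#' dermal sublayers from [dermis_mu_a()] with their tabulated blood and water
#' fractions; stratum corneum, fat, muscle and bone carry fixed tabulated
#' coefficients. Muscle thickness is the remainder that brings the stack to
#' exactly `total_thickness`.
#'
#' @param phenotype A single row of [skin_phenotypes()] or a label
#'   (`"light"`, `"moderate"`, `"dark"`).
#' @param state A [hemodynamic_state()].
#' @param constants A [chromophore_constants()].
#' @param wavelengths Wavelengths (nm) to resolve; default both oximetry
#'   wavelengths.
#' @param total_thickness Source-detector separation in mm (finger
#'   thickness), default 13.
#' @param layer_overrides Optional tibble with columns `layer` and any of
#'   `thickness`, `vb`, `vw` to override defaults.
#' @param bone_radius Radius (mm) of the bone cylinder embedded in the
#'   muscle slab, axis perpendicular to the optical axis.
#' @param lateral_halfwidth Lateral half-extent of the finger (mm) from the
#'   optical axis; packets wandering beyond it leave through the side faces
#'   and are tallied as escaped. Defaults to half the finger thickness
#'   (the finger is about as wide as it is thick); `Inf` gives laterally
#'   infinite slabs.
#' @param refractive_index Tissue refractive index (all layers share it;
#'   internal interfaces are index-matched).
#' @param ambient_index Refractive index of the surrounding air.
#' @return A `tissue_stack`: a tibble of layers (one row per layer x
#'   wavelength) with attributes `bone`, `total_thickness`,
#'   `refractive_index`, `ambient_index`.
#' @export
#' @examples
#' stack <- build_finger_model("dark", hemodynamic_state(0.70, "diastole"))
#' attr(stack, "total_thickness")
build_finger_model <- function(phenotype,
                               state,
                               constants = chromophore_constants(),
                               wavelengths = c(660, 940),
                               total_thickness = 13,
                               layer_overrides = NULL,
                               bone_radius = 2,
                               lateral_halfwidth = total_thickness / 2,
                               refractive_index = 1.4,
                               ambient_index = 1.0) {
  if (is.character(phenotype)) phenotype <- skin_phenotypes(phenotype)
  stopifnot(nrow(phenotype) == 1, inherits(state, "hemodynamic_state"))
  vmel <- phenotype$vmel

  geom <- default_layer_constants()
  if (!is.null(layer_overrides)) {
    bad <- setdiff(layer_overrides$layer, geom$layer)
    if (length(bad)) stop("unknown layer name(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (col in intersect(names(layer_overrides), c("thickness", "vb", "vw"))) {
      idx <- match(layer_overrides$layer, geom$layer)
      geom[[col]][idx] <- ifelse(is.na(layer_overrides[[col]]),
                                 geom[[col]][idx], layer_overrides[[col]])
    }
  }

  skin_names <- c("stratum_corneum", "epidermis", "papillary_dermis",
                  "upper_blood_net", "reticular_dermis", "deep_blood_net")
  side <- geom[match(c(skin_names, "fat"), geom$layer), ]
  side_thick <- sum(side$thickness)
  muscle_thick <- total_thickness - 2 * side_thick
  if (muscle_thick <= 0) {
    stop("layer thicknesses exceed the total finger thickness", call. = FALSE)
  }
  if (bone_radius >= muscle_thick / 2) {
    stop("bone cylinder is not contained inside the muscle slab",
         call. = FALSE)
  }

  order_names <- c(skin_names, "fat", "muscle", "fat", rev(skin_names))
  thick <- c(side$thickness[1:6], side$thickness[7], muscle_thick,
             side$thickness[7], rev(side$thickness[1:6]))

  layer_tbl <- tibble::tibble(
    index = seq_along(order_names),
    layer = order_names,
    thickness = thick
  )
  layer_tbl$vb <- geom$vb[match(layer_tbl$layer, geom$layer)]
  layer_tbl$vw <- geom$vw[match(layer_tbl$layer, geom$layer)]

  fixed <- fixed_optical_constants()
  dermal <- c("papillary_dermis", "upper_blood_net", "reticular_dermis",
              "deep_blood_net")

  per_wl <- purrr::map_dfr(wavelengths, function(wl) {
    tbl <- layer_tbl
    tbl$wavelength <- wl
    fx <- fixed[fixed$wavelength == wl, ]
    m <- match(tbl$layer, fx$layer)
    tbl$mu_s <- fx$mu_s[m]
    tbl$g <- fx$g[m]
    tbl$mu_a <- fx$mu_a[m]
    epi <- tbl$layer == "epidermis"
    tbl$mu_a[epi] <- epidermis_mu_a(vmel, tbl$vw[epi], wl, constants)
    for (i in which(tbl$layer %in% dermal)) {
      vb <- pulsatile_blood_volumes(tbl$vb[i], state$phase)
      tbl$mu_a[i] <- dermis_mu_a(state, vb[["v_arterial"]], vb[["v_venous"]],
                                 tbl$vw[i], wl, constants)
    }
    tbl
  })

  bone_fx <- fixed[fixed$layer == "bone", ]
  bone <- list(
    radius = bone_radius,
    center_z = side_thick + muscle_thick / 2,
    layer = "muscle",
    mu_a = stats::setNames(bone_fx$mu_a, bone_fx$wavelength),
    mu_s = stats::setNames(bone_fx$mu_s, bone_fx$wavelength),
    g = stats::setNames(bone_fx$g, bone_fx$wavelength)
  )

  new_tissue_stack(per_wl, bone = bone, total_thickness = total_thickness,
                   refractive_index = refractive_index,
                   ambient_index = ambient_index,
                   lateral_halfwidth = lateral_halfwidth,
                   phenotype = as.character(phenotype$skin[1]),
                   state = state)
}

new_tissue_stack <- function(layers, bone = NULL, total_thickness,
                             refractive_index, ambient_index,
                             lateral_halfwidth = Inf,
                             phenotype = NA_character_, state = NULL) {
  stopifnot(all(layers$thickness > 0), all(layers$mu_a >= 0),
            all(layers$mu_s >= 0), all(abs(layers$g) <= 1),
            all(is.finite(layers$mu_a)), all(is.finite(layers$mu_s)))
  for (wl in unique(layers$wavelength)) {
    tot <- sum(layers$thickness[layers$wavelength == wl])
    if (abs(tot - total_thickness) > 1e-9) {
      stop("layer thicknesses do not sum to the total finger thickness",
           call. = FALSE)
    }
  }
  structure(layers,
            class = c("tissue_stack", class(tibble::tibble()))) -> out
  attr(out, "bone") <- bone
  attr(out, "total_thickness") <- total_thickness
  attr(out, "refractive_index") <- refractive_index
  attr(out, "ambient_index") <- ambient_index
  attr(out, "lateral_halfwidth") <- lateral_halfwidth
  attr(out, "phenotype") <- phenotype
  attr(out, "state") <- state
  out
}

#' Single-slab phantom for analytic engine validation
#'
#' A homogeneous one-layer stack (no bone) used to validate the transport
#' engine against closed-form results such as Beer-Lambert transmittance.
#'
#' @param mu_a,mu_s Absorption and scattering coefficients (mm^-1).
#' @param g Scattering anisotropy.
#' @param thickness Slab thickness in mm.
#' @param refractive_index Slab index; 1 gives index-matched boundaries.
#' @param wavelength Nominal wavelength label for the row (does not affect
#'   transport).
#' @return A `tissue_stack` with a single layer.
#' @export
#' @examples
#' make_homogeneous_phantom(1, 0, 0, 1)  # Beer-Lambert slab, T = exp(-1)
make_homogeneous_phantom <- function(mu_a, mu_s, g, thickness,
                                     refractive_index = 1.0,
                                     wavelength = 660) {
  stopifnot(mu_a >= 0, mu_s >= 0, abs(g) <= 1)
  if (thickness <= 0) stop("thickness must be positive", call. = FALSE)
  layers <- tibble::tibble(
    index = 1L, layer = "phantom", thickness = thickness,
    vb = 0, vw = 0, wavelength = wavelength,
    mu_s = mu_s, g = g, mu_a = mu_a
  )
  new_tissue_stack(layers, bone = NULL, total_thickness = thickness,
                   refractive_index = refractive_index, ambient_index = 1.0,
                   lateral_halfwidth = Inf)
}

#' Export the optical-property table of a stack
#'
#' @param stack A `tissue_stack`.
#' @return A tibble with columns `layer`, `wavelength_nm`, `mu_a_mm`,
#'   `mu_s_mm`, `g`, `n`, `thickness_mm`, `vb`, `vw`.
#' @export
optical_table <- function(stack) {
  stopifnot(inherits(stack, "tissue_stack"))
  tibble::tibble(
    layer = stack$layer,
    wavelength_nm = stack$wavelength,
    mu_a_mm = stack$mu_a,
    mu_s_mm = stack$mu_s,
    g = stack$g,
    n = attr(stack, "refractive_index"),
    thickness_mm = stack$thickness,
    vb = stack$vb,
    vw = stack$vw
  )
}
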