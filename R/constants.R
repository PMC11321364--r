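#' Chromophore absorption constants
#'
#' Bundle of the spectroscopic constants used to assemble layer absorption
#' coefficients: the melanin and tissue-baseline power laws, water and
#' hemoglobin absorption at the two oximetry wavelengths, and the hematocrit
#' the hemoglobin values refer to.
#'
#' The epidermal melanin term is `vmel * 6.6e10 * lambda^-3.33` (mm^-1 with
#' lambda in nm); the pigment- and blood-free tissue baseline is
#' `7.84e7 * lambda^-3.255`. Hemoglobin absorption (whole blood at 45%
#' hematocrit) is 0.15 / 1.64 mm^-1 at 660 nm and 0.65 / 0.43 mm^-1 at 940 nm
#' for oxy- and deoxyhemoglobin respectively. Water absorption defaults to
#' 4.15e-4 mm^-1 at 660 nm and 2.67e-2 mm^-1 at 940 nm.
#'
#' @param wavelengths Wavelengths (nm) the constant maps must cover.
#' @param mu_a_water Named numeric: water absorption (mm^-1) per wavelength.
#' @param mu_a_hbo2 Named numeric: oxyhemoglobin absorption (mm^-1).
#' @param mu_a_hhb Named numeric: deoxyhemoglobin absorption (mm^-1).
#' @param melanin_prefactor,melanin_exponent Melanin power law.
#' @param baseline_prefactor,baseline_exponent Baseline-tissue power law.
#' @param hematocrit Hematocrit fraction of the blood the hemoglobin
#'   coefficients describe.
#' @return An object of class `chromophore_constants` (a named list).
#' @export
#' @examples
#' cc <- chromophore_constants()
#' cc$mu_a_hhb[["660"]]
chromophore_constants <- function(wavelengths = c(660, 940),
                                  mu_a_water = c("660" = 4.15e-4, "940" = 2.67e-2),
                                  mu_a_hbo2 = c("660" = 0.15, "940" = 0.65),
                                  mu_a_hhb = c("660" = 1.64, "940" = 0.43),
                                  melanin_prefactor = 6.6e10,
                                  melanin_exponent = -3.33,
                                  baseline_prefactor = 7.84e7,
                                  baseline_exponent = -3.255,
                                  hematocrit = 0.45) {
  stopifnot(melanin_prefactor > 0, baseline_prefactor > 0,
            all(mu_a_water >= 0), all(mu_a_hbo2 >= 0), all(mu_a_hhb >= 0),
            hematocrit > 0, hematocrit < 1)
  keys <- as.character(wavelengths)
  for (m in list(mu_a_water, mu_a_hbo2, mu_a_hhb)) {
    if (!all(keys %in% names(m))) {
      stop("absorption maps must be defined for every configured wavelength",
           call. = FALSE)
    }
  }
  structure(
    list(
      wavelengths = wavelengths,
      melanin_prefactor = melanin_prefactor,
      melanin_exponent = melanin_exponent,
      baseline_prefactor = baseline_prefactor,
      baseline_exponent = baseline_exponent,
      mu_a_water = mu_a_water[keys],
      mu_a_hbo2 = mu_a_hbo2[keys],
      mu_a_hhb = mu_a_hhb[keys],
      hematocrit = hematocrit
    ),
    class = "chromophore_constants"
  )
}

#' Skin phototypes and their melanosome volume fractions
#'
#' The three modelled pigmentation groups: Fitzpatrick type I (light,
#' epidermal melanosome volume fraction 2.55%), type IV (moderate, 15.5%)
#' and type VI (dark, 30.5%).
#'
#' @param label One or more of `"light"`, `"moderate"`, `"dark"`; default all.
#' @return A tibble with columns `skin` and `vmel`.
#' @export
#' @examples
#' skin_phenotypes()
skin_phenotypes <- function(label = c("light", "moderate", "dark")) {
  label <- match.arg(label, several.ok = TRUE)
  all <- tibble::tibble(
    skin = factor(c("light", "moderate", "dark"),
                  levels = c("light", "moderate", "dark")),
    vmel = c(0.0255, 0.155, 0.305)
  )
  all[match(label, all$skin), ]
}

#' Hemodynamic state of the finger model
#'
#' Arterial saturation, venous saturation and cardiac phase. Venous
#' saturation defaults to 10 percentage points below arterial.
#'
#' @param sat_a Arterial oxygen saturation fraction, in `[0.70, 1.00]`.
#' @param phase `"diastole"` or `"systole"`.
#' @param sat_v Venous oxygen saturation fraction; default `sat_a - 0.10`.
#' @return A named list of class `hemodynamic_state`.
#' @export
hemodynamic_state <- function(sat_a, phase = c("diastole", "systole"),
                              sat_v = sat_a - 0.10) {
  phase <- match.arg(phase)
  if (sat_a < 0.70 || sat_a > 1.00) {
    stop("sat_a must lie in [0.70, 1.00]", call. = FALSE)
  }
  if (sat_v < 0 || sat_v > 1) stop("sat_v must lie in [0, 1]", call. = FALSE)
  structure(list(sat_a = sat_a, sat_v = sat_v, phase = phase),
            class = "hemodynamic_state")
}

# Fixed per-layer optical data: mu_a/mu_s/g for the non-dermal layers and
# scattering defaults for the skin sublayers (the dermal and epidermal
# scattering values are generic skin-optics defaults; g is shared across the
# six skin sublayers). vb is the diastolic blood volume fraction, vw water.
default_layer_constants <- function() {
  tibble::tribble(
    ~layer,             ~thickness, ~vb,  ~vw,
    "stratum_corneum",  0.02,       0,    0.05,
    "epidermis",        0.08,       0,    0.20,
    "papillary_dermis", 0.18,       0.04, 0.50,
    "upper_blood_net",  0.08,       0.30, 0.60,
    "reticular_dermis", 1.50,       0.04, 0.60,
    "deep_blood_net",   0.10,       0.10, 0.70,
    "fat",              0.80,       0,    0,
    "muscle",           NA,         0,    0,
    "bone",             NA,         0,    0
  )
}

# Per-wavelength fixed coefficients (mm^-1, dimensionless g); dermal and
# epidermal mu_a are computed, not tabulated, hence NA here.
fixed_optical_constants <- function() {
  tibble::tribble(
    ~layer,             ~wavelength, ~mu_a,  ~mu_s, ~g,
    "stratum_corneum",  660,         0.0495, 25.62, 0.91,
    "stratum_corneum",  940,         0.0170, 5.68,  0.94,
    "epidermis",        660,         NA,     18.7,  0.91,
    "epidermis",        940,         NA,     12.0,  0.94,
    "papillary_dermis", 660,         NA,     18.7,  0.91,
    "papillary_dermis", 940,         NA,     12.0,  0.94,
    "upper_blood_net",  660,         NA,     18.7,  0.91,
    "upper_blood_net",  940,         NA,     12.0,  0.94,
    "reticular_dermis", 660,         NA,     18.7,  0.91,
    "reticular_dermis", 940,         NA,     12.0,  0.94,
    "deep_blood_net",   660,         NA,     18.7,  0.91,
    "deep_blood_net",   940,         NA,     12.0,  0.94,
    "fat",              660,         0.0104, 6.20,  0.90,
    "fat",              940,         0.0170, 5.42,  0.90,
    "muscle",           660,         0.0816, 8.61,  0.88,
    "muscle",           940,         0.0401, 5.81,  0.91,
    "bone",             660,         0.0351, 34.45, 0.92,
    "bone",             940,         0.0457, 24.70, 0.93
  )
}
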