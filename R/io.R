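#' Load a packaged fixture table
#'
#' The package bundles plain-text transcriptions of the published study
#' tables used by the deterministic analytics: the simulated AC/DC table
#' (`"table2_acdc"`), the clinical cohort table and its printed summary
#' (`"table3_cohort"`, `"table3_summary"`), and the calibration-equation
#' coefficients (`"calibration_coefficients"`). Every fixture is
#' checksum-pinned; a mismatch (an edited installation) is an error.
#'
#' @param name Fixture name.
#' @return A tibble.
#' @export
#' @examples
#' load_fixture("calibration_coefficients")
load_fixture <- function(name) {
  manifest <- utils::read.csv(
    system.file("extdata", "checksums.csv", package = "pulseoxmc"),
    stringsAsFactors = FALSE)
  row <- manifest[manifest$name == name, ]
  if (nrow(row) != 1) {
    stop("unknown fixture: ", name, " (available: ",
         paste(manifest$name, collapse = ", "), ")", call. = FALSE)
  }
  path <- system.file("extdata", row$file, package = "pulseoxmc")
  if (!nzchar(path)) stop("fixture file missing: ", row$file, call. = FALSE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, row$md5)) {
    stop("fixture checksum mismatch for ", name, ": expected ", row$md5,
         ", got ", md5, call. = FALSE)
  }
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

config_schema_keys <- c(
  "phenotypes", "sao2_grid", "wavelengths", "preset", "photons", "seed",
  "max_launched", "batch_size", "geometry", "source_radius",
  "detector_radius", "roulette_threshold", "roulette_survival", "out_dir")

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, validates it against the schema, applies
#' the documented defaults for absent keys, and returns an
#' [experiment_config()]. Unknown keys are rejected with a field-level
#' message. An empty file yields the full default configuration.
#'
#' Recognised keys: `phenotypes` (labels, or maps with `label` and `vmel`),
#' `sao2_grid`, `wavelengths`, `preset`, `photons`, `seed`, `max_launched`,
#' `batch_size`, `source_radius`, `detector_radius`, `roulette_threshold`,
#' `roulette_survival`, `out_dir`, and `geometry` with `total_thickness`,
#' `bone_radius` and per-layer overrides under `layers`.
#'
#' @param path Path to a YAML file.
#' @return An `experiment_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), config_schema_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- list()

  if (!is.null(cfg$phenotypes)) {
    ph <- cfg$phenotypes
    if (is.character(ph)) {
      args$phenotypes <- skin_phenotypes(ph)
    } else {
      tbl <- purrr::map_dfr(ph, function(p) {
        if (is.character(p)) return(skin_phenotypes(p))
        if (is.null(p$label) || is.null(p$vmel)) {
          stop("phenotypes entries need 'label' and 'vmel'", call. = FALSE)
        }
        if (p$vmel < 0 || p$vmel > 1) {
          stop("phenotypes: vmel must be a fraction in [0, 1], got ",
               p$vmel, call. = FALSE)
        }
        tibble::tibble(skin = p$label, vmel = p$vmel)
      })
      args$phenotypes <- tbl
    }
  }
  for (k in c("sao2_grid", "wavelengths", "preset", "photons", "seed",
              "max_launched", "batch_size", "source_radius",
              "detector_radius", "roulette_threshold", "roulette_survival",
              "out_dir")) {
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  }
  if (!is.null(cfg$sao2_grid)) args$sao2_grid <- unlist(cfg$sao2_grid)
  if (!is.null(cfg$wavelengths)) args$wavelengths <- unlist(cfg$wavelengths)

  if (!is.null(cfg$geometry)) {
    geo_keys <- c("total_thickness", "bone_radius", "layers")
    unknown <- setdiff(names(cfg$geometry), geo_keys)
    if (length(unknown)) {
      stop("unknown geometry key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (!is.null(cfg$geometry$total_thickness)) {
      args$total_thickness <- cfg$geometry$total_thickness
    }
    if (!is.null(cfg$geometry$bone_radius)) {
      args$bone_radius <- cfg$geometry$bone_radius
    }
    if (!is.null(cfg$geometry$layers)) {
      args$layer_overrides <- purrr::map_dfr(cfg$geometry$layers, function(l) {
        tibble::tibble(layer = l$layer,
                       thickness = l$thickness %||% NA_real_,
                       vb = l$vb %||% NA_real_,
                       vw = l$vw %||% NA_real_)
      })
    }
  }
  do.call(experiment_config, args)
}

# recursively sort names so the hash is stable under key reordering
sort_keys <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && any(nzchar(names(x)))) {
      x <- x[order(names(x))]
    }
    lapply(x, sort_keys)
  } else x
}

#' Hash a configuration
#'
#' MD5 of the canonical (recursively key-sorted) JSON serialisation; stable
#' under key reordering.
#'
#' @param config An `experiment_config` (or any list).
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  x <- unclass(config)
  x$phenotypes <- if (!is.null(x$phenotypes)) as.list(x$phenotypes)
  json <- jsonlite::toJSON(sort_keys(x), auto_unbox = TRUE, digits = NA,
                           null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

#' Reproducibility manifest for a run
#'
#' @param config The `experiment_config` used.
#' @param raw The [run_grid()] output (supplies per-condition launch
#'   counts).
#' @param timestamp Optional ISO-8601 timestamp; defaults to the current
#'   time.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(config, raw = NULL,
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")) {
  budgets <- NULL
  if (!is.null(raw)) {
    budgets <- raw[, intersect(names(raw),
                               c("skin", "sao2", "phase", "wavelength",
                                 "launched", "detected_count"))]
  }
  structure(list(
    config_hash = config_hash(config),
    seed = config$seed,
    preset = config$preset,
    photons = config$photons,
    version = as.character(utils::packageVersion("pulseoxmc")),
    timestamp = timestamp,
    budgets = budgets
  ), class = "run_manifest")
}

#' Write the result tables of an experiment
#'
#' Serialises an [assemble_tables()] result to CSV/JSON with fixed column
#' order: the raw transmittance grid, the AC/DC table in the printed wide
#' layout (skin rows, one column per SaO2, per wavelength, four decimals),
#' the calibration coefficients, the bias table with its mean-bias row (one
#' decimal), and the correction factors. Overwrites idempotently:
#' re-running on identical inputs produces byte-identical files.
#'
#' @param result An `experiment_result`.
#' @param out_dir Output directory (created if needed).
#' @param manifest Optional [run_manifest()] written alongside.
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(result, out_dir, manifest = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  w <- function(obj, file, writer) {
    p <- file.path(out_dir, file)
    writer(obj, p)
    paths <<- c(paths, p)
  }
  wcsv <- function(df, p) utils::write.csv(df, p, row.names = FALSE)
  wjson <- function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                               digits = NA, pretty = TRUE)

  if (!is.null(result$raw)) w(result$raw, "transmittance.csv", wcsv)

  if (!is.null(result$acdc)) {
    long <- result$acdc |>
      tidyr::pivot_longer(dplyr::all_of(c("acdc_660", "acdc_940")),
                          names_to = "wavelength", names_prefix = "acdc_",
                          values_to = "acdc") |>
      dplyr::mutate(acdc = round_half_up(.data$acdc, 4))
    wide <- tidyr::pivot_wider(
      long[, c("skin", "sao2", "wavelength", "acdc")],
      names_from = "sao2", values_from = "acdc")
    wide <- wide[order(wide$wavelength, match(wide$skin,
                                              c("light", "moderate",
                                                "dark"))), ]
    w(wide, "acdc.csv", wcsv)
  }

  curves <- result$curves %||% result$printed_curves
  if (!is.null(curves)) {
    w(purrr::map(curves, function(cv) {
      list(label = cv$label, intercept = cv$intercept, slope = cv$slope)
    }), "calibration_curves.json", wjson)
  }

  if (!is.null(result$bias)) {
    tbl <- purrr::imap_dfr(result$bias, function(rep, nm) {
      tibble::tibble(skin = nm, sao2 = rep$sao2,
                     spo2 = rep$spo2_rounded, bias = rep$bias_rounded)
    })
    means <- purrr::imap_dfr(result$bias, function(rep, nm) {
      tibble::tibble(skin = nm, sao2 = NA_real_, spo2 = NA_real_,
                     bias = mean_bias(rep, rounded = TRUE))
    })
    w(dplyr::bind_rows(tbl, means), "bias.csv", wcsv)
  }

  if (!is.null(result$multipliers)) {
    w(purrr::map(result$multipliers, function(m) {
      list(kind = m$kind, factor = m$factor,
           profile = as.list(m$profile))
    }), "correction_factors.json", wjson)
  }

  if (!is.null(manifest)) w(unclass(manifest), "run_manifest.json", wjson)
  invisible(paths)
}
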