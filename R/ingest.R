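#' Standardized forcing units per global change factor
#'
#' Treatment magnitudes are expressed in standardized units before sensitivities
#' are computed: per 100 ppm CO2 increase (eCO2), per 1 degree C warming (eT),
#' per 10 % precipitation change (iP and dP), per 1 g m-2 yr-1 nitrogen
#' addition (eN), and per 10 ppb ozone increase (eO3).
#'
#' @format Named numeric vector: the native-unit size of one standardized unit.
#' @export
standard_units <- c(eCO2 = 100, eT = 1, iP = 10, dP = 10, eN = 1, eO3 = 10)

#' Convert a raw treatment magnitude to standardized forcing units
#'
#' Divides the raw magnitude by the factor's standardized unit size (see
#' [standard_units]). For precipitation decrease (`dP`) the magnitude of the
#' decrease is supplied as a positive percentage; direction is carried by the
#' factor code, so a negative pooled sensitivity reads "% change in g_s per
#' 10 % precipitation decrease".
#'
#' @param factor Character vector of factor codes (`eCO2`, `eT`, `iP`, `dP`,
#'   `eN`, `eO3`).
#' @param raw_magnitude Numeric vector of magnitudes in the factor's native
#'   units (ppm, degrees C, |%| change, g m-2 yr-1, ppb). Must be positive.
#' @return Numeric vector of standardized magnitudes (delta).
#' @examples
#' standardize_magnitude("eCO2", 300) # 3 standardized units
#' standardize_magnitude(c("eO3", "dP"), c(50, 40))
#' @export
standardize_magnitude <- function(factor, raw_magnitude) {
  bad <- setdiff(unique(factor), GCF_CODES)
  if (length(bad) > 0) {
    abort(paste0("Unknown global change factor code(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (any(!is.na(raw_magnitude) & raw_magnitude <= 0)) {
    abort("Treatment magnitude must be positive (supply decreases as positive magnitudes).")
  }
  unname(raw_magnitude / standard_units[factor])
}

#' Vapor pressure deficit from temperature and actual vapor pressure
#'
#' Saturation vapor pressure follows the Tetens-type form
#' `VPsat = 0.611 * exp(17.502 * T / (240.97 + T))` kPa, and
#' `VPD = VPsat - VP`. A negative result (actual vapor pressure above
#' saturation) is returned as-is with a warning rather than clamped.
#'
#' @param temp Air temperature, degrees C. Must exceed -240.97.
#' @param vp Actual vapor pressure, kPa.
#' @return Vapor pressure deficit, kPa.
#' @examples
#' vapor_pressure_deficit(25, 1.5)
#' @export
vapor_pressure_deficit <- function(temp, vp) {
  if (any(!is.na(temp) & temp <= -240.97)) {
    abort("Temperature at or below -240.97 C is outside the formula's domain.")
  }
  vpsat <- 0.611 * exp(17.502 * temp / (240.97 + temp))
  vpd <- vpsat - vp
  if (any(!is.na(vpd) & vpd < 0)) {
    warn("Vapor pressure exceeds saturation for some inputs; negative VPD returned unclamped.")
  }
  vpd
}

# Canonical column names for the observation table.
OBS_COLUMNS <- c(
  "study_id", "site_id", "species", "biome", "pft", "factors",
  "magnitude_1", "magnitude_2",
  "mean_T", "se_T", "n_T", "mean_C", "se_C", "n_C",
  "setting", "duration", "mat", "ai", "monthly_temp", "vp"
)

REQUIRED_COLUMNS <- c(
  "study_id", "site_id", "species", "factors", "magnitude_1",
  "mean_T", "se_T", "n_T", "mean_C", "se_C", "n_C"
)

#' Read a column-name schema from a YAML file
#'
#' The observation CSV need not use the package's canonical column names; a
#' YAML map of `canonical: actual` pairs renames them on read. Entries for
#' columns already canonically named may be omitted.
#'
#' @param path Path to a YAML file whose top level maps canonical names (see
#'   [read_observations]) to the column names used in the CSV.
#' @return A named character vector usable as the `schema` argument of
#'   [read_observations].
#' @export
read_schema <- function(path) {
  m <- yaml::read_yaml(path)
  unlist(m)
}

parse_factor_set <- function(x) {
  # "eCO2" or "eCO2+eT" -> sorted canonical "eCO2+eT" string
  parts <- strsplit(as.character(x), "\\s*\\+\\s*")
  vapply(parts, function(p) {
    p <- p[nzchar(p)]
    paste(p[order(match(p, GCF_CODES))], collapse = "+")
  }, character(1))
}

#' Read and validate an observation table
#'
#' Reads a CSV of paired control/treatment stomatal-conductance observations,
#' applies the inclusion criteria, and returns the validated rows as a tibble.
#' Each rejected row is reported (not an error) with the criterion it violated;
#' the rejection log is attached as attribute `"rejections"` and summarised in
#' a message.
#'
#' Inclusion criteria applied per row: positive control and treatment means
#' (the log ratio must be defined), at least three replicates in each arm,
#' non-negative standard errors, a recognised factor set of one or two factor
#' codes, and positive treatment magnitudes for every factor present.
#'
#' @param path CSV file path (UTF-8, header row) or a data frame already in
#'   memory.
#' @param schema Optional named character vector or YAML path ([read_schema])
#'   mapping canonical column names to the file's column names. Canonical
#'   names: `study_id`, `site_id`, `species`, `biome`, `pft`, `factors`
#'   (one or two codes joined by `+`), `magnitude_1`, `magnitude_2`,
#'   `mean_T`, `se_T`, `n_T`, `mean_C`, `se_C`, `n_C`, `setting`, `duration`,
#'   `mat`, `ai`, `monthly_temp`, `vp`.
#' @param dispersion Either `"se"` (default) or `"sd"`; with `"sd"` the
#'   dispersion columns are converted to standard errors via division by
#'   `sqrt(n)`.
#' @param quiet Suppress the rejection-summary message.
#' @return A tibble of validated observations in canonical columns, with a
#'   `vpd` column derived where `monthly_temp` and `vp` are present, and the
#'   rejection log in `attr(, "rejections")`.
#' @export
read_observations <- function(path, schema = NULL, dispersion = c("se", "sd"),
                              quiet = FALSE) {
  dispersion <- match.arg(dispersion)
  df <- if (is.data.frame(path)) {
    as_tibble(path)
  } else {
    if (!file.exists(path)) abort(paste0("File not found: ", path))
    as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                              fileEncoding = "UTF-8"))
  }
  if (is.character(schema) && length(schema) == 1 && file.exists(schema) &&
      is.null(names(schema))) {
    schema <- read_schema(schema)
  }
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      actual <- schema[[canon]]
      if (!actual %in% names(df)) {
        abort(paste0("Schema maps '", canon, "' to column '", actual,
                     "', which is absent from the input."))
      }
      names(df)[names(df) == actual] <- canon
    }
  }
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (opt in setdiff(OBS_COLUMNS, names(df))) df[[opt]] <- NA
  df <- df[OBS_COLUMNS]
  num_cols <- c("magnitude_1", "magnitude_2", "mean_T", "se_T", "n_T",
                "mean_C", "se_C", "n_C", "duration", "mat", "ai",
                "monthly_temp", "vp")
  df[num_cols] <- lapply(df[num_cols], as.numeric)

  if (dispersion == "sd") {
    df$se_T <- df$se_T / sqrt(df$n_T)
    df$se_C <- df$se_C / sqrt(df$n_C)
  }

  df$factors <- parse_factor_set(df$factors)
  n_fac <- lengths(strsplit(df$factors, "\\+"))
  codes_ok <- vapply(strsplit(df$factors, "\\+"),
                     function(p) all(p %in% GCF_CODES), logical(1))
  mag2_ok <- n_fac < 2 | (!is.na(df$magnitude_2) & df$magnitude_2 > 0)

  reasons <- list(
    "mean not positive: log-ratio undefined" =
      !(df$mean_T > 0 & df$mean_C > 0) | is.na(df$mean_T) | is.na(df$mean_C),
    "fewer than three replicates (n >= 3 required)" =
      is.na(df$n_T) | is.na(df$n_C) | df$n_T < 3 | df$n_C < 3,
    "negative or missing standard error" =
      is.na(df$se_T) | is.na(df$se_C) | df$se_T < 0 | df$se_C < 0,
    "unrecognised or empty factor set" =
      !codes_ok | !(n_fac %in% c(1L, 2L)),
    "non-positive treatment magnitude" =
      is.na(df$magnitude_1) | df$magnitude_1 <= 0 | !mag2_ok
  )
  reason_mat <- do.call(cbind, reasons)
  bad <- rowSums(reason_mat, na.rm = TRUE) > 0
  rejections <- tibble(
    row = which(bad),
    reason = apply(reason_mat[bad, , drop = FALSE], 1, function(r) {
      paste(names(reasons)[which(r)], collapse = "; ")
    })
  )
  ok <- df[!bad, , drop = FALSE]
  ok$vpd <- ifelse(!is.na(ok$monthly_temp) & !is.na(ok$vp),
                   suppressWarnings(
                     vapor_pressure_deficit(ok$monthly_temp, ok$vp)),
                   NA_real_)
  if (!quiet && nrow(rejections) > 0) {
    inform(paste0(nrow(rejections), " of ", nrow(df),
                  " rows rejected by inclusion criteria; see attr(x, \"rejections\")."))
  }
  attr(ok, "rejections") <- rejections
  ok
}
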