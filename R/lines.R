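#' Construct an emission line
#'
#' An emission line pairs an element/ionization-stage label with its
#' characteristic wavelength and a dimensionless emissivity that converts an
#' elemental concentration (ug/kg) into a peak amplitude (detector counts).
#'
#' @param element chemical element symbol (e.g. `"Fe"`).
#' @param stage ionization stage label, `"I"` (neutral) or `"II"` (singly
#'   ionized).
#' @param wavelength line centre in nm; must lie in the 200-550 nm
#'   acquisition window.
#' @param emissivity positive scale factor: peak amplitude =
#'   `emissivity * concentration(element)`.
#' @return a one-row data frame with columns `element`, `stage`,
#'   `wavelength_nm`, `emissivity`.
#' @export
emission_line <- function(element, stage, wavelength, emissivity) {
  stopifnot(is.character(element), length(element) == 1L)
  if (!stage %in% c("I", "II"))
    stopf("ionization stage must be 'I' or 'II', got '%s'", stage)
  if (!is_scalar_num(wavelength) || wavelength < 200 || wavelength > 550)
    stopf("wavelength %s nm outside the 200-550 nm acquisition range",
          format(wavelength))
  if (!is_scalar_num(emissivity) || emissivity <= 0)
    stopf("emissivity must be a positive scalar")
  data.frame(element = element, stage = stage, wavelength_nm = wavelength,
             emissivity = emissivity, stringsAsFactors = FALSE)
}

# Analytical lines used by the simulator, with relative line strengths
# (dimensionless, per line within an element) reflecting which transitions
# dominate in mid-UV/visible LIBS of organic matrices. Ionization-stage
# labels are used verbatim as supplied by the source line list.
.line_table <- function() {
  tab <- rbind(
    c("Fe", "I", 300.75, 0.90),
    c("Fe", "I", 359.30, 0.70),
    c("Fe", "I", 388.24, 0.60),
    c("Fe", "I", 393.36, 1.00),
    c("Fe", "I", 396.75, 0.95),
    c("Fe", "I", 405.32, 0.50),
    c("Fe", "I", 422.60, 0.80),
    c("Fe", "II", 247.92, 1.00),
    c("Fe", "II", 280.28, 0.60),
    c("Fe", "II", 315.28, 0.70),
    c("Cr", "I", 403.33, 0.60),
    c("Cr", "I", 404.42, 1.00),
    c("Cr", "I", 427.42, 0.70),
    c("Cr", "I", 443.93, 0.50),
    c("Cr", "II", 285.23, 0.80),
    c("Cr", "II", 397.96, 1.00),
    c("Cu", "II", 279.57, 1.00),
    c("Cu", "II", 300.47, 0.70),
    c("Cu", "II", 520.71, 0.50),
    c("Na", "II", 292.35, 1.00),
    c("K",  "II", 428.88, 1.00))
  data.frame(element = tab[, 1], stage = tab[, 2],
             wavelength_nm = as.numeric(tab[, 3]),
             strength = as.numeric(tab[, 4]), stringsAsFactors = FALSE)
}

#' Default emission-line library
#'
#' Returns the analytical lines the simulator places on the 200-550 nm grid:
#' Fe I/II, Cr I/II, Cu II, Na II and K II transitions. Default emissivities
#' are scaled per element by `1 / median(concentration across origins)` so
#' that trace elements spanning five orders of magnitude of concentration
#' (K at ~1e7 ug/kg down to Cr at ~1e2 ug/kg) all produce visible peaks;
#' the overall scale is normalized so the tallest default peak is about
#' `peak_max` counts.
#'
#' @param profiles origin profiles used to normalize emissivities; defaults
#'   to [default_origin_profiles()].
#' @param peak_max target height (counts) of the tallest noise-free peak
#'   under the default profiles.
#' @return data frame with columns `element`, `stage`, `wavelength_nm`,
#'   `emissivity`.
#' @export
default_line_library <- function(profiles = default_origin_profiles(),
                                 peak_max = 1e4) {
  tab <- .line_table()
  conc <- sapply(profiles, function(p) {
    v <- p$concentrations[tab$element]
    ifelse(is.na(v), 0, v)
  })                                   # lines x origins
  med <- apply(conc, 1, stats::median)
  med[med <= 0] <- 1
  emis <- tab$strength / med
  amp_max <- max(emis * conc)
  tab$emissivity <- emis * peak_max / amp_max
  tab$strength <- NULL
  tab
}

#' Default origin concentration profiles
#'
#' Elemental concentrations (ug/kg) of Na, K, Ca, Cr, Mn, Fe and Cu for the
#' four coffee origins the simulator emulates, as determined by ICP-MS for
#' the reference pellets.
#'
#' @return a list of four profiles; each is a list with `origin` (label) and
#'   `concentrations` (named numeric vector, ug/kg).
#' @export
default_origin_profiles <- function() {
  conc <- rbind(
    Na = c(13421.43, 8167.56, 8481.90, 11527.01),
    K  = c(11465852.26, 17195739.59, 12627503.01, 15561426.92),
    Ca = c(344222.74, 532753.06, 357557.97, 505804.29),
    Cr = c(372.91, 93.54, 209.15, 118.12),
    Mn = c(38195.74, 51395.28, 14992.81, 78978.92),
    Fe = c(23921.60, 15891.07, 12189.72, 22542.08),
    Cu = c(10888.66, 1539.17, 15010.54, 9088.13))
  origins <- c("Kenya", "Ethiopia", "Colombia", "Yunnan")
  lapply(seq_along(origins), function(i) {
    origin_profile(origins[i], conc[, i])
  })
}

#' Construct an origin profile
#'
#' @param origin class label.
#' @param concentrations named numeric vector, element -> ug/kg, all >= 0.
#' @return a list with `origin` and `concentrations`, class
#'   `"origin_profile"`.
#' @export
origin_profile <- function(origin, concentrations) {
  stopifnot(is.character(origin), length(origin) == 1L)
  if (is.null(names(concentrations)) || any(!nzchar(names(concentrations))))
    stopf("concentrations must be a named vector of element -> ug/kg")
  if (any(concentrations < 0))
    stopf("concentrations must be non-negative")
  structure(list(origin = origin,
                 concentrations = concentrations),
            class = "origin_profile")
}
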