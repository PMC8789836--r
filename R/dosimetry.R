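# Absorbed dose from fluence and LET. For a parallel beam D = F * LET / rho
# with rho the density of water; in the units used throughout (F in um^-2,
# LET in keV/um, rho in kg/m^3) the conversion constant is
# 1.602176634e-16 J/keV / 1e-18 m^3/um^3 = 160.2176634.

#' Particle fluence from per-nucleus track counts
#'
#' Fluence is the mean number of tracks per nucleus divided by the mean
#' nuclear (projected) area. Its uncertainty is the standard error of the
#' per-nucleus count/area ratios; supply `delta_f` directly to override.
#'
#' @param counts Integer vector: tracks counted in each nucleus.
#' @param areas Numeric vector: projected area of each nucleus, um^2.
#' @param delta_f Optional fluence uncertainty, um^-2 (otherwise the SE of
#'   the per-nucleus ratios).
#' @return Object of class `fluence_measurement`: `fluence`, `delta_f`,
#'   `n_nuclei`, `counts`, `areas`.
#' @export
#' @examples
#' fluence_from_tracks(c(1, 2, 3), c(100, 100, 100))$fluence  # 0.02
fluence_from_tracks <- function(counts, areas, delta_f = NULL) {
  if (length(counts) == 0L || length(counts) != length(areas))
    .stopf("'counts' and 'areas' must be non-empty and of equal length")
  if (any(counts < 0)) .stopf("track counts must be non-negative")
  if (any(areas <= 0)) .stopf("nuclear areas must be positive")
  f <- mean(counts) / mean(areas)
  if (is.null(delta_f)) {
    ratios <- counts / areas
    delta_f <- if (length(ratios) > 1L) sd(ratios) / sqrt(length(ratios))
               else 0
  }
  structure(list(fluence = f, delta_f = delta_f,
                 n_nuclei = length(counts), counts = counts, areas = areas),
            class = "fluence_measurement")
}

#' Absorbed dose from fluence and LET
#'
#' `D = F * LET / rho`, i.e. `0.1602 Gy` per unit of `F * LET` at the density
#' of water (1 keV = 1.602176634e-16 J).
#'
#' @param fluence Particle fluence, um^-2.
#' @param let LET, keV/um.
#' @param rho Density of the medium, kg/m^3 (water by default).
#' @return Dose in Gy.
#' @export
#' @examples
#' dose(0.011, 66)   # 0.116 Gy (rounds to 0.12)
#' dose(0.015, 500)  # 1.20 Gy
dose <- function(fluence, let, rho = 1000) {
  .check_number(fluence, "fluence", 0)
  .check_number(let, "let", 0)
  .check_number(rho, "rho", 0, strict = TRUE)
  fluence * let * .KEV_PER_UM3_TO_J_PER_M3 / rho
}

#' Dose uncertainty by linear propagation
#'
#' `delta_D = (LET / rho) * delta_F + (F / rho) * delta_LET`, the linear
#' (non-quadrature) propagation conventional in this assay.
#'
#' @param fluence,delta_fluence Fluence and its uncertainty, um^-2.
#' @param let,delta_let LET and its uncertainty, keV/um.
#' @param rho Density, kg/m^3.
#' @return Dose uncertainty in Gy.
#' @export
#' @examples
#' dose_uncertainty(0.010, 0.003, 66, 19)  # ~0.06 Gy
dose_uncertainty <- function(fluence, delta_fluence, let, delta_let,
                             rho = 1000) {
  .check_number(fluence, "fluence", 0)
  .check_number(delta_fluence, "delta_fluence", 0)
  .check_number(let, "let", 0)
  .check_number(delta_let, "delta_let", 0)
  .check_number(rho, "rho", 0, strict = TRUE)
  (let * delta_fluence + fluence * delta_let) *
    .KEV_PER_UM3_TO_J_PER_M3 / rho
}

#' Total dose of a mixed particle field
#'
#' For `n` particle components, `D = (1/rho) * sum(F_i * LET_i)`; component
#' uncertainties (linear propagation) add up.
#'
#' @param components data.frame with columns `fluence` and `let` (um^-2,
#'   keV/um) and optionally `delta_fluence`, `delta_let` (default 0).
#' @param rho Density, kg/m^3.
#' @return Object of class `dose_estimate`: `dose`, `delta_dose`, `rho` and
#'   per-component breakdown `components` (with `dose_gy`, `delta_dose_gy`).
#' @export
#' @examples
#' mixed_field_dose(data.frame(fluence = c(0.011, 0.015), let = c(66, 500)))
mixed_field_dose <- function(components, rho = 1000) {
  if (!is.data.frame(components))
    components <- as.data.frame(components)
  if (nrow(components) == 0L) {
    return(structure(list(dose = 0, delta_dose = 0, rho = rho,
                          components = components),
                     class = "dose_estimate"))
  }
  need <- c("fluence", "let")
  miss <- setdiff(need, names(components))
  if (length(miss))
    .stopf("components is missing column(s): %s", paste(miss, collapse = ", "))
  if (is.null(components$delta_fluence)) components$delta_fluence <- 0
  if (is.null(components$delta_let)) components$delta_let <- 0
  components$dose_gy <- mapply(dose, components$fluence, components$let,
                               MoreArgs = list(rho = rho))
  components$delta_dose_gy <- mapply(dose_uncertainty,
                                     components$fluence,
                                     components$delta_fluence,
                                     components$let, components$delta_let,
                                     MoreArgs = list(rho = rho))
  structure(list(dose = sum(components$dose_gy),
                 delta_dose = sum(components$delta_dose_gy),
                 rho = rho, components = components),
            class = "dose_estimate")
}

#' @export
print.dose_estimate <- function(x, ...) {
  cat(sprintf("<dose_estimate> D = %.3g +/- %.2g Gy (%d component%s)\n",
              x$dose, x$delta_dose, nrow(x$components),
              if (nrow(x$components) == 1L) "" else "s"))
  invisible(x)
}

#' @export
print.fluence_measurement <- function(x, ...) {
  cat(sprintf("<fluence_measurement> F = %.3g +/- %.2g um^-2 (%d nuclei)\n",
              x$fluence, x$delta_f, x$n_nuclei))
  invisible(x)
}
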