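#' Calibration standards table
#'
#' Builds the table of protein standards used to calibrate the
#' contrast-to-mass line. The default set mirrors a typical mass-photometry
#' calibration series (protein A 42 kDa; alcohol dehydrogenase dimer and
#' tetramer 73.5 / 147 kDa; beta-amylase dimer and tetramer 112 / 224 kDa);
#' measured contrasts must be supplied.
#'
#' @param name Character vector of standard names.
#' @param mass_kda Known masses in kDa (> 0).
#' @param contrast Measured mean contrasts (> 0).
#' @return A tibble with columns `name`, `mass_kda`, `contrast`.
#' @export
calibration_standards <- function(name, mass_kda, contrast) {
  stopifnot(length(name) == length(mass_kda),
            length(mass_kda) == length(contrast))
  if (any(mass_kda <= 0)) stop("mass_kda must be positive")
  if (any(contrast <= 0)) stop("contrast must be positive")
  tibble::tibble(name = as.character(name),
                 mass_kda = as.numeric(mass_kda),
                 contrast = as.numeric(contrast))
}

#' Linear contrast-to-mass calibration model
#'
#' The interferometric contrast of a landing protein scales linearly with
#' its molecular mass: `contrast = slope * mass + intercept`. The default
#' constants are the calibration of the McsB oligomerization measurements
#' (slope 5.023e-5 per kDa, intercept 1.261e-4), under which a 42 kDa
#' monomer has contrast 2.2e-3 and an 84 kDa dimer 4.3e-3.
#'
#' @param slope Contrast per kDa (> 0).
#' @param intercept Dimensionless contrast offset.
#' @param r_squared Optional fit quality (from [fit_calibration()]).
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(slope = 5.023e-5, intercept = 1.261e-4,
                              r_squared = NA_real_) {
  if (!is.finite(slope) || slope <= 0) stop("slope must be positive")
  structure(list(slope = as.numeric(slope),
                 intercept = as.numeric(intercept),
                 r_squared = as.numeric(r_squared)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> contrast = %.4g/kDa * mass + %.4g (R2 = %s)\n",
              x$slope, x$intercept,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared))))
  invisible(x)
}

#' Fit the calibration line to standards
#'
#' Ordinary least squares of contrast as a function of mass:
#' `contrast = slope * mass + intercept`.
#'
#' @param standards Tibble from [calibration_standards()] (>= 2 distinct
#'   masses).
#' @return A [calibration_model()].
#' @export
fit_calibration <- function(standards) {
  if (nrow(standards) < 2L) stop("need at least 2 calibration standards")
  if (length(unique(standards$mass_kda)) < 2L)
    stop("calibration standards must span at least 2 distinct masses")
  fit <- stats::lm(contrast ~ mass_kda, data = standards)
  cf <- stats::coef(fit)
  calibration_model(slope = cf[["mass_kda"]], intercept = cf[["(Intercept)"]],
                    r_squared = summary(fit)$r.squared)
}

#' Convert contrast to molecular mass
#'
#' `mass = (contrast - intercept) / slope`. Contrasts below the intercept
#' map to negative masses; they are returned as-is (callers flag/exclude
#' them) rather than clipped.
#'
#' @param contrast Contrast magnitude(s).
#' @param model A [calibration_model()].
#' @return Mass(es) in kDa.
#' @export
contrast_to_mass <- function(contrast, model = calibration_model()) {
  stopifnot(inherits(model, "calibration_model"))
  (contrast - model$intercept) / model$slope
}

#' Convert molecular mass to contrast
#'
#' Inverse of [contrast_to_mass()]: `contrast = slope * mass + intercept`.
#'
#' @param mass_kda Mass(es) in kDa.
#' @param model A [calibration_model()].
#' @return Contrast magnitude(s).
#' @export
mass_to_contrast <- function(mass_kda, model = calibration_model()) {
  stopifnot(inherits(model, "calibration_model"))
  model$slope * mass_kda + model$intercept
}

#' Build a number-weighted mass distribution with n-mer assignment
#'
#' Converts fitted event contrasts to masses, bins them into a
#' number-weighted histogram (each landing molecule counts once, so an
#' oligomer contributes a single count to its species peak), and assigns
#' each event to an n-mer species: event mass `m` is assigned to
#' `n = round(m / monomer)` when `n >= 1` and
#' `|m - n * monomer| <= 0.3 * monomer`; otherwise it stays unassigned.
#' Edge-flagged events and negative masses are excluded from assignment
#' (negative masses remain in the raw mass table).
#'
#' @param events Fitted-event tibble (needs `contrast`; optional `edge`).
#' @param model A [calibration_model()].
#' @param monomer_mass_kda Monomer mass defining the n-mer ladder.
#' @param bin_width_kda Histogram bin width in kDa.
#' @return An object of class `mass_distribution`: `masses_kda`,
#'   `bin_width_kda`, `breaks`, `counts`, and `species` (tibble `n_mer`,
#'   `count`, `fraction`; fractions relative to all non-edge events).
#' @export
build_mass_distribution <- function(events, model = calibration_model(),
                                    monomer_mass_kda = 42,
                                    bin_width_kda = 5) {
  if (nrow(events) == 0L) stop("no events to build a distribution from")
  if (!"edge" %in% names(events)) events$edge <- FALSE
  ev <- events[!events$edge, , drop = FALSE]
  if (nrow(ev) == 0L) stop("all events are edge-flagged")
  if (any(!is.finite(ev$contrast)))
    stop("events contain non-finite contrasts")
  masses <- contrast_to_mass(ev$contrast, model)
  lo <- floor(min(c(masses, 0)) / bin_width_kda) * bin_width_kda
  hi <- ceiling(max(masses) / bin_width_kda) * bin_width_kda
  breaks <- seq(lo, max(hi, lo + bin_width_kda), by = bin_width_kda)
  counts <- graphics::hist(masses, breaks = breaks, plot = FALSE)$counts
  n_total <- length(masses)
  nm <- round(masses / monomer_mass_kda)
  assigned <- nm >= 1 & masses > 0 &
    abs(masses - nm * monomer_mass_kda) <= 0.3 * monomer_mass_kda
  sp <- table(nm[assigned])
  species <- tibble::tibble(n_mer = as.integer(names(sp)),
                            count = as.integer(sp),
                            fraction = as.numeric(sp) / n_total)
  structure(list(masses_kda = masses, bin_width_kda = bin_width_kda,
                 breaks = breaks, counts = counts, species = species,
                 n_events = n_total,
                 n_unassigned = n_total - sum(assigned)),
            class = "mass_distribution")
}

#' @export
print.mass_distribution <- function(x, ...) {
  cat(sprintf("<mass_distribution> %d events, %d unassigned, bin %g kDa\n",
              x$n_events, x$n_unassigned, x$bin_width_kda))
  print(x$species)
  invisible(x)
}
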