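fit_half_window <- 3L

#' Fit the PSF model to one candidate event
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `A * psf_profile(r) + b` over the candidate's square ratiometric
#' neighborhood, with the PSF shape held fixed and only amplitude `A`,
#' sub-pixel center `(row, col)` and constant offset `b` free. At monomer
#' signal-to-noise a full shape refit is unstable, so the shape comes from
#' the (global) model, mirroring fixed-PSF fitting practice.
#'
#' The patch is taken from the single ratiometric frame at the candidate's
#' peak frame. That frame already averages the full `navg` raw frames
#' before and after the landing, so it carries the complete temporal signal
#' window and recovers the step amplitude without the ramp bias a plain
#' average over post-landing ratiometric frames would introduce.
#'
#' The fitted amplitude magnitude is the event's interferometric contrast.
#' Candidates whose patch is clipped by the field border are fitted on the
#' clipped patch and flagged `edge = TRUE` (excluded from mass statistics
#' downstream); non-converged fits are flagged, not dropped.
#'
#' @param ratio A [ratiometric_contrast()] stack.
#' @param candidate One-row tibble from [detect_candidates()].
#' @param model A [psf_model()].
#' @param params A [detection_params()] (patch radius, navg).
#' @return One-row tibble: `frame`, `row`, `col` (continuous px),
#'   `contrast`, `residual_rms`, `converged`, `edge`, plus the candidate's
#'   `score1`, `score2`, `cluster_size`.
#' @export
fit_event <- function(ratio, candidate, model = psf_model(),
                      params = detection_params()) {
  stopifnot(inherits(ratio, "ratio_stack"))
  d <- dim(ratio$frames)
  ti <- candidate$frame - ratio$t_first + 1L
  ti <- min(max(ti, 1L), d[3])
  pr <- params$patch_radius_px
  r0 <- candidate$row - pr; r1 <- candidate$row + pr
  c0 <- candidate$col - pr; c1 <- candidate$col + pr
  edge <- r0 < 1L || c0 < 1L || r1 > d[1] || c1 > d[2]
  r0 <- max(r0, 1L); c0 <- max(c0, 1L)
  r1 <- min(r1, d[1]); c1 <- min(c1, d[2])
  # Average the contrast patch over +/- fit_half_window frames around the
  # estimated landing frame and undo the known triangular attenuation
  # (a ratiometric frame d frames off the landing carries 1 - |d|/navg of
  # the amplitude). This makes the amplitude second-order insensitive to
  # small errors in the landing-frame estimate, which otherwise bias the
  # contrast low by |d|/navg.
  dd <- (-fit_half_window):fit_half_window
  dd <- dd[ti + dd >= 1L & ti + dd <= d[3]]
  atten <- mean(pmax(1 - abs(dd) / ratio$navg, 0))
  patch <- ratio$frames[r0:r1, c0:c1, ti + dd, drop = FALSE]
  patch <- rowMeans(patch, dims = 2L) / atten
  ri <- rep(r0:r1, times = c1 - c0 + 1L)
  ci <- rep(c0:c1, each = r1 - r0 + 1L)
  y <- as.vector(patch)
  b0 <- stats::median(y)
  a0 <- patch[candidate$row - r0 + 1L, candidate$col - c0 + 1L] - b0
  resid_fn <- function(p) {
    r <- sqrt((ri - p[2])^2 + (ci - p[3])^2)
    p[1] * psf_profile(r, model) + p[4] - y
  }
  fit <- try(suppressWarnings(minpack.lm::nls.lm(
    par = c(a0, candidate$row, candidate$col, b0),
    fn = resid_fn,
    lower = c(-Inf, candidate$row - pr, candidate$col - pr, -Inf),
    upper = c(Inf, candidate$row + pr, candidate$col + pr, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 100))), silent = TRUE)
  if (inherits(fit, "try-error")) {
    p <- c(a0, candidate$row, candidate$col, b0)
    conv <- FALSE
    rms <- sqrt(mean(resid_fn(p)^2))
  } else {
    p <- fit$par
    conv <- fit$info %in% 1:4
    rms <- sqrt(mean(fit$fvec^2))
  }
  tibble::tibble(frame = as.integer(candidate$frame),
                 row = p[2], col = p[3], contrast = abs(p[1]),
                 residual_rms = rms, converged = conv, edge = edge,
                 score1 = candidate$score1, score2 = candidate$score2,
                 cluster_size = candidate$cluster_size)
}

#' Fit all candidates of a movie
#'
#' @param ratio A [ratiometric_contrast()] stack.
#' @param candidates Tibble from [detect_candidates()].
#' @param model A [psf_model()].
#' @param params A [detection_params()].
#' @return Tibble of fitted events, one row per candidate.
#' @export
fit_events <- function(ratio, candidates, model = psf_model(),
                       params = detection_params()) {
  if (nrow(candidates) == 0L)
    return(tibble::tibble(frame = integer(), row = numeric(),
                          col = numeric(), contrast = numeric(),
                          residual_rms = numeric(), converged = logical(),
                          edge = logical(), score1 = numeric(),
                          score2 = numeric(), cluster_size = integer()))
  dplyr::bind_rows(lapply(seq_len(nrow(candidates)), function(i)
    fit_event(ratio, candidates[i, ], model, params)))
}

#' Run the full detection and fitting pipeline on one movie
#'
#' Convenience wrapper: ratiometric transform, two-filter candidate
#' detection, and per-candidate PSF fitting.
#'
#' @param movie An `mp_movie`.
#' @param params A [detection_params()].
#' @param model A [psf_model()].
#' @return List with `ratio`, `candidates`, and `events` (fitted).
#' @export
analyze_movie <- function(movie, params = detection_params(),
                          model = psf_model()) {
  mom <- window_moments(movie$stack, params$navg)
  ratio <- suppressWarnings(ratio_from_moments(mom))
  candidates <- detect_candidates(movie, ratio, params, .moments = mom)
  events <- fit_events(ratio, candidates, model, params)
  list(ratio = ratio, candidates = candidates, events = events)
}
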