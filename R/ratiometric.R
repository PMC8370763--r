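# Moving-window first/second moments of every pixel time trace.
#
# For each valid frame t the "before" block is [t-navg, t-1] and the "after"
# block [t, t+navg-1]; the landing frame belongs to the after block. Valid
# t run from navg+1 to n_frames-navg (1-based), so both blocks always have
# exactly navg frames. Returns per-pixel window means and unbiased
# variances as npix x nvalid matrices. Shared by the ratiometric transform
# and the detection filters; the rolling-window pass lives in C++ (src/).
window_moments <- function(stack, navg) {
  d <- dim(stack)
  npix <- d[1] * d[2]; nf <- d[3]
  navg <- as.integer(navg)
  if (navg < 2L) stop("navg must be >= 2")
  if (nf < 2L * navg + 1L)
    stop(sprintf("movie too short: need at least %d frames for navg = %d",
                 2L * navg + 1L, navg))
  mom <- window_moments_cpp(as.vector(stack), npix, nf, navg)
  mom$navg <- navg
  mom$t_first <- navg + 1L
  mom$n_valid <- nf - 2L * navg
  mom$dim <- d
  mom
}

ratio_from_moments <- function(mom) {
  bad <- sum(mom$mean_before <= 0)
  if (bad > 0)
    warning(sprintf("%d pixel value(s) with non-positive denominator", bad))
  fr <- mom$mean_after / mom$mean_before - 1
  structure(list(frames = array(fr, c(mom$dim[1], mom$dim[2], mom$n_valid)),
                 t_first = mom$t_first, navg = mom$navg,
                 n_bad_denom = bad),
            class = "ratio_stack")
}

#' Ratiometric background removal
#'
#' Converts an intensity movie into a stack of dimensionless contrast
#' frames by comparing temporally averaged blocks around every frame:
#'
#' \deqn{r_t = \frac{\mathrm{mean}(I_{t..t+n_{avg}-1})}
#'                  {\mathrm{mean}(I_{t-n_{avg}..t-1})} - 1}
#'
#' The ratio of block means removes any static background (speckle, uneven
#' illumination) exactly and is invariant under global intensity rescaling.
#' A landing event of contrast `a` produces a dip of amplitude `-a` at its
#' landing frame, ramping linearly over the window on either side. Contrast
#' frames exist only for frames with full before/after blocks; frames
#' outside that range are absent, not zero-filled.
#'
#' @param movie An `mp_movie`.
#' @param navg Window length in frames (production default 21).
#' @return An object of class `ratio_stack`: list with `frames` (3-D array
#'   `[row, col, valid_t]`), `t_first` (movie frame index, 1-based, of the
#'   first contrast frame), `navg`, and `n_bad_denom` (count of
#'   non-positive denominator pixels, flagged).
#' @export
ratiometric_contrast <- function(movie, navg = 21L) {
  stopifnot(inherits(movie, "mp_movie"))
  ratio_from_moments(window_moments(movie$stack, navg))
}

#' @export
print.ratio_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<ratio_stack> %d x %d px, %d contrast frames (navg = %d, t0 = %d)\n",
    d[1], d[2], d[3], x$navg, x$t_first))
  invisible(x)
}
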