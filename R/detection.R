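#' Detection parameters
#'
#' Parameters of the two-filter landing-event detector. `t1` thresholds the
#' temporal filter score `-ln(p)` (filter 1), where `p` is the two-sided
#' significance of the intensity jump between the `navg`-frame blocks before
#' and after a frame, referenced to the single-frame noise scale of the
#' pixel (see [filter1_stack()]). `t2` thresholds the radial-symmetry score
#' of the local ratiometric neighborhood (filter 2, in `[0, 1]`). The
#' production operating point of the analysis is `navg = 21`, `t1 = 1.2`,
#' `t2 = 0.15`.
#'
#' @param navg Temporal window length in frames.
#' @param t1 Filter-1 threshold on `-ln(p)` (>= 0).
#' @param t2 Filter-2 radial-symmetry threshold in `[0, 1]`.
#' @param patch_radius_px Half-width of the square neighborhood used for
#'   filter 2 and for PSF fitting (patch side `2*patch_radius_px + 1`).
#' @param min_cluster_px Minimum pixel-cluster size for a candidate.
#' @param merge_radius_px,merge_frames Spatiotemporal non-maximum
#'   suppression tolerances: of two candidates closer than these, only the
#'   higher filter-1 score survives. `merge_frames = NULL` defaults to
#'   `navg`, the temporal footprint of one landing.
#' @param statistic Filter-1 statistic: `"jump"` (production; jump amplitude
#'   referenced to single-frame noise) or `"welch"` (per-pixel Welch t-test
#'   of the window samples).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(navg = 21L, t1 = 1.2, t2 = 0.15,
                             patch_radius_px = 6L, min_cluster_px = 2L,
                             merge_radius_px = 5, merge_frames = NULL,
                             statistic = c("jump", "welch")) {
  statistic <- match.arg(statistic)
  navg <- as.integer(navg)
  if (navg < 2L) stop("navg must be >= 2")
  if (t1 < 0) stop("t1 must be >= 0")
  if (t2 < 0 || t2 > 1) stop("t2 must lie in [0, 1]")
  if (is.null(merge_frames)) merge_frames <- navg
  structure(list(navg = navg, t1 = t1, t2 = t2,
                 patch_radius_px = as.integer(patch_radius_px),
                 min_cluster_px = as.integer(min_cluster_px),
                 merge_radius_px = as.numeric(merge_radius_px),
                 merge_frames = as.integer(merge_frames),
                 statistic = statistic),
            class = "detection_params")
}

#' Welch two-sample t-test score
#'
#' The filter-1 score of a single pixel/frame in its textbook form:
#' `-ln(p)` where `p` is the two-sided p-value of Welch's unequal-variance
#' t-test comparing the `navg` intensity values before an event with the
#' `navg` values after it. Degenerate inputs (both samples constant and
#' equal) score 0; constant but different samples score `Inf`.
#'
#' @param before,after Numeric vectors of equal length >= 2.
#' @return The score `-ln(p)` (non-negative, possibly `Inf`).
#' @examples
#' ttest_score(rep(1, 21), rep(1, 21))   # 0
#' @export
ttest_score <- function(before, after) {
  n1 <- length(before); n2 <- length(after)
  if (n1 < 2L || n2 < 2L) stop("both samples need at least 2 values")
  m1 <- mean(before); m2 <- mean(after)
  v1 <- stats::var(before); v2 <- stats::var(after)
  se2 <- v1 / n1 + v2 / n2
  if (se2 <= 0) return(if (m1 == m2) 0 else Inf)
  tt <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  # -ln(2 * P(T_df > |t|)), computed on the log scale for stability
  -(log(2) + stats::pt(-abs(tt), df, log.p = TRUE))
}

# Jump-significance z statistic for all pixels/frames from window moments:
# z = (mean_after - mean_before) / s_frame, with s_frame the pooled
# single-frame standard deviation. Thresholding -ln(2*Phi(-|z|)) at t1 is
# equivalent to |z| >= qnorm(1 - exp(-t1)/2).
rel_noise_floor <- 1e-4

# The relative noise floor guards the degenerate zero-noise case: even an
# ideal shot-noise-free recording retains residual systematics (laser
# intensity noise, camera quantization) at the 1e-4 level of the local
# intensity, so the frame std is clamped there. Inactive at any realistic
# operating noise (~1e-3); scale-invariant by construction.
jump_z <- function(mom) {
  jump_z_cpp(mom$mean_before, mom$mean_after,
             mom$var_before, mom$var_after, rel_noise_floor)
}

jump_score_from_z <- function(z) {
  -(log(2) + stats::pnorm(-abs(z), log.p = TRUE))
}

welch_score_matrix <- function(mom) {
  n <- mom$navg
  se2 <- (mom$var_before + mom$var_after) / n
  se2 <- pmax(se2, (rel_noise_floor * mom$mean_before)^2 * 2 / n)  # same floor
  dmean <- mom$mean_after - mom$mean_before
  tt <- dmean / sqrt(se2)
  df <- se2^2 / ((mom$var_before / n)^2 / (n - 1) +
                 (mom$var_after / n)^2 / (n - 1))
  sc <- -(log(2) + stats::pt(-abs(tt), df, log.p = TRUE))
  sc[se2 <= 0 & dmean == 0] <- 0
  sc[se2 <= 0 & dmean != 0] <- Inf
  sc
}

#' Filter-1 score stack
#'
#' Scores every pixel of every valid frame for a sudden, persistent
#' intensity change: the `navg` raw-intensity values before the frame are
#' compared with the `navg` values from the frame on, and the score is
#' `-ln(p)` of the two-sided significance of the block difference.
#'
#' Two statistics are available. `"welch"` is the per-sample Welch t-test
#' ([ttest_score()]) applied to the window values. `"jump"` (the production
#' statistic) measures the block-mean difference in units of the pooled
#' single-frame noise, `z = (m_after - m_before)/s_frame`, and scores
#' `-ln(2*pnorm(-|z|))`: the threshold then directly controls the smallest
#' intensity-jump amplitude that exceeds the random noise fluctuations
#' (`t1 = 1.2` admits jumps above about 1.03 single-frame standard
#' deviations, i.e. 3.4 standard errors of the block difference), which is
#' what makes a sparse, cluster-forming detection mask possible. Both are
#' invariant under affine intensity rescaling of the movie.
#'
#' @param movie An `mp_movie`.
#' @param params A [detection_params()].
#' @return A list of class `score_stack`: `frames` (3-D array of scores),
#'   `t_first`, `navg`, `statistic`.
#' @export
filter1_stack <- function(movie, params = detection_params()) {
  stopifnot(inherits(movie, "mp_movie"), inherits(params, "detection_params"))
  mom <- window_moments(movie$stack, params$navg)
  sc <- switch(params$statistic,
               jump = jump_score_from_z(jump_z(mom)),
               welch = welch_score_matrix(mom))
  structure(list(frames = array(sc, c(mom$dim[1], mom$dim[2], mom$n_valid)),
                 t_first = mom$t_first, navg = mom$navg,
                 statistic = params$statistic),
            class = "score_stack")
}

# Cached radial geometry for a patch of half-width pr: unit vectors from
# every interior pixel to the patch center, center pixel excluded.
radial_geometry <- function(pr) {
  side <- 2L * pr + 1L
  idx <- 2:(side - 1L)                       # interior (central differences)
  off <- idx - (pr + 1L)
  dr <- matrix(off, length(idx), length(idx))
  dc <- t(dr)
  rad <- sqrt(dr^2 + dc^2)
  ur <- dr / rad; uc <- dc / rad
  ctr <- rad == 0
  ur[ctr] <- 0; uc[ctr] <- 0
  list(idx = idx, ur = ur, uc = uc)
}

rs_score_core <- function(patch, geom) {
  i <- geom$idx
  gr <- (patch[i + 1L, i] - patch[i - 1L, i]) / 2
  gc <- (patch[i, i + 1L] - patch[i, i - 1L]) / 2
  den <- sum(sqrt(gr^2 + gc^2))
  if (den <= 0) return(0)
  abs(sum(gr * geom$ur + gc * geom$uc)) / den
}

#' Radial symmetry score of an image patch
#'
#' Filter 2 of the detector: a bounded `[0, 1]` measure of how consistently
#' the local intensity gradients of a neighborhood point along the radial
#' direction to the patch center. With gradient `g_i` (central differences)
#' and radial unit vector `u_i` at interior pixel `i`:
#'
#' \deqn{s = \frac{|\sum_i g_i \cdot u_i|}{\sum_i |g_i|}}
#'
#' A radially symmetric spot (dip or peak) centered in the patch has every
#' gradient parallel to its radial direction with a common orientation, so
#' `s = 1`. For a planar ramp the signed radial projections cancel by
#' symmetry (`s` near 0), and for isotropic noise the incoherent sum stays
#' small (about `1/sqrt(n)`), so the production threshold `t2 = 0.15`
#' rejects both while keeping diffraction-limited spots.
#'
#' @param patch Square numeric matrix of odd side length >= 5.
#' @return Score in `[0, 1]`.
#' @export
radial_symmetry_score <- function(patch) {
  if (!is.matrix(patch) || nrow(patch) != ncol(patch))
    stop("patch must be a square matrix")
  side <- nrow(patch)
  if (side %% 2L == 0L) stop("patch side length must be odd")
  if (side < 5L) stop("patch too small for gradient estimation")
  pr <- (side - 1L) %/% 2L
  rs_score_core(patch, radial_geometry(pr))
}

# sparse 8-connected components via union-find over pixel keys
label_components8 <- function(rows, cols, nrow_field) {
  n <- length(rows)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  key <- (cols - 1L) * nrow_field + rows
  ord <- order(key)
  kmap <- key[ord]
  for (doff in list(c(1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L))) {
    nb <- (cols + doff[2] - 1L) * nrow_field + rows + doff[1]
    ok <- rows + doff[1] >= 1L & rows + doff[1] <= nrow_field
    j <- match(nb, kmap)
    hit <- which(!is.na(j) & ok)
    for (i in hit) {
      a <- find(i); b <- find(ord[j[i]])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Filter-2 score image of one contrast frame
#'
#' Evaluates the radial-symmetry score of every pixel neighborhood of a
#' single ratiometric frame at once, via FFT cross-correlations of the
#' gradient fields with the fixed radial-direction kernels. Identical (to
#' numerical precision) to calling [radial_symmetry_score()] on each
#' `(2*patch_radius+1)^2` patch; pixels closer than `patch_radius + 1` to
#' the border score 0.
#'
#' @param frame Numeric matrix (one ratiometric contrast frame).
#' @param patch_radius Neighborhood half-width in px.
#' @return Matrix of scores in `[0, 1]`, same size as `frame`.
#' @export
filter2_frame <- function(frame, patch_radius = 6L) {
  filter2_frame_fft(frame, fft_kernels(patch_radius, dim(frame)))
}

# precomputed FFTs of the radial-direction / unit kernels, zero-padded to
# the frame size and centered at (1,1) for cross-correlation
fft_kernels <- function(pr, d) {
  geom <- radial_geometry(pr)
  side <- 2L * pr - 1L              # interior grid of the patch
  embed <- function(k) {
    m <- matrix(0, d[1], d[2])
    # offset grid runs -(pr-1)..(pr-1); wrap negative offsets
    ix <- ((-(pr - 1L)):(pr - 1L)) %% d[1] + 1L
    iy <- ((-(pr - 1L)):(pr - 1L)) %% d[2] + 1L
    m[ix, iy] <- k
    stats::fft(m)
  }
  list(pr = pr, d = d,
       ur = embed(geom$ur), uc = embed(geom$uc),
       ones = embed(matrix(1, side, side)))
}

xcorr <- function(ffta, fftk, d) {
  Re(stats::fft(ffta * Conj(fftk), inverse = TRUE)) / prod(d)
}

filter2_frame_fft <- function(frame, kern) {
  d <- kern$d
  gr <- matrix(0, d[1], d[2]); gc <- matrix(0, d[1], d[2])
  i <- 2:(d[1] - 1L); j <- 2:(d[2] - 1L)
  gr[i, ] <- (frame[i + 1L, ] - frame[i - 1L, ]) / 2
  gc[, j] <- (frame[, j + 1L] - frame[, j - 1L]) / 2
  mag <- sqrt(gr^2 + gc^2)
  num <- abs(xcorr(stats::fft(gr), kern$ur, d) +
             xcorr(stats::fft(gc), kern$uc, d))
  den <- xcorr(stats::fft(mag), kern$ones, d)
  sc <- ifelse(den > 0, num / pmax(den, .Machine$double.xmin), 0)
  sc <- pmin(pmax(sc, 0), 1)
  pr <- kern$pr
  sc[c(seq_len(pr + 1L), (d[1] - pr):d[1]), ] <- 0
  sc[, c(seq_len(pr + 1L), (d[2] - pr):d[2])] <- 0
  sc
}

#' Detect candidate landing events
#'
#' Applies both filters to every valid frame, forms 8-connected pixel
#' clusters of the binary mask `(filter1 >= t1) & (filter2 >= t2)`, keeps
#' clusters of at least `min_cluster_px` pixels anchored at their maximal
#' filter-1 pixel, and suppresses duplicates of the same landing by keeping
#' only the highest filter-1 candidate within `merge_radius_px` and
#' `merge_frames` (non-maximum suppression).
#'
#' Filter 1 is evaluated on the raw intensity traces; filter 2 on the
#' ratiometric contrast frames, and never within `patch_radius_px + 1` of
#' the field border.
#'
#' @param movie An `mp_movie`.
#' @param ratio The matching [ratiometric_contrast()] stack (same `navg`).
#' @param params A [detection_params()].
#' @param .moments Optional precomputed [window_moments] of the movie (used
#'   internally to share work with the ratiometric transform).
#' @return A tibble of candidates: `frame` (movie frame of maximal filter-1
#'   response), `row`, `col` (integer pixel of the cluster anchor),
#'   `score1`, `score2`, `cluster_size`.
#' @export
detect_candidates <- function(movie, ratio, params = detection_params(),
                              .moments = NULL) {
  stopifnot(inherits(movie, "mp_movie"), inherits(ratio, "ratio_stack"),
            inherits(params, "detection_params"))
  if (ratio$navg != params$navg)
    stop("ratio stack navg does not match detection params")
  d <- dim(movie$stack)
  mom <- if (is.null(.moments)) window_moments(movie$stack, params$navg)
         else .moments
  empty <- tibble::tibble(frame = integer(), row = integer(),
                          col = integer(), score1 = numeric(),
                          score2 = numeric(), cluster_size = integer())
  if (params$statistic == "jump") {
    z <- jump_z(mom)
    zcrit <- -stats::qnorm(exp(-params$t1) / 2)
    pass1 <- abs(z) >= zcrit
  } else {
    sc1 <- welch_score_matrix(mom)
    pass1 <- sc1 >= params$t1
  }
  pass1[is.na(pass1)] <- FALSE
  if (!any(pass1)) return(empty)
  npix <- d[1] * d[2]
  cand <- list()
  PM <- matrix(pass1, npix)
  npass <- colSums(PM)
  frames_with <- which(npass >= params$min_cluster_px)
  # dense masks (the welch statistic) amortize better through the full
  # FFT score image; sparse masks through per-patch evaluation
  dense <- mean(npass[frames_with]) > 0.005 * npix
  kern <- if (dense) fft_kernels(params$patch_radius_px, d[1:2])
  pr <- params$patch_radius_px
  geom <- radial_geometry(pr)
  for (t in frames_with) {
    p1 <- which(PM[, t])
    if (dense) {
      f2img <- filter2_frame_fft(ratio$frames[, , t], kern)
      f2 <- f2img[p1]
    } else {
      f2 <- numeric(length(p1))
      rr <- ((p1 - 1L) %% d[1]) + 1L
      cc <- ((p1 - 1L) %/% d[1]) + 1L
      interior <- rr > pr + 1L & rr <= d[1] - pr - 1L &
                  cc > pr + 1L & cc <= d[2] - pr - 1L
      for (k in which(interior)) {
        patch <- ratio$frames[(rr[k] - pr):(rr[k] + pr),
                              (cc[k] - pr):(cc[k] + pr), t]
        f2[k] <- rs_score_core(patch, geom)
      }
    }
    sel <- p1[f2 >= params$t2]
    f2sel <- f2[f2 >= params$t2]
    if (length(sel) < params$min_cluster_px) next
    prow <- ((sel - 1L) %% d[1]) + 1L
    pcol <- ((sel - 1L) %/% d[1]) + 1L
    lab <- label_components8(prow, pcol, d[1])
    s1 <- if (params$statistic == "jump")
      jump_score_from_z(z[sel + (t - 1L) * npix])
    else sc1[sel + (t - 1L) * npix]
    for (lb in unique(lab)) {
      m <- which(lab == lb)
      if (length(m) < params$min_cluster_px) next
      a <- m[which.max(s1[m])]
      cand[[length(cand) + 1L]] <-
        list(frame = t, row = prow[a], col = pcol[a],
             score1 = s1[a], score2 = f2sel[a],
             cluster_size = length(m))
    }
  }
  if (!length(cand)) return(empty)
  cd <- tibble::tibble(
    frame = vapply(cand, `[[`, integer(1), "frame") + ratio$t_first - 1L,
    row = vapply(cand, `[[`, integer(1), "row"),
    col = vapply(cand, `[[`, integer(1), "col"),
    score1 = vapply(cand, `[[`, numeric(1), "score1"),
    score2 = vapply(cand, `[[`, numeric(1), "score2"),
    cluster_size = vapply(cand, `[[`, integer(1), "cluster_size"))
  # non-maximum suppression in (space, time); the kept candidate takes the
  # temporal centroid of its merged per-frame detections as its landing
  # frame (the per-frame response is symmetric around the landing, so the
  # centroid is unbiased where the score argmax is noise-picked)
  ord <- order(-cd$score1, -cd$cluster_size)
  alive <- rep(TRUE, nrow(cd))
  frame_fit <- cd$frame
  for (i in ord) {
    if (!alive[i]) next
    close_sp <- (cd$row - cd$row[i])^2 + (cd$col - cd$col[i])^2 <=
      params$merge_radius_px^2
    close_tm <- abs(cd$frame - cd$frame[i]) <= params$merge_frames
    grp <- which(close_sp & close_tm & alive)
    frame_fit[i] <- as.integer(round(mean(cd$frame[grp])))
    alive[setdiff(grp, i)] <- FALSE
  }
  cd$frame <- frame_fit
  out <- cd[alive, ]
  out[order(out$frame, out$row, out$col), ]
}
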