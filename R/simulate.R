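#' Parameters for synthetic landing-event movies
#'
#' Defines the study conditions emulated by the simulator: 1000 frames
#' carrying 100 landing events that may not approach each other closer than
#' 12 px spatially unless separated by at least 26 frames temporally, at an
#' effective frame rate of 500 Hz and 70.2 nm effective pixel size. The
#' default event contrast 2.2e-3 is the expected interferometric contrast of
#' a 42 kDa protein monomer.
#'
#' `noise_sigma` (per-pixel, per-frame temporal noise on a background of
#' 1.0) is the single free nuisance parameter of the simulation; the
#' benchmark module fixes it by anchoring the monomer true-positive rate
#' (see [calibrate_noise()]). The static speckle pattern emulates the glass
#' surface background; it is constant in time and therefore cancels in the
#' ratiometric processing.
#'
#' `edge_margin_px` keeps event centers away from the field border so that
#' every planted event has a full fitting neighborhood, mirroring the usual
#' border guard band of real analyses.
#'
#' @param n_frames Number of frames.
#' @param n_events Number of landing events.
#' @param field_px Field edge length in effective px.
#' @param contrast Event contrast magnitude(s); a scalar, or a vector that is
#'   sampled per event (recycled to `n_events`).
#' @param min_sep_px Spatial exclusion radius in px.
#' @param min_sep_frames Temporal exclusion in frames.
#' @param noise_sigma Std of i.i.d. per-pixel per-frame Gaussian noise.
#' @param speckle_amp Std of the static background speckle pattern.
#' @param speckle_corr_px Correlation length (Gaussian) of the speckle, px.
#' @param edge_margin_px Guard band between event centers and the border.
#' @param frame_rate_hz,pixel_size_nm Metadata stamped on the movie.
#' @param seed RNG seed used when none is supplied to the simulation calls.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_frames = 1000L, n_events = 100L,
                              field_px = 128L, contrast = 2.2e-3,
                              min_sep_px = 12, min_sep_frames = 26L,
                              noise_sigma = 0, speckle_amp = 5e-3,
                              speckle_corr_px = 3, edge_margin_px = 10,
                              frame_rate_hz = 500, pixel_size_nm = 70.2,
                              seed = 1L) {
  p <- list(n_frames = as.integer(n_frames), n_events = as.integer(n_events),
            field_px = as.integer(field_px), contrast = as.numeric(contrast),
            min_sep_px = as.numeric(min_sep_px),
            min_sep_frames = as.integer(min_sep_frames),
            noise_sigma = as.numeric(noise_sigma),
            speckle_amp = as.numeric(speckle_amp),
            speckle_corr_px = as.numeric(speckle_corr_px),
            edge_margin_px = as.numeric(edge_margin_px),
            frame_rate_hz = as.numeric(frame_rate_hz),
            pixel_size_nm = as.numeric(pixel_size_nm),
            seed = as.integer(seed))
  stopifnot(p$n_frames >= 1L, p$n_events >= 0L, p$field_px >= 4L,
            all(p$contrast >= 0), p$min_sep_px >= 0, p$min_sep_frames >= 0L,
            p$noise_sigma >= 0, p$speckle_amp >= 0, p$edge_margin_px >= 0)
  if (p$n_events > 0L && p$n_frames <= 2L * p$min_sep_frames)
    stop("n_frames too small for the temporal guard band")
  structure(p, class = "simulation_params")
}

#' Place ground-truth landing events under exclusion constraints
#'
#' Draws event positions uniformly over the allowed region (field minus the
#' edge guard band; landing frames keep `min_sep_frames` clear frames at
#' both ends so every event has full before/after windows), by rejection
#' sampling: a proposal is kept only if, against every accepted event, it is
#' at least `min_sep_px` away spatially OR at least `min_sep_frames` away
#' temporally.
#'
#' @param params A [simulation_params()].
#' @param seed Optional seed overriding `params$seed`.
#' @param max_tries Rejection-sampling budget before declaring the
#'   constraints infeasible.
#' @return A tibble with columns `frame` (integer landing frame, 1-based),
#'   `row`, `col` (continuous px, 1-based) and `contrast`.
#' @export
place_events <- function(params, seed = NULL, max_tries = 1e5) {
  stopifnot(inherits(params, "simulation_params"))
  if (!is.null(seed)) set.seed(seed) else set.seed(params$seed)
  n <- params$n_events
  contrasts <- rep_len(params$contrast, max(n, 1L))
  if (n == 0L)
    return(tibble::tibble(frame = integer(), row = numeric(),
                          col = numeric(), contrast = numeric()))
  lo <- 1 + params$edge_margin_px
  hi <- params$field_px - params$edge_margin_px
  if (hi <= lo) stop("edge margin leaves no room for events")
  f_lo <- params$min_sep_frames + 1L
  f_hi <- params$n_frames - params$min_sep_frames
  if (f_hi < f_lo) stop("no admissible landing frames")
  rows <- numeric(n); cols <- numeric(n); frames <- integer(n)
  placed <- 0L; tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("event placement infeasible after ", max_tries, " attempts")
    r <- stats::runif(1, lo, hi); c <- stats::runif(1, lo, hi)
    f <- sample.int(f_hi - f_lo + 1L, 1L) + f_lo - 1L
    if (placed > 0L) {
      i <- seq_len(placed)
      d2 <- (rows[i] - r)^2 + (cols[i] - c)^2
      ok <- d2 >= params$min_sep_px^2 |
        abs(frames[i] - f) >= params$min_sep_frames
      if (!all(ok)) next
    }
    placed <- placed + 1L
    rows[placed] <- r; cols[placed] <- c; frames[placed] <- f
  }
  tibble::tibble(frame = frames, row = rows, col = cols,
                 contrast = contrasts[seq_len(n)])
}

#' Pairwise exclusion check for an event list
#'
#' Brute-force O(n^2) verification that every event pair is separated by at
#' least `min_sep_px` spatially or `min_sep_frames` temporally.
#'
#' @param events Event tibble as returned by [place_events()].
#' @param min_sep_px,min_sep_frames Exclusion radii.
#' @return `TRUE` if all pairs satisfy the predicate, else `FALSE`.
#' @export
check_exclusion <- function(events, min_sep_px = 12, min_sep_frames = 26) {
  n <- nrow(events)
  if (n < 2L) return(TRUE)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- sqrt((events$row[i] - events$row[j])^2 +
              (events$col[i] - events$col[j])^2)
    df <- abs(events$frame[i] - events$frame[j])
    if (d < min_sep_px && df < min_sep_frames) return(FALSE)
  }
  TRUE
}

# Static speckle background: low-pass filtered Gaussian random field,
# normalized to unit std then scaled. FFT convolution with wrap-around.
speckle_field <- function(field_px, corr_px) {
  w <- matrix(stats::rnorm(field_px^2), field_px, field_px)
  if (corr_px <= 0) return(w)
  ax <- c(0:(field_px %/% 2), -((field_px - field_px %/% 2 - 1):1))
  g <- exp(-outer(ax^2, ax^2, `+`) / (2 * corr_px^2))
  g <- g / sum(g)
  f <- Re(stats::fft(stats::fft(w) * stats::fft(g), inverse = TRUE)) /
    field_px^2
  f / stats::sd(f)
}

#' Simulate a landing-event movie
#'
#' Builds a stack `1 + speckle + noise` and adds each event's rendered PSF
#' to every frame at or after its landing frame (a landed particle
#' persists). Deterministic for a fixed seed.
#'
#' @param params A [simulation_params()].
#' @param model A [psf_model()].
#' @param seed Optional seed overriding `params$seed`.
#' @return A list with elements `movie` (an `mp_movie`) and `truth` (the
#'   ground-truth event tibble).
#' @export
simulate_movie <- function(params, model = psf_model(), seed = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  if (is.null(seed)) seed <- params$seed
  truth <- place_events(params, seed = seed)
  # placement consumed part of the stream; background continues from there
  d <- c(params$field_px, params$field_px, params$n_frames)
  stack <- array(1, d)
  if (params$speckle_amp > 0) {
    sp <- params$speckle_amp * speckle_field(params$field_px,
                                             params$speckle_corr_px)
    stack <- stack + as.vector(sp)   # recycled over frames
  }
  if (params$noise_sigma > 0)
    stack <- stack + array(stats::rnorm(prod(d), sd = params$noise_sigma), d)
  movie <- mp_movie(stack,
                    movie_metadata(params$frame_rate_hz,
                                   params$pixel_size_nm, 1L, 1L,
                                   "normalized"))
  movie <- inject_events(movie, truth, model)
  list(movie = movie, truth = truth)
}

#' Inject landing events into an existing background movie
#'
#' Adds each event's PSF persistently from its landing frame to the end of
#' the movie; the background itself is untouched. This is the semi-synthetic
#' construction: planted ground-truth events over an arbitrary (e.g.
#' recorded or simulated buffer-only) background.
#'
#' @param movie Background `mp_movie`.
#' @param events Event tibble (`frame`, `row`, `col`, `contrast`).
#' @param model A [psf_model()].
#' @return A new `mp_movie` with events added.
#' @export
inject_events <- function(movie, events, model = psf_model()) {
  stopifnot(inherits(movie, "mp_movie"))
  d <- dim(movie$stack)
  if (d[1] != d[2] && nrow(events) > 0 &&
      (max(events$row) > d[1] || max(events$col) > d[2]))
    stop("event positions do not fit the background geometry")
  stack <- movie$stack
  nf <- d[3]
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (ev$frame < 1 || ev$frame > nf)
      stop("event landing frame outside the movie")
    if (ev$row < 1 || ev$row > d[1] || ev$col < 1 || ev$col > d[2])
      stop("event position outside the field")
    w <- render_event_window(min(d[1], d[2]), ev, model)
    tt <- ev$frame:nf
    stack[w$rows, w$cols, tt] <-
      stack[w$rows, w$cols, tt] + as.vector(w$patch)
  }
  mp_movie(stack, movie$metadata)
}

#' Write / read ground-truth event tables
#'
#' Plain CSV with columns `frame,row,col,contrast`.
#'
#' @param events Event tibble.
#' @param path CSV path.
#' @return `path` (write) or the event tibble (read).
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
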