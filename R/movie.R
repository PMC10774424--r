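#' Render a unit population as a synthetic movie
#'
#' Draws each unit as 1-5 Gaussian blobs inside a dedicated, non-overlapping
#' ROI box on a square field; pixel values are the sum of blob intensities
#' scaled by the unit's fluorescence trace, plus Gaussian pixel noise. Stands
#' in for raw image stacks with hand-segmented multi-neuron regions. All
#' coordinates are 0-based with half-open boxes `[x0, x1) x [y0, y1)`.
#'
#' @param population A `unit_population` from [simulate_unit_population()],
#'   or `NULL` together with `f` (frames x units matrix; may have 0 columns
#'   for a pure-noise stack).
#' @param field_px Field side length in pixels. Default 64.
#' @param roi_px ROI box side length in pixels. Default 8.
#' @param pixel_noise_sd Gaussian pixel noise SD. Default 1.
#' @param seed Integer seed (blob placement and pixel noise).
#' @param f Optional frames x units matrix overriding `population$f`.
#' @param n_neurons Optional integer vector (per unit) overriding
#'   `population$units$n_neurons`.
#'
#' @return A list of class `unit_movie`: `stack` (array height x width x
#'   frames), `rois` (tibble `unit_id, x0, y0, x1, y1`, 0-based half-open).
#' @export
render_movie <- function(population = NULL,
                         field_px = 64,
                         roi_px = 8,
                         pixel_noise_sd = 1,
                         seed = 1,
                         f = NULL,
                         n_neurons = NULL) {
  if (is.null(f)) {
    stopifnot(inherits(population, "unit_population"))
    f <- population$f
  }
  n_units <- ncol(f)
  n_frames <- nrow(f)
  if (is.null(n_neurons)) {
    n_neurons <- if (!is.null(population)) population$units$n_neurons
                 else rep(3L, n_units)
  }
  per_row <- floor(field_px / roi_px)
  if (n_units > per_row^2) {
    abort(sprintf("field too small: %d ROI slots for %d units",
                  per_row^2, n_units))
  }
  local_rng(seed)
  rois <- tibble(
    unit_id = colnames(f) %||% sprintf("u%03d", seq_len(n_units)),
    x0 = ((seq_len(n_units) - 1) %% per_row) * roi_px,
    y0 = ((seq_len(n_units) - 1) %/% per_row) * roi_px
  )
  if (n_units > 0) {
    rois$x1 <- rois$x0 + roi_px
    rois$y1 <- rois$y0 + roi_px
  } else {
    rois$x0 <- rois$y0 <- rois$x1 <- rois$y1 <- numeric(0)
  }

  stack <- array(rnorm(field_px * field_px * n_frames, 0, pixel_noise_sd),
                 c(field_px, field_px, n_frames))
  if (n_units > 0) {
    px <- seq_len(field_px) - 0.5  # pixel centers, 0-based geometry
    for (u in seq_len(n_units)) {
      k <- n_neurons[u]
      cx <- runif(k, rois$x0[u] + 1.5, rois$x1[u] - 1.5)
      cy <- runif(k, rois$y0[u] + 1.5, rois$y1[u] - 1.5)
      sig <- runif(k, 0.7, 1.2)
      blob <- matrix(0, field_px, field_px)
      for (b in seq_len(k)) {
        gx <- exp(-(px - cx[b])^2 / (2 * sig[b]^2))
        gy <- exp(-(px - cy[b])^2 / (2 * sig[b]^2))
        blob <- blob + outer(gy, gx)  # rows = y, cols = x
      }
      blob <- blob / sum(blob) * roi_px^2  # unit ROI mean of 1 per unit f
      ys <- (rois$y0[u] + 1):rois$y1[u]
      xs <- (rois$x0[u] + 1):rois$x1[u]
      sub <- blob[ys, xs]
      stack[ys, xs, ] <- stack[ys, xs, , drop = FALSE] +
        array(outer(as.vector(sub), f[, u]), c(length(ys), length(xs),
                                               n_frames))
    }
  }
  structure(list(stack = stack, rois = rois), class = "unit_movie")
}

#' Extract ROI-mean traces from a movie
#'
#' Computes the mean pixel value inside each ROI box for every frame. ROI
#' coordinates are 0-based and half-open; boxes outside the frame bounds are
#' rejected.
#'
#' @param stack Array height x width x frames (or a `unit_movie`).
#' @param rois Tibble with columns `unit_id, x0, y0, x1, y1` (ignored when
#'   `stack` is a `unit_movie` and `rois` is `NULL`).
#' @return A frames x ROIs matrix of ROI means, columns named by `unit_id`.
#' @export
extract_roi_traces <- function(stack, rois = NULL) {
  if (inherits(stack, "unit_movie")) {
    if (is.null(rois)) rois <- stack$rois
    stack <- stack$stack
  }
  stopifnot(length(dim(stack)) == 3, is.data.frame(rois))
  h <- dim(stack)[1]
  w <- dim(stack)[2]
  if (any(rois$x0 < 0 | rois$y0 < 0 | rois$x1 > w | rois$y1 > h |
            rois$x1 <= rois$x0 | rois$y1 <= rois$y0)) {
    abort("ROI out of frame bounds")
  }
  out <- vapply(seq_len(nrow(rois)), function(i) {
    ys <- (rois$y0[i] + 1):rois$y1[i]
    xs <- (rois$x0[i] + 1):rois$x1[i]
    colMeans(matrix(stack[ys, xs, ], length(ys) * length(xs), dim(stack)[3]))
  }, numeric(dim(stack)[3]))
  out <- matrix(out, nrow = dim(stack)[3])
  colnames(out) <- rois$unit_id
  out
}

#' Write a movie stack as multi-page TIFF with an ROI table
#'
#' @param movie A `unit_movie`.
#' @param tiff_path Path of the TIFF file (float samples).
#' @param roi_path Path of the ROI CSV (`unit_id, x0, y0, x1, y1`).
#' @return Invisibly, the paths.
#' @export
write_movie_tiff <- function(movie, tiff_path, roi_path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required to write TIFF stacks")
  }
  rng <- range(movie$stack)
  span <- if (diff(rng) > 0) diff(rng) else 1
  frames <- lapply(seq_len(dim(movie$stack)[3]),
                   function(k) (movie$stack[, , k] - rng[1]) / span)
  tiff::writeTIFF(frames, tiff_path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(offset = rng[1], scale = span),
                       paste0(tiff_path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  readr::write_csv(movie$rois, roi_path)
  invisible(c(tiff_path, roi_path))
}

#' Read a movie stack written by [write_movie_tiff()]
#'
#' @param tiff_path Path of the multi-page TIFF.
#' @param roi_path Path of the ROI CSV.
#' @return A `unit_movie` list.
#' @export
read_movie_tiff <- function(tiff_path, roi_path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required to read TIFF stacks")
  }
  frames <- tiff::readTIFF(tiff_path, all = TRUE)
  stack <- array(unlist(frames), c(dim(frames[[1]]), length(frames)))
  meta_path <- paste0(tiff_path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    stack <- stack * meta$scale + meta$offset
  }
  rois <- readr::read_csv(roi_path, show_col_types = FALSE)
  structure(list(stack = stack, rois = as_tibble(rois)),
            class = "unit_movie")
}
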