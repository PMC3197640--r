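#' Camera model for synthetic marker videos
#'
#' Describes the synthetic video geometry used to exercise the
#' figure-recognition stage: a grayscale frame (intensities in \[0, 1\])
#' containing two dark square markers at the post tips (the top and bottom
#' ends of the EHT), whose separation shrinks as the tissue contracts.
#'
#' @param pixels_per_mm image scale.
#' @param frame_rate nominal frame rate, Hz; must be at least twice the
#'   beating frequency being recorded.
#' @param frame_width,frame_height frame size in pixels (columns, rows).
#' @param noise_sd sd of additive Gaussian pixel noise (intensity units).
#' @param background,foreground background and marker intensity levels.
#' @param marker_size_mm side length of the square markers, mm.
#' @return object of class `camera_model`.
#' @export
camera_model <- function(pixels_per_mm = 10, frame_rate = 50,
                         frame_width = 24, frame_height = 160,
                         noise_sd = 0, background = 0.8, foreground = 0.2,
                         marker_size_mm = 1) {
  stopifnot(pixels_per_mm > 0, frame_rate > 0, frame_width >= 4,
            frame_height >= 8, noise_sd >= 0, background > foreground,
            marker_size_mm > 0)
  structure(list(pixels_per_mm = pixels_per_mm, frame_rate = frame_rate,
                 frame_width = as.integer(frame_width),
                 frame_height = as.integer(frame_height),
                 noise_sd = noise_sd, background = background,
                 foreground = foreground, marker_size_mm = marker_size_mm),
            class = "camera_model")
}

# exact coverage of interval [lo, hi] (pixel units) within each unit pixel
pixel_coverage <- function(lo, hi, n) {
  j <- seq_len(n)
  pmax(0, pmin(hi, j) - pmax(lo, j - 1))
}

#' Render synthetic video frames from a deflection trace
#'
#' Renders one grayscale frame per trace sample: two dark square markers a
#' distance `rest_separation_mm - delta(t)/1000` apart (posts bend toward
#' each other during contraction), drawn with exact sub-pixel area
#' coverage, plus optional Gaussian pixel noise. Deterministic per seed.
#' A marker reaching the frame edge is a render error.
#'
#' @param trace a [contraction_trace()] in `"um"` (deflection). Frames are
#'   rendered on the trace's own time grid, which must respect the
#'   camera's Nyquist condition.
#' @param camera a [camera_model()].
#' @param rest_separation_mm marker separation at rest (diastole), mm.
#' @param seed integer seed for pixel noise.
#' @return object of class `frame_stack`: `frames` (list of matrices,
#'   rows = y), `timestamps`, `camera`, `rest_separation_mm`, and
#'   `truth_centers_px` (true marker centre rows per frame, for
#'   validation).
#' @export
render_frames <- function(trace, camera, rest_separation_mm = 10, seed = 1L) {
  stopifnot(inherits(trace, "contraction_trace"),
            inherits(camera, "camera_model"))
  if (trace_unit(trace) != "um") {
    stop_param("render_frames needs a deflection trace (um)")
  }
  ppm <- camera$pixels_per_mm
  h <- camera$frame_height; w <- camera$frame_width
  half_px <- camera$marker_size_mm * ppm / 2
  x_c <- w / 2
  cov_x <- pixel_coverage(x_c - half_px, x_c + half_px, w)
  h_mm <- h / ppm
  y_top_mm <- (h_mm - rest_separation_mm) / 2
  sep_mm <- rest_separation_mm - trace$value / 1000
  y_bot_mm <- y_top_mm + sep_mm
  lo <- (y_top_mm * ppm) - half_px
  hi <- (y_bot_mm * ppm) + half_px
  if (y_top_mm * ppm - half_px < 0 || max(y_bot_mm) * ppm + half_px > h ||
      x_c - half_px < 0 || x_c + half_px > w || min(sep_mm) * ppm < 2 * half_px) {
    stop_param("marker leaves the frame (or markers collide); ",
               "enlarge the frame or rest separation")
  }
  amp <- camera$foreground - camera$background
  cov_top <- pixel_coverage(y_top_mm * ppm - half_px,
                            y_top_mm * ppm + half_px, h)
  with_seed(seed, {
    frames <- lapply(seq_len(nrow(trace)), function(i) {
      y_b <- y_bot_mm[i] * ppm
      cov_y <- cov_top + pixel_coverage(y_b - half_px, y_b + half_px, h)
      fr <- camera$background + amp * outer(cov_y, cov_x)
      if (camera$noise_sd > 0) {
        fr <- fr + matrix(stats::rnorm(h * w, 0, camera$noise_sd), h, w)
      }
      fr
    })
    structure(list(frames = frames, timestamps = trace$time_s,
                   camera = camera,
                   rest_separation_mm = rest_separation_mm,
                   truth_centers_px = cbind(top = rep(y_top_mm * ppm,
                                                      nrow(trace)),
                                            bottom = y_bot_mm * ppm)),
              class = "frame_stack")
  })
}

# Otsu's automatic threshold on a 256-bin histogram
otsu_threshold <- function(v) {
  r <- range(v)
  if (diff(r) == 0) return(r[1])
  breaks <- seq(r[1], r[2], length.out = 257)
  counts <- tabulate(findInterval(v, breaks, all.inside = TRUE), 256)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w1 <- cumsum(counts)
  w2 <- sum(counts) - w1
  m1 <- cumsum(counts * mids) / pmax(w1, 1)
  m2 <- (sum(counts * mids) - cumsum(counts * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  mids[which.max(between)]
}

# 4-connected component labelling of a logical matrix (breadth-first)
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  todo <- which(mask)
  for (p in todo) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    queue <- p
    lab[p] <- cur
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (q - 1L) %% h + 1L
      cc <- (q - 1L) %/% h + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc2 <- cc + d[2]
        if (rr >= 1L && rr <= h && cc2 >= 1L && cc2 <= w) {
          q2 <- (cc2 - 1L) * h + rr
          if (mask[q2] && lab[q2] == 0L) {
            lab[q2] <- cur
            queue <- c(queue, q2)
          }
        }
      }
    }
  }
  lab
}

# grow a logical mask by one pixel in the four cardinal directions
dilate1 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  out[-1, ] <- out[-1, ] | mask[-h, ]
  out[-h, ] <- out[-h, ] | mask[-1, ]
  out[, -1] <- out[, -1] | mask[, -w]
  out[, -w] <- out[, -w] | mask[, -1]
  out
}

#' Detect the two post markers in one frame
#'
#' Segments dark pixels with an automatic (Otsu) intensity threshold, keeps
#' the two largest 4-connected components, grows each by one pixel to
#' recover partially covered edge pixels, and returns their
#' darkness-weighted centroids (weights `median(frame) - intensity`,
#' clipped at zero), which gives sub-pixel precision on area-coverage
#' rendered markers. Any other component count flags the frame as lost.
#'
#' @param frame numeric matrix (grayscale image, rows = y).
#' @return list: `ok` (logical), and when `ok`, `centroids` -- a 2x2 matrix
#'   with columns `y`, `x` (pixel units), rows ordered top to bottom.
#' @export
detect_markers <- function(frame) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  thr <- otsu_threshold(as.numeric(frame))
  mask <- frame < thr
  if (!any(mask) || all(mask)) return(list(ok = FALSE))
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  big <- order(sizes, decreasing = TRUE)
  big <- big[sizes[big] >= 4]       # ignore speckle components
  if (length(big) < 2) return(list(ok = FALSE))
  big <- big[1:2]
  if (length(sizes) > 2 && any(sizes[-big] >= 4)) return(list(ok = FALSE))
  bg <- stats::median(frame)
  cents <- t(vapply(big, function(b) {
    m <- dilate1(lab == b)
    idx <- which(m)
    wgt <- pmax(bg - frame[idx], 0)
    r <- (idx - 1L) %% nrow(frame) + 1L
    cc <- (idx - 1L) %/% nrow(frame) + 1L
    c(y = sum(wgt * (r - 0.5)) / sum(wgt),
      x = sum(wgt * (cc - 0.5)) / sum(wgt))
  }, numeric(2)))
  cents <- cents[order(cents[, "y"]), , drop = FALSE]
  list(ok = TRUE, centroids = cents)
}

#' Track post deflection through a frame stack
#'
#' Runs [detect_markers()] on every frame, converts the inter-marker
#' separation to millimetres, estimates the rest (diastolic) separation as
#' the upper decile of the separation series, and returns the deflection
#' trace `delta(t) = rest - separation(t)`. Lost frames are linearly
#' interpolated and counted; more than 5% lost is a tracking error.
#'
#' @param stack a `frame_stack` from [render_frames()].
#' @return a [contraction_trace()] in `"um"`, with attributes
#'   `lost_frames` (count) and `rest_separation_mm` (estimate).
#' @export
track_deflection <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  ppm <- stack$camera$pixels_per_mm
  sep_px <- vapply(stack$frames, function(fr) {
    d <- detect_markers(fr)
    if (!d$ok) NA_real_ else diff(d$centroids[, "y"])
  }, numeric(1))
  lost <- sum(is.na(sep_px))
  if (lost > 0.05 * length(sep_px)) {
    stop_param("more than 5% of frames lost marker detection")
  }
  if (lost > 0) {
    ok <- !is.na(sep_px)
    sep_px <- stats::approx(stack$timestamps[ok], sep_px[ok],
                            xout = stack$timestamps, rule = 2)$y
  }
  sep_mm <- sep_px / ppm
  rest_mm <- eht_percentile(sep_mm, 0.9)
  tr <- contraction_trace(stack$timestamps, (rest_mm - sep_mm) * 1000,
                          unit = "um", well_id = "video")
  attr(tr, "lost_frames") <- lost
  attr(tr, "rest_separation_mm") <- rest_mm
  tr
}
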