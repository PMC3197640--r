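#' Sarcomere orientation sample
#'
#' Orientation angles of prominent sarcomeric structures measured in one
#' immunofluorescence image by one rater. Orientations are axial
#' (undirected), defined modulo 180 degrees; angles are canonicalised into
#' \[0, 180) on construction. 10-20 structures per image is the advisory
#' protocol range.
#'
#' @param angles_deg numeric vector of orientation angles, degrees.
#' @param image_id,rater_id labels.
#' @return object of class `angle_sample`.
#' @export
angle_sample <- function(angles_deg, image_id = "img", rater_id = "r1") {
  stopifnot(is.numeric(angles_deg), all(is.finite(angles_deg)))
  structure(list(angles = angles_deg %% 180,
                 image_id = image_id, rater_id = rater_id),
            class = "angle_sample")
}

# circular axial mean direction of a set of orientations, degrees in [0,180)
axial_mean_deg <- function(angles_deg) {
  th <- angles_deg * pi / 90  # doubled angles in radians
  (atan2(mean(sin(th)), mean(cos(th))) * 90 / pi) %% 180
}

#' Angle dispersion of a sarcomere orientation sample
#'
#' Interquartile range of the orientation angles, after axial
#' canonicalisation: the sample is rotated so its circular axial mean maps
#' to 90 degrees and folded into \[0, 180), which makes the dispersion
#' invariant under a common rotation of the whole image and avoids the
#' 0/180 wrap-around artefact. Percentiles follow the package convention
#' ([eht_percentile()]). For a concentrated sample away from the wrap this
#' reduces to the plain IQR.
#'
#' @param sample an [angle_sample()] (or a bare numeric vector of degrees),
#'   at least 4 angles.
#' @return dispersion in degrees.
#' @export
angle_dispersion <- function(sample) {
  angles <- if (inherits(sample, "angle_sample")) sample$angles
            else as.numeric(sample) %% 180
  if (length(angles) < 4) stop_param("angle_dispersion needs >= 4 angles")
  centred <- (angles - axial_mean_deg(angles) + 90) %% 180
  q <- eht_percentile(centred, c(0.25, 0.75))
  q[2] - q[1]
}

#' Alignment score
#'
#' The inverse of the relative angle dispersion, with dispersion expressed
#' relative to 90 degrees (90 deg = 100% = 1). A dispersion of 9 degrees
#' (10%, 0.1) therefore scores 10; 90 degrees scores 1. Zero dispersion is
#' returned as `Inf` with attribute `degenerate = TRUE` rather than a
#' fabricated finite score.
#'
#' @param dispersion_deg angle dispersion in degrees, >= 0.
#' @return dimensionless score `90 / dispersion_deg`.
#' @export
alignment_score <- function(dispersion_deg) {
  if (!is_scalar_num(dispersion_deg) || dispersion_deg < 0) {
    stop_param("dispersion must be a non-negative number of degrees")
  }
  if (dispersion_deg == 0) {
    return(structure(Inf, degenerate = TRUE))
  }
  90 / dispersion_deg
}

#' Aggregate alignment scores and compare tissue formats
#'
#' Computes one alignment score per (image, rater) sample, averages scores
#' across raters within each image first, then summarises per group
#' (e.g. EHT vs EB format) and compares the two groups with a two-sample
#' two-tailed Student's t-test (equal variances). Images with missing
#' raters are kept with the raters available and flagged.
#'
#' @param angles data.frame with columns `image_id`, `rater_id`,
#'   `angle_deg`, `group` (exactly two groups, >= 2 images each).
#' @return list of class `alignment_comparison`: `per_image` (image, group,
#'   n_raters, score), `per_group` (group, n_images, mean, sd), `t`,
#'   `p_value`.
#' @export
aggregate_alignment <- function(angles) {
  stopifnot(is.data.frame(angles),
            all(c("image_id", "rater_id", "angle_deg", "group") %in%
                  names(angles)))
  groups <- unique(angles$group)
  if (length(groups) != 2) stop_param("exactly two groups are required")
  per_image <- do.call(rbind, lapply(unique(angles$image_id), function(img) {
    sub <- angles[angles$image_id == img, ]
    raters <- unique(sub$rater_id)
    scores <- vapply(raters, function(r) {
      a <- sub$angle_deg[sub$rater_id == r]
      alignment_score(angle_dispersion(angle_sample(a, img, r)))
    }, numeric(1))
    data.frame(image_id = img, group = sub$group[1],
               n_raters = length(raters), score = mean(scores))
  }))
  n_img <- table(per_image$group)
  if (any(n_img < 2)) stop_param("each group needs >= 2 images")
  per_group <- do.call(rbind, lapply(groups, function(g) {
    s <- per_image$score[per_image$group == g]
    data.frame(group = g, n_images = length(s), mean = mean(s),
               sd = stats::sd(s))
  }))
  a <- per_image$score[per_image$group == groups[1]]
  b <- per_image$score[per_image$group == groups[2]]
  if (isTRUE(all.equal(stats::sd(c(a - mean(a), b - mean(b))), 0)) ||
      (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))) {
    t <- 0; p <- 1  # identical groups: no evidence of difference
  } else {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    t <- unname(tt$statistic); p <- tt$p.value
  }
  structure(list(per_image = per_image, per_group = per_group,
                 t = t, p_value = p),
            class = "alignment_comparison")
}

#' Generate synthetic sarcomere orientation angles
#'
#' Axial wrapped-normal sample: angles concentrated around `mean_deg` with
#' spread `sd_deg` (EHT-like alignment along the force lines), or uniform
#' on \[0, 180) when `sd_deg = Inf` (EB-like random orientation).
#'
#' @param n number of structures measured.
#' @param mean_deg mean orientation, degrees.
#' @param sd_deg angular spread, degrees; `Inf` for uniform.
#' @param seed integer seed.
#' @return numeric vector of angles in \[0, 180).
#' @export
generate_angles <- function(n, mean_deg = 90, sd_deg = 10, seed = 1L) {
  stopifnot(n >= 1, sd_deg >= 0)
  with_seed(seed, {
    if (is.infinite(sd_deg)) stats::runif(n, 0, 180)
    else (mean_deg + stats::rnorm(n, 0, sd_deg)) %% 180
  })
}
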