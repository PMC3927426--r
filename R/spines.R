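#' Define a synthetic dendrite/spine scene
#'
#' Geometry and photometry of a dendritic segment with spines, for
#' rendering longitudinal 3D fluorescence stacks with known ground truth.
#' Spines and shaft are rendered as 3D Gaussians (intrinsic size convolved
#' with the imaging point-spread function); stacks get mixed
#' Poisson-Gaussian noise.
#'
#' @param dendrite_path `n x 3` matrix of path vertices (um).
#' @param spine_positions `m x 3` matrix of spine head centers (um).
#' @param spine_intensities Total fluorescence per spine (arbitrary units,
#'   >= 0).
#' @param shaft_intensity Shaft fluorescence density (units/um, >= 0).
#' @param background_intensity Constant background level (>= 0).
#' @param voxel_size_um Length-3 voxel size (x, y, z; > 0).
#' @param psf_sigma_um PSF Gaussian sigma (um; scalar isotropic or
#'   length 3).
#' @param turnover List with `p_lost_per_2h` (probability in `[0, 1]` that
#'   a spine disappears over 2 h) and `size_scale_per_24h` (multiplicative
#'   intensity change per 24 h).
#' @param spine_sigma_um Intrinsic spine-head Gaussian sigma (um).
#' @param shaft_sigma_um Intrinsic shaft radius sigma (um).
#' @return A `spine_scene` object.
#' @export
spine_scene <- function(dendrite_path, spine_positions, spine_intensities,
                        shaft_intensity = 50, background_intensity = 2,
                        voxel_size_um = c(0.3, 0.3, 1),
                        psf_sigma_um = 0.3,
                        turnover = list(p_lost_per_2h = 0,
                                        size_scale_per_24h = 1),
                        spine_sigma_um = 0.35, shaft_sigma_um = 0.3) {
  dendrite_path <- as.matrix(dendrite_path)
  spine_positions <- as.matrix(spine_positions)
  stopifnot(ncol(dendrite_path) == 3, ncol(spine_positions) == 3,
            nrow(spine_positions) == length(spine_intensities),
            all(spine_intensities >= 0), shaft_intensity >= 0,
            background_intensity >= 0, all(voxel_size_um > 0))
  p <- turnover$p_lost_per_2h %||% 0
  stopifnot(p >= 0, p <= 1)
  if (length(psf_sigma_um) == 1) psf_sigma_um <- rep(psf_sigma_um, 3)
  structure(list(dendrite_path = dendrite_path,
                 spine_positions = spine_positions,
                 spine_intensities = spine_intensities,
                 shaft_intensity = shaft_intensity,
                 background_intensity = background_intensity,
                 voxel_size_um = voxel_size_um,
                 psf_sigma_um = psf_sigma_um,
                 turnover = list(p_lost_per_2h = p,
                                 size_scale_per_24h =
                                   turnover$size_scale_per_24h %||% 1),
                 spine_sigma_um = spine_sigma_um,
                 shaft_sigma_um = shaft_sigma_um),
            class = "spine_scene")
}

#' A default straight-dendrite scene with evenly spaced spines
#'
#' @param n_spines Number of spines.
#' @param length_um Dendrite length (um).
#' @param seed Seed for spine intensities.
#' @param ... Passed to [spine_scene()].
#' @return A [spine_scene()].
#' @export
default_spine_scene <- function(n_spines = 12, length_um = 24, seed = 1,
                                ...) {
  set.seed(seed)
  xs <- seq(2, length_um - 2, length.out = n_spines)
  side <- rep(c(1, -1), length.out = n_spines)
  path <- cbind(seq(0, length_um, by = 0.5), 6, 5)
  pos <- cbind(xs, 6 + side * 3.0, 5)
  spine_scene(dendrite_path = path, spine_positions = pos,
              spine_intensities = runif(n_spines, 60, 140), ...)
}

.gauss_blob <- function(arr, center_vox, sigma_vox, total) {
  dims <- dim(arr)
  idx <- vector("list", 3)
  g <- vector("list", 3)
  for (a in 1:3) {
    half <- max(2L, ceiling(4 * sigma_vox[a]))
    r <- floor(center_vox[a] - half):ceiling(center_vox[a] + half)
    r <- r[r >= 1 & r <= dims[a]]
    if (!length(r)) return(arr)
    k <- exp(-0.5 * ((r - center_vox[a]) / sigma_vox[a])^2)
    idx[[a]] <- r
    g[[a]] <- k / sum(k)
  }
  blob <- outer(outer(g[[1]], g[[2]]), g[[3]]) * total
  arr[idx[[1]], idx[[2]], idx[[3]]] <-
    arr[idx[[1]], idx[[2]], idx[[3]]] + blob
  arr
}

#' Generate longitudinal synthetic spine image stacks
#'
#' Renders one 3D stack per imaging session. Between sessions, each spine
#' is lost with the scene's per-2-h probability (losses are permanent) and
#' surviving spine intensities scale as `size_scale_per_24h^(dt / 24)`.
#' The ground-truth table records per-session presence and intensity
#' scale; head/shaft/background ROIs are derived from the scene geometry.
#'
#' @param scene A [spine_scene()].
#' @param session_times_h Session times (h, >= 2 sessions, increasing).
#' @param seed Integer seed.
#' @param noise `NULL` for noiseless stacks, or a list with `gain`
#'   (photons per intensity unit, Poisson stage) and `read_sd` (Gaussian
#'   read noise SD, intensity units).
#' @param margin_um Empty margin around the scene (um).
#' @return Object of class `spine_stacks`: `stacks` (list of 3D arrays),
#'   `truth` (`data.frame`: `session`, `time_h`, `spine_id`, `present`,
#'   `scale`, `true_total`), `rois` (per spine: `head`, `shaft`;
#'   plus `background`), `voxel_size_um`, `session_times_h`.
#' @export
generate_spine_stacks <- function(scene, session_times_h = c(0, 2, 24, 26),
                                  seed = 1, noise = list(gain = 20,
                                                         read_sd = 0.05),
                                  margin_um = 3) {
  stopifnot(inherits(scene, "spine_scene"), length(session_times_h) >= 2,
            !is.unsorted(session_times_h))
  set.seed(seed)
  vox <- scene$voxel_size_um
  allpts <- rbind(scene$dendrite_path, scene$spine_positions)
  lo <- apply(allpts, 2, min) - margin_um
  hi <- apply(allpts, 2, max) + margin_um
  dims <- pmax(4L, ceiling((hi - lo) / vox))
  if (any(scene$spine_positions < rep(lo, each = nrow(scene$spine_positions))) ||
      any(scene$spine_positions > rep(hi, each = nrow(scene$spine_positions))))
    stop("scene geometry exceeds the stack bounds")
  to_vox <- function(p) (p - lo) / vox + 0.5   # voxel-center coordinates

  sig_spine <- sqrt(scene$spine_sigma_um^2 + scene$psf_sigma_um^2) / vox
  sig_shaft <- sqrt(scene$shaft_sigma_um^2 + scene$psf_sigma_um^2) / vox

  # shaft samples every 0.2 um of arc length
  path <- scene$dendrite_path
  seglen <- sqrt(rowSums(diff(path)^2))
  shaft_pts <- do.call(rbind, lapply(seq_len(nrow(path) - 1), function(i) {
    nstep <- max(1L, ceiling(seglen[i] / 0.2))
    s <- seq(0, 1, length.out = nstep + 1)[-(nstep + 1)]
    cbind(path[i, 1] + s * (path[i + 1, 1] - path[i, 1]),
          path[i, 2] + s * (path[i + 1, 2] - path[i, 2]),
          path[i, 3] + s * (path[i + 1, 3] - path[i, 3]))
  }))
  ds <- sum(seglen) / nrow(shaft_pts)

  base <- array(scene$background_intensity, dims)
  for (i in seq_len(nrow(shaft_pts)))
    base <- .gauss_blob(base, to_vox(shaft_pts[i, ]), sig_shaft,
                        scene$shaft_intensity * ds)

  n_sp <- nrow(scene$spine_positions)
  n_se <- length(session_times_h)
  present <- matrix(TRUE, n_se, n_sp)
  p_lost <- scene$turnover$p_lost_per_2h
  for (j in seq_len(n_se)[-1]) {
    dt <- session_times_h[j] - session_times_h[j - 1]
    p_keep <- (1 - p_lost)^(dt / 2)
    present[j, ] <- present[j - 1, ] & (runif(n_sp) < p_keep)
  }
  scale_t <- scene$turnover$size_scale_per_24h^(session_times_h / 24)

  stacks <- vector("list", n_se)
  truth <- list()
  for (j in seq_len(n_se)) {
    st <- base
    for (i in seq_len(n_sp)) {
      if (present[j, i])
        st <- .gauss_blob(st, to_vox(scene$spine_positions[i, ]), sig_spine,
                          scene$spine_intensities[i] * scale_t[j])
    }
    if (!is.null(noise)) {
      g <- noise$gain %||% 20
      st <- array(rpois(length(st), pmax(st, 0) * g) / g +
                    rnorm(length(st), 0, noise$read_sd %||% 0), dims)
    }
    stacks[[j]] <- st
    truth[[j]] <- data.frame(session = j, time_h = session_times_h[j],
                             spine_id = seq_len(n_sp),
                             present = present[j, ], scale = scale_t[j],
                             true_total = scene$spine_intensities *
                               scale_t[j] * present[j, ])
  }

  box <- function(cv, half) {
    list(x = c(max(1L, floor(cv[1] - half[1])),
               min(dims[1], ceiling(cv[1] + half[1]))),
         y = c(max(1L, floor(cv[2] - half[2])),
               min(dims[2], ceiling(cv[2] + half[2]))),
         z = c(max(1L, floor(cv[3] - half[3])),
               min(dims[3], ceiling(cv[3] + half[3]))))
  }
  rois <- lapply(seq_len(n_sp), function(i) {
    cv <- to_vox(scene$spine_positions[i, ])
    d2 <- rowSums((shaft_pts - matrix(scene$spine_positions[i, ],
                                      nrow(shaft_pts), 3, byrow = TRUE))^2)
    near <- shaft_pts[order(d2)[seq_len(min(10, nrow(shaft_pts)))], ,
                      drop = FALSE]   # ~2-um shaft segment nearest the neck
    sv <- to_vox(colMeans(near))
    list(head = box(cv, pmax(2, 2.5 * sig_spine)),
         shaft = box(sv, pmax(1.5, 2 * sig_shaft)))
  })
  # background: a large slab inside the empty margin on the low-y side,
  # big enough that its mean is far more precise than head-ROI photometry
  background <- list(x = c(2L, max(3L, dims[1] - 1L)),
                     y = c(2L, max(3L, floor((margin_um - 1.2) / vox[2]))),
                     z = c(1L, dims[3]))
  structure(list(stacks = stacks, truth = do.call(rbind, truth),
                 rois = rois, background = background,
                 voxel_size_um = vox, session_times_h = session_times_h,
                 scene = scene),
            class = "spine_stacks")
}

#' @export
print.spine_stacks <- function(x, ...) {
  d <- dim(x$stacks[[1]])
  cat(sprintf("Spine stacks: %d sessions of %dx%dx%d voxels, %d spines\n",
              length(x$stacks), d[1], d[2], d[3],
              nrow(x$scene$spine_positions)))
  invisible(x)
}

.roi_values <- function(stack, roi) {
  stack[roi$x[1]:roi$x[2], roi$y[1]:roi$y[2], roi$z[1]:roi$z[2]]
}

#' Measure normalized spine size from a 3D stack
#'
#' Integrated optical density of the spine head (sum over the head ROI
#' minus the mean background times the ROI voxel count), normalized to the
#' background-subtracted mean brightness of the adjacent dendritic shaft.
#' Negative integrated densities are clipped to 0 with a warning.
#' Optional Gaussian smoothing is for display/detection only; measurements
#' are taken on unsmoothed intensities.
#'
#' @param stack 3D numeric array.
#' @param head_roi,shaft_roi,background_roi ROI boxes: lists with `x`,
#'   `y`, `z` index ranges (`c(lo, hi)`).
#' @return One-row `data.frame`: `integrated_od`, `shaft_mean`,
#'   `normalized_size`.
#' @export
measure_spine_size <- function(stack, head_roi, shaft_roi, background_roi) {
  for (r in list(head_roi, shaft_roi, background_roi))
    if (any(vapply(r, function(v) v[2] < v[1], TRUE)))
      stop("empty ROI")
  bg <- mean(.roi_values(stack, background_roi))
  head_v <- .roi_values(stack, head_roi)
  iod <- sum(head_v) - bg * length(head_v)
  if (iod < 0) {
    warning("negative integrated optical density clipped to 0")
    iod <- 0
  }
  shaft_mean <- mean(.roi_values(stack, shaft_roi)) - bg
  if (shaft_mean <= 0) stop("shaft ROI is not brighter than background")
  data.frame(integrated_od = iod, shaft_mean = shaft_mean,
             normalized_size = iod / shaft_mean)
}

#' Measure every spine of a generated stack set
#'
#' @param stacks A [generate_spine_stacks()] object.
#' @param sessions Sessions to measure (default all).
#' @return `data.frame` with `session`, `time_h`, `spine_id`, `present`
#'   (ground truth) and the [measure_spine_size()] columns.
#' @export
measure_spine_stacks <- function(stacks, sessions = NULL) {
  stopifnot(inherits(stacks, "spine_stacks"))
  if (is.null(sessions)) sessions <- seq_along(stacks$stacks)
  out <- list()
  for (j in sessions) {
    for (i in seq_along(stacks$rois)) {
      m <- measure_spine_size(stacks$stacks[[j]], stacks$rois[[i]]$head,
                              stacks$rois[[i]]$shaft, stacks$background)
      tr <- stacks$truth[stacks$truth$session == j &
                           stacks$truth$spine_id == i, ]
      out[[length(out) + 1L]] <- cbind(
        data.frame(session = j, time_h = tr$time_h, spine_id = i,
                   present = tr$present), m)
    }
  }
  do.call(rbind, out)
}

#' Spine size index across a 24-h imaging interval
#'
#' Ratio of a spine's normalized size at the later session to the earlier
#' one (`time 24 size / time 0 size`). Spines absent in either session or
#' with zero size at time 0 are excluded (`NA`).
#'
#' @param size_t0,size_t24 Normalized sizes ([measure_spine_size()]) of
#'   matched spines at the two sessions.
#' @param present_t0,present_t24 Optional presence flags.
#' @return Numeric vector of size indices (`NA` where undefined).
#' @export
spine_size_index <- function(size_t0, size_t24, present_t0 = NULL,
                             present_t24 = NULL) {
  stopifnot(length(size_t0) == length(size_t24))
  idx <- size_t24 / size_t0
  idx[size_t0 <= 0] <- NA_real_
  if (!is.null(present_t0)) idx[!present_t0] <- NA_real_
  if (!is.null(present_t24)) idx[!present_t24] <- NA_real_
  idx
}

#' Spine stability across a 2-h imaging interval
#'
#' Percentage of the spines present in the first session that are still
#' present in the second.
#'
#' @param present_t0,present_t1 Logical presence vectors for matched
#'   spines.
#' @return Percentage in `[0, 100]`.
#' @export
spine_stability <- function(present_t0, present_t1) {
  stopifnot(length(present_t0) == length(present_t1))
  n0 <- sum(present_t0)
  if (n0 == 0) stop("no spines present in the first session")
  100 * sum(present_t0 & present_t1) / n0
}

#' Match spines across sessions by nearest neighbor
#'
#' Greedy nearest-neighbor matching of spine coordinates within a
#' tolerance (after any rigid alignment the caller applies).
#'
#' @param pos_a,pos_b `n x 3` coordinate matrices (um).
#' @param tol_um Maximum match distance (um).
#' @return `data.frame` with `a`, `b` (row indices; `NA` where unmatched)
#'   for every spine in `pos_a`.
#' @export
match_spines <- function(pos_a, pos_b, tol_um = 0.5) {
  pos_a <- as.matrix(pos_a); pos_b <- as.matrix(pos_b)
  used <- rep(FALSE, nrow(pos_b))
  b_idx <- rep(NA_integer_, nrow(pos_a))
  for (i in seq_len(nrow(pos_a))) {
    d <- sqrt(rowSums((pos_b - matrix(pos_a[i, ], nrow(pos_b), 3,
                                      byrow = TRUE))^2))
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_um) {
      b_idx[i] <- j
      used[j] <- TRUE
    }
  }
  data.frame(a = seq_len(nrow(pos_a)), b = b_idx)
}

#' Write / read a 3D stack as multi-page TIFF
#'
#' Stacks are stored as 32-bit float TIFF pages (one z-plane per page),
#' scaled to `[0, 1]` by `scale`.
#'
#' @param stack 3D array.
#' @param path File path.
#' @param scale Intensity scale factor; values are divided by it on write
#'   and multiplied back on read.
#' @return `path` (write) or the 3D array (read).
#' @export
write_stack_tiff <- function(stack, path, scale = max(stack)) {
  pages <- lapply(seq_len(dim(stack)[3]), function(z)
    pmin(pmax(stack[, , z] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  attr(path, "scale") <- scale
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- pages[[z]]
  arr * scale
}
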