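#' Layered wall-thickness measurement by normal rays
#'
#' Emulates caliper-style thickness measurement of a layered wall: at
#' `n_locations` sample points spread evenly over the wall mid-surface, a
#' ray is cast along the local wall normal and the chord length of each
#' sublayer along that ray is reported in micrometres.
#'
#' The mid-surface and normals come from two distance fields: distance to
#' the endocardial-side exterior and to the epicardial-side exterior
#' (exterior voxels adjacent to the endocardial / epicardial layer,
#' respectively). Mid-surface voxels are those where the two distances are
#' nearly equal; the normal is the gradient of their difference. "Evenly
#' distributed" means equally spaced positions along the mid-surface's
#' principal extent (first principal component of the mid-surface voxel
#' cloud); when several mid-surface voxels are equally near a target
#' position, one is chosen reproducibly by the seed. Layer boundaries
#' along each ray are located by bisection on the label field, so an
#' axis-aligned slab is measured exactly.
#'
#' @param labels a [label_map] (or integer array) with sublayer labels
#'   `layer_labels` forming a contiguous wall and 0 outside.
#' @param n_locations number of measurement locations (`>= 1`).
#' @param seed integer seed for the reproducible location choice.
#' @param voxel_size_um voxel size (µm); from the label-map attribute when
#'   available.
#' @param layer_labels integer labels of the endocardial, myocardial and
#'   epicardial sublayers, in order from the inner side.
#' @param layer_names names attached to the sublayer factor.
#' @return An object of class `thickness_set`: a data frame with columns
#'   `location`, `sublayer` (factor), `thickness_um`, plus one row per
#'   location with `sublayer = "total"` omitted — totals are available via
#'   `attr(x, "total_um")`. Locations whose ray leaves the volume before
#'   crossing all layers are skipped with a warning; fewer usable
#'   locations than requested is an error.
#' @export
measure_layer_thickness <- function(labels, n_locations = 15, seed = 1,
                                    voxel_size_um = NULL,
                                    layer_labels = c(1L, 2L, 3L),
                                    layer_names = c("endocardium",
                                                    "myocardium",
                                                    "epicardium")) {
  v <- vol_voxel(labels, voxel_size_um)
  lab <- vol_data(labels)
  d <- dim(lab)
  stopifnot(n_locations >= 1, length(layer_labels) == 3L)
  wall <- array(lab %in% layer_labels, d)
  if (!any(wall)) stop("no wall voxels found", call. = FALSE)

  # exterior compartments touching the inner / outer sublayer
  ext <- !wall
  inner_seed <- dilate1(array(lab == layer_labels[1], d)) & ext
  outer_seed <- dilate1(array(lab == layer_labels[3], d)) & ext
  if (!any(inner_seed) || !any(outer_seed))
    stop("wall does not separate an inner and an outer exterior",
         call. = FALSE)
  de <- .edt3(inner_seed, d)
  dp <- .edt3(outer_seed, d)

  mid <- wall & abs(de - dp) <= 1
  if (!any(mid)) stop("empty wall mid-surface", call. = FALSE)
  idx <- which(mid)
  ai <- arrayInd(idx, d)

  # interior voxels only (central differences need all six neighbors)
  interior <- ai[, 1] > 1 & ai[, 1] < d[1] & ai[, 2] > 1 & ai[, 2] < d[2] &
    ai[, 3] > 1 & ai[, 3] < d[3]
  if (!any(interior)) stop("wall mid-surface touches the volume border",
                           call. = FALSE)
  ai <- ai[interior, , drop = FALSE]
  idx <- idx[interior]
  pts <- cbind((ai[, 3] - 1), (ai[, 2] - 1), (ai[, 1] - 1)) # voxel (x,y,z)

  # outward normals from the smoothed inner-vs-outer distance difference
  sdf <- gauss_filter3(de - dp, 1.0)
  s2 <- d[1]; s3 <- d[1] * d[2]
  gz <- (sdf[idx + 1] - sdf[idx - 1]) / 2
  gy <- (sdf[idx + s2] - sdf[idx - s2]) / 2
  gx <- (sdf[idx + s3] - sdf[idx - s3]) / 2
  nn <- sqrt(gx^2 + gy^2 + gz^2)
  defined <- nn > 0
  nrm_all <- cbind(gx, gy, gz) / nn

  # measurable mid-surface: the full-thickness ray along +-normal must
  # stay inside the volume (clearance estimated from the distance fields)
  Lout <- dp[idx] + 3   # outward travel to the epicardial-side exterior
  Lin <- de[idx] + 3    # inward travel to the endocardial-side exterior
  inb <- function(p, k) p >= 0 & p <= d[k] - 1
  clear <- defined &
    inb(pts[, 1] + Lout * nrm_all[, 1], 3) &
    inb(pts[, 1] - Lin * nrm_all[, 1], 3) &
    inb(pts[, 2] + Lout * nrm_all[, 2], 2) &
    inb(pts[, 2] - Lin * nrm_all[, 2], 2) &
    inb(pts[, 3] + Lout * nrm_all[, 3], 1) &
    inb(pts[, 3] - Lin * nrm_all[, 3], 1)
  if (!any(clear))
    stop("no measurable mid-surface location: every normal ray leaves the volume",
         call. = FALSE)
  ai <- ai[clear, , drop = FALSE]
  pts <- pts[clear, , drop = FALSE]
  nrm_all <- nrm_all[clear, , drop = FALSE]

  # locations spread evenly along the principal extent of the measurable
  # mid-surface
  pc <- prcomp(pts, center = TRUE, scale. = FALSE)
  tcoord <- pc$x[, 1]
  tr <- range(tcoord)
  targets <- tr[1] + (seq_len(n_locations) - 0.5) / n_locations * diff(tr)

  records <- list()
  totals <- numeric(0)
  used <- 0L
  skipped <- 0L
  max_try <- 30L

  for (li in seq_len(n_locations)) {
    tt <- targets[li]
    # candidates nearest the target position along the principal extent;
    # ties broken by a seeded shuffle so the choice is reproducible
    ord <- order(abs(tcoord - tt))
    cand <- ord[seq_len(min(max_try, length(ord)))]
    cand <- with_seed(seed + li, {
      eps <- abs(tcoord[cand] - tt)
      cand[order(eps, sample.int(length(cand)))]
    })
    chords <- NULL
    for (ci in cand) {
      chords <- ray_layer_chords(lab, d, pts[ci, ], nrm_all[ci, ],
                                 layer_labels)
      if (!is.null(chords)) break
    }
    if (is.null(chords)) { skipped <- skipped + 1L; next }
    used <- used + 1L
    records[[used]] <- data.frame(
      location = used,
      sublayer = layer_names,
      thickness_um = chords * v
    )
    totals[used] <- sum(chords) * v
  }
  if (skipped > 0)
    warning(sprintf("%d location(s) skipped: ray left the volume", skipped))
  if (used < n_locations)
    stop(sprintf("only %d of %d locations usable", used, n_locations),
         call. = FALSE)
  out <- do.call(rbind, records)
  out$sublayer <- factor(out$sublayer, levels = layer_names)
  attr(out, "total_um") <- totals
  attr(out, "voxel_size_um") <- v
  class(out) <- c("thickness_set", class(out))
  out
}

# 6-neighborhood binary dilation
dilate1 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

# nearest-neighbor label lookup at continuous voxel coordinates (x, y, z);
# returns -1L outside the grid
label_at <- function(lab, d, p) {
  ix <- round(p[1]) + 1; iy <- round(p[2]) + 1; iz <- round(p[3]) + 1
  if (ix < 1 || iy < 1 || iz < 1 || ix > d[3] || iy > d[2] || iz > d[1])
    return(-1L)
  lab[iz, iy, ix]
}

# refine a label transition between ray parameters t0 (label a) and t1 by
# bisection; returns the crossing parameter
bisect_crossing <- function(lab, d, p0, nrm, t0, t1, a) {
  for (i in 1:60) {
    tm <- (t0 + t1) / 2
    if (identical(label_at(lab, d, p0 + tm * nrm), a)) t0 <- tm else t1 <- tm
    if (t1 - t0 < 1e-9) break
  }
  (t0 + t1) / 2
}

# chord length (in voxels) of each wall layer along the ray through p0
# (voxel coords) with unit direction nrm; NULL if the ray leaves the grid
# before clearing the wall on either side
ray_layer_chords <- function(lab, d, p0, nrm, layer_labels) {
  step <- 0.25
  limit <- sum(d)   # generous travel bound
  walk <- function(sgn) {
    t <- 0
    repeat {
      t <- t + step
      if (t > limit) return(NA_real_)
      l <- label_at(lab, d, p0 + sgn * t * nrm)
      if (l == -1L) return(NA_real_)              # left the volume
      if (!(l %in% layer_labels)) return(sgn * t)
    }
  }
  t_in <- walk(-1); t_out <- walk(1)
  if (is.na(t_in) || is.na(t_out)) return(NULL)

  # find all label transitions between t_in and t_out by coarse scan +
  # bisection refinement
  ts <- seq(t_in, t_out, by = step)
  if (ts[length(ts)] < t_out) ts <- c(ts, t_out)
  labs <- vapply(ts, function(t) label_at(lab, d, p0 + t * nrm), integer(1))
  cuts <- numeric(0); seq_labs <- labs[1]
  for (i in seq_len(length(ts) - 1L)) {
    if (labs[i + 1] != labs[i]) {
      cuts <- c(cuts, bisect_crossing(lab, d, p0, nrm, ts[i], ts[i + 1],
                                      labs[i]))
      seq_labs <- c(seq_labs, labs[i + 1])
    }
  }
  bounds <- c(t_in, cuts, t_out)
  seg_len <- diff(bounds)
  chords <- vapply(layer_labels, function(L)
    sum(seg_len[seq_labs == L]), numeric(1))
  if (any(chords <= 0)) return(NULL)              # ray missed a layer
  chords
}

#' @export
print.thickness_set <- function(x, ...) {
  cat(sprintf("<thickness_set> %d locations x %d sublayers\n",
              max(x$location), nlevels(x$sublayer)))
  print(summary.thickness_set(x))
  invisible(x)
}

#' @export
summary.thickness_set <- function(object, ...) {
  agg <- aggregate(thickness_um ~ sublayer, data = object,
                   FUN = function(z) c(mean = mean(z), sd = sd(z)))
  data.frame(sublayer = agg$sublayer,
             mean_um = agg$thickness_um[, "mean"],
             sd_um = agg$thickness_um[, "sd"])
}

#' Mitral-annular-disjunction profile
#'
#' Measures the displacement of the valve-hinge curve from the myocardial
#' crest curve in fixed angular steps around the annulus. Both curves are
#' parameterized by their angle about the annular axis; at each grid
#' angle, the two curves are linearly interpolated and the disjunction is
#' the distance between the interpolated points — along the axis by
#' default (`mode = "axial"`), or the full 3-D distance
#' (`mode = "euclidean"`).
#'
#' @param hinge,crest [landmark_curve()] objects (hinge of the mural
#'   leaflet; crest of the adjacent ventricular myocardium).
#' @param axis_origin,axis_direction annular axis (point and direction,
#'   `(x, y, z)` µm). A fitted [centerline()] can supply both.
#' @param step_deg angular step of the profile (degrees); 5 by default.
#' @param mode `"axial"` or `"euclidean"`.
#' @param origin_angle_deg angular origin; default is the angle of the
#'   first hinge point.
#' @return An object of class `mad_profile`: data frame with columns
#'   `angle_deg` (strictly increasing, constant step) and
#'   `disjunction_um` (`>= 0`).
#' @export
compute_mad_profile <- function(hinge, crest, axis_origin, axis_direction,
                                step_deg = 5,
                                mode = c("axial", "euclidean"),
                                origin_angle_deg = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(hinge, "landmark_curve"),
            inherits(crest, "landmark_curve"), step_deg > 0)
  ax <- axis_direction / sqrt(sum(axis_direction^2))
  ob <- orthobasis(ax)

  param <- function(curve) {
    p <- sweep(curve_points(curve), 2, axis_origin)
    s <- drop(p %*% ax)
    r <- p - s %o% ax
    th <- atan2(drop(r %*% ob$v), drop(r %*% ob$u)) * 180 / pi
    th <- unwrap_deg(th)
    list(theta = th, s = s, p = curve_points(curve))
  }
  H <- param(hinge); C <- param(crest)

  if (is.null(origin_angle_deg)) origin_angle_deg <- H$theta[1]
  H$theta <- H$theta - origin_angle_deg
  C$theta <- C$theta - origin_angle_deg
  # bring the crest arc onto the same 360-degree branch as the hinge arc
  C$theta <- C$theta -
    360 * round((mean(range(C$theta)) - mean(range(H$theta))) / 360)

  for (obj in list(H, C)) {
    gaps <- abs(diff(obj$theta))
    if (length(gaps) && max(gaps) > step_deg)
      stop(sprintf(
        "angular gap of %.2f deg exceeds the %.2f deg step: refusing to interpolate",
        max(gaps), step_deg), call. = FALSE)
  }

  lo <- max(min(H$theta), min(C$theta))
  hi <- min(max(H$theta), max(C$theta))
  if (lo >= hi)
    stop("hinge and crest arcs do not overlap", call. = FALSE)
  grid <- seq(lo, hi, by = step_deg)

  if (mode == "axial") {
    hs <- approx(H$theta, H$s, xout = grid)$y
    cs <- approx(C$theta, C$s, xout = grid)$y
    dist <- abs(hs - cs)
  } else {
    interp3 <- function(P, th) {
      cbind(approx(th, P[, 1], xout = grid)$y,
            approx(th, P[, 2], xout = grid)$y,
            approx(th, P[, 3], xout = grid)$y)
    }
    hp <- interp3(H$p, H$theta); cp <- interp3(C$p, C$theta)
    dist <- sqrt(rowSums((hp - cp)^2))
  }
  structure(
    data.frame(angle_deg = grid, disjunction_um = dist),
    class = c("mad_profile", "data.frame"),
    mode = mode, step_deg = step_deg
  )
}

# unwrap a degree sequence so consecutive differences are < 180 in
# magnitude (curves sampled finely around an arc)
unwrap_deg <- function(th) {
  if (length(th) < 2) return(th)
  d <- diff(th)
  d <- d - 360 * round(d / 360)
  th[1] + c(0, cumsum(d))
}

#' @export
print.mad_profile <- function(x, ...) {
  cat(sprintf(
    "<mad_profile> %d nodes, %g deg step (%s mode)\n  disjunction %.1f-%.1f um (mean %.1f)\n",
    nrow(x), attr(x, "step_deg"), attr(x, "mode"),
    min(x$disjunction_um), max(x$disjunction_um), mean(x$disjunction_um)))
  invisible(x)
}

#' @export
plot.mad_profile <- function(x, ...) {
  plot(x$angle_deg, x$disjunction_um, type = "b", pch = 16,
       xlab = "angle around annulus (deg)", ylab = "disjunction (um)",
       main = "Mitral annular disjunction profile", ...)
  invisible(x)
}

#' Contrast-to-noise ratio of tissue ROIs against a background ROI
#'
#' For each replicate region of interest, `CNR = |mean(tissue) -
#' mean(background)| / sd(background)`, the single-background CNR
#' definition with the embedding medium (agar) as background. Note the
#' exact formula used by any particular acquisition report may differ;
#' this definition is invariant under global affine intensity maps with
#' positive gain.
#'
#' @param volume an [image_volume].
#' @param tissue_rois either an integer array on the volume grid whose
#'   distinct positive values are replicate ROIs of one tissue, or a named
#'   list of such arrays (one per tissue, e.g. aorta / LV wall /
#'   epicardial fat with 5 replicates each).
#' @param background_roi logical or 0/1 array marking the background ROI.
#' @return An object of class `cnr_report`: data frame with one row per
#'   tissue x replicate (`tissue`, `replicate`, `tissue_mean`,
#'   `tissue_sd`, `background_mean`, `background_sd`, `cnr`) plus a
#'   per-tissue summary in `attr(x, "summary")` (mean and sd of CNR over
#'   replicates).
#' @export
compute_cnr <- function(volume, tissue_rois, background_roi) {
  stopifnot(is_image_volume(volume))
  a <- volume$data
  bg <- vol_data(background_roi) != 0
  if (!any(bg)) stop("background ROI is empty", call. = FALSE)
  bg_vals <- a[bg]
  if (length(bg_vals) < 2 || sd(bg_vals) == 0)
    stop("undefined CNR: background sd is zero", call. = FALSE)
  mu_b <- mean(bg_vals); sd_b <- sd(bg_vals)

  if (!is.list(tissue_rois)) tissue_rois <- list(tissue = tissue_rois)
  if (is.null(names(tissue_rois)))
    names(tissue_rois) <- paste0("tissue", seq_along(tissue_rois))

  rows <- list()
  for (tn in names(tissue_rois)) {
    roi <- vol_data(tissue_rois[[tn]])
    if (any(roi != 0 & bg))
      stop("tissue ROI overlaps the background ROI", call. = FALSE)
    reps <- sort(unique(roi[roi > 0]))
    if (length(reps) == 0)
      stop(sprintf("tissue ROI '%s' is empty", tn), call. = FALSE)
    for (rp in reps) {
      vals <- a[roi == rp]
      rows[[length(rows) + 1L]] <- data.frame(
        tissue = tn, replicate = as.integer(rp),
        tissue_mean = mean(vals), tissue_sd = sd(vals),
        background_mean = mu_b, background_sd = sd_b,
        cnr = abs(mean(vals) - mu_b) / sd_b
      )
    }
  }
  out <- do.call(rbind, rows)
  smry <- aggregate(cnr ~ tissue, data = out,
                    FUN = function(z) c(mean = mean(z), sd = sd(z),
                                        n = length(z)))
  smry <- data.frame(tissue = smry$tissue,
                     cnr_mean = smry$cnr[, "mean"],
                     cnr_sd = smry$cnr[, "sd"],
                     n = as.integer(smry$cnr[, "n"]))
  structure(out, class = c("cnr_report", class(out)), summary = smry)
}

#' @export
print.cnr_report <- function(x, ...) {
  cat("<cnr_report> per-replicate CNR against the background ROI\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  cat("summary over replicates:\n")
  print.data.frame(attr(x, "summary"), digits = 4, row.names = FALSE)
  invisible(x)
}
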