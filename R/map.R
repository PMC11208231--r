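## Cortical map features: amplitude-weighted centre of gravity and map area
## (alpha-shape or convex hull of the MEP-positive sites on their best-fit
## plane).

#' Centre of gravity of a motor map
#'
#' The amplitude-weighted centroid of the MEP-positive stimulation sites:
#' `CoG_axis = sum(V_i * coord_i) / sum(V_i)` per axis, with `V_i` the MEP
#' peak-to-peak amplitude at site `i`. Coordinates are in template (MNI-like)
#' millimetres: X medio-lateral, Y posterior-anterior, Z vertical.
#'
#' @param coords numeric matrix (n x 3) of site coordinates in mm.
#' @param amplitudes positive MEP amplitudes in microvolts, length n.
#' @return named numeric 3-vector `c(x, y, z)` in mm.
#' @examples
#' compute_cog(rbind(c(0, 0, 0), c(2, 0, 0)), c(1, 1))  # (1, 0, 0)
#' @export
compute_cog <- function(coords, amplitudes) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) stop("no sites supplied", call. = FALSE)
  if (ncol(coords) != 3L) stop("coords must be n x 3", call. = FALSE)
  if (length(amplitudes) != nrow(coords)) {
    stop("one amplitude per site required", call. = FALSE)
  }
  if (any(!is.finite(coords)) || any(!is.finite(amplitudes))) {
    stop("coordinates and amplitudes must be finite", call. = FALSE)
  }
  if (any(amplitudes <= 0)) {
    stop("site amplitudes must be positive", call. = FALSE)
  }
  w <- amplitudes / sum(amplitudes)
  out <- as.numeric(crossprod(w, coords))
  names(out) <- c("x", "y", "z")
  out
}

## ---------------------------------------------------------------------------
## 2-D Delaunay triangulation (Bowyer-Watson) and alpha-complex area.
## Coordinates are deterministically micro-jittered for the *topology* only
## (breaks exact cocircularity, e.g. on regular grids); triangle areas and
## circumradii are evaluated on the original coordinates.

circumcircle <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < .Machine$double.eps * 1e3 *
      max(abs(c(ax, ay, bx, by, cx, cy, 1)))^2) {
    return(c(NA_real_, NA_real_, Inf))
  }
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  c(ux, uy, sqrt((ux - ax)^2 + (uy - ay)^2))
}

## Deterministic pseudo-jitter independent of R's RNG state.
.jitter_unit <- function(i) {
  (((i * 2654435761) %% 4294967296) / 4294967296) - 0.5
}

#' Delaunay triangulation of planar points
#'
#' Bowyer-Watson incremental triangulation. Exactly cocircular
#' configurations (regular grids) are disambiguated by a deterministic
#' micro-jitter that only affects which diagonal is chosen, not the
#' coordinates reported.
#'
#' @param x,y point coordinates.
#' @return integer matrix, one row per triangle, columns the three vertex
#'   indices into `x`/`y`; zero rows if fewer than 3 points or all points
#'   collinear.
#' @export
delaunay_triangulation <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) return(matrix(integer(0), ncol = 3L))
  scale <- max(diff(range(x)), diff(range(y)), 1e-12)
  eps <- 1e-9 * scale
  jx <- x + eps * vapply(seq_len(n), .jitter_unit, numeric(1))
  jy <- y + eps * vapply(seq_len(n) + n, .jitter_unit, numeric(1))

  cx <- mean(range(jx)); cy <- mean(range(jy))
  R <- 20 * scale
  px <- c(jx, cx - 2 * R, cx + 2 * R, cx)
  py <- c(jy, cy - R, cy - R, cy + 2 * R)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L

  tris <- matrix(c(s1, s2, s3), ncol = 3L)
  circ <- matrix(circumcircle(px[s1], py[s1], px[s2], py[s2], px[s3], py[s3]),
                 ncol = 3L)

  for (i in seq_len(n)) {
    inside <- (px[i] - circ[, 1])^2 + (py[i] - circ[, 2])^2 <= circ[, 3]^2
    inside[!is.finite(circ[, 3])] <- TRUE
    bad <- which(inside)
    if (length(bad) == 0L) next  # degenerate; point on no circumcircle
    edges <- rbind(tris[bad, c(1L, 2L), drop = FALSE],
                   tris[bad, c(2L, 3L), drop = FALSE],
                   tris[bad, c(3L, 1L), drop = FALSE])
    key <- paste(pmin(edges[, 1], edges[, 2]),
                 pmax(edges[, 1], edges[, 2]))
    boundary <- edges[key %in% names(which(table(key) == 1L)), ,
                      drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    circ <- circ[-bad, , drop = FALSE]
    if (nrow(boundary) > 0L) {
      newt <- cbind(boundary, i)
      newc <- t(apply(newt, 1L, function(tr) {
        circumcircle(px[tr[1]], py[tr[1]], px[tr[2]], py[tr[2]],
                     px[tr[3]], py[tr[3]])
      }))
      tris <- rbind(tris, newt)
      circ <- rbind(circ, newc)
    }
  }
  keep <- tris[, 1] <= n & tris[, 2] <= n & tris[, 3] <= n
  out <- tris[keep, , drop = FALSE]
  dimnames(out) <- NULL
  out
}

triangle_area <- function(ax, ay, bx, by, cx, cy) {
  abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay)) / 2
}

#' Planar map area by alpha shape or convex hull
#'
#' `convex_hull` is the area of the convex hull polygon (shoelace formula).
#' `alpha_shape` is the area of the alpha complex: the union of Delaunay
#' triangles whose circumradius is at most `alpha`; it tends to the convex
#' hull as `alpha` grows and carves out large empty regions (non-convex
#' maps) at small `alpha`.
#'
#' @param x,y planar coordinates in mm.
#' @param method `"alpha_shape"` (default) or `"convex_hull"`.
#' @param alpha alpha radius in mm (default 15).
#' @return area in mm^2.
#' @export
planar_area <- function(x, y, method = c("alpha_shape", "convex_hull"),
                        alpha = 15) {
  method <- match.arg(method)
  if (length(x) < 3L) return(0)
  if (method == "convex_hull") {
    h <- grDevices::chull(x, y)
    return(polygon_area(x[h], y[h]))
  }
  check_scalar(alpha, "alpha", lower = 0, strict_lower = TRUE)
  tris <- delaunay_triangulation(x, y)
  if (nrow(tris) == 0L) return(0)
  total <- 0
  for (k in seq_len(nrow(tris))) {
    tr <- tris[k, ]
    cc <- circumcircle(x[tr[1]], y[tr[1]], x[tr[2]], y[tr[2]],
                       x[tr[3]], y[tr[3]])
    if (is.finite(cc[3]) && cc[3] <= alpha) {
      total <- total + triangle_area(x[tr[1]], y[tr[1]], x[tr[2]], y[tr[2]],
                                     x[tr[3]], y[tr[3]])
    }
  }
  total
}

#' Cortical map area from 3-D stimulation sites
#'
#' Projects the MEP-positive site coordinates onto their best-fit plane
#' (principal axes of the 3-D point cloud) and returns the planar area of
#' the alpha shape (default) or convex hull of the projected points.
#' Degenerate maps (fewer than 3 sites, or collinear sites) report area 0
#' with a `degenerate` attribute set, not an error: the CoG of such a map is
#' still defined and the map remains reportable.
#'
#' @param coords numeric matrix (n x 3), site coordinates in mm.
#' @param method `"alpha_shape"` or `"convex_hull"`.
#' @param alpha alpha radius in mm (default 15).
#' @return area in mm^2, with attribute `degenerate` (logical).
#' @export
compute_area <- function(coords, method = c("alpha_shape", "convex_hull"),
                         alpha = 15) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  degenerate <- FALSE
  if (nrow(coords) < 3L) {
    degenerate <- TRUE
    area <- 0
  } else {
    pc <- stats::prcomp(coords, center = TRUE, scale. = FALSE)
    if (pc$sdev[2] < 1e-9 * max(pc$sdev[1], 1e-12)) {
      degenerate <- TRUE   # collinear point cloud: no in-plane extent
      area <- 0
    } else {
      area <- planar_area(pc$x[, 1], pc$x[, 2], method = method,
                          alpha = alpha)
    }
  }
  if (degenerate) {
    warning("degenerate map (<3 sites or collinear); area set to 0",
            call. = FALSE)
  }
  structure(area, degenerate = degenerate)
}

#' Summarize a muscle's MEP records into a motor map
#'
#' Joins the accepted-and-retained MEP records to their stimulation
#' coordinates by `stim_id` and computes the CoG and area. A session with no
#' accepted MEPs yields a missing map (`missing = TRUE`, `NA` features),
#' which the modelling stage drops as a missing outcome.
#'
#' @param muscle muscle label.
#' @param meps MEP record data.frame (from [process_epochs()] or
#'   [detect_meps()] + [filter_low_amplitude()]).
#' @param coords data.frame with columns `stim_id`, `x`, `y`, `z` (mm).
#' @param method,alpha forwarded to [compute_area()].
#' @return list of class `motor_map`: `muscle`, `sites` (data.frame with
#'   coordinates and amplitudes of retained sites), `cog`, `area`,
#'   `n_sites`, `missing`, `degenerate`.
#' @export
summarize_map <- function(muscle, meps, coords,
                          method = c("alpha_shape", "convex_hull"),
                          alpha = 15) {
  method <- match.arg(method)
  keep <- meps[meps$accepted, , drop = FALSE]
  if (nrow(keep) == 0L) {
    return(structure(list(muscle = muscle, sites = NULL,
                          cog = c(x = NA_real_, y = NA_real_, z = NA_real_),
                          area = NA_real_, n_sites = 0L,
                          missing = TRUE, degenerate = FALSE),
                     class = "motor_map"))
  }
  idx <- match(keep$stim_id, coords$stim_id)
  if (anyNA(idx)) {
    stop(sprintf("no coordinates for stimulation id(s): %s",
                 paste(keep$stim_id[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  }
  xyz <- as.matrix(coords[idx, c("x", "y", "z")])
  cog <- compute_cog(xyz, keep$peak_to_peak)
  area <- if (nrow(xyz) >= 3L) {
    suppressWarnings(compute_area(xyz, method = method, alpha = alpha))
  } else {
    structure(0, degenerate = TRUE)
  }
  structure(list(
    muscle = muscle,
    sites = data.frame(stim_id = keep$stim_id, xyz,
                       amplitude = keep$peak_to_peak),
    cog = cog,
    area = as.numeric(area),
    n_sites = nrow(keep),
    missing = FALSE,
    degenerate = isTRUE(attr(area, "degenerate"))
  ), class = "motor_map")
}

#' @export
print.motor_map <- function(x, ...) {
  if (x$missing) {
    cat(sprintf("<motor_map> %s: missing (no accepted MEPs)\n", x$muscle))
  } else {
    cat(sprintf(
      "<motor_map> %s: %d sites, CoG (%.1f, %.1f, %.1f) mm, area %.0f mm^2%s\n",
      x$muscle, x$n_sites, x$cog[1], x$cog[2], x$cog[3], x$area,
      if (x$degenerate) " [degenerate]" else ""))
  }
  invisible(x)
}

#' Mirror left-hemisphere maps for hemisphere pooling
#'
#' Stimulation targets the hemisphere contralateral to the most painful
#' side, so cohorts mix left- and right-hemisphere maps. Before group
#' analysis, left-hemisphere CoG X coordinates are mirrored (X to -X) so
#' that "more lateral" has one sign across the cohort.
#'
#' @param map_table data.frame with at least `cog_x` and `hemisphere`
#'   (`"left"`/`"right"`) columns.
#' @return the table with `cog_x` sign-flipped on left-hemisphere rows.
#' @export
pool_hemispheres <- function(map_table) {
  stopifnot(all(c("cog_x", "hemisphere") %in% names(map_table)))
  left <- map_table$hemisphere == "left"
  map_table$cog_x[left] <- -map_table$cog_x[left]
  map_table
}
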