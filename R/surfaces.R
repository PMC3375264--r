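#' Scene surfaces for analytic ray casting
#'
#' Surfaces are defined in a world frame whose origin is the camera's nodal
#' point, with y up and z the reference "straight ahead" direction; the
#' camera may be rotated within that frame (see [camera_pose()]). All
#' distances are metres.
#'
#' * `ground_plane(d_g)`: horizontal plane `y = -d_g` (camera `d_g` above it).
#' * `tilted_plane(normal, d)`: plane `normal . P = d` with unit `normal`
#'   pointing toward the camera side and `d > 0` the distance along it.
#' * `box_post(centre, w, h, depth)`: axis-aligned box (a square post of
#'   width/depth `w` unless `depth` is given) centred at `centre`, height `h`.
#' * `cylinder_post(centre, radius, h)`: vertical cylinder.
#'
#' @param d_g,d positive distances (m).
#' @param normal unit normal (length 3).
#' @param centre length-3 centre of the post (m).
#' @param w,h,radius,depth post width, height, radius, depth (m).
#' @return a `scene_surface` object.
#' @name scene_surfaces
NULL

surface <- function(type, ...) {
  structure(list(type = type, ...), class = c(paste0("surface_", type), "scene_surface"))
}

#' @rdname scene_surfaces
#' @export
ground_plane <- function(d_g) {
  stopifnot(d_g > 0)
  surface("plane", normal = c(0, 1, 0), offset = -d_g)
}

#' @rdname scene_surfaces
#' @export
tilted_plane <- function(normal, d) {
  normal <- as.numeric(normal)
  stopifnot(length(normal) == 3, d > 0)
  normal <- normal / sqrt(sum(normal^2))
  surface("plane", normal = normal, offset = d)
}

#' @rdname scene_surfaces
#' @export
box_post <- function(centre, w = 0.2, h = 1, depth = w) {
  centre <- as.numeric(centre)
  stopifnot(length(centre) == 3, w > 0, h > 0, depth > 0)
  surface("box",
          lo = centre - c(w / 2, h / 2, depth / 2),
          hi = centre + c(w / 2, h / 2, depth / 2),
          centre = centre, w = w, h = h, d = depth)
}

#' @rdname scene_surfaces
#' @export
cylinder_post <- function(centre, radius = 0.1, h = 1) {
  centre <- as.numeric(centre)
  stopifnot(length(centre) == 3, radius > 0, h > 0)
  surface("cylinder", centre = centre, radius = radius,
          ylim = c(centre[2] - h / 2, centre[2] + h / 2))
}

#' Camera pose (orientation) in the scene frame
#'
#' The camera sits at the origin; its orientation is a yaw rotation about the
#' world y axis followed by a pitch rotation about the already-rotated x
#' axis, with zero roll (the composition order used for gaze-stabilizing
#' rotations throughout). `look_at()` returns the pose whose optical axis
#' passes through a given world point.
#'
#' @param yaw,pitch angles in radians.
#' @return list with the 3x3 camera-to-world rotation `R` and the angles.
#' @export
camera_pose <- function(yaw = 0, pitch = 0) {
  Ry <- matrix(c(cos(yaw), 0, sin(yaw), 0, 1, 0, -sin(yaw), 0, cos(yaw)),
               3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(pitch), -sin(pitch), 0, sin(pitch), cos(pitch)),
               3, 3, byrow = TRUE)
  list(R = Ry %*% Rx, yaw = yaw, pitch = pitch)
}

#' @rdname camera_pose
#' @param target length-3 world point the optical axis should pass through.
#' @export
look_at <- function(target) {
  target <- as.numeric(target)
  n <- sqrt(sum(target^2))
  stopifnot(n > 0)
  camera_pose(yaw = atan2(target[1], target[3]), pitch = asin(-target[2] / n))
}

#' World -> camera coordinate change for a pose
#' @param pose a [camera_pose()].
#' @param p length-3 point or velocity in the world frame.
#' @return the same quantity in camera coordinates.
#' @export
world_to_camera <- function(pose, p) as.numeric(t(pose$R) %*% as.numeric(p))

#' Depth map container
#'
#' Per-pixel positive scene depth (camera-frame z, metres) with a hit mask,
#' analytic image-plane partials of the depth where the hit surface is
#' smooth, a per-pixel surface id, and a depth-discontinuity flag raised at
#' boundaries between surfaces (and at silhouette depth jumps).
#'
#' @param Z,dZdx,dZdy numeric matrices (height x width); partials are in
#'   metres per image-plane unit, analytic (y-up) convention.
#' @param mask logical matrix of ray hits.
#' @param surface_id integer matrix (0 = miss).
#' @param disc logical matrix of discontinuity flags.
#' @return object of class `depth_map`.
#' @export
depth_map <- function(Z, mask = NULL, dZdx = NULL, dZdy = NULL,
                      surface_id = NULL, disc = NULL) {
  stopifnot(is.matrix(Z))
  if (is.null(mask)) mask <- is.finite(Z)
  if (any(Z[mask] <= 0)) stop("depth must be positive wherever hit")
  if (is.null(disc)) disc <- matrix(FALSE, nrow(Z), ncol(Z))
  structure(list(Z = Z, mask = mask, dZdx = dZdx, dZdy = dZdy,
                 surface_id = surface_id, disc = disc),
            class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf("<depth_map> %dx%d px, %d miss, Z in [%.3g, %.3g] m, %d disc px\n",
              ncol(x$Z), nrow(x$Z), sum(!x$mask),
              suppressWarnings(min(x$Z[x$mask])),
              suppressWarnings(max(x$Z[x$mask])), sum(x$disc)))
  invisible(x)
}

# per-surface ray intersection; d* are matrices of world-frame ray direction
# components (camera-frame z component of the unnormalized direction is 1,
# so the ray parameter t equals camera depth Z). Returns t and the surface
# gradient (unnormalized normal) at the hit.
intersect_surface <- function(s, dx, dy, dz) {
  if (s$type == "plane") {
    denom <- s$normal[1] * dx + s$normal[2] * dy + s$normal[3] * dz
    t <- s$offset / denom
    t[!is.finite(t) | t <= 0] <- Inf
    list(t = t, gx = s$normal[1] + 0 * t, gy = s$normal[2] + 0 * t,
         gz = s$normal[3] + 0 * t)
  } else if (s$type == "box") {
    # camera at origin: slab entry/exit per axis
    nearfar <- function(d, lo, hi) {
      t1 <- ifelse(d != 0, lo / d, ifelse(lo <= 0, -Inf, Inf))
      t2 <- ifelse(d != 0, hi / d, ifelse(hi >= 0, Inf, -Inf))
      list(near = pmin(t1, t2), far = pmax(t1, t2))
    }
    ax <- nearfar(dx, s$lo[1], s$hi[1])
    ay <- nearfar(dy, s$lo[2], s$hi[2])
    az <- nearfar(dz, s$lo[3], s$hi[3])
    tmin <- pmax(ax$near, ay$near, az$near)
    tmax <- pmin(ax$far, ay$far, az$far)
    t <- ifelse(tmax >= tmin & tmin > 0, tmin, Inf)
    # entry face normal: the axis whose slab entry is binding
    gx <- ifelse(t == ax$near, -sign(dx), 0)
    gy <- ifelse(t == ay$near, -sign(dy), 0)
    gz <- ifelse(t == az$near, -sign(dz), 0)
    list(t = t, gx = gx, gy = gy, gz = gz)
  } else if (s$type == "cylinder") {
    a <- dx^2 + dz^2
    b <- -2 * (dx * s$centre[1] + dz * s$centre[3])
    cc <- s$centre[1]^2 + s$centre[3]^2 - s$radius^2
    disc <- b^2 - 4 * a * cc
    t <- ifelse(disc >= 0 & a > 0, (-b - sqrt(pmax(disc, 0))) / (2 * a), Inf)
    yhit <- t * dy
    t[!is.finite(t) | t <= 0 | yhit < s$ylim[1] | yhit > s$ylim[2]] <- Inf
    list(t = t, gx = t * dx - s$centre[1], gy = 0 * t,
         gz = t * dz - s$centre[3])
  } else stop("unknown surface type: ", s$type)
}

#' Analytic depth map by ray casting
#'
#' Casts one ray per pixel centre through a list of surfaces and keeps the
#' nearest intersection. Depth partials with respect to the analytic image
#' coordinates are obtained by implicit differentiation of the hit surface's
#' implicit equation, so they are exact wherever the surface is smooth.
#' Pixels whose 4-neighbours hit a different surface, or across which the
#' depth jumps by more than `jump_rel` relative, are flagged as
#' discontinuities.
#'
#' @param cam a [camera_model()].
#' @param scene list of [scene_surfaces].
#' @param pose a [camera_pose()] (default: looking along world z).
#' @param jump_rel relative depth jump that flags a discontinuity.
#' @return a [depth_map()].
#' @export
raycast_depth <- function(cam, scene, pose = camera_pose(), jump_rel = 0.03) {
  if (inherits(scene, "scene_surface")) scene <- list(scene)
  stopifnot(length(scene) >= 1)
  g <- camera_grid(cam)
  R <- pose$R
  # unnormalized camera-frame direction (x/f, y/f, 1): t equals depth Z
  cx <- g$x / cam$f; cy <- g$y / cam$f
  dx <- R[1, 1] * cx + R[1, 2] * cy + R[1, 3]
  dy <- R[2, 1] * cx + R[2, 2] * cy + R[2, 3]
  dz <- R[3, 1] * cx + R[3, 2] * cy + R[3, 3]
  t <- matrix(Inf, cam$height, cam$width)
  id <- matrix(0L, cam$height, cam$width)
  gx <- gy <- gz <- matrix(0, cam$height, cam$width)
  for (i in seq_along(scene)) {
    hit <- intersect_surface(scene[[i]], dx, dy, dz)
    closer <- hit$t < t
    t[closer] <- hit$t[closer]
    id[closer] <- i
    gx[closer] <- hit$gx[closer]
    gy[closer] <- hit$gy[closer]
    gz[closer] <- hit$gz[closer]
  }
  mask <- is.finite(t)
  Z <- ifelse(mask, t, NA_real_)
  # implicit differentiation: dZ/dx = -t (grad.r1) / (f grad.d), r1 = R[,1]
  gdotd <- gx * dx + gy * dy + gz * dz
  gdot1 <- gx * R[1, 1] + gy * R[2, 1] + gz * R[3, 1]
  gdot2 <- gx * R[1, 2] + gy * R[2, 2] + gz * R[3, 2]
  dZdx <- ifelse(mask & gdotd != 0, -t * gdot1 / (cam$f * gdotd), NA_real_)
  dZdy <- ifelse(mask & gdotd != 0, -t * gdot2 / (cam$f * gdotd), NA_real_)
  # discontinuity flags from surface-id changes and silhouette depth jumps
  disc <- matrix(FALSE, cam$height, cam$width)
  dif <- function(m, dr, dc) {
    sh <- matrix(NA, nrow(m), ncol(m))
    rs <- seq_len(nrow(m)); cs <- seq_len(ncol(m))
    sh[rs[(1 + max(0, dr)):(nrow(m) + min(0, dr))],
       cs[(1 + max(0, dc)):(ncol(m) + min(0, dc))]] <-
      m[rs[(1 - min(0, dr)):(nrow(m) - max(0, dr))],
        cs[(1 - min(0, dc)):(ncol(m) - max(0, dc))]]
    sh
  }
  gl <- sqrt(gx^2 + gy^2 + gz^2); gl[gl == 0] <- 1
  nxm <- gx / gl; nym <- gy / gl; nzm <- gz / gl
  hx <- 1 / cam$px_per_unit; hy <- 1 / cam$px_per_unit_y
  for (sh in list(c(0, 1), c(1, 0))) {
    idn <- dif(id, sh[1], sh[2]); Zn <- dif(Z, sh[1], sh[2])
    ndot <- nxm * dif(nxm, sh[1], sh[2]) + nym * dif(nym, sh[1], sh[2]) +
      nzm * dif(nzm, sh[1], sh[2])
    # a silhouette jump is one the surface's own slope cannot explain;
    # steep but smooth depth (e.g. ground toward the horizon) is not flagged
    pred <- if (sh[2] == 1) abs(dZdx) * hx else abs(dZdy) * hy
    pred <- pmax(pred, dif(pred, sh[1], sh[2]), na.rm = TRUE)  # steeper side
    dz <- abs(Zn - Z)
    jump <- (idn != id & idn > 0L & id > 0L & !is.na(idn)) |
      (dz > jump_rel * pmin(Zn, Z) & dz > 4 * pred & !is.na(dz - pred)) |
      (ndot < 0.999 & !is.na(ndot) & idn > 0L & id > 0L)  # crease (box corner)
    jump[is.na(jump)] <- FALSE
    back <- dif(jump, -sh[1], -sh[2]); back[is.na(back)] <- FALSE
    disc <- disc | jump | back
  }
  depth_map(Z, mask = mask, dZdx = dZdx, dZdy = dZdy,
            surface_id = id, disc = disc)
}
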