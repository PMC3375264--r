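#' Behavioural scenario presets
#'
#' Fully instantiated synthetic scenes for the two gaze strategies, matching
#' the foveal sensor of the behavioural simulations (240 x 240 pixels,
#' 1 cm x 1 cm display, focal length 2748.45 px: a 5 x 5 degree field of
#' view), a ground plane 1 m below the camera, and a square post 0.2 m wide
#' and 1 m tall whose centre is 2 m away along the reference axis.
#'
#' * `"approach"`: gaze is locked on the centre of the post's front face and
#'   the observer translates along gaze at 1 m/s — gaze and heading are
#'   aligned, the compensatory rotation is zero, and the rendered flow is a
#'   pure expansion with FOE = COM = the fixated centre.
#' * `"avoidance"`: the observer translates along `(-0.35, 0, 0.94)` m/s
#'   (heading about 20 degrees to the left of the reference axis, walking
#'   past the post) while gazing at the mid-height of the post's outer
#'   (left) vertical edge — an apical edge with the ground plane behind it.
#'   The stabilized scene point is the background point seen along the
#'   edge-grazing gaze ray ("next to the edge"), so the near post keeps a
#'   strong, nearly laminar translational flow while the distant background
#'   is rotation-dominated in the opposite direction; the COM sits at the
#'   fixated edge location, displaced from the FOE, and the flow direction
#'   and speed jump sharply across the edge.
#'
#' Overridable defaults (via `overrides`): `camera`, `d_g` (camera height,
#' m), `post_w`, `post_h` (m), `post_centre` (world frame), `speed` (m/s),
#' `v_dir` (world frame heading), `fixation` (world frame point),
#' `post_type` (`"box"` or `"cylinder"`; the cylindrical pillar shows the
#' same qualitative behaviour).
#'
#' @param name `"approach"` or `"avoidance"`.
#' @param overrides named list of overrides (see Details).
#' @return list with `camera`, `scene` (surface list), `pose`
#'   ([camera_pose()]), `motion` ([self_motion()], camera frame),
#'   `fixation_world`, `depth` ([depth_map()]) and `flow` ([flow_field()]).
#' @export
make_scenario <- function(name = c("approach", "avoidance"),
                          overrides = list()) {
  name <- match.arg(name)
  p <- list(camera = camera_model(), d_g = 1, post_w = 0.2, post_h = 1,
            post_centre = NULL, speed = 1, v_dir = NULL, fixation = NULL,
            post_type = "box")
  bad <- setdiff(names(overrides), names(p))
  if (length(bad)) stop("unknown override(s): ", paste(bad, collapse = ", "))
  p[names(overrides)] <- overrides
  if (is.null(p$post_centre))
    p$post_centre <- c(0, p$post_h / 2 - p$d_g, 2)
  if (p$d_g <= 0 || p$post_w <= 0 || p$post_h <= 0 || p$speed <= 0)
    stop("invalid scenario configuration")
  post <- if (p$post_type == "box")
    box_post(p$post_centre, w = p$post_w, h = p$post_h)
  else cylinder_post(p$post_centre, radius = p$post_w / 2, h = p$post_h)
  scene <- list(ground_plane(p$d_g), post)
  face_z <- p$post_centre[3] - p$post_w / 2
  if (is.null(p$fixation)) {
    if (name == "approach") {
      p$fixation <- c(p$post_centre[1], p$post_centre[2], face_z)  # face centre
    } else {
      # gaze grazes the outer vertical edge at mid-height; the stabilized
      # scene point is the background point visible just beyond the edge
      # (the ground along the same ray), so the foreground keeps a strong
      # translational flow while the distant background is rotation-dominated
      edge <- c(p$post_centre[1] - p$post_w / 2, p$post_centre[2], face_z)
      p$fixation <- if (edge[2] < 0) edge * (-p$d_g / edge[2]) else edge
    }
  }
  pose <- look_at(p$fixation)
  if (is.null(p$v_dir))
    p$v_dir <- if (name == "approach") p$fixation else c(-0.35, 0, 0.94)
  v_world <- p$speed * p$v_dir / sqrt(sum(p$v_dir^2))
  v_cam <- world_to_camera(pose, v_world)
  fix_cam <- world_to_camera(pose, p$fixation)
  motion <- self_motion(v = v_cam, fixation = fixation_spec(fix_cam))
  depth <- raycast_depth(p$camera, scene, pose)
  flow <- render_flow(p$camera, depth, motion)
  list(camera = p$camera, scene = scene, pose = pose, motion = motion,
       fixation_world = p$fixation, depth = depth, flow = flow,
       name = name, params = p)
}

#' Wide-field multi-obstacle scenario
#'
#' A 320 x 640 pixel sensor spanning a 50 degree horizontal field of view,
#' with several posts standing on the ground plane at distinct depths. The
#' observer fixates the outer edge of the nearest post (placed near the
#' centre of the visual field) while translating obliquely, as in the
#' avoidance strategy; flow-derivative responses are largest at the fixated
#' nearest obstacle, which is what makes it segmentable.
#'
#' @param overrides named list: `camera`, `d_g`, `speed`, `v_dir`,
#'   `posts` (list of `c(x, z, w, h)` world placements, nearest first),
#'   `fixation`.
#' @return as [make_scenario()].
#' @export
wide_field_scenario <- function(overrides = list()) {
  p <- list(camera = camera_model(f_px = 686.18, width = 640L, height = 320L,
                                  sensor_w = 0.02),
            d_g = 1, speed = 1, v_dir = c(0.35, 0, 0.94),
            posts = list(c(0, 2, 0.2, 1), c(-1.5, 4, 0.3, 1.2),
                         c(1.8, 5, 0.3, 1.2)),
            fixation = NULL)
  bad <- setdiff(names(overrides), names(p))
  if (length(bad)) stop("unknown override(s): ", paste(bad, collapse = ", "))
  p[names(overrides)] <- overrides
  scene <- c(list(ground_plane(p$d_g)),
             lapply(p$posts, function(q)
               box_post(c(q[1], q[4] / 2 - p$d_g, q[2]), w = q[3], h = q[4])))
  if (is.null(p$fixation)) {
    if (length(p$posts)) {
      q <- p$posts[[which.min(vapply(p$posts, `[`, 0, 2))]]
      p$fixation <- c(q[1] + q[3] / 2, q[4] / 2 - p$d_g, q[2] - q[3] / 2)
    } else p$fixation <- c(0, 0, 5)
  }
  pose <- look_at(p$fixation)
  v_world <- p$speed * p$v_dir / sqrt(sum(p$v_dir^2))
  motion <- self_motion(v = world_to_camera(pose, v_world),
                        fixation = fixation_spec(world_to_camera(pose, p$fixation)))
  depth <- raycast_depth(p$camera, scene, pose)
  flow <- render_flow(p$camera, depth, motion)
  list(camera = p$camera, scene = scene, pose = pose, motion = motion,
       fixation_world = p$fixation, depth = depth, flow = flow,
       name = "wide", params = p)
}
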