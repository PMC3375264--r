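cam <- camera_model()

test_that("ray-cast depth agrees with closed-form surfaces", {
  # fronto-parallel plane at 2 m: constant depth, zero partials
  dm <- raycast_depth(cam, tilted_plane(c(0, 0, 1), 2))
  expect_true(all(dm$mask))
  expect_equal(max(abs(dm$Z - 2)), 0, tolerance = 1e-12)
  expect_equal(max(abs(dm$dZdx)), 0, tolerance = 1e-12)
  # general plane: Z = d f / (n . (x, y, f))
  n <- c(sin(0.4), 0.1, sqrt(1 - sin(0.4)^2 - 0.01))
  dm2 <- raycast_depth(cam, tilted_plane(n, 1.5))
  g <- camera_grid(cam)
  Zref <- 1.5 * cam$f / (n[1] * g$x + n[2] * g$y + n[3] * cam$f)
  expect_lt(max(abs(dm2$Z - Zref) / Zref), 1e-9)
  # ground plane: symbolic ray-plane solution per pixel
  dm3 <- raycast_depth(cam, ground_plane(1))
  sel <- dm3$mask
  expect_lt(max(abs(dm3$Z[sel] - cam$f / (-g$y[sel]))), 1e-9)
  expect_false(any(sel[g$y >= 0]))
  # analytic partials match central differences of the depth raster
  h <- 1 / cam$px_per_unit
  num <- (dm3$Z[, 3:cam$width] - dm3$Z[, 1:(cam$width - 2)]) / (2 * h)
  an <- dm3$dZdx[, 2:(cam$width - 1)]
  ok <- erode_mask(dm3$mask, 2)[, 2:(cam$width - 1)] & is.finite(num - an)
  expect_lt(max(abs(num - an)[ok] / pmax(abs(an[ok]), 1)), 1e-3)
})

test_that("composite scenes take the nearest hit and flag discontinuities", {
  # narrow post so that ground remains visible beside it in the fovea
  sc <- list(ground_plane(1), box_post(c(0, -0.5, 2), w = 0.05, h = 1))
  dm <- raycast_depth(cam, sc, pose = look_at(c(0, -0.5, 2)))
  dg <- raycast_depth(cam, sc[[1]], pose = look_at(c(0, -0.5, 2)))
  db <- raycast_depth(cam, sc[[2]], pose = look_at(c(0, -0.5, 2)))
  both <- dg$mask & db$mask
  expect_true(all(dm$Z[both] <= pmin(dg$Z[both], db$Z[both]) + 1e-12))
  on_post <- dm$surface_id == 2
  expect_true(any(on_post))
  expect_equal(unname(range(dm$Z[on_post])), c(2.014, 2.058), tolerance = 1e-3)
  # background neighbours across the post boundary are strictly deeper
  expect_gt(min(dm$Z[dm$surface_id == 1]), 1.9)
  expect_true(any(dm$disc))
  # cylinder intersections agree with the closed-form tangent geometry
  cyl <- cylinder_post(c(0, -0.5, 2), radius = 0.1, h = 1)
  dmc <- raycast_depth(cam, cyl)
  mid <- (cam$height + 1) / 2
  expect_equal(min(dmc$Z, na.rm = TRUE), 1.9, tolerance = 1e-6)
})

test_that("scenario presets are deterministic and scale linearly in speed", {
  a1 <- make_scenario("approach")
  a2 <- make_scenario("approach")
  expect_identical(a1$depth$Z, a2$depth$Z)
  expect_identical(a1$flow$u, a2$flow$u)
  a4 <- make_scenario("approach", overrides = list(speed = 4))
  expect_identical(a4$flow$u, 4 * a1$flow$u)
  expect_identical(a4$flow$v, 4 * a1$flow$v)
  expect_error(make_scenario("approach", overrides = list(speed = -1)),
               "invalid")
  expect_error(make_scenario("approach", overrides = list(nope = 1)),
               "unknown override")
})

test_that("approach preset gives pure expansion with COM = FOE = centre", {
  ap <- approach_scenario()
  expect_equal(ap$motion$v[1:2], c(0, 0), tolerance = 1e-15)
  foe <- find_foe(ap$motion$v, ap$camera)
  expect_equal(c(foe$x, foe$y), c(0, 0), tolerance = 1e-15)
  com <- find_com(ap$flow)
  expect_equal(c(com$x, com$y), c(0, 0), tolerance = 1e-5)
  # flow points away from the centre everywhere off-centre
  g <- camera_grid(ap$camera)
  r2 <- g$x^2 + g$y^2
  expect_gt(min((ap$flow$u * g$x + ap$flow$v * g$y)[r2 > 1e-8]), 0)
})

test_that("avoidance preset: expansional foreground, laminar background", {
  av <- avoidance_scenario()
  expect_gt(abs(atan2(av$motion$v[1], av$motion$v[3])) * 180 / pi, 10)
  fg <- av$depth$surface_id == 2
  bg <- av$depth$surface_id == 1
  # the near post carries a coherent translation-led flow; the background
  # direction is set by the compensatory rotation, ~180 degrees away
  dir_fg <- (atan2(av$flow$v[fg], av$flow$u[fg]) * 180 / pi) %% 360
  med_fg <- median(dir_fg)
  om <- fixation_rates(av$camera, av$motion$v, av$motion$fixation)
  rot_dir <- (atan2(om[1] * av$camera$f, -om[2] * av$camera$f) * 180 / pi) %% 360
  expect_lt(circular_distance(med_fg, (rot_dir + 180) %% 360), 30)
  # sharp speed discontinuity across the fixated edge
  cc <- round(av$camera$width / 2)
  spd <- sqrt(av$flow$u^2 + av$flow$v^2)
  for (rr in round(av$camera$height / 2) + c(-40, 30, 60))
    expect_gt(spd[rr, cc + 6] / spd[rr, cc - 6], 5)
})

test_that("wide-field scenario concentrates responses on the nearest post", {
  w <- wide_scenario()
  expect_equal(w$camera$fov_deg, 50, tolerance = 0.01)
  comp <- decompose(jacobian_fd(w$flow))
  combined <- pmax(abs(comp$div), abs(comp$curl), abs(comp$shear1),
                   abs(comp$shear2))
  pk <- arrayInd(which.max(ifelse(is.finite(combined), combined, -Inf)),
                 dim(combined))
  near_cols <- range(which(apply(w$depth$surface_id == 2, 2, any)))
  expect_gte(pk[2], near_cols[1] - 2)
  expect_lte(pk[2], near_cols[2] + 2)
  # peak |div| at the nearer post's edge exceeds the farther posts' peaks
  post_peak <- function(id) {
    m <- dilate_or <- w$depth$surface_id == id
    for (i in 1:2) {
      nr <- nrow(m); nc <- ncol(m)
      m[, 1:(nc - 1)] <- m[, 1:(nc - 1)] | m[, 2:nc]
      m[, 2:nc] <- m[, 2:nc] | m[, 1:(nc - 1)]
    }
    max(combined[m], na.rm = TRUE)
  }
  expect_gt(post_peak(2), post_peak(3))
  expect_gt(post_peak(2), post_peak(4))
  # all posts removed: a smooth ground field without discontinuity flags
  w0 <- wide_field_scenario(overrides = list(posts = list()))
  expect_false(any(w0$depth$disc & w0$depth$mask))
})

test_that("two posts at 2 m and 4 m follow the 1/Z law across their edges", {
  w2 <- wide_field_scenario(overrides = list(
    posts = list(c(-0.8, 2, 0.2, 1), c(0.8, 4, 0.2, 1)),
    fixation = c(0, -0.5, 3)))
  comp <- decompose(jacobian_fd(w2$flow))
  combined <- pmax(abs(comp$div), abs(comp$curl), abs(comp$shear1),
                   abs(comp$shear2))
  peak_at <- function(id) max(combined[dilate_near(w2$depth$surface_id == id)],
                              na.rm = TRUE)
  dilate_near <- function(m) {
    nc <- ncol(m)
    m[, 1:(nc - 1)] <- m[, 1:(nc - 1)] | m[, 2:nc]
    m[, 2:nc] <- m[, 2:nc] | m[, 1:(nc - 1)]
    m
  }
  p2 <- max(combined[dilate_near(w2$depth$surface_id == 2)], na.rm = TRUE)
  p4 <- max(combined[dilate_near(w2$depth$surface_id == 3)], na.rm = TRUE)
  # closed-form oracle: the flow jump across an edge scales with the
  # difference of inverse depths between post and background
  Zb2 <- median(w2$depth$Z[w2$depth$surface_id == 1])
  expect_gt(p2, p4)
  expect_lt(abs(p2 / p4) / ((1 / 2) / (1 / 4)), 4)
  expect_gt(abs(p2 / p4) / ((1 / 2) / (1 / 4)), 1 / 4)
})

test_that("direction histograms characterise the two strategies", {
  ap <- approach_scenario()
  hl <- direction_histograms(ap$flow, "left-half")
  hr <- direction_histograms(ap$flow, "right-half")
  # expansion: each half supports a ~180 degree fan, pointing outward
  expect_equal(histogram_support(hl), 180, tolerance = 20)
  expect_equal(histogram_support(hr), 180, tolerance = 20)
  expect_true(all(hl$counts[hl$centers > 270 | hl$centers < 90] == 0))
  # uniform lateral field: a single occupied bin
  uni <- flow_field(matrix(0.5, 64, 64), matrix(0, 64, 64),
                    camera_model(f_px = 64, width = 64, sensor_w = 1))
  hu <- direction_histograms(uni, "full")
  expect_equal(sum(hu$counts > 0), 1)
  expect_equal(hu$centers[which.max(hu$counts)], 5)
  # avoidance: two narrow modes approximately 180 degrees apart
  av <- avoidance_scenario()
  m <- histogram_modes(direction_histograms(av$flow, "full"))
  expect_lt(abs(m$separation - 180), 15)
  expect_error(direction_histograms(flow_field(
    matrix(0, 32, 32), matrix(0, 32, 32),
    camera_model(f_px = 32, width = 32, sensor_w = 1))), "empty region")
})
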