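cam <- camera_model()
cmp4 <- c("div", "curl", "shear1", "shear2")

test_that("analytic Jacobian reproduces canonical fields", {
  dm <- raycast_depth(cam, tilted_plane(c(0, 0, 1), 2))
  # pure roll: off-diagonal +/- omega_z, diagonal zero
  Jr <- jacobian_analytic(cam, dm, self_motion(omega = c(0, 0, 0.2)))
  expect_equal(max(abs(Jr$dudx)), 0)
  expect_equal(max(abs(Jr$dvdy)), 0)
  expect_equal(unique(as.vector(Jr$dudy)), 0.2)
  expect_equal(unique(as.vector(Jr$dvdx)), -0.2)
  # fronto-parallel plane, forward motion: diagonal v_z / Z
  Jf <- jacobian_analytic(cam, dm, self_motion(v = c(0, 0, 1.3)))
  expect_equal(unique(round(as.vector(Jf$dudx), 12)), 1.3 / 2)
  expect_equal(max(abs(Jf$dudy)), 0)
  # both match central differences of the rendered fields
  for (mo in list(self_motion(omega = c(0, 0, 0.2)),
                  self_motion(v = c(0, 0, 1.3)))) {
    J <- jacobian_analytic(cam, dm, mo)
    Jn <- jacobian_fd(render_flow(cam, dm, mo))
    m <- J$mask & Jn$mask
    for (nm in c("dudx", "dudy", "dvdx", "dvdy"))
      expect_lt(max(abs(J[[nm]][m] - Jn[[nm]][m])), 1e-8)
  }
})

test_that("jacobian_analytic falls back to finite differences without partials", {
  Z <- matrix(2, cam$height, cam$width)
  dm <- depth_map(Z)  # no analytic partials attached
  J <- jacobian_analytic(cam, dm, self_motion(v = c(0.1, 0, 1)))
  expect_identical(J$provenance, "finite-difference")
})

test_that("decompose is the pinned linear bijection and recompose inverts it", {
  g <- camera_grid(cam)
  mkJ <- function(u, v) jacobian_fd(flow_field(u, v, cam))
  # isotropic expansion u = x, v = y
  J1 <- mkJ(g$x, g$y)
  c1 <- decompose(J1)
  m <- c1$mask
  expect_equal(unique(round(c1$div[m], 9)), 2)
  for (nm in c("curl", "shear1", "shear2"))
    expect_lt(max(abs(c1[[nm]][m])), 1e-9)
  # roll field u = -y, v = x: exclusively curl
  c2 <- decompose(mkJ(-g$y, g$x))
  expect_equal(unique(round(c2$curl[m], 9)), 2)
  for (nm in c("div", "shear1", "shear2"))
    expect_lt(max(abs(c2[[nm]][m])), 1e-9)
  # u = a y, v = a x: exclusively Type II shear, value 2a
  a <- 0.7
  c3 <- decompose(mkJ(a * g$y, a * g$x))
  expect_equal(unique(round(c3$shear2[m], 9)), 2 * a)
  for (nm in c("div", "curl", "shear1"))
    expect_lt(max(abs(c3[[nm]][m])), 1e-9)
  # u = x, v = -y: exclusively Type I shear
  c4 <- decompose(mkJ(g$x, -g$y))
  expect_equal(unique(round(c4$shear1[m], 9)), 2)
  # recompose is the exact inverse
  J <- jacobian_analytic(cam, raycast_depth(cam, tilted_plane(c(0.3, 0.1, 0.95), 2)),
                         self_motion(v = c(0.3, -0.2, 1),
                                     fixation = fixation_spec(c(0, 0, 2))))
  J2 <- recompose(decompose(J))
  for (nm in c("dudx", "dudy", "dvdx", "dvdy"))
    expect_equal(J2[[nm]], J[[nm]], tolerance = 1e-15)
})

test_that("tilted-plane closed forms match their oracle and structure", {
  f <- cam$f
  # frontal plane, forward motion: div = 2 v_z / d only
  c0 <- components_translation_plane(0, 2, c(0, 0, 1), 0.01 * f, cam = cam)
  expect_equal(c0$div, 1)
  expect_equal(c0$curl + c0$shear1 + c0$shear2, 0)
  # alpha > 0, v_x only: affine-in-x divergence with zero slope (constant),
  # generic v: affine with nonzero slope
  xs <- seq(0.05, 0.5, length.out = 9) * f
  cx <- components_translation_plane(0.3, 2, c(0.4, 0.2, 1), xs, y = 0, cam)
  fit <- lm(cx$div ~ xs)
  expect_gt(abs(coef(fit)[2]), 0)
  expect_lt(max(abs(residuals(fit))), 1e-12)
  # finite-difference oracle on the rendered flow at the same locations
  pl <- tilted_plane(c(sin(0.3), 0, cos(0.3)), 2)
  dm <- raycast_depth(cam, pl)
  v <- c(0.4, 0.2, 1)
  fl <- render_flow(cam, dm, self_motion(v = v))
  Jn <- jacobian_fd(fl)
  cn <- decompose(Jn)
  xs <- seq(0.005, 0.035, length.out = 6) * f  # within the raster
  pp <- plane_to_pixel(cam, xs, 0 * xs)
  for (i in seq_along(xs)) {
    r <- round(pp$row[i]); cl <- round(pp$col[i])
    at <- pixel_to_plane(cam, cl, r)
    ref <- components_translation_plane(0.3, 2, v, at$x, at$y, cam)
    for (nm in cmp4)
      expect_equal(cn[[nm]][r, cl], ref[[nm]], tolerance = 1e-6)
  }
  expect_error(components_translation_plane(pi / 2, 2, v, 0.1, cam = cam),
               "tangential")
})

test_that("parallel-plane components obey the hyperbola law with curl = shear II", {
  f <- cam$f
  v <- c(0.3, 0.2, 1)
  xo <- c(0.1, 0.2, 0.4) * f
  cp <- components_parallel_plane(xo, v, cam)
  for (nm in cmp4) {
    prod <- cp[[nm]] * xo
    expect_equal(max(prod) - min(prod), 0, tolerance = 1e-12 * max(abs(prod)))
  }
  expect_identical(cp$curl, cp$shear2)
  # strictly decreasing magnitude in |x_off|, diverging toward zero offset
  xs <- seq(0.01, 0.5, length.out = 20) * f
  cps <- components_parallel_plane(xs, v, cam)
  expect_true(all(diff(abs(cps$div)) < 0))
  expect_identical(class(components_parallel_plane(0, v, cam)),
                   "tangential_singularity")
  # finite-difference oracle: gaze-parallel plane rendered and differenced
  # at the evaluation point
  at <- c(0.02, 0.015) * f
  for (xoff in c(0.1, 0.25) * f) {
    dm <- raycast_depth(cam, tilted_plane(c(1, 0, 0), xoff))
    cn <- decompose(jacobian_fd(render_flow(cam, dm, self_motion(v = v))))
    pp <- plane_to_pixel(cam, at[1], at[2])
    r <- round(pp$row); cl <- round(pp$col)
    atpx <- pixel_to_plane(cam, cl, r)
    got <- components_parallel_plane(xoff, v, cam, at = c(atpx$x, atpx$y))
    for (nm in cmp4) {
      expect_equal(cn[[nm]][r, cl], got[[nm]], tolerance = 1e-6)
    }
  }
})

test_that("cylinder components diverge at both ends with curl = shear II", {
  f <- cam$f
  v <- c(0.3, 0.2, 1)
  R <- 0.05 * f
  xs <- seq(0.02, 0.98, length.out = 99) * R
  cc <- components_cylinder(R, v, xs, cam = cam)
  expect_identical(cc$curl, cc$shear2)
  adiv <- abs(cc$div)
  i <- which.min(adiv)
  expect_gt(i, 5); expect_lt(i, 99)
  expect_true(all(diff(adiv[1:i]) < 0))
  expect_true(all(diff(adiv[i:99]) > 0))
  ends <- abs(components_cylinder(R, v, c(1e-4, 1 - 1e-8) * R, cam = cam)$div)
  expect_gt(ends[1] / adiv[i], 100)
  expect_gt(ends[2] / adiv[i], 100)
  expect_error(components_cylinder(R, v, c(0.5, 1.2) * R, cam = cam),
               "inside")
})

test_that("apical-edge components are axis-exclusive and additive", {
  ed <- apical_edge(P0 = c(0.1, -1, 1.9), h = 1, d_g = 1,
                    yaw = 0.08, pitch = -0.25)
  # sideward: divergence and Type I shear only
  c_vx <- components_apical_edge(ed, c(1, 0, 0), cam, lambda = 0.3)
  expect_gt(abs(c_vx$div), 0)
  expect_equal(c_vx$div, c_vx$shear1)
  expect_equal(c_vx$curl, 0); expect_equal(c_vx$shear2, 0)
  # vertical: curl and Type II shear only
  c_vy <- components_apical_edge(ed, c(0, 1, 0), cam, lambda = 0.3)
  expect_gt(abs(c_vy$curl), 0)
  expect_equal(c_vy$curl, c_vy$shear2)
  expect_equal(c_vy$div, 0); expect_equal(c_vy$shear1, 0)
  # forward: all four (generic off-axis geometry)
  c_vz <- components_apical_edge(ed, c(0, 0, 1), cam, lambda = 0.3)
  for (nm in cmp4) expect_gt(abs(c_vz[[nm]]), 0)
  # mixed motion combines additively
  v <- c(0.3, -0.2, 1)
  c_all <- components_apical_edge(ed, v, cam, lambda = 0.3)
  for (nm in cmp4)
    expect_equal(c_all[[nm]],
                 0.3 * components_apical_edge(ed, c(1, 0, 0), cam, lambda = 0.3)[[nm]] -
                 0.2 * components_apical_edge(ed, c(0, 1, 0), cam, lambda = 0.3)[[nm]] +
                 components_apical_edge(ed, c(0, 0, 1), cam, lambda = 0.3)[[nm]],
                 tolerance = 1e-12)
  # image-point interface respects the 0.5 px edge-line tolerance
  on <- components_apical_edge(ed, v, cam, lambda = 0.4)
  back <- components_apical_edge(ed, v, cam, x = on$x, y = on$y)
  expect_equal(back$lambda, 0.4, tolerance = 1e-9)
  expect_error(components_apical_edge(ed, v, cam,
                                      x = on$x + 5 / cam$px_per_unit,
                                      y = on$y),
               "not on the projected edge line")
  # the edge contribution scales as 1/dx toward the discontinuity
  dxs <- c(1, 2, 4) / cam$px_per_unit
  ch <- components_apical_edge(ed, c(1, 0, 0), cam, lambda = 0.3, dx = dxs)
  expect_equal(ch$div * dxs, rep((ch$div * dxs)[1], 3), tolerance = 1e-12)
})

test_that("classify_curve identifies the four response families", {
  x <- seq(0.05, 0.5, length.out = 12)
  expect_identical(classify_curve(x, 2 + 3 * x), "/")
  expect_identical(classify_curve(x, rep(1.5, 12)), "-")
  expect_identical(classify_curve(x, 0.2 / x), "∩")
  x2 <- seq(0.01, 0.5, length.out = 12)
  expect_identical(classify_curve(x2, 4 + 0.2 / x2), "∩")
  expect_identical(classify_curve(x, rep(1e-12, 12), scale = 1), "0")
  expect_identical(classify_curve(x, x^(-1.5)), "∩")
  expect_error(classify_curve(c(1, 2, 3), c(1, 2, 3)))
})

test_that("strategy signatures match the closed forms row by row", {
  f <- cam$f
  xs <- seq(0.05, 0.5, length.out = 12) * f
  classes_for <- function(cc) {
    sc <- max(vapply(cc[cmp4], function(z) max(abs(z)), 0))
    if (sc == 0) sc <- 1
    unname(coarse_class(vapply(cmp4, function(nm)
      classify_curve(xs, cc[[nm]] + 0 * xs, scale = sc), "")))
  }
  for (vax in c("vx", "vy", "vz")) {
    v <- c(vx = 0, vy = 0, vz = 0); v[vax] <- 1; v <- unname(v)
    # approach, normal tilted within xz; declination along x
    got <- classes_for(components_translation_plane(0.3, 2, v, xs,
                                                    y = 0.01 * f, cam))
    expect_identical(got, predict_signature("target-approach", "nx", vax),
                     label = paste("nx", vax))
    # approach, normal tilted within yz; declination along y
    got <- classes_for(components_translation_plane(0.3, 2, v, x = 0.01 * f,
                                                    y = xs, cam,
                                                    tilt_axis = "y"))
    expect_identical(got, predict_signature("target-approach", "ny", vax),
                     label = paste("ny", vax))
    # avoidance, tangential plane; declination = plane offset
    got <- classes_for(components_parallel_plane(xs, v, cam))
    expect_identical(got,
                     predict_signature("obstacle-avoidance", "tangential", vax),
                     label = paste("tangential", vax))
    # avoidance, apical edge; declination = across-edge sampling offset
    ed <- apical_edge(P0 = c(0.1, -1, 1.9), h = 1, d_g = 1,
                      yaw = 0.08, pitch = -0.25)
    dxs <- seq(0.5, 5, length.out = 12) / cam$px_per_unit
    ce <- components_apical_edge(ed, v, cam, lambda = 0.3, dx = dxs)
    sc <- max(vapply(cmp4, function(nm) max(abs(ce[[nm]])), 0))
    got <- unname(coarse_class(vapply(cmp4, function(nm)
      classify_curve(dxs, ce[[nm]] + 0 * dxs, scale = sc), "")))
    expect_identical(got, predict_signature("obstacle-avoidance", "apical", vax),
                     label = paste("apical", vax))
  }
  expect_error(predict_signature("target-approach", "bogus", "vx"), "surface")
})
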