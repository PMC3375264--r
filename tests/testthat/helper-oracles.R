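# Convention-free trajectory oracles: project a scene point, advance the
# camera by one micro-step of its motion, reproject, and divide the image
# displacement by the step. These never touch the package's flow formulas.

rot_about <- function(axis, th) {
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

project <- function(f, P) c(f * P[1] / P[3], f * P[2] / P[3])

# passive observer: camera translates v*dt and rotates omega*dt
oracle_flow_passive <- function(cam, P, v, omega, dt = 1e-7) {
  p0 <- project(cam$f, P)
  th <- sqrt(sum(omega^2)) * dt
  Rdt <- if (th > 0) rot_about(omega, th) else diag(3)
  P1 <- drop(t(Rdt) %*% (P - v * dt))
  (project(cam$f, P1) - p0) / dt
}

# fixating observer: camera translates v*dt, then performs the yaw-then-
# pitch (zero roll) rotation that returns the fixated point to its original
# image location; solved numerically by Newton iteration
oracle_flow_fixating <- function(cam, P, v, Fp, dt = 1e-7) {
  f <- cam$f
  p0 <- project(f, P)
  pF <- project(f, Fp)
  F1 <- Fp - v * dt
  Ry <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                           3, 3, byrow = TRUE)
  Rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                           3, 3, byrow = TRUE)
  resid <- function(ang) {
    R <- Ry(ang[1]) %*% Rx(ang[2])
    project(f, drop(t(R) %*% F1)) - pF
  }
  ang <- c(0, 0)
  for (i in 1:6) {   # Newton with numeric Jacobian
    r0 <- resid(ang)
    h <- 1e-9
    J <- cbind((resid(ang + c(h, 0)) - r0) / h,
               (resid(ang + c(0, h)) - r0) / h)
    ang <- ang - drop(solve(J, r0))
    if (sqrt(sum(resid(ang)^2)) < 1e-18 * f) break
  }
  R <- Ry(ang[1]) %*% Rx(ang[2])
  P1 <- drop(t(R) %*% (P - v * dt))
  (project(f, P1) - p0) / dt
}

# shrink a logical mask away from its FALSE boundary
erode_mask <- function(m, k) {
  out <- m
  for (i in seq_len(k)) {
    nr <- nrow(out); nc <- ncol(out)
    sh <- out
    sh[1:(nr - 1), ] <- sh[1:(nr - 1), ] & out[2:nr, ]
    sh[2:nr, ] <- sh[2:nr, ] & out[1:(nr - 1), ]
    sh[, 1:(nc - 1)] <- sh[, 1:(nc - 1)] & sh[, 2:nc]
    sh[, 2:nc] <- sh[, 2:nc] & sh[, 1:(nc - 1)]
    out <- sh
  }
  out
}

# shared scenario fixtures, built once per test file
approach_scenario <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_scenario("approach")
    val
  }
})
avoidance_scenario <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_scenario("avoidance")
    val
  }
})
wide_scenario <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- wide_field_scenario()
    val
  }
})

component_names4 <- c("div", "curl", "shear1", "shear2")

max_jacobian_relerr <- function(scenario, erode = 2) {
  J <- jacobian_analytic(scenario$camera, scenario$depth, scenario$motion)
  Jf <- jacobian_fd(scenario$flow)
  m <- erode_mask(J$mask & Jf$mask & !scenario$depth$disc, erode)
  scale <- max(abs(J$dudx[m]), abs(J$dudy[m]), abs(J$dvdx[m]),
               abs(J$dvdy[m]))
  worst <- 0
  for (nm in c("dudx", "dudy", "dvdx", "dvdy"))
    worst <- max(worst, max(abs(J[[nm]][m] - Jf[[nm]][m])) / scale)
  worst
}
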