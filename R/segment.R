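#' Flow-discontinuity detection and obstacle segmentation
#'
#' Segments the fixated (closest) obstacle from component maps: each of the
#' four components is z-scored over the valid region, the combined response
#' is the maximum absolute z-score per pixel, and pixels above the given
#' percentile of the combined response form candidate edges. Candidate
#' pixels are grouped by 8-connected labelling; stripes of opposite
#' dominant sign lying within `pair_px` of one another are paired into a
#' single object (responses of opponent sign flank a depth edge), and a
#' group that finds no opposite-signed partner is flagged ungrouped rather
#' than merged. The fixated object is the group containing the global
#' response peak.
#'
#' @param components a `component_field` (see [decompose()],
#'   [apply_bank()], [cortical_components()]).
#' @param percentile threshold percentile of the combined response
#'   (default 99).
#' @param min_z absolute floor on the combined z-score: candidate edges
#'   must stand out from the field by at least this many standard
#'   deviations, so a smooth field (e.g. pure expansion) yields an empty
#'   result rather than its top percentile.
#' @param pair_px pairing distance (pixels) for opposite-sign grouping.
#' @return object of class `segmentation_result`: logical `mask` (pixels of
#'   the fixated object's stripes), integer matrix `labels`, data frame
#'   `edges` (row, col, combined response, sign), per-component `peaks`
#'   (value and location), list `groups` (member labels, `grouped` flag),
#'   `fixated_group`, and the `threshold` used. A flat field yields an
#'   empty result, not an error.
#' @export
detect_discontinuities <- function(components, percentile = 99,
                                   min_z = 3, pair_px = 5) {
  nm <- c("div", "curl", "shear1", "shear2")
  ok <- components$mask & Reduce(`&`, lapply(components[nm], is.finite))
  if (!any(ok)) stop("no finite component values")
  zs <- lapply(nm, function(n) {
    v <- components[[n]]
    mu <- mean(v[ok]); sdv <- stats::sd(v[ok])
    if (!is.finite(sdv) || sdv == 0) sdv <- Inf   # flat component
    z <- (v - mu) / sdv
    z[!ok] <- 0
    z
  })
  names(zs) <- nm
  absz <- lapply(zs, abs)
  combined <- pmax(absz$div, absz$curl, absz$shear1, absz$shear2)
  dominant <- matrix(0, nrow(combined), ncol(combined))
  for (n in nm) {
    sel <- absz[[n]] == combined & combined > 0
    dominant[sel] <- sign(zs[[n]][sel])
  }
  peaks <- lapply(nm, function(n) {
    idx <- arrayInd(which.max(ifelse(ok, abs(components[[n]]), -Inf)),
                    dim(combined))
    list(value = components[[n]][idx], row = idx[1], col = idx[2])
  })
  names(peaks) <- nm
  thr <- max(stats::quantile(combined[ok], percentile / 100, names = FALSE),
             min_z)
  cand <- ok & combined >= thr & combined > min_z
  empty <- structure(list(mask = cand & FALSE,
                          labels = matrix(0L, nrow(combined), ncol(combined)),
                          edges = data.frame(), peaks = peaks, groups = list(),
                          fixated_group = NA_integer_, threshold = thr,
                          combined = combined),
                     class = "segmentation_result")
  if (!any(cand)) return(empty)
  labels <- label_components(cand)
  nlab <- max(labels)
  lab_sign <- integer(nlab); lab_peak <- numeric(nlab)
  for (l in seq_len(nlab)) {
    sel <- labels == l
    lab_peak[l] <- max(combined[sel])
    s <- sum(dominant[sel] * combined[sel])
    lab_sign[l] <- sign(s)
  }
  # pair opposite signs within a dilation of pair_px
  near <- matrix(FALSE, nlab, nlab)
  for (l in seq_len(nlab)) {
    d <- dilate_mask(labels == l, pair_px)
    for (m in seq_len(nlab)) if (m != l && any(d & labels == m))
      near[l, m] <- TRUE
  }
  assigned <- integer(nlab)
  groups <- list()
  for (l in order(lab_peak, decreasing = TRUE)) {
    if (assigned[l] > 0) next
    partners <- which(near[l, ] & lab_sign != lab_sign[l] & assigned == 0)
    gid <- length(groups) + 1L
    members <- c(l, partners)
    assigned[members] <- gid
    groups[[gid]] <- list(members = members,
                          grouped = length(partners) > 0,
                          peak = lab_peak[l])
  }
  gpk <- arrayInd(which.max(ifelse(cand, combined, -Inf)), dim(combined))
  fixated <- assigned[labels[gpk[1], gpk[2]]]
  mask <- matrix(FALSE, nrow(cand), ncol(cand))
  for (l in which(assigned == fixated)) mask <- mask | labels == l
  ij <- which(cand, arr.ind = TRUE)
  edges <- data.frame(row = ij[, 1], col = ij[, 2],
                      response = combined[cand],
                      sign = dominant[cand],
                      group = assigned[labels[cand]])
  structure(list(mask = mask, labels = labels, edges = edges, peaks = peaks,
                 groups = groups, fixated_group = fixated, threshold = thr,
                 combined = combined),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> %d edge px, %d groups (%d grouped), thr %.3g\n",
    nrow(x$edges), length(x$groups),
    sum(vapply(x$groups, `[[`, TRUE, "grouped")), x$threshold))
  invisible(x)
}

# 8-connected labelling of a logical mask (iterative BFS, no recursion)
label_components <- function(mask) {
  labels <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  nxt <- 0L
  todo <- which(mask)
  for (p in todo) {
    if (labels[p] != 0L) next
    nxt <- nxt + 1L
    queue <- p; labels[p] <- nxt
    while (length(queue)) {
      q <- queue[length(queue)]; queue <- queue[-length(queue)]
      r <- (q - 1L) %% nr + 1L; cc <- (q - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr < 1 || rr > nr || c2 < 1 || c2 > nc) next
        qq <- (c2 - 1L) * nr + rr
        if (mask[qq] && labels[qq] == 0L) {
          labels[qq] <- nxt
          queue <- c(queue, qq)
        }
      }
    }
  }
  labels
}

# binary dilation by k pixels (chessboard metric) via shift-or
dilate_mask <- function(mask, k) {
  out <- mask
  for (i in seq_len(k)) {
    nr <- nrow(out); nc <- ncol(out)
    sh <- out
    sh[1:(nr - 1), ] <- sh[1:(nr - 1), ] | out[2:nr, ]
    sh[2:nr, ] <- sh[2:nr, ] | out[1:(nr - 1), ]
    sh[, 1:(nc - 1)] <- sh[, 1:(nc - 1)] | sh[, 2:nc]
    sh[, 2:nc] <- sh[, 2:nc] | sh[, 1:(nc - 1)]
    out <- sh
  }
  out
}

#' Edge localization metrics against ground truth
#'
#' Precision and recall of detected edge pixels against ground-truth
#' depth-discontinuity flags, with a localization tolerance: a detected
#' pixel is correct if a true discontinuity lies within `tol_px`
#' (chessboard) and a true pixel is recovered if a detection lies within
#' `tol_px`.
#'
#' @param result a [detect_discontinuities()] result.
#' @param truth logical matrix of ground-truth discontinuity pixels.
#' @param tol_px localization tolerance in pixels.
#' @return list with `precision`, `recall`, `n_detected`, `n_truth`.
#' @export
edge_metrics <- function(result, truth, tol_px = 2) {
  det <- matrix(FALSE, nrow(truth), ncol(truth))
  if (nrow(result$edges)) det[cbind(result$edges$row, result$edges$col)] <- TRUE
  td <- dilate_mask(truth, tol_px)
  dd <- dilate_mask(det, tol_px)
  list(precision = if (any(det)) sum(det & td) / sum(det) else NA_real_,
       recall = if (any(truth)) sum(truth & dd) / sum(truth) else NA_real_,
       n_detected = sum(det), n_truth = sum(truth))
}
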