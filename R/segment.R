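## Growing-space segmentation, crown delineation, crown metrics, and
## detection-to-stem matching.

#' Segment a CHM into per-tree growing spaces
#'
#' Marker-controlled watershed on the Gaussian-smoothed CHM (flooding from
#' the markers downhill, which is watershed on the inverted surface).
#' Markers default to local maxima of the smoothed CHM above `min_height`;
#' alternatively, known stem positions can be supplied. Every cell of the
#' raster is assigned to exactly one segment, so the segments tile the
#' image; each segment contains a tree crown plus any adjacent gap.
#'
#' @param chm a pit-closed [chm_raster()].
#' @param sigma Gaussian smoothing SD in cells (default 1.5).
#' @param markers optional data frame with `x`, `y` stem coordinates; when
#'   `NULL`, local maxima of the smoothed CHM are used.
#' @param min_height minimum apex height (m) for automatic markers.
#' @param window local-maximum window radius in cells.
#' @return an object of class `segment_map`: `labels` (integer matrix),
#'   `apices` (data frame `label`, `row`, `col`, `x`, `y`, `height`),
#'   `sigma`, and the raster geometry.
#' @export
segment_growing_spaces <- function(chm, sigma = 1.5, markers = NULL,
                                   min_height = 2, window = 2L) {
  sm <- gaussian_smooth(chm$values, sigma)
  if (is.null(markers)) {
    mk <- local_maxima(sm, r = window, min_height = min_height)
  } else {
    mk <- chm_cell_of(chm, markers$x, markers$y)
  }
  mk <- mk[!duplicated(mk[, c(1, 2), drop = FALSE]), , drop = FALSE]
  if (nrow(mk) == 0L)
    stop("no watershed markers found (raise the CHM or lower `min_height`)",
         call. = FALSE)
  markmat <- matrix(0L, nrow(sm), ncol(sm))
  markmat[mk] <- seq_len(nrow(mk))
  labels <- .watershed_flood(sm, markmat)
  # apex = segment maximum on the raw CHM
  labs <- sort(unique(as.integer(labels)))
  cells_by_lab <- split(seq_along(labels),
                        factor(as.integer(labels), levels = labs))
  apex_idx <- vapply(cells_by_lab,
                     function(ii) ii[which.max(chm$values[ii])], integer(1))
  ar <- (apex_idx - 1L) %% nrow(sm) + 1L
  ac <- (apex_idx - 1L) %/% nrow(sm) + 1L
  xy <- chm_xy_of(chm, ar, ac)
  apices <- data.frame(label = labs, row = ar, col = ac,
                       x = xy[, "x"], y = xy[, "y"],
                       height = chm$values[cbind(ar, ac)],
                       row.names = NULL)
  structure(list(labels = labels, apices = apices, sigma = sigma,
                 cellsize = chm$cellsize, xll = chm$xll, yll = chm$yll),
            class = "segment_map")
}

#' Delineate crowns within growing spaces
#'
#' Within each growing-space segment the crown is the 4-connected component
#' containing the apex of cells whose height is at least
#' `max(min_h, frac * apex_height)`, excluding gap (ground) area. Segments
#' with no gap keep crown == growing space.
#'
#' @param segments a [segment_growing_spaces()] result.
#' @param chm the matching `chm_raster`.
#' @param min_h absolute height floor of the rule, m.
#' @param frac apex-height fraction of the rule.
#' @return integer matrix of crown labels (0 outside crowns).
#' @export
delineate_crowns <- function(segments, chm, min_h = 1.0, frac = 0.3) {
  labels <- segments$labels
  crowns <- matrix(0L, nrow(labels), ncol(labels))
  for (i in seq_len(nrow(segments$apices))) {
    l <- segments$apices$label[i]
    thr <- max(min_h, frac * segments$apices$height[i])
    if (segments$apices$height[i] < thr)
      stop("crown rule excludes the apex of segment ", l, call. = FALSE)
    mask <- labels == l & chm$values >= thr
    comp <- .connected_component(mask, segments$apices$row[i],
                                 segments$apices$col[i])
    crowns[comp] <- l
  }
  crowns
}

## Crown boundary: crown cells 4-adjacent to a non-crown cell (raster edge
## counts as outside).
crown_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
           pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  mask & !inner
}

## Discrete surface area of heights over `mask`: per-cell slope factor
## sqrt(1 + |grad h|^2) from central/one-sided differences restricted to
## mask cells, times cell area. Flat surfaces give exactly the planar area.
surface_area <- function(h, mask, cellsize) {
  nr <- nrow(h); nc <- ncol(h)
  shift <- function(m, dr, dc) {
    out <- matrix(NA_real_, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  hm <- h; hm[!mask] <- NA_real_
  grad1d <- function(plus, minus) {
    g <- (plus - minus) / (2 * cellsize)               # central
    one_p <- (plus - hm) / cellsize                    # forward
    one_m <- (hm - minus) / cellsize                   # backward
    g[is.na(g)] <- one_p[is.na(g)]
    g[is.na(g)] <- one_m[is.na(g)]
    g[is.na(g)] <- 0
    g
  }
  gx <- grad1d(shift(hm, 0L, 1L), shift(hm, 0L, -1L))
  gy <- grad1d(shift(hm, 1L, 0L), shift(hm, -1L, 0L))
  sum(sqrt(1 + gx[mask]^2 + gy[mask]^2)) * cellsize^2
}

#' Crown metrics for every segment
#'
#' Computes the nine per-tree crown morphology metrics from the CHM, the
#' growing-space segmentation, and the delineated crowns:
#' `GA_P` (growing-space area, m^2), `CA_P` (crown area, m^2),
#' `CR = sqrt(CA_P / pi)` (crown radius, m), `A_CG = CA_P / GA_P`,
#' `CL` (apex height minus mean crown-boundary height, m),
#' `CV_F` (volume between crown surface and ground, m^3),
#' `CV_P` (volume between crown surface and the crown base, taken as the
#' mean boundary height, m^3), `CS_T` (surface area of the crown height
#' surface, m^2), and `CS_C` (surface area of the Gaussian-smoothed crown
#' surface, m^2).
#'
#' @param chm `chm_raster`. @param segments `segment_map`.
#' @param crowns crown label matrix from [delineate_crowns()].
#' @return data frame keyed by `label` with apex position and the nine
#'   metrics.
#' @export
compute_metrics <- function(chm, segments, crowns) {
  ca <- chm$cellsize^2
  sm <- gaussian_smooth(chm$values, segments$sigma)
  out <- segments$apices[, c("label", "row", "col", "x", "y", "height")]
  names(out)[2:6] <- c("apex_row", "apex_col", "apex_x", "apex_y",
                       "apex_height")
  m <- matrix(NA_real_, nrow(out), 9,
              dimnames = list(NULL, c("CR", "CL", "GA_P", "CA_P", "A_CG",
                                      "CS_C", "CS_T", "CV_F", "CV_P")))
  for (i in seq_len(nrow(out))) {
    l <- out$label[i]
    seg_mask <- segments$labels == l
    crown <- crowns == l
    if (!any(crown)) stop("empty crown for segment ", l, call. = FALSE)
    b <- crown_boundary(crown)
    hb <- chm$values[b]
    apexh <- out$apex_height[i]
    GA_P <- sum(seg_mask) * ca
    CA_P <- sum(crown) * ca
    base <- mean(hb)
    m[i, ] <- c(CR = sqrt(CA_P / pi),
                CL = apexh - base,
                GA_P = GA_P, CA_P = CA_P, A_CG = CA_P / GA_P,
                CS_C = surface_area(sm, crown, chm$cellsize),
                CS_T = surface_area(chm$values, crown, chm$cellsize),
                CV_F = sum(chm$values[crown]) * ca,
                CV_P = sum(pmax(0, chm$values[crown] - base)) * ca)
  }
  cbind(out, as.data.frame(m))
}

#' Match detected apices to planted stem positions
#'
#' One-to-one assignment minimising the summed squared distance (Hungarian
#' algorithm); pairs farther apart than `max_dist` are left unassigned.
#' Unmatched detections flag potential segmentation errors (split or
#' spurious crowns); unmatched planted positions flag missed trees.
#'
#' @param detected,planted data frames with `x`, `y` columns.
#' @param max_dist maximum pairing distance, m.
#' @return list with `pairs` (data frame `detected`, `planted`, `dist` of
#'   row indices), `unmatched_detected`, `unmatched_planted`.
#' @export
match_trees <- function(detected, planted, max_dist = 1.6) {
  if (max_dist <= 0) stop("`max_dist` must be positive", call. = FALSE)
  nd <- nrow(detected); np <- nrow(planted)
  if (nd == 0L || np == 0L)
    return(list(pairs = data.frame(detected = integer(), planted = integer(),
                                   dist = numeric()),
                unmatched_detected = seq_len(nd),
                unmatched_planted = seq_len(np)))
  d2 <- outer(detected$x, planted$x, "-")^2 + outer(detected$y, planted$y, "-")^2
  BIG <- max(max_dist^2, max(d2[d2 <= max_dist^2], 0)) * (nd + np + 1) + 1
  cost <- ifelse(d2 > max_dist^2, BIG, d2)
  flip <- nd > np
  asg <- if (flip) .hungarian_assign(t(cost)) else .hungarian_assign(cost)
  if (flip) {
    pairs <- data.frame(detected = asg, planted = seq_len(np))
  } else {
    pairs <- data.frame(detected = seq_len(nd), planted = asg)
  }
  pairs$dist <- sqrt(d2[cbind(pairs$detected, pairs$planted)])
  pairs <- pairs[pairs$dist <= max_dist, , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unmatched_detected = setdiff(seq_len(nd), pairs$detected),
       unmatched_planted = setdiff(seq_len(np), pairs$planted))
}

#' Calibrate the segmentation smoothing level
#'
#' Stand-in for operator calibration: tries each candidate `sigma`, segments
#' the CHM with automatic markers, and returns the sigma maximising the
#' number of one-to-one matches to the known stem positions.
#'
#' @param chm a pit-closed `chm_raster`.
#' @param stems data frame with `x`, `y` of live stems.
#' @param sigmas candidate smoothing SDs (cells).
#' @param max_dist matching distance, m.
#' @return list `sigma` (best value) and `matches` (named count vector).
#' @export
calibrate_sigma <- function(chm, stems, sigmas = c(1, 1.5, 2, 3),
                            max_dist = 1.6) {
  counts <- vapply(sigmas, function(s) {
    seg <- segment_growing_spaces(chm, sigma = s)
    nrow(match_trees(seg$apices, stems, max_dist)$pairs)
  }, numeric(1))
  names(counts) <- sigmas
  list(sigma = sigmas[which.max(counts)], matches = counts)
}

#' Write a segment label raster / crown outlines
#'
#' `write_segment_labels()` stores the integer label matrix as an ESRI
#' ASCII grid. `write_crowns_geojson()` writes one GeoJSON polygon feature
#' per crown as the convex hull of its cell centres (an approximation for
#' concave crowns; the label rasters carry the exact shapes).
#'
#' @param segments a `segment_map`. @param crowns crown label matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_segment_labels <- function(segments, path) {
  chm <- chm_raster(segments$labels + 0, cellsize = segments$cellsize,
                    xll = segments$xll, yll = segments$yll)
  write_ascii_grid(chm, path, digits = 8)
}

#' @rdname write_segment_labels
#' @export
write_crowns_geojson <- function(segments, crowns, path) {
  geo <- list(type = "FeatureCollection", features = list())
  ref <- chm_raster(crowns + 0, cellsize = segments$cellsize,
                    xll = segments$xll, yll = segments$yll)
  for (l in sort(unique(crowns[crowns > 0]))) {
    idx <- which(crowns == l, arr.ind = TRUE)
    xy <- chm_xy_of(ref, idx[, 1], idx[, 2])
    hull <- grDevices::chull(xy)
    ring <- xy[c(hull, hull[1]), , drop = FALSE]
    geo$features[[length(geo$features) + 1L]] <- list(
      type = "Feature",
      properties = list(label = l),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                        function(i) c(ring[i, 1], ring[i, 2])))))
  }
  jsonlite::write_json(geo, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
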