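# Watershed segmentation, crown delineation, crown metrics, matching.

# Analytic cone crown surface centred at (cx, cy).
cone_chm <- function(centres, h, R, cellsize = 0.25, extent = 16) {
  n <- ceiling(extent / cellsize)
  m <- matrix(0, n, n)
  for (i in seq_len(nrow(centres))) {
    for (r in seq_len(n)) {
      y <- extent - (r - 0.5) * cellsize
      x <- (seq_len(n) - 0.5) * cellsize
      d <- sqrt((x - centres[i, 1])^2 + (y - centres[i, 2])^2)
      m[r, ] <- pmax(m[r, ], ifelse(d <= R, h[i] * (1 - d / R), 0))
    }
  }
  chm_raster(m, cellsize = cellsize)
}

test_that("watershed splits two symmetric cones at the midline", {
  chm <- cone_chm(rbind(c(4, 8), c(12, 8)), h = c(10, 10), R = 4)
  seg <- segment_growing_spaces(chm, sigma = 1.5,
                                markers = data.frame(x = c(4, 12), y = c(8, 8)))
  expect_equal(nrow(seg$apices), 2)
  # labels tile the image
  expect_true(all(seg$labels > 0))
  # boundary within one cell of the equidistant line x = 8
  b <- seg$labels[, -1] != seg$labels[, -ncol(seg$labels)]
  bcols <- which(b, arr.ind = TRUE)[, 2]
  bx <- (bcols) * chm$cellsize  # boundary between col and col+1
  expect_true(all(abs(bx - 8) <= 2 * chm$cellsize))
  # apices recover the cone tips
  expect_equal(sort(seg$apices$x), c(4, 12) + 0.125, tolerance = 0.15)
})

test_that("a single cone yields one all-covering segment", {
  chm <- cone_chm(rbind(c(8, 8)), h = 10, R = 5)
  seg <- segment_growing_spaces(chm, sigma = 1)
  expect_equal(nrow(seg$apices), 1)
  expect_true(all(seg$labels == seg$apices$label[1]))
  # growing-space areas sum to the raster area (tiling invariant)
  expect_equal(sum(seg$labels > 0) * chm$cellsize^2,
               nrow(chm$values) * ncol(chm$values) * chm$cellsize^2)
})

test_that("zero markers is an error", {
  flat <- chm_raster(matrix(0.5, 20, 20))
  expect_error(segment_growing_spaces(flat, sigma = 1, min_height = 2),
               "markers")
})

test_that("crown delineation excludes gap area and keeps the apex", {
  chm <- cone_chm(rbind(c(8, 8)), h = 10, R = 3)  # ground ring around crown
  seg <- segment_growing_spaces(chm, sigma = 1)
  crowns <- delineate_crowns(seg, chm, min_h = 1, frac = 0.3)
  expect_true(all(chm$values[crowns == 0] < 3))    # excluded cells are low
  expect_true(crowns[seg$apices$row[1], seg$apices$col[1]] > 0)
  # crown within growing space
  expect_true(all(seg$labels[crowns > 0] == crowns[crowns > 0]))
  # gap-free segment: crown == growing space
  full <- chm_raster(matrix(10, 10, 10))
  segf <- segment_growing_spaces(full, sigma = 0.5,
                                 markers = data.frame(x = 1.25, y = 1.25))
  cf <- delineate_crowns(segf, full)
  expect_true(all(cf == segf$labels))
})

test_that("crown metrics match closed forms on a cylinder crown", {
  # 4 x 4 m flat-top crown of height 10 inside a 8 x 8 m segment
  cellsize <- 0.25
  n <- 32
  m <- matrix(0, n, n)
  crown_cells <- 16 + ((-7):8)                      # 16 cells = 4 m
  m[crown_cells, crown_cells] <- 10
  chm <- chm_raster(m, cellsize = cellsize)
  seg <- structure(list(
    labels = matrix(1L, n, n),
    apices = data.frame(label = 1L, row = 16L, col = 16L,
                        x = 15.5 * cellsize, y = (n - 15.5) * cellsize,
                        height = 10),
    sigma = 0, cellsize = cellsize, xll = 0, yll = 0),
    class = "segment_map")
  crowns <- delineate_crowns(seg, chm, min_h = 1, frac = 0.3)
  met <- compute_metrics(chm, seg, crowns)
  expect_equal(met$CA_P, 16)                        # 4 x 4 m
  expect_equal(met$GA_P, 64)                        # full segment
  expect_equal(met$A_CG, 0.25)
  expect_equal(met$CR, sqrt(16 / pi))
  expect_equal(met$CV_F, 160)                       # 16 m^2 x 10 m
  expect_equal(met$CL, 0)                           # flat top
  expect_equal(met$CV_P, 0)                         # base = top
  expect_equal(met$CS_T, 16)                        # flat surface
  expect_equal(met$CS_C, 16)
  # CR inversion: CA_P = pi -> CR = 1
  expect_equal(sqrt(pi / pi), 1)
  # invariants
  expect_true(met$CA_P <= met$GA_P && met$CS_T >= met$CA_P &&
                met$CV_P <= met$CV_F)
})

test_that("cone crown volume converges to the continuous integral", {
  R <- 2; h <- 6
  err <- vapply(c(0.25, 0.125), function(cs) {
    chm <- cone_chm(rbind(c(5, 5)), h = h, R = R, cellsize = cs, extent = 10)
    seg <- segment_growing_spaces(chm, sigma = 0.5,
                                  markers = data.frame(x = 5, y = 5))
    crowns <- (chm$values > 0) * seg$labels
    met <- compute_metrics(chm, seg, crowns)
    abs(met$CV_F - pi * R^2 * h / 3)
  }, numeric(1))
  expect_lt(err[2], err[1] + 1e-9)                  # finer grid no worse
  expect_lt(err[2] / (pi * R^2 * h / 3), 0.05)      # within 5% at 0.125 m
})

test_that("matching: identity, jitter, surplus detections, brute force", {
  pts <- expand.grid(x = seq(0, 9.6, 3.2), y = seq(0, 9.6, 3.2))
  # identical sets -> identity matching at zero cost
  m0 <- match_trees(pts, pts, max_dist = 1.6)
  expect_equal(m0$pairs$detected, m0$pairs$planted)
  expect_equal(sum(m0$pairs$dist), 0)
  # jitter well below spacing -> identity recovered
  set.seed(4)
  jit <- pts + matrix(runif(2 * nrow(pts), -0.3, 0.3), ncol = 2)
  names(jit) <- c("x", "y")
  m1 <- match_trees(jit, pts, max_dist = 1.6)
  expect_equal(m1$pairs$detected, m1$pairs$planted)
  # one extra detection -> exactly one unmatched detection
  extra <- rbind(jit, data.frame(x = 50, y = 50))
  m2 <- match_trees(extra, pts, max_dist = 1.6)
  expect_equal(length(m2$unmatched_detected), 1L)
  expect_equal(m2$unmatched_detected, nrow(extra))
  # optimality against full enumeration on small instances
  set.seed(9)
  for (k in 1:5) {
    det <- data.frame(x = runif(5, 0, 10), y = runif(5, 0, 10))
    pla <- data.frame(x = runif(6, 0, 10), y = runif(6, 0, 10))
    got <- match_trees(det, pla, max_dist = 6)
    want <- brute_force_assignment(det, pla, max_dist = 6)
    cost <- function(pairs) sum((det$x[pairs[, 1]] - pla$x[pairs[, 2]])^2 +
                                  (det$y[pairs[, 1]] - pla$y[pairs[, 2]])^2)
    expect_equal(cost(as.matrix(got$pairs[, 1:2])), cost(want),
                 tolerance = 1e-10)
  }
})

test_that("segment and crown products serialize to grid and GeoJSON", {
  chm <- cone_chm(rbind(c(4, 8), c(12, 8)), h = c(10, 9), R = 4)
  seg <- segment_growing_spaces(chm, sigma = 1,
                                markers = data.frame(x = c(4, 12), y = c(8, 8)))
  crowns <- delineate_crowns(seg, chm)
  asc <- withr::local_tempfile(fileext = ".asc")
  write_segment_labels(seg, asc)
  back <- read_ascii_grid(asc)
  expect_equal(back$values, seg$labels + 0, tolerance = 0)
  gj <- withr::local_tempfile(fileext = ".geojson")
  write_crowns_geojson(seg, crowns, gj)
  parsed <- jsonlite::read_json(gj)
  expect_equal(parsed$type, "FeatureCollection")
  expect_length(parsed$features, 2)
})

test_that("segmentation recall on a synthetic trial stays high", {
  tr <- make_trial(n_replicates = 1, seed = 21, mortality = 0.05)
  ph <- tr$trees
  chm <- simulate_chm(ph, resolution = 0.25, seed = 22)
  chm <- close_pits(chm, 3)
  seg <- segment_growing_spaces(chm, sigma = 1.5)
  live <- ph[ph$alive, ]
  m <- match_trees(stats::setNames(seg$apices[, c("x", "y")], c("x", "y")),
                   live[, c("x", "y")], max_dist = 1.6)
  recall <- nrow(m$pairs) / nrow(live)
  expect_gte(recall, 0.95)
})
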