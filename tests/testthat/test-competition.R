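# Competition indices: radius rule, neighbourhoods, formulations,
# standardization, enumeration, buffer edge correction.

grid_positions <- function(nr, nc, spacing = 3.2) {
  g <- expand.grid(col = seq_len(nc), row = seq_len(nr))
  data.frame(x = (g$col - 1) * spacing, y = (g$row - 1) * spacing)
}

test_that("radius_for_mean_count matches formula, scaling, and sampling", {
  expect_equal(radius_for_mean_count(3.2, 20), 3.2 * sqrt(21 / pi))
  expect_equal(radius_for_mean_count(6.4, 20),
               2 * radius_for_mean_count(3.2, 20))    # linear in spacing
  # sampling oracle: mean neighbour count over random centres on a fine grid
  set.seed(2)
  sp <- 2.1; k <- 12
  r <- radius_for_mean_count(sp, k)
  g <- grid_positions(40, 40, sp)
  centres <- data.frame(x = runif(300, 15 * sp, 25 * sp),
                        y = runif(300, 15 * sp, 25 * sp))
  counts <- vapply(seq_len(300), function(i)
    sum((g$x - centres$x[i])^2 + (g$y - centres$y[i])^2 <= r^2),
    numeric(1))
  # circle holds k + 1 grid points on average (incl. the notional centre)
  expect_lt(abs(mean(counts) - (k + 1)), 3 * sd(counts) / sqrt(300) + 0.2)
})

test_that("area neighbourhoods enumerate the expected grid offsets", {
  g <- grid_positions(3, 3, 1)
  adj <- neighbors_area(g, 1.5)
  centre <- which(g$x == 1 & g$y == 1)
  corner <- which(g$x == 0 & g$y == 0)
  expect_equal(length(adj[[centre]]), 8)
  expect_equal(length(adj[[corner]]), 3)
  # radius below the minimum spacing: empty everywhere
  expect_true(all(lengths(neighbors_area(g, 0.5)) == 0))
  # 3.2 m grid at the 8.273 m radius: interior tree has exactly 20
  gg <- grid_positions(11, 11)
  mid <- which(gg$x == 5 * 3.2 & gg$y == 5 * 3.2)
  adj2 <- neighbors_area(gg, radius_for_mean_count(3.2, 20))
  expect_equal(length(adj2[[mid]]), 20)
  # symmetry
  expect_true(all(vapply(seq_along(adj), function(i)
    all(vapply(adj[[i]], function(j) i %in% adj[[j]], logical(1))),
    logical(1))))
  expect_error(neighbors_area(rbind(g, g[1, ]), 1.5), "duplicate")
})

test_that("boundary neighbourhoods respect raster adjacency", {
  # two segments splitting a raster
  two <- matrix(rep(1:2, each = 12), 4, 6)
  adj <- neighbors_boundary(two)
  expect_equal(adj[["1"]], 2)
  expect_equal(adj[["2"]], 1)
  # 3x3 checkerboard of square segments: centre touches 4 under
  # 4-connectivity, 8 under 8-connectivity
  nine <- kronecker(matrix(1:9, 3, 3, byrow = TRUE), matrix(1L, 4, 4))
  adj9 <- neighbors_boundary(nine)
  expect_setequal(adj9[["5"]], c(2, 4, 6, 8))
  adj9c <- neighbors_boundary(nine, connectivity = 8)
  expect_setequal(adj9c[["5"]], c(1:4, 6:9))
  # brute-force adjacency oracle on a random label map
  set.seed(6)
  seg <- segment_growing_spaces(
    chm_raster(matrix(runif(400, 3, 9), 20, 20)), sigma = 2)
  lab <- seg$labels
  expect_equal(lapply(neighbors_boundary(lab), as.integer),
               lapply(naive_boundary_adjacency(lab), as.integer))
})

test_that("CI formulations match single-term arithmetic and the oracle", {
  # one neighbour, c_j = c_i, L = 2
  pos <- data.frame(x = c(0, 2), y = c(0, 0))
  adj <- neighbors_area(pos, 3)
  expect_equal(compute_ci(c(5, 5), pos, adj, "CIA")$ci_raw, c(0.5, 0.5))
  expect_equal(compute_ci(c(5, 5), pos, adj, "CIB")$ci_raw, c(0.25, 0.25))
  expect_equal(compute_ci(c(5, 5), pos, adj, "CIC")$ci_raw, c(0.5, 0.5))
  # uniform grid with equal crown metrics: the printed 20-neighbour sum
  gg <- grid_positions(11, 11)
  mid <- which(gg$x == 5 * 3.2 & gg$y == 5 * 3.2)
  adj2 <- neighbors_area(gg, radius_for_mean_count(3.2, 20))
  cia <- compute_ci(rep(1, nrow(gg)), gg, adj2, "CIA", reference = mid,
                    quiet = TRUE)$ci_raw
  hand <- 4 / 3.2 + 4 / (3.2 * sqrt(2)) + 4 / 6.4 + 8 / (3.2 * sqrt(5))
  expect_equal(cia, hand, tolerance = 1e-12)
  expect_equal(cia, 3.877, tolerance = 1e-3)
  # scale invariance: doubling every c leaves all three unchanged
  set.seed(3)
  cv <- runif(nrow(gg), 1, 4)
  for (f in c("CIA", "CIB", "CIC"))
    expect_equal(compute_ci(cv, gg, adj2, f)$ci_raw,
                 compute_ci(2 * cv, gg, adj2, f)$ci_raw)
  # vectorized implementation vs double-loop oracle, 100-tree instance
  set.seed(8)
  p100 <- data.frame(x = runif(100, 0, 40), y = runif(100, 0, 40))
  c100 <- runif(100, 0.5, 5)
  adj100 <- neighbors_area(p100, 9)
  for (f in c("CIA", "CIB", "CIC"))
    expect_equal(compute_ci(c100, p100, adj100, f, quiet = TRUE)$ci_raw,
                 naive_ci_area(c100, as.matrix(p100), 9, f),
                 tolerance = 1e-10)
  # non-positive reference metric errors with the tree named
  expect_error(compute_ci(c(0, 5), pos, adj, "CIA"), "tree")
})

test_that("standardization has exact mean 0 and sample SD 1", {
  expect_equal(standardize(c(2, 4, 6)), c(-1, 0, 1))
  set.seed(5)
  z <- standardize(rnorm(200, 50, 9))
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_error(standardize(rep(3, 10)), "constant")
})

test_that("spec enumeration produces the full labelled factorial", {
  specs <- enumerate_specs()
  expect_equal(nrow(specs), 54)
  expect_equal(anyDuplicated(specs$label), 0L)
  expect_equal(nrow(enumerate_specs("CV_F", "CIA", "NB")), 1)
  expect_error(enumerate_specs(character(0)), "non-empty")
})

test_that("the buffer equalizes edge and interior neighbourhoods", {
  # trial = 10x10 grid; buffer = 3 extra rings of the same grid
  sp <- 3.2
  all_g <- grid_positions(16, 16, sp)
  inner <- all_g$x >= 3 * sp & all_g$x <= 12 * sp &
           all_g$y >= 3 * sp & all_g$y <= 12 * sp
  trial <- all_g[inner, ]; buffer <- all_g[!inner, ]
  r <- radius_for_mean_count(sp, 20)
  with_buf <- neighbors_area(rbind(trial, buffer), r)
  without <- neighbors_area(trial, r)
  edge <- which(trial$x == 3 * sp)[3]              # a trial-edge tree
  interior <- which(trial$x == 7 * sp & trial$y == 7 * sp)
  expect_equal(length(with_buf[[edge]]), length(with_buf[[interior]]))
  expect_lt(length(without[[edge]]), length(with_buf[[edge]]))
  # and the CI drops accordingly when the buffer is removed
  cia_with <- compute_ci(rep(1, nrow(trial) + nrow(buffer)),
                         rbind(trial, buffer), with_buf, "CIA",
                         reference = edge)$ci_raw
  cia_without <- compute_ci(rep(1, nrow(trial)), trial, without, "CIA",
                            reference = edge)$ci_raw
  expect_lt(cia_without, cia_with)
})

test_that("standardization set excludes buffer competitors", {
  tr <- make_trial(n_replicates = 1, seed = 31, buffer_width = 10)
  ph <- tr$trees
  live <- ph[ph$alive, ]
  buf <- simulate_buffer(ph, seed = 32)
  pos <- rbind(live[, c("x", "y")], buf[, c("x", "y")])
  cvals <- c(live$H, buf$H)
  ct <- competition_table(list(H = cvals), "H", "CIA", pos,
                          n_trial = nrow(live), neighborhood = "NA",
                          radius = radius_for_mean_count(3.2, 20))
  expect_equal(nrow(ct), nrow(live))               # trial rows only
  expect_lt(abs(mean(ct$ci_std)), 1e-10)
  expect_lt(abs(sd(ct$ci_std) - 1), 1e-10)
  # oracle: recompute the standardization from the raw trial values
  expect_equal(ct$ci_std, (ct$ci_raw - mean(ct$ci_raw)) / sd(ct$ci_raw))
})
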