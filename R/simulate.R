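## Phenotype and canopy simulation with known genetic, site, and
## competition structure.

#' Simulation parameters for trial phenotypes
#'
#' The generative model for a focal trait (tree height, metres) is
#' `y = mu + control + rep + iblock + a + beta_comp * CI* + xi + eta`, where
#' `a` is the additive genetic value (covariance `sigma2_A * A(pedigree)`),
#' `xi` a separable AR1 x AR1 site field, `eta` iid noise, and `CI*` the
#' standardized Hegyi-type CIA competition index of neighbours' baseline
#' sizes (a single-pass mechanism: baseline sizes are drawn first, the trait
#' is then penalised, avoiding an iterated growth model). The remaining
#' traits (DBH, V via V182, D38, A) are derived from the same latent
#' components with trait-specific scale and noise.
#'
#' @param mu trait mean (m). @param control_effect fixed offset for control
#'   families (m).
#' @param sigma2_A,sigma2_rep,sigma2_iblock,sigma2_xi,sigma2_eta variance
#'   components (additive, replicate, incomplete block, spatially
#'   correlated, independent).
#' @param rho_row,rho_col AR1 autocorrelations of the site field, |rho| < 1.
#' @param beta_comp competition coefficient per unit standardized index
#'   (negative: more crowded, smaller tree).
#' @param baseline_cv coefficient of variation of the lognormal baseline
#'   sizes feeding the simulated competition index.
#' @param mortality mortality probability in `[0, 1)`.
#' @param seed master seed; all stage seeds derive from it.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(mu = 9, control_effect = 0.5,
                       sigma2_A = 1, sigma2_rep = 0.2, sigma2_iblock = 0.1,
                       sigma2_xi = 1, sigma2_eta = 1,
                       rho_row = 0.6, rho_col = 0.6,
                       beta_comp = -0.3, baseline_cv = 0.2,
                       mortality = 0.1, seed = 1L) {
  vs <- c(sigma2_A = sigma2_A, sigma2_rep = sigma2_rep,
          sigma2_iblock = sigma2_iblock, sigma2_xi = sigma2_xi,
          sigma2_eta = sigma2_eta)
  if (any(!is.finite(vs)) || any(vs < 0))
    stop("all variance components must be finite and >= 0", call. = FALSE)
  if (abs(rho_row) >= 1 || abs(rho_col) >= 1)
    stop("|rho| must be < 1", call. = FALSE)
  if (mortality < 0 || mortality >= 1)
    stop("`mortality` must be in [0, 1)", call. = FALSE)
  p <- as.list(environment())
  class(p) <- "sim_params"
  p
}

## Gene-drop breeding values down a topologically ordered pedigree.
## Mendelian sampling variance is sigma2_A * (1 - 0.25 * n_known_parents)
## for non-inbred parents (exact for founders and their crosses).
simulate_breeding_values <- function(pedigree, sigma2_A) {
  n <- nrow(pedigree)
  a <- numeric(n)
  if (sigma2_A == 0) return(stats::setNames(a, pedigree$id))
  s <- match(pedigree$sire, pedigree$id)
  d <- match(pedigree$dam, pedigree$id)
  s[is.na(pedigree$sire) | pedigree$sire == 0] <- NA   # 0 codes "unknown"
  d[is.na(pedigree$dam) | pedigree$dam == 0] <- NA
  z <- stats::rnorm(n)
  for (i in seq_len(n)) {
    mid <- 0; known <- 0L
    if (!is.na(s[i])) { mid <- mid + 0.5 * a[s[i]]; known <- known + 1L }
    if (!is.na(d[i])) { mid <- mid + 0.5 * a[d[i]]; known <- known + 1L }
    a[i] <- mid + z[i] * sqrt(sigma2_A * (1 - 0.25 * known))
  }
  stats::setNames(a, pedigree$id)
}

#' Simulate a buffer stand around the trial
#'
#' Continues the planting grid for `buffer_width` metres beyond the trial
#' footprint and thins it by independent Poisson thinning to
#' `buffer_density` stems per hectare. Buffer trees get heights (for the CHM
#' and as competition baselines) but no pedigree, design factors, or
#' phenotype records.
#'
#' @param trees a `tree_table` (provides extent, spacing, design).
#' @param seed integer seed.
#' @param h_mu,h_sd mean and SD of buffer tree heights (m).
#' @return data frame with `x`, `y`, `H`, `buffer = TRUE`.
#' @export
simulate_buffer <- function(trees, seed, h_mu = 9, h_sd = 1.5) {
  design <- attr(trees, "design")
  ext <- attr(trees, "extent")
  sp <- design$spacing
  w <- design$buffer_width
  if (w <= 0) return(data.frame(x = numeric(), y = numeric(),
                                H = numeric(), buffer = logical()))
  gx <- seq(-sp * ceiling(w / sp), ext["x"] - sp + sp * ceiling(w / sp),
            by = sp)
  gy <- seq(-sp * ceiling(w / sp), ext["y"] - sp + sp * ceiling(w / sp),
            by = sp)
  g <- expand.grid(x = gx, y = gy)
  inside <- g$x > -sp / 2 & g$x < ext["x"] - sp / 2 &
            g$y > -sp / 2 & g$y < ext["y"] - sp / 2
  g <- g[!inside, , drop = FALSE]
  keep_p <- min(1, design$buffer_density * sp^2 / 1e4)
  with_seed(seed, {
    keep <- stats::runif(nrow(g)) < keep_p
    g <- g[keep, , drop = FALSE]
    g$H <- pmax(2, stats::rnorm(nrow(g), h_mu, h_sd))
  })
  g$buffer <- TRUE
  rownames(g) <- NULL
  g
}

#' Simulate phenotypes on a trial
#'
#' Draws every component of the generative model in [sim_params()] and
#' returns the tree table augmented with the five traits (`H` m, `DBH` cm,
#' `V` m^3, `D38` percent in 5-point steps, `A` km/s) and the true simulated
#' effects (`true_a`, `true_site`, `true_eta`, `true_comp`, `ci_true`,
#' `baseline`) kept for parameter-recovery tests. Dead trees keep their grid
#' position and get `NA` traits. Buffer trees (optional) contribute to the
#' competition index but are never standardization or phenotype rows.
#'
#' @param trees `tree_table` (after [apply_mortality()] if desired).
#' @param pedigree matching `pedigree` (e.g. [pedigree_for_trees()]).
#' @param sim a [sim_params()] object.
#' @param buffer optional buffer stand from [simulate_buffer()].
#' @return the phenotype table (class `tree_table`), one row per planting
#'   position.
#' @export
simulate_phenotypes <- function(trees, pedigree, sim, buffer = NULL) {
  if (!inherits(sim, "sim_params"))
    stop("`sim` must come from sim_params()", call. = FALSE)
  n <- nrow(trees)
  n_rows <- attr(trees, "n_rows") %||% max(trees$row)
  n_cols <- attr(trees, "n_cols") %||% max(trees$col)
  sp <- (attr(trees, "design") %||% list(spacing = 3.2))$spacing

  with_seed(child_seed(sim$seed, 11L), {
    bv <- simulate_breeding_values(pedigree, sim$sigma2_A)
    a <- unname(bv[match(trees$tree_id, pedigree$id)])
    if (anyNA(a)) stop("trees missing from pedigree", call. = FALSE)

    reps <- sort(unique(trees$rep))
    rep_eff <- stats::rnorm(length(reps), 0, sqrt(sim$sigma2_rep))
    u_rep <- rep_eff[match(trees$rep, reps)]
    ib_key <- paste(trees$rep, trees$iblock)
    ibs <- unique(ib_key)
    ib_eff <- stats::rnorm(length(ibs), 0, sqrt(sim$sigma2_iblock))
    u_ib <- ib_eff[match(ib_key, ibs)]

    xi_field <- simulate_ar1_field(n_rows, n_cols, sim$rho_row, sim$rho_col,
                                   sim$sigma2_xi)
    xi <- xi_field[cbind(trees$row, trees$col)]
    eta <- stats::rnorm(n, 0, sqrt(sim$sigma2_eta))

    # single-pass competition: lognormal baseline sizes, CIA index,
    # standardized over live trial trees
    sdlog <- sqrt(log(1 + sim$baseline_cv^2))
    baseline <- exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
    ci_raw <- rep(0, n)
    if (sim$beta_comp != 0) {
      alive <- trees$alive
      pos <- rbind(cbind(trees$x[alive], trees$y[alive]),
                   if (!is.null(buffer) && nrow(buffer))
                     cbind(buffer$x, buffer$y))
      cvals <- c(baseline[alive],
                 if (!is.null(buffer) && nrow(buffer))
                   exp(stats::rnorm(nrow(buffer), -sdlog^2 / 2, sdlog)))
      radius <- radius_for_mean_count(sp, 20)
      adj <- neighbors_area(pos, radius)
      ci <- compute_ci(cvals, pos, adj, "CIA",
                       reference = seq_len(sum(alive)), quiet = TRUE)
      ci_raw[alive] <- ci$ci_raw
    }
    ci_std <- if (stats::sd(ci_raw[trees$alive]) > 0)
      (ci_raw - mean(ci_raw[trees$alive])) / stats::sd(ci_raw[trees$alive])
    else rep(0, n)

    comp <- sim$beta_comp * ci_std
    y <- sim$mu + ifelse(trees$control, sim$control_effect, 0) +
      u_rep + u_ib + a + comp + xi + eta

    a_sd <- if (sim$sigma2_A > 0) sqrt(sim$sigma2_A) else 1
    xi_sd <- if (sim$sigma2_xi > 0) sqrt(sim$sigma2_xi) else 1
    H <- pmax(2, y)
    DBH <- pmax(2, 16 + 2 * (y - sim$mu) + stats::rnorm(n, 0, 1))
    V <- compute_volume(DBH, H)
    d38_lat <- 30 + 12 * xi / xi_sd - 5 * a / a_sd + stats::rnorm(n, 0, 8)
    D38 <- pmin(100, pmax(0, 5 * round(d38_lat / 5)))
    A <- 2.8 + 0.15 * a / a_sd + 0.08 * xi / xi_sd + stats::rnorm(n, 0, 0.2)
  })

  out <- trees
  out$H <- H; out$DBH <- DBH; out$V <- V; out$D38 <- D38; out$A <- A
  out$true_a <- a; out$true_site <- xi; out$true_eta <- eta
  out$true_comp <- comp; out$ci_true <- ci_std; out$baseline <- baseline
  for (tr in c("H", "DBH", "V", "D38", "A")) out[[tr]][!out$alive] <- NA_real_
  attr(out, "sim") <- sim
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Crown radius allometry used by the CHM simulator (m).
crown_radius_from_height <- function(h) pmax(0.6, pmin(2.4, 0.24 * h))

#' Simulate a canopy height model raster
#'
#' Builds a CHM directly (no point cloud): each live tree contributes a
#' generalized-cone crown surface `z(d) = h * (1 - (d / rc)^shape)` clipped
#' at zero, the raster is the per-cell maximum over all trees (trial and
#' buffer), Gaussian sensor noise is added, and random single-cell pits
#' (dropouts set to ground level) are punched at rate `pit_rate`. Ground
#' cells are 0.
#'
#' @param trees `tree_table` with simulated `H` (dead trees are skipped).
#' @param buffer optional [simulate_buffer()] output.
#' @param resolution cell size in metres (default 0.25).
#' @param shape crown profile exponent (1 = cone; >1 rounder).
#' @param noise_sd additive noise SD, m.
#' @param pit_rate per-cell pit probability.
#' @param margin extra metres of raster beyond the outermost stem.
#' @param seed integer seed.
#' @return a [chm_raster()] with attribute `n_pits`.
#' @export
simulate_chm <- function(trees, buffer = NULL, resolution = 0.25,
                         shape = 1.5, noise_sd = 0.03, pit_rate = 0.001,
                         margin = 3, seed = 1L) {
  if (resolution <= 0) stop("`resolution` must be positive", call. = FALSE)
  live <- trees[trees$alive & !is.na(trees$H), c("x", "y", "H")]
  stems <- rbind(live, if (!is.null(buffer) && nrow(buffer))
    buffer[, c("x", "y", "H")])
  if (!nrow(stems)) stop("no live trees to rasterize", call. = FALSE)
  # snap the origin so stems on the planting lattice land on cell centres
  # (the apex cell then carries the full tree height)
  snap <- function(v) floor(v / resolution) * resolution - resolution / 2
  xll <- snap(min(stems$x) - margin); yll <- snap(min(stems$y) - margin)
  xmax <- max(stems$x) + margin; ymax <- max(stems$y) + margin
  nc <- ceiling((xmax - xll) / resolution)
  nr <- ceiling((ymax - yll) / resolution)
  ymax <- yll + nr * resolution        # raster top edge, on the lattice
  z <- matrix(0, nr, nc)
  rc_all <- crown_radius_from_height(stems$H)
  for (i in seq_len(nrow(stems))) {
    rc <- rc_all[i]; h <- stems$H[i]
    c0 <- floor((stems$x[i] - rc - xll) / resolution) + 1L
    c1 <- ceiling((stems$x[i] + rc - xll) / resolution)
    r0 <- floor((ymax - (stems$y[i] + rc)) / resolution) + 1L
    r1 <- ceiling((ymax - (stems$y[i] - rc)) / resolution)
    cs <- max(1L, c0):min(nc, c1)
    rs <- max(1L, r0):min(nr, r1)
    cx <- xll + (cs - 0.5) * resolution
    cy <- ymax - (rs - 0.5) * resolution
    d <- sqrt(outer((cy - stems$y[i])^2, (cx - stems$x[i])^2, "+"))
    surf <- h * (1 - (d / rc)^shape)
    surf[d > rc] <- 0
    z[rs, cs] <- pmax(z[rs, cs], pmax(surf, 0))
  }
  n_pits <- 0L
  if (noise_sd > 0 || pit_rate > 0) {
    with_seed(seed, {
      if (noise_sd > 0) {
        canopy <- z > 0
        z[canopy] <- pmax(0, z[canopy] + stats::rnorm(sum(canopy), 0, noise_sd))
      }
      if (pit_rate > 0) {
        pits <- which(stats::runif(length(z)) < pit_rate)
        n_pits <- length(pits)
        z[pits] <- 0
      }
    })
  }
  chm <- chm_raster(z, cellsize = resolution, xll = xll, yll = yll)
  attr(chm, "n_pits") <- n_pits
  chm
}
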