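## Trial design: incomplete-block, single-tree-plot layouts on a uniform grid.

#' Trial design parameters
#'
#' Describes an incomplete-block progeny trial with single-tree plots on a
#' uniform planting grid. Defaults reproduce a 75-block radiata pine trial:
#' 25 replicates of 3 incomplete blocks, each block a 6 x 6 grid of trees at
#' 3.2 m spacing (block extent 19.2 x 19.2 m), 96 families of which 6 are
#' controls present in every block, surrounded by a 50 m buffer stand thinned
#' to 786 stems per hectare.
#'
#' @param n_replicates number of replicates.
#' @param iblocks_per_replicate incomplete blocks per replicate.
#' @param block_rows,block_cols tree grid dimensions within one block.
#' @param spacing planting grid spacing in metres.
#' @param block_arrangement integer vector `c(rows, cols)` giving the layout
#'   of blocks on the ground; must multiply to the total block count. The
#'   default arranges replicates in a near-square grid with each replicate's
#'   incomplete blocks side by side.
#' @param n_families total number of families, controls included.
#' @param n_controls number of control families (present in every block).
#' @param buffer_width width of the surrounding buffer stand, metres.
#' @param buffer_density buffer stocking, stems per hectare.
#' @return an object of class `trial_design` (a validated list).
#' @export
trial_design_params <- function(n_replicates = 25,
                                iblocks_per_replicate = 3,
                                block_rows = 6, block_cols = 6,
                                spacing = 3.2,
                                block_arrangement = NULL,
                                n_families = 96, n_controls = 6,
                                buffer_width = 50, buffer_density = 786) {
  for (nm in c("n_replicates", "iblocks_per_replicate", "block_rows",
               "block_cols", "n_families", "n_controls"))
    stopifnot_scalar_count(get(nm), nm)
  if (!is.numeric(spacing) || spacing <= 0)
    stop("`spacing` must be positive", call. = FALSE)
  if (n_controls >= n_families)
    stop("`n_controls` must be smaller than `n_families`", call. = FALSE)
  if (buffer_width < 0 || buffer_density < 0)
    stop("buffer parameters must be non-negative", call. = FALSE)
  n_blocks <- n_replicates * iblocks_per_replicate
  if (is.null(block_arrangement)) {
    # replicates in a near-square grid, iblocks of one replicate side by side
    rep_rows <- floor(sqrt(n_replicates))
    while (n_replicates %% rep_rows != 0L) rep_rows <- rep_rows - 1L
    block_arrangement <- c(rep_rows, (n_replicates %/% rep_rows) *
                                       iblocks_per_replicate)
  }
  block_arrangement <- as.integer(block_arrangement)
  if (length(block_arrangement) != 2L ||
      prod(block_arrangement) != n_blocks)
    stop("`block_arrangement` must be c(rows, cols) with rows*cols = ",
         n_blocks, call. = FALSE)
  p <- list(n_replicates = as.integer(n_replicates),
            iblocks_per_replicate = as.integer(iblocks_per_replicate),
            block_rows = as.integer(block_rows),
            block_cols = as.integer(block_cols),
            spacing = as.numeric(spacing),
            block_arrangement = block_arrangement,
            n_families = as.integer(n_families),
            n_controls = as.integer(n_controls),
            buffer_width = as.numeric(buffer_width),
            buffer_density = as.numeric(buffer_density))
  class(p) <- "trial_design"
  p
}

#' Generate the planting grid for a trial design
#'
#' Lays the blocks out on the ground and returns one row per planting
#' position, with global grid indices, metric coordinates, and the block /
#' replicate / incomplete-block membership of every position. Deterministic:
#' no randomness is involved.
#'
#' Coordinates follow `x = (col - 1) * spacing`, `y = (row - 1) * spacing`
#' with 1-based grid indices; row 1 is the northern edge.
#'
#' @param params a [trial_design_params()] object.
#' @return an object of class `trial_layout`: a data frame with columns
#'   `pos_id`, `block`, `rep`, `iblock`, `row`, `col`, `x`, `y`, plus
#'   attributes `n_rows`, `n_cols`, `spacing`, `extent` (metres x, y) and
#'   `design`.
#' @examples
#' lay <- generate_layout(trial_design_params())
#' nrow(lay)                       # 2700 positions
#' attr(lay, "extent")             # 288 x 96 m (75 blocks of 19.2 m)
#' @export
generate_layout <- function(params) {
  if (!inherits(params, "trial_design"))
    stop("`params` must come from trial_design_params()", call. = FALSE)
  br <- params$block_rows; bc <- params$block_cols
  arr <- params$block_arrangement
  n_blocks <- params$n_replicates * params$iblocks_per_replicate
  # block b (1-based, replicate-major) sits at block-grid position
  bg_row <- ((seq_len(n_blocks) - 1L) %/% arr[2L]) + 1L
  bg_col <- ((seq_len(n_blocks) - 1L) %% arr[2L]) + 1L
  rep_id <- ((seq_len(n_blocks) - 1L) %/% params$iblocks_per_replicate) + 1L
  ib_id  <- ((seq_len(n_blocks) - 1L) %% params$iblocks_per_replicate) + 1L

  within_row <- rep(seq_len(br), times = bc)
  within_col <- rep(seq_len(bc), each = br)
  n_per_block <- br * bc

  block <- rep(seq_len(n_blocks), each = n_per_block)
  row <- (bg_row[block] - 1L) * br + rep(within_row, n_blocks)
  col <- (bg_col[block] - 1L) * bc + rep(within_col, n_blocks)
  lay <- data.frame(pos_id = seq_len(n_blocks * n_per_block),
                    block = block,
                    rep = rep_id[block],
                    iblock = ib_id[block],
                    row = row, col = col,
                    x = (col - 1L) * params$spacing,
                    y = (row - 1L) * params$spacing)
  lay <- lay[order(lay$row, lay$col), ]
  lay$pos_id <- seq_len(nrow(lay))
  rownames(lay) <- NULL
  attr(lay, "n_rows") <- arr[1L] * br
  attr(lay, "n_cols") <- arr[2L] * bc
  attr(lay, "spacing") <- params$spacing
  attr(lay, "extent") <- c(x = arr[2L] * bc * params$spacing,
                           y = arr[1L] * br * params$spacing)
  attr(lay, "design") <- params
  class(lay) <- c("trial_layout", "data.frame")
  lay
}

#' Ground area of a trial layout
#'
#' Block footprint area (block extent squared times block count), in
#' hectares. With the default design this is 75 x 19.2 m x 19.2 m = 2.76 ha.
#'
#' @param layout a `trial_layout`.
#' @return area in hectares.
#' @export
layout_area_ha <- function(layout) {
  d <- attr(layout, "design")
  n_blocks <- d$n_replicates * d$iblocks_per_replicate
  n_blocks * (d$block_rows * d$spacing) * (d$block_cols * d$spacing) / 1e4
}

#' Assign families to planting positions
#'
#' Every block receives each control family exactly once plus a set of
#' non-control families, all distinct, so a 36-tree block holds 36 different
#' families. The non-control families of each replicate are partitioned at
#' random across its incomplete blocks (a family appears in exactly one
#' incomplete block per replicate); any remainder when the non-control count
#' does not divide evenly is spread one-per-iblock. Positions within a block
#' are randomized. Families `1..n_controls` are the controls.
#'
#' @param layout a `trial_layout`.
#' @param params the matching `trial_design_params()`.
#' @param seed integer seed; the same seed reproduces the assignment exactly.
#' @return a `tree_table` data frame: `tree_id`, `family`, `control`, `rep`,
#'   `iblock`, `block`, `row`, `col`, `x`, `y`, `alive`.
#' @export
assign_families <- function(layout, params, seed) {
  if (!inherits(layout, "trial_layout"))
    stop("`layout` must come from generate_layout()", call. = FALSE)
  n_slots <- params$block_rows * params$block_cols
  n_nc_needed <- n_slots - params$n_controls
  if (n_nc_needed < 0)
    stop("more control families than block positions", call. = FALSE)
  controls <- seq_len(params$n_controls)
  noncontrols <- seq(params$n_controls + 1L, params$n_families)
  k <- params$iblocks_per_replicate
  base_size <- length(noncontrols) %/% k
  if (base_size < n_nc_needed)
    stop("design error: only ", base_size, " non-control families per ",
         "incomplete block but ", n_nc_needed, " distinct families needed ",
         "to fill a block", call. = FALSE)

  fam_col <- integer(nrow(layout))
  ord <- integer(nrow(layout))
  with_seed(seed, {
    for (r in seq_len(params$n_replicates)) {
      shuffled <- sample(noncontrols)
      # even partition; remainder families spread one per iblock
      sizes <- rep(base_size, k)
      rem <- length(noncontrols) - base_size * k
      if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
      groups <- split(shuffled, rep(seq_len(k), times = sizes))
      for (ib in seq_len(k)) {
        idx <- which(layout$rep == r & layout$iblock == ib)
        fams <- c(controls, sample(groups[[ib]], n_nc_needed))
        fam_col[idx] <- fams[sample.int(length(fams))]
      }
    }
  })
  trees <- data.frame(tree_id = layout$pos_id,
                      family = fam_col,
                      control = fam_col <= params$n_controls,
                      rep = layout$rep, iblock = layout$iblock,
                      block = layout$block,
                      row = layout$row, col = layout$col,
                      x = layout$x, y = layout$y,
                      alive = TRUE)
  for (a in c("n_rows", "n_cols", "spacing", "extent", "design"))
    attr(trees, a) <- attr(layout, a)
  class(trees) <- c("tree_table", "data.frame")
  trees
}

#' Apply random mortality to a tree table
#'
#' Flags each tree dead independently with probability `rate`. Dead trees
#' keep their grid coordinates (gaps stay in the grid) and any trait columns
#' (`H`, `DBH`, `V`, `D38`, `A`) are set to `NA`.
#'
#' @param trees a `tree_table`.
#' @param rate mortality probability in `[0, 1)`.
#' @param seed integer seed.
#' @return the tree table with updated `alive` flags.
#' @export
apply_mortality <- function(trees, rate, seed) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    stop("`rate` must be in [0, 1)", call. = FALSE)
  dead <- with_seed(seed, stats::runif(nrow(trees)) < rate)
  trees$alive <- trees$alive & !dead
  for (tr in intersect(c("H", "DBH", "V", "D38", "A"), names(trees)))
    trees[[tr]][!trees$alive] <- NA_real_
  trees
}
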