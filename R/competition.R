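## Distance-weighted (Hegyi-type) competition indices: three formulations x
## nine crown metrics x two neighbourhood definitions.

#' Neighbourhood radius for a target mean neighbour count
#'
#' On a uniform planting grid with the given spacing, the radius at which a
#' circle holds an expected `k + 1` grid points (the reference tree plus
#' `k` neighbours): `radius = spacing * sqrt((k + 1) / pi)`. With 3.2 m spacing
#' and k = 20 this is the 8.273 m radius used for the area neighbourhood.
#'
#' @param spacing grid spacing, m (> 0).
#' @param k target mean neighbour count (>= 1).
#' @return radius in metres.
#' @examples
#' radius_for_mean_count(3.2, 20) # 8.273
#' @export
radius_for_mean_count <- function(spacing, k) {
  if (spacing <= 0) stop("`spacing` must be positive", call. = FALSE)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  spacing * sqrt((k + 1) / pi)
}

#' Area-method neighbourhoods (fixed radius)
#'
#' For each tree, the indices of all trees within `radius` metres
#' (0 < distance <= radius). Callers exclude dead trees by filtering the
#' position set first; buffer trees are eligible competitors simply by being
#' rows of `positions`.
#'
#' @param positions two-column matrix or data frame of x, y (m).
#' @param radius neighbourhood radius, m.
#' @return list of integer index vectors, one per tree (symmetric relation).
#' @export
neighbors_area <- function(positions, radius) {
  if (radius <= 0) stop("`radius` must be positive", call. = FALSE)
  p <- as.matrix(positions)[, 1:2, drop = FALSE]
  if (anyDuplicated(p))
    stop("duplicate coordinates: zero distance is undefined in a ",
         "distance-weighted index", call. = FALSE)
  n <- nrow(p)
  # grid-bucket the points so the scan is near-linear in n
  cell <- radius
  bx <- floor(p[, 1] / cell); by <- floor(p[, 2] / cell)
  key <- paste(bx, by)
  buckets <- split(seq_len(n), key)
  out <- vector("list", n)
  r2 <- radius^2
  for (i in seq_len(n)) {
    cand <- unlist(buckets[paste(rep(bx[i] + (-1:1), each = 3),
                                 rep(by[i] + (-1:1), times = 3))],
                   use.names = FALSE)
    d2 <- (p[cand, 1] - p[i, 1])^2 + (p[cand, 2] - p[i, 2])^2
    out[[i]] <- cand[d2 > 0 & d2 <= r2]
  }
  out
}

#' Boundary-method neighbourhoods (shared segment boundary)
#'
#' Two trees are neighbours iff their growing-space segments share at least
#' one pair of adjacent raster cells. 4-connectivity is the default; the
#' choice is exposed because either convention is defensible.
#'
#' @param segments a `segment_map` (or a bare integer label matrix).
#' @param connectivity 4 (edge-adjacent) or 8 (also corner-adjacent).
#' @return named list mapping each segment label to the integer vector of
#'   adjacent segment labels (symmetric).
#' @export
neighbors_boundary <- function(segments, connectivity = 4) {
  labels <- if (inherits(segments, "segment_map")) segments$labels else segments
  if (!connectivity %in% c(4, 8))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  nr <- nrow(labels); nc <- ncol(labels)
  pair_up <- function(a, b) {
    keep <- a != b
    unique(rbind(cbind(a[keep], b[keep]), cbind(b[keep], a[keep])))
  }
  pairs <- rbind(
    pair_up(labels[-nr, , drop = FALSE], labels[-1, , drop = FALSE]),
    pair_up(labels[, -nc, drop = FALSE], labels[, -1, drop = FALSE]))
  if (connectivity == 8) {
    pairs <- rbind(pairs,
      pair_up(labels[-nr, -nc, drop = FALSE], labels[-1, -1, drop = FALSE]),
      pair_up(labels[-nr, -1, drop = FALSE], labels[-1, -nc, drop = FALSE]))
    pairs <- unique(pairs)
  }
  labs <- sort(unique(as.integer(labels)))
  adj <- lapply(labs, function(l) sort(unique(pairs[pairs[, 1] == l, 2])))
  names(adj) <- labs
  adj
}

#' Hegyi-type competition indices
#'
#' For each reference tree i with neighbours j at distances `L_ij` and crown
#' metric values `c`, the three distance-weighted size-ratio formulations:
#' `CIA = sum((c_j / c_i) / L_ij)` (units 1/m),
#' `CIB = sum((c_j / c_i) / L_ij^2)` (1/m^2),
#' `CIC = sum((c_j / c_i)^2 / L_ij)` (1/m).
#' With `c` = DBH and an area neighbourhood, CIA is the classic Hegyi
#' index. Trees with an empty neighbourhood get CI = 0 (kept, with a
#' warning, so design matrices stay complete).
#'
#' @param c_values positive crown metric values, one per row of `positions`.
#' @param positions x, y matrix (m), same order as `c_values`.
#' @param adjacency neighbour index list from [neighbors_area()] (or any
#'   list of integer vectors into the rows).
#' @param formulation `"CIA"`, `"CIB"`, or `"CIC"`.
#' @param reference indices of the reference trees to evaluate (default:
#'   all); lets buffer trees act as competitors without receiving an index.
#' @param quiet suppress the empty-neighbourhood warning.
#' @return data frame `index` (reference row), `ci_raw`, `n_neighbors`.
#' @export
compute_ci <- function(c_values, positions, adjacency,
                       formulation = c("CIA", "CIB", "CIC"),
                       reference = NULL, quiet = FALSE) {
  formulation <- match.arg(formulation)
  p <- as.matrix(positions)[, 1:2, drop = FALSE]
  if (is.null(reference)) reference <- seq_len(nrow(p))
  bad <- reference[!is.finite(c_values[reference]) | c_values[reference] <= 0]
  if (length(bad))
    stop("non-positive crown metric for reference tree(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  ci <- numeric(length(reference))
  nn <- integer(length(reference))
  for (k in seq_along(reference)) {
    i <- reference[k]
    j <- adjacency[[i]]
    nn[k] <- length(j)
    if (!length(j)) next
    L <- sqrt((p[j, 1] - p[i, 1])^2 + (p[j, 2] - p[i, 2])^2)
    ratio <- c_values[j] / c_values[i]
    ci[k] <- switch(formulation,
                    CIA = sum(ratio / L),
                    CIB = sum(ratio / L^2),
                    CIC = sum(ratio^2 / L))
  }
  if (any(nn == 0L) && !quiet)
    warning(sum(nn == 0L), " reference tree(s) had an empty neighbourhood; ",
            "CI set to 0", call. = FALSE)
  data.frame(index = reference, ci_raw = ci, n_neighbors = nn)
}

#' Enumerate competition-index configurations
#'
#' Full Cartesian product of crown metrics x formulations x neighbourhood
#' methods, with unique labels like `"CV_F:CIA:NB"`. The default nine
#' metrics, three formulations, and two neighbourhoods give 54
#' configurations.
#'
#' @param metrics crown metric names.
#' @param formulations subset of CIA/CIB/CIC.
#' @param neighborhoods subset of `c("NA", "NB")` (area, boundary).
#' @return data frame `metric`, `formulation`, `neighborhood`, `label`.
#' @export
enumerate_specs <- function(metrics = c("CR", "CL", "GA_P", "CA_P", "A_CG",
                                        "CS_C", "CS_T", "CV_F", "CV_P"),
                            formulations = c("CIA", "CIB", "CIC"),
                            neighborhoods = c("NA", "NB")) {
  if (!length(metrics) || !length(formulations) || !length(neighborhoods))
    stop("all spec dimensions must be non-empty", call. = FALSE)
  g <- expand.grid(metric = metrics, formulation = formulations,
                   neighborhood = neighborhoods,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g$label <- paste(g$metric, g$formulation, g$neighborhood, sep = ":")
  if (anyDuplicated(g$label)) stop("duplicate spec labels", call. = FALSE)
  g
}

#' Competition table for one configuration
#'
#' End-to-end helper: given per-tree crown metric values and positions for
#' trial trees (plus optional buffer trees as competitors only), builds the
#' neighbourhood, computes the chosen formulation, and standardizes the
#' index over the trial trees (mean 0, sample SD 1). Buffer trees contribute
#' to the sums but never to the standardization.
#'
#' @param values named list or data frame holding the crown metric column.
#' @param metric crown metric name (column of `values`).
#' @param formulation CIA/CIB/CIC.
#' @param positions x, y for all trees (trial first, then buffer).
#' @param n_trial number of leading rows that are trial trees.
#' @param neighborhood `"NA"` (needs `radius`) or `"NB"` (needs `segments`,
#'   plus `labels_by_tree` mapping tree rows to segment labels).
#' @param radius area-method radius, m.
#' @param segments `segment_map` for the boundary method.
#' @param labels_by_tree integer segment label per tree row.
#' @return data frame `index`, `ci_raw`, `ci_std`, `n_neighbors`.
#' @export
competition_table <- function(values, metric, formulation, positions,
                              n_trial, neighborhood = c("NA", "NB"),
                              radius = NULL, segments = NULL,
                              labels_by_tree = NULL) {
  neighborhood <- match.arg(neighborhood)
  cvals <- if (is.data.frame(values)) values[[metric]] else values[[metric]]
  if (neighborhood == "NA") {
    if (is.null(radius)) stop("area method needs `radius`", call. = FALSE)
    adj <- neighbors_area(positions, radius)
  } else {
    if (is.null(segments) || is.null(labels_by_tree))
      stop("boundary method needs `segments` and `labels_by_tree`",
           call. = FALSE)
    lab_adj <- neighbors_boundary(segments)
    tree_of_label <- match(as.integer(names(lab_adj)), labels_by_tree)
    adj <- lapply(seq_len(nrow(as.matrix(positions))), function(i) {
      nb_labs <- lab_adj[[as.character(labels_by_tree[i])]]
      tr <- tree_of_label[match(nb_labs, as.integer(names(lab_adj)))]
      tr[!is.na(tr)]
    })
  }
  ci <- compute_ci(cvals, positions, adj, formulation,
                   reference = seq_len(n_trial), quiet = TRUE)
  ci$ci_std <- standardize(ci$ci_raw)
  ci[, c("index", "ci_raw", "ci_std", "n_neighbors")]
}
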