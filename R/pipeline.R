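## End-to-end pipeline: configuration, file contracts, validation, and the
## simulate -> crowns -> compete -> fit -> evaluate orchestration.

#' Default pipeline configuration
#'
#' A nested list mirroring the trial constants (25 replicates x 3
#' incomplete blocks of 6 x 6 trees at 3.2 m; 0.25 m CHM; 8.273 m area
#' radius; 50 m buffer) with every random stage tied to an explicit seed.
#' Stored on disk as JSON; [read_config()] rejects unknown keys so typos
#' fail loudly.
#'
#' @param seed master seed; stage seeds derive from it.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    design = list(n_replicates = 25L, iblocks_per_replicate = 3L,
                  block_rows = 6L, block_cols = 6L, spacing = 3.2,
                  n_families = 96L, n_controls = 6L,
                  buffer_width = 50, buffer_density = 786),
    simulation = list(mu = 9, control_effect = 0.5, sigma2_A = 1,
                      sigma2_rep = 0.2, sigma2_iblock = 0.1,
                      sigma2_xi = 1, sigma2_eta = 1,
                      rho_row = 0.6, rho_col = 0.6, beta_comp = -0.3,
                      baseline_cv = 0.2, mortality = 0.1,
                      family_type = "half_sib"),
    chm = list(resolution = 0.25, noise_sd = 0.03, pit_rate = 0.001,
               kernel = 3L, sigma = 1.5, crown_min_h = 1.0,
               crown_frac = 0.3, match_dist = 1.6),
    competition = list(radius = "auto", k_neighbors = 20L,
                       connectivity = 4L),
    models = list(traits = c("H", "DBH", "V", "D38", "A"),
                  families = c("B", "BA", "BC", "BAC"),
                  competition = "fixed", n_starts = 3L,
                  specs = "all"),
    evaluation = list(bic_convention = "printed"))
}

#' Read / write a pipeline configuration
#'
#' JSON round trip of the configuration. Reading validates against
#' [default_config()]: unknown keys are rejected and missing keys filled
#' with defaults.
#'
#' @param path JSON file. @param config configuration list.
#' @return `read_config()`: the validated list; `write_config()`: `path`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- default_config()
  check <- function(x, r, where) {
    unknown <- setdiff(names(x), names(r))
    if (length(unknown))
      stop("unknown config key(s) at ", where, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    for (k in names(r)) {
      if (is.list(r[[k]]) && !is.null(x[[k]]))
        x[[k]] <- check(x[[k]], r[[k]], paste0(where, "$", k))
      else if (is.null(x[[k]])) x[[k]] <- r[[k]]
    }
    x
  }
  check(cfg, ref, "config")
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write the standard file contracts
#'
#' Tree table CSV (`tree_id, family, control, rep, iblock, row, col, x, y,
#' alive, H, DBH, V, D38, A`), pedigree CSV (`id, sire, dam`; 0 = unknown),
#' and the truth JSON (simulation parameters plus per-tree true effects for
#' recovery tests).
#'
#' @param trees phenotype/tree table. @param pedigree pedigree.
#' @param sim `sim_params`. @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_table <- function(trees, path) {
  cols <- intersect(c("tree_id", "family", "control", "rep", "iblock",
                      "row", "col", "x", "y", "alive",
                      "H", "DBH", "V", "D38", "A"), names(trees))
  utils::write.csv(as.data.frame(trees)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tree_table
#' @export
write_pedigree <- function(pedigree, path) {
  ped <- as.data.frame(pedigree)[, c("id", "sire", "dam")]
  ped$sire[is.na(ped$sire)] <- 0L
  ped$dam[is.na(ped$dam)] <- 0L
  utils::write.csv(ped, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tree_table
#' @export
write_truth_json <- function(trees, sim, path) {
  truth <- list(params = unclass(sim),
                trees = as.data.frame(trees)[, intersect(
                  c("tree_id", "true_a", "true_site", "true_eta",
                    "true_comp", "ci_true", "baseline"), names(trees))])
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Validate pipeline input files
#'
#' Checks column schemas of the tree and pedigree CSVs, pedigree
#' topological ordering, duplicate grid cells, and (optionally) CHM nodata
#' handling, returning pass/fail with per-problem messages.
#'
#' @param tree_csv,pedigree_csv,chm_asc file paths (`NULL` to skip a check).
#' @return list `ok` (logical) and `messages` (character).
#' @export
validate_inputs <- function(tree_csv = NULL, pedigree_csv = NULL,
                            chm_asc = NULL) {
  msgs <- character(0)
  if (!is.null(tree_csv)) {
    if (!file.exists(tree_csv)) stop("unreadable file: ", tree_csv,
                                     call. = FALSE)
    tr <- utils::read.csv(tree_csv)
    need <- c("tree_id", "family", "rep", "iblock", "row", "col", "x", "y")
    miss <- setdiff(need, names(tr))
    if (length(miss))
      msgs <- c(msgs, paste0("tree table missing column(s): ",
                             paste(miss, collapse = ", ")))
    if (all(c("row", "col") %in% names(tr)) &&
        anyDuplicated(tr[, c("row", "col")])) {
      d <- which(duplicated(tr[, c("row", "col")]))[1]
      msgs <- c(msgs, paste0("duplicate grid cell at tree table line ",
                             d + 1L, " (row ", tr$row[d], ", col ",
                             tr$col[d], ")"))
    }
  }
  if (!is.null(pedigree_csv)) {
    if (!file.exists(pedigree_csv)) stop("unreadable file: ", pedigree_csv,
                                         call. = FALSE)
    ped <- utils::read.csv(pedigree_csv)
    miss <- setdiff(c("id", "sire", "dam"), names(ped))
    if (length(miss))
      msgs <- c(msgs, paste0("pedigree missing column(s): ",
                             paste(miss, collapse = ", ")))
    else {
      pos <- seq_len(nrow(ped))
      for (pcol in c("sire", "dam")) {
        par <- match(ped[[pcol]], ped$id)
        bad <- which(!is.na(par) & par >= pos)
        if (length(bad))
          msgs <- c(msgs, paste0("pedigree ordering failure: id ",
                                 ped$id[bad[1]], " (line ", bad[1] + 1L,
                                 ") appears before its ", pcol))
      }
    }
  }
  if (!is.null(chm_asc)) {
    chm <- tryCatch(read_ascii_grid(chm_asc), error = function(e) e)
    if (inherits(chm, "error"))
      msgs <- c(msgs, paste0("CHM: ", conditionMessage(chm)))
    else if (any(chm$values != chm$nodata & chm$values < 0))
      msgs <- c(msgs, "CHM contains negative non-nodata heights")
  }
  list(ok = length(msgs) == 0L, messages = msgs)
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> crowns -> compete -> fit (study plan) -> evaluate
#' from one configuration, writing every stage product plus a run manifest
#' (config hash, file checksums, timestamps) under `out_dir`. Deterministic
#' given the config: re-running reproduces identical checksums for every
#' deterministic stage.
#'
#' @param config list from [default_config()] / [read_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest list, invisibly; stage products on disk.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }
  paths <- list()
  seed <- config$seed

  ## -- simulate ----------------------------------------------------------
  stage("simulate", {
    des <- do.call(trial_design_params, config$design)
    lay <- generate_layout(des)
    trees <- assign_families(lay, des, seed = child_seed(seed, 1L))
    simc <- config$simulation
    sim <- sim_params(mu = simc$mu, control_effect = simc$control_effect,
                      sigma2_A = simc$sigma2_A, sigma2_rep = simc$sigma2_rep,
                      sigma2_iblock = simc$sigma2_iblock,
                      sigma2_xi = simc$sigma2_xi,
                      sigma2_eta = simc$sigma2_eta,
                      rho_row = simc$rho_row, rho_col = simc$rho_col,
                      beta_comp = simc$beta_comp,
                      baseline_cv = simc$baseline_cv,
                      mortality = simc$mortality, seed = child_seed(seed, 2L))
    trees <- apply_mortality(trees, sim$mortality, child_seed(seed, 3L))
    ped <- pedigree_for_trees(trees, simc$family_type)
    buffer <- simulate_buffer(trees, child_seed(seed, 4L), h_mu = simc$mu)
    trees <- simulate_phenotypes(trees, ped, sim, buffer)
    chm <- simulate_chm(trees, buffer, resolution = config$chm$resolution,
                        noise_sd = config$chm$noise_sd,
                        pit_rate = config$chm$pit_rate,
                        seed = child_seed(seed, 5L))
    paths$trees <- write_tree_table(trees, file.path(out_dir, "trees.csv"))
    paths$pedigree <- write_pedigree(ped, file.path(out_dir, "pedigree.csv"))
    paths$truth <- write_truth_json(trees, sim,
                                     file.path(out_dir, "truth.json"))
    paths$chm <- write_ascii_grid(chm, file.path(out_dir, "chm.asc"))
    trees_g <- trees; buffer_g <- buffer; chm_g <- chm; ped_g <- ped
  })
  trees <- trees_g; buffer <- buffer_g; chm <- chm_g; ped <- ped_g

  ## -- crowns ------------------------------------------------------------
  stage("crowns", {
    chm2 <- close_pits(chm, config$chm$kernel)
    seg <- segment_growing_spaces(chm2, sigma = config$chm$sigma)
    crowns <- delineate_crowns(seg, chm2, min_h = config$chm$crown_min_h,
                               frac = config$chm$crown_frac)
    met <- compute_metrics(chm2, seg, crowns)
    live <- trees[trees$alive, ]
    m <- match_trees(met[, c("apex_x", "apex_y")] |>
                       stats::setNames(c("x", "y")),
                     live[, c("x", "y")], config$chm$match_dist)
    met$tree_id <- NA_integer_
    met$tree_id[m$pairs$detected] <- live$tree_id[m$pairs$planted]
    paths$segments <- write_segment_labels(seg,
                                            file.path(out_dir, "segments.asc"))
    paths$metrics <- {
      utils::write.csv(met, file.path(out_dir, "metrics.csv"),
                       row.names = FALSE)
      file.path(out_dir, "metrics.csv")
    }
    seg_g <- seg; met_g <- met
  })
  seg <- seg_g; met <- met_g

  ## -- compete -----------------------------------------------------------
  stage("compete", {
    specs <- if (identical(config$models$specs, "all")) enumerate_specs()
             else enumerate_specs()[match(config$models$specs,
                                          enumerate_specs()$label), ]
    sp <- config$design$spacing
    radius <- if (identical(config$competition$radius, "auto"))
      radius_for_mean_count(sp, config$competition$k_neighbors)
    else as.numeric(config$competition$radius)
    matched <- met[!is.na(met$tree_id), ]
    ord <- order(match(matched$tree_id, trees$tree_id))
    matched <- matched[ord, ]
    unmatched <- met[is.na(met$tree_id), ]   # buffer / spurious segments
    allmet <- rbind(matched, unmatched)
    n_trial <- nrow(matched)
    pos <- data.frame(x = allmet$apex_x, y = allmet$apex_y)
    ci_all <- lapply(seq_len(nrow(specs)), function(i) {
      ct <- competition_table(allmet, specs$metric[i], specs$formulation[i],
                              pos, n_trial,
                              neighborhood = specs$neighborhood[i],
                              radius = radius, segments = seg,
                              labels_by_tree = allmet$label)
      data.frame(tree_id = matched$tree_id, label = specs$label[i],
                 ci_raw = ct$ci_raw, ci_std = ct$ci_std,
                 n_neighbors = ct$n_neighbors)
    })
    ci_tab <- do.call(rbind, ci_all)
    paths$ci <- {
      utils::write.csv(ci_tab, file.path(out_dir, "ci.csv"),
                       row.names = FALSE)
      file.path(out_dir, "ci.csv")
    }
    ci_g <- ci_tab; specs_g <- specs
  })
  ci_tab <- ci_g; specs <- specs_g

  ## -- fit ---------------------------------------------------------------
  stage("fit", {
    plan <- build_study_plan(config$models$traits,
                             if (any(c("BC", "BAC") %in%
                                     config$models$families)) specs,
                             paired = FALSE)
    plan <- plan[plan$family %in% config$models$families, , drop = FALSE]
    utils::write.csv(plan, file.path(out_dir, "study_plan.csv"),
                     row.names = FALSE)
    A <- additive_matrix(ped)
    fits <- vector("list", nrow(plan))
    for (i in seq_len(nrow(plan))) {
      dat <- as.data.frame(trees)
      sp_i <- model_spec(plan$family[i], plan$trait[i],
                         ci_column = "ci_std", ci_label = plan$ci_label[i],
                         competition = config$models$competition)
      if (!is.na(plan$ci_label[i])) {
        sub <- ci_tab[ci_tab$label == plan$ci_label[i], ]
        dat$ci_std <- sub$ci_std[match(dat$tree_id, sub$tree_id)]
      }
      fits[[i]] <- fit_ace(dat, sp_i, A = A,
                           options = fit_options(
                             n_starts = config$models$n_starts))
    }
    names(fits) <- paste(plan$trait, plan$family, plan$ci_label, sep = "|")
    fit_rows <- lapply(fits, function(f)
      list(family = f$spec$family, trait = f$spec$trait,
           ci_label = f$spec$ci_label, vc = as.list(f$vc),
           vc_se = as.list(f$vc_se), LL = f$LL, t = f$t, nu = f$nu,
           h2 = f$h2, h2_se = f$h2_se, converged = f$converged))
    paths$fits <- file.path(out_dir, "fits.json")
    jsonlite::write_json(fit_rows, paths$fits, auto_unbox = TRUE,
                         digits = NA)
    fits_g <- fits
  })
  fits <- fits_g

  ## -- evaluate ----------------------------------------------------------
  stage("evaluate", {
    cors <- do.call(rbind, lapply(split(ci_tab, ci_tab$label), function(s) {
      do.call(rbind, lapply(config$models$traits, function(tr) {
        tv <- trees[[tr]][match(s$tree_id, trees$tree_id)]
        r <- tryCatch(correlate_ci(s$ci_std, tv), error = function(e) NA_real_)
        data.frame(trait = tr, ci_label = s$label[1], r = r)
      }))
    }))
    rep_out <- rank_and_report(fits, cors)
    utils::write.csv(rep_out$ranking,
                     file.path(out_dir, "table3_analogue.csv"),
                     row.names = FALSE)
    if (!is.null(rep_out$best_specs))
      utils::write.csv(rep_out$best_specs,
                       file.path(out_dir, "table4_analogue.csv"),
                       row.names = FALSE)
    paths$ranking <- file.path(out_dir, "table3_analogue.csv")
  })

  files <- unlist(paths)
  manifest <- list(
    config = config,
    config_hash = unname(tools::md5sum(
      write_config(config, file.path(out_dir, "config.json")))),
    version = as.character(utils::packageVersion("aceforest")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
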