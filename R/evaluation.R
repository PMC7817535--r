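## Model comparison and reporting: likelihood-ratio D, AIC/BIC, improvement
## percentages, competition-metric ranking, and the factorial study plan.

#' Likelihood-ratio test between two REML fits
#'
#' `D = 2 (LL_M - LL_B)`. Because the extra parameters are variances tested
#' on the boundary of their space, the p-value uses the chi-square mixture
#' `p = 0.5 P(chisq_q >= D) + 0.5 P(chisq_{q-1} >= D)` with `chisq_0` a
#' point mass at zero. `q` defaults to the number of variance/correlation
#' parameters present in the test model and absent from the base model
#' (residual `e` and nugget `eta` are treated as the same parameter), so a
#' BA-vs-B comparison uses q = 3 (`xi`, `rho_row`, `rho_col`). A negative D
#' is reported with a warning (optimizer artifact: the larger model can
#' always emulate the smaller at boundary values).
#'
#' @param fit_M,fit_B converged `ace_fit`s of the test and base model.
#' @param q degrees of freedom of the mixture; `NULL` = derive from the
#'   variance parameter names as above.
#' @return named numeric `c(D, p, q)`.
#' @export
likelihood_ratio <- function(fit_M, fit_B, q = NULL) {
  if (!fit_M$converged || !fit_B$converged)
    stop("both fits must have converged", call. = FALSE)
  same_fixed <- identical(sort(fit_M$fixed$term), sort(fit_B$fixed$term))
  if (!same_fixed)
    warning("fixed effects differ between the models; REML log-likelihoods ",
            "are only heuristically comparable", call. = FALSE)
  alias <- function(nm) ifelse(nm == "eta", "e", nm)
  new_par <- setdiff(alias(names(fit_M$vc)), alias(names(fit_B$vc)))
  if (is.null(q)) q <- max(length(new_par), 1L)
  D <- 2 * (fit_M$LL - fit_B$LL)
  if (D < 0)
    warning("negative likelihood-ratio statistic (D = ",
            formatC(D, digits = 4), "): optimizer artifact", call. = FALSE)
  upper <- function(df, x) if (df <= 0) as.numeric(x <= 0)
                           else stats::pchisq(x, df, lower.tail = FALSE)
  p <- if (D <= 0) 1 else 0.5 * upper(q, D) + 0.5 * upper(q - 1, D)
  c(D = D, p = p, q = q)
}

#' Information criteria of a fit
#'
#' `AIC = -2LL + 2t`; BIC as printed in the source field convention
#' `-2LL + 2 t log(nu)` (`bic_convention = "printed"`, the default) or the
#' conventional `-2LL + t log(nu)` (`"standard"`), with `t` the number of
#' variance parameters and `nu = n - p` the residual degrees of freedom
#' (natural log).
#'
#' @param fit converged `ace_fit`.
#' @param bic_convention `"printed"` or `"standard"`.
#' @return named numeric `c(AIC, BIC, t, nu)`.
#' @export
information_criteria <- function(fit,
                                 bic_convention = c("printed", "standard")) {
  bic_convention <- match.arg(bic_convention)
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  if (fit$nu <= 0) stop("non-positive residual degrees of freedom",
                        call. = FALSE)
  aic <- -2 * fit$LL + 2 * fit$t
  bic <- -2 * fit$LL +
    (if (bic_convention == "printed") 2 else 1) * fit$t * log(fit$nu)
  c(AIC = aic, BIC = bic, t = fit$t, nu = fit$nu)
}

#' Improvement of a spatial model over the base model
#'
#' Percentage change in narrow-sense heritability and in residual variance:
#' `100 (h2_M - h2_B) / h2_B` and `100 (eps_M - eps_B) / eps_B`, where the
#' residual `eps` is the iid residual for B/BC and the units component for
#' AR1 models. Accepts either fitted objects or bare numbers.
#'
#' @param fit_M,fit_B `ace_fit`s, or numeric `c(h2, eps)` pairs.
#' @return named numeric `c(dh2_pct, deps_pct)`.
#' @export
improvement <- function(fit_M, fit_B) {
  extract <- function(f) {
    if (inherits(f, "ace_fit"))
      c(f$h2, f$vc[[if (f$spec$spatial) "eta" else "e"]])
    else as.numeric(f)
  }
  m <- extract(fit_M); b <- extract(fit_B)
  if (!is.finite(b[1]) || b[1] == 0)
    stop("base heritability is zero or undefined", call. = FALSE)
  if (length(m) > 1 && length(b) > 1) {
    if (!is.finite(b[2]) || b[2] == 0)
      stop("base residual variance is zero or undefined", call. = FALSE)
    c(dh2_pct = 100 * (m[1] - b[1]) / b[1],
      deps_pct = 100 * (m[2] - b[2]) / b[2])
  } else {
    c(dh2_pct = 100 * (m[1] - b[1]) / b[1], deps_pct = NA_real_)
  }
}

#' Pearson correlation between competition indices and traits
#'
#' Pairwise-complete Pearson r per (competition configuration, trait) pair;
#' the sign convention is kept (higher competition with smaller size traits
#' is expected to give negative r).
#'
#' @param ci numeric competition index per tree.
#' @param trait numeric trait per tree (same order).
#' @return Pearson correlation coefficient.
#' @export
correlate_ci <- function(ci, trait) {
  ok <- is.finite(ci) & is.finite(trait)
  if (sum(ok) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(ci[ok]) == 0 || stats::sd(trait[ok]) == 0)
    stop("zero variance in one of the columns", call. = FALSE)
  stats::cor(ci[ok], trait[ok])
}

#' Build the factorial study plan
#'
#' B and BA once per trait, plus the competition models once per trait per
#' configuration. Two counting conventions exist: the field accounting
#' treats each (trait, configuration) combination as one *run* in which the
#' nested BC and BAC pair is fitted together, giving
#' `2 |traits| + |traits| |specs|` runs — 280 for five traits and 54
#' configurations. `paired = FALSE` expands the pair into separate BC and
#' BAC rows (so one trait with one configuration lists the four fits B,
#' BA, BC, BAC), which is the form the pipeline executes.
#'
#' @param traits character vector of trait names.
#' @param specs data frame of competition configurations (needs a `label`
#'   column, e.g. from [enumerate_specs()]), or `NULL` for none.
#' @param paired count BC+BAC per configuration as one run (default) or as
#'   two separate rows.
#' @return data frame `trait`, `family`, `ci_label` (`NA` for B/BA) of
#'   class `study_plan`.
#' @export
build_study_plan <- function(traits, specs = NULL, paired = TRUE) {
  if (!length(traits)) stop("`traits` must be non-empty", call. = FALSE)
  labels <- unique(if (is.null(specs)) character(0) else specs$label)
  comp_fams <- if (paired) "BC+BAC" else c("BC", "BAC")
  plan <- rbind(
    expand.grid(trait = traits, family = c("B", "BA"),
                ci_label = NA_character_,
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE),
    if (length(labels))
      expand.grid(trait = traits, family = comp_fams,
                  ci_label = labels,
                  stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
  plan <- unique(plan)
  plan <- plan[order(plan$trait, plan$family, plan$ci_label,
                     na.last = FALSE), ]
  rownames(plan) <- NULL
  class(plan) <- c("study_plan", "data.frame")
  plan
}

#' Rank fitted models and build the report tables
#'
#' Produces the two report tables of a full evaluation: per trait, all
#' model runs ranked by descending log-likelihood with D, p, h2 +/- SE, and
#' the percentage improvements over the base model (zero for the base row
#' itself); and, per trait, the best competition-bearing model with its
#' crown metric, formulation, neighbourhood, and (optionally) the Pearson
#' correlation between its index and the trait.
#'
#' @param fits named list of converged `ace_fit`s; non-converged entries
#'   are dropped with a warning.
#' @param correlations optional data frame `trait`, `ci_label`, `r`.
#' @return list `ranking` (Table-3-style data frame) and `best_specs`
#'   (Table-4-style data frame).
#' @export
rank_and_report <- function(fits, correlations = NULL) {
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (any(!conv))
    warning(sum(!conv), " non-converged fit(s) omitted from the report",
            call. = FALSE)
  fits <- fits[conv]
  if (!length(fits)) stop("no converged fits to report", call. = FALSE)
  rows <- lapply(fits, function(f)
    data.frame(trait = f$spec$trait, family = f$spec$family,
               ci_label = f$spec$ci_label %||% NA_character_,
               LL = f$LL, h2 = f$h2, h2_se = f$h2_se,
               eps = f$vc[[if (f$spec$spatial) "eta" else "e"]],
               stringsAsFactors = FALSE))
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- list()
  for (tr in unique(tab$trait)) {
    sub <- tab[tab$trait == tr, , drop = FALSE]
    base_i <- which(sub$family == "B")
    sub$D <- sub$p <- NA_real_
    sub$dh2_pct <- sub$deps_pct <- NA_real_
    if (length(base_i) == 1L) {
      base_fit <- fits[[which(vapply(fits, function(f)
        f$spec$trait == tr && f$spec$family == "B", logical(1)))[1]]]
      for (i in seq_len(nrow(sub))) {
        if (i == base_i) { sub$dh2_pct[i] <- 0; sub$deps_pct[i] <- 0; next }
        fi <- which(vapply(fits, function(f)
          f$spec$trait == tr && f$spec$family == sub$family[i] &&
            identical(f$spec$ci_label %||% NA_character_, sub$ci_label[i]),
          logical(1)))[1]
        lr <- suppressWarnings(likelihood_ratio(fits[[fi]], base_fit))
        sub$D[i] <- lr["D"]; sub$p[i] <- lr["p"]
        imp <- improvement(fits[[fi]], base_fit)
        sub$dh2_pct[i] <- imp["dh2_pct"]; sub$deps_pct[i] <- imp["deps_pct"]
      }
    }
    sub <- sub[order(-sub$LL), , drop = FALSE]
    sub$rank <- seq_len(nrow(sub))
    out[[tr]] <- sub
  }
  ranking <- do.call(rbind, c(out, list(make.row.names = FALSE)))

  comp <- ranking[ranking$family %in% c("BC", "BAC"), , drop = FALSE]
  best <- NULL
  if (nrow(comp)) {
    best <- do.call(rbind, lapply(split(comp, comp$trait), function(s)
      s[which.max(s$LL), , drop = FALSE]))
    rownames(best) <- NULL
    parts <- strsplit(best$ci_label, ":", fixed = TRUE)
    ok3 <- lengths(parts) == 3L
    best$metric <- ifelse(ok3, vapply(parts, `[`, "", 1L), NA)
    best$formulation <- ifelse(ok3, vapply(parts, `[`, "", 2L), NA)
    best$neighborhood <- ifelse(ok3, vapply(parts, `[`, "", 3L), NA)
    if (!is.null(correlations))
      best$r <- correlations$r[match(paste(best$trait, best$ci_label),
                                     paste(correlations$trait,
                                           correlations$ci_label))]
  }
  list(ranking = ranking, best_specs = best)
}
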