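# Model comparison statistics and report assembly.

fake_fit <- function(family, trait, LL, h2 = 0.3, eps = 1, h2_se = 0.05,
                     ci_label = NULL, t = if (family %in% c("BA", "BAC")) 5 else 4,
                     nu = 100) {
  spatial <- family %in% c("BA", "BAC")
  vc_names <- if (spatial) c("A", "xi", "rho_row", "rho_col", "eta")
              else c("A", "rep", "ib", "e")
  vc <- stats::setNames(rep(0.5, length(vc_names)), vc_names)
  vc[[if (spatial) "eta" else "e"]] <- eps
  fixed_terms <- c("(Intercept)", "control",
                   if (!is.null(ci_label)) "competition")
  structure(list(vc = vc, vc_se = vc * 0.1,
                 vc_cov = diag(length(vc)) * 0.01,
                 fixed = data.frame(term = fixed_terms,
                                    estimate = 0, se = 1),
                 LL = LL, neg2ll = -2 * LL, t = t, nu = nu, n = nu + 2,
                 h2 = h2, h2_se = h2_se, converged = TRUE,
                 spec = list(family = family, trait = trait,
                             ci_label = ci_label,
                             spatial = spatial)),
            class = "ace_fit")
}

test_that("likelihood ratio D, boundary mixture p, and q derivation", {
  fb <- fake_fit("B", "H", LL = -1800)
  fm <- fake_fit("BA", "H", LL = -1291)
  lr <- likelihood_ratio(fm, fb)
  expect_equal(unname(lr["D"]), 1018)               # 2 * (−1291 − (−1800))
  expect_equal(unname(lr["q"]), 3)                  # xi, rho_row, rho_col
  # equal likelihoods: D = 0, p = 1
  lr0 <- likelihood_ratio(fake_fit("BA", "H", -100), fake_fit("B", "H", -100))
  expect_equal(unname(lr0["D"]), 0)
  expect_equal(unname(lr0["p"]), 1)
  # one boundary parameter at the chi-square critical value
  lr1 <- likelihood_ratio(fake_fit("BA", "H", -98.0795),
                          fake_fit("B", "H", -100), q = 1)
  expect_equal(unname(lr1["p"]),
               0.5 * pchisq(2 * (100 - 98.0795), 1, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(unname(likelihood_ratio(fake_fit("BA", "H", -98.0795),
                                       fake_fit("B", "H", -100),
                                       q = 1)["p"]), 0.025, tolerance = 1e-3)
  # negative D warns
  expect_warning(likelihood_ratio(fake_fit("BA", "H", -101),
                                  fake_fit("B", "H", -100)), "negative")
})

test_that("information criteria implement both BIC conventions", {
  f <- fake_fit("B", "H", LL = -10, t = 2)
  expect_equal(unname(information_criteria(f)["AIC"]), 24)
  f2 <- fake_fit("B", "H", LL = -100, t = 3, nu = 50)
  expect_equal(unname(information_criteria(f2)["BIC"]),
               200 + 6 * log(50), tolerance = 1e-10)
  expect_equal(unname(information_criteria(f2, "standard")["BIC"]),
               200 + 3 * log(50), tolerance = 1e-10)
  # AIC ordering is invariant to a common LL shift
  g1 <- fake_fit("B", "H", -100, t = 3); g2 <- fake_fit("BA", "H", -90, t = 5)
  d0 <- information_criteria(g1)["AIC"] - information_criteria(g2)["AIC"]
  g1$LL <- g1$LL + 7; g2$LL <- g2$LL + 7
  d1 <- information_criteria(g1)["AIC"] - information_criteria(g2)["AIC"]
  expect_equal(unname(d0), unname(d1))
})

test_that("improvement percentages reproduce hand arithmetic", {
  expect_equal(unname(improvement(0.4862, 0.4261)["dh2_pct"]),
               14.10, tolerance = 5e-3)
  same <- improvement(fake_fit("BA", "H", -10, h2 = 0.3, eps = 1),
                      fake_fit("B", "H", -12, h2 = 0.3, eps = 1))
  expect_equal(unname(same), c(0, 0))
  halved <- improvement(fake_fit("BA", "H", -10, h2 = 0.3, eps = 0.5),
                        fake_fit("B", "H", -12, h2 = 0.3, eps = 1))
  expect_equal(unname(halved["deps_pct"]), -50)
  expect_error(improvement(fake_fit("BA", "H", -1, h2 = 0.2),
                           fake_fit("B", "H", -1, h2 = 0)), "zero")
})

test_that("correlation helper matches the textbook formula", {
  x <- c(1, 2, 4, 5, 7, 8, 9, 11, 12, 15)
  y <- c(2.2, 2.9, 4.8, 5.1, 7.5, 7.9, 9.4, 11.2, 11.9, 15.5)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate_ci(x, y), hand)
  expect_equal(correlate_ci(1:5, 2 * (1:5) + 3), 1)
  expect_equal(correlate_ci(1:5, -2 * (1:5)), -1)
  expect_error(correlate_ci(1:5, rep(2, 5)), "zero variance")
  expect_error(correlate_ci(1:2, 1:2), "3 complete")
})

test_that("study plan counts follow both run-accounting conventions", {
  # paired accounting (BC+BAC fitted per trait x configuration as one run):
  # 2*5 + 5*54 = 280 runs for the full factorial
  expect_equal(nrow(build_study_plan(c("H", "DBH", "V", "D38", "A"),
                                     enumerate_specs())), 280)
  # expanded accounting lists every fit separately
  expect_equal(nrow(build_study_plan("H", enumerate_specs()[1, ],
                                     paired = FALSE)), 4)  # B BA BC BAC
  expect_equal(nrow(build_study_plan("H")), 2)             # B BA
  plan <- build_study_plan(c("H", "DBH"), enumerate_specs()[1:3, ],
                           paired = FALSE)
  expect_equal(sum(plan$family == "B"), 2)          # once per trait
  expect_equal(sum(plan$family == "BAC"), 6)        # per trait per spec
  expect_error(build_study_plan(character(0)), "non-empty")
})

test_that("ranking report orders by LL and zeroes the base row", {
  fits <- list(
    fake_fit("B", "H", -1800, h2 = 0.2969, eps = 1.0),
    fake_fit("BA", "H", -1758, h2 = 0.3425, eps = 0.75),
    fake_fit("BC", "H", -1381, h2 = 0.3011, eps = 0.67, ci_label = "CV_F:CIA:NB"),
    fake_fit("BAC", "H", -1291, h2 = 0.4117, eps = 0.35, ci_label = "CV_F:CIA:NB"))
  rep_out <- rank_and_report(fits)
  r <- rep_out$ranking
  expect_equal(r$family, c("BAC", "BC", "BA", "B"))  # descending LL
  expect_equal(r$rank, 1:4)
  expect_equal(r$dh2_pct[r$family == "B"], 0)
  expect_equal(r$deps_pct[r$family == "B"], 0)
  expect_equal(r$dh2_pct[r$family == "BAC"],
               100 * (0.4117 - 0.2969) / 0.2969)
  best <- rep_out$best_specs
  expect_equal(best$family, "BAC")
  expect_equal(best$metric, "CV_F")
  expect_equal(best$formulation, "CIA")
  expect_equal(best$neighborhood, "NB")
  # correlations are joined onto the best-spec table
  cors <- data.frame(trait = "H", ci_label = "CV_F:CIA:NB", r = -0.54)
  expect_equal(rank_and_report(fits, cors)$best_specs$r, -0.54)
})
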