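# Independent oracles used across the suite. These deliberately take the
# slow, literal route (explicit projection matrices, double loops, full
# enumeration) so they share no code with the package implementations.

# REML -2LL via the explicit dense projection matrix P.
naive_neg2ll <- function(y, X, V) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(determinant(V)$modulus + determinant(XtViX)$modulus +
               t(y) %*% P %*% y + (n - p) * log(2 * pi))
}

# Competition indices by a double loop over all pairs.
naive_ci_area <- function(cvals, pos, radius, formulation) {
  n <- nrow(pos)
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      L <- sqrt((pos[i, 1] - pos[j, 1])^2 + (pos[i, 2] - pos[j, 2])^2)
      if (L > radius) next
      r <- cvals[j] / cvals[i]
      out[i] <- out[i] + switch(formulation,
                                CIA = r / L, CIB = r / L^2, CIC = r^2 / L)
    }
  }
  out
}

# Boundary adjacency by scanning every 4-adjacent cell pair.
naive_boundary_adjacency <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  labs <- sort(unique(as.integer(labels)))
  adj <- stats::setNames(lapply(labs, function(l) integer(0)),
                         as.character(labs))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (d in list(c(1, 0), c(0, 1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 > nr || c2 > nc) next
      a <- labels[r, c]; b <- labels[r2, c2]
      if (a != b) {
        adj[[as.character(a)]] <- union(adj[[as.character(a)]], b)
        adj[[as.character(b)]] <- union(adj[[as.character(b)]], a)
      }
    }
  }
  lapply(adj, sort)
}

# Optimal assignment by full enumeration of permutations (n <= 6).
brute_force_assignment <- function(detected, planted, max_dist) {
  nd <- nrow(detected); np <- nrow(planted)
  stopifnot(nd <= 6, np <= 6)
  d2 <- outer(detected$x, planted$x, "-")^2 +
        outer(detected$y, planted$y, "-")^2
  BIG <- (max(d2) + 1) * (nd + np)
  cost <- ifelse(d2 > max_dist^2, BIG, d2)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  k <- min(nd, np)
  best <- NULL; best_cost <- Inf
  for (rows in utils::combn(nd, k, simplify = FALSE))
    for (p in perms(seq_len(np))) {
      cols <- p[seq_len(k)]
      tot <- sum(cost[cbind(rows, cols)])
      if (tot < best_cost) { best_cost <- tot; best <- cbind(rows, cols) }
    }
  keep <- d2[best] <= max_dist^2
  best[keep, , drop = FALSE]
}

# Additive relationship between two ids estimated by gene dropping.
gene_drop_relationship <- function(ped, id1, id2, n_drops = 20000) {
  n <- nrow(ped)
  s <- match(ped$sire, ped$id); d <- match(ped$dam, ped$id)
  i1 <- match(id1, ped$id); i2 <- match(id2, ped$id)
  next_allele <- 0L
  same <- 0
  for (rep in seq_len(n_drops)) {
    al <- matrix(0L, n, 2)
    next_allele <- 0L
    for (i in seq_len(n)) {
      for (k in 1:2) {
        par <- if (k == 1) s[i] else d[i]
        if (is.na(par)) {
          next_allele <- next_allele + 1L
          al[i, k] <- next_allele
        } else {
          al[i, k] <- al[par, sample(2, 1)]
        }
      }
    }
    # 2 * coancestry: prob. a random allele from each is IBD, x2
    same <- same + mean(outer(al[i1, ], al[i2, ], "=="))
  }
  2 * same / n_drops
}

# A compact simulated trial used by several test files.
make_trial <- function(n_replicates = 2, seed = 1, mortality = 0.1,
                       sigma2_rep = 0, sigma2_iblock = 0,
                       sigma2_xi = 1, rho = 0.6, beta_comp = -0.3,
                       sigma2_A = 1, sigma2_eta = 1, buffer_width = 0) {
  d <- trial_design_params(n_replicates = n_replicates,
                           buffer_width = buffer_width)
  lay <- generate_layout(d)
  trees <- assign_families(lay, d, seed = seed)
  trees <- apply_mortality(trees, mortality, seed = seed + 1)
  ped <- pedigree_for_trees(trees)
  sim <- sim_params(sigma2_A = sigma2_A, sigma2_rep = sigma2_rep,
                    sigma2_iblock = sigma2_iblock, sigma2_xi = sigma2_xi,
                    sigma2_eta = sigma2_eta, rho_row = rho, rho_col = rho,
                    beta_comp = beta_comp, mortality = mortality,
                    seed = seed + 2)
  pheno <- simulate_phenotypes(trees, ped, sim)
  list(design = d, trees = pheno, pedigree = ped, sim = sim)
}
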