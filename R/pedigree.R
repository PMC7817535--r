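## Pedigrees and the additive (numerator) relationship matrix.

#' Simulate a family pedigree
#'
#' Builds the pedigree for `n_families` families with `n_offspring` offspring
#' each. For open-pollinated half-sib families each family has one known
#' sire and unknown dams; for control-crossed full-sib families each family
#' has a known sire and a known dam. Founders precede offspring, so the
#' result is topologically ordered. Unknown parents are coded `0`.
#'
#' @param n_families number of families.
#' @param n_offspring offspring per family.
#' @param family_type `"half_sib"` (default) or `"full_sib"`.
#' @return a `pedigree` data frame with columns `id`, `sire`, `dam`, and for
#'   offspring rows a `family` column (`NA` for founders).
#' @export
simulate_pedigree <- function(n_families, n_offspring,
                              family_type = c("half_sib", "full_sib")) {
  stopifnot_scalar_count(n_families, "n_families")
  stopifnot_scalar_count(n_offspring, "n_offspring")
  family_type <- match.arg(family_type)
  n_founders <- if (family_type == "half_sib") n_families else 2L * n_families
  founders <- data.frame(id = seq_len(n_founders), sire = 0L, dam = 0L,
                         family = NA_integer_)
  fam <- rep(seq_len(n_families), each = n_offspring)
  off_id <- n_founders + seq_along(fam)
  if (family_type == "half_sib") {
    sire <- fam; dam <- rep(0L, length(fam))
  } else {
    sire <- 2L * fam - 1L; dam <- 2L * fam
  }
  ped <- rbind(founders,
               data.frame(id = off_id, sire = sire, dam = dam, family = fam))
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Pedigree for an existing tree table
#'
#' As [simulate_pedigree()], but offspring ids are the `tree_id`s of `trees`
#' and each tree is attached to its assigned family. Founder ids are placed
#' below the smallest tree id (negative if necessary) so tree ids are
#' preserved verbatim.
#'
#' @param trees a `tree_table` from [assign_families()].
#' @param family_type `"half_sib"` or `"full_sib"`.
#' @return a `pedigree` data frame (founders first).
#' @export
pedigree_for_trees <- function(trees, family_type = c("half_sib", "full_sib")) {
  family_type <- match.arg(family_type)
  fams <- sort(unique(trees$family))
  n_fam <- length(fams)
  n_founders <- if (family_type == "half_sib") n_fam else 2L * n_fam
  # founders get negative ids: never 0 (the unknown code) and never a
  # collision with the positive tree ids
  founder_id <- -rev(seq_len(n_founders))
  founders <- data.frame(id = founder_id, sire = 0L, dam = 0L,
                         family = NA_integer_)
  fi <- match(trees$family, fams)
  if (family_type == "half_sib") {
    sire <- founder_id[fi]; dam <- rep(0L, nrow(trees))
  } else {
    sire <- founder_id[2L * fi - 1L]; dam <- founder_id[2L * fi]
  }
  ped <- rbind(founders,
               data.frame(id = trees$tree_id, sire = sire, dam = dam,
                          family = trees$family))
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Additive relationship matrix (tabular method)
#'
#' Computes the numerator relationship matrix A from a topologically ordered
#' pedigree by the tabular recursion: `A[i,i] = 1 + 0.5 * A[sire, dam]` and
#' `A[i,j] = 0.5 * (A[j, sire(i)] + A[j, dam(i)])`, with unknown parents
#' contributing zero. Diagonals are `1 + F` (F the inbreeding coefficient);
#' parent-offspring entries are 0.5 and half-sib entries 0.25 for non-inbred,
#' unrelated parents.
#'
#' @param pedigree data frame with columns `id`, `sire`, `dam`; `0` or `NA`
#'   marks an unknown parent; parents must appear before their offspring.
#' @return symmetric matrix with dimnames = pedigree ids.
#' @export
additive_matrix <- function(pedigree) {
  id <- pedigree$id
  if (anyDuplicated(id)) stop("duplicate ids in pedigree", call. = FALSE)
  n <- length(id)
  s <- match(pedigree$sire, id)  # NA when unknown
  d <- match(pedigree$dam, id)
  known_s <- !is.na(pedigree$sire) & pedigree$sire != 0
  known_d <- !is.na(pedigree$dam) & pedigree$dam != 0
  if (any(known_s & is.na(s)) || any(known_d & is.na(d)))
    stop("pedigree refers to parents absent from `id`", call. = FALSE)
  if (any(s[known_s] >= which(known_s)) || any(d[known_d] >= which(known_d)))
    stop("pedigree is not topologically ordered (offspring before parent); ",
         "first offending id: ",
         id[which(known_s & s >= seq_len(n) | known_d & d >= seq_len(n))[1L]],
         call. = FALSE)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    prev <- seq_len(i - 1L)
    if (i > 1L) {
      row_i <- numeric(i - 1L)
      if (!is.na(si)) row_i <- row_i + 0.5 * A[prev, si]
      if (!is.na(di)) row_i <- row_i + 0.5 * A[prev, di]
      A[prev, i] <- row_i
      A[i, prev] <- row_i
    }
    A[i, i] <- 1 + if (!is.na(si) && !is.na(di)) 0.5 * A[si, di] else 0
  }
  A
}
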