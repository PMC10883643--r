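## Solvent-accessible surface area --------------------------------------
##
## Shrake-Rupley numerical SASA: deterministic quasi-uniform sphere points
## (golden-spiral lattice) on each atom's solvent-expanded sphere; a point
## is accessible when it falls inside no neighbouring expanded sphere.
## Element-level van der Waals radii; hydrogens are excluded.

SASA_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                H = 1.20, D = 1.20)

# deterministic golden-spiral lattice on the unit sphere
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' @param model `abag_structure`; hydrogens are ignored.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sphere points per atom (default 960); more points,
#'   smoother convergence.
#' @return list: `total` (Angstrom^2), `per_residue` (data.frame chain,
#'   resno, insert, area), `per_atom` (numeric vector in atom order).
#' @export
sasa <- function(model, probe = 1.4, n_points = 960L) {
  at <- model$atoms[!model$atoms$hydrogen, , drop = FALSE]
  if (!nrow(at)) stop("no non-hydrogen atoms")
  unknown <- setdiff(unique(at$element), names(SASA_RADII))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  r <- SASA_RADII[at$element] + probe
  xyz <- cbind(at$x, at$y, at$z)
  n <- nrow(at)
  pts <- sphere_points(n_points)

  # neighbour candidates: pairs whose expanded spheres can intersect
  rmax <- max(r)
  cand <- cross_pairs_within(xyz, xyz, 2 * rmax)
  cand <- cand[cand$i != cand$j, , drop = FALSE]
  keep <- {
    d2 <- rowSums((xyz[cand$i, , drop = FALSE] -
                     xyz[cand$j, , drop = FALSE])^2)
    d2 < (r[cand$i] + r[cand$j])^2
  }
  cand <- cand[keep, , drop = FALSE]
  nb <- split(cand$j, factor(cand$i, levels = seq_len(n)))

  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb[[i]]) {
      if (!any(acc)) break
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & d2 >= r[j]^2
    }
    per_atom[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }

  key <- res_key(at$chain, at$resno, at$insert)
  first <- !duplicated(key)
  per_res <- data.frame(chain = at$chain[first], resno = at$resno[first],
                        insert = at$insert[first],
                        area = as.numeric(
                          tapply(per_atom, factor(key, levels = key[first]),
                                 sum)),
                        stringsAsFactors = FALSE)
  list(total = sum(per_atom), per_residue = per_res, per_atom = per_atom)
}

#' Buried surface area on binding
#'
#' Interface burial: SASA of the isolated antibody component plus SASA of
#' the isolated antigen component minus SASA of the complex, all in the
#' bound conformation.
#'
#' @param case `abag_case`.
#' @param probe probe radius (default 1.4 A).
#' @param n_points sphere points per atom (default 960).
#' @return buried area in Angstrom^2.
#' @export
delta_asa <- function(case, probe = 1.4, n_points = 960L) {
  cplx <- case$bound
  ab <- subset_chains(cplx, case$antibody_chains)
  ag <- subset_chains(cplx, case$antigen_chains)
  sasa(ab, probe, n_points)$total + sasa(ag, probe, n_points)$total -
    sasa(cplx, probe, n_points)$total
}
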