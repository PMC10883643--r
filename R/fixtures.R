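## Synthetic fixtures ---------------------------------------------------
##
## Toy poly-alanine antibody-antigen complexes with controlled
## conformational change. Chains are helix-like curves with N/CA/C/O/CB
## atoms; the two sides approach closely enough to form 5 A contacts and a
## 10 A interface. Unbound copies are the bound components transformed by a
## chosen perturbation plus an arbitrary rigid motion (which every metric
## must be invariant to).
##
## The "rigid_shift" perturbation displaces each interface residue of one
## side by t_i * u, where the per-residue amplitudes t lie in the null
## space of the superposition fit conditions (sum(t) = 0 and
## sum(t_i * centered CA_i) = 0) and are scaled to RMS magnitude d. Under
## these constraints the optimal interface superposition is the identity,
## so the resulting interface RMSD equals d exactly — a literal rigid shift
## of the whole component would instead be absorbed by the fit.

#' Fixture specification
#'
#' @param n_res_ab,n_res_ag residues per antibody chain / antigen chain.
#' @param antibody `"single_domain"` (one H chain) or `"mab"` (H + L).
#' @param approach closest approach between the two sides in Angstrom.
#' @param perturbation one of `"none"`, `"rigid_shift"`, `"hinge_rotation"`,
#'   `"cdr_displacement"`.
#' @param magnitude perturbation size: RMS displacement in Angstrom
#'   (rigid_shift, cdr_displacement) or rotation angle in degrees
#'   (hinge_rotation).
#' @param perturb_side `"antigen"` (default), `"antibody"` or `"both"`
#'   (`"both"` shifts each side's interface by RMS magnitude d, so the
#'   entire-interface RMSD equals d as well).
#' @param seed integer fixing all randomness.
#' @return list of class `abag_fixture_spec`.
#' @export
fixture_spec <- function(n_res_ab = 110L, n_res_ag = 60L,
                         antibody = c("single_domain", "mab"),
                         approach = 4.5,
                         perturbation = c("none", "rigid_shift",
                                          "hinge_rotation",
                                          "cdr_displacement"),
                         magnitude = 0,
                         perturb_side = c("antigen", "antibody", "both"),
                         seed = 1L) {
  antibody <- match.arg(antibody)
  perturbation <- match.arg(perturbation)
  perturb_side <- match.arg(perturb_side)
  if (magnitude < 0) stop("magnitude must be >= 0")
  structure(list(n_res_ab = n_res_ab, n_res_ag = n_res_ag,
                 antibody = antibody, approach = approach,
                 perturbation = perturbation, magnitude = magnitude,
                 perturb_side = perturb_side, seed = as.integer(seed)),
            class = "abag_fixture_spec")
}

AA20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

# deterministic varied sequence per chain id: aperiodic so that pairwise
# alignments of fixture chains are unambiguous (an all-ALA chain would
# align equally well at any offset)
fixture_sequence <- function(chain, n_res) {
  with_seed(1000L + utf8ToInt(substr(chain, 1, 1)),
            sample(AA20, n_res, replace = TRUE))
}

# helix-like C-alpha trace plus crude N/C/O/CB positions for one chain
helix_chain <- function(chain, n_res, origin = c(0, 0, 0),
                        radius = 2.3, rise = 1.5, turn_deg = 100) {
  i <- seq_len(n_res)
  seq3 <- fixture_sequence(chain, n_res)
  ang <- (i - 1) * turn_deg * pi / 180
  ca <- cbind(origin[1] + (i - 1) * rise,
              origin[2] + radius * cos(ang),
              origin[3] + radius * sin(ang))
  off <- list(N = c(-1.0, 0.8, 0.3), C = c(1.1, 0.6, -0.3),
              O = c(1.3, 1.7, -0.4), CB = c(0.1, -1.1, 1.0))
  rows <- lapply(i, function(r) {
    nm <- c("N", "CA", "C", "O", "CB")
    xyz <- rbind(ca[r, ] + off$N, ca[r, ], ca[r, ] + off$C,
                 ca[r, ] + off$O, ca[r, ] + off$CB)
    data.frame(serial = 0L, name = nm, altloc = "", resname = seq3[r],
               chain = chain, resno = r, insert = "",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               occ = 1, element = substr(nm, 1, 1),
               hydrogen = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

new_structure <- function(id, atoms, roles) {
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, roles = roles,
                 resolution = NA_real_, release_date = as.Date(NA)),
            class = "abag_structure")
}

random_rigid_motion <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  list(rotation = rotation_about_axis(ax, stats::runif(1, 0, 2 * pi)),
       translation = stats::runif(3, -20, 20))
}

# amplitudes t (length n, RMS = d) with sum(t) = 0 and t orthogonal to the
# centered coordinates: the least-squares fit of the displaced set onto the
# original is then exactly the identity
null_space_amplitudes <- function(ca, d) {
  n <- nrow(ca)
  if (n < 5)
    stop("need at least 5 interface residues for a controlled displacement")
  cc <- sweep(ca, 2, colMeans(ca))
  M <- rbind(rep(1, n), t(cc))            # 4 x n constraints
  qq <- qr(t(M))                          # null space: M %*% ns = 0
  ns <- qr.Q(qq, complete = TRUE)[, (qq$rank + 1):n, drop = FALSE]
  w <- stats::rnorm(ncol(ns))
  t0 <- as.vector(ns %*% w)
  t0 * d / sqrt(mean(t0^2))
}

# displace each interface residue of `mod` by t_i * u with the null-space
# amplitude construction (see file header); post-fit interface RMSD = d
apply_interface_shift <- function(mod, ires, d) {
  ca <- mod$atoms[mod$atoms$name == "CA", , drop = FALSE]
  ikey <- res_key(ires$chain, ires$resno, ires$insert)
  ca <- ca[res_key(ca$chain, ca$resno, ca$insert) %in% ikey, , drop = FALSE]
  amp <- null_space_amplitudes(cbind(ca$x, ca$y, ca$z), d)
  u <- c(0, 0.6, 0.8); u <- u / sqrt(sum(u^2))
  rk <- res_key(ca$chain, ca$resno, ca$insert)
  akey <- res_key(mod$atoms$chain, mod$atoms$resno, mod$atoms$insert)
  idx <- match(akey, rk)
  hit <- !is.na(idx)
  mod$atoms$x[hit] <- mod$atoms$x[hit] + amp[idx[hit]] * u[1]
  mod$atoms$y[hit] <- mod$atoms$y[hit] + amp[idx[hit]] * u[2]
  mod$atoms$z[hit] <- mod$atoms$z[hit] + amp[idx[hit]] * u[3]
  mod
}

#' Generate a toy antibody-antigen case
#'
#' Builds a bound complex and unbound copies of both components, the unbound
#' side(s) carrying the requested conformational perturbation plus an
#' arbitrary rigid motion. For `rigid_shift` the interface RMSD implied by
#' the construction equals the requested magnitude; for `cdr_displacement`
#' the CDR3 RMSD equals it. The CDR annotation (Chothia heavy-chain loops)
#' is attached to the case.
#'
#' @param spec an [fixture_spec()].
#' @param case_id case identifier.
#' @return `abag_case` with attribute `expected` recording the construction
#'   parameters.
#' @export
generate_toy_case <- function(spec = fixture_spec(), case_id = "toy") {
  stopifnot(inherits(spec, "abag_fixture_spec"))
  with_seed(spec$seed, generate_toy_case_impl(spec, case_id))
}

generate_toy_case_impl <- function(spec, case_id) {
  dy <- spec$approach + 6.9        # axis separation giving ~approach gap
  ag <- helix_chain("A", spec$n_res_ag, origin = c(0, 0, 0))
  ab_chains <- "H"
  ab <- helix_chain("H", spec$n_res_ab,
                    origin = c((spec$n_res_ag - spec$n_res_ab) * 1.5 / 2,
                               dy, 0))
  roles <- c(H = "single_domain", A = "antigen")
  if (spec$antibody == "mab") {
    ab_chains <- c("H", "L")
    lt <- helix_chain("L", spec$n_res_ab,
                      origin = c((spec$n_res_ag - spec$n_res_ab) * 1.5 / 2,
                                 dy + 3, 9))
    ab <- rbind(ab, lt)
    roles <- c(H = "heavy", L = "light", A = "antigen")
  }
  bound <- new_structure(case_id, rbind(ab, ag), roles)

  # impossible geometry guard
  a_xyz <- as.matrix(bound$atoms[bound$atoms$chain %in% ab_chains,
                                 c("x", "y", "z")])
  g_xyz <- as.matrix(bound$atoms[bound$atoms$chain == "A",
                                 c("x", "y", "z")])
  if (nrow(cross_pairs_within(a_xyz, g_xyz, 1.8)))
    stop("impossible geometry: antibody and antigen chains overlap")

  ann <- cbind(chain = "H", chothia_cdr_ranges("heavy"))
  class(ann) <- c("abag_cdr_annotation", "data.frame")

  case0 <- complex_case(bound, ab_chains, "A", case_id = case_id,
                        cdr_annotation = ann)

  unb_ab <- subset_chains(bound, ab_chains, id = paste0(case_id, "_ab_u"))
  unb_ag <- subset_chains(bound, "A", id = paste0(case_id, "_ag_u"))

  target <- if (spec$perturb_side == "antibody") "antibody" else "antigen"
  if (spec$perturbation == "rigid_shift" && spec$magnitude > 0) {
    iface <- interface_residues(case0, 10)
    sides <- if (spec$perturb_side == "both") c("antigen", "antibody")
    else target
    for (s in sides) {
      ires <- if (s == "antigen") iface$antigen else iface$antibody
      mod <- if (s == "antigen") unb_ag else unb_ab
      mod <- apply_interface_shift(mod, ires, spec$magnitude)
      if (s == "antigen") unb_ag <- mod else unb_ab <- mod
    }
  } else if (spec$perturbation == "hinge_rotation" && spec$magnitude > 0) {
    mod <- if (target == "antigen") unb_ag else unb_ab
    ch <- chain_ids(mod)[1]
    res <- chain_residues(mod, ch)
    hinge <- res$resno[ceiling(nrow(res) / 2)]
    pivot_row <- which(mod$atoms$chain == ch & mod$atoms$resno == hinge &
                         mod$atoms$name == "CA")[1]
    pivot <- as.numeric(mod$atoms[pivot_row, c("x", "y", "z")])
    R <- rotation_about_axis(c(0, 0, 1), spec$magnitude * pi / 180)
    move <- mod$atoms$chain == ch & mod$atoms$resno > hinge
    xyz <- as.matrix(mod$atoms[move, c("x", "y", "z")])
    xyz <- sweep(sweep(xyz, 2, pivot) %*% t(R), 2, pivot, "+")
    mod$atoms[move, c("x", "y", "z")] <- xyz
    if (target == "antigen") unb_ag <- mod else unb_ab <- mod
  } else if (spec$perturbation == "cdr_displacement" && spec$magnitude > 0) {
    u <- c(0, 0.6, 0.8); u <- u / sqrt(sum(u^2))
    rng <- ann[ann$cdr == "CDR3", ]
    move <- unb_ab$atoms$chain == "H" &
      unb_ab$atoms$resno >= rng$start & unb_ab$atoms$resno <= rng$end
    unb_ab$atoms$x[move] <- unb_ab$atoms$x[move] + spec$magnitude * u[1]
    unb_ab$atoms$y[move] <- unb_ab$atoms$y[move] + spec$magnitude * u[2]
    unb_ab$atoms$z[move] <- unb_ab$atoms$z[move] + spec$magnitude * u[3]
  }

  # arbitrary rigid motions: unbound structures arrive in their own frames
  m1 <- random_rigid_motion(); m2 <- random_rigid_motion()
  unb_ab <- transform_structure(unb_ab, m1$rotation, m1$translation)
  unb_ag <- transform_structure(unb_ag, m2$rotation, m2$translation)

  out <- complex_case(bound, ab_chains, "A", case_id = case_id,
                      unbound_antibody = list(unb_ab),
                      unbound_antigen = list(unb_ag),
                      cdr_annotation = ann)
  attr(out, "expected") <- list(perturbation = spec$perturbation,
                                magnitude = spec$magnitude,
                                side = spec$perturb_side)
  out
}

#' Generate a family of near-duplicate cases with a known redundancy graph
#'
#' Copies of one toy complex whose pairwise sequence identities and
#' structural divergence are controlled: copy `k` carries substitutions at
#' `round((1 - identity_targets[k]) * n_res_ag)` antigen positions (mutation
#' blocks are disjoint across copies, so the pairwise identity between
#' copies i and j is exactly `1 - k_i/n - k_j/n`), and copies flagged
#' `divergent` get a large hinge rotation of the antigen so the
#' whole-complex RMSD exceeds the 5 A redundancy cutoff. Two copies are
#' expected to be redundant when their pairwise antigen identity exceeds
#' 60% and they are structurally alike (both divergent copies get distinct
#' rotations, so any pair involving a divergent copy is non-redundant).
#'
#' @param n_copies number of family members (>= 2).
#' @param identity_targets numeric vector (length `n_copies`) of per-copy
#'   sequence identity to the base complex; default all 1.
#' @param divergent logical vector flagging structurally divergent copies.
#' @param base_spec [fixture_spec()] for the base complex.
#' @param seed integer seed.
#' @return list: `cases` (list of `abag_case`), `expected_edges`
#'   (data.frame `case_a`, `case_b`, `redundant`), `identity` (pairwise
#'   matrix).
#' @export
generate_redundant_family <- function(n_copies = 2,
                                      identity_targets = rep(1, n_copies),
                                      divergent = rep(FALSE, n_copies),
                                      base_spec = fixture_spec(),
                                      seed = 1L) {
  stopifnot(n_copies >= 2, length(identity_targets) == n_copies,
            length(divergent) == n_copies)
  with_seed(seed, {
    base <- generate_toy_case_impl(base_spec, "fam")
    n <- base_spec$n_res_ag
    k_mut <- round((1 - identity_targets) * n)
    if (sum(k_mut) > n)
      stop("identity targets require more disjoint mutations than residues")
    # disjoint mutation sets scattered over the chain (clustered terminal
    # blocks could be skipped by an ends-free alignment, breaking the
    # identity guarantee)
    perm <- sample(n)
    blocks <- if (sum(k_mut) > 0)
      split(perm[seq_len(sum(k_mut))],
            rep(seq_len(n_copies), times = k_mut))
    else list()
    cases <- vector("list", n_copies)
    for (cidx in seq_len(n_copies)) {
      cs <- base
      cs$case_id <- sprintf("fam%02d", cidx)
      cs$bound$id <- cs$case_id
      muts <- blocks[[as.character(cidx)]] %||% integer(0)
      if (length(muts)) {
        sel <- cs$bound$atoms$chain == "A" & cs$bound$atoms$resno %in% muts
        old_aa <- fixture_sequence("A", n)[muts]
        new_aa <- vapply(old_aa, function(a)
          sample(setdiff(AA20, a), 1), character(1))
        cs$bound$atoms$resname[sel] <-
          new_aa[match(cs$bound$atoms$resno[sel], muts)]
      }
      if (divergent[cidx]) {
        # distinct large hinge per divergent copy -> pairwise RMSD > 5 A
        angle <- 60 + 40 * cidx
        at <- cs$bound$atoms
        res <- chain_residues(cs$bound, "A")
        hinge <- res$resno[ceiling(nrow(res) / 2)]
        pivot_row <- which(at$chain == "A" & at$resno == hinge &
                             at$name == "CA")[1]
        pivot <- as.numeric(at[pivot_row, c("x", "y", "z")])
        R <- rotation_about_axis(c(0, 1, 0), angle * pi / 180)
        move <- at$chain == "A" & at$resno > hinge
        xyz <- as.matrix(at[move, c("x", "y", "z")])
        at[move, c("x", "y", "z")] <-
          sweep(sweep(xyz, 2, pivot) %*% t(R), 2, pivot, "+")
        cs$bound$atoms <- at
      }
      # unbound copies track the (possibly mutated/diverged) bound
      cs$unbound_antibody <- list(subset_chains(
        cs$bound, cs$antibody_chains, id = paste0(cs$case_id, "_ab_u")))
      cs$unbound_antigen <- list(subset_chains(
        cs$bound, cs$antigen_chains, id = paste0(cs$case_id, "_ag_u")))
      cases[[cidx]] <- cs
    }

    idm <- diag(1, n_copies)
    rows <- list(); r <- 0L
    for (i in seq_len(n_copies - 1)) for (j in seq(i + 1, n_copies)) {
      idm[i, j] <- idm[j, i] <- 1 - (k_mut[i] + k_mut[j]) / n
      seq_ok <- idm[i, j] > 0.60
      struct_ok <- !divergent[i] && !divergent[j]
      r <- r + 1L
      rows[[r]] <- data.frame(case_a = cases[[i]]$case_id,
                              case_b = cases[[j]]$case_id,
                              redundant = seq_ok && struct_ok,
                              stringsAsFactors = FALSE)
    }
    list(cases = cases, expected_edges = do.call(rbind, rows),
         identity = idm)
  })
}

#' Write a case's structure files to a directory
#'
#' Benchmark layout: `<case>_bound.pdb`, `<case>_ab_u<i>.pdb`,
#' `<case>_ag_u<i>.pdb`, `<case>_cdr.tsv` plus a `manifest.csv` row.
#'
#' @param case `abag_case`.
#' @param dir output directory (created if needed).
#' @return data.frame manifest row, invisibly.
#' @export
write_case_files <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(dir, case$case_id)
  write_structure(case$bound, paste0(pre, "_bound.pdb"))
  for (i in seq_along(case$unbound_antibody))
    write_structure(case$unbound_antibody[[i]],
                    sprintf("%s_ab_u%d.pdb", pre, i))
  for (i in seq_along(case$unbound_antigen))
    write_structure(case$unbound_antigen[[i]],
                    sprintf("%s_ag_u%d.pdb", pre, i))
  if (!is.null(case$cdr_annotation))
    write_cdr_annotation(case$cdr_annotation, paste0(pre, "_cdr.tsv"))
  row <- data.frame(
    case_id = case$case_id,
    antibody_chains = paste(case$antibody_chains, collapse = ";"),
    antigen_chains = paste(case$antigen_chains, collapse = ";"),
    antibody_type = if (length(case$antibody_chains) > 1) "mAb" else "sdAb",
    pairing_state = case$pairing_state,
    n_unbound_ab = length(case$unbound_antibody),
    n_unbound_ag = length(case$unbound_antigen),
    stringsAsFactors = FALSE
  )
  invisible(row)
}

#' Read a case back from a directory written by [write_case_files()]
#'
#' @param dir directory holding the files.
#' @param case_id case identifier (file prefix).
#' @param manifest_row optional manifest row with chain assignments.
#' @return `abag_case`.
#' @export
read_case_files <- function(dir, case_id, manifest_row = NULL) {
  pre <- file.path(dir, case_id)
  bound <- read_structure(paste0(pre, "_bound.pdb"), id = case_id)
  if (is.null(manifest_row)) {
    mf <- utils::read.csv(file.path(dir, "manifest.csv"),
                          stringsAsFactors = FALSE)
    manifest_row <- mf[mf$case_id == case_id, , drop = FALSE]
    if (!nrow(manifest_row)) stop("case not in manifest: ", case_id)
  }
  ab_chains <- strsplit(manifest_row$antibody_chains, ";")[[1]]
  ag_chains <- strsplit(manifest_row$antigen_chains, ";")[[1]]
  read_side <- function(tag, n) {
    lapply(seq_len(n), function(i) {
      read_structure(sprintf("%s_%s_u%d.pdb", pre, tag, i),
                     id = sprintf("%s_%s_u%d", case_id, tag, i))
    })
  }
  ann_path <- paste0(pre, "_cdr.tsv")
  complex_case(
    bound, ab_chains, ag_chains, case_id = case_id,
    unbound_antibody = read_side("ab", manifest_row$n_unbound_ab),
    unbound_antigen = read_side("ag", manifest_row$n_unbound_ag),
    cdr_annotation = if (file.exists(ann_path))
      read_cdr_annotation(ann_path) else NULL
  )
}
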