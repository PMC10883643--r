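## Interface definition and conformational-change metrics ---------------
##
## Interface residues: any non-hydrogen atom within 10 A of any
## non-hydrogen atom of the binding partner. Contacts: the same definition
## at 5 A, recorded as residue pairs. I-RMSD: C-alpha RMSD over interface
## residues after superposing the unbound interface onto the bound one.
## f_non-nat: fraction of the superposed-unbound contact set absent from
## the native (bound) contact set.

#' Interface residues of a bound complex
#'
#' A residue belongs to the interface when any of its non-hydrogen atoms
#' lies within `cutoff` of any non-hydrogen atom of the other side.
#'
#' @param case `abag_case`.
#' @param cutoff distance cutoff in Angstrom (default 10).
#' @return list of class `abag_interface`: `antibody` and `antigen` residue
#'   tables (chain, resno, insert) and the `cutoff` used.
#' @export
interface_residues <- function(case, cutoff = 10) {
  stopifnot(inherits(case, "abag_case"), cutoff > 0)
  ab <- side_atoms(case, "antibody")
  ag <- side_atoms(case, "antigen")
  if (!nrow(ab) || !nrow(ag)) stop("a side of the interface has no atoms")
  pr <- cross_pairs_within(cbind(ab$x, ab$y, ab$z),
                           cbind(ag$x, ag$y, ag$z), cutoff)
  out <- list(
    antibody = unique_residues(ab[unique(pr$i), , drop = FALSE]),
    antigen = unique_residues(ag[unique(pr$j), , drop = FALSE]),
    cutoff = cutoff
  )
  class(out) <- "abag_interface"
  out
}

side_atoms <- function(case, side) {
  chains <- if (side == "antibody") case$antibody_chains
  else case$antigen_chains
  at <- case$bound$atoms
  at[at$chain %in% chains & !at$hydrogen, , drop = FALSE]
}

unique_residues <- function(at) {
  key <- res_key(at$chain, at$resno, at$insert)
  first <- !duplicated(key)
  data.frame(chain = at$chain[first], resno = at$resno[first],
             insert = at$insert[first], stringsAsFactors = FALSE)
}

#' Residue-residue contacts across the interface
#'
#' Residue pairs (one antibody, one antigen) with any two non-hydrogen
#' atoms within `cutoff` (default 5 A).
#'
#' @param case `abag_case`.
#' @param cutoff distance cutoff in Angstrom (default 5).
#' @return data.frame of class `abag_contacts`: columns `chain_ab, resno_ab,
#'   insert_ab, chain_ag, resno_ag, insert_ag`, attribute `cutoff`.
#' @export
contacts <- function(case, cutoff = 5) {
  stopifnot(inherits(case, "abag_case"), cutoff > 0)
  ab <- side_atoms(case, "antibody")
  ag <- side_atoms(case, "antigen")
  if (!nrow(ab) || !nrow(ag)) stop("a side of the interface has no atoms")
  contact_pairs(ab, ag, cutoff)
}

contact_pairs <- function(ab, ag, cutoff) {
  pr <- cross_pairs_within(cbind(ab$x, ab$y, ab$z),
                           cbind(ag$x, ag$y, ag$z), cutoff)
  ka <- res_key(ab$chain[pr$i], ab$resno[pr$i], ab$insert[pr$i])
  kg <- res_key(ag$chain[pr$j], ag$resno[pr$j], ag$insert[pr$j])
  both <- paste(ka, kg, sep = "~")
  first <- !duplicated(both)
  out <- data.frame(
    chain_ab = ab$chain[pr$i][first], resno_ab = ab$resno[pr$i][first],
    insert_ab = ab$insert[pr$i][first],
    chain_ag = ag$chain[pr$j][first], resno_ag = ag$resno[pr$j][first],
    insert_ag = ag$insert[pr$j][first],
    stringsAsFactors = FALSE
  )
  attr(out, "cutoff") <- cutoff
  class(out) <- c("abag_contacts", "data.frame")
  out
}

contact_keys <- function(ct) {
  paste(res_key(ct$chain_ab, ct$resno_ab, ct$insert_ab),
        res_key(ct$chain_ag, ct$resno_ag, ct$insert_ag), sep = "~")
}

# residue maps bound -> primary unbound structures, one list per side;
# chains are paired by identical id when possible, else by best alignment
case_maps <- function(case, which_ab = 1L, which_ag = 1L) {
  list(
    antibody = side_maps(case$bound, case$antibody_chains,
                         case$unbound_antibody[[which_ab]]),
    antigen = side_maps(case$bound, case$antigen_chains,
                        case$unbound_antigen[[which_ag]])
  )
}

side_maps <- function(bound, bound_chains, unbound) {
  u_chains <- chain_ids(unbound)
  pairs <- if (all(bound_chains %in% u_chains)) {
    cbind(bound_chains, bound_chains)
  } else {
    # greedy best-score assignment by sequence identity
    avail <- u_chains
    t(vapply(bound_chains, function(bc) {
      ids <- vapply(avail, function(uc)
        sequence_identity(chain_sequence(bound, bc),
                          chain_sequence(unbound, uc)), numeric(1))
      best <- avail[which.max(ids)]
      avail <<- setdiff(avail, best)
      c(bc, best)
    }, character(2)))
  }
  lapply(seq_len(nrow(pairs)), function(i)
    residue_map(bound, unbound, pairs[i, 1], pairs[i, 2]))
}

# interface C-alpha pairing for one side: bound coords, unbound coords
interface_ca_pairs <- function(case, side, interface, maps) {
  ires <- if (side == "antibody") interface$antibody else interface$antigen
  unb <- if (side == "antibody") case$unbound_antibody[[1]]
  else case$unbound_antigen[[1]]
  ikeys <- res_key(ires$chain, ires$resno, ires$insert)
  xa <- list(); xb <- list(); k <- 0L
  for (mp in maps[[side]]) {
    kb <- res_key(mp$chain_b, mp$resno_b, mp$insert_b)
    sel <- kb %in% ikeys
    if (!any(sel)) next
    ca_b <- ca_lookup(case$bound, mp$chain_b[1])
    ca_u <- ca_lookup(unb, mp$chain_u[1])
    want_b <- kb[sel]
    want_u <- res_key(mp$chain_u, mp$resno_u, mp$insert_u)[sel]
    ok <- want_b %in% rownames(ca_b) & want_u %in% rownames(ca_u)
    if (!any(ok)) next
    k <- k + 1L
    xa[[k]] <- ca_b[want_b[ok], , drop = FALSE]
    xb[[k]] <- ca_u[want_u[ok], , drop = FALSE]
  }
  if (!k) return(list(bound = matrix(numeric(0), 0, 3),
                      unbound = matrix(numeric(0), 0, 3)))
  list(bound = do.call(rbind, xa), unbound = do.call(rbind, xb))
}

#' Interface RMSD
#'
#' C-alpha RMSD over interface residues, computed by superposing the unbound
#' interface C-alpha set of the requested side onto its bound counterpart.
#' `side = "combined"` fits each component on its own interface set and
#' pools the squared deviations of both sides into one RMSD (the
#' entire-interface value used for difficulty classification).
#'
#' @param case `abag_case` with unbound structures on the required side(s).
#' @param side `"antibody"`, `"antigen"` or `"combined"`.
#' @param cutoff interface cutoff in Angstrom (default 10).
#' @param interface optional precomputed [interface_residues()] result.
#' @param maps optional precomputed [case_maps()] result.
#' @return RMSD in Angstrom.
#' @export
i_rmsd <- function(case, side = c("combined", "antibody", "antigen"),
                   cutoff = 10, interface = NULL, maps = NULL) {
  side <- match.arg(side)
  interface <- interface %||% interface_residues(case, cutoff)
  maps <- maps %||% case_maps(case)
  one_side <- function(s) {
    pr <- interface_ca_pairs(case, s, interface, maps)
    if (nrow(pr$bound) == 0)
      stop(sprintf("no interface C-alpha atoms mapped on the %s side", s))
    sup <- kabsch_superpose(pr$bound, pr$unbound)
    fitted <- apply_superposition(pr$unbound, sup)
    rowSums((pr$bound - fitted)^2)
  }
  if (side != "combined") return(sqrt(mean(one_side(side))))
  sq <- c(one_side("antibody"), one_side("antigen"))
  sqrt(mean(sq))
}

#' Fraction of non-native contacts
#'
#' Each unbound component is superposed onto the bound complex via its
#' interface C-alpha fit; contacts of the superposed unbound pair are
#' recomputed at the contact cutoff and compared, as residue pairs in bound
#' numbering, with the native contact set. Returns the fraction of model
#' contacts that are not native. When the superposed pair makes no contacts
#' at all the value is 1 by convention and carries attribute
#' `no_model_contacts = TRUE`.
#'
#' @param case `abag_case` with unbound structures on both sides.
#' @param contact_cutoff contact distance in Angstrom (default 5).
#' @param interface_cutoff interface definition cutoff (default 10).
#' @param interface,maps optional precomputed helpers, as in [i_rmsd()].
#' @return fraction in `[0,1]`.
#' @export
f_non_nat <- function(case, contact_cutoff = 5, interface_cutoff = 10,
                      interface = NULL, maps = NULL) {
  native <- contacts(case, contact_cutoff)
  if (!nrow(native)) stop("bound complex has no contacts: no interface")
  interface <- interface %||% interface_residues(case, interface_cutoff)
  maps <- maps %||% case_maps(case)

  superposed_side <- function(s) {
    pr <- interface_ca_pairs(case, s, interface, maps)
    if (nrow(pr$bound) == 0)
      stop(sprintf("no interface C-alpha atoms mapped on the %s side", s))
    sup <- kabsch_superpose(pr$bound, pr$unbound)
    unb <- if (s == "antibody") case$unbound_antibody[[1]]
    else case$unbound_antigen[[1]]
    at <- unb$atoms[!unb$atoms$hydrogen, , drop = FALSE]
    xyz <- apply_superposition(cbind(at$x, at$y, at$z), sup)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    # relabel residues to bound numbering so contact pairs are comparable;
    # unbound residues without a bound counterpart stay as-is (their
    # contacts can never match a native pair)
    for (mp in maps[[s]]) {
      ku <- res_key(at$chain, at$resno, at$insert)
      from <- res_key(mp$chain_u, mp$resno_u, mp$insert_u)
      idx <- match(ku, from)
      hit <- !is.na(idx) & at$chain == mp$chain_u[1]
      at$chain[hit] <- mp$chain_b[idx[hit]]
      at$resno[hit] <- mp$resno_b[idx[hit]]
      at$insert[hit] <- mp$insert_b[idx[hit]]
    }
    at
  }

  ab <- superposed_side("antibody")
  ag <- superposed_side("antigen")
  model <- contact_pairs(ab, ag, contact_cutoff)
  if (!nrow(model)) {
    out <- 1
    attr(out, "no_model_contacts") <- TRUE
    return(out)
  }
  mean(!(contact_keys(model) %in% contact_keys(native)))
}

#' Per-component RMSD between bound and unbound structures
#'
#' Whole-chain C-alpha RMSD of one side's primary unbound structure against
#' its bound conformation (superposed over all mapped C-alpha atoms).
#'
#' @param case `abag_case`.
#' @param side `"antibody"` or `"antigen"`.
#' @param maps optional precomputed [case_maps()] result.
#' @return RMSD in Angstrom.
#' @export
component_rmsd <- function(case, side = c("antibody", "antigen"),
                           maps = NULL) {
  side <- match.arg(side)
  maps <- maps %||% case_maps(case)
  unb <- if (side == "antibody") case$unbound_antibody[[1]]
  else case$unbound_antigen[[1]]
  mapped_rmsd(case$bound, unb, maps[[side]], atom_selection = "CA")
}

#' All conformational-change metrics for one case
#'
#' Computes component RMSDs, per-side and combined I-RMSD, f_non-nat,
#' buried surface area and (when a CDR annotation is available) per-CDR
#' RMSDs, using the primary (first listed) unbound structures.
#'
#' @param case `abag_case` with unbound structures on both sides.
#' @param config thresholds, see [run_config()].
#' @return one-row data.frame: `case_id, rmsd_ab, rmsd_ag, i_rmsd_ab,
#'   i_rmsd_ag, i_rmsd_combined, f_non_nat, delta_asa` plus one column per
#'   annotated CDR.
#' @export
interface_metrics <- function(case, config = run_config()) {
  interface <- interface_residues(case, config$interface_cutoff)
  maps <- case_maps(case)
  out <- data.frame(
    case_id = case$case_id,
    rmsd_ab = component_rmsd(case, "antibody", maps),
    rmsd_ag = component_rmsd(case, "antigen", maps),
    i_rmsd_ab = i_rmsd(case, "antibody", config$interface_cutoff,
                       interface, maps),
    i_rmsd_ag = i_rmsd(case, "antigen", config$interface_cutoff,
                       interface, maps),
    i_rmsd_combined = i_rmsd(case, "combined", config$interface_cutoff,
                             interface, maps),
    f_non_nat = as.numeric(f_non_nat(case, config$contact_cutoff,
                                     config$interface_cutoff,
                                     interface, maps)),
    delta_asa = delta_asa(case, probe = config$sasa_probe,
                          n_points = config$sasa_points),
    stringsAsFactors = FALSE
  )
  if (!is.null(case$cdr_annotation)) {
    cdr <- cdr_rmsd(case, case$cdr_annotation, maps = maps)
    for (nm in names(cdr)) out[[paste0("cdr_", tolower(nm))]] <- cdr[[nm]]
  }
  out
}
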