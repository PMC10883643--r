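## ComplexCase ----------------------------------------------------------
##
## One benchmark case: a bound antibody-antigen interface plus any unbound
## partner structures, the pairing state that records which sides have
## unbound structures, and (once computed) conformational-change metrics and
## a difficulty label.

#' Construct a benchmark complex case
#'
#' @param bound `abag_structure` holding the bound complex.
#' @param antibody_chains,antigen_chains chain ids of the two sides; must be
#'   disjoint and present in `bound`.
#' @param case_id case identifier (defaults to the bound structure id).
#' @param unbound_antibody,unbound_antigen lists of `abag_structure` unbound
#'   partners (possibly empty).
#' @param cdr_annotation optional CDR annotation (see [read_cdr_annotation()]).
#' @return object of class `abag_case`. The `pairing_state` field is
#'   `"UU"`, `"UB"`, `"BU"` or `"BB"` according to which sides have at least
#'   one unbound structure (antibody side first).
#' @export
complex_case <- function(bound, antibody_chains, antigen_chains,
                         case_id = bound$id,
                         unbound_antibody = list(),
                         unbound_antigen = list(),
                         cdr_annotation = NULL) {
  stopifnot(inherits(bound, "abag_structure"))
  if (length(intersect(antibody_chains, antigen_chains)))
    stop("antibody and antigen chain-id sets must be disjoint")
  missing <- setdiff(c(antibody_chains, antigen_chains), chain_ids(bound))
  if (length(missing))
    stop(sprintf("chain id(s) %s not present; available: %s",
                 paste(missing, collapse = ", "),
                 paste(chain_ids(bound), collapse = ", ")))
  state <- pairing_state(length(unbound_antibody) > 0,
                         length(unbound_antigen) > 0)
  structure(
    list(case_id = case_id, bound = bound,
         antibody_chains = antibody_chains, antigen_chains = antigen_chains,
         unbound_antibody = unbound_antibody,
         unbound_antigen = unbound_antigen,
         pairing_state = state, cdr_annotation = cdr_annotation,
         metrics = NULL, difficulty = NULL),
    class = "abag_case"
  )
}

pairing_state <- function(ab_unbound, ag_unbound) {
  if (ab_unbound && ag_unbound) "UU"
  else if (ab_unbound) "UB"
  else if (ag_unbound) "BU"
  else "BB"
}

#' @export
print.abag_case <- function(x, ...) {
  cat(sprintf(
    "<abag_case> %s [%s]: antibody {%s}, antigen {%s}, %d/%d unbound\n",
    x$case_id, x$pairing_state,
    paste(x$antibody_chains, collapse = ","),
    paste(x$antigen_chains, collapse = ","),
    length(x$unbound_antibody), length(x$unbound_antigen)))
  if (!is.null(x$difficulty)) cat("  difficulty:", x$difficulty, "\n")
  invisible(x)
}

#' Reduce a complex to the fewest chains reflecting the binding process
#'
#' Keeps exactly the named antibody and antigen chains of the bound model and
#' drops everything else (extra copies in the asymmetric unit, bystander
#' chains), producing a minimal benchmark case.
#'
#' @param model bound `abag_structure`.
#' @param antibody_chains,antigen_chains chain ids to retain for each side.
#' @param case_id case identifier (default: model id).
#' @return `abag_case` with pairing state `"BB"` (no unbound structures yet).
#' @export
extract_minimal_case <- function(model, antibody_chains, antigen_chains,
                                 case_id = model$id) {
  keep <- c(antibody_chains, antigen_chains)
  bound <- subset_chains(model, keep, id = case_id)
  bound$roles[antibody_chains] <-
    ifelse(length(antibody_chains) == 1, "single_domain",
           model$roles[antibody_chains])
  bound$roles[antigen_chains] <- "antigen"
  complex_case(bound, antibody_chains, antigen_chains, case_id = case_id)
}

#' Split a multi-interface complex into one case per interface
#'
#' Some complexes bind the same antigen through two distinct interfaces; each
#' interface becomes its own benchmark case with an id suffix `"_1"`, `"_2"`,
#' ... in input order. Cases are independent copies: mutating one never
#' affects another.
#'
#' @param model bound `abag_structure`.
#' @param interface_defs list of `list(antibody = <chain ids>,
#'   antigen = <chain ids>)`, one per interface.
#' @return list of `abag_case`.
#' @export
split_interfaces <- function(model, interface_defs) {
  stopifnot(length(interface_defs) >= 1)
  lapply(seq_along(interface_defs), function(i) {
    def <- interface_defs[[i]]
    extract_minimal_case(model, def$antibody, def$antigen,
                         case_id = paste0(model$id, "_", i))
  })
}

## Residue correspondence ------------------------------------------------

#' Align two chains and return the residue-level correspondence
#'
#' End-gap-free global alignment (Biostrings "overlap" type, BLOSUM62) of the
#' two chain sequences; only match/mismatch columns are kept, so the map is
#' injective in both directions.
#'
#' @param bound,unbound `abag_structure` objects.
#' @param bound_chain,unbound_chain chain ids to align.
#' @return data.frame of class `abag_residue_map` with columns
#'   `chain_b, resno_b, insert_b, chain_u, resno_u, insert_u`, ordered along
#'   the bound chain.
#' @export
residue_map <- function(bound, unbound, bound_chain, unbound_chain) {
  res_b <- chain_residues(bound, bound_chain)
  res_u <- chain_residues(unbound, unbound_chain)
  seq_b <- chain_sequence(bound, bound_chain)
  seq_u <- chain_sequence(unbound, unbound_chain)
  cols <- aligned_columns(seq_b, seq_u)
  if (!nrow(cols)) stop("no alignment overlap between chains")
  out <- data.frame(
    chain_b = bound_chain, resno_b = res_b$resno[cols$i],
    insert_b = res_b$insert[cols$i],
    chain_u = unbound_chain, resno_u = res_u$resno[cols$j],
    insert_u = res_u$insert[cols$j],
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("abag_residue_map", "data.frame")
  out
}

# match/mismatch column indices (i into seq a, j into seq b) of an
# end-gap-free global alignment
aligned_columns <- function(seq_a, seq_b) {
  sm <- get_blosum62()
  pa <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "overlap",
                                      substitutionMatrix = sm,
                                      gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ia <- Biostrings::start(Biostrings::pattern(pa)) - 1L + cumsum(p != "-")
  ib <- Biostrings::start(Biostrings::subject(pa)) - 1L + cumsum(s != "-")
  keep <- p != "-" & s != "-"
  data.frame(i = ia[keep], j = ib[keep])
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Truncate an unbound chain to the region aligned with its bound chain
#'
#' Unbound structures are often longer than the bound chain they pair with
#' (extra domains, tags). Truncation keeps only the unbound residues that
#' align to bound positions so that docking inputs match the bound lengths.
#' The input structure is not modified.
#'
#' @param unbound,bound `abag_structure` objects.
#' @param unbound_chain,bound_chain chain ids; default to the single chain of
#'   each structure when unambiguous.
#' @return a copy of `unbound` with the named chain truncated; never longer
#'   than the bound chain, residue order preserved.
#' @export
truncate_unbound <- function(unbound, bound,
                             unbound_chain = NULL, bound_chain = NULL) {
  unbound_chain <- unbound_chain %||% only_chain(unbound)
  bound_chain <- bound_chain %||% only_chain(bound)
  map <- residue_map(bound, unbound, bound_chain, unbound_chain)
  keep_keys <- res_key(map$chain_u, map$resno_u, map$insert_u)
  out <- unbound
  at <- out$atoms
  in_chain <- at$chain == unbound_chain
  keys <- res_key(at$chain, at$resno, at$insert)
  out$atoms <- at[!in_chain | keys %in% keep_keys, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

only_chain <- function(model) {
  ch <- chain_ids(model)
  if (length(ch) != 1)
    stop("structure has several chains; specify the chain id explicitly")
  ch
}
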