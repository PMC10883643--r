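## Unbound-structure screening ------------------------------------------
##
## Candidate unbound structures for each bound chain come from a sequence
## search against the PDB sequence database. A hit is accepted when
##   identity > 93%, alignment coverage > 80%, E-value < 1e-5
## (all strict). Cases are then grouped by which sides have at least one
## accepted unbound structure: UU / UB / BU / BB.

#' Default screening and redundancy thresholds
#'
#' All tunable cutoffs of the curation pipeline with their standard values:
#' unbound-hit screening (identity > 0.93, coverage > 0.80, E < 1e-5),
#' complex redundancy (identity > 0.60, E < 1e-30, RMSD < 5 A), interface
#' definition (10 A) and contact definition (5 A), difficulty criteria
#' (Rigid: I-RMSD < 1.5 A and f_non-nat < 0.40; Difficult: I-RMSD > 2.2 A),
#' and SASA numerics (probe 1.4 A, 960 sphere points).
#'
#' @param ... named overrides of any default.
#' @return named list of thresholds, class `abag_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    unbound_identity_min = 0.93,
    unbound_coverage_min = 0.80,
    unbound_evalue_max   = 1e-5,
    redundant_identity_min = 0.60,
    redundant_evalue_max   = 1e-30,
    redundant_rmsd_max     = 5.0,
    interface_cutoff = 10.0,
    contact_cutoff   = 5.0,
    rigid_irmsd_max     = 1.5,
    rigid_fnn_max       = 0.40,
    difficult_irmsd_min = 2.2,
    sasa_probe  = 1.4,
    sasa_points = 960L,
    tie_break = "lexicographic",
    seed = NULL
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "abag_config")
}

#' Read / write a flat JSON run configuration
#' @param path JSON file path.
#' @return for `read_run_config`, an `abag_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_run_config
#' @param config an `abag_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Construct an alignment hit
#'
#' One sequence-search result between a bound chain (query) and a candidate
#' unbound chain (subject).
#'
#' @param query_id,subject_id chain identifiers.
#' @param identity fraction identical positions in `[0,1]`.
#' @param coverage fraction of the query length aligned, in `[0,1]`
#'   (`NA` when the query length is unknown).
#' @param e_value non-negative expectation value.
#' @param query_range,subject_range optional `c(start, end)` aligned ranges.
#' @return one-row data.frame of class `abag_hit`.
#' @export
alignment_hit <- function(query_id, subject_id, identity, coverage, e_value,
                          query_range = c(NA_integer_, NA_integer_),
                          subject_range = c(NA_integer_, NA_integer_)) {
  if (!is.na(identity) && (identity < 0 || identity > 1))
    stop("identity must be a fraction in [0,1]")
  if (!is.na(coverage) && (coverage < 0 || coverage > 1))
    stop("coverage must be a fraction in [0,1]")
  if (!is.na(e_value) && e_value < 0) stop("e_value must be >= 0")
  out <- data.frame(query_id = query_id, subject_id = subject_id,
                    identity = identity, coverage = coverage,
                    e_value = e_value,
                    q_start = query_range[1], q_end = query_range[2],
                    s_start = subject_range[1], s_end = subject_range[2],
                    stringsAsFactors = FALSE)
  class(out) <- c("abag_hit", "data.frame")
  out
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Standard 12 columns: qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore. Percent identity is converted to a
#' fraction. Coverage is the aligned query span over the query length, so it
#' can only be filled in when `query_lengths` provides the bound chain
#' lengths; otherwise it is `NA` and hits cannot pass the unbound screen.
#'
#' @param path tab-separated file without header.
#' @param query_lengths optional named integer vector, query id -> residue
#'   count of the bound chain.
#' @return data.frame of hits (class `abag_hit`).
#' @export
read_blast_tab <- function(path, query_lengths = NULL) {
  cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
            "gapopen", "q_start", "q_end", "s_start", "s_end",
            "e_value", "bitscore")
  tab <- utils::read.delim(path, header = FALSE, col.names = cols,
                           stringsAsFactors = FALSE)
  tab$identity <- tab$pident / 100
  tab$coverage <- NA_real_
  if (!is.null(query_lengths)) {
    ql <- query_lengths[tab$query_id]
    tab$coverage <- (tab$q_end - tab$q_start + 1) / as.numeric(ql)
  }
  out <- tab[, c("query_id", "subject_id", "identity", "coverage",
                 "e_value", "q_start", "q_end", "s_start", "s_end")]
  class(out) <- c("abag_hit", "data.frame")
  out
}

#' Accept or reject a candidate unbound-structure hit
#'
#' A hit identifies a usable unbound structure when identity exceeds 93%,
#' alignment coverage exceeds 80% and the E-value is below 1e-5 — all
#' strict inequalities, so boundary values fail.
#'
#' @param hit data.frame with columns `identity`, `coverage`, `e_value`
#'   (one or more rows).
#' @param config thresholds, see [run_config()].
#' @return logical vector, one per row.
#' @export
accept_unbound_hit <- function(hit, config = run_config()) {
  ok <- hit$identity > config$unbound_identity_min &
    hit$coverage > config$unbound_coverage_min &
    hit$e_value < config$unbound_evalue_max
  ok & !is.na(ok)
}

#' Collect the accepted unbound candidates for one bound chain
#'
#' Filters the hit table to the query, applies the unbound screen,
#' de-duplicates by subject (best identity kept, then lowest E-value) and
#' sorts by identity descending then E-value ascending.
#'
#' @param hits hit table (see [read_blast_tab()] or [alignment_hit()]).
#' @param query_id bound chain identifier; unknown ids yield an empty set.
#' @param config thresholds, see [run_config()].
#' @return data.frame of accepted hits, class `abag_candidate_set`, with the
#'   query id as attribute `query_id`.
#' @export
collect_unbound_candidates <- function(hits, query_id,
                                       config = run_config()) {
  sub <- hits[hits$query_id == query_id, , drop = FALSE]
  sub <- sub[accept_unbound_hit(sub, config), , drop = FALSE]
  sub <- sub[order(-sub$identity, sub$e_value), , drop = FALSE]
  sub <- sub[!duplicated(sub$subject_id), , drop = FALSE]
  rownames(sub) <- NULL
  attr(sub, "query_id") <- query_id
  class(sub) <- c("abag_candidate_set", "data.frame")
  sub
}

#' Assign the pairing state of a complex from its candidate sets
#'
#' A side is "unbound" when every one of its bound chains has at least one
#' accepted unbound candidate. UU: both sides unbound; UB: antibody only;
#' BU: antigen only; BB: neither. The four states are exhaustive and
#' mutually exclusive.
#'
#' @param ab_candidates,ag_candidates lists of candidate sets (one per bound
#'   chain of that side); a plain integer vector of candidate counts is also
#'   accepted.
#' @return one of `"UU"`, `"UB"`, `"BU"`, `"BB"`.
#' @export
categorize_case <- function(ab_candidates, ag_candidates) {
  n_of <- function(x) {
    if (is.numeric(x)) x
    else vapply(x, function(s) nrow(s) %||% length(s), numeric(1))
  }
  if (length(ab_candidates) == 0 || length(ag_candidates) == 0)
    stop("each side needs one candidate set per bound chain")
  ab_ok <- all(n_of(ab_candidates) >= 1)
  ag_ok <- all(n_of(ag_candidates) >= 1)
  pairing_state(ab_ok, ag_ok)
}

#' Write candidate sets to CSV
#'
#' One row per (query chain, accepted subject), mirroring per-pairing-state
#' candidate sheets.
#'
#' @param candidate_sets named list of `abag_candidate_set` (names = query
#'   ids).
#' @param path output CSV path.
#' @export
write_candidate_sets <- function(candidate_sets, path) {
  rows <- lapply(candidate_sets, function(s) {
    if (!nrow(s)) return(NULL)
    data.frame(query_id = attr(s, "query_id"), subject_id = s$subject_id,
               identity = s$identity, coverage = s$coverage,
               e_value = s$e_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(query_id = character(0), subject_id = character(0),
                      identity = numeric(0), coverage = numeric(0),
                      e_value = numeric(0))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
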