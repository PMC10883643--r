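## Redundancy graph -----------------------------------------------------
##
## Two complexes are redundant when every corresponding chain type matches
## at sequence level (identity > 60%, E-value < 1e-30, strict) AND the
## whole-complex C-alpha RMSD after least-squares superposition is below
## 5 A. Redundant pairs become edges of an undirected graph over case ids;
## greedy deletion of maximum-degree nodes until all degrees are zero leaves
## a non-redundant (independent) retained set.

#' Sequence-level redundancy between two corresponding chains
#'
#' @param best_hit data.frame with columns `identity` (fraction) and
#'   `e_value` — the best alignment between corresponding chains of two
#'   complexes. Vectorized over rows.
#' @param config thresholds, see [run_config()].
#' @return logical: identity > 60% and E-value < 1e-30 (both strict).
#' @export
sequence_redundant <- function(best_hit, config = run_config()) {
  ok <- best_hit$identity > config$redundant_identity_min &
    best_hit$e_value < config$redundant_evalue_max
  ok & !is.na(ok)
}

#' Complex-level redundancy verdict
#'
#' A pair of complexes is redundant only if every chain type passes the
#' sequence criterion and the superposed whole-complex RMSD is below 5 A.
#' High sequence identity alone is not enough: complexes with identical
#' sequences can still bind in markedly different orientations and are then
#' kept as distinct cases.
#'
#' @param seq_flags logical vector, one element per chain type (e.g. heavy,
#'   light, antigen), each the [sequence_redundant()] outcome for that type.
#' @param rmsd C-alpha RMSD (Angstrom) after whole-complex superposition, or
#'   `NA` when not computed.
#' @param config thresholds, see [run_config()].
#' @return logical scalar.
#' @export
complex_redundant <- function(seq_flags, rmsd, config = run_config()) {
  stopifnot(length(seq_flags) >= 1)
  if (!all(seq_flags)) return(FALSE)
  if (is.na(rmsd))
    stop("all chain types match at sequence level; structure comparison ",
         "(RMSD) is required to decide redundancy")
  isTRUE(rmsd < config$redundant_rmsd_max)
}

#' Build the redundancy graph from pairwise verdicts
#'
#' @param verdicts data.frame with columns `case_a`, `case_b`, `redundant`
#'   (logical). Duplicate and reversed pairs collapse onto a single
#'   undirected edge; self-pairs are ignored.
#' @param nodes character vector of all case ids (isolated nodes are
#'   preserved even when they appear in no verdict).
#' @return `igraph` undirected graph with vertex names = case ids.
#' @export
build_graph <- function(verdicts, nodes) {
  nodes <- as.character(unique(nodes))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(verdicts)) {
    red <- verdicts[which(verdicts$redundant), , drop = FALSE]
    if (nrow(red)) {
      bad <- setdiff(unique(c(red$case_a, red$case_b)), nodes)
      if (length(bad))
        stop("verdict references unknown case id(s): ",
             paste(bad, collapse = ", "))
      a <- pmin(red$case_a, red$case_b)
      b <- pmax(red$case_a, red$case_b)
      keep <- a != b & !duplicated(paste(a, b))
      if (any(keep))
        g <- igraph::add_edges(g, rbind(a[keep], b[keep]))
    }
  }
  g
}

#' Prune a redundancy graph by iterative maximum-degree deletion
#'
#' Repeatedly recomputes node degrees, deletes one node of maximum degree
#' together with its incident edges, and stops when every remaining node has
#' degree zero. Ties at the maximum degree are broken lexicographically by
#' case id by default (reproducible), or uniformly at random when `seed` is
#' given. Isolated nodes are never removed, so the retained set always
#' contains every node that was never redundant with anything.
#'
#' @param g `igraph` undirected graph with named vertices (see
#'   [build_graph()]).
#' @param seed optional integer; when given, maximum-degree ties are broken
#'   by a seeded uniform draw instead of lexicographic order.
#' @return list with `retained` (character vector of surviving case ids,
#'   sorted) and `log` (data.frame `step`, `removed`, `degree` in removal
#'   order).
#' @export
prune_max_degree <- function(g, seed = NULL) {
  stopifnot(igraph::is_igraph(g))
  log_removed <- character(0)
  log_degree <- integer(0)
  run <- function() {
    repeat {
      deg <- igraph::degree(g)
      dmax <- if (length(deg)) max(deg) else 0L
      if (dmax == 0L) break
      cand <- sort(names(deg)[deg == dmax])
      victim <- if (is.null(seed)) cand[1] else sample(cand, 1)
      log_removed <<- c(log_removed, victim)
      log_degree <<- c(log_degree, dmax)
      g <<- igraph::delete_vertices(g, victim)
    }
  }
  if (is.null(seed)) run() else with_seed(seed, run())
  list(
    retained = sort(igraph::V(g)$name),
    log = data.frame(step = seq_along(log_removed), removed = log_removed,
                     degree = log_degree, stringsAsFactors = FALSE)
  )
}

#' Pairwise redundancy verdicts for a set of cases
#'
#' Evaluates every unordered pair: per-chain-type sequence identity (from a
#' hits table or computed by alignment) and, only where all chain types
#' match, the whole-complex C-alpha RMSD via `rmsd_provider`.
#'
#' @param cases list of `abag_case`.
#' @param hits optional data.frame with columns `case_a`, `case_b`,
#'   `chain_type`, `identity`, `e_value` giving the best alignment per chain
#'   type for each pair. When `NULL`, identity is computed from the stored
#'   sequences with an end-gap-free alignment and the E-value surrogate is
#'   0 for identity above the threshold region (suitable for synthetic
#'   fixtures and local curation without a search engine).
#' @param rmsd_provider function(case_a, case_b) -> RMSD in Angstrom;
#'   defaults to [case_ca_rmsd()]. A provider failure marks the pair
#'   `unresolved` instead of silently deciding.
#' @param config thresholds, see [run_config()].
#' @return data.frame `case_a, case_b, sequence_redundant, rmsd, redundant,
#'   unresolved`.
#' @export
redundancy_verdicts <- function(cases, hits = NULL,
                                rmsd_provider = case_ca_rmsd,
                                config = run_config()) {
  ids <- vapply(cases, function(cs) cs$case_id, character(1))
  names(cases) <- ids
  n <- length(cases)
  rows <- list(); k <- 0L
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      a <- cases[[i]]; b <- cases[[j]]
      flags <- pair_sequence_flags(a, b, hits, config)
      seq_red <- all(flags)
      rmsd <- NA_real_; red <- FALSE; unresolved <- FALSE
      if (seq_red) {
        rmsd <- tryCatch(rmsd_provider(a, b), error = function(e) NA_real_)
        if (is.na(rmsd)) unresolved <- TRUE
        else red <- rmsd < config$redundant_rmsd_max
      }
      k <- k + 1L
      rows[[k]] <- data.frame(case_a = ids[i], case_b = ids[j],
                              sequence_redundant = seq_red, rmsd = rmsd,
                              redundant = red, unresolved = unresolved,
                              stringsAsFactors = FALSE)
    }
  }
  if (!k) return(data.frame(case_a = character(0), case_b = character(0),
                            sequence_redundant = logical(0),
                            rmsd = numeric(0), redundant = logical(0),
                            unresolved = logical(0)))
  do.call(rbind, rows)
}

# per-chain-type sequence flags for one pair; chain types correspond by
# role order (antibody chains in order, then antigen chains)
pair_sequence_flags <- function(a, b, hits, config) {
  ch_a <- c(a$antibody_chains, a$antigen_chains)
  ch_b <- c(b$antibody_chains, b$antigen_chains)
  if (length(ch_a) != length(ch_b)) return(FALSE)
  if (!is.null(hits)) {
    sub <- hits[(hits$case_a == a$case_id & hits$case_b == b$case_id) |
                  (hits$case_a == b$case_id & hits$case_b == a$case_id),
                , drop = FALSE]
    if (!nrow(sub)) return(FALSE)
    return(vapply(split(sub, sub$chain_type), function(s) {
      best <- s[which.max(s$identity), , drop = FALSE]
      sequence_redundant(best, config)
    }, logical(1)))
  }
  vapply(seq_along(ch_a), function(k) {
    sa <- chain_sequence(a$bound, ch_a[k])
    sb <- chain_sequence(b$bound, ch_b[k])
    cols <- aligned_columns(sa, sb)
    idn <- if (nrow(cols))
      mean(strsplit(sa, "")[[1]][cols$i] == strsplit(sb, "")[[1]][cols$j])
    else 0
    # local surrogate: a chain-length alignment has a vanishing E-value,
    # a fragmentary one is non-significant
    ev <- if (nrow(cols) >= 20) 1e-60 else 10
    sequence_redundant(data.frame(identity = idn, e_value = ev), config)
  }, logical(1))
}

#' Fraction identical positions between two sequences
#'
#' End-gap-free global alignment; identity = identical columns over aligned
#' (match/mismatch) columns.
#'
#' @param seq_a,seq_b character strings (1-letter amino-acid codes).
#' @return fraction in `[0,1]`.
#' @export
sequence_identity <- function(seq_a, seq_b) {
  cols <- aligned_columns(seq_a, seq_b)
  if (!nrow(cols)) return(0)
  a <- strsplit(seq_a, "")[[1]][cols$i]
  b <- strsplit(seq_b, "")[[1]][cols$j]
  mean(a == b)
}

#' Whole-complex C-alpha RMSD between two cases
#'
#' Chain correspondence follows the antibody/antigen roles; residues are
#' mapped by sequence alignment, C-alpha coordinates pooled over all chains,
#' and the RMSD computed after a single least-squares superposition of the
#' pooled set.
#'
#' @param a,b `abag_case` objects with the same chain-type composition.
#' @return RMSD in Angstrom.
#' @export
case_ca_rmsd <- function(a, b) {
  ch_a <- c(a$antibody_chains, a$antigen_chains)
  ch_b <- c(b$antibody_chains, b$antigen_chains)
  if (length(ch_a) != length(ch_b))
    stop("cases have different chain-type composition")
  xa <- list(); xb <- list()
  for (k in seq_along(ch_a)) {
    map <- residue_map(a$bound, b$bound, ch_a[k], ch_b[k])
    ca_a <- ca_lookup(a$bound, ch_a[k])
    ca_b <- ca_lookup(b$bound, ch_b[k])
    ka <- res_key(map$chain_b, map$resno_b, map$insert_b)
    kb <- res_key(map$chain_u, map$resno_u, map$insert_u)
    ok <- ka %in% rownames(ca_a) & kb %in% rownames(ca_b)
    xa[[k]] <- ca_a[ka[ok], , drop = FALSE]
    xb[[k]] <- ca_b[kb[ok], , drop = FALSE]
  }
  A <- do.call(rbind, xa); B <- do.call(rbind, xb)
  if (nrow(A) < 3) stop("fewer than 3 mapped C-alpha atoms")
  kabsch_superpose(A, B)$fit_rmsd
}

# C-alpha coordinates of one chain keyed by residue
ca_lookup <- function(model, chain) {
  at <- model$atoms
  sel <- at$chain == chain & at$name == "CA" & !at$hydrogen
  at <- at[sel, , drop = FALSE]
  m <- cbind(at$x, at$y, at$z)
  rownames(m) <- res_key(at$chain, at$resno, at$insert)
  m
}

#' Remove redundancy from a set of cases
#'
#' Convenience wrapper: verdicts, graph, prune.
#'
#' @inheritParams redundancy_verdicts
#' @param seed optional tie-break seed forwarded to [prune_max_degree()].
#' @return list `retained`, `log`, `verdicts`, `graph`.
#' @export
dedupe_cases <- function(cases, hits = NULL, rmsd_provider = case_ca_rmsd,
                         config = run_config(), seed = NULL) {
  v <- redundancy_verdicts(cases, hits, rmsd_provider, config)
  ids <- vapply(cases, function(cs) cs$case_id, character(1))
  g <- build_graph(v, ids)
  pr <- prune_max_degree(g, seed = seed)
  c(pr, list(verdicts = v, graph = g))
}

#' Incrementally update a stored non-redundant benchmark
#'
#' New cases are compared with every stored case (and with each other) under
#' the sequence (identity > 60%, E < 1e-30) and structure (RMSD < 5 A)
#' criteria. A new case similar to nothing establishes a distinct group and
#' is added outright. Cases similar to something form redundant groups
#' (connected components with at least one edge); maximum-degree pruning is
#' re-run on each such component only, so untouched stored cases are never
#' reconsidered. The result is again edge-free.
#'
#' @param stored character vector of stored case ids OR list of stored
#'   `abag_case` (ids are taken from the cases). Assumed internally
#'   non-redundant (edge-free) — the output of a previous prune.
#' @param new_cases list of `abag_case` to consider adding.
#' @param stored_cases list of stored `abag_case` when `stored` is an id
#'   vector (needed to compare structures).
#' @param hits optional pairwise hits table (see [redundancy_verdicts()]).
#' @param rmsd_provider function(case_a, case_b) -> RMSD; failures flag the
#'   pair unresolved and the affected new case is NOT added.
#' @param config thresholds, see [run_config()].
#' @param seed optional tie-break seed.
#' @return list `retained` (updated id set), `added`, `removed`,
#'   `unresolved` (new case ids whose comparisons failed), `log`.
#' @export
update_benchmark <- function(stored, new_cases, stored_cases = NULL,
                             hits = NULL, rmsd_provider = case_ca_rmsd,
                             config = run_config(), seed = NULL) {
  if (is.character(stored)) {
    stored_ids <- stored
    stored_cases <- stored_cases %||% list()
  } else {
    stored_cases <- stored
    stored_ids <- vapply(stored_cases, function(cs) cs$case_id, character(1))
  }
  if (length(new_cases) == 0)
    return(list(retained = sort(stored_ids), added = character(0),
                removed = character(0), unresolved = character(0),
                log = data.frame(step = integer(0), removed = character(0),
                                 degree = integer(0))))

  new_ids <- vapply(new_cases, function(cs) cs$case_id, character(1))
  all_cases <- c(stored_cases, new_cases)
  names(all_cases) <- c(vapply(stored_cases, function(cs) cs$case_id,
                               character(1)), new_ids)

  # verdicts for new-vs-stored and new-vs-new pairs only (the stored set is
  # edge-free by precondition)
  rows <- list(); k <- 0L; unresolved <- character(0)
  for (m in seq_along(new_ids)) {
    ni <- new_ids[m]
    others <- c(stored_ids, new_ids[seq_len(m - 1L)])
    for (oi in others) {
      a <- all_cases[[ni]]; b <- all_cases[[oi]]
      if (is.null(a) || is.null(b)) next
      flags <- pair_sequence_flags(a, b, hits, config)
      seq_red <- all(flags)
      rmsd <- NA_real_; red <- FALSE
      if (seq_red) {
        rmsd <- tryCatch(rmsd_provider(a, b), error = function(e) NA_real_)
        if (is.na(rmsd)) unresolved <- union(unresolved, ni)
        else red <- rmsd < config$redundant_rmsd_max
      }
      k <- k + 1L
      rows[[k]] <- data.frame(case_a = ni, case_b = oi,
                              redundant = red, stringsAsFactors = FALSE)
    }
  }
  verdicts <- if (k) do.call(rbind, rows)
  else data.frame(case_a = character(0), case_b = character(0),
                  redundant = logical(0))

  usable_new <- setdiff(new_ids, unresolved)
  g <- build_graph(verdicts[verdicts$case_a %in% c(stored_ids, usable_new) &
                              verdicts$case_b %in% c(stored_ids, usable_new),
                            , drop = FALSE],
                   c(stored_ids, usable_new))

  comp <- igraph::components(g)
  retained <- character(0)
  logs <- list()
  for (cid in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == cid]
    sub <- igraph::induced_subgraph(g, members)
    if (igraph::ecount(sub) == 0) {
      retained <- c(retained, members)
    } else {
      pr <- prune_max_degree(sub, seed = seed)
      retained <- c(retained, pr$retained)
      logs[[length(logs) + 1]] <- pr$log
    }
  }
  log <- if (length(logs)) do.call(rbind, logs)
  else data.frame(step = integer(0), removed = character(0),
                  degree = integer(0))
  list(retained = sort(retained),
       added = sort(setdiff(intersect(retained, new_ids), stored_ids)),
       removed = sort(setdiff(stored_ids, retained)),
       unresolved = sort(unresolved),
       log = log)
}

#' Write / read the retained-set manifest and removal log
#'
#' @param result output of [dedupe_cases()] or [update_benchmark()].
#' @param manifest_path CSV path for the retained ids.
#' @param log_path optional JSON-lines path for the removal log.
#' @export
write_retained_manifest <- function(result, manifest_path, log_path = NULL) {
  utils::write.csv(data.frame(case_id = result$retained),
                   manifest_path, row.names = FALSE)
  if (!is.null(log_path)) {
    con <- file(log_path, "w"); on.exit(close(con))
    if (nrow(result$log)) {
      for (i in seq_len(nrow(result$log)))
        writeLines(jsonlite::toJSON(as.list(result$log[i, ]),
                                    auto_unbox = TRUE), con)
    }
  }
  invisible(manifest_path)
}
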