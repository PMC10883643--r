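# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's blocked distance search, igraph machinery and Kabsch
# implementation so that agreement is a genuine cross-check.

# O(N^2) residue-level interface scan: full distance matrix, no blocking.
brute_interface <- function(case, cutoff) {
  at <- case$bound$atoms[!case$bound$atoms$hydrogen, , drop = FALSE]
  ab <- at[at$chain %in% case$antibody_chains, , drop = FALSE]
  ag <- at[at$chain %in% case$antigen_chains, , drop = FALSE]
  d <- sqrt(outer(ab$x, ag$x, "-")^2 + outer(ab$y, ag$y, "-")^2 +
              outer(ab$z, ag$z, "-")^2)
  hit <- d <= cutoff
  rkey <- function(df) paste(df$chain, df$resno, df$insert)
  list(
    antibody = sort(unique(rkey(ab)[apply(hit, 1, any)])),
    antigen = sort(unique(rkey(ag)[apply(hit, 2, any)]))
  )
}

# O(N^2) residue-pair contact scan.
brute_contacts <- function(case, cutoff) {
  at <- case$bound$atoms[!case$bound$atoms$hydrogen, , drop = FALSE]
  ab <- at[at$chain %in% case$antibody_chains, , drop = FALSE]
  ag <- at[at$chain %in% case$antigen_chains, , drop = FALSE]
  d <- sqrt(outer(ab$x, ag$x, "-")^2 + outer(ab$y, ag$y, "-")^2 +
              outer(ab$z, ag$z, "-")^2)
  idx <- which(d <= cutoff, arr.ind = TRUE)
  rkey <- function(df, i) paste(df$chain[i], df$resno[i], df$insert[i])
  sort(unique(paste(rkey(ab, idx[, 1]), rkey(ag, idx[, 2]), sep = "~")))
}

# canonical keys for the package's outputs, comparable with the above
iface_keys <- function(res) sort(paste(res$chain, res$resno, res$insert))
contact_key_strings <- function(ct) {
  sort(paste(paste(ct$chain_ab, ct$resno_ab, ct$insert_ab),
             paste(ct$chain_ag, ct$resno_ag, ct$insert_ag), sep = "~"))
}

# Independent re-implementation of the greedy max-degree deletion loop on a
# plain adjacency matrix (lexicographic tie-break).
brute_prune <- function(adj, ids) {
  stopifnot(nrow(adj) == length(ids))
  alive <- rep(TRUE, length(ids))
  repeat {
    deg <- rowSums(adj[alive, alive, drop = FALSE])
    if (!length(deg) || max(deg) == 0) break
    cand <- ids[alive][deg == max(deg)]
    victim <- sort(cand)[1]
    alive[match(victim, ids)] <- FALSE
  }
  sort(ids[alive])
}

# adjacency matrix of labelled graph number `code` on n nodes (edge bits in
# fixed pair order)
graph_from_code <- function(code, n) {
  adj <- matrix(0L, n, n)
  k <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (bitwAnd(code, bitwShiftL(1L, k)) != 0L) adj[i, j] <- adj[j, i] <- 1L
    k <- k + 1L
  }
  adj
}

adj_to_verdicts <- function(adj, ids) {
  idx <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(case_a = character(0), case_b = character(0),
                      redundant = logical(0)))
  data.frame(case_a = ids[idx[, 1]], case_b = ids[idx[, 2]],
             redundant = TRUE, stringsAsFactors = FALSE)
}

# retained set is independent in the original adjacency?
is_independent <- function(retained, adj, ids) {
  sel <- match(retained, ids)
  all(adj[sel, sel] == 0L)
}

# small random fixture for metric oracle scans (<= 500 atoms)
random_small_case <- function(seed) {
  pert <- c("none", "rigid_shift")[1 + seed %% 2]
  mag <- if (pert == "none") 0 else 0.5 + (seed %% 5) / 2
  side <- c("antigen", "antibody", "both")[1 + seed %% 3]
  generate_toy_case(
    fixture_spec(n_res_ab = 45L, n_res_ag = 40L,
                 approach = 4 + (seed %% 2) * 0.4,
                 perturbation = pert, magnitude = mag,
                 perturb_side = side, seed = seed),
    case_id = sprintf("rnd%03d", seed))
}
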