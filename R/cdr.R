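## CDR loops and framework masks ----------------------------------------
##
## CDR boundaries follow Chothia numbering and arrive as an annotation
## (per chain: CDR1/2/3 residue-number ranges) produced by an external
## numbering tool or by the fixture generator; the toolkit does not infer
## numbering from sequence.

#' Chothia CDR ranges
#'
#' Standard Chothia loop boundaries in Chothia numbering, usable as a
#' default annotation for chains that are already Chothia-numbered.
#'
#' @param role `"heavy"` or `"light"` (single-domain antibodies use the
#'   heavy-chain definitions).
#' @return data.frame `cdr`, `start`, `end`.
#' @export
chothia_cdr_ranges <- function(role = c("heavy", "light")) {
  role <- match.arg(role)
  if (role == "heavy")
    data.frame(cdr = c("CDR1", "CDR2", "CDR3"),
               start = c(26L, 52L, 95L), end = c(32L, 56L, 102L))
  else
    data.frame(cdr = c("CDR1", "CDR2", "CDR3"),
               start = c(24L, 50L, 89L), end = c(34L, 56L, 97L))
}

#' Read / write a CDR annotation table
#'
#' Tab-separated columns: `chain`, `cdr` (CDR1/CDR2/CDR3), `start`, `end`
#' (inclusive residue numbers; insertion codes within the range belong to
#' the loop).
#'
#' @param path TSV path.
#' @return data.frame of class `abag_cdr_annotation`.
#' @export
read_cdr_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chain", "cdr", "start", "end")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  class(ann) <- c("abag_cdr_annotation", "data.frame")
  ann
}

#' @rdname read_cdr_annotation
#' @param annotation annotation data.frame.
#' @export
write_cdr_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Per-CDR C-alpha RMSD between bound and unbound antibody
#'
#' The unbound antibody is superposed onto the bound one over the framework
#' (all non-CDR) C-alpha atoms; each CDR's RMSD is then measured over that
#' loop's mapped C-alpha atoms without refitting, so loop motion relative
#' to a fixed framework is what is reported. A CDR whose range has no
#' mapped residues in the unbound structure is reported `NA`; the others
#' are still computed.
#'
#' @param case `abag_case` with an unbound antibody.
#' @param annotation CDR annotation (see [read_cdr_annotation()]); defaults
#'   to the annotation stored on the case.
#' @param maps optional precomputed [case_maps()] result.
#' @return named numeric vector, one value per `chain.cdr` (single antibody
#'   chain: plain CDR names).
#' @export
cdr_rmsd <- function(case, annotation = case$cdr_annotation, maps = NULL) {
  if (is.null(annotation)) stop("no CDR annotation available")
  if (!length(case$unbound_antibody)) stop("case has no unbound antibody")
  maps <- maps %||% case_maps(case)
  unb <- case$unbound_antibody[[1]]

  in_range <- function(resno, chain, ann_chain) {
    hit <- rep(FALSE, length(resno))
    sub <- annotation[annotation$chain == ann_chain, , drop = FALSE]
    for (i in seq_len(nrow(sub)))
      hit <- hit | (resno >= sub$start[i] & resno <= sub$end[i])
    hit
  }

  # framework fit over all antibody chains jointly
  fa <- list(); fb <- list(); k <- 0L
  loop_pairs <- list()
  for (mp in maps$antibody) {
    ch <- mp$chain_b[1]
    ca_b <- ca_lookup(case$bound, ch)
    ca_u <- ca_lookup(unb, mp$chain_u[1])
    kb <- res_key(mp$chain_b, mp$resno_b, mp$insert_b)
    ku <- res_key(mp$chain_u, mp$resno_u, mp$insert_u)
    ok <- kb %in% rownames(ca_b) & ku %in% rownames(ca_u)
    cdr_flag <- in_range(mp$resno_b, ch, ch)
    fw <- ok & !cdr_flag
    if (any(fw)) {
      k <- k + 1L
      fa[[k]] <- ca_b[kb[fw], , drop = FALSE]
      fb[[k]] <- ca_u[ku[fw], , drop = FALSE]
    }
    sub <- annotation[annotation$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      inloop <- ok & mp$resno_b >= sub$start[i] & mp$resno_b <= sub$end[i]
      nm <- if (length(maps$antibody) > 1) paste(ch, sub$cdr[i], sep = ".")
      else sub$cdr[i]
      loop_pairs[[nm]] <- list(
        bound = ca_b[kb[inloop], , drop = FALSE],
        unbound = ca_u[ku[inloop], , drop = FALSE]
      )
    }
  }
  if (!k) stop("no mapped framework C-alpha atoms for the superposition")
  sup <- kabsch_superpose(do.call(rbind, fa), do.call(rbind, fb))

  vapply(loop_pairs, function(lp) {
    if (!nrow(lp$bound)) return(NA_real_)
    fitted <- apply_superposition(lp$unbound, sup)
    sqrt(mean(rowSums((lp$bound - fitted)^2)))
  }, numeric(1))
}

#' Antibody framework residue ranges masked during docking
#'
#' Chothia-numbered framework blocks excluded from predicted interfaces so
#' docking favours the CDRs. Heavy chain: 6-22, 39-46, 81-91, 106-end;
#' light chain: 7-20, 38-44, 76-85, 101-end (`end = Inf` denotes the chain
#' terminus). Defined for antibody chains only.
#'
#' @param role `"heavy"` or `"light"`.
#' @return data.frame `start`, `end` (4 rows).
#' @export
framework_block_ranges <- function(role = c("heavy", "light")) {
  role <- tryCatch(match.arg(role), error = function(e)
    stop("framework blocks are defined for antibody chains only ",
         "(role must be 'heavy' or 'light')"))
  if (role == "heavy")
    data.frame(start = c(6L, 39L, 81L, 106L), end = c(22, 46, 91, Inf))
  else
    data.frame(start = c(7L, 38L, 76L, 101L), end = c(20, 44, 85, Inf))
}
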