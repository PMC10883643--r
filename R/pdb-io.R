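## Structure model ------------------------------------------------------
##
## An abag_structure is a cleaned, ATOM-only coordinate set:
##   id           - structure identifier (PDB id, optionally "_1"/"_2" for a
##                  split interface)
##   atoms        - data.frame, one row per atom, file order preserved:
##                  serial, name, altloc, resname, chain, resno, insert,
##                  x, y, z, occ, element, hydrogen (logical)
##   roles        - named character: chain id -> one of "heavy", "light",
##                  "single_domain", "antigen", "unknown"
##   resolution   - Angstrom or NA
##   release_date - Date or NA

# 3-letter -> 1-letter amino-acid codes; nonstandard residues observed in
# ATOM records are mapped to their nearest standard parent for sequence
# derivation (coordinates keep the original residue name).
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V",
  MSE = "M", SEC = "C", PYL = "K", HYP = "P", MLY = "K", CSO = "C",
  PTR = "Y", SEP = "S", TPO = "T"
)

res_key <- function(chain, resno, insert) paste(chain, resno, insert, sep = "|")

guess_element <- function(name) {
  # PDB atom-name conventions: strip digits/primes, element is the leading
  # alphabetic part; two-character elements in protein chains are rare
  # (SE of selenomethionine handled via the element column when present).
  nm <- gsub("[^A-Za-z]", "", name)
  ifelse(nchar(nm) == 0, "", toupper(substr(nm, 1, 1)))
}

#' Read a PDB-format structure, keeping ATOM records only
#'
#' Parses fixed-column ATOM records from PDB text. HETATM, ANISOU, waters
#' and everything that is not an ATOM coordinate record are dropped, so the
#' result holds only the polymer coordinates a docking benchmark file keeps.
#' Only the first NMR model is read. Hydrogens are retained in the atom
#' table but flagged, and every distance-based computation in the package
#' ignores them.
#'
#' @param pdb_text character: either a file path or PDB-format text
#'   (single string with newlines, or a character vector of lines).
#' @param altloc_policy how to collapse alternate locations:
#'   `"highest_occupancy"` (default; ties broken by the alphabetically first
#'   altloc id) or `"first"` (first record encountered wins).
#' @param id structure identifier; defaults to the file base name or "model".
#' @return an object of class `abag_structure`.
#' @export
read_structure <- function(pdb_text,
                           altloc_policy = c("highest_occupancy", "first"),
                           id = NULL) {
  altloc_policy <- match.arg(altloc_policy)
  if (length(pdb_text) == 1 && !grepl("\n", pdb_text) &&
      file.exists(pdb_text)) {
    if (is.null(id))
      id <- sub("\\.(pdb|ent)$", "", basename(pdb_text), ignore.case = TRUE)
    lines <- readLines(pdb_text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(pdb_text, "\n", fixed = TRUE), use.names = FALSE)
  }
  if (is.null(id)) id <- "model"

  # first model only
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]

  resolution <- NA_real_
  rl <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
  if (length(rl)) {
    m <- regmatches(rl[1], regexpr("[0-9]+\\.?[0-9]*(?= +ANGSTROM)",
                                   rl[1], perl = TRUE))
    if (length(m)) resolution <- as.numeric(m)
  }

  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "ATOM ")
  idx <- which(is_atom)
  if (!length(idx)) stop("no ATOM records found: empty model")
  rec <- lines[idx]

  f <- function(s, e) substr(rec, s, e)
  num <- function(s, e, what) {
    raw <- trimws(f(s, e))
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop(sprintf("malformed %s field in ATOM record at line %d: '%s'",
                   what, idx[bad[1]], lines[idx[bad[1]]]))
    v
  }

  atoms <- data.frame(
    serial  = suppressWarnings(as.integer(trimws(f(7, 11)))),
    name    = trimws(f(13, 16)),
    altloc  = trimws(f(17, 17)),
    resname = trimws(f(18, 20)),
    chain   = f(22, 22),
    resno   = suppressWarnings(as.integer(trimws(f(23, 26)))),
    insert  = trimws(f(27, 27)),
    x = num(31, 38, "x-coordinate"),
    y = num(39, 46, "y-coordinate"),
    z = num(47, 54, "z-coordinate"),
    occ = {
      o <- suppressWarnings(as.numeric(trimws(f(55, 60))))
      o[is.na(o)] <- 1
      o
    },
    element = trimws(f(77, 78)),
    stringsAsFactors = FALSE
  )
  bad_res <- which(is.na(atoms$resno))
  if (length(bad_res))
    stop(sprintf("malformed residue number in ATOM record at line %d",
                 idx[bad_res[1]]))
  atoms$element <- ifelse(atoms$element == "",
                          guess_element(atoms$name), toupper(atoms$element))
  atoms$hydrogen <- atoms$element %in% c("H", "D")

  # drop waters however they were recorded
  atoms <- atoms[!(atoms$resname %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (!nrow(atoms)) stop("no ATOM records found: empty model")

  # collapse altlocs per (chain, resno, insert, name)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, sep = "|")
  if (anyDuplicated(key)) {
    if (altloc_policy == "first") {
      keep <- !duplicated(key)
    } else {
      ord <- order(key, -atoms$occ, atoms$altloc)
      keep_rows <- ord[!duplicated(key[ord])]
      keep <- logical(nrow(atoms)); keep[keep_rows] <- TRUE
    }
    atoms <- atoms[keep, , drop = FALSE]
  }
  rownames(atoms) <- NULL

  chains <- unique(atoms$chain)
  roles <- stats::setNames(rep("unknown", length(chains)), chains)
  structure(
    list(id = id, atoms = atoms, roles = roles,
         resolution = resolution, release_date = as.Date(NA)),
    class = "abag_structure"
  )
}

#' Write a structure as PDB ATOM records
#'
#' Emits fixed-column ATOM lines in input atom order, a TER record after each
#' chain, and END. Chain ids, residue numbering and insertion codes are
#' preserved verbatim.
#'
#' @param model an `abag_structure`.
#' @param path optional file path; when `NULL` the text is returned invisibly.
#' @return the PDB text, invisibly, as a single string.
#' @export
write_structure <- function(model, path = NULL) {
  stopifnot(inherits(model, "abag_structure"))
  at <- model$atoms
  if (is.null(at) || nrow(at) == 0)
    stop("cannot write an empty structure (no chains/atoms)")
  if (any(abs(at$x) >= 10000 | abs(at$y) >= 10000 | abs(at$z) >= 10000) ||
      any(at$x <= -1000 | at$y <= -1000 | at$z <= -1000))
    stop("coordinates exceed the PDB fixed-width %8.3f field")

  fmt_name <- function(name, element) {
    # element symbol occupies columns 13-14; single-letter elements with
    # short names are right-shifted one column per PDB convention
    ifelse(nchar(name) >= 4 | nchar(element) >= 2,
           formatC(name, width = -4),
           formatC(paste0(" ", name), width = -4))
  }
  serial <- seq_len(nrow(at))
  lines <- sprintf(
    "ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    serial, fmt_name(at$name, at$element), at$altloc, at$resname,
    at$chain, at$resno, at$insert, at$x, at$y, at$z, at$occ, 0,
    at$element
  )
  # TER after each chain block
  out <- character(0)
  for (ch in unique(at$chain)) {
    rows <- which(at$chain == ch)
    out <- c(out, lines[rows], "TER")
  }
  out <- c(out, "END")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(out, path)
  invisible(txt)
}

#' @export
print.abag_structure <- function(x, ...) {
  at <- x$atoms
  nres <- length(unique(res_key(at$chain, at$resno, at$insert)))
  cat(sprintf("<abag_structure> %s: %d chains (%s), %d residues, %d atoms\n",
              x$id, length(unique(at$chain)),
              paste(unique(at$chain), collapse = ","),
              nres, nrow(at)))
  invisible(x)
}

#' Chain ids of a structure
#' @param model an `abag_structure`.
#' @return character vector of chain identifiers in file order.
#' @export
chain_ids <- function(model) unique(model$atoms$chain)

#' Residue table of one chain
#'
#' @param model an `abag_structure`.
#' @param chain chain id.
#' @return data.frame (chain, resno, insert, resname) in file order, one row
#'   per residue.
#' @export
chain_residues <- function(model, chain) {
  at <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  if (!nrow(at)) stop(sprintf("chain '%s' not present (available: %s)",
                              chain, paste(chain_ids(model), collapse = ", ")))
  key <- res_key(at$chain, at$resno, at$insert)
  first <- !duplicated(key)
  data.frame(chain = at$chain[first], resno = at$resno[first],
             insert = at$insert[first], resname = at$resname[first],
             stringsAsFactors = FALSE)
}

#' One-letter sequence of a chain
#'
#' Derived from residue names; nonstandard residues map to their standard
#' parent (e.g. MSE to M), unknowns to X.
#'
#' @inheritParams chain_residues
#' @return single character string.
#' @export
chain_sequence <- function(model, chain) {
  res <- chain_residues(model, chain)
  letters1 <- AA3TO1[res$resname]
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}

#' Subset a structure to named chains
#' @param model an `abag_structure`.
#' @param chains chain ids to keep.
#' @param id id for the subset (default: same as input).
#' @return `abag_structure` containing only the named chains.
#' @export
subset_chains <- function(model, chains, id = model$id) {
  missing <- setdiff(chains, chain_ids(model))
  if (length(missing))
    stop(sprintf("chain id(s) %s not present; available: %s",
                 paste(missing, collapse = ", "),
                 paste(chain_ids(model), collapse = ", ")))
  out <- model
  out$id <- id
  out$atoms <- model$atoms[model$atoms$chain %in% chains, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out$roles <- model$roles[names(model$roles) %in% chains]
  out
}

# non-hydrogen coordinate matrix (optionally restricted to atom names)
atom_coords <- function(model, names = NULL, heavy_only = TRUE) {
  at <- model$atoms
  if (heavy_only) at <- at[!at$hydrogen, , drop = FALSE]
  if (!is.null(names)) at <- at[at$name %in% names, , drop = FALSE]
  list(coords = cbind(at$x, at$y, at$z), atoms = at)
}

# apply rigid motion (rotation R then translation t) to all atoms
transform_structure <- function(model, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- cbind(model$atoms$x, model$atoms$y, model$atoms$z)
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}
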