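## Least-squares superposition ------------------------------------------

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation mapping coordinate set `b` onto
#' `a` with minimum RMSD (SVD of the cross-covariance, reflection corrected
#' so the rotation determinant is +1).
#'
#' @param a,b numeric N x 3 matrices of paired coordinates (Angstrom),
#'   N >= 3 and not collinear.
#' @return object of class `abag_superposition`: list with `rotation`
#'   (3 x 3), `translation` (length 3) and `fit_rmsd` (Angstrom). The fitted
#'   copy of `b` is `b %*% t(rotation) + translation` rowwise (see
#'   [apply_superposition()]).
#' @export
kabsch_superpose <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == 3, ncol(b) == 3)
  if (nrow(a) != nrow(b)) stop("coordinate sets must have equal lengths")
  if (nrow(a) < 3) stop("at least 3 paired points are required")
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  if (svd(ac)$d[2] < 1e-8 || svd(bc)$d[2] < 1e-8)
    stop("degenerate (collinear) coordinate set")
  H <- crossprod(bc, ac)           # sum over points of b_c a_c^T
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- ca - as.vector(R %*% cb)
  fitted <- bc %*% t(R)
  rmsd <- sqrt(mean(rowSums((ac - fitted)^2)))
  structure(list(rotation = R, translation = tr, fit_rmsd = rmsd),
            class = "abag_superposition")
}

#' Apply a superposition to coordinates
#' @param coords N x 3 matrix.
#' @param sup `abag_superposition` from [kabsch_superpose()].
#' @return transformed N x 3 matrix.
#' @export
apply_superposition <- function(coords, sup) {
  sweep(as.matrix(coords) %*% t(sup$rotation), 2, sup$translation, "+")
}

#' RMSD between two structures over a residue map
#'
#' Gathers the selected atoms of every mapped residue present in both
#' structures, superposes the second onto the first over that selection and
#' returns the post-fit RMSD.
#'
#' @param a,b `abag_structure` objects (e.g. bound and unbound).
#' @param map `abag_residue_map` (or list of maps, one per chain pair).
#' @param atom_selection `"CA"` (default), `"backbone"` (N, CA, C, O) or
#'   `"all"` (all non-hydrogen atoms matched by name within each residue).
#' @return RMSD in Angstrom.
#' @export
mapped_rmsd <- function(a, b, map, atom_selection = c("CA", "backbone", "all")) {
  atom_selection <- match.arg(atom_selection)
  pair <- mapped_coords(a, b, map, atom_selection)
  if (nrow(pair$a) == 0) stop("residue map is empty or maps no shared atoms")
  kabsch_superpose(pair$a, pair$b)$fit_rmsd
}

# paired coordinate matrices over a residue map for the given selection
mapped_coords <- function(a, b, map, atom_selection = "CA") {
  if (is.data.frame(map)) map <- list(map)
  sel_names <- switch(atom_selection,
                      CA = "CA",
                      backbone = c("N", "CA", "C", "O"),
                      all = NULL)
  xa <- list(); xb <- list(); k <- 0L
  for (mp in map) {
    if (!nrow(mp)) next
    at_a <- a$atoms[!a$atoms$hydrogen, , drop = FALSE]
    at_b <- b$atoms[!b$atoms$hydrogen, , drop = FALSE]
    if (!is.null(sel_names)) {
      at_a <- at_a[at_a$name %in% sel_names, , drop = FALSE]
      at_b <- at_b[at_b$name %in% sel_names, , drop = FALSE]
    }
    key_a <- paste(res_key(at_a$chain, at_a$resno, at_a$insert), at_a$name,
                   sep = "@")
    key_b <- paste(res_key(at_b$chain, at_b$resno, at_b$insert), at_b$name,
                   sep = "@")
    names_a <- if (is.null(sel_names)) unique(at_a$name) else sel_names
    for (nm in names_a) {
      want_a <- paste(res_key(mp$chain_b, mp$resno_b, mp$insert_b), nm,
                      sep = "@")
      want_b <- paste(res_key(mp$chain_u, mp$resno_u, mp$insert_u), nm,
                      sep = "@")
      ia <- match(want_a, key_a); ib <- match(want_b, key_b)
      ok <- !is.na(ia) & !is.na(ib)
      if (!any(ok)) next
      k <- k + 1L
      xa[[k]] <- cbind(at_a$x[ia[ok]], at_a$y[ia[ok]], at_a$z[ia[ok]])
      xb[[k]] <- cbind(at_b$x[ib[ok]], at_b$y[ib[ok]], at_b$z[ib[ok]])
    }
  }
  if (!k) return(list(a = matrix(numeric(0), 0, 3),
                      b = matrix(numeric(0), 0, 3)))
  list(a = do.call(rbind, xa), b = do.call(rbind, xb))
}
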