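#' Round half up
#'
#' Rounds to `digits` decimal places with ties going away from zero for
#' positive values (the convention that reproduces printed benchmark
#' percentages such as 27.68 and 57.14), unlike base [round()] which rounds
#' half to even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half up.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Percentage share, printed-style
#'
#' `part / whole * 100`, rounded half up to two decimals — the arithmetic
#' behind benchmark composition tables.
#'
#' @param part,whole numeric.
#' @return numeric percentage with two decimals.
#' @export
percent_share <- function(part, whole) {
  round_half_up(part / whole * 100, 2)
}

# Evaluate expr with the RNG seeded; restores the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# All cross-set atom pairs within `cutoff` Angstrom, computed in
# memory-bounded blocks; exact (no spatial approximation).
# a, b: numeric matrices n x 3. Returns data.frame(i, j) of row indices.
cross_pairs_within <- function(a, b, cutoff, block = 1500L) {
  stopifnot(ncol(a) == 3, ncol(b) == 3)
  cut2 <- cutoff^2
  acc <- list(); k <- 0L
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) return(data.frame(i = integer(0), j = integer(0)))
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  for (s in seq(1L, na, by = block)) {
    e <- min(s + block - 1L, na)
    ab <- a[s:e, , drop = FALSE]
    for (s2 in seq(1L, nb, by = block)) {
      e2 <- min(s2 + block - 1L, nb)
      bb <- b[s2:e2, , drop = FALSE]
      # squared distances via expansion: |x|^2 + |y|^2 - 2 x.y
      d2 <- outer(a2[s:e], b2[s2:e2], "+") - 2 * tcrossprod(ab, bb)
      hit <- which(d2 <= cut2, arr.ind = TRUE)
      if (nrow(hit)) {
        k <- k + 1L
        acc[[k]] <- cbind(hit[, 1L] + s - 1L, hit[, 2L] + s2 - 1L)
      }
    }
  }
  if (k == 0L) return(data.frame(i = integer(0), j = integer(0)))
  m <- do.call(rbind, acc)
  data.frame(i = m[, 1L], j = m[, 2L])
}

# Rotation matrix about unit axis u by angle theta (radians).
rotation_about_axis <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
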