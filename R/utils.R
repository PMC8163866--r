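# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded simulators never disturb the global stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a finite numeric scalar", name)
  if (x < lower || x > upper)
    stopf("`%s` = %g is outside [%g, %g]", name, x, lower, upper)
  invisible(x)
}

#' Moving-window box mean of a matrix (window w x w, w odd).
#'
#' Uses summed-area tables; windows are truncated at the borders, so every
#' output pixel is the mean over the intersection of the window with the
#' image (no padding bias).
#' @noRd
box_mean <- function(m, w) {
  if (w %% 2L != 1L || w < 1L) stopf("window must be odd and >= 1")
  if (w == 1L) return(m)
  h <- (w - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  # summed-area table with a zero border
  sat <- matrix(0, nr + 1L, nc + 1L)
  sat[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  r0 <- pmax(seq_len(nr) - h - 1L, 0L); r1 <- pmin(seq_len(nr) + h, nr)
  c0 <- pmax(seq_len(nc) - h - 1L, 0L); c1 <- pmin(seq_len(nc) + h, nc)
  S <- sat[r1 + 1L, c1 + 1L, drop = FALSE] - sat[r0 + 1L, c1 + 1L, drop = FALSE] -
    sat[r1 + 1L, c0 + 1L, drop = FALSE] + sat[r0 + 1L, c0 + 1L, drop = FALSE]
  cnt <- outer(r1 - r0, c1 - c0)
  S / cnt
}

#' Bilinear sampling of matrix `m` at fractional (row, col) positions.
#'
#' Positions are 1-based matrix coordinates. Outside the cell-centre hull the
#' boundary cell pair is extrapolated linearly, which keeps affine fields
#' exact across grid changes.
#' @noRd
bilinear_sample <- function(m, rows, cols) {
  nr <- nrow(m); nc <- ncol(m)
  i0 <- pmin(pmax(floor(rows), 1L), max(nr - 1L, 1L))
  j0 <- pmin(pmax(floor(cols), 1L), max(nc - 1L, 1L))
  fr <- rows - i0
  fc <- cols - j0
  i1 <- pmin(i0 + 1L, nr); j1 <- pmin(j0 + 1L, nc)
  v00 <- m[cbind(i0, j0)]; v10 <- m[cbind(i1, j0)]
  v01 <- m[cbind(i0, j1)]; v11 <- m[cbind(i1, j1)]
  v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
}

#' Dice coefficient of two logical masks.
#' @param a,b logical matrices of equal shape.
#' @return Scalar in [0, 1]; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(is.logical(a), is.logical(b), all(dim(a) == dim(b)))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Boundary pixels of a mask (pixels with at least one 4-neighbour outside).
#' @noRd
mask_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  mask & !inner
}

#' Symmetric Hausdorff distance between the boundaries of two masks
#'
#' Distances are Euclidean in pixel units over boundary pixels (pixels of a
#' mask with a 4-neighbour outside it).
#' @param a,b logical matrices of equal shape; both must be non-empty.
#' @return Distance in pixels.
#' @export
boundary_hausdorff <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  pa <- which(mask_boundary(a), arr.ind = TRUE)
  pb <- which(mask_boundary(b), arr.ind = TRUE)
  if (nrow(pa) == 0L || nrow(pb) == 0L)
    stopf("empty mask: Hausdorff distance undefined")
  d2 <- outer(pa[, 1L], pb[, 1L], "-")^2 + outer(pa[, 2L], pb[, 2L], "-")^2
  sqrt(max(max(apply(d2, 1L, min)), max(apply(d2, 2L, min))))
}
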