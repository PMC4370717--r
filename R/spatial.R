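# Contiguity matrices, Moran's I, the distance-class correlogram, and the
# permutation significance test used on model residuals.

#' Build a binary contiguity matrix from an edge list
#'
#' @param edges Data frame (or 2-column matrix) of unit-id pairs; each row says
#'   the two units are contiguous. Either order, duplicates allowed.
#' @param units Character vector of all unit ids (fixes matrix order).
#' @return Symmetric 0/1 matrix with zero diagonal and `units` as dimnames.
#' @examples
#' contiguity_matrix(data.frame(a = "A", b = "B"), units = c("A", "B", "C"))
#' @export
contiguity_matrix <- function(edges, units) {
  stopifnot(length(units) == length(unique(units)))
  units <- as.character(units)
  w <- matrix(0, length(units), length(units), dimnames = list(units, units))
  if (NROW(edges)) {
    a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
    if (any(a == b)) stop("self-edges are not allowed")
    bad <- setdiff(c(a, b), units)
    if (length(bad)) stop("edge endpoints not among units: ",
                          paste(unique(bad), collapse = ", "))
    w[cbind(a, b)] <- 1
    w[cbind(b, a)] <- 1
  }
  w
}

check_weights <- function(w) {
  if (!is.matrix(w) || nrow(w) != ncol(w) ||
      is.null(rownames(w)) || !identical(rownames(w), colnames(w)))
    stop("'w' must be a square matrix with matching row/column names")
  if (!isTRUE(all.equal(w, t(w)))) stop("'w' must be symmetric")
  if (any(diag(w) != 0)) stop("'w' must have a zero diagonal")
  invisible(w)
}

#' Moran's I spatial autocorrelation
#'
#' \deqn{I = \frac{n}{\sum_{ij} w_{ij}} \,
#'   \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}, \quad z_i = x_i - \bar x}
#' computed with the binary (non-row-standardised) weights used throughout the
#' package.
#'
#' @param x Numeric vector, one value per unit, in the order of `w` (or named
#'   and reordered to match).
#' @param w Contiguity/weights matrix ([contiguity_matrix()]).
#' @return A single number.
#' @export
morans_i <- function(x, w) {
  check_weights(w)
  if (!is.null(names(x))) {
    if (!identical(sort(names(x)), sort(rownames(w))))
      stop("names of 'x' do not match the units of 'w'")
    x <- x[rownames(w)]
  }
  n <- length(x)
  if (n != nrow(w)) stop("'x' and 'w' differ in size")
  if (n < 2) stop("need at least two units")
  s0 <- sum(w)
  if (s0 == 0) stop("weights sum to zero: no connected pairs")
  z <- x - mean(x)
  den <- sum(z^2)
  if (den == 0) stop("Moran's I undefined for a constant field")
  (n / s0) * as.numeric(crossprod(z, w %*% z)) / den
}

#' Moran's I correlogram over distance classes
#'
#' For each distance class `(lower, upper]` a binary weights matrix connects
#' unit pairs whose centroid distance falls in the class, and Moran's I is
#' computed. The class of maximal I identifies the scale of strongest spatial
#' autocorrelation (for contiguous administrative regions this is typically the
#' nearest-neighbour class).
#'
#' @param x Per-unit values (named or in `coords` order).
#' @param coords Two-column matrix/data.frame of centroid coordinates (km),
#'   one row per unit.
#' @param breaks Increasing numeric vector of class edges (km); class k is
#'   `(breaks[k], breaks[k+1]]`.
#' @param flat_tol If every |I| is below this, the correlogram is flagged flat
#'   (no stable scale of autocorrelation) with a warning.
#' @return An object of class `"fb_correlogram"`: data.frame `lower`, `upper`,
#'   `n_pairs`, `morans_i`, with attributes `peak` (index of the maximal-I
#'   class) and `flat`.
#' @export
moran_correlogram <- function(x, coords, breaks, flat_tol = 0.1) {
  coords <- as.matrix(coords)
  if (length(breaks) < 2) stop("need at least one distance class (two edges)")
  if (is.unsorted(breaks, strictly = TRUE)) stop("'breaks' must be increasing")
  d <- as.matrix(stats::dist(coords))
  units <- rownames(d) <- colnames(d) <-
    if (!is.null(names(x))) names(x) else as.character(seq_len(nrow(coords)))
  k <- length(breaks) - 1
  out <- data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
                    n_pairs = NA_integer_, morans_i = NA_real_)
  for (j in seq_len(k)) {
    w <- (d > out$lower[j] & d <= out$upper[j]) * 1
    diag(w) <- 0
    dimnames(w) <- list(units, units)
    out$n_pairs[j] <- sum(w) / 2
    if (sum(w) == 0) {
      warning("distance class (", out$lower[j], ", ", out$upper[j],
              "] contains no pairs; Moran's I missing")
      next
    }
    out$morans_i[j] <- morans_i(x, w)
  }
  ok <- !is.na(out$morans_i)
  peak <- if (any(ok)) which.max(replace(out$morans_i, !ok, -Inf)) else NA_integer_
  flat <- all(abs(out$morans_i[ok]) < flat_tol)
  if (flat) warning("flat correlogram: no distance class shows |I| >= ", flat_tol)
  structure(out, peak = peak, flat = flat, class = c("fb_correlogram", "data.frame"))
}

#' @export
print.fb_correlogram <- function(x, ...) {
  cat("Moran's I correlogram (", nrow(x), " distance classes)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  if (!is.na(attr(x, "peak")))
    cat("Maximal I in class (", x$lower[attr(x, "peak")], ", ",
        x$upper[attr(x, "peak")], "]\n", sep = "")
  if (isTRUE(attr(x, "flat"))) cat("Correlogram is flat.\n")
  invisible(x)
}

#' @export
plot.fb_correlogram <- function(x, ...) {
  mid <- (x$lower + x$upper) / 2
  graphics::plot(mid, x$morans_i, type = "b", pch = 19,
                 xlab = "distance class midpoint (km)", ylab = "Moran's I", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Permutation test for Moran's I
#'
#' Significance of spatial autocorrelation by random relabelling: values are
#' permuted over units `n_perm` times and the p-value is
#' `(1 + #permutations at least as extreme) / (n_perm + 1)`. This is the
#' standard randomisation test for Moran's I (sometimes loosely called a
#' bootstrap); two-sided on |I| by default.
#'
#' @inheritParams morans_i
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed (mandatory).
#' @param alternative `"two.sided"` (on |I|), `"greater"` or `"less"`.
#' @return List with `statistic` (observed I), `p_value`, `n_perm`,
#'   `alternative`.
#' @export
morans_i_test <- function(x, w, n_perm = 999, seed,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (missing(seed)) stop("'seed' is required")
  if (n_perm < 99) stop("use at least 99 permutations")
  check_weights(w)
  if (!is.null(names(x))) x <- x[rownames(w)]
  n <- length(x)
  s0 <- sum(w)
  z <- x - mean(x)
  den <- sum(z^2)
  if (den == 0) stop("Moran's I undefined for a constant field")
  i_of <- function(zz) (n / s0) * as.numeric(crossprod(zz, w %*% zz)) / den
  i_obs <- i_of(z)
  rng <- local_rng(seed)
  on.exit(rng())
  i_perm <- vapply(seq_len(n_perm), function(k) i_of(z[sample.int(n)]),
                   numeric(1))
  extreme <- switch(alternative,
                    two.sided = abs(i_perm) >= abs(i_obs),
                    greater = i_perm >= i_obs,
                    less = i_perm <= i_obs)
  list(statistic = i_obs, p_value = (1 + sum(extreme)) / (n_perm + 1),
       n_perm = n_perm, alternative = alternative)
}
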