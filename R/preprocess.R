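#' Filter genes with low or mostly-absent expression
#'
#' Retains exactly the genes whose mean expression over the diel cycle is at
#' least `min_mean` AND whose fraction of zero-valued sampling points is below
#' `max_zero_fraction`. Gene order is preserved; the operation is idempotent.
#'
#' @param m a [diel_matrix()].
#' @param min_mean minimum mean FPKM (default 0.01).
#' @param max_zero_fraction genes with at least this fraction of zero points
#'   are removed (default 0.5, i.e. "fewer than half the points zero").
#' @return A filtered `diel_matrix`; the number of removed genes is attached
#'   as attribute `n_removed`.
#' @export
filter_low_expression <- function(m, min_mean = 0.01, max_zero_fraction = 0.5) {
  stopifnot(inherits(m, "diel_matrix"),
            min_mean >= 0, max_zero_fraction >= 0, max_zero_fraction <= 1)
  if (length(m$timepoints) == 0L) stop("matrix has zero time points")
  means <- rowMeans(m$values)
  zfrac <- rowMeans(m$values == 0)
  keep <- means >= min_mean & zfrac < max_zero_fraction
  out <- diel_matrix(m$values[keep, , drop = FALSE], m$timepoints,
                     m$gene_ids[keep], m$species_id)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Drop genes with any negative expression value
#'
#' Negative values can arise upstream (e.g. from background-corrected
#' platforms or interpolation artifacts when clamping is disabled); such
#' genes are removed entirely.
#'
#' @param m a [diel_matrix()].
#' @return A `diel_matrix` containing only all-non-negative genes, with
#'   attribute `n_removed`.
#' @export
remove_negative <- function(m) {
  stopifnot(inherits(m, "diel_matrix"))
  keep <- rowSums(m$values < 0) == 0
  out <- diel_matrix(m$values[keep, , drop = FALSE], m$timepoints,
                     m$gene_ids[keep], m$species_id)
  attr(out, "n_removed") <- sum(!keep)
  out
}

# Not-a-knot cubic spline: solve for second derivatives M at the knots.
# Continuity of s'' at interior knots plus third-derivative continuity at the
# second and second-to-last knot (the "not-a-knot" conditions). Returns a
# function evaluating the spline; points beyond the knot span are evaluated
# with the first/last cubic piece (the spline's own polynomial extension).
not_a_knot_spline <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 4L, length(y) == n, !is.unsorted(x, strictly = TRUE))
  h <- diff(x)
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i]     <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    rhs[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  # (M2 - M1)/h1 == (M3 - M2)/h2  and the mirrored condition at the far end
  A[1, 1:3] <- c(h[2], -(h[1] + h[2]), h[1])
  A[n, (n - 2):n] <- c(h[n - 1], -(h[n - 2] + h[n - 1]), h[n - 2])
  M <- solve(A, rhs)
  function(t) {
    i <- findInterval(t, x, all.inside = TRUE)
    hi <- h[i]
    dl <- x[i + 1] - t
    dr <- t - x[i]
    M[i] * dl^3 / (6 * hi) + M[i + 1] * dr^3 / (6 * hi) +
      (y[i] / hi - M[i] * hi / 6) * dl +
      (y[i + 1] / hi - M[i + 1] * hi / 6) * dr
  }
}

#' Resample a diel matrix onto a finer sampling grid
#'
#' Fills in expression values at additional hours by per-gene not-a-knot
#' cubic-spline interpolation, the boundary condition used by the common
#' pandas/scipy cubic interpolators. Values at the original hours are carried
#' over unchanged. Target hours beyond the last knot (e.g. hour 22 for a
#' 0-20 h grid) are evaluated with the end cubic piece. Negative interpolants
#' are clamped to 0 so resampling can never remove a gene downstream; the
#' number of clamped cells is attached as attribute `n_clamped`.
#'
#' @param m a [diel_matrix()] with at least 4 time points.
#' @param target_hours hours of the output grid; must contain every original
#'   sampling hour (hour 24 is canonicalized to 0 first).
#' @return A `diel_matrix` on `target_hours`.
#' @export
interpolate_timepoints <- function(m, target_hours) {
  stopifnot(inherits(m, "diel_matrix"))
  if (length(m$timepoints) < 4L)
    stop("need at least 4 time points to interpolate")
  target <- sort(unique(canonicalize_hours(target_hours)))
  missing <- setdiff(round(m$timepoints, 9), round(target, 9))
  if (length(missing))
    stop("target grid is missing original hour(s): ",
         paste(missing, collapse = ", "))
  is_orig <- round(target, 9) %in% round(m$timepoints, 9)
  new_h <- target[!is_orig]
  out <- matrix(0, nrow(m$values), length(target))
  out[, is_orig] <- m$values[, match(round(target[is_orig], 9),
                                     round(m$timepoints, 9)), drop = FALSE]
  n_clamped <- 0L
  if (length(new_h)) {
    for (g in seq_len(nrow(m$values))) {
      s <- not_a_knot_spline(m$timepoints, m$values[g, ])
      v <- s(new_h)
      n_clamped <- n_clamped + sum(v < 0)
      out[g, !is_orig] <- pmax(v, 0)
    }
  }
  res <- diel_matrix(out, target, m$gene_ids, m$species_id)
  attr(res, "n_clamped") <- n_clamped
  res
}

#' Normalize each gene's profile to integer pseudo-counts
#'
#' Converts each gene's profile to relative (shape-only) expression and scales
#' it to integer pseudo-counts totalling exactly `scale`, using
#' largest-remainder rounding: floors are assigned first, then the remaining
#' units go to the time points with the largest fractional parts (earlier
#' columns win exact ties). The result is invariant under positive rescaling
#' of a profile, so only the within-gene diel shape matters downstream.
#'
#' @param m a non-negative [diel_matrix()] with no all-zero rows (filter
#'   first; an all-zero row is an error naming the gene).
#' @param scale positive integer total per gene (default 1000).
#' @return An object of class `diel_counts`: list with `species_id`,
#'   `timepoints`, `gene_ids`, integer matrix `counts` (rows sum to `scale`)
#'   and `scale`.
#' @export
normalize_diel <- function(m, scale = 1000L) {
  stopifnot(inherits(m, "diel_matrix"))
  scale <- as.integer(scale)
  stopifnot(length(scale) == 1L, scale >= 1L)
  if (any(m$values < 0)) stop("negative expression values present")
  rs <- rowSums(m$values)
  if (any(rs == 0))
    stop("all-zero profile for gene(s): ",
         paste(m$gene_ids[rs == 0], collapse = ", "))
  target <- scale * m$values / rs
  counts <- floor(target)
  frac <- target - counts
  deficit <- scale - as.integer(round(rowSums(counts)))
  for (g in which(deficit > 0L)) {
    idx <- order(frac[g, ], decreasing = TRUE)[seq_len(deficit[g])]
    counts[g, idx] <- counts[g, idx] + 1
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- m$gene_ids
  structure(list(species_id = m$species_id, timepoints = m$timepoints,
                 gene_ids = m$gene_ids, counts = counts, scale = scale),
            class = "diel_counts")
}

#' @export
print.diel_counts <- function(x, ...) {
  cat(sprintf("diel_counts: species '%s', %d genes, scale %d\n",
              x$species_id, length(x$gene_ids), x$scale))
  invisible(x)
}
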