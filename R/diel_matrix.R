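#' Diel expression matrix
#'
#' Container for one species' genes x ordered diel time points of non-negative
#' (FPKM) expression values over a single 24-h light/dark cycle. Sampling
#' hours are expressed as hours after the start of the light period; hour 24
#' wraps to hour 0 (one cycle), so a header hour of 24 is canonicalized to 0
#' and columns are re-ordered to strictly increasing hours in [0, 24).
#'
#' @param values numeric matrix, genes in rows, time points in columns.
#' @param timepoints numeric vector of sampling hours, one per column.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#' @param species_id short species label.
#'
#' @return An object of class `diel_matrix`: a list with elements
#'   `species_id`, `timepoints` (strictly increasing, in `[0, 24)`),
#'   `gene_ids`, and `values` (matrix with `gene_ids` rownames).
#' @export
#' @examples
#' m <- diel_matrix(matrix(1:6, 2), c(0, 2, 4), c("g1", "g2"), "kfed")
#' m$timepoints
diel_matrix <- function(values, timepoints, gene_ids, species_id) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  timepoints <- canonicalize_hours(timepoints)
  if (anyDuplicated(timepoints))
    stop("duplicate sampling hours (after canonicalizing 24 to 0): ",
         paste(timepoints[duplicated(timepoints)], collapse = ", "))
  if (length(timepoints) != ncol(values))
    stop("length(timepoints) != ncol(values)")
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) != nrow(values)")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene IDs: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (any(!nzchar(gene_ids))) stop("empty gene ID")
  ord <- order(timepoints)
  values <- values[, ord, drop = FALSE]
  timepoints <- timepoints[ord]
  rownames(values) <- gene_ids
  colnames(values) <- paste0("h", format_hour(timepoints))
  structure(
    list(species_id = as.character(species_id)[1],
         timepoints = timepoints,
         gene_ids = gene_ids,
         values = values),
    class = "diel_matrix")
}

# hour 24 == hour 0 on the diel cycle; reduce modulo 24 and keep [0, 24)
canonicalize_hours <- function(h) {
  h <- as.numeric(h)
  if (any(!is.finite(h))) stop("non-finite sampling hour")
  if (any(h < 0 | h > 24)) stop("sampling hours must lie in [0, 24]")
  ifelse(h == 24, 0, h)
}

format_hour <- function(h) {
  ifelse(h == round(h), format(as.integer(round(h))), format(h))
}

#' @export
print.diel_matrix <- function(x, ...) {
  cat(sprintf("diel_matrix: species '%s', %d genes x %d time points (h %s)\n",
              x$species_id, length(x$gene_ids), length(x$timepoints),
              paste(format_hour(x$timepoints), collapse = ",")))
  invisible(x)
}

#' @export
dim.diel_matrix <- function(x) dim(x$values)

#' Rotate every profile around the diel cycle
#'
#' Shifts each gene's profile by `hours` on the 24-h clock: the value observed
#' at hour t becomes the value at hour t + `hours` (mod 24). The sampling grid
#' must be closed under the rotation (e.g. any shift that is a multiple of the
#' sampling interval on a regular grid).
#'
#' @param m a [diel_matrix()].
#' @param hours rotation in hours.
#' @return A `diel_matrix` on the same grid with rotated profiles.
#' @export
rotate_profiles <- function(m, hours) {
  stopifnot(inherits(m, "diel_matrix"))
  new_h <- (m$timepoints + hours) %% 24
  idx <- match(round(new_h, 9), round(m$timepoints, 9))
  if (anyNA(idx))
    stop("grid is not closed under a rotation of ", hours, " h")
  vals <- m$values
  vals[, idx] <- m$values
  diel_matrix(vals, m$timepoints, m$gene_ids, m$species_id)
}
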