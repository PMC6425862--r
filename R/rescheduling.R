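#' Spearman rank correlation (average ranks, explicit Pearson)
#'
#' Pearson product-moment correlation of the mid-rank (average-rank) vectors
#' of `x` and `y`. Ties receive the mean of the ranks they span. Constant
#' series have no defined rank correlation and raise an error, which callers
#' treat as "criterion not evaluable".
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return The correlation, in `[-1, 1]`.
#' @export
#' @examples
#' spearman_rho(c(1, 2, 2, 4), c(1, 3, 2, 4))  # 4.5 / sqrt(22.5)
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    stop("constant series: rank correlation undefined")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# expression profile of one gene restricted to the hours shared by two grids
.common_profile <- function(mat, gene, hours) {
  idx <- match(round(hours, 9), round(mat$timepoints, 9))
  mat$values[match(gene, mat$gene_ids), idx]
}

#' Call rescheduled diel expression per ortholog group
#'
#' For every combination of one CAM-species gene and one gene from each of
#' the two C3 species within an ortholog group, evaluates the two
#' rescheduling criteria: (1) the CAM gene is significantly enriched in dawn
#' or dusk while both C3 orthologs are enriched in the opposite window
#' (opposite by label, since light regimes may differ); (2) the CAM gene's
#' expression has Spearman correlation below `rho_neg` with both C3 orthologs
#' while the two C3 orthologs correlate above `rho_pos` with each other,
#' computed on the hours shared by each pair of sampling grids. A combination
#' is rescheduled iff both criteria hold; a group is rescheduled iff at least
#' one of its combinations is (all combinations are emitted so stricter rules
#' can be applied downstream).
#'
#' Groups missing one of the three species (or whose genes were all filtered
#' out upstream) are skipped with a recorded reason, not an error; trios with
#' a constant profile get `NA` correlations and an `NA` criterion-2 flag.
#'
#' @param ogs list of [ortholog_group()] objects (a single group is also
#'   accepted).
#' @param calls named list, species ID -> `enrichment_calls` data.frame from
#'   [call_phase()].
#' @param matrices named list, species ID -> [diel_matrix()] holding the
#'   profiles to correlate (by default the raw post-interpolation
#'   expression; pass normalized values to correlate shapes instead —
#'   Spearman is rank-based, so within-gene monotone rescalings do not change
#'   it).
#' @param cam_species species ID of the CAM species.
#' @param c3_species character vector of exactly two C3 species IDs.
#' @param rho_neg CAM-vs-C3 correlation must be strictly below this
#'   (default -0.6).
#' @param rho_pos C3-vs-C3 correlation must be strictly above this
#'   (default 0.6).
#' @return A data.frame of class `rescheduling_calls`, one row per evaluated
#'   combination, with columns `og_id, cam_gene, c3_geneA, c3_geneB,
#'   cam_phase, c3_phaseA, c3_phaseB, rho_cam_A, rho_cam_B, rho_AB,
#'   criterion1, criterion2, rescheduled`. Skipped groups are recorded in
#'   attribute `skipped` (data.frame `og_id`, `reason`).
#' @export
call_rescheduled <- function(ogs, calls, matrices, cam_species, c3_species,
                             rho_neg = -0.6, rho_pos = 0.6) {
  if (inherits(ogs, "ortholog_group")) ogs <- list(ogs)
  stopifnot(length(cam_species) == 1L, length(c3_species) == 2L)
  species <- c(cam_species, c3_species)
  if (!all(species %in% names(calls)))
    stop("missing enrichment calls for species: ",
         paste(setdiff(species, names(calls)), collapse = ", "))
  if (!all(species %in% names(matrices)))
    stop("missing expression matrix for species: ",
         paste(setdiff(species, names(matrices)), collapse = ", "))
  phase_of <- lapply(calls[species], function(df)
    stats::setNames(df$phase, df$gene_id))
  spA <- c3_species[1]; spB <- c3_species[2]
  hrs_cam_A <- intersect(round(matrices[[cam_species]]$timepoints, 9),
                         round(matrices[[spA]]$timepoints, 9))
  hrs_cam_B <- intersect(round(matrices[[cam_species]]$timepoints, 9),
                         round(matrices[[spB]]$timepoints, 9))
  hrs_A_B <- intersect(round(matrices[[spA]]$timepoints, 9),
                       round(matrices[[spB]]$timepoints, 9))
  if (min(length(hrs_cam_A), length(hrs_cam_B), length(hrs_A_B)) < 3L)
    stop("species sampling grids share fewer than 3 hours")

  rows <- list()
  skipped <- list()
  safe_rho <- function(x, y, hours, m1, m2)
    tryCatch(spearman_rho(.common_profile(m1, x, hours),
                          .common_profile(m2, y, hours)),
             error = function(e) NA_real_)

  for (og in ogs) {
    present <- lapply(species, function(sp) {
      g <- og$members[[sp]]
      g[g %in% names(phase_of[[sp]]) &
          g %in% matrices[[sp]]$gene_ids]
    })
    names(present) <- species
    absent <- species[lengths(present) == 0L]
    if (length(absent)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        og_id = og$og_id,
        reason = paste0("no expressed gene for species: ",
                        paste(absent, collapse = ",")),
        stringsAsFactors = FALSE)
      next
    }
    combos <- expand.grid(cam_gene = present[[cam_species]],
                          c3_geneA = present[[spA]],
                          c3_geneB = present[[spB]],
                          stringsAsFactors = FALSE)
    for (r in seq_len(nrow(combos))) {
      cg <- combos$cam_gene[r]; ga <- combos$c3_geneA[r]
      gb <- combos$c3_geneB[r]
      cam_phase <- unname(phase_of[[cam_species]][cg])
      phA <- unname(phase_of[[spA]][ga])
      phB <- unname(phase_of[[spB]][gb])
      opposite <- switch(cam_phase, dawn = "dusk", dusk = "dawn", NA)
      crit1 <- cam_phase %in% c("dawn", "dusk") &&
        !is.na(opposite) && phA == opposite && phB == opposite
      rho_a <- safe_rho(cg, ga, hrs_cam_A,
                        matrices[[cam_species]], matrices[[spA]])
      rho_b <- safe_rho(cg, gb, hrs_cam_B,
                        matrices[[cam_species]], matrices[[spB]])
      rho_ab <- safe_rho(ga, gb, hrs_A_B, matrices[[spA]], matrices[[spB]])
      crit2 <- if (anyNA(c(rho_a, rho_b, rho_ab))) NA else
        rho_a < rho_neg && rho_b < rho_neg && rho_ab > rho_pos
      rows[[length(rows) + 1L]] <- data.frame(
        og_id = og$og_id, cam_gene = cg, c3_geneA = ga, c3_geneB = gb,
        cam_phase = cam_phase, c3_phaseA = phA, c3_phaseB = phB,
        rho_cam_A = rho_a, rho_cam_B = rho_b, rho_AB = rho_ab,
        criterion1 = crit1, criterion2 = crit2,
        rescheduled = crit1 & crit2,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(
      data.frame(matrix(ncol = 13, nrow = 0)),
      c("og_id", "cam_gene", "c3_geneA", "c3_geneB", "cam_phase",
        "c3_phaseA", "c3_phaseB", "rho_cam_A", "rho_cam_B", "rho_AB",
        "criterion1", "criterion2", "rescheduled"))
  class(res) <- c("rescheduling_calls", "data.frame")
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(og_id = character(), reason = character())
  res
}

#' Group-level rescheduling verdicts
#'
#' Collapses per-combination rescheduling evidence to one verdict per
#' ortholog group: rescheduled iff at least one combination passed both
#' criteria (`NA` criterion-2 combinations do not count).
#'
#' @param calls a `rescheduling_calls` data.frame from [call_rescheduled()].
#' @return A data.frame with columns `og_id`, `n_combinations`,
#'   `rescheduled`.
#' @export
rescheduled_groups <- function(calls) {
  stopifnot(inherits(calls, "rescheduling_calls"))
  ids <- unique(calls$og_id)
  data.frame(
    og_id = ids,
    n_combinations = vapply(ids, function(i) sum(calls$og_id == i),
                            integer(1)),
    rescheduled = vapply(ids, function(i) {
      any(calls$rescheduled[calls$og_id == i], na.rm = TRUE)
    }, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
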