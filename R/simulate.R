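#' Specification of a synthetic multi-species diel study
#'
#' Defines the conditions of a simulated three-species diel experiment with
#' known ground truth: one CAM species and two C3 species, one gene per
#' species per ortholog group. The first `n_rescheduled` groups are planted
#' anti-phase (the CAM peak 12 h away from the shared C3 peak); the remaining
#' groups are conserved, all three peaks coinciding. Profiles are cosines on
#' a baseline with multiplicative log-normal noise, the simplest unimodal
#' diel shape with closed-form expectations — the analysis only consumes
#' within-gene relative shape, so the exact waveform is immaterial.
#'
#' Defaults mirror a moderate planted-signal study: 200 groups of which 20
#' rescheduled, baseline 10 FPKM, peak-to-baseline amplitude ratio 3, noise
#' standard deviation 0.2 on the log scale, two species sampled every 2 h and
#' one every 4 h over one 24-h cycle.
#'
#' @param n_ogs number of ortholog groups (one gene per species each).
#' @param n_rescheduled number of groups planted anti-phase
#'   (`<= n_ogs`).
#' @param baseline trough expression level (FPKM, > 0).
#' @param amplitude_ratio peak-to-baseline ratio (>= 0; 0 gives flat
#'   profiles).
#' @param noise_sigma standard deviation of the Gaussian noise applied on
#'   the log scale (>= 0).
#' @param grids named list, species ID -> sampling hours.
#' @param cam_peak_hour,c3_peak_hour planted peak phases; for rescheduled
#'   groups they must be 12 h apart on the 24-h clock.
#' @param conserved_peaks `"uniform"` (default; each conserved group draws
#'   one peak uniformly from the sampling grid, shared by all three species)
#'   or `"fixed"` (all conserved groups peak at `c3_peak_hour`). The default
#'   emulates a real transcriptome, where peak phases are spread around the
#'   clock; the window-enrichment test measures each gene against the
#'   transcriptome-wide dusk/dawn balance, so a study in which every gene
#'   peaks at the same hour has, by construction, no enriched genes.
#' @param cam_species,c3_species role assignment; `c3_species` has exactly
#'   two entries and all three must name entries of `grids`.
#' @param seed integer seed making the study reproducible.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_ogs = 200L, n_rescheduled = 20L,
                           baseline = 10, amplitude_ratio = 3,
                           noise_sigma = 0.2,
                           grids = list(cam = seq(0, 22, 2),
                                        c3a = seq(0, 22, 2),
                                        c3b = seq(0, 20, 4)),
                           cam_peak_hour = 12, c3_peak_hour = 0,
                           conserved_peaks = c("uniform", "fixed"),
                           cam_species = "cam",
                           c3_species = c("c3a", "c3b"),
                           seed = 1L) {
  conserved_peaks <- match.arg(conserved_peaks)
  n_ogs <- as.integer(n_ogs); n_rescheduled <- as.integer(n_rescheduled)
  if (n_rescheduled > n_ogs)
    stop("n_rescheduled exceeds n_ogs")
  stopifnot(n_ogs >= 1L, n_rescheduled >= 0L, baseline > 0,
            amplitude_ratio >= 0, noise_sigma >= 0,
            length(c3_species) == 2L)
  species <- c(cam_species, c3_species)
  if (!all(species %in% names(grids)))
    stop("grids must name every species")
  if ((cam_peak_hour - c3_peak_hour) %% 24 != 12 && n_rescheduled > 0L)
    stop("rescheduled groups require CAM and C3 peaks 12 h apart")
  structure(list(n_ogs = n_ogs, n_rescheduled = n_rescheduled,
                 baseline = baseline, amplitude_ratio = amplitude_ratio,
                 noise_sigma = noise_sigma, grids = grids,
                 cam_peak_hour = cam_peak_hour, c3_peak_hour = c3_peak_hour,
                 conserved_peaks = conserved_peaks,
                 cam_species = cam_species, c3_species = c3_species,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# cos(2*pi*(t - peak)/24), evaluated through the mirror-symmetric distance to
# the peak so that hours equidistant from the peak give bitwise-equal values
# and profiles 12 h apart have exactly reversed rank orders (plain cos()
# breaks these exact ties in the last ulp, perturbing rank correlations)
diel_cosine <- function(t, peak) {
  d <- (t - peak) %% 24
  d <- ifelse(d > 12, 24 - d, d)
  cospi(d / 12)
}

#' Simulate one gene's diel expression profile
#'
#' `x_t = baseline * (1 + amplitude_ratio * (1 + cos(2*pi*(t - peak)/24))/2)
#' * exp(e_t)` with `e_t ~ Normal(0, noise_sigma^2)`; strictly positive by
#' construction. Uses R's global random number stream: seed with
#' [set.seed()] for reproducibility.
#'
#' @param peak_hour hour of peak expression.
#' @param baseline trough level (> 0).
#' @param amplitude_ratio peak-to-baseline ratio (>= 0).
#' @param noise_sigma log-scale noise standard deviation (>= 0).
#' @param grid non-empty vector of sampling hours.
#' @return Numeric vector of expression values, one per grid hour.
#' @export
generate_profile <- function(peak_hour, baseline, amplitude_ratio,
                             noise_sigma, grid) {
  if (length(grid) == 0L) stop("empty sampling grid")
  stopifnot(baseline > 0, amplitude_ratio >= 0, noise_sigma >= 0)
  shape <- 1 + amplitude_ratio * (1 + diel_cosine(grid, peak_hour)) / 2
  noise <- if (noise_sigma > 0)
    exp(stats::rnorm(length(grid), 0, noise_sigma)) else rep(1, length(grid))
  baseline * shape * noise
}

#' Generate a complete synthetic diel study
#'
#' Produces one [diel_matrix()] per species, the matching ortholog groups
#' (one gene per species per group) and a truth table labelling each group
#' `"rescheduled"` or `"conserved"`. Deterministic given the spec (including
#' its seed).
#'
#' @param spec a [synthetic_spec()].
#' @return A list with elements `matrices` (named list of `diel_matrix`),
#'   `ortholog_groups` (list of [ortholog_group()]), `truth` (data.frame
#'   `og_id`, `label`, `peak_cam`, `peak_c3`) and `spec`.
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  species <- c(spec$cam_species, spec$c3_species)
  og_ids <- sprintf("OG%04d", seq_len(spec$n_ogs))
  planted <- seq_len(spec$n_ogs) <= spec$n_rescheduled
  peaks_c3 <- rep(spec$c3_peak_hour, spec$n_ogs)
  if (spec$conserved_peaks == "uniform" && any(!planted)) {
    pool <- spec$grids[[spec$cam_species]]
    peaks_c3[!planted] <- sample(pool, sum(!planted), replace = TRUE)
  }
  peaks_cam <- ifelse(planted, (peaks_c3 + 12) %% 24, peaks_c3)

  profiles <- lapply(species, function(sp) {
    grid <- spec$grids[[sp]]
    peaks <- if (sp == spec$cam_species) peaks_cam else peaks_c3
    vals <- t(vapply(seq_len(spec$n_ogs), function(i)
      generate_profile(peaks[i], spec$baseline, spec$amplitude_ratio,
                       spec$noise_sigma, grid),
      numeric(length(grid))))
    diel_matrix(vals, grid, paste0(og_ids, "_", sp), sp)
  })
  names(profiles) <- species

  ogs <- lapply(seq_len(spec$n_ogs), function(i)
    ortholog_group(og_ids[i],
                   stats::setNames(as.list(paste0(og_ids[i], "_", species)),
                                   species)))
  truth <- data.frame(og_id = og_ids,
                      label = ifelse(planted, "rescheduled", "conserved"),
                      peak_cam = peaks_cam, peak_c3 = peaks_c3,
                      stringsAsFactors = FALSE)
  list(matrices = profiles, ortholog_groups = ogs, truth = truth,
       spec = spec)
}

#' Write a synthetic study to a directory
#'
#' Writes `expression_<species>.tsv` per species, `ortholog_groups.tsv`
#' (long format) and `truth.tsv`, the formats consumed by [run_all()].
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (sp in names(study$matrices)) {
    p <- file.path(dir, paste0("expression_", sp, ".tsv"))
    write_expression(study$matrices[[sp]], p)
    paths[[paste0("expression_", sp)]] <- p
  }
  paths$ortholog_groups <- file.path(dir, "ortholog_groups.tsv")
  write_ortholog_groups(study$ortholog_groups, paths$ortholog_groups)
  paths$truth <- file.path(dir, "truth.tsv")
  utils::write.table(study$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
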