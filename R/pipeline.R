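#' Build and validate a pipeline run configuration
#'
#' @param species list of per-species entries, each a list with `id`, `role`
#'   (`"cam"` or `"c3"`), `expression` (path to the expression TSV) and
#'   `windows` (list with 3-hour vectors `dusk` and `dawn`). Exactly one
#'   species must have role `cam` and exactly two role `c3`.
#' @param ortholog_groups path to the long-format ortholog-group TSV.
#' @param outdir output directory for per-stage artifacts.
#' @param common_hours target sampling grid; species sampled more coarsely
#'   are resampled onto the union of their own grid and this one (default
#'   every 2 h, 0-22).
#' @param alpha FDR level for the phase calls (default 0.05).
#' @param rho_neg,rho_pos Spearman thresholds for the rescheduling criteria
#'   (defaults -0.6 and 0.6).
#' @param min_mean_fpkm,max_zero_fraction low-expression filter thresholds
#'   (defaults 0.01 and 0.5).
#' @param normalization_scale pseudo-count total per gene (default 1000).
#' @param rho_on correlate `"raw"` (post-interpolation FPKM, default) or
#'   `"normalized"` (pseudo-count) profiles.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(species, ortholog_groups, outdir,
                       common_hours = seq(0, 22, 2), alpha = 0.05,
                       rho_neg = -0.6, rho_pos = 0.6,
                       min_mean_fpkm = 0.01, max_zero_fraction = 0.5,
                       normalization_scale = 1000L,
                       rho_on = c("raw", "normalized")) {
  rho_on <- match.arg(rho_on)
  stopifnot(is.list(species), length(species) == 3L)
  ids <- vapply(species, `[[`, character(1), "id")
  roles <- vapply(species, `[[`, character(1), "role")
  if (anyDuplicated(ids)) stop("duplicate species IDs in config")
  if (sum(roles == "cam") != 1L)
    stop("config must name exactly one 'cam' species (got ",
         sum(roles == "cam"), ")")
  if (sum(roles == "c3") != 2L)
    stop("config must name exactly two 'c3' species (got ",
         sum(roles == "c3"), ")")
  common_hours <- sort(unique(canonicalize_hours(common_hours)))
  for (s in species) {
    if (!all(c("id", "role", "expression", "windows") %in% names(s)))
      stop("species entry missing fields: ",
           paste(setdiff(c("id", "role", "expression", "windows"),
                         names(s)), collapse = ", "))
    for (w in c("dusk", "dawn"))
      if (length(s$windows[[w]]) != 3L)
        stop("species ", s$id, ": ", w, " window must list 3 hours")
    wh <- canonicalize_hours(unlist(s$windows))
    if (!all(round(wh, 9) %in% round(common_hours, 9)))
      stop("species ", s$id, ": window hour(s) ",
           paste(setdiff(round(wh, 9), round(common_hours, 9)),
                 collapse = ", "),
           " not on the post-interpolation grid")
  }
  structure(list(species = species, ortholog_groups = ortholog_groups,
                 outdir = outdir, common_hours = common_hours,
                 alpha = alpha, rho_neg = rho_neg, rho_pos = rho_pos,
                 min_mean_fpkm = min_mean_fpkm,
                 max_zero_fraction = max_zero_fraction,
                 normalization_scale = as.integer(normalization_scale),
                 rho_on = rho_on),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path path to the YAML file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  y$species <- lapply(y$species, function(s) {
    s$expression <- resolve(s$expression)
    s
  })
  y$ortholog_groups <- resolve(y$ortholog_groups)
  if (!is.null(y$outdir)) y$outdir <- resolve(y$outdir)
  do.call(run_config, y)
}

#' Run the full rescheduling pipeline
#'
#' Executes, per species: read expression, resample to the common 2-h grid
#' where needed, drop negative profiles, apply the low-expression filter,
#' normalize to pseudo-counts, compute window sums and call phases; then
#' combines the per-species calls across ortholog groups into rescheduling
#' verdicts. Every stage writes its artifact into `config$outdir`
#' (`enrichment_<species>.tsv`, `rescheduling.tsv`,
#' `rescheduled_groups.tsv`), and a `manifest.json` records the config hash
#' and per-stage record counts. Deterministic given fixed inputs and config.
#'
#' @param config a `run_config` (or path to a YAML file).
#' @param quiet suppress progress messages.
#' @return The manifest, invisibly (a list; also written as JSON).
#' @export
run_all <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  cfg_json <- file.path(config$outdir, "config.json")
  jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_json)),
                   species = list())

  ids <- vapply(config$species, `[[`, character(1), "id")
  roles <- vapply(config$species, `[[`, character(1), "role")
  cam_sp <- ids[roles == "cam"]
  c3_sp <- ids[roles == "c3"]

  matrices <- list()   # post-interpolation raw expression
  counts <- list()     # normalized pseudo-counts
  calls <- list()
  for (s in config$species) {
    m <- read_expression(s$expression, species_id = s$id)
    n_in <- length(m$gene_ids)
    target <- sort(unique(c(m$timepoints, config$common_hours)))
    n_clamped <- 0L
    if (length(target) > length(m$timepoints)) {
      n_orig <- length(m$timepoints)
      m <- interpolate_timepoints(m, target)
      n_clamped <- attr(m, "n_clamped")
      say(sprintf("[%s] resampled %d -> %d time points (%d values clamped to 0)",
                  s$id, n_orig, length(target), n_clamped))
    }
    m <- remove_negative(m)
    n_neg <- attr(m, "n_removed")
    m <- filter_low_expression(m, config$min_mean_fpkm,
                               config$max_zero_fraction)
    n_low <- attr(m, "n_removed")
    say(sprintf("[%s] %d genes in, %d negative removed, %d low-expression removed, %d tested",
                s$id, n_in, n_neg, n_low, length(m$gene_ids)))
    if (length(m$gene_ids) == 0L)
      stop("stage preprocess [", s$id, "]: no genes left after filtering")
    prof <- normalize_diel(m, config$normalization_scale)
    ws <- window_sums(prof,
                      time_window("dusk", s$windows$dusk),
                      time_window("dawn", s$windows$dawn))
    ec <- call_phase(ws, config$alpha)
    out <- file.path(config$outdir, paste0("enrichment_", s$id, ".tsv"))
    write_results(ec, out)
    matrices[[s$id]] <- m
    counts[[s$id]] <- prof
    calls[[s$id]] <- ec
    manifest$species[[s$id]] <- list(
      role = s$role, n_genes_input = n_in, n_removed_negative = n_neg,
      n_removed_low_expression = n_low, n_clamped = n_clamped,
      n_genes_tested = length(m$gene_ids),
      n_dawn = sum(ec$phase == "dawn"), n_dusk = sum(ec$phase == "dusk"),
      n_neither = sum(ec$phase == "neither"),
      enrichment_file = basename(out))
  }

  ogs <- read_ortholog_groups(config$ortholog_groups)
  rho_mats <- if (config$rho_on == "raw") matrices else
    lapply(counts, function(pc)
      diel_matrix(pc$counts, pc$timepoints, pc$gene_ids, pc$species_id))
  rc <- call_rescheduled(ogs, calls, rho_mats, cam_sp, c3_sp,
                         config$rho_neg, config$rho_pos)
  write_results(rc, file.path(config$outdir, "rescheduling.tsv"))
  groups <- rescheduled_groups(rc)
  utils::write.table(groups,
                     file.path(config$outdir, "rescheduled_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  skipped <- attr(rc, "skipped")
  say(sprintf("%d ortholog groups: %d evaluated (%d combinations), %d skipped, %d rescheduled",
              length(ogs), nrow(groups), nrow(rc), nrow(skipped),
              sum(groups$rescheduled)))

  manifest$rescheduling <- list(
    n_ortholog_groups = length(ogs),
    n_groups_evaluated = nrow(groups),
    n_combinations = nrow(rc),
    n_groups_skipped = nrow(skipped),
    n_rescheduled_groups = sum(groups$rescheduled),
    rescheduling_file = "rescheduling.tsv",
    groups_file = "rescheduled_groups.tsv")
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
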