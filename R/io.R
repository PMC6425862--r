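#' Read a diel expression matrix from TSV
#'
#' Expression files are UTF-8, tab-separated, unquoted, with one header row:
#' the first header cell must be `gene_id` and the remaining cells sampling
#' hours, optionally prefixed with `h` (e.g. `h0`, `h2`, ... or `0`, `2`,
#' ...). Hour 24 is canonicalized to hour 0 at parse time.
#'
#' @param path path to the TSV file.
#' @param species_id species label attached to the result; defaults to the
#'   file name without extension.
#' @return A [diel_matrix()].
#' @export
read_expression <- function(path, species_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "gene_id")
    stop("malformed header in ", path, ": first column must be 'gene_id'")
  hour_lab <- sub("^h", "", header[-1])
  hours <- suppressWarnings(as.numeric(hour_lab))
  if (anyNA(hours))
    stop("malformed header in ", path, ": column '",
         header[-1][which(is.na(hours))[1]], "' does not parse as an hour")
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = c("character",
                                          rep("numeric", length(hours))),
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tab[[1]]))
    stop("duplicate gene IDs in ", path, ": ",
         paste(unique(tab[[1]][duplicated(tab[[1]])]), collapse = ", "))
  if (is.null(species_id))
    species_id <- sub("\\.[^.]*$", "", basename(path))
  diel_matrix(as.matrix(tab[, -1, drop = FALSE]), hours, tab[[1]], species_id)
}

#' Write a diel expression matrix to TSV
#'
#' Inverse of [read_expression()]: full-precision values, so a write/read
#' round trip reproduces the matrix field for field.
#'
#' @param m a [diel_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "diel_matrix"))
  vals <- format(m$values, digits = 15, trim = TRUE, scientific = FALSE)
  out <- cbind(gene_id = m$gene_ids, vals)
  colnames(out) <- c("gene_id", paste0("h", format_hour(m$timepoints)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ortholog group
#'
#' A mapping from one ortholog-group ID to the member gene IDs of each
#' species carrying the group.
#'
#' @param og_id group identifier.
#' @param members named list, species ID -> non-empty character vector of
#'   gene IDs.
#' @return An object of class `ortholog_group`.
#' @export
ortholog_group <- function(og_id, members) {
  stopifnot(is.list(members), !is.null(names(members)))
  if (anyDuplicated(names(members)))
    stop("species listed twice in ortholog group ", og_id)
  for (sp in names(members)) {
    g <- as.character(members[[sp]])
    if (length(g) == 0L || any(!nzchar(g)))
      stop("empty gene ID for species ", sp, " in group ", og_id)
    members[[sp]] <- g
  }
  structure(list(og_id = as.character(og_id), members = members),
            class = "ortholog_group")
}

#' @export
print.ortholog_group <- function(x, ...) {
  cat(sprintf("ortholog_group %s: %s\n", x$og_id,
              paste(sprintf("%s(%d)", names(x$members),
                            lengths(x$members)), collapse = " ")))
  invisible(x)
}

#' Read ortholog groups from long-format TSV
#'
#' One row per member gene, columns `og_id`, `species_id`, `gene_id`.
#' Rows are grouped by `og_id`; member lists preserve file order.
#'
#' @param path path to the TSV file.
#' @return A list of [ortholog_group()] objects, in first-appearance order.
#' @export
read_ortholog_groups <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", colClasses = "character",
                           stringsAsFactors = FALSE)
  need <- c("og_id", "species_id", "gene_id")
  if (!all(need %in% names(tab)))
    stop("ortholog group file ", path, " is missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  if (any(!nzchar(tab$gene_id)))
    stop("empty gene_id cell in ", path)
  ids <- unique(tab$og_id)
  lapply(ids, function(id) {
    sub <- tab[tab$og_id == id, , drop = FALSE]
    ortholog_group(id, split(sub$gene_id,
                             factor(sub$species_id,
                                    levels = unique(sub$species_id))))
  })
}

#' Write ortholog groups to long-format TSV
#'
#' @param ogs list of [ortholog_group()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_groups <- function(ogs, path) {
  rows <- do.call(rbind, lapply(ogs, function(og) {
    data.frame(og_id = og$og_id,
               species_id = rep(names(og$members), lengths(og$members)),
               gene_id = unlist(og$members, use.names = FALSE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(og_id = character(), species_id = character(),
                       gene_id = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# column contracts for the two tabular result kinds
.enrichment_cols <- c("gene_id", "dusk_sum", "dawn_sum", "p_dusk", "p_dawn",
                      "q_dusk", "q_dawn", "phase")
.rescheduling_cols <- c("og_id", "cam_gene", "c3_geneA", "c3_geneB",
                        "cam_phase", "c3_phaseA", "c3_phaseB",
                        "rho_cam_A", "rho_cam_B", "rho_AB",
                        "criterion1", "criterion2", "rescheduled")

#' Write enrichment or rescheduling calls to TSV
#'
#' Columns are written in a fixed, documented order
#' (enrichment: `gene_id, dusk_sum, dawn_sum, p_dusk, p_dawn, q_dusk, q_dawn,
#' phase`; rescheduling: `og_id, cam_gene, c3_geneA, c3_geneB, cam_phase,
#' c3_phaseA, c3_phaseB, rho_cam_A, rho_cam_B, rho_AB, criterion1,
#' criterion2, rescheduled`). Real-valued columns (p, q, rho) are rendered at
#' 6 significant digits.
#'
#' @param calls a data.frame of class `enrichment_calls` (from
#'   [call_phase()]) or `rescheduling_calls` (from [call_rescheduled()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(calls, path) {
  if (inherits(calls, "enrichment_calls")) {
    cols <- .enrichment_cols
    real <- c("p_dusk", "p_dawn", "q_dusk", "q_dawn")
  } else if (inherits(calls, "rescheduling_calls")) {
    cols <- .rescheduling_cols
    real <- c("rho_cam_A", "rho_cam_B", "rho_AB")
  } else {
    stop("calls must be an 'enrichment_calls' or 'rescheduling_calls' ",
         "data.frame; got ", paste(class(calls), collapse = "/"))
  }
  stopifnot(all(cols %in% names(calls)))
  out <- calls[, cols, drop = FALSE]
  for (cl in real)
    out[[cl]] <- ifelse(is.na(out[[cl]]), "NA", sprintf("%.6g", out[[cl]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back result TSVs written by [write_results()]
#'
#' @param path path to the TSV file.
#' @param kind `"enrichment"` or `"rescheduling"`.
#' @return A data.frame with the corresponding class attribute restored.
#' @export
read_results <- function(path, kind = c("enrichment", "rescheduling")) {
  kind <- match.arg(kind)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           colClasses = NA)
  cols <- if (kind == "enrichment") .enrichment_cols else .rescheduling_cols
  if (!identical(names(tab), cols))
    stop("unexpected columns in ", path)
  for (cl in intersect(c("gene_id", "og_id", "cam_gene", "c3_geneA",
                         "c3_geneB", "cam_phase", "c3_phaseA", "c3_phaseB",
                         "phase"), cols))
    tab[[cl]] <- as.character(tab[[cl]])
  class(tab) <- c(if (kind == "enrichment") "enrichment_calls"
                  else "rescheduling_calls", "data.frame")
  tab
}

#' Read literature-homology hit records (JSON lines)
#'
#' One JSON object per line with keys `query_id`, `subject_id`, `evalue`,
#' `snippets` (array of strings, may be empty), `publication_ids` (array of
#' strings).
#'
#' @param path path to the JSON-lines file.
#' @return A list of hit records (each a list with the five fields).
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    hit_record(rec$query_id, rec$subject_id, rec$evalue,
               as.character(rec$snippets), as.character(rec$publication_ids))
  })
}

#' Construct a single homology hit record
#'
#' @param query_id query protein/gene ID.
#' @param subject_id matched database protein ID.
#' @param evalue BLAST E-value of the hit (non-negative).
#' @param snippets character vector of free-text snippets attached to the
#'   hit (may be empty).
#' @param publication_ids character vector of publication identifiers.
#' @return A list of class `hit_record`.
#' @export
hit_record <- function(query_id, subject_id, evalue,
                       snippets = character(), publication_ids = character()) {
  evalue <- as.numeric(evalue)
  if (length(evalue) != 1L || is.na(evalue) || evalue < 0)
    stop("evalue must be a single non-negative number")
  structure(list(query_id = as.character(query_id),
                 subject_id = as.character(subject_id),
                 evalue = evalue,
                 snippets = as.character(snippets),
                 publication_ids = as.character(publication_ids)),
            class = "hit_record")
}

#' Write hit records as JSON lines
#'
#' @param records list of [hit_record()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(list(query_id = jsonlite::unbox(r$query_id),
                          subject_id = jsonlite::unbox(r$subject_id),
                          evalue = jsonlite::unbox(r$evalue),
                          snippets = r$snippets,
                          publication_ids = r$publication_ids),
                     digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene list (one ID per line)
#'
#' @param path path to the file; blank lines are ignored.
#' @return Character vector of gene IDs.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ids <- trimws(readLines(path, warn = FALSE))
  ids[nzchar(ids)]
}
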