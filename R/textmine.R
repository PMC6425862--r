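#' Filter literature-homology hits by E-value and keywords
#'
#' Keeps the hit records whose E-value is at most `max_evalue` and whose
#' snippets mention at least one keyword. Matching is case-insensitive; with
#' `mode = "substring"` (default) keywords match as plain substrings, so
#' "stomata" also matches "stomatal"; with `mode = "regex"` each keyword is
#' treated as a regular expression.
#'
#' @param records list of [hit_record()] objects.
#' @param keywords non-empty character vector (default
#'   `c("stomata", "guard cell")`).
#' @param max_evalue keep hits with `evalue <= max_evalue` (default 1e-3).
#' @param mode `"substring"` or `"regex"`.
#' @return The kept subset of `records` (same order); idempotent.
#' @export
filter_hits <- function(records, keywords = c("stomata", "guard cell"),
                        max_evalue = 1e-3, mode = c("substring", "regex")) {
  mode <- match.arg(mode)
  if (length(keywords) == 0L || any(!nzchar(keywords)))
    stop("keywords must be non-empty")
  keep <- vapply(records, function(r) {
    if (r$evalue > max_evalue) return(FALSE)
    if (length(r$snippets) == 0L) return(FALSE)
    if (mode == "substring") {
      sn <- tolower(r$snippets)
      any(vapply(tolower(keywords),
                 function(k) any(grepl(k, sn, fixed = TRUE)), logical(1)))
    } else {
      any(vapply(keywords,
                 function(k) any(grepl(k, r$snippets, ignore.case = TRUE,
                                       perl = TRUE)), logical(1)))
    }
  }, logical(1))
  records[keep]
}

#' Summarize kept hits per species
#'
#' Mirrors the per-species hit summary of a literature-homology screen:
#' total counts include record multiplicity; unique counts are distinct
#' subject proteins.
#'
#' @param records list of [hit_record()] objects.
#' @param species_of named character vector mapping `subject_id` to a
#'   species label; every subject must be mapped.
#' @return A data.frame with columns `species`, `total_hits`,
#'   `unique_subjects`, sorted by decreasing `total_hits`.
#' @export
summarize_by_species <- function(records, species_of) {
  if (length(records) == 0L)
    return(data.frame(species = character(), total_hits = integer(),
                      unique_subjects = integer()))
  subj <- vapply(records, function(r) r$subject_id, character(1))
  unmapped <- setdiff(unique(subj), names(species_of))
  if (length(unmapped))
    stop("unmapped subject ID(s): ", paste(unmapped, collapse = ", "))
  sp <- unname(species_of[subj])
  tot <- table(sp)
  uni <- tapply(subj, sp, function(s) length(unique(s)))
  out <- data.frame(species = names(tot),
                    total_hits = as.integer(tot),
                    unique_subjects = as.integer(uni[names(tot)]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total_hits, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Three-way partition of stomata-related gene categories
#'
#' Given the set of genes annotated as stomata-related (GO), the set of
#' genes known from curation as key stomatal genes, and the set recovered by
#' literature mining, computes the "underexplored" genes — literature-mined
#' genes carrying neither a GO annotation nor known-key status — together
#' with all seven Venn region sizes.
#'
#' @param go_set,known_set,litmined_set character vectors of gene IDs (the
#'   three sets may overlap arbitrarily).
#' @return An object of class `category_partition`: list with the three
#'   de-duplicated input sets, `underexplored`, and `venn` (named integer
#'   vector of the 7 region sizes: `go_only`, `known_only`, `lit_only`,
#'   `go_known`, `go_lit`, `known_lit`, `all_three`).
#' @export
partition_categories <- function(go_set, known_set, litmined_set) {
  go <- unique(as.character(go_set))
  kn <- unique(as.character(known_set))
  lit <- unique(as.character(litmined_set))
  under <- setdiff(lit, union(go, kn))
  inx <- function(set, g, k, l)
    sum((set %in% go) == g & (set %in% kn) == k & (set %in% lit) == l)
  u <- union(union(go, kn), lit)
  venn <- c(go_only    = inx(u, TRUE,  FALSE, FALSE),
            known_only = inx(u, FALSE, TRUE,  FALSE),
            lit_only   = inx(u, FALSE, FALSE, TRUE),
            go_known   = inx(u, TRUE,  TRUE,  FALSE),
            go_lit     = inx(u, TRUE,  FALSE, TRUE),
            known_lit  = inx(u, FALSE, TRUE,  TRUE),
            all_three  = inx(u, TRUE,  TRUE,  TRUE))
  structure(list(go_set = go, known_set = kn, litmined_set = lit,
                 underexplored = under, venn = venn),
            class = "category_partition")
}

#' @export
print.category_partition <- function(x, ...) {
  cat(sprintf(paste0("category_partition: GO %d, known %d, ",
                     "literature-mined %d -> underexplored %d\n"),
              length(x$go_set), length(x$known_set),
              length(x$litmined_set), length(x$underexplored)))
  invisible(x)
}
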