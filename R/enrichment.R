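#' Dawn/dusk sampling window
#'
#' A labeled set of three sampling hours summarizing a gene's diel phase.
#' For a 12-h light / 12-h dark regime the dusk window covers 10, 12 and 14 h
#' after the start of the light period and the dawn window 22, 24 (== 0) and
#' 2 h; a 10-h light regime shifts dusk to 8, 10 and 12 h. Windows are
#' per-species configuration, never hard-coded downstream.
#'
#' @param label `"dawn"` or `"dusk"`.
#' @param hours numeric vector of 3 sampling hours; hour 24 is canonicalized
#'   to 0.
#' @return An object of class `time_window`.
#' @export
#' @examples
#' time_window("dawn", c(22, 24, 2))  # stored as hours 22, 0, 2
time_window <- function(label, hours) {
  label <- match.arg(label, c("dawn", "dusk"))
  hours <- canonicalize_hours(hours)
  if (length(hours) != 3L || anyDuplicated(hours))
    stop("a time window is a set of 3 distinct sampling hours")
  structure(list(label = label, hours = hours), class = "time_window")
}

#' @export
print.time_window <- function(x, ...) {
  cat(sprintf("time_window %s: h %s\n", x$label,
              paste(format_hour(x$hours), collapse = ",")))
  invisible(x)
}

#' Sum pseudo-counts over the dusk and dawn windows
#'
#' Builds the two-column matrix at the heart of the phase test: one row per
#' gene, one column summing the normalized counts over the dusk-window hours
#' and one over the dawn-window hours.
#'
#' @param profiles a `diel_counts` object from [normalize_diel()].
#' @param dusk,dawn [time_window()] objects; their hour sets must be disjoint
#'   and present on the sampling grid.
#' @return A data.frame of class `window_counts` with columns `gene_id`,
#'   `dusk_sum`, `dawn_sum`.
#' @export
window_sums <- function(profiles, dusk, dawn) {
  stopifnot(inherits(profiles, "diel_counts"),
            inherits(dusk, "time_window"), inherits(dawn, "time_window"),
            dusk$label == "dusk", dawn$label == "dawn")
  if (length(intersect(dusk$hours, dawn$hours)))
    stop("dusk and dawn windows overlap")
  grid <- round(profiles$timepoints, 9)
  col_of <- function(w) {
    idx <- match(round(w$hours, 9), grid)
    if (anyNA(idx))
      stop("window hour(s) ", paste(w$hours[is.na(idx)], collapse = ", "),
           " absent from the sampling grid of species '",
           profiles$species_id, "'")
    idx
  }
  res <- data.frame(
    gene_id = profiles$gene_ids,
    dusk_sum = as.integer(rowSums(profiles$counts[, col_of(dusk),
                                                  drop = FALSE])),
    dawn_sum = as.integer(rowSums(profiles$counts[, col_of(dawn),
                                                  drop = FALSE])),
    stringsAsFactors = FALSE)
  class(res) <- c("window_counts", "data.frame")
  res
}

#' Right tail of the Fisher exact test
#'
#' Probability of observing a first cell at least as large as `a` under the
#' hypergeometric law fixed by the margins of the 2x2 table
#' `rbind(c(a, b), c(c, d))`, accumulated on the log-factorial scale.
#' Vectorized over the four cells.
#'
#' @param a,b,c,d non-negative integer cell counts; the total must be >= 1.
#' @return Right-tail p-value(s) in `[0, 1]`.
#' @export
#' @examples
#' fisher_right_tail(3, 1, 1, 3)  # 17/70
fisher_right_tail <- function(a, b, c, d) {
  len <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), len); b <- rep_len(as.numeric(b), len)
  c <- rep_len(as.numeric(c), len); d <- rep_len(as.numeric(d), len)
  cells <- cbind(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells)))
    stop("cells must be non-negative integers")
  if (any(rowSums(cells) < 1)) stop("table total must be at least 1")
  vapply(seq_len(len), function(i) {
    k <- a[i] + b[i]            # first row margin
    m <- a[i] + c[i]            # first column margin
    n <- b[i] + d[i]
    N <- m + n
    supp <- a[i]:min(k, m)
    logp <- lchoose(m, supp) + lchoose(n, k - supp) - lchoose(N, k)
    min(1, sum(sort(exp(logp))))
  }, numeric(1))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: with order statistics `p(1) <= ... <= p(m)`, the
#' q-value of `p(i)` is `min_{j >= i} m * p(j) / j` (capped at 1) and a
#' hypothesis is rejected iff its q-value is at most `alpha` — equivalently,
#' iff its p-value is at most `p(k)` for the largest `k` with
#' `p(k) <= k * alpha / m`.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return A data.frame with columns `p`, `q`, `reject`, in input order.
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  p <- as.numeric(pvalues)
  if (any(is.na(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L)
    return(data.frame(p = numeric(), q = numeric(), reject = logical()))
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  data.frame(p = p, q = q, reject = q <= alpha)
}

# 2x2 table for gene g against the transcriptome-wide dusk/dawn balance:
# [[ S_W(g), S_opp(g) ], [ total_W - S_W(g), total_opp - S_opp(g) ]]
.phase_pvalues <- function(ws) {
  Dk <- sum(ws$dusk_sum)
  Dn <- sum(ws$dawn_sum)
  list(p_dusk = fisher_right_tail(ws$dusk_sum, ws$dawn_sum,
                                  Dk - ws$dusk_sum, Dn - ws$dawn_sum),
       p_dawn = fisher_right_tail(ws$dawn_sum, ws$dusk_sum,
                                  Dn - ws$dawn_sum, Dk - ws$dusk_sum))
}

#' Call each gene's diel phase: dawn, dusk, or neither
#'
#' For every gene, a right-tailed Fisher exact test asks whether its window
#' counts are over-represented in the dusk (resp. dawn) window relative to
#' the transcriptome-wide dusk/dawn balance of the species. The
#' Benjamini-Hochberg procedure is applied separately to the dusk p-value
#' vector and the dawn p-value vector (FDR controlled per species and
#' time-window); the phase is the rejected window, `"neither"` if none. In
#' the (practically impossible) event both windows are rejected the smaller
#' q-value wins; an exact tie falls back to `"neither"` with a warning.
#'
#' @param counts a `window_counts` data.frame from [window_sums()].
#' @param alpha FDR level (default 0.05).
#' @return A data.frame of class `enrichment_calls` with columns `gene_id`,
#'   `dusk_sum`, `dawn_sum`, `p_dusk`, `p_dawn`, `q_dusk`, `q_dawn`, `phase`.
#' @export
call_phase <- function(counts, alpha = 0.05) {
  stopifnot(inherits(counts, "window_counts") || is.data.frame(counts))
  stopifnot(nrow(counts) >= 1L)
  pv <- .phase_pvalues(counts)
  fdr_dusk <- bh_fdr(pv$p_dusk, alpha)
  fdr_dawn <- bh_fdr(pv$p_dawn, alpha)
  phase <- rep("neither", nrow(counts))
  phase[fdr_dusk$reject] <- "dusk"
  phase[fdr_dawn$reject] <- "dawn"
  both <- fdr_dusk$reject & fdr_dawn$reject
  if (any(both)) {
    tie <- both & fdr_dusk$q == fdr_dawn$q
    phase[both] <- ifelse(fdr_dusk$q[both] < fdr_dawn$q[both],
                          "dusk", "dawn")
    if (any(tie)) {
      phase[tie] <- "neither"
      warning(sum(tie), " gene(s) rejected in both windows with tied ",
              "q-values; set to 'neither'")
    }
  }
  res <- data.frame(gene_id = counts$gene_id,
                    dusk_sum = counts$dusk_sum,
                    dawn_sum = counts$dawn_sum,
                    p_dusk = pv$p_dusk, p_dawn = pv$p_dawn,
                    q_dusk = fdr_dusk$q, q_dawn = fdr_dawn$q,
                    phase = phase,
                    stringsAsFactors = FALSE)
  class(res) <- c("enrichment_calls", "data.frame")
  res
}
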