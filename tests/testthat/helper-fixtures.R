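# shared fixture builders; everything is generated in code at test time

grid2h <- seq(0, 22, 2)
grid4h <- seq(0, 20, 4)

win12 <- list(dusk = c(10, 12, 14), dawn = c(22, 24, 2))  # 12-h light regime
win10 <- list(dusk = c(8, 10, 12), dawn = c(22, 24, 2))   # 10-h light regime

make_matrix <- function(values, hours = grid2h, ids = NULL, sp = "spX") {
  values <- rbind(values)
  if (is.null(ids))
    ids <- if (nrow(values)) paste0("g", seq_len(nrow(values)))
           else character(0)
  diel_matrix(values, hours, ids, sp)
}

# cosine profile peaking at `peak` on `hours`, trough `base`, peak base*(1+amp);
# mirror-symmetric evaluation as in the generator, so exact ties are exact
cosine_profile <- function(peak, hours = grid2h, base = 10, amp = 3) {
  d <- (hours - peak) %% 24
  d <- ifelse(d > 12, 24 - d, d)
  base * (1 + amp * (1 + cospi(d / 12)) / 2)
}

# three-species config for a written synthetic study
study_config <- function(paths, outdir, windows = win12, ...) {
  run_config(
    species = list(
      list(id = "cam", role = "cam", expression = paths$expression_cam,
           windows = windows),
      list(id = "c3a", role = "c3", expression = paths$expression_c3a,
           windows = windows),
      list(id = "c3b", role = "c3", expression = paths$expression_c3b,
           windows = windows)),
    ortholog_groups = paths$ortholog_groups, outdir = outdir, ...)
}

# brute-force right-tail Fisher oracle: enumerate every table with the
# observed margins using choose() only
fisher_tail_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  supp <- max(0, r1 + c1 - N):min(r1, c1)
  prob <- choose(c1, supp) * choose(N - c1, r1 - supp) / choose(N, r1)
  sum(prob[supp >= a])
}
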