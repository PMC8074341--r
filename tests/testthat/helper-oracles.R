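# Independent oracles and small fixture builders shared across test files.

# all permutations of a vector (n <= 8 in tests)
permutations_of <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- vector("list", 0)
  for (i in seq_along(v))
    for (p in permutations_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# Kendall S between x and ref by direct pair counting
kendall_s <- function(x, ref) {
  sx <- sign(outer(x, x, "-"))
  sr <- sign(outer(ref, ref, "-"))
  sum(sx[upper.tri(sx)] * sr[upper.tri(sr)])
}

# hand-written BH step-up, independent of stats::p.adjust
bh_stepup_ref <- function(p) {
  ok <- !is.na(p)
  q <- rep(NA_real_, length(p))
  pp <- p[ok]
  n <- length(pp)
  if (n == 0) return(q)
  o <- order(pp)
  adj <- pp[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  qq <- numeric(n)
  qq[o] <- adj
  q[ok] <- qq
  q
}

# expression_set holding given per-gene rows at the given times
make_es <- function(rows, times, ind = rep("r1", length(times)),
                    genes = sprintf("g%d", seq_len(nrow(rows)))) {
  colnames(rows) <- paste0("s", seq_along(times))
  rownames(rows) <- genes
  expression_set(rows, data.frame(sample = colnames(rows), time = times,
                                  ind = ind, stringsAsFactors = FALSE))
}

# noise-free single-gene series from a curve spec on an hourly day
cosine_series <- function(A = 1, Tt = 24, phi = 0, times = 0:23) {
  evaluate_curve(curve_spec("cosine", A, Tt, phi), times, t0 = min(times))
}
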