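#' Configuration for the non-parametric rhythm tests
#'
#' @param min_period,max_period period search window (hours).
#' @param period_step spacing of the JTK period grid (hours).
#' @param lag_step spacing of the JTK phase-lag grid (hours); NULL uses the
#'   data's native sampling resolution.
#' @param ofac Lomb-Scargle frequency oversampling factor.
#' @param q_threshold calling threshold on the BH-adjusted p-value.
#' @return a list of class \code{np_config}.
#' @export
np_config <- function(min_period = 20, max_period = 28, period_step = 1,
                      lag_step = NULL, ofac = 4, q_threshold = 0.05) {
  if (min_period <= 0 || max_period < min_period)
    stop("need 0 < min_period <= max_period", call. = FALSE)
  structure(list(min_period = min_period, max_period = max_period,
                 period_step = period_step, lag_step = lag_step,
                 ofac = ofac, q_threshold = q_threshold),
            class = "np_config")
}

# ---- exact null distribution of the Jonckheere-Terpstra / Kendall S ---------
#
# For a reference waveform with tied groups of sizes n_1..n_g (data assumed
# untied), the concordant-pair count JT has the inversion-number distribution
# of a multiset permutation, whose generating function factorizes into
# Gaussian binomials -- i.e. the convolution of Mann-Whitney U(m_k, n_k)
# distributions with m_k the number of items placed before group k. Each U
# distribution comes from stats::dwilcox; the convolution is exact.

.jtk_cache <- new.env(parent = emptyenv())

.conv <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  la <- length(a)
  for (i in seq_along(b))
    out[i:(i + la - 1L)] <- out[i:(i + la - 1L)] + a * b[i]
  out
}

# probability mass of JT over 0..sum_{i<j} n_i n_j for tied-group sizes
.jt_null <- function(sizes) {
  key <- paste(sort(sizes), collapse = ",")
  hit <- .jtk_cache[[key]]
  if (!is.null(hit)) return(hit)
  d <- 1
  placed <- 0L
  for (n in sizes) {
    if (placed > 0L && n > 0L)
      d <- .conv(d, stats::dwilcox(0:(placed * n), placed, n))
    placed <- placed + n
  }
  .jtk_cache[[key]] <- d
  d
}

# two-sided tail lookup table: p2[s0/step + 1] = P(|S| >= s0), S = 2*JT - M
.jt_two_sided <- function(dist) {
  M <- length(dist) - 1L
  upper <- rev(cumsum(rev(dist)))   # upper[k+1] = P(JT >= k)
  lower <- cumsum(dist)             # lower[k+1] = P(JT <= k)
  function(s_abs) {
    jt_hi <- ceiling((M + s_abs) / 2)
    jt_lo <- floor((M - s_abs) / 2)
    p <- ifelse(jt_hi > M, 0, upper[pmin(jt_hi, M) + 1L]) +
      ifelse(jt_lo < 0, 0, lower[pmax(jt_lo, 0L) + 1L])
    # when s_abs = 0 both tails cover the whole distribution
    pmin(p, 1)
  }
}

# grid of (period, lag) hypotheses and their cosine reference waves
.jtk_grid <- function(times, config) {
  periods <- seq(config$min_period, config$max_period, by = config$period_step)
  lag_step <- config$lag_step
  if (is.null(lag_step)) lag_step <- min(diff(sort(unique(times))))
  grid <- do.call(rbind, lapply(periods, function(Tt)
    data.frame(period = Tt, lag = seq(0, Tt - lag_step, by = lag_step))))
  refs <- lapply(seq_len(nrow(grid)), function(g)
    round(cos(2 * pi * (times - grid$lag[g]) / grid$period[g]), 9))
  list(grid = grid, refs = refs)
}

# core engine shared by the per-gene and matrix interfaces.
# X: genes x samples. Returns data.frame(p, q, best_period, best_lag, tau).
.jtk_engine <- function(X, times, config) {
  if (ncol(X) < 6) stop("JTK needs at least 6 samples", call. = FALSE)
  gr <- .jtk_grid(times, config)
  G <- nrow(gr$grid)
  if (G == 0) stop("empty period/lag grid", call. = FALSE)
  n <- ncol(X)
  pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  # sign of all pairwise differences: hypotheses x pairs and pairs x genes
  ref_sign <- t(vapply(gr$refs, function(r) sign(r[pair[, 1]] - r[pair[, 2]]),
                       numeric(nrow(pair))))
  if (G == 1) ref_sign <- matrix(ref_sign, nrow = 1)
  dat_sign <- apply(X, 1, function(x) sign(x[pair[, 1]] - x[pair[, 2]]))
  S <- ref_sign %*% dat_sign                       # Kendall S per hypothesis/gene
  npair <- nrow(pair)
  ties_ref <- rowSums(ref_sign == 0)
  ties_dat <- colSums(dat_sign == 0)

  P <- matrix(1, G, ncol(S))
  for (g in seq_len(G)) {
    sizes <- as.integer(table(gr$refs[[g]]))
    pf <- .jt_two_sided(.jt_null(sizes))
    P[g, ] <- pf(abs(S[g, ]))
  }
  best <- apply(P, 2, which.min)
  idx <- cbind(best, seq_along(best))
  minp <- P[idx]
  denom <- sqrt((npair - ties_ref[best]) * (npair - ties_dat))
  tau <- ifelse(denom > 0, S[idx] / denom, 0)
  data.frame(gene = rownames(X),
             p = pmin(1, minp * G),               # Bonferroni over the grid
             q = NA_real_,
             best_period = gr$grid$period[best],
             best_lag = gr$grid$lag[best],
             tau = tau,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' JTK-style rank test for rhythmicity of one series
#'
#' For every period/phase-lag hypothesis on a grid, a cosine reference is
#' evaluated at the sampling times (replicates sharing a time share the
#' reference value and so form tied groups) and Kendall's S between data and
#' reference is computed. The two-sided p-value uses the exact null
#' distribution of S under the reference's tie structure, obtained by
#' convolution of Mann-Whitney null distributions. The minimum p over the
#' grid is Bonferroni-corrected by the number of hypotheses and capped at 1.
#'
#' @param values numeric vector of one gene's expression.
#' @param times sampling times (hours), one per value.
#' @param config an \code{\link{np_config}}.
#' @return list: p, best_period, best_lag, tau (Kendall tau-b at the optimum).
#' @export
jtk_test <- function(values, times, config = np_config()) {
  X <- matrix(values, nrow = 1, dimnames = list("g", NULL))
  r <- .jtk_engine(X, times, config)
  list(p = r$p, best_period = r$best_period, best_lag = r$best_lag, tau = r$tau)
}

#' Run the JTK-style test on every gene of a dataset
#' @param es an \code{\link{expression_set}}.
#' @param config an \code{\link{np_config}}.
#' @return data.frame: gene, p, q (BH across genes), best_period, best_lag, tau.
#' @export
run_jtk <- function(es, config = np_config()) {
  es <- .canonicalize(es)
  out <- .jtk_engine(es$x, es$time, config)
  out$q <- bh_adjust(out$p)
  out
}

# ---- Lomb-Scargle ----------------------------------------------------------

# power matrix (freqs x genes) of the variance-normalized periodogram
.ls_engine <- function(X, times, config) {
  n <- ncol(X)
  if (n < 6) stop("Lomb-Scargle needs at least 6 samples", call. = FALSE)
  span <- diff(range(times))
  fmin <- 1 / config$max_period
  fmax <- 1 / config$min_period
  df <- 1 / (config$ofac * span)
  freqs <- seq(fmin, fmax, by = df)
  if (length(freqs) == 0) freqs <- fmin
  xc <- X - rowMeans(X)
  v <- apply(X, 1, stats::var)
  P <- matrix(0, length(freqs), nrow(X))
  tau <- numeric(length(freqs))
  for (k in seq_along(freqs)) {
    w <- 2 * pi * freqs[k]
    tau[k] <- atan2(sum(sin(2 * w * times)), sum(cos(2 * w * times))) / (2 * w)
    cc <- cos(w * (times - tau[k]))
    ss <- sin(w * (times - tau[k]))
    num_c <- (xc %*% cc)^2 / sum(cc^2)
    num_s <- (xc %*% ss)^2 / sum(ss^2)
    P[k, ] <- (num_c + num_s) / 2
  }
  P <- sweep(P, 2, pmax(v, 1e-300), "/")
  P[, v <= 0] <- 0
  list(P = P, freqs = freqs, tau = tau, xc = xc, var = v)
}

# false-alarm probability of the peak power among M independent frequencies
.ls_fap <- function(peak, M) {
  p <- -expm1(M * log1p(-pmin(exp(-peak), 1 - 1e-16)))
  pmin(pmax(p, 1e-300), 1)
}

#' Lomb-Scargle periodogram test for rhythmicity of one series
#'
#' Standard variance-normalized Lomb-Scargle periodogram (valid for uneven
#' sampling) scanned over the frequencies corresponding to
#' \code{[min_period, max_period]} with oversampling factor \code{ofac}. The
#' peak power P is converted to a false-alarm probability
#' \eqn{p = 1 - (1 - e^{-P})^M} where M counts independent frequencies in the
#' scanned range (the oversampled bins divided by \code{ofac}).
#'
#' @param values numeric vector of one gene's expression.
#' @param times sampling times (hours).
#' @param config an \code{\link{np_config}}.
#' @return list: p, best_period, peak_power, phase (peak time of the fitted
#'   sinusoid, hours modulo the best period).
#' @export
lomb_scargle_test <- function(values, times, config = np_config()) {
  X <- matrix(values, nrow = 1, dimnames = list("g", NULL))
  r <- run_ls_matrix(X, times, config)
  list(p = r$p, best_period = r$best_period, peak_power = r$peak_power,
       phase = r$phase)
}

# matrix-level Lomb-Scargle; X: genes x samples
run_ls_matrix <- function(X, times, config = np_config()) {
  eng <- .ls_engine(X, times, config)
  M <- max(1L, as.integer(round(length(eng$freqs) / config$ofac)))
  best <- apply(eng$P, 2, which.max)
  peak <- eng$P[cbind(best, seq_along(best))]
  p <- .ls_fap(peak, M)
  p[eng$var <= 0] <- 1
  # phase of the best-frequency sinusoid, reported as its peak time mod period
  phase <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    k <- best[i]
    w <- 2 * pi * eng$freqs[k]
    cc <- cos(w * (times - eng$tau[k]))
    ss <- sin(w * (times - eng$tau[k]))
    a <- sum(eng$xc[i, ] * cc) / sum(cc^2)
    b <- sum(eng$xc[i, ] * ss) / sum(ss^2)
    phase[i] <- (atan2(b, a) / w + eng$tau[k]) %% (1 / eng$freqs[k])
  }
  data.frame(gene = rownames(X), p = p, q = NA_real_,
             best_period = 1 / eng$freqs[best], peak_power = peak,
             phase = phase, stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the Lomb-Scargle test on every gene of a dataset
#' @param es an \code{\link{expression_set}}.
#' @param config an \code{\link{np_config}}.
#' @return data.frame: gene, p, q (BH across genes), best_period, peak_power,
#'   phase.
#' @export
run_ls <- function(es, config = np_config()) {
  es <- .canonicalize(es)
  out <- run_ls_matrix(es$x, es$time, config)
  out$q <- bh_adjust(out$p)
  out
}

#' MetaCycle-style integration of the JTK and Lomb-Scargle results
#'
#' Fisher-combines the two p-values per gene (\code{\link{fisher_combine}}),
#' BH-adjusts the combined p across genes, and reports a consensus period
#' (arithmetic mean of the two period estimates) and a consensus phase (a
#' circular mean of the two phase estimates weighted by \eqn{-\ln p}; a
#' reporting convenience, not used for calling).
#'
#' @param jtk data.frame from \code{\link{run_jtk}} (or a single-row
#'   equivalent).
#' @param ls data.frame from \code{\link{run_ls}}, same genes in the same
#'   order.
#' @return data.frame: gene, p_jtk, p_ls, p_meta, q_meta, period, phase.
#' @export
meta_combine <- function(jtk, ls) {
  if (!identical(jtk$gene, ls$gene))
    stop("JTK and Lomb-Scargle results must cover the same genes in the same order",
         call. = FALSE)
  pj <- pmin(pmax(jtk$p, 1e-300), 1)
  pl <- pmin(pmax(ls$p, 1e-300), 1)
  p_meta <- vapply(seq_along(pj), function(i) fisher_combine(c(pj[i], pl[i])),
                   numeric(1))
  period <- (jtk$best_period + ls$best_period) / 2
  wj <- -log(pj); wl <- -log(pl)
  wj[wj + wl == 0] <- 1; wl[is.na(wl)] <- 0
  aj <- 2 * pi * jtk$best_lag / jtk$best_period
  al <- 2 * pi * ls$phase / ls$best_period
  ang <- atan2(wj * sin(aj) + wl * sin(al), wj * cos(aj) + wl * cos(al))
  phase <- (ang / (2 * pi) * period) %% period
  data.frame(gene = jtk$gene, p_jtk = jtk$p, p_ls = ls$p, p_meta = p_meta,
             q_meta = bh_adjust(p_meta), period = period, phase = phase,
             stringsAsFactors = FALSE)
}
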