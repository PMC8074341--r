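#' Configuration for the in-silico circadian benchmark generator
#'
#' Defaults emulate the benchmark design this package is built around: a 24-h
#' experiment sampled hourly with three replicates, 10,000 genes of which 30%
#' are rhythmic, rhythmic shapes drawn uniformly from the eight-template
#' catalogue, periods uniform on 20--28 h and phases half-normal with scale
#' 0.2 h. Non-rhythmic genes are Gaussian with per-gene mean and standard
#' deviation drawn from gamma distributions; rhythmic genes get a gamma-drawn
#' baseline, a gamma-drawn amplitude and per-sample Gaussian replicate noise
#' whose standard deviation is drawn from the same gamma as the non-rhythmic
#' one.
#'
#' @param n_genes total number of genes.
#' @param frac_rhythmic proportion of rhythmic genes in [0, 1].
#' @param duration experiment length in hours.
#' @param sampling_interval hours between consecutive time points; must divide
#'   \code{duration}.
#' @param n_replicates replicates per time point.
#' @param period_range range (hours) of the uniform period distribution.
#' @param phase_scale scale (hours) of the half-normal phase distribution.
#' @param amp_shape,amp_scale gamma parameters of rhythmic amplitudes.
#' @param mean_shape,mean_scale gamma parameters of per-gene baseline means.
#' @param sd_shape,sd_scale gamma parameters of per-gene noise/replicate
#'   standard deviations.
#' @param seed integer seed; the dataset is bit-reproducible given the seed.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 10000, frac_rhythmic = 0.30,
                       duration = 24, sampling_interval = 1, n_replicates = 3,
                       period_range = c(20, 28), phase_scale = 0.2,
                       amp_shape = 5, amp_scale = 1.2,
                       mean_shape = 2, mean_scale = 4,
                       sd_shape = 2, sd_scale = 0.5,
                       seed = NULL) {
  if (frac_rhythmic < 0 || frac_rhythmic > 1)
    stop("frac_rhythmic must be in [0, 1]", call. = FALSE)
  if (duration <= 0 || sampling_interval <= 0)
    stop("duration and sampling_interval must be positive", call. = FALSE)
  if (abs(duration / sampling_interval - round(duration / sampling_interval)) > 1e-9)
    stop("sampling_interval must divide duration", call. = FALSE)
  if (n_replicates < 1 || n_genes < 1) stop("need >= 1 gene and replicate", call. = FALSE)
  if (length(period_range) != 2 || diff(period_range) < 0 || period_range[1] <= 0)
    stop("period_range must be an increasing positive pair", call. = FALSE)
  scales <- c(phase_scale, amp_shape, amp_scale, mean_shape, mean_scale,
              sd_shape, sd_scale)
  if (any(scales <= 0)) stop("all distribution hyper-parameters must be > 0", call. = FALSE)
  structure(list(n_genes = n_genes, frac_rhythmic = frac_rhythmic,
                 duration = duration, sampling_interval = sampling_interval,
                 n_replicates = n_replicates, period_range = period_range,
                 phase_scale = phase_scale,
                 amp_shape = amp_shape, amp_scale = amp_scale,
                 mean_shape = mean_shape, mean_scale = mean_scale,
                 sd_shape = sd_shape, sd_scale = sd_scale, seed = seed),
            class = "sim_config")
}

# round-half-up, so e.g. 0.5 -> 1 regardless of IEEE round-to-even
.round_half_up <- function(x) floor(x + 0.5)

.run_seeded <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else rm(".Random.seed", envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  eval.parent(substitute(expr))
}

#' Simulate a benchmark expression dataset with known rhythmicity ground truth
#'
#' Exactly \code{round(n_genes * frac_rhythmic)} genes (round-half-up) are
#' rhythmic. Each rhythmic gene draws a shape uniformly from the eight
#' templates, a period from U(period_range), a phase from
#' half-normal(phase_scale), an amplitude and a baseline from the configured
#' gamma distributions, and shape extras from fixed documented ranges
#' (decay 0.01--0.08 1/h; |slope| 0.5--2 amplitudes per cycle; exponential
#' coefficient 0.5--2 amplitudes with rate 0.05--0.2 1/h; pulse width 1.5--4 h).
#' Gaussian replicate noise is added per sample. A \code{cosine_outlier} gene
#' is a cosine series with one uniformly chosen sample displaced by
#' U(3, 5) amplitudes in a random direction. Non-rhythmic genes are
#' independent Gaussian per sample with gamma-drawn per-gene mean and sd.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a list with elements \code{expr} (an
#'   \code{\link{expression_set}}) and \code{truth} (data.frame: gene,
#'   rhythmic, shape, amplitude, period, phase, lambda, slope, exp_coeff,
#'   exp_rate, peak_width, baseline, noise_sd, outlier_sample).
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 50, seed = 1))
#' dim(sim$expr)
#' table(sim$truth$rhythmic)
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config", call. = FALSE)
  .run_seeded(config$seed, {
    tp <- seq(0, config$duration - config$sampling_interval,
              by = config$sampling_interval)
    reps <- paste0("r", seq_len(config$n_replicates))
    time <- rep(tp, each = config$n_replicates)
    ind <- rep(reps, times = length(tp))
    sample_id <- paste0("t", time, "_", ind)
    ns <- length(sample_id)
    ng <- config$n_genes
    n_rhy <- .round_half_up(ng * config$frac_rhythmic)
    gene <- sprintf("gene_%05d", seq_len(ng))
    rhythmic <- c(rep(TRUE, n_rhy), rep(FALSE, ng - n_rhy))

    truth <- data.frame(gene = gene, rhythmic = rhythmic,
                        shape = NA_character_, amplitude = NA_real_,
                        period = NA_real_, phase = NA_real_,
                        lambda = NA_real_, slope = NA_real_,
                        exp_coeff = NA_real_, exp_rate = NA_real_,
                        peak_width = NA_real_, baseline = NA_real_,
                        noise_sd = NA_real_, outlier_sample = NA_character_,
                        stringsAsFactors = FALSE)
    x <- matrix(NA_real_, ng, ns, dimnames = list(gene, sample_id))

    truth$baseline <- stats::rgamma(ng, shape = config$mean_shape,
                                    scale = config$mean_scale)
    truth$noise_sd <- stats::rgamma(ng, shape = config$sd_shape,
                                    scale = config$sd_scale)

    if (n_rhy > 0) {
      shapes <- sample(curve_shapes(), n_rhy, replace = TRUE)
      A <- stats::rgamma(n_rhy, shape = config$amp_shape, scale = config$amp_scale)
      Tt <- stats::runif(n_rhy, config$period_range[1], config$period_range[2])
      phi <- abs(stats::rnorm(n_rhy, 0, config$phase_scale))
      truth$shape[1:n_rhy] <- shapes
      truth$amplitude[1:n_rhy] <- A
      truth$period[1:n_rhy] <- Tt
      truth$phase[1:n_rhy] <- phi
      t0 <- min(time)
      for (i in seq_len(n_rhy)) {
        par <- list(amplitude = A[i], period = Tt[i], phase = phi[i])
        sh <- shapes[i]
        if (sh == "dampened_cosine") {
          par$lambda <- stats::runif(1, 0.01, 0.08)
          truth$lambda[i] <- par$lambda
        } else if (sh == "cosine_linear") {
          par$slope <- sample(c(-1, 1), 1) * stats::runif(1, 0.5, 2) *
            A[i] / config$duration
          truth$slope[i] <- par$slope
        } else if (sh == "cosine_exponential") {
          par$exp_coeff <- stats::runif(1, 0.5, 2) * A[i]
          par$exp_rate <- stats::runif(1, 0.05, 0.2)
          truth$exp_coeff[i] <- par$exp_coeff
          truth$exp_rate[i] <- par$exp_rate
        } else if (sh == "peak") {
          par$peak_width <- stats::runif(1, 1.5, 4)
          truth$peak_width[i] <- par$peak_width
        }
        y <- truth$baseline[i] + .eval_curve(sh, par, time, t0 = t0) +
          stats::rnorm(ns, 0, truth$noise_sd[i])
        if (sh == "cosine_outlier") {
          j <- sample.int(ns, 1)
          y[j] <- y[j] + sample(c(-1, 1), 1) * stats::runif(1, 3, 5) * A[i]
          truth$outlier_sample[i] <- sample_id[j]
        }
        x[i, ] <- y
      }
    }
    if (ng > n_rhy) {
      idx <- (n_rhy + 1):ng
      x[idx, ] <- truth$baseline[idx] +
        matrix(stats::rnorm(length(idx) * ns), length(idx), ns) * truth$noise_sd[idx]
    }

    meta <- data.frame(sample = sample_id, time = time, ind = ind,
                       stringsAsFactors = FALSE)
    list(expr = expression_set(x, meta), truth = truth)
  })
}

#' Thin a dataset to a coarser sampling interval
#'
#' Keeps only the samples whose time, relative to the first sampled time, is a
#' multiple of \code{interval}. Replicates travel with their time point; any
#' ground-truth table is unaffected (genes are untouched).
#'
#' @param es an \code{\link{expression_set}}.
#' @param interval target sampling interval (hours); must be a multiple of the
#'   dataset's native interval.
#' @return an \code{expression_set} with the retained samples.
#' @export
downsample <- function(es, interval) {
  if (!inherits(es, "expression_set")) stop("es must be an expression_set", call. = FALSE)
  tms <- sort(unique(es$time))
  native <- min(diff(tms))
  if (interval < native ||
      abs(interval / native - round(interval / native)) > 1e-9)
    stop("interval (", interval, ") must be a multiple of the native sampling ",
         "interval (", native, ")", call. = FALSE)
  rel <- (es$time - min(es$time)) / interval
  keep <- abs(rel - round(rel)) < 1e-9
  expression_set(es$x[, keep, drop = FALSE], sample_meta(es)[keep, , drop = FALSE])
}
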