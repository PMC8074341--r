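#' Configuration for the parametric curve-fitting rhythm caller
#'
#' @param algorithm non-linear least-squares engine:
#'   \code{"levenberg-marquardt"} (default; box-constrained trust-region via
#'   \pkg{minpack.lm}), \code{"port"} (bounded quasi-Newton via
#'   \code{stats::nls}) or \code{"gauss-newton"} (\code{stats::nls} default;
#'   period bounds not enforced by this engine, fits at/outside the bounds are
#'   flagged).
#' @param init_period starting value for the period (hours); 24 by default,
#'   i.e. the period sought for circadian transcripts.
#' @param min_period,max_period box constraints on the period (hours).
#' @param use_random_effect if TRUE and the metadata carries more than one
#'   individual, a per-individual intercept with L2 shrinkage toward zero is
#'   estimated alongside the curve (a light approximation of a random
#'   intercept), absorbing systematic replicate offsets.
#' @param ranef_shrinkage shrinkage weight \eqn{\kappa} of the intercept
#'   update \eqn{b_j = \sum r_{ij} / (n_j + \kappa)}.
#' @param ranef_iterations alternating curve-fit / intercept-update rounds.
#' @param q_threshold,r2_threshold calling rule: a gene is rhythmic when its
#'   BH-adjusted Fisher-combined amplitude+period p-value is below
#'   \code{q_threshold} and its R-squared is at least \code{r2_threshold}.
#' @param max_iterations,tol optimizer iteration cap and convergence tolerance.
#' @return a list of class \code{circan_config}.
#' @export
circan_config <- function(algorithm = c("levenberg-marquardt", "port", "gauss-newton"),
                          init_period = 24, min_period = 20, max_period = 28,
                          use_random_effect = TRUE,
                          ranef_shrinkage = 1, ranef_iterations = 2,
                          q_threshold = 0.05, r2_threshold = 0.7,
                          max_iterations = 80, tol = 1e-8) {
  algorithm <- match.arg(algorithm)
  if (!(min_period < init_period && init_period < max_period))
    stop("need min_period < init_period < max_period", call. = FALSE)
  if (q_threshold <= 0 || q_threshold > 1) stop("q_threshold must be in (0, 1]", call. = FALSE)
  structure(list(algorithm = algorithm, init_period = init_period,
                 min_period = min_period, max_period = max_period,
                 use_random_effect = use_random_effect,
                 ranef_shrinkage = ranef_shrinkage,
                 ranef_iterations = max(1L, as.integer(ranef_iterations)),
                 q_threshold = q_threshold, r2_threshold = r2_threshold,
                 max_iterations = max_iterations, tol = tol),
            class = "circan_config")
}

#' Standardize one gene's expression to mean 0, sd 1
#'
#' \eqn{Z_{ti} = (X_{ti} - \mu_i) / S_i} with \eqn{\mu_i} the gene's mean
#' across samples and \eqn{S_i} its sample standard deviation. A
#' zero-variance gene cannot be standardized and is flagged unfittable rather
#' than raising an error, so matrix-level callers can skip it with an explicit
#' status.
#'
#' @param values numeric vector of one gene's per-sample expression.
#' @return list with \code{z} (standardized values or NULL), \code{mu},
#'   \code{s} and \code{ok} (FALSE when the gene is constant or has fewer than
#'   3 finite values).
#' @export
standardize <- function(values) {
  if (!is.numeric(values)) stop("values must be numeric", call. = FALSE)
  if (sum(is.finite(values)) < 3 || any(!is.finite(values)))
    return(list(z = NULL, mu = NA_real_, s = NA_real_, ok = FALSE))
  mu <- mean(values)
  s <- stats::sd(values)
  if (!is.finite(s) || s <= 0)
    return(list(z = NULL, mu = mu, s = s, ok = FALSE))
  list(z = (values - mu) / s, mu = mu, s = s, ok = TRUE)
}

#' Starting values for fitting one shape
#'
#' Amplitude starts at half the range of the standardized values, the period
#' at \code{config$init_period}, the phase at 0; decay/slope/exponential
#' extras start at 0 and the pulse width at one eighth of the starting period.
#'
#' @param z standardized values (numeric vector).
#' @param shape a fitting shape.
#' @param config a \code{\link{circan_config}}.
#' @return named numeric vector of starting values in
#'   \code{curve_parameter_names(shape)} order.
#' @export
initial_values <- function(z, shape, config = circan_config()) {
  nm <- curve_parameter_names(shape)
  st <- c(amplitude = abs(max(z) - min(z)) / 2,
          period = config$init_period, phase = 0,
          lambda = 0, slope = 0, exp_coeff = 0, exp_rate = 0,
          peak_width = config$init_period / 8)
  st[nm]
}

# box constraints per parameter; period box from config, amplitude >= 0,
# mild boxes on rate-type extras to keep noise fits identifiable
.param_bounds <- function(shape, config) {
  lower <- c(amplitude = 0, period = config$min_period, phase = -Inf,
             lambda = -0.5, slope = -Inf, exp_coeff = -Inf, exp_rate = 0,
             peak_width = 0.5)
  upper <- c(amplitude = Inf, period = config$max_period, phase = Inf,
             lambda = 0.5, slope = Inf, exp_coeff = Inf, exp_rate = 1,
             peak_width = config$max_period)
  nm <- curve_parameter_names(shape)
  list(lower = lower[nm], upper = upper[nm])
}

# one bounded NLS solve of `shape` (plus a free baseline/MESOR nuisance
# parameter) against y at `times`; returns list or NULL
.nls_solve <- function(shape, start, y, times, t0, config) {
  nm <- names(start)
  b <- .param_bounds(shape, config)
  lower <- c(-Inf, b$lower)
  upper <- c(Inf, b$upper)
  if (!"baseline" %in% nm) start <- c(baseline = 0, start)
  if (config$algorithm == "levenberg-marquardt") {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = start, lower = lower, upper = upper,
        fn = function(p, tt, yy)
          yy - p[["baseline"]] - .eval_curve(shape, as.list(p), tt, t0 = t0),
        tt = times, yy = y,
        control = minpack.lm::nls.lm.control(maxiter = config$max_iterations,
                                             ftol = config$tol, ptol = config$tol))),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    est <- fit$par
    conv <- fit$info %in% 1:3 && is.finite(fit$deviance)
    return(list(est = est, hessian = fit$hessian, deviance = fit$deviance,
                fitted = y - fit$fvec, converged = conv))
  }
  # stats::nls route (port honours bounds; gauss-newton does not)
  fml <- stats::as.formula(paste0(
    "yy ~ baseline + .curve_f('", shape, "', tt, ", t0, ", ",
    paste(setdiff(names(start), "baseline"), collapse = ", "), ")"))
  dat <- list(yy = y, tt = times)
  args <- list(formula = fml, data = dat, start = as.list(start),
               control = stats::nls.control(maxiter = config$max_iterations,
                                            tol = 1e-6, minFactor = 1e-10,
                                            warnOnly = TRUE))
  if (config$algorithm == "port") {
    args$algorithm <- "port"
    args$lower <- lower
    args$upper <- upper
  }
  fit <- tryCatch(suppressWarnings(do.call(stats::nls, args)),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  est <- stats::coef(fit)
  grad <- attr(fit$m$gradient(), "gradient")
  if (is.null(grad)) grad <- fit$m$gradient()
  list(est = est, hessian = crossprod(grad), deviance = stats::deviance(fit),
       fitted = stats::fitted(fit), converged = fit$convInfo$isConv %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wald standard errors from J'J. A rank-deficient J'J (e.g. an exponential
# term collapsing to a constant) leaves the unidentified directions with
# infinite variance while keeping finite SEs for well-identified parameters,
# instead of failing the whole covariance.
.wald_se <- function(jtj, resvar) {
  p <- nrow(jtj)
  eg <- tryCatch(eigen(jtj, symmetric = TRUE), error = function(e) NULL)
  if (is.null(eg) || !all(is.finite(eg$values))) return(rep(Inf, p))
  tol <- max(eg$values, 0) * 1e-10
  good <- eg$values > tol
  se <- numeric(p)
  for (i in seq_len(p)) {
    null_load <- if (any(!good)) max(abs(eg$vectors[i, !good])) else 0
    se[i] <- if (null_load > 1e-8) Inf
    else sqrt(sum(eg$vectors[i, good]^2 / eg$values[good]) * resvar)
  }
  se[!is.finite(se)] <- Inf
  se
}

# helper referenced from the stats::nls formula built in .nls_solve
.curve_f <- function(shape, t, t0, amplitude, period, phase,
                     lambda = 0, slope = 0, exp_coeff = 0, exp_rate = 0,
                     peak_width = 3) {
  .eval_curve(shape, list(amplitude = amplitude, period = period, phase = phase,
                          lambda = lambda, slope = slope, exp_coeff = exp_coeff,
                          exp_rate = exp_rate, peak_width = peak_width), t, t0 = t0)
}

#' Fit one curve template to one standardized gene
#'
#' Bounded non-linear least squares of the template against the standardized
#' values, with the period constrained to
#' \code{[min_period, max_period]}. A free baseline (the cosinor MESOR) is
#' always fitted alongside the template as a nuisance parameter: templates
#' whose mean over a partial cycle is non-zero (e.g. the Gaussian pulse
#' train, or any template when the window is not a whole number of periods)
#' would otherwise be unrepresentable on mean-centred standardized data and
#' the period estimate would be biased. With multiple individuals and
#' \code{use_random_effect}, per-individual intercepts with L2 shrinkage are
#' alternated with the curve fit, absorbing replicate offsets; they are
#' treated as nuisance, so the residual degrees of freedom for the Wald tests
#' stay \eqn{n - p_{curve}}. Per-parameter two-sided p-values come from
#' asymptotic t statistics using the Jacobian-based covariance; a singular
#' Jacobian yields infinite standard errors and p = 1 rather than a failure.
#' If the first solve does not converge, two alternative phase starts (a
#' quarter and a half starting period) are tried.
#'
#' @param z standardized values.
#' @param times sampling times (hours), one per value.
#' @param individuals individual/replicate ids, one per value (or NULL).
#' @param shape a fitting shape.
#' @param config a \code{\link{circan_config}}.
#' @return list of class \code{fit_result}: shape, estimates, se, p (named
#'   vectors), intercepts, r2, aic, bic, converged, at_bound, status.
#' @export
fit_shape <- function(z, times, individuals = NULL, shape,
                      config = circan_config()) {
  nm <- curve_parameter_names(shape)
  n <- length(z)
  p <- length(nm)
  p_fit <- p + 1L   # curve parameters plus the baseline (MESOR) nuisance
  fail <- function(status) {
    est <- stats::setNames(rep(NA_real_, p), nm)
    list(shape = shape, estimates = est, se = est,
         p = stats::setNames(rep(1, p), nm), intercepts = NULL, baseline = NA_real_,
         r2 = NA_real_, aic = NA_real_, bic = NA_real_,
         converged = FALSE, at_bound = FALSE, status = status)
  }
  if (n < p_fit + 2) return(fail("too_few_samples"))
  t0 <- min(times)
  use_re <- isTRUE(config$use_random_effect) && !is.null(individuals) &&
    length(unique(individuals)) > 1
  ind_f <- if (use_re) factor(individuals)
  start0 <- initial_values(z, shape, config)

  # shrunk per-individual intercepts from the residuals of a curve fit
  update_intercepts <- function(est) {
    res <- z - est[["baseline"]] - .eval_curve(shape, as.list(est), times, t0 = t0)
    sums <- tapply(res, ind_f, sum)
    ns <- tabulate(ind_f)
    stats::setNames(as.numeric(sums) / (ns + config$ranef_shrinkage),
                    levels(ind_f))
  }

  # alternating refinement: intercept update, then curve refit, starting from
  # an intercept-free fit (the selection among starts is done without the
  # random effect, which only shifts replicate means and does not change
  # which basin a start lands in)
  refine_re <- function(fit) {
    if (!use_re || is.null(fit) || !fit$converged) {
      if (!is.null(fit)) fit$intercepts <- NULL
      return(fit)
    }
    intercepts <- stats::setNames(rep(0, nlevels(ind_f)), levels(ind_f))
    for (it in seq_len(max(0L, config$ranef_iterations - 1L))) {
      intercepts <- update_intercepts(fit$est)
      refit <- .nls_solve(shape, fit$est, z - intercepts[ind_f], times, t0, config)
      if (is.null(refit) || !refit$converged) break
      fit <- refit
    }
    fit$intercepts <- intercepts
    fit
  }

  run_from <- function(start) .nls_solve(shape, start, z, times, t0, config)

  starts <- list(start0)
  # trend shapes get a second, trend-first start (trend term from a direct
  # regression, amplitude from the detrended residual range) so that a series
  # dominated by its trend is not absorbed into a spurious long-period cosine
  if (shape == "cosine_linear") {
    ct <- times - mean(times)
    sl <- sum(ct * z) / sum(ct^2)
    alt <- start0
    alt[["slope"]] <- sl
    alt[["amplitude"]] <- abs(max(z - sl * times) - min(z - sl * times)) / 2
    starts <- c(starts, list(alt))
  } else if (shape == "cosine_exponential") {
    k0 <- 0.1
    e <- exp(-k0 * (times - t0))
    ce <- e - mean(e)
    alt <- start0
    alt[["exp_rate"]] <- k0
    alt[["exp_coeff"]] <- sum(ce * z) / sum(ce^2)
    starts <- c(starts, list(alt))
  } else if (shape == "peak") {
    # a pulse train showing a single pulse in the window identifies its period
    # only through the neighbouring pulse's tail, so the period surface is
    # nearly flat and start-sensitive: seed the pulse at the observed maximum
    # and try short, default and long period starts
    for (T0 in unique(c(config$init_period, config$min_period + 1,
                        config$max_period - 1))) {
      alt <- start0
      alt[["amplitude"]] <- max(z) - min(z)
      alt[["period"]] <- T0
      alt[["phase"]] <- times[which.max(z)]
      starts <- c(starts, list(alt))
    }
  }
  fit <- NULL
  for (st in starts) {
    cand <- run_from(st)
    if (!is.null(cand) && cand$converged &&
        (is.null(fit) || !fit$converged || cand$deviance < fit$deviance))
      fit <- cand
    else if (is.null(fit)) fit <- cand
  }
  if (is.null(fit) || !fit$converged) {
    for (ph in config$init_period * c(1 / 4, 1 / 2)) {
      alt <- start0
      alt[["phase"]] <- ph
      cand <- run_from(alt)
      if (!is.null(cand) && cand$converged &&
          (is.null(fit) || !fit$converged || cand$deviance < fit$deviance)) {
        fit <- cand
      }
      if (!is.null(fit) && fit$converged) break
    }
  }
  fit <- refine_re(fit)
  if (is.null(fit)) return(fail("fit_error"))

  est_all <- fit$est                      # baseline first, then curve params
  rdf <- n - p_fit
  resvar <- fit$deviance / rdf
  se_all <- .wald_se(fit$hessian, resvar)
  tval <- est_all / se_all
  tval[se_all == 0 & est_all == 0] <- 0   # 0/0 from an exact-zero estimate on a perfect fit
  pval_all <- 2 * stats::pt(abs(tval), rdf, lower.tail = FALSE)
  pval_all[!is.finite(pval_all)] <- 1
  names(se_all) <- names(pval_all) <- names(est_all)
  est <- est_all[nm]
  se <- se_all[nm]
  pval <- pval_all[nm]

  ss_tot <- sum((z - mean(z))^2)
  r2 <- 1 - fit$deviance / ss_tot
  # identical Gaussian criterion across shapes (p_fit curve+baseline
  # parameters plus the residual variance) so AIC comparisons are fair
  aic <- n * log(max(fit$deviance, 1e-300) / n) + 2 * (p_fit + 1)
  bic <- n * log(max(fit$deviance, 1e-300) / n) + log(n) * (p_fit + 1)

  b <- .param_bounds(shape, config)
  at_bound <- any(abs(est - b$lower) < 1e-6 | abs(est - b$upper) < 1e-6,
                  na.rm = TRUE)

  list(shape = shape, estimates = est, se = se, p = pval,
       intercepts = fit$intercepts, baseline = est_all[["baseline"]],
       r2 = r2, aic = aic, bic = bic,
       converged = isTRUE(fit$converged), at_bound = at_bound,
       status = if (isTRUE(fit$converged)) "ok" else "not_converged")
}

#' Pick the best fit by lowest AIC
#'
#' Among converged fits, returns the one with minimal AIC; ties are broken by
#' lower BIC, then by the fixed shape order of \code{curve_shapes(TRUE)}. If
#' no fit converged, an all-NA record with status \code{"no_fit"} is returned.
#'
#' @param fits a non-empty list of \code{fit_result}s.
#' @return a single \code{fit_result}.
#' @export
select_best_fit <- function(fits) {
  if (length(fits) == 0) stop("empty fit list", call. = FALSE)
  conv <- Filter(function(f) isTRUE(f$converged) && is.finite(f$aic), fits)
  if (length(conv) == 0) {
    rec <- fits[[1]]
    rec$shape <- NA_character_
    rec$estimates[] <- NA_real_
    rec$converged <- FALSE
    rec$status <- "no_fit"
    return(rec)
  }
  ord <- order(vapply(conv, `[[`, 0, "aic"),
               vapply(conv, `[[`, 0, "bic"),
               match(vapply(conv, `[[`, "", "shape"), .FITTING_SHAPES))
  conv[[ord[1]]]
}

#' Combine p-values with Fisher's method
#'
#' \eqn{X^2 = -2 \sum_i \ln p_i} referred to a chi-square distribution with
#' \eqn{2k} degrees of freedom. p-values are floored at 1e-300 before the log
#' so that a numerically-zero p cannot produce an infinite statistic.
#'
#' @param p_values vector of p-values in (0, 1].
#' @return the combined p-value.
#' @examples
#' fisher_combine(c(1, 1))        # 1
#' fisher_combine(c(0.05, 0.05))  # ~0.0175
#' @export
fisher_combine <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (length(p_values) < 1 || any(is.na(p_values)))
    stop("need >= 1 non-missing p-value", call. = FALSE)
  if (any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  p_values <- pmax(p_values, 1e-300)
  x2 <- -2 * sum(log(p_values))
  stats::pchisq(x2, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (delegated to
#' \code{stats::p.adjust}); NAs are carried through without entering the
#' family size.
#'
#' @param p_values vector of p-values in [0, 1] (NA allowed).
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Run the parametric curve-fitting rhythm caller on a dataset
#'
#' Per gene: standardize, fit each of the seven templates, keep the
#' lowest-AIC converged fit, Fisher-combine the amplitude and period Wald
#' p-values, then BH-adjust the combined p across all genes with a converged
#' best fit. A gene is called rhythmic when \code{combined_q < q_threshold}
#' and \code{r2 >= r2_threshold}. Amplitude-like estimates (amplitude, slope,
#' exponential coefficient) are rescaled back to the original expression
#' units via the gene's standard deviation; the phase is reported modulo the
#' period into [0, period). Works on uneven or gappy sampling: no regular
#' time grid is assumed.
#'
#' @param es an \code{\link{expression_set}}.
#' @param config a \code{\link{circan_config}}.
#' @param shapes fitting shapes to try (default: all seven).
#' @param verbose print progress every 500 genes.
#' @return data.frame, one row per gene, with the best shape, parameter
#'   estimates/SEs/p-values, amplitude and period q-values, R-squared,
#'   AIC/BIC, combined_p, combined_q and the rhythmic flag.
#' @export
run_circan <- function(es, config = circan_config(),
                       shapes = curve_shapes(fitting = TRUE), verbose = FALSE) {
  if (!inherits(es, "expression_set")) stop("es must be an expression_set", call. = FALSE)
  stopifnot(all(shapes %in% .FITTING_SHAPES))
  es <- .canonicalize(es)
  ng <- nrow(es$x)
  genes <- rownames(es$x)
  allpar <- c("amplitude", "period", "phase", "lambda", "slope",
              "exp_coeff", "exp_rate", "peak_width")
  out <- data.frame(gene = genes, status = "ok", shape = NA_character_,
                    stringsAsFactors = FALSE)
  for (pn in allpar) out[[pn]] <- NA_real_
  out$amplitude_se <- out$amplitude_p <- out$period_se <- out$period_p <-
    out$phase_p <- out$r2 <- out$aic <- out$bic <- NA_real_
  out$converged <- FALSE
  out$at_bound <- FALSE
  out$mean_expr <- out$sd_expr <- out$combined_p <- NA_real_

  rescale <- c("amplitude", "slope", "exp_coeff")  # expression-unit parameters
  for (i in seq_len(ng)) {
    if (verbose && i %% 500 == 0)
      message("fitting gene ", i, "/", ng)
    std <- standardize(es$x[i, ])
    out$mean_expr[i] <- std$mu
    out$sd_expr[i] <- std$s
    if (!std$ok) {
      out$status[i] <- "unfittable"
      next
    }
    fits <- lapply(shapes, function(sh)
      fit_shape(std$z, es$time, es$ind, sh, config))
    best <- select_best_fit(fits)
    out$status[i] <- best$status
    out$converged[i] <- best$converged
    if (!best$converged) next
    out$shape[i] <- best$shape
    est <- best$estimates
    est[["phase"]] <- est[["phase"]] %% est[["period"]]
    for (pn in names(est)) {
      scale <- if (pn %in% rescale) std$s else 1
      out[[pn]][i] <- est[[pn]] * scale
    }
    out$amplitude_se[i] <- best$se[["amplitude"]] * std$s
    out$amplitude_p[i] <- best$p[["amplitude"]]
    out$period_se[i] <- best$se[["period"]]
    out$period_p[i] <- best$p[["period"]]
    out$phase_p[i] <- best$p[["phase"]]
    out$r2[i] <- best$r2
    out$aic[i] <- best$aic
    out$bic[i] <- best$bic
    out$at_bound[i] <- best$at_bound
    out$combined_p[i] <- fisher_combine(c(max(best$p[["amplitude"]], 1e-300),
                                          max(best$p[["period"]], 1e-300)))
  }
  # multiple-testing family: genes with a converged best fit
  out$amplitude_q <- out$period_q <- out$combined_q <- NA_real_
  fam <- which(out$converged)
  out$amplitude_q[fam] <- bh_adjust(out$amplitude_p[fam])
  out$period_q[fam] <- bh_adjust(out$period_p[fam])
  out$combined_q[fam] <- bh_adjust(out$combined_p[fam])
  out$rhythmic <- !is.na(out$combined_q) & out$combined_q < config$q_threshold &
    !is.na(out$r2) & out$r2 >= config$r2_threshold
  out
}
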