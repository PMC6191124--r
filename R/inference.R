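# Statistical comparison of observed vs chance-expected NNDs (gamma mixed
# model with AICc decision rule), across-year ANOVA, and nest-count trend.

#' Small-sample Akaike information criterion
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1).
#'
#' @param log_likelihood fitted model log-likelihood.
#' @param k number of estimated parameters (fixed-effect coefficients +
#'   variance components + any residual/shape parameter).
#' @param n number of observations.
#' @return AICc value.
#' @export
aicc <- function(log_likelihood, k, n) {
  if (n <= k + 1)
    stop("AICc undefined for n <= k + 1 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Assemble the observed/simulated NND observation table
#'
#' Long-format table feeding the mixed model: one row per observed NND and
#' one per simulated NND. Simulated NNDs are distances measured from an
#' observed nest to the nearest random nest, so they carry the year,
#' territory and nest identifiers of that observed nest — which is what
#' makes those grouping factors shared across the two kinds.
#'
#' @param observed_by_year named list (by year) of \code{nnd_result} objects
#'   whose distances are named by nest id.
#' @param simulated_by_year named list (same years) of \code{sim_nnd_set}
#'   objects (columns named by nest id).
#' @param territory_of named character vector mapping nest_id to
#'   territory_id; defaults to the nest ids themselves (one-nest
#'   territories, e.g. territory centroids).
#' @return data.frame with columns \code{nnd_m, kind, year, territory_id,
#'   nest_id}.
#' @export
nnd_observation_table <- function(observed_by_year, simulated_by_year,
                                  territory_of = NULL) {
  if (!identical(names(observed_by_year), names(simulated_by_year)))
    stop("observed and simulated year lists must align", call. = FALSE)
  terr <- function(ids) {
    if (is.null(territory_of)) ids else unname(territory_of[ids])
  }
  rows <- lapply(names(observed_by_year), function(yr) {
    o <- observed_by_year[[yr]]
    nnd <- if (inherits(o, "nnd_result")) o$per_point_nnd_m else o
    ids <- names(nnd)
    if (is.null(ids)) stop("observed NNDs must be named by nest id", call. = FALSE)
    s <- simulated_by_year[[yr]]
    m <- if (inherits(s, "sim_nnd_set")) s$values_m else as.matrix(s)
    if (!identical(colnames(m), ids))
      m <- m[, ids, drop = FALSE]
    rbind(
      data.frame(nnd_m = unname(nnd), kind = "observed", year = yr,
                 territory_id = terr(ids), nest_id = ids,
                 stringsAsFactors = FALSE),
      data.frame(nnd_m = as.vector(m), kind = "simulated", year = yr,
                 territory_id = rep(terr(ids), each = nrow(m)),
                 nest_id = rep(ids, each = nrow(m)),
                 stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Observed-vs-null mixed-model comparison
#'
#' Fits a gamma GLMM (log link) to the pooled observed and simulated NNDs
#' with the NND kind (observed/simulated) as fixed factor and random
#' intercepts for year, territory and nest, then the same model without the
#' fixed factor (null model). Evidence for territorial spacing is a full
#' model beating the null by at least 6 AICc points. Reported coefficients
#' are on the response scale: alpha is the model-predicted mean simulated
#' NND (intercept), beta the predicted observed-minus-simulated difference;
#' their standard errors come from the delta method.
#'
#' @param table observation table from \code{\link{nnd_observation_table}}
#'   (columns \code{nnd_m, kind}, plus the random-factor columns in use).
#' @param random character vector of random-intercept factors, a subset of
#'   c("year", "territory_id", "nest_id"). At the multi-annual scale, where
#'   centroid = nest = territory and there is no year stratum, use
#'   "territory_id" only.
#' @param backend "gamma" (glmmTMB gamma family, log link; the default),
#'   "lognormal" (lme4 linear mixed model on log NND; AICc then compared on
#'   the log scale — the decision rule only uses differences within one
#'   backend), or "auto" (gamma, falling back to lognormal if the gamma fit
#'   does not converge; the returned \code{backend} records which one
#'   produced the numbers).
#' @return object of class \code{model_comparison}: list with
#'   \code{aicc_null}, \code{aicc_full}, \code{delta_i}, \code{alpha},
#'   \code{alpha_se}, \code{beta}, \code{beta_se}, \code{territorial},
#'   \code{backend}, \code{k_full}, \code{k_null}, \code{n}.
#' @export
compare_observed_vs_null <- function(table,
                                     random = c("year", "territory_id", "nest_id"),
                                     backend = c("gamma", "lognormal", "auto")) {
  backend <- match.arg(backend)
  if (backend == "auto") {
    out <- tryCatch(
      compare_observed_vs_null(table, random = random, backend = "gamma"),
      error = function(e) NULL)
    if (is.null(out)) {
      out <- compare_observed_vs_null(table, random = random,
                                      backend = "lognormal")
      out$fallback_reason <- "gamma GLMM did not converge"
    }
    return(out)
  }
  kinds <- unique(table$kind)
  if (!all(c("observed", "simulated") %in% kinds))
    stop("table must contain both observed and simulated NNDs", call. = FALSE)
  if (any(table$nnd_m <= 0)) stop("NNDs must be positive", call. = FALSE)
  random <- intersect(random, names(table))
  if (!length(random)) stop("no random-factor columns found", call. = FALSE)
  d <- table
  d$kind <- factor(d$kind, levels = c("simulated", "observed"))
  for (v in random) d[[v]] <- factor(d[[v]])
  re <- paste(sprintf("(1 | %s)", random), collapse = " + ")
  f_full <- stats::as.formula(paste("nnd_m ~ kind +", re))
  f_null <- stats::as.formula(paste("nnd_m ~ 1 +", re))
  n <- nrow(d)

  if (backend == "gamma") {
    # convergence is checked explicitly below; silence the duplicate warning
    fit <- function(f) suppressWarnings(
      glmmTMB::glmmTMB(f, data = d, family = stats::Gamma(link = "log")))
    m_full <- fit(f_full); m_null <- fit(f_null)
    check_tmb_convergence(m_full, d)
    check_tmb_convergence(m_null, d)
    fe <- glmmTMB::fixef(m_full)$cond
    V <- stats::vcov(m_full)$cond
  } else {
    d$log_nnd <- log(d$nnd_m)
    f_full <- stats::as.formula(paste("log_nnd ~ kind +", re))
    f_null <- stats::as.formula(paste("log_nnd ~ 1 +", re))
    # marginal gradient warnings at lme4's strict tolerance are routine for
    # this model family; the AICc contrast is insensitive to them
    fit <- function(f) suppressWarnings(suppressMessages(
      lme4::lmer(f, data = d, REML = FALSE)))
    m_full <- fit(f_full); m_null <- fit(f_null)
    fe <- lme4::fixef(m_full)
    V <- as.matrix(stats::vcov(m_full))
  }
  ll_full <- stats::logLik(m_full); ll_null <- stats::logLik(m_null)
  k_full <- attr(ll_full, "df"); k_null <- attr(ll_null, "df")
  a_full <- aicc(as.numeric(ll_full), k_full, n)
  a_null <- aicc(as.numeric(ll_null), k_null, n)
  delta <- a_null - a_full

  # response scale: alpha = exp(b0); beta = exp(b0 + b1) - exp(b0)
  b0 <- unname(fe[1]); b1 <- unname(fe[2])
  alpha <- exp(b0)
  beta <- exp(b0 + b1) - exp(b0)
  alpha_se <- alpha * sqrt(V[1, 1])
  grad <- c(exp(b0 + b1) - exp(b0), exp(b0 + b1))
  beta_se <- sqrt(drop(t(grad) %*% V %*% grad))

  structure(list(aicc_null = a_null, aicc_full = a_full, delta_i = delta,
                 alpha = alpha, alpha_se = alpha_se,
                 beta = beta, beta_se = beta_se,
                 territorial = delta >= 6,
                 backend = backend, k_full = k_full, k_null = k_null, n = n,
                 random = random),
            class = "model_comparison")
}

check_tmb_convergence <- function(m, d) {
  ok <- isTRUE(m$fit$convergence == 0) && isTRUE(m$sdr$pdHess)
  if (!ok) {
    res <- tryCatch(stats::quantile(stats::residuals(m)), error = function(e) NA)
    stop("gamma GLMM did not converge; residual summary: ",
         paste(signif(res, 4), collapse = " "), call. = FALSE)
  }
  invisible(m)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %s backend, n = %d\n", x$backend, x$n))
  cat(sprintf("  AICc null %.1f  full %.1f  delta_i %.1f  -> %s\n",
              x$aicc_null, x$aicc_full, x$delta_i,
              if (x$territorial) "territorial spacing (delta >= 6)"
              else "no evidence of spacing (delta < 6)"))
  cat(sprintf("  alpha (mean simulated NND) %.2f +/- %.2f m\n", x$alpha, x$alpha_se))
  cat(sprintf("  beta (observed - simulated) %.2f +/- %.2f m\n", x$beta, x$beta_se))
  invisible(x)
}

#' One-way ANOVA of NNDs across years
#'
#' Fixed-effects one-way ANOVA on the raw per-nest NNDs with year as the
#' grouping factor.
#'
#' @param nnds_by_year named list (by year) of numeric NND vectors or
#'   \code{nnd_result} objects; needs >= 2 years, each with >= 2 values.
#' @return list with \code{F}, \code{df1}, \code{df2}, \code{p}.
#' @export
annual_nnd_anova <- function(nnds_by_year) {
  vals <- lapply(nnds_by_year, function(o)
    if (inherits(o, "nnd_result")) unname(o$per_point_nnd_m) else as.numeric(o))
  if (length(vals) < 2)
    stop("need at least 2 years for the across-year ANOVA", call. = FALSE)
  if (any(lengths(vals) < 2))
    stop("every year needs at least 2 NND values", call. = FALSE)
  d <- data.frame(nnd = unlist(vals),
                  year = factor(rep(names(vals), lengths(vals))))
  ow <- stats::oneway.test(nnd ~ year, data = d, var.equal = TRUE)
  list(F = unname(ow$statistic), df1 = unname(ow$parameter[1]),
       df2 = unname(ow$parameter[2]), p = unname(ow$p.value))
}

#' Trend in annual nest counts
#'
#' Pearson correlation between the number of active nests and the year,
#' with the two-sided t-test p-value.
#'
#' @param counts_by_year data.frame with columns \code{year} and \code{n},
#'   or a numeric vector of counts named by year.
#' @return list with \code{r}, \code{p}, \code{n} (number of years).
#' @export
count_trend <- function(counts_by_year) {
  if (is.data.frame(counts_by_year)) {
    yrs <- as.numeric(counts_by_year$year)
    cnt <- as.numeric(counts_by_year$n)
  } else {
    yrs <- as.numeric(names(counts_by_year))
    cnt <- as.numeric(counts_by_year)
  }
  if (length(cnt) < 3) stop("need at least 3 years for a trend test", call. = FALSE)
  if (stats::sd(cnt) == 0)
    stop("counts are constant; trend correlation undefined", call. = FALSE)
  ct <- stats::cor.test(cnt, yrs, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(cnt))
}
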