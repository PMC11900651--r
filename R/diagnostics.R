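#' Conditional weighted residuals
#'
#' FOCE residual diagnostic: per subject, the linearized population
#' residual `r = y - f(eta_hat) + G * eta_hat` is decorrelated by the
#' Cholesky factor of the approximate marginal covariance
#' `Sigma = G omega^2 G' + V`. Under a correct model CWRES are
#' approximately standard normal, so values should lie mostly within
#' plus/minus 3.
#'
#' @param fit a `vcm_fit` from [fit_population()].
#' @return data.frame with `id`, `time`, `type`, `dv`, `ipred`
#'   (conditional prediction), `pred` (population prediction at
#'   `eta = 0`), `cwres`, and a `flagged` column marking observations
#'   whose conditional covariance was numerically singular.
#' @export
cwres <- function(fit) {
  stopifnot(inherits(fit, "vcm_fit"))
  om2 <- omega_sd(fit$model)^2
  out <- lapply(fit$subjects, function(s) {
    n <- length(s$y)
    Sig <- diag(s$v, n) + om2 * tcrossprod(s$g)
    r <- s$y - s$f + s$g * s$eta
    cw <- tryCatch(forwardsolve(t(chol(Sig)), r), error = function(e) NULL)
    flagged <- is.null(cw)
    if (flagged) cw <- rep(NA_real_, n)
    data.frame(id = s$id, time = s$t, type = s$type, dv = s$y,
               ipred = s$f, pred = s$f - s$g * s$eta, cwres = cw,
               flagged = flagged)
  })
  do.call(rbind, out)
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets from the fitted model (new etas
#' and residual draws at the observed design), bins observations by time
#' after the most recent dose, and compares observed percentiles with the
#' simulation bands.
#'
#' @param fit a `vcm_fit`.
#' @param n_sim number of simulated replicates.
#' @param probs percentiles to track (default 5th, 50th, 95th).
#' @param n_bins number of time-after-dose bins (equal-count binning).
#' @param seed RNG seed.
#' @return object of class `vcm_vpc`: a data.frame with one row per bin
#'   and percentile, holding the observed percentile and the 2.5%, 50%,
#'   97.5% envelope of that percentile across replicates; bins that end up
#'   empty are dropped with a notice.
#' @export
vpc <- function(fit, n_sim = 1000, probs = c(0.05, 0.5, 0.95),
                n_bins = 4, seed = NULL) {
  stopifnot(inherits(fit, "vcm_fit"))
  prep <- pk_subjects(fit$data)
  model <- fit$model
  tad <- unlist(lapply(prep, function(s) {
    vapply(s$t, function(ti) {
      prior <- s$dose_t[s$dose_t <= ti]
      ti - if (length(prior)) max(prior) else 0
    }, 0)
  }))
  obs <- unlist(lapply(prep, `[[`, "y"))
  breaks <- unique(quantile(tad, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 2) breaks <- range(tad) + c(-1e-9, 1e-9)
  bin <- cut(tad, breaks, include.lowest = TRUE)
  keep <- table(bin) > 0
  if (any(!keep)) message("dropping ", sum(!keep), " empty VPC bin(s)")

  pct_by_bin <- function(y) {
    do.call(rbind, lapply(levels(bin)[keep], function(b) {
      quantile(y[bin == b], probs = probs, names = FALSE)
    }))
  }
  obs_p <- pct_by_bin(obs)

  sims <- with_seed(derive_seed(seed, "vpc"), {
    lapply(seq_len(n_sim), function(r) {
      y <- unlist(lapply(prep, function(s) {
        eta <- sample_eta(model, 1)
        p <- pk_params(cl_typical(model, s$cov) * exp(eta), model$q,
                       vc_typical(model, s$cov), model$vp)
        f <- concentration(p, data.frame(time = s$dose_t, amt = s$dose_amt,
                                         dur = s$dose_dur), s$t)
        pmax(f + sqrt(model$sigma$add^2 + (model$sigma$prop * f)^2) *
               rnorm(length(f)), 0)
      }))
      pct_by_bin(y)
    })
  })
  arr <- simplify2array(sims)  # bins x probs x reps
  env <- apply(arr, c(1, 2), quantile, probs = c(0.025, 0.5, 0.975))

  bins_kept <- levels(bin)[keep]
  mids <- vapply(bins_kept, function(b) median(tad[bin == b]), 0)
  out <- do.call(rbind, lapply(seq_along(probs), function(j) {
    data.frame(bin = bins_kept, tad_mid = mids, pctl = 100 * probs[j],
               observed = obs_p[, j], sim_lo = env[1, , j],
               sim_med = env[2, , j], sim_hi = env[3, , j])
  }))
  rownames(out) <- NULL
  class(out) <- c("vcm_vpc", "data.frame")
  out
}

#' @export
plot.vcm_vpc <- function(x, ...) {
  df <- as.data.frame(x)
  plot(range(df$tad_mid), range(c(df$observed, df$sim_lo, df$sim_hi)),
       type = "n", xlab = "time after dose (h)",
       ylab = "concentration (mg/L)", main = "Visual predictive check", ...)
  for (p in unique(df$pctl)) {
    d <- df[df$pctl == p, ]
    d <- d[order(d$tad_mid), ]
    graphics::polygon(c(d$tad_mid, rev(d$tad_mid)),
                      c(d$sim_lo, rev(d$sim_hi)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(d$tad_mid, d$observed, type = "b", pch = 19)
  }
  invisible(x)
}
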