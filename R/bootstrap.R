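#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement, refits the model (warm-started at
#' the point estimates, without standard errors for speed), and summarizes
#' the replicate estimates by their median, SD, CV% and percentile 95%
#' interval. Replicates that fail to converge are counted and excluded; a
#' warning is raised when more than 20% fail.
#'
#' @param fit a `vcm_fit` from [fit_population()].
#' @param n_boot number of bootstrap replicates.
#' @param seed RNG seed for the resampling.
#' @param indices optional list of subject-ID vectors, one per replicate,
#'   overriding random resampling (e.g. the identity resample for
#'   checks).
#' @param fix passed through to [fit_population()].
#' @return object of class `vcm_bootstrap`: list with `summary` (one row
#'   per parameter: estimate = replicate median, se, cv_pct, ci_lo,
#'   ci_hi), `replicates` (matrix), `n_failed`.
#' @export
pk_bootstrap <- function(fit, n_boot = 1000, seed = NULL, indices = NULL,
                         fix = character()) {
  stopifnot(inherits(fit, "vcm_fit"))
  data <- fit$data
  ids <- unique(data$ID)
  if (!is.null(indices)) n_boot <- length(indices)
  draws <- with_seed(derive_seed(seed, "bootstrap"), {
    lapply(seq_len(n_boot), function(b) {
      if (!is.null(indices)) indices[[b]]
      else sample(ids, length(ids), replace = TRUE)
    })
  })
  layout_names <- fit$estimates$param
  reps <- matrix(NA_real_, n_boot, length(layout_names),
                 dimnames = list(NULL, layout_names))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    take <- draws[[b]]
    blocks <- lapply(seq_along(take), function(j) {
      blk <- data[data$ID == take[j], , drop = FALSE]
      blk$ID <- j  # duplicated subjects become distinct IDs
      blk
    })
    boot_data <- as_pk_dataset(do.call(rbind, blocks))
    bf <- tryCatch(
      fit_population(boot_data, init = fit$model, fix = fix, se = FALSE),
      error = function(e) NULL)
    if (is.null(bf) || !bf$converged) {
      n_failed <- n_failed + 1L
      next
    }
    reps[b, bf$estimates$param] <- bf$estimates$estimate
  }
  if (n_failed > 0.2 * n_boot) {
    warning(sprintf("%d of %d bootstrap replicates failed to converge",
                    n_failed, n_boot))
  }
  ok <- reps[rowSums(is.na(reps)) == 0, , drop = FALSE]
  summ <- data.frame(
    param = layout_names,
    estimate = apply(ok, 2, median),
    se = apply(ok, 2, sd),
    cv_pct = 100 * apply(ok, 2, sd) / abs(apply(ok, 2, median)),
    ci_lo = apply(ok, 2, quantile, 0.025),
    ci_hi = apply(ok, 2, quantile, 0.975),
    row.names = NULL)
  structure(list(summary = summ, replicates = reps, n_failed = n_failed,
                 n_boot = n_boot),
            class = "vcm_bootstrap")
}

#' @export
print.vcm_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap: %d replicates (%d failed)\n", x$n_boot,
              x$n_failed))
  tab <- x$summary
  tab[-1] <- lapply(tab[-1], signif, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}
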