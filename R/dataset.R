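#' NONMEM-style pharmacokinetic event dataset
#'
#' A `pk_dataset` is a data.frame in the usual event schema: one row per
#' dosing event (`EVID = 1`, with `AMT` in mg and `RATE` in mg/h) or
#' observation (`EVID = 0`, with `DV` in mg/L and `MDV = 0`), plus the
#' baseline covariate columns `AGE`, `SEX` (1 = male, 0 = female), `WT`,
#' `HT`, `SCR`, `ALB`. Optional columns `TYPE` ("peak"/"trough") and
#' `BLQ` (below limit of quantitation flag) are carried when present.
#'
#' `as_pk_dataset()` validates and canonicalizes: required columns exist,
#' times are non-negative, rows are sorted by subject and time
#' (observations before a simultaneous dose, so a pre-dose trough sits
#' ahead of the dose it precedes), and every observation is preceded by at
#' least one dose.
#'
#' @param df a data.frame in the event schema.
#' @param lloq optional limit of quantitation used to (re)compute `BLQ`.
#' @return a `pk_dataset`.
#' @export
as_pk_dataset <- function(df, lloq = NULL) {
  req <- c("ID", "TIME", "EVID", "AMT", "RATE", "DV", "MDV",
           "AGE", "SEX", "WT", "HT", "SCR", "ALB")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("missing mandatory columns: ", paste(miss, collapse = ", "))
  }
  bad <- which(!is.finite(df$TIME) | df$TIME < 0)
  if (length(bad)) {
    stop("negative or missing TIME at rows: ",
         paste(head(bad, 5), collapse = ", "))
  }
  if (!all(df$EVID %in% c(0, 1))) stop("EVID must be 0 or 1")
  if (is.null(df$TYPE)) df$TYPE <- ""
  if (!is.null(lloq)) {
    df$BLQ <- as.integer(df$EVID == 0 & !is.na(df$DV) & df$DV < lloq)
  } else if (is.null(df$BLQ)) {
    df$BLQ <- 0L
  }
  df <- df[order(df$ID, df$TIME, df$EVID), , drop = FALSE]
  rownames(df) <- NULL
  for (id in unique(df$ID)) {
    sub <- df[df$ID == id, ]
    doses <- sub$TIME[sub$EVID == 1]
    if (!length(doses)) stop(sprintf("subject %s has no dose events", id))
    obs <- sub$TIME[sub$EVID == 0]
    if (length(obs) && min(obs) < min(doses)) {
      stop(sprintf("subject %s has an observation before any dose", id))
    }
  }
  class(df) <- c("pk_dataset", "data.frame")
  df
}

#' Read / write a pharmacokinetic dataset as CSV
#'
#' The on-disk format is a plain one-header-line CSV in the event schema
#' described at [as_pk_dataset()]. Reading validates and canonicalizes, so
#' a shuffled file round-trips to the same in-memory dataset.
#'
#' @param path CSV file path.
#' @param lloq optional limit of quantitation; observation rows with `DV`
#'   below it are flagged `BLQ`.
#' @param x a `pk_dataset` (or compatible data.frame) to write.
#' @return `read_pk_dataset()` returns a `pk_dataset`;
#'   `write_pk_dataset()` returns `path` invisibly.
#' @export
read_pk_dataset <- function(path, lloq = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_pk_dataset(df, lloq = lloq)
}

#' @rdname read_pk_dataset
#' @export
write_pk_dataset <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

# Split a dataset into per-subject structures used by the estimation
# kernels: observation vectors (BLQ rows excluded, mirroring the
# exclusion of below-LOQ samples from the analysis), the dose schedule,
# and derived covariates.
pk_subjects <- function(data, drop_blq = TRUE) {
  stopifnot(inherits(data, "pk_dataset") || is.data.frame(data))
  out <- list()
  for (id in unique(data$ID)) {
    sub <- data[data$ID == id, ]
    obs <- sub[sub$EVID == 0, ]
    if (drop_blq && !is.null(obs$BLQ)) obs <- obs[obs$BLQ == 0, ]
    dose <- sub[sub$EVID == 1, ]
    cov <- data.frame(age = sub$AGE[1],
                      sex = ifelse(sub$SEX[1] == 1, "male", "female"),
                      weight = sub$WT[1], height = sub$HT[1],
                      scr = sub$SCR[1], alb = sub$ALB[1],
                      stringsAsFactors = FALSE)
    cov <- derive_covariates(cov)
    if (nrow(obs) == 0) next  # nothing informative for fitting
    out[[length(out) + 1]] <- list(
      id = id,
      y = obs$DV, t = obs$TIME, type = obs$TYPE,
      dose_t = dose$TIME, dose_amt = dose$AMT,
      dose_dur = ifelse(dose$RATE > 0, dose$AMT / dose$RATE, 0),
      cov = cov)
  }
  if (!length(out)) stop("dataset has no usable observations")
  out
}
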