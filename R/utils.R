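#' Convert renal clearance between mL/min and L/h
#'
#' Creatinine clearance is reported in mL/min clinically but enters the
#' clearance model in L/h. 1 mL/min = 0.06 L/h.
#'
#' @param x numeric vector of clearances.
#' @return numeric vector in the target unit.
#' @examples
#' ml_min_to_l_h(51.5)   # 3.09 L/h
#' l_h_to_ml_min(3.09)   # 51.5 mL/min
#' @export
ml_min_to_l_h <- function(x) x * 0.06

#' @rdname ml_min_to_l_h
#' @export
l_h_to_ml_min <- function(x) x / 0.06

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards, so seeded stages never
# perturb each other's draws. A NULL seed uses (and advances) the current
# stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a per-stage seed from a master seed so that adding a stage does
# not change another stage's draws. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  stages <- c(covariates = 11L, regimens = 23L, observations = 37L,
              fit = 41L, bootstrap = 53L, vpc = 67L, pta = 71L,
              nomogram = 83L, map = 89L, pipeline = 97L)
  off <- stages[[stage]]
  as.integer((as.double(seed) * 101L + off) %% 2147483647)
}

# Round to the nearest positive multiple of `step`, half-up, floor at one
# step (dose grids are 250-mg multiples).
round_to_step <- function(x, step = 250) {
  pmax(step, step * floor(x / step + 0.5))
}

stop_if_not_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be positive and finite", what), call. = FALSE)
  }
  invisible(x)
}
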