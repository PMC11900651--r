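#' Stepwise covariate selection
#'
#' Forward inclusion / backward elimination on the clearance and central
#' volume covariate models. At each forward step every remaining
#' candidate is fitted; the candidate with the largest drop in the
#' objective function is added if the drop exceeds `forward_threshold`
#' (3.85, i.e. P < 0.05 for one parameter). Clearance is the clinically
#' meaningful parameter here, so when the best clearance candidate and the
#' best volume candidate lie within 3.85 of each other the clearance
#' candidate wins. Backward elimination then removes, one at a time, any
#' included term whose removal raises the objective by less than
#' `backward_threshold`.
#'
#' Continuous candidates enter as power terms normalized to their cohort
#' median; `sex` enters as a multiplicative factor on the female
#' indicator.
#'
#' @param data a [pk_dataset].
#' @param base starting [vcm_model()] (no covariate terms by default).
#' @param cl_candidates covariate names considered on clearance.
#' @param vc_candidates covariate names considered on the central volume
#'   (use `character()` to search clearance only).
#' @param forward_threshold,backward_threshold objective-function change
#'   criteria.
#' @param fix,control passed to [fit_population()].
#' @return list with `path` (one row per evaluated step: action,
#'   candidate, OFV, delta OFV, AIC, number of parameters, accepted),
#'   `model` (final fitted model) and `fit` (final `vcm_fit`).
#' @export
stepwise_select <- function(data,
                            base = vcm_model(cl_terms = list(),
                                             vc_terms = list()),
                            cl_candidates = c("bmi", "alb", "clcr", "egfr"),
                            vc_candidates = c("age", "sex", "weight",
                                              "bmi", "alb"),
                            forward_threshold = 3.85,
                            backward_threshold = 3.85,
                            fix = character(), control = list()) {
  prep <- pk_subjects(data)
  covs <- do.call(rbind, lapply(prep, `[[`, "cov"))

  make_term <- function(name) {
    if (name == "sex") {
      cov_term("female", est = 0.1, type = "factor")
    } else {
      cov_term(name, ref = median(covs[[name]]), est = 0.1, type = "power")
    }
  }
  cand <- rbind(
    if (length(cl_candidates))
      data.frame(target = "cl", name = cl_candidates),
    if (length(vc_candidates))
      data.frame(target = "vc", name = vc_candidates))

  add_term <- function(model, target, name) {
    tm <- make_term(name)
    slot <- paste0(target, "_terms")
    model[[slot]] <- c(model[[slot]], list(tm))
    model
  }
  in_model <- function(model, target, name) {
    nm <- if (name == "sex") "female" else name
    any(vapply(model[[paste0(target, "_terms")]],
               function(t) t$cov == nm, TRUE))
  }

  path <- list()
  note <- function(step, action, target, name, ofv, delta, aic, npar,
                   accepted) {
    path[[length(path) + 1]] <<- data.frame(
      step = step, action = action,
      candidate = paste(target, name, sep = ":"),
      ofv = ofv, delta_ofv = delta, aic = aic, n_par = npar,
      accepted = accepted)
  }

  cur_fit <- fit_population(data, init = base, fix = fix,
                            control = control, se = FALSE)
  cur <- cur_fit$model
  note(0, "base", "", "", cur_fit$ofv, NA, cur_fit$aic, cur_fit$n_par, TRUE)

  step <- 0
  repeat {
    step <- step + 1
    todo <- cand[!mapply(in_model, list(cur), cand$target, cand$name), ,
                 drop = FALSE]
    if (!nrow(todo)) break
    trials <- lapply(seq_len(nrow(todo)), function(i) {
      m <- add_term(cur, todo$target[i], todo$name[i])
      tryCatch(fit_population(data, init = m, fix = fix, control = control,
                              se = FALSE),
               error = function(e) NULL)
    })
    delta <- vapply(trials, function(f) {
      if (is.null(f)) -Inf else cur_fit$ofv - f$ofv
    }, 0)
    for (i in seq_len(nrow(todo))) {
      note(step, "forward", todo$target[i], todo$name[i],
           if (is.null(trials[[i]])) NA else trials[[i]]$ofv, delta[i],
           if (is.null(trials[[i]])) NA else trials[[i]]$aic,
           if (is.null(trials[[i]])) NA else trials[[i]]$n_par, FALSE)
    }
    ok <- delta > forward_threshold
    if (!any(ok)) break
    # clearance priority: a volume candidate must beat the best clearance
    # candidate by more than the significance threshold to be chosen
    pick <- which.max(delta)
    if (todo$target[pick] == "vc") {
      cl_ok <- ok & todo$target == "cl"
      if (any(cl_ok)) {
        best_cl <- which(cl_ok)[which.max(delta[cl_ok])]
        if (delta[pick] - delta[best_cl] <= forward_threshold) {
          pick <- best_cl
        }
      }
    }
    cur_fit <- trials[[pick]]
    cur <- cur_fit$model
    idx <- length(path) - nrow(todo) + pick
    path[[idx]]$accepted <- TRUE
  }

  # backward elimination
  repeat {
    terms <- rbind(
      if (length(cur$cl_terms))
        data.frame(target = "cl", idx = seq_along(cur$cl_terms)),
      if (length(cur$vc_terms))
        data.frame(target = "vc", idx = seq_along(cur$vc_terms)))
    if (is.null(terms) || !nrow(terms)) break
    step <- step + 1
    drops <- lapply(seq_len(nrow(terms)), function(i) {
      m <- cur
      slot <- paste0(terms$target[i], "_terms")
      m[[slot]] <- m[[slot]][-terms$idx[i]]
      tryCatch(fit_population(data, init = m, fix = fix, control = control,
                              se = FALSE),
               error = function(e) NULL)
    })
    rise <- vapply(drops, function(f) {
      if (is.null(f)) Inf else f$ofv - cur_fit$ofv
    }, 0)
    for (i in seq_len(nrow(terms))) {
      slot <- paste0(terms$target[i], "_terms")
      nm <- cur[[slot]][[terms$idx[i]]]$cov
      note(step, "backward", terms$target[i], nm,
           if (is.null(drops[[i]])) NA else drops[[i]]$ofv, rise[i],
           if (is.null(drops[[i]])) NA else drops[[i]]$aic,
           if (is.null(drops[[i]])) NA else drops[[i]]$n_par, FALSE)
    }
    weakest <- which.min(rise)
    if (rise[weakest] >= backward_threshold) break
    cur_fit <- drops[[weakest]]
    cur <- cur_fit$model
    idx <- length(path) - nrow(terms) + weakest
    path[[idx]]$accepted <- TRUE
  }

  final_fit <- fit_population(data, init = cur, fix = fix,
                              control = control, se = TRUE)
  list(path = do.call(rbind, path), model = final_fit$model,
       fit = final_fit)
}
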