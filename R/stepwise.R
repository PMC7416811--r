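#' Define the model scope for one biomarker's Cox model
#'
#' A scope lists the candidate terms the stepwise search may use: the biomarker
#' itself (always retained, so every risk-profile column carries its
#' biomarker's information), the clinical confounders, and interactions of the
#' biomarker with selected confounders.
#'
#' @param biomarker Biomarker column name.
#' @param confounders Confounder column names (default: age, gender, therapy
#'   and primary-tumour diagnosis).
#' @param interaction_with Confounders whose interaction with the biomarker is
#'   a candidate term (default: therapy and diagnosis).
#' @param forced_terms Terms that may never be dropped (default: the biomarker
#'   main effect).
#' @return A `model_scope` object.
#' @export
model_scope <- function(biomarker,
                        confounders = c("age", "gender", "therapy", "diagnosis"),
                        interaction_with = c("therapy", "diagnosis"),
                        forced_terms = biomarker) {
  rc_assert(all(interaction_with %in% confounders),
            "interaction_with must be a subset of confounders")
  interactions <- if (length(interaction_with) > 0) {
    paste0(biomarker, ":", interaction_with)
  } else character()
  scope <- structure(list(
    biomarker = biomarker, confounders = confounders,
    interactions = interactions, forced_terms = forced_terms),
    class = "model_scope")
  rc_assert(all(forced_terms %in% c(biomarker, confounders, interactions)),
            "forced_terms must belong to the scope")
  scope
}

#' Scopes for a panel of biomarkers
#'
#' @param biomarkers Character vector of biomarker column names.
#' @param ... Passed to [model_scope()].
#' @return Named list of `model_scope` objects.
#' @export
default_scopes <- function(biomarkers, ...) {
  setNames(lapply(biomarkers, model_scope, ...), biomarkers)
}

scope_terms <- function(scope) {
  c(scope$biomarker, scope$confounders, scope$interactions)
}

# terms droppable/addable given the current model, respecting hierarchy:
# an interaction may only be present together with both its main effects
stepwise_moves <- function(current, scope) {
  all_terms <- scope_terms(scope)
  present_inter <- current[is_interaction(current)]
  inter_parents <- unique(unlist(strsplit(present_inter, ":", fixed = TRUE)))
  drops <- setdiff(current, scope$forced_terms)
  drops <- drops[!(drops %in% inter_parents)]
  adds <- setdiff(all_terms, current)
  adds <- adds[vapply(adds, function(term) {
    if (!is_interaction(term)) return(TRUE)
    all(strsplit(term, ":", fixed = TRUE)[[1]] %in% current)
  }, logical(1))]
  list(drop = drops, add = adds)
}

#' Stepwise AIC selection of a per-biomarker Cox model
#'
#' Bidirectional stepwise search over the scope's terms, starting from the full
#' model. At each step every single-term addition and deletion is evaluated and
#' the move with the largest AIC decrease is taken; the search stops at a local
#' AIC minimum. Forced terms are never dropped, and model hierarchy is
#' respected (a biomarker-by-confounder interaction can only be present while
#' both main effects are).
#'
#' @param cohort Cohort data frame.
#' @param scope A [model_scope()].
#' @param ties,time_col,event_col Passed to [fit_cox()].
#' @return The selected `cox_fit`, with the search path in `$stepwise_path`
#'   (tibble of step, move, term, AIC) and the scope in `$scope`.
#' @export
stepwise_aic <- function(cohort, scope, ties = "efron",
                         time_col = "time", event_col = "event") {
  rc_assert(inherits(scope, "model_scope"), "`scope` must be a model_scope")
  refit <- function(terms) fit_cox(cohort, terms, ties = ties,
                                   time_col = time_col, event_col = event_col)
  current <- scope_terms(scope)
  fit <- refit(current)  # full model must be fittable; errors propagate
  path <- list(tibble::tibble(step = 0L, move = "start",
                              term = NA_character_, AIC = fit$aic))
  step <- 0L
  repeat {
    moves <- stepwise_moves(current, scope)
    candidates <- c(
      lapply(moves$drop, function(t) list(move = "drop", term = t,
                                          terms = setdiff(current, t))),
      lapply(moves$add, function(t) list(move = "add", term = t,
                                         terms = c(current, t))))
    if (length(candidates) == 0) break
    fits <- lapply(candidates, function(cand) {
      tryCatch(refit(cand$terms), error = function(e) NULL)
    })
    # a candidate whose likelihood did not converge has no trustworthy AIC
    aics <- vapply(fits, function(f) {
      if (is.null(f) || !f$converged) Inf else f$aic
    }, numeric(1))
    best <- which.min(aics)
    if (aics[best] >= fit$aic - 1e-10) break
    step <- step + 1L
    current <- candidates[[best]]$terms
    fit <- fits[[best]]
    path[[length(path) + 1]] <- tibble::tibble(
      step = step, move = candidates[[best]]$move,
      term = candidates[[best]]$term, AIC = fit$aic)
  }
  fit$scope <- scope
  fit$stepwise_path <- dplyr::bind_rows(path)
  fit
}
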