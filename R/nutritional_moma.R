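# Minimal-metabolic-adjustment chain across nutrient transitions and its
# comparison with phase-wise FBA.
#
# At each transition the previous phase's flux distribution plays the role of
# the wild type and the new phase's bounds the role of the mutant: the
# returned flux vector minimises the adjustment to the reference subject to
# steady state and the new bounds. No biomass floor is imposed; growth emerges
# from the minimal adjustment.

#' One minimal-adjustment (MOMA) step
#'
#' Returns the flux vector `v` minimising `||v - ref||^2` (or the L1 analogue)
#' subject to `S v = 0` and the supplied bounds.
#'
#' @param model A [metabolic_model()].
#' @param lb,ub Bounds of the new phase.
#' @param reference Reference flux vector (previous phase's solution), in the
#'   model's reaction order.
#' @param norm `"L2"` (canonical quadratic MOMA) or `"L1"`.
#' @return List with named `flux`, Euclidean `distance` to the reference and
#'   `status`.
#' @export
moma_step <- function(model, lb, ub, reference, norm = c("L2", "L1")) {
  norm <- match.arg(norm)
  S <- stoichiometric_matrix(model)
  n <- length(model$reactions)
  stopifnot(length(reference) == n)
  reference <- as.numeric(reference)
  if (norm == "L2") {
    res <- solve_qp_box(reference, S, lb, ub)
    if (res$status != "optimal") {
      stop("MOMA step infeasible: no steady-state flux within the phase bounds",
           call. = FALSE)
    }
    v <- res$flux
  } else {
    # v minimising sum |v - ref|: variables (v, t), t >= |v - ref|
    obj <- c(rep(0, n), rep(1, n))
    Aub <- rbind(cbind(diag(n), -diag(n)), cbind(-diag(n), -diag(n)))
    bub <- c(reference, -reference)
    fb <- .finite_bounds(lb, ub)
    big <- max(abs(c(fb$lb, fb$ub, reference))) * 2 + 1
    res <- solve_lp_general(obj, Aub = Aub, bub = bub,
                            lb = c(fb$lb, rep(0, n)), ub = c(fb$ub, rep(big, n)),
                            Aeq = cbind(S, matrix(0, nrow(S), n)),
                            beq = rep(0, nrow(S)), maximize = FALSE)
    if (res$status != "optimal") {
      stop("MOMA step (L1) infeasible or solver failure", call. = FALSE)
    }
    v <- res$flux[seq_len(n)]
  }
  names(v) <- names(model$reactions)
  list(flux = v, distance = sqrt(sum((v - reference)^2)), status = "optimal")
}

#' Chain of minimal-adjustment optimisations across all transitions
#'
#' The FBA solution of the first modelled phase seeds the chain; each
#' subsequent phase's flux vector is the minimal adjustment of the previous
#' one under the new uptake bounds, and becomes the next reference. For ten
#' modelled phases the chain covers nine transitions, so the resulting flux
#' matrix has one column fewer than the FBA matrix.
#'
#' @param model A [metabolic_model()].
#' @param pp A `"phase_parameterization"`.
#' @param reference Optional explicit reference flux vector for the first
#'   phase; defaults to that phase's FBA solution.
#' @param norm Adjustment norm, see [moma_step()].
#' @return List of class `"moma_chain"`: `fluxes` (a `"flux_matrix"` with
#'   method `"nMOMA"`, columns from the second modelled phase onwards), `mu`
#'   (biomass flux of each solution), `distances` (per transition, named
#'   `T<i>`), and `reference` (the seeding vector).
#' @export
run_moma_chain <- function(model, pp, reference = NULL, norm = c("L2", "L1")) {
  norm <- match.arg(norm)
  stopifnot(length(pp$phases) >= 2L)
  if (is.null(reference)) {
    bnd1 <- phase_bounds(model, pp, pp$phases[1])
    res1 <- fba(model, bnd1$lb, bnd1$ub)
    if (res1$status != "optimal") {
      stop("FBA of the first modelled phase failed; no reference available",
           call. = FALSE)
    }
    reference <- res1$flux
  }
  rxns <- names(model$reactions)
  later <- pp$phases[-1]
  fx <- matrix(0, length(rxns), length(later),
               dimnames = list(rxns, paste0("P", later)))
  dist <- stats::setNames(numeric(length(later)),
                          paste0("T", seq_along(later)))
  ref <- as.numeric(reference)
  for (k in seq_along(later)) {
    bnd <- phase_bounds(model, pp, later[k])
    step <- tryCatch(
      moma_step(model, bnd$lb, bnd$ub, ref, norm = norm),
      error = function(e) {
        stop("MOMA chain aborted at transition T", k, " (phase ", later[k],
             "): ", conditionMessage(e), call. = FALSE)
      }
    )
    fx[, k] <- step$flux
    dist[k] <- step$distance
    ref <- step$flux
  }
  mu <- fx[model$biomass, ]
  structure(
    list(fluxes = structure(fx, mu = mu, method = "nMOMA",
                            class = c("flux_matrix", "matrix", "array")),
         mu = mu, distances = dist, reference = reference, norm = norm),
    class = "moma_chain"
  )
}

#' @export
print.moma_chain <- function(x, ...) {
  cat("Nutritional-MOMA chain over", ncol(x$fluxes), "phases;",
      "adjustment distances:", paste(signif(x$distances, 3), collapse = " "), "\n")
  invisible(x)
}

#' Compare FBA and minimal-adjustment flux predictions
#'
#' Over the phases present in both matrices: per-phase counts of active
#' reactions under each method and of reactions active under both; and, per
#' subsystem and phase, the fraction of the subsystem's reactions active only
#' under FBA, only under the minimal-adjustment chain, or under both.
#'
#' @param fba_fm FBA flux matrix.
#' @param moma_fm Minimal-adjustment flux matrix (e.g. `chain$fluxes`).
#' @param model The model supplying subsystem labels.
#' @param tol Flux-carrying threshold.
#' @return List with data frames `per_phase` (phase, n_active_fba,
#'   n_active_moma, n_shared) and `per_subsystem` (subsystem, phase,
#'   frac_fba_only, frac_moma_only, frac_both).
#' @export
compare_methods <- function(fba_fm, moma_fm, model, tol = 1e-9) {
  if (!identical(sort(rownames(fba_fm)), sort(rownames(moma_fm)))) {
    stop("flux matrices cover different reaction sets", call. = FALSE)
  }
  moma_fm <- moma_fm[rownames(fba_fm), , drop = FALSE]
  phases <- intersect(colnames(fba_fm), colnames(moma_fm))
  if (!length(phases)) stop("no shared phases to compare", call. = FALSE)
  a_f <- abs(fba_fm[, phases, drop = FALSE]) > tol
  a_m <- abs(moma_fm[, phases, drop = FALSE]) > tol
  per_phase <- data.frame(
    phase = phases,
    n_active_fba = colSums(a_f),
    n_active_moma = colSums(a_m),
    n_shared = colSums(a_f & a_m),
    row.names = NULL
  )
  subs <- vapply(model$reactions[rownames(fba_fm)], `[[`, "", "subsystem")
  subs[!nzchar(subs)] <- "unassigned"
  sizes <- table(subs)
  fba_only <- rowsum((a_f & !a_m) + 0L, subs)
  moma_only <- rowsum((!a_f & a_m) + 0L, subs)
  both <- rowsum((a_f & a_m) + 0L, subs)
  per_subsystem <- do.call(rbind, lapply(phases, function(p) {
    data.frame(
      subsystem = rownames(fba_only),
      phase = p,
      frac_fba_only = fba_only[, p] / as.numeric(sizes[rownames(fba_only)]),
      frac_moma_only = moma_only[, p] / as.numeric(sizes[rownames(moma_only)]),
      frac_both = both[, p] / as.numeric(sizes[rownames(both)]),
      row.names = NULL
    )
  }))
  list(per_phase = per_phase, per_subsystem = per_subsystem)
}
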