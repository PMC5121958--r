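# Classification of per-transition flux behaviour and network-rewiring
# summaries.

#' Per-phase activity summary of a flux matrix
#'
#' A reaction is active in a phase when `|v| > tol`. Returns per-phase active
#' counts, the ever-active and never-active reaction sets, and the mean/sd of
#' the per-phase counts. When the final phase carries no flux at all (growth
#' rate near zero), it is excluded from the mean/sd.
#'
#' @param fm Flux matrix (reactions x phases).
#' @param tol Flux-carrying threshold; scalar or one value per phase.
#' @return List with `active` (logical matrix), `per_phase` (counts),
#'   `ever_active`, `never_active`, `mean_active`, `sd_active` and
#'   `excluded_final_phase` (logical).
#' @export
activity_summary <- function(fm, tol = 1e-9) {
  act <- abs(fm) > rep(tol, length.out = ncol(fm))[col(fm)]
  per_phase <- colSums(act)
  drop_last <- ncol(fm) > 1L && per_phase[ncol(fm)] == 0L
  counted <- if (drop_last) per_phase[-ncol(fm)] else per_phase
  list(
    active = act,
    per_phase = per_phase,
    ever_active = rownames(fm)[rowSums(act) > 0],
    never_active = rownames(fm)[rowSums(act) == 0],
    mean_active = mean(counted),
    sd_active = stats::sd(counted),
    excluded_final_phase = drop_last
  )
}

#' Classify reactions across one phase transition
#'
#' For reactions active in either of the two phases: a reaction whose flux
#' changes sign (both magnitudes above `tol_active`) is *reversed*; otherwise
#' the absolute flux decides *increased* / *decreased* (change larger than
#' `tol_change`) or *unchanged*. The three sets plus *unchanged* partition the
#' active-in-either reactions; *turned_on* / *turned_off* additionally record
#' activity switches (a reaction turning on is also counted as increased).
#'
#' @param fm Flux matrix (reactions x phases).
#' @param transition Transition index T (phase column T vs T+1).
#' @param tol_active Flux-carrying threshold.
#' @param tol_change Minimal absolute-flux change that counts as a change.
#' @return List of class `"transition_report"` with character-vector fields
#'   `increased`, `decreased`, `reversed`, `turned_on`, `turned_off`,
#'   `unchanged`, `active_either`, the `transition` index and `n_changing`
#'   (increased + decreased + reversed).
#' @export
classify_transition <- function(fm, transition, tol_active = 1e-9,
                                tol_change = 1e-6) {
  stopifnot(transition >= 1, transition + 1 <= ncol(fm))
  v1 <- fm[, transition]
  v2 <- fm[, transition + 1]
  a1 <- abs(v1) > tol_active
  a2 <- abs(v2) > tol_active
  either <- a1 | a2
  rev_ <- either & a1 & a2 & (sign(v1) * sign(v2) < 0)
  d <- abs(v2) - abs(v1)
  inc <- either & !rev_ & d > tol_change
  dec <- either & !rev_ & d < -tol_change
  unch <- either & !rev_ & !inc & !dec
  ids <- rownames(fm)
  structure(
    list(
      transition = transition,
      increased = ids[inc],
      decreased = ids[dec],
      reversed = ids[rev_],
      turned_on = ids[!a1 & a2],
      turned_off = ids[a1 & !a2],
      unchanged = ids[unch],
      active_either = ids[either],
      n_changing = sum(inc) + sum(dec) + sum(rev_)
    ),
    class = "transition_report"
  )
}

#' Classify all transitions of a flux matrix
#'
#' @inheritParams classify_transition
#' @return List of [classify_transition()] reports, one per consecutive phase
#'   pair, named `T<i>`, with the growth-rate-adjusted decreasing sets filled
#'   in by [adjust_decreasing()].
#' @export
classify_transitions <- function(fm, tol_active = 1e-9, tol_change = 1e-6) {
  reports <- lapply(seq_len(ncol(fm) - 1L), classify_transition, fm = fm,
                    tol_active = tol_active, tol_change = tol_change)
  names(reports) <- paste0("T", seq_along(reports))
  adjust_decreasing(reports)
}

#' Remove consistently decreasing reactions from the decreased sets
#'
#' A steadily falling growth rate makes some reactions decrease at every
#' transition for purely systemic reasons. Reactions that are classified as
#' decreasing at *every* transition in which they are active are removed from
#' each transition's decreased set; the result is stored as
#' `adjusted_decreased` on every report.
#'
#' @param reports List of `"transition_report"` objects.
#' @return The reports, each with fields `adjusted_decreased` and (on the
#'   list) attribute `"consistent_decliners"`.
#' @export
adjust_decreasing <- function(reports) {
  all_active <- unique(unlist(lapply(reports, `[[`, "active_either")))
  consistent <- vapply(all_active, function(r) {
    in_any <- FALSE
    for (rep_ in reports) {
      if (!(r %in% rep_$active_either)) next
      in_any <- TRUE
      if (!(r %in% rep_$decreased)) return(FALSE)
    }
    in_any
  }, TRUE)
  decliners <- all_active[consistent]
  reports <- lapply(reports, function(rep_) {
    rep_$adjusted_decreased <- setdiff(rep_$decreased, decliners)
    rep_
  })
  attr(reports, "consistent_decliners") <- decliners
  reports
}

#' Tabular summary of transition reports
#'
#' @param reports Output of [classify_transitions()].
#' @return Data frame with one row per transition: counts of changing,
#'   increased, decreased, adjusted decreased, reversed, turned on/off.
#' @export
transition_summary <- function(reports) {
  data.frame(
    transition = vapply(reports, `[[`, 0L, "transition"),
    n_changing = vapply(reports, `[[`, 0L, "n_changing"),
    n_increased = vapply(reports, function(r) length(r$increased), 0L),
    n_decreased = vapply(reports, function(r) length(r$decreased), 0L),
    n_adjusted_decreased = vapply(reports, function(r) {
      length(if (is.null(r$adjusted_decreased)) r$decreased else r$adjusted_decreased)
    }, 0L),
    n_reversed = vapply(reports, function(r) length(r$reversed), 0L),
    n_turned_on = vapply(reports, function(r) length(r$turned_on), 0L),
    n_turned_off = vapply(reports, function(r) length(r$turned_off), 0L),
    row.names = NULL
  )
}

#' Normalize a flux matrix by the predicted growth rate
#'
#' Divides each phase column by that phase's predicted growth rate, expressing
#' fluxes as fractions of biomass production (the biomass reaction's own
#' normalized flux is 1 in every growth phase). Columns with zero growth are
#' left as they are and flagged.
#'
#' @param fm A `"flux_matrix"` with attribute `mu`.
#' @param mu Optional growth-rate vector overriding the attribute.
#' @return The normalized flux matrix; attribute `"unnormalized_phases"` lists
#'   columns left untouched.
#' @export
normalize_by_growth <- function(fm, mu = attr(fm, "mu")) {
  if (is.null(mu)) stop("no growth-rate attribute on flux matrix", call. = FALSE)
  stopifnot(length(mu) == ncol(fm))
  out <- unclass(fm)
  ok <- mu > 0
  out[, ok] <- sweep(out[, ok, drop = FALSE], 2, mu[ok], `/`)
  structure(out, mu = ifelse(ok, 1, 0), method = paste0(attr(fm, "method"), "/mu"),
            unnormalized_phases = colnames(fm)[!ok],
            class = c("flux_matrix", "matrix", "array"))
}

#' Active-reaction counts per pathway (subsystem) per phase
#'
#' @param fm Flux matrix (reactions x phases).
#' @param model The model supplying subsystem labels; reactions with an empty
#'   label are aggregated under `"unassigned"`.
#' @param tol Flux-carrying threshold.
#' @return Matrix subsystems x phases of active-reaction counts.
#' @export
pathway_activity <- function(fm, model, tol = 1e-9) {
  subs <- vapply(model$reactions[rownames(fm)], `[[`, "", "subsystem")
  subs[!nzchar(subs)] <- "unassigned"
  act <- abs(fm) > tol
  rowsum(act + 0L, group = subs)
}
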