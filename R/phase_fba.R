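# Phase-wise flux balance analysis and flux variability analysis.

#' Map amino acids to their exchange reactions
#'
#' An amino acid `aa` maps to the exchange reaction whose single metabolite is
#' `<aa>_e` (or `<aa>_c` as fallback, or literally `<aa>`).
#'
#' @param model A [metabolic_model()].
#' @param amino_acids Character vector of amino-acid names.
#' @return Named character vector (NA for amino acids with no exchange).
#' @export
amino_acid_exchanges <- function(model, amino_acids) {
  ex_met <- vapply(model$reactions[model$exchanges],
                   function(r) names(r$stoich), "")
  out <- vapply(amino_acids, function(a) {
    for (cand in c(paste0(a, "_e"), paste0(a, "_c"), a)) {
      hit <- model$exchanges[ex_met == cand]
      if (length(hit)) return(hit[1])
    }
    NA_character_
  }, "")
  names(out) <- amino_acids
  out
}

#' Flux bounds of a model under one phase's medium
#'
#' Starting from the model's own bounds, every amino-acid exchange gets a
#' lower bound equal to minus that phase's uptake flux (uptake is a negative
#' exchange flux, so the magnitude of the estimated uptake rate is what is
#' imposed); an amino acid with UF 0 cannot be taken up. Salt and gas
#' exchanges keep the model's bounds (they are assumed open in the model, as
#' is usual for a defined medium).
#'
#' @param model A [metabolic_model()].
#' @param pp A `"phase_parameterization"`.
#' @param phase A modelled phase index (element of `pp$phases`).
#' @return List with numeric vectors `lb`, `ub` over all reactions.
#' @export
phase_bounds <- function(model, pp, phase) {
  stopifnot(phase %in% pp$phases)
  bnd <- model_bounds(model)
  col <- match(phase, pp$phases)
  ex <- amino_acid_exchanges(model, pp$amino_acids)
  unknown <- pp$amino_acids[is.na(ex) & pp$uf[, col] > 0]
  if (length(unknown)) {
    stop("no exchange reaction found for consumed amino acid(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (a in pp$amino_acids[!is.na(ex)]) {
    uf <- pp$uf[a, col]
    if (is.na(uf)) uf <- 0
    bnd <- .set_uptake(bnd, model, ex[[a]], uf)
  }
  bnd
}

# Cap the uptake capacity of an exchange at `rate`, respecting the reaction's
# sign convention (stoichiometric coefficient -1: uptake is negative flux;
# +1: uptake is positive flux).
.set_uptake <- function(bnd, model, ex_id, rate) {
  coef <- model$reactions[[ex_id]]$stoich[[1]]
  if (coef < 0) {
    bnd$lb[ex_id] <- -rate
    if (bnd$ub[ex_id] < -rate) bnd$ub[ex_id] <- -rate
  } else {
    bnd$ub[ex_id] <- rate
    if (bnd$lb[ex_id] > rate) bnd$lb[ex_id] <- rate
  }
  bnd
}

#' Single flux balance analysis
#'
#' Maximises the biomass reaction subject to steady state (`S v = 0`) and the
#' given bounds.
#'
#' @param model A [metabolic_model()].
#' @param lb,ub Optional bounds (default: the model's).
#' @param objective Reaction id to maximise (default: biomass).
#' @return List with `status`, named `flux` vector and `objective` value.
#' @export
fba <- function(model, lb = NULL, ub = NULL, objective = model$biomass) {
  S <- stoichiometric_matrix(model)
  bnd <- model_bounds(model)
  if (!is.null(lb)) bnd$lb <- lb
  if (!is.null(ub)) bnd$ub <- ub
  obj <- as.numeric(names(model$reactions) == objective)
  res <- solve_lp(obj, S, bnd$lb, bnd$ub, maximize = TRUE)
  if (res$status == "optimal") names(res$flux) <- names(model$reactions)
  res
}

# parsimonious refinement: minimise total absolute flux at fixed biomass
.pfba_refine <- function(S, lb, ub, bio_idx, opt) {
  n <- ncol(S)
  # variables: p (forward part), q (backward part); v = p - q
  ub_p <- pmax(ub, 0)
  ub_q <- pmax(-lb, 0)
  Aeq <- cbind(S, -S)
  beq <- rep(0, nrow(S))
  bio_row <- rep(0, 2 * n)
  bio_row[bio_idx] <- 1
  bio_row[n + bio_idx] <- -1
  Aeq <- rbind(Aeq, bio_row)
  beq <- c(beq, opt)
  res <- solve_lp_general(rep(1, 2 * n), Aeq = Aeq, beq = beq,
                          lb = rep(0, 2 * n), ub = c(ub_p, ub_q),
                          maximize = FALSE)
  if (res$status != "optimal") return(NULL)
  res$flux[seq_len(n)] - res$flux[n + seq_len(n)]
}

#' Phase-wise flux balance analysis
#'
#' Runs one biomass-maximising FBA per modelled phase under that phase's
#' uptake bounds and assembles the reaction x phase flux matrix.
#'
#' @param model A [metabolic_model()].
#' @param pp A `"phase_parameterization"`.
#' @param parsimonious If `TRUE`, each phase's flux vector is post-processed
#'   by minimising the total absolute flux at the fixed biomass optimum
#'   (pFBA-style). This stabilises reaction counts across LP solvers but is a
#'   post-processing choice, off by default.
#' @return A `"flux_matrix"`: numeric matrix (reactions x phases, columns
#'   `P<phase>`) with attributes `mu` (per-phase biomass optimum), `method`
#'   (`"FBA"`) and `status` (per-phase solver status). Infeasible phases give
#'   an all-zero column.
#' @export
run_phase_fba <- function(model, pp, parsimonious = FALSE) {
  S <- stoichiometric_matrix(model)
  rxns <- names(model$reactions)
  bio_idx <- match(model$biomass, rxns)
  obj <- as.numeric(seq_along(rxns) == bio_idx)
  fx <- matrix(0, length(rxns), length(pp$phases),
               dimnames = list(rxns, paste0("P", pp$phases)))
  mu <- stats::setNames(rep(0, length(pp$phases)), colnames(fx))
  status <- stats::setNames(rep("optimal", length(pp$phases)), colnames(fx))
  for (k in seq_along(pp$phases)) {
    bnd <- phase_bounds(model, pp, pp$phases[k])
    res <- solve_lp(obj, S, bnd$lb, bnd$ub, maximize = TRUE)
    if (res$status != "optimal") {
      status[k] <- res$status
      next
    }
    v <- res$flux
    if (parsimonious) {
      v2 <- .pfba_refine(S, bnd$lb, bnd$ub, bio_idx, res$objective)
      if (!is.null(v2)) v <- v2
    }
    fx[, k] <- v
    mu[k] <- res$objective
  }
  structure(fx, mu = mu, method = if (parsimonious) "pFBA" else "FBA",
            status = status, class = c("flux_matrix", "matrix", "array"))
}

#' Growth screen on single-amino-acid minimal media
#'
#' For each amino acid in turn: all amino-acid uptakes are closed except the
#' tested one (lower bound -`uptake`), nitrogen-salt uptake is closed so the
#' amino acid is the sole C and N source, and the biomass optimum is recorded.
#'
#' @param model A [metabolic_model()].
#' @param amino_acids Amino acids to screen; defaults to every amino acid with
#'   a recognisable exchange reaction (`EX_<aa>` over `<aa>_e`).
#' @param uptake Uptake rate imposed on the tested amino acid
#'   (mmol gDW^-1 h^-1).
#' @param nitrogen_exchanges Exchange reaction ids closed for uptake during
#'   the screen; by default those whose metabolite name contains an ammonium
#'   tag (nh3/nh4).
#' @return Data frame `amino_acid`, `growth_rate`, `rank` sorted by decreasing
#'   growth (NA growth for amino acids with no exchange reaction).
#' @export
minimal_media_screen <- function(model, amino_acids = NULL, uptake = 1,
                                 nitrogen_exchanges = NULL) {
  ex_met <- vapply(model$reactions[model$exchanges], function(r) names(r$stoich), "")
  if (is.null(amino_acids)) {
    amino_acids <- sub("_e$", "", ex_met[grepl("_e$", ex_met)])
    amino_acids <- setdiff(amino_acids, c("o2", "nh4", "co2", "biomass"))
  }
  ex <- amino_acid_exchanges(model, amino_acids)
  if (is.null(nitrogen_exchanges)) {
    nitrogen_exchanges <- model$exchanges[grepl("nh3|nh4", ex_met, ignore.case = TRUE)]
  }
  S <- stoichiometric_matrix(model)
  bnd0 <- model_bounds(model)
  obj <- as.numeric(names(model$reactions) == model$biomass)
  gr <- vapply(amino_acids, function(a) {
    if (is.na(ex[[a]])) return(NA_real_)
    bnd <- bnd0
    for (e in c(ex[!is.na(ex)], nitrogen_exchanges)) {
      bnd <- .set_uptake(bnd, model, e, 0)
    }
    bnd <- .set_uptake(bnd, model, ex[[a]], uptake)
    res <- solve_lp(obj, S, bnd$lb, bnd$ub, maximize = TRUE)
    if (res$status == "optimal") res$objective else 0
  }, 0)
  out <- data.frame(amino_acid = amino_acids, growth_rate = gr,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$growth_rate, out$amino_acid), ]
  out$rank <- rank(-out$growth_rate, ties.method = "min")
  rownames(out) <- NULL
  out
}

#' Phase-wise flux variability analysis
#'
#' For each modelled phase, fixes the biomass flux at (a fraction of) that
#' phase's FBA optimum and computes the admissible minimum and maximum flux of
#' every reaction. The span `v = f_max / f_min` classifies reactions as fixed
#' (`v = 1`, i.e. `f_max = f_min`) or flexible. When `f_min` is 0 the ratio is
#' undefined and reported as NA; the fixed/flexible call then falls back on
#' `f_max - f_min`.
#'
#' @param model A [metabolic_model()].
#' @param pp A `"phase_parameterization"`.
#' @param optimality_fraction Biomass must reach at least this fraction of the
#'   phase optimum (default 1: strict optimality).
#' @param tol Width below which a range counts as fixed.
#' @return An object of class `"fva_result"`: list with matrices `min`, `max`,
#'   `span` (reactions x phases) and character matrix `class`
#'   (`"fixed"`/`"flexible"`), plus `mu` (the per-phase optima used).
#' @export
run_phase_fva <- function(model, pp, optimality_fraction = 1, tol = 1e-9) {
  stopifnot(optimality_fraction > 0, optimality_fraction <= 1)
  S <- stoichiometric_matrix(model)
  rxns <- names(model$reactions)
  bio_idx <- match(model$biomass, rxns)
  obj_bio <- as.numeric(seq_along(rxns) == bio_idx)
  nph <- length(pp$phases)
  fmin <- fmax <- matrix(NA_real_, length(rxns), nph,
                         dimnames = list(rxns, paste0("P", pp$phases)))
  mu <- stats::setNames(rep(NA_real_, nph), colnames(fmin))
  for (k in seq_len(nph)) {
    bnd <- phase_bounds(model, pp, pp$phases[k])
    base <- solve_lp(obj_bio, S, bnd$lb, bnd$ub, maximize = TRUE)
    if (base$status != "optimal") next
    mu[k] <- base$objective
    lb <- bnd$lb
    lb[bio_idx] <- max(lb[bio_idx], optimality_fraction * base$objective)
    for (j in seq_along(rxns)) {
      obj <- as.numeric(seq_along(rxns) == j)
      lo <- solve_lp(obj, S, lb, bnd$ub, maximize = FALSE)
      hi <- solve_lp(obj, S, lb, bnd$ub, maximize = TRUE)
      fmin[j, k] <- if (lo$status == "optimal") lo$objective else NA_real_
      fmax[j, k] <- if (hi$status == "optimal") hi$objective else NA_real_
    }
  }
  span <- ifelse(abs(fmin) > tol, fmax / fmin, NA_real_)
  cls <- ifelse(is.na(fmax - fmin), "flexible",
                ifelse(abs(fmax - fmin) <= tol, "fixed", "flexible"))
  structure(list(min = fmin, max = fmax, span = span, class = cls, mu = mu,
                 optimality_fraction = optimality_fraction),
            class = "fva_result")
}

#' @export
print.fva_result <- function(x, ...) {
  nflex <- colSums(x$class == "flexible", na.rm = TRUE)
  cat("FVA over", ncol(x$min), "phases,", nrow(x$min), "reactions;",
      "flexible per phase:", paste(nflex, collapse = " "), "\n")
  invisible(x)
}

#' Write a flux matrix as TSV (reactions x phases)
#'
#' @param fm A `"flux_matrix"` (or plain matrix).
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_flux_matrix <- function(fm, path) {
  df <- data.frame(reaction = rownames(fm), as.data.frame(unclass(fm)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flux matrix written by [write_flux_matrix()]
#' @param path TSV path.
#' @return Numeric matrix reactions x phases.
#' @export
read_flux_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
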