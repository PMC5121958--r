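# Fed-batch parameterization: per-phase yields and per-amino-acid uptake-flux
# bounds derived from a growth curve.
#
# Phase i is the hour between time points i-1 and i. Its growth rate GR_i is
# the mu recorded at the start of the interval, and the concentration entering
# the uptake-flux ratio is the mass concentration at the start of the phase
# (what is available during that hour).

#' Biomass (g/l) per OD unit from a calibration triple
#'
#' @param calibration List or numeric vector `(dry_weight_g, od_ref, volume_l)`:
#'   a measured cell dry weight (g), the optical density at the same time, and
#'   the culture volume (l).
#' @return `dry_weight / (od_ref * volume)` in g l^-1 OD^-1.
#' @export
biomass_per_od <- function(calibration) {
  v <- unlist(calibration)
  if (length(v) != 3L) stop("calibration must have three elements", call. = FALSE)
  names(v) <- c("dry_weight_g", "od_ref", "volume_l")
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("calibration values must be positive and finite", call. = FALSE)
  }
  unname(v["dry_weight_g"] / (v["od_ref"] * v["volume_l"]))
}

#' Mass concentrations (g/l) of a growth curve
#'
#' Converts the molar concentration columns (mM) to mass concentrations via
#' `conc_molar * MW * 1e-3`.
#'
#' @param curve A [growth_curve()].
#' @return Matrix amino acids x time points (g/l).
#' @export
mass_concentrations <- function(curve) {
  aa <- curve$amino_acids
  m <- t(as.matrix(curve$data[paste0("conc_", aa)])) * curve$mw[aa] * 1e-3
  dimnames(m) <- list(aa, curve$data$time_h)
  m
}

#' Per-phase biomass and concentration deltas
#'
#' For each phase (transition between consecutive time points) computes the
#' biomass increment (from OD via [biomass_per_od()]) and the per-amino-acid
#' mass-concentration decrease, clamped at zero when a concentration rises
#' from one hour to the next (nutrient accumulation).
#'
#' @param curve A [growth_curve()] with at least two time points.
#' @return List with `phase` (1..n), `gr` (growth rate of each phase),
#'   `delta_biomass` (g/l), `delta_conc` (amino acids x phases matrix, g/l)
#'   and `mass_conc` (amino acids x time points, g/l).
#' @export
compute_deltas <- function(curve) {
  stopifnot(inherits(curve, "growth_curve"))
  df <- curve$data
  if (nrow(df) < 2L) stop("growth curve needs at least two time points", call. = FALSE)
  n <- nrow(df) - 1L
  conv <- biomass_per_od(curve$calibration)
  biomass <- df$OD * conv
  mass_conc <- mass_concentrations(curve)
  delta_conc <- pmax(mass_conc[, 1:n, drop = FALSE] - mass_conc[, 2:(n + 1), drop = FALSE], 0)
  colnames(delta_conc) <- seq_len(n)
  list(
    phase = seq_len(n),
    gr = df$mu_per_h[seq_len(n)],
    delta_biomass = diff(biomass),
    delta_conc = delta_conc,
    mass_conc = mass_conc
  )
}

#' Per-phase yield: biomass formed per amino-acid carbon consumed
#'
#' `yield_i = delta_biomass_i / sum_aa delta_conc[aa, i]` (g/g). A phase with
#' zero biomass increment has yield 0; a phase with nonzero biomass increment
#' but zero total consumption cannot be parameterized and gets `NA` (flagged).
#'
#' @param deltas Output of [compute_deltas()].
#' @return Numeric vector of yields with attribute `"unparameterizable"`
#'   listing the flagged phases.
#' @export
compute_yields <- function(deltas) {
  total <- colSums(deltas$delta_conc)
  y <- ifelse(total > 0, deltas$delta_biomass / total,
              ifelse(abs(deltas$delta_biomass) < 1e-12, 0, NA_real_))
  attr(y, "unparameterizable") <- deltas$phase[is.na(y)]
  y
}

#' Per-phase, per-amino-acid uptake fluxes
#'
#' Implements, for each phase i and amino acid aa,
#' `UF_aa^i = (conc_aa^i / sum_a conc_a^i) * (GR^i / yield^i) / (MW_aa * 1e-3)`
#' in mmol gDW^-1 h^-1, where the concentration ratio is computed on mass
#' concentrations (g/l) at the start of the phase over all amino acids with
#' nonzero concentration. The flux is then multiplied by a per-phase scale
#' constant. An amino acid whose concentration did not decrease during the
#' phase (`delta_conc = 0`), or whose concentration is zero, gets UF 0; a
#' phase with zero growth rate gets all-zero UF.
#'
#' @param curve A [growth_curve()].
#' @param yields Output of [compute_yields()].
#' @param deltas Output of [compute_deltas()] (recomputed when omitted).
#' @param scale Either `"none"` (constants all 1; the formula exactly as
#'   written) or `"normalize"` (each phase's constant chosen so the total
#'   carbon-mass uptake flux `sum UF*MW*1e-3` equals `reference`).
#' @param scale_constants Optional explicit per-phase constants, overriding
#'   `scale`.
#' @param reference Target total carbon-mass uptake flux (g gDW^-1 h^-1) for
#'   `scale = "normalize"`.
#' @return Matrix amino acids x phases of uptake fluxes, with attributes
#'   `"scale_constants"` and `"unparameterizable"` (phases where GR > 0 but
#'   yield is 0 or NA).
#' @export
compute_uptake_fluxes <- function(curve, yields, deltas = NULL,
                                  scale = c("none", "normalize"),
                                  scale_constants = NULL, reference = 1) {
  scale <- match.arg(scale)
  if (is.null(deltas)) deltas <- compute_deltas(curve)
  n <- length(deltas$phase)
  aa <- curve$amino_acids
  mw <- curve$mw[aa]
  uf <- matrix(0, length(aa), n, dimnames = list(aa, deltas$phase))
  bad <- integer(0)
  for (i in seq_len(n)) {
    gr <- deltas$gr[i]
    if (gr <= 0) next
    y <- yields[i]
    if (is.na(y) || y <= 0) {
      bad <- c(bad, i)
      uf[, i] <- NA_real_
      next
    }
    cm <- deltas$mass_conc[, i] # start of phase i (time point i-1)
    denom <- sum(cm[cm > 0])
    if (denom <= 0) next
    ratio <- ifelse(cm > 0, cm / denom, 0)
    ufi <- ratio * (gr / y) / (mw * 1e-3)
    ufi[deltas$delta_conc[, i] <= 0] <- 0
    uf[, i] <- ufi
  }
  if (is.null(scale_constants)) {
    scale_constants <- rep(1, n)
    if (scale == "normalize") {
      tot <- colSums(uf * mw * 1e-3)
      scale_constants <- ifelse(is.na(tot) | tot <= 0, 1, reference / tot)
    }
  }
  stopifnot(length(scale_constants) == n)
  uf <- sweep(uf, 2, scale_constants, `*`)
  attr(uf, "scale_constants") <- scale_constants
  attr(uf, "unparameterizable") <- bad
  uf
}

#' Select the phases to model
#'
#' Drops trailing phases that show neither growth nor amino-acid consumption
#' (the tail of a fed-batch run after all usable substrates are gone); phases
#' without growth in the middle of the curve are retained.
#'
#' @param curve A [growth_curve()].
#' @param deltas Output of [compute_deltas()] (recomputed when omitted).
#' @param tol Consumption below this total (g/l) counts as zero.
#' @return Integer vector of modelled phase indices.
#' @export
select_phases <- function(curve, deltas = NULL, tol = 1e-12) {
  if (is.null(deltas)) deltas <- compute_deltas(curve)
  dead <- deltas$gr <= 0 & colSums(deltas$delta_conc) <= tol
  keep <- rev(cumprod(rev(dead))) == 0 # FALSE only for the trailing dead block
  if (!any(keep)) stop("all phases are without growth and uptake", call. = FALSE)
  deltas$phase[keep]
}

#' Parameterize a growth curve
#'
#' End-to-end wrapper: deltas, yields, modelled-phase selection and uptake
#' fluxes.
#'
#' @inheritParams compute_uptake_fluxes
#' @return An object of class `"phase_parameterization"`: list with `phases`
#'   (modelled phase indices), `gr`, `yield`, `delta_biomass`, `delta_conc`,
#'   `uf` (amino acids x modelled phases), `scale_constants`, `amino_acids`,
#'   `mw` and `unparameterizable`.
#' @export
parameterize_growth <- function(curve, scale = c("none", "normalize"),
                                scale_constants = NULL, reference = 1) {
  scale <- match.arg(scale)
  deltas <- compute_deltas(curve)
  yields <- compute_yields(deltas)
  phases <- select_phases(curve, deltas)
  uf <- compute_uptake_fluxes(curve, yields, deltas, scale = scale,
                              scale_constants = scale_constants,
                              reference = reference)
  structure(
    list(
      phases = phases,
      gr = deltas$gr[phases],
      yield = yields[phases],
      delta_biomass = deltas$delta_biomass[phases],
      delta_conc = deltas$delta_conc[, phases, drop = FALSE],
      uf = uf[, phases, drop = FALSE],
      scale_constants = attr(uf, "scale_constants")[phases],
      amino_acids = curve$amino_acids,
      mw = curve$mw,
      unparameterizable = attr(uf, "unparameterizable")
    ),
    class = "phase_parameterization"
  )
}

#' @export
print.phase_parameterization <- function(x, ...) {
  cat("Phase parameterization: ", length(x$phases), " modelled phases (",
      paste(range(x$phases), collapse = "-"), "), ",
      length(x$amino_acids), " amino acids\n", sep = "")
  invisible(x)
}

#' Write a phase parameterization as TSV
#'
#' One row per modelled phase: phase, GR, yield, scale constant, then one
#' UF_<aa> column per amino acid.
#'
#' @param pp A `"phase_parameterization"`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_parameterization <- function(pp, path) {
  df <- data.frame(phase = pp$phases, GR = pp$gr, yield = pp$yield,
                   scale = pp$scale_constants)
  uft <- t(pp$uf)
  colnames(uft) <- paste0("UF_", rownames(pp$uf))
  utils::write.table(cbind(df, uft), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
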