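# Synthetic study system: a toy metabolic network and fed-batch growth curves
# with hierarchical amino-acid depletion, so the full multi-phase pipeline can
# run self-contained.

#' Molar weights of the twenty proteinogenic amino acids (g/mol)
#'
#' Used to convert molar concentrations of the growth medium into mass
#' concentrations during parameterization.
#'
#' @format Named numeric vector (lower-case three-letter codes).
#' @export
amino_acid_mw <- c(
  ala = 89.09, arg = 174.20, asn = 132.12, asp = 133.10, cys = 121.16,
  gln = 146.15, glu = 147.13, gly = 75.07, his = 155.15, ile = 131.17,
  leu = 131.17, lys = 146.19, met = 149.21, phe = 165.19, pro = 115.13,
  ser = 105.09, thr = 119.12, trp = 204.23, tyr = 181.19, val = 117.15
)

.default_aa_names <- function(n) {
  pref <- c("glu", "ser", "asn", "asp", "ala", "leu", "gly", "tyr", "phe",
            "ile", "val", "his", "pro", "gln", "thr", "lys", "arg", "met",
            "cys", "trp")
  if (n > length(pref)) stop("at most ", length(pref), " amino acids supported", call. = FALSE)
  pref[seq_len(n)]
}

#' Build a toy constraint-based model around a set of amino acids
#'
#' The network contains, per amino acid, an exchange reaction, a transporter,
#' a degradation route into a central carbon pool and a biosynthesis route
#' back from it (so every amino acid can be either consumed or synthesised); a
#' cyclic TCA-like core oxidising the carbon pool to CO2 while regenerating
#' redox carriers; an oxidative-phosphorylation step converting redox carriers
#' and O2 into the energy currency; salt/O2/NH4/CO2 exchanges; and a biomass
#' reaction consuming one unit of every amino acid plus energy. Degradation of
#' earlier amino acids in the list releases more energy, making them the
#' "preferred" substrates (the first amino acid supports the fastest growth
#' in a single-substrate screen). Every enzymatic reaction carries a GPR over
#' synthetic gene ids and a subsystem label.
#'
#' @param n_amino_acids Number of amino acids (>= 2).
#' @param seed Integer seed controlling the synthetic GPR structure; the
#'   construction is fully deterministic given the seed.
#' @param amino_acids Optional names; defaults to a fixed panel starting with
#'   glutamate.
#' @return A validated [metabolic_model()]. Feasible by construction: any
#'   single amino acid supplied at 1 mmol gDW^-1 h^-1 plus salts gives a
#'   positive biomass optimum.
#' @export
make_toy_model <- function(n_amino_acids, seed = 1L, amino_acids = NULL) {
  stopifnot(n_amino_acids >= 2)
  aa <- if (is.null(amino_acids)) .default_aa_names(n_amino_acids) else amino_acids
  stopifnot(length(aa) == n_amino_acids)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  gene_counter <- 0L
  next_genes <- function(k) {
    ids <- sprintf("g%04d", gene_counter + seq_len(k))
    gene_counter <<- gene_counter + k
    ids
  }
  gpr_complex <- function(n_sub, isozyme_prob = 0.3) {
    core <- paste(next_genes(n_sub), collapse = " and ")
    if (stats::runif(1) < isozyme_prob) {
      iso <- next_genes(1L)
      core <- if (n_sub > 1L) sprintf("(%s) or %s", core, iso) else sprintf("%s or %s", core, iso)
    }
    core
  }
  # energy bonus of degradation, decreasing along the amino-acid list
  e_bonus <- round(seq(1, 0.2, length.out = n_amino_acids), 3)
  rxns <- list()
  add <- function(...) rxns[[length(rxns) + 1L]] <<- reaction(...)
  for (k in seq_len(n_amino_acids)) {
    a <- aa[k]
    add(sprintf("EX_%s", a), stats::setNames(-1, sprintf("%s_e", a)),
        lb = -1000, ub = 1000, gpr = "", subsystem = "Exchange")
    add(sprintf("T_%s", a),
        stats::setNames(c(-1, 1), c(sprintf("%s_e", a), sprintf("%s_c", a))),
        lb = 0, ub = 1000, gpr = gpr_complex(sample(1:2, 1)),
        subsystem = "Transport")
    add(sprintf("DEG_%s", a),
        stats::setNames(c(-1, 1, 1, e_bonus[k]),
                        c(sprintf("%s_c", a), "cpool_c", "nh4_c", "atp_c")),
        lb = 0, ub = 1000, gpr = gpr_complex(sample(1:3, 1)),
        subsystem = "Amino acid degradation")
    add(sprintf("SYN_%s", a),
        stats::setNames(c(-1, -1, -1, 1),
                        c("cpool_c", "nh4_c", "atp_c", sprintf("%s_c", a))),
        lb = 0, ub = 1000, gpr = gpr_complex(sample(1:2, 1)),
        subsystem = "Amino acid biosynthesis")
  }
  add("TCA_ENTRY", c(cpool_c = -1, oaa_c = -1, cit_c = 1),
      lb = 0, ub = 1000, gpr = gpr_complex(1), subsystem = "TCA cycle")
  add("TCA_IDH", c(cit_c = -1, akg_c = 1, nadh_c = 1, co2_c = 1),
      lb = 0, ub = 1000, gpr = gpr_complex(2), subsystem = "TCA cycle")
  add("TCA_KGD", c(akg_c = -1, oaa_c = 1, nadh_c = 1, co2_c = 1),
      lb = 0, ub = 1000, gpr = gpr_complex(2), subsystem = "TCA cycle")
  add("OXPHOS", c(nadh_c = -1, o2_c = -0.5, atp_c = 2),
      lb = 0, ub = 1000, gpr = paste(next_genes(4L), collapse = " and "),
      subsystem = "Oxidative phosphorylation")
  # anabolic demand per amino acid is small relative to typical uptake, so
  # surplus substrate is catabolised (degradation routes carry flux while the
  # amino acid is fed and shut down when it is depleted)
  biomass_st <- stats::setNames(rep(-0.01, n_amino_acids), sprintf("%s_c", aa))
  biomass_st <- c(biomass_st, atp_c = -2, biomass_c = 1)
  add("BIOMASS", biomass_st, lb = 0, ub = 1000, gpr = "", subsystem = "Biomass")
  add("EX_biomass", c(biomass_c = -1), lb = 0, ub = 1000, gpr = "", subsystem = "Exchange")
  add("EX_o2", c(o2_c = -1), lb = -1000, ub = 1000, gpr = "", subsystem = "Exchange")
  add("EX_nh4", c(nh4_c = -1), lb = -1000, ub = 1000, gpr = "", subsystem = "Exchange")
  add("EX_co2", c(co2_c = -1), lb = 0, ub = 1000, gpr = "", subsystem = "Exchange")
  metabolic_model(rxns, biomass = "BIOMASS",
                  id = sprintf("toy_%daa_seed%d", n_amino_acids, seed))
}

#' Define a synthetic fed-batch growth scenario
#'
#' Encodes the study conditions the growth-curve generator emulates: an
#' hourly-resolved fed-batch culture on a mixture of amino acids that are
#' depleted hierarchically, with a monotonically non-increasing growth-rate
#' profile whose last two steps are zero (no growth, no uptake), one planted
#' transient concentration increase (nutrient accumulation), and a major
#' metabolic switch at which several amino acids are exhausted at once while
#' a new set enters use one phase later.
#'
#' @param n_amino_acids Number of amino acids in the medium.
#' @param n_phases Number of hourly time steps (default 12; >= 3).
#' @param growth_rate_profile Per-phase growth rates mu (h^-1), non-increasing
#'   by default, ending in two zero phases.
#' @param depletion_schedule Named integer vector: for each amino acid, the
#'   last phase with nonzero consumption.
#' @param onset_schedule Named integer vector: first phase in which each amino
#'   acid is consumed.
#' @param yield Planted biomass yield (g biomass per g amino-acid carbon
#'   consumed) used to distribute consumption.
#' @param noise_sd Relative (multiplicative) noise on concentrations (default 0:
#'   the planted depletion structure holds exactly).
#' @param calibration List `(dry_weight_g, od_ref, volume_l)` anchoring the
#'   biomass-per-OD conversion; defaults to the 1.28 g / 3.8 OD / 1.4 l
#'   fed-batch anchor.
#' @param accumulation List `(aa, time, factor)`: plant a transient
#'   concentration increase of `aa` at time `time` (hours).
#' @param preferred_weight Relative consumption weight of the first (preferred)
#'   amino acid versus the others.
#' @param seed Integer seed.
#' @return A list of class `"synthetic_scenario"`; `major_switch` records the
#'   planted major-switch transition index.
#' @export
synthetic_scenario <- function(n_amino_acids = 6L,
                               n_phases = 12L,
                               growth_rate_profile = NULL,
                               depletion_schedule = NULL,
                               onset_schedule = NULL,
                               yield = 0.45,
                               noise_sd = 0,
                               calibration = list(dry_weight_g = 1.28, od_ref = 3.8,
                                                  volume_l = 1.4),
                               accumulation = NULL,
                               preferred_weight = 2,
                               seed = 1L) {
  stopifnot(n_phases >= 3, n_amino_acids >= 2)
  aa <- .default_aa_names(n_amino_acids)
  n_live <- n_phases - 2L
  if (is.null(growth_rate_profile)) {
    growth_rate_profile <- c(seq(0.40, 0.08, length.out = n_live), 0, 0)
  }
  stopifnot(length(growth_rate_profile) == n_phases, all(growth_rate_profile >= 0))
  if (is.null(depletion_schedule)) {
    # first amino acid consumed throughout; a block of early substrates is
    # exhausted together at the major switch; late substrates run to the end
    switch_phase <- max(2L, min(3L, n_live - 1L))
    depl <- stats::setNames(rep(n_live, n_amino_acids), aa)
    early <- aa[seq(2L, min(4L, n_amino_acids))]
    depl[early] <- switch_phase
    depletion_schedule <- depl
  }
  if (is.null(onset_schedule)) {
    onset <- stats::setNames(rep(1L, n_amino_acids), aa)
    late <- aa[depletion_schedule[aa] == n_live & aa != aa[1L]]
    early_depl <- depletion_schedule[depletion_schedule < n_live]
    if (length(late) && length(early_depl)) {
      onset[late] <- min(max(early_depl) + 2L, n_live)
    }
    onset_schedule <- onset
  }
  if (any(depletion_schedule >= n_phases)) {
    stop("depletion schedule references phase >= n_phases", call. = FALSE)
  }
  if (any(onset_schedule > depletion_schedule[names(onset_schedule)])) {
    stop("onset after depletion for some amino acid", call. = FALSE)
  }
  if (is.null(accumulation)) {
    acc_aa <- names(depletion_schedule)[depletion_schedule < n_live][1]
    accumulation <- if (!is.na(acc_aa)) {
      list(aa = acc_aa, time = max(1L, depletion_schedule[[acc_aa]] - 1L), factor = 1.15)
    }
  } else if (identical(accumulation, FALSE)) {
    accumulation <- NULL
  }
  major_switch <- max(depletion_schedule[depletion_schedule < n_live],
                      -Inf)
  structure(
    list(n_amino_acids = n_amino_acids, amino_acids = aa, n_phases = n_phases,
         growth_rate_profile = growth_rate_profile,
         depletion_schedule = depletion_schedule,
         onset_schedule = onset_schedule,
         yield = yield, noise_sd = noise_sd, calibration = calibration,
         accumulation = accumulation, preferred_weight = preferred_weight,
         major_switch = if (is.finite(major_switch)) as.integer(major_switch) else NA_integer_,
         seed = as.integer(seed)),
    class = "synthetic_scenario"
  )
}

#' Generate a synthetic fed-batch growth curve
#'
#' Produces a time-indexed table (one row per time point, 0..n_phases hours)
#' of optical density, growth rate and molar amino-acid concentrations (mM),
#' consistent with the scenario: OD grows exponentially at the per-phase mu;
#' total carbon consumed in each phase equals the biomass increment divided by
#' the planted yield; consumption is split across the amino acids active in
#' that phase; each amino acid's concentration decreases until its depletion
#' phase and is zero afterwards; one planted transient concentration increase
#' exercises the nutrient-accumulation clamp. The growth-rate column of row t
#' is the rate over the interval [t, t+1).
#'
#' @param scenario A [synthetic_scenario()].
#' @return A `"growth_curve"` object (see [growth_curve()]) with the scenario
#'   attached as attribute `"scenario"`.
#' @export
make_growth_curve <- function(scenario = synthetic_scenario()) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sc <- scenario
  n <- sc$n_phases
  aa <- sc$amino_acids
  mu <- sc$growth_rate_profile
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(sc$seed)
  cal <- sc$calibration
  conv <- biomass_per_od(cal) # g/l per OD
  # anchor the OD trajectory so that OD at the end of growth equals od_ref
  n_live <- max(which(mu > 0), 1L)
  od0 <- cal$od_ref / exp(sum(mu[seq_len(n_live)]))
  od <- od0 * exp(c(0, cumsum(mu)))
  biomass <- od * conv
  delta_biomass <- diff(biomass)
  total_cons <- delta_biomass / sc$yield # g/l of amino acid consumed per phase
  w <- stats::setNames(rep(1, length(aa)), aa)
  w[aa[1]] <- sc$preferred_weight
  active <- vapply(seq_len(n), function(i) {
    sc$onset_schedule[aa] <= i & sc$depletion_schedule[aa] >= i & mu[i] > 0
  }, logical(length(aa)))
  if (length(aa) == 1L) active <- matrix(active, nrow = 1)
  rownames(active) <- aa
  cons <- matrix(0, length(aa), n, dimnames = list(aa, NULL))
  for (i in seq_len(n)) {
    if (total_cons[i] <= 0) next
    act <- active[, i]
    if (!any(act)) {
      stop("phase ", i, " has growth but no active amino acid", call. = FALSE)
    }
    cons[act, i] <- total_cons[i] * w[act] / sum(w[act])
  }
  # mass concentration at times 0..n: what remains to be consumed
  conc_mass <- t(apply(cons, 1, function(row) rev(c(0, cumsum(rev(row))))))
  dimnames(conc_mass) <- list(aa, NULL)
  # planted nutrient accumulation: a transient rise at one time point
  if (!is.null(sc$accumulation)) {
    a <- sc$accumulation
    tb <- a$time + 1L # column index of time tb
    if (a$aa %in% aa && tb > 1L && tb <= n) {
      conc_mass[a$aa, tb] <- conc_mass[a$aa, tb - 1L] * a$factor
    }
  }
  if (sc$noise_sd > 0) {
    nz <- conc_mass > 0
    noise <- matrix(stats::rnorm(length(conc_mass), 0, sc$noise_sd), nrow(conc_mass))
    conc_mass[nz] <- pmax(conc_mass[nz] * (1 + noise[nz]), 0)
  }
  mw <- amino_acid_mw[aa]
  conc_molar <- conc_mass / mw * 1000 # mM
  df <- data.frame(time_h = 0:n, OD = od, mu_per_h = c(mu, 0))
  for (a in aa) df[[paste0("conc_", a)]] <- conc_molar[a, ]
  gc <- growth_curve(df, mw = mw, calibration = cal)
  attr(gc, "scenario") <- sc
  gc
}

#' Construct a growth-curve object
#'
#' @param data Data frame with columns `time_h`, `OD`, `mu_per_h` and one
#'   `conc_<aa>` column (molar concentration, mM) per amino acid. Row t's
#'   `mu_per_h` is the growth rate over the hour starting at `time_h`.
#' @param mw Named numeric vector of molar weights (g/mol) covering every
#'   amino acid in `data`.
#' @param calibration List `(dry_weight_g, od_ref, volume_l)` used to convert
#'   OD into biomass (g/l).
#' @return An object of class `"growth_curve"`.
#' @export
growth_curve <- function(data, mw, calibration) {
  stopifnot(is.data.frame(data),
            all(c("time_h", "OD", "mu_per_h") %in% names(data)))
  if (is.unsorted(data$time_h, strictly = TRUE)) {
    stop("time points must be strictly increasing", call. = FALSE)
  }
  conc_cols <- grep("^conc_", names(data), value = TRUE)
  aa <- sub("^conc_", "", conc_cols)
  if (!length(aa)) stop("growth curve has no conc_<aa> columns", call. = FALSE)
  if (any(vapply(conc_cols, function(cc) any(data[[cc]] < 0), TRUE))) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  missing_mw <- setdiff(aa, names(mw))
  if (length(missing_mw)) {
    stop("molar weight missing for amino acid(s): ",
         paste(missing_mw, collapse = ", "), call. = FALSE)
  }
  if (any(mw[aa] <= 0)) stop("molar weights must be positive", call. = FALSE)
  structure(
    list(data = data, amino_acids = aa, mw = mw[aa], calibration = calibration),
    class = "growth_curve"
  )
}

#' @export
print.growth_curve <- function(x, ...) {
  cat("Growth curve: ", nrow(x$data) - 1L, " hourly phases, ",
      length(x$amino_acids), " amino acids (",
      paste(x$amino_acids, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Write a growth curve as CSV plus a sidecar JSON
#'
#' The CSV holds the time-indexed table; the sidecar records molar weights and
#' the biomass calibration triple.
#'
#' @param curve A [growth_curve()].
#' @param csv_path Output CSV path.
#' @param sidecar_path Output JSON path; defaults to `<csv>.json`.
#' @return `csv_path`, invisibly.
#' @export
write_growth_curve <- function(curve, csv_path,
                               sidecar_path = paste0(csv_path, ".json")) {
  utils::write.csv(curve$data, csv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(mw = as.list(curve$mw), calibration = curve$calibration),
    sidecar_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(csv_path)
}

#' Read a growth curve from CSV plus sidecar JSON
#'
#' @param csv_path CSV written by [write_growth_curve()] (or equivalently
#'   formatted real data).
#' @param sidecar_path JSON with `mw` and `calibration`.
#' @return A [growth_curve()].
#' @export
read_growth_curve <- function(csv_path, sidecar_path = paste0(csv_path, ".json")) {
  if (!file.exists(csv_path)) stop("growth-curve file not found: ", csv_path, call. = FALSE)
  if (!file.exists(sidecar_path)) stop("sidecar JSON not found: ", sidecar_path, call. = FALSE)
  df <- utils::read.csv(csv_path, check.names = FALSE)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  growth_curve(df, mw = unlist(side$mw), calibration = as.list(side$calibration))
}
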