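# Minimal-adjustment chain across nutrient transitions.

test_that("a MOMA step with unchanged bounds returns the reference, distance 0", {
  m <- fx$model
  bnd <- phase_bounds(m, fx$pp, 1)
  ref <- fx$fba[, 1]
  step <- moma_step(m, bnd$lb, bnd$ub, ref)
  expect_equal(unname(step$flux), unname(ref), tolerance = 1e-9)
  expect_equal(step$distance, 0, tolerance = 1e-9)
  # an all-zero reference with permissive bounds stays at zero
  bnd0 <- model_bounds(m)
  step0 <- moma_step(m, bnd0$lb, bnd0$ub, rep(0, length(m$reactions)))
  expect_equal(max(abs(step0$flux)), 0, tolerance = 1e-10)
})

test_that("a MOMA step solves the KKT system exactly on a small free instance", {
  m <- tiny_chain_model()
  S <- stoichiometric_matrix(m)
  ref <- c(2, -1, 3, 0.5)
  big <- rep(100, 4)
  step <- moma_step(m, -big, big, ref)
  kkt <- ref - t(S) %*% solve(S %*% t(S), S %*% ref)
  expect_equal(unname(step$flux), as.vector(kkt), tolerance = 1e-8)
  expect_lt(max(abs(S %*% step$flux)), 1e-8)
})

test_that("the chain covers one transition per phase pair and is anchored at the first phase", {
  ch <- run_moma_chain(fx$model, fx$pp)
  expect_equal(ncol(ch$fluxes), length(fx$pp$phases) - 1L)
  expect_equal(colnames(ch$fluxes), paste0("P", fx$pp$phases[-1]))
  expect_length(ch$distances, length(fx$pp$phases) - 1L)
  expect_identical(attr(ch$fluxes, "method"), "nMOMA")
  expect_equal(unname(ch$reference), unname(fx$fba[, 1]), tolerance = 1e-9)
})

test_that("identical media across phases give zero adjustment everywhere; a planted switch dominates", {
  m <- make_toy_model(3, seed = 2)
  aa <- c("glu", "ser", "asn")
  mkpp <- function(uf) {
    structure(list(phases = seq_len(ncol(uf)), gr = rep(0.2, ncol(uf)),
                   yield = rep(0.5, ncol(uf)), delta_biomass = rep(0.1, ncol(uf)),
                   delta_conc = uf, uf = uf, scale_constants = rep(1, ncol(uf)),
                   amino_acids = aa, mw = amino_acid_mw[aa],
                   unparameterizable = integer(0)),
              class = "phase_parameterization")
  }
  uf_same <- matrix(1, 3, 5, dimnames = list(aa, NULL))
  ch_same <- run_moma_chain(m, mkpp(uf_same))
  expect_equal(unname(ch_same$distances), rep(0, 4), tolerance = 1e-8)
  # one switch: ser and asn vanish after phase 3
  uf_switch <- uf_same
  uf_switch[c("ser", "asn"), 4:5] <- 0
  ch_sw <- run_moma_chain(m, mkpp(uf_switch))
  expect_gt(ch_sw$distances[[3]], max(ch_sw$distances[-3]) + 1e-6)
})

test_that("minimal adjustment is never beaten by the FBA solution, and biomass is sub-optimal", {
  m <- fx$model
  pp <- fx$pp
  ch <- run_moma_chain(m, pp)
  fm <- fx$fba
  ref <- fx$fba[, 1]
  for (k in seq_along(pp$phases[-1])) {
    phase_col <- paste0("P", pp$phases[-1][k])
    d_moma <- sqrt(sum((ch$fluxes[, phase_col] - ref)^2))
    d_fba <- sqrt(sum((fm[, phase_col] - ref)^2))
    expect_lte(d_moma, d_fba + 1e-7)
    # biomass of the minimal-adjustment solution cannot exceed the FBA optimum
    expect_lte(ch$fluxes[m$biomass, phase_col], attr(fm, "mu")[[phase_col]] + 1e-7)
    ref <- ch$fluxes[, phase_col]
  }
})

test_that("the L1 variant also respects bounds and steady state", {
  m <- fx$model
  bnd <- phase_bounds(m, fx$pp, 4)
  ref <- fx$fba[, 3]
  step <- moma_step(m, bnd$lb, bnd$ub, ref, norm = "L1")
  S <- stoichiometric_matrix(m)
  expect_lt(max(abs(S %*% step$flux)), 1e-6)
  expect_true(all(step$flux >= bnd$lb - 1e-7 & step$flux <= bnd$ub + 1e-7))
  # L1 adjustment never exceeds that of staying put would imply; compare cost
  expect_lte(sum(abs(step$flux - ref)), sum(abs(fx$fba[, 4] - ref)) + 1e-6)
})

test_that("method comparison counts shared activity and excludes unshared phases", {
  fm <- fx$fba
  ch <- run_moma_chain(fx$model, fx$pp)
  cmp <- compare_methods(fm, ch$fluxes, fx$model)
  expect_false("P1" %in% cmp$per_phase$phase) # P1 exists only for FBA
  expect_true(all(cmp$per_phase$n_shared <= cmp$per_phase$n_active_fba))
  expect_true(all(cmp$per_phase$n_shared <= cmp$per_phase$n_active_moma))
  # identical matrices: shared = active, only-fractions zero
  cmp2 <- compare_methods(fm, fm, fx$model)
  expect_equal(cmp2$per_phase$n_shared, cmp2$per_phase$n_active_fba)
  expect_true(all(cmp2$per_subsystem$frac_fba_only == 0))
  expect_true(all(cmp2$per_subsystem$frac_moma_only == 0))
  # disjoint active sets: shared 0
  a <- matrix(c(1, 0, 0, 2), 2, 2, dimnames = list(c("r1", "r2"), c("P1", "P2")))
  b <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("r1", "r2"), c("P1", "P2")))
  mm <- metabolic_model(list(reaction("r1", c(x_c = -1)),
                             reaction("r2", c(x_c = -1))), biomass = "r1")
  cmp3 <- compare_methods(a, b, mm)
  expect_true(all(cmp3$per_phase$n_shared == 0))
  # mismatched reaction sets are an alignment error
  expect_error(compare_methods(a, b[1, , drop = FALSE], mm), "different reaction sets")
})

test_that("the minimal-adjustment chain keeps more reactions active than FBA early on", {
  ch <- run_moma_chain(fx$model, fx$pp)
  cmp <- compare_methods(fx$fba, ch$fluxes, fx$model)
  early <- cmp$per_phase[cmp$per_phase$phase %in% paste0("P", 2:5), ]
  expect_true(all(early$n_active_moma >= early$n_active_fba))
  expect_gt(mean(cmp$per_phase$n_active_moma - cmp$per_phase$n_active_fba), 0)
})
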