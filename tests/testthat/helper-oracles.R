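# Independent oracles and shared fixtures.

# Brute-force LP oracle: enumerate all basic solutions of
# {S v = 0, lb <= v <= ub} directly from the stoichiometric matrix and return
# the best objective value (NULL if no feasible vertex). Exponential; tiny
# instances only.
lp_vertex_oracle <- function(obj, S, lb, ub, maximize = TRUE) {
  n <- ncol(S)
  qt <- qr(t(S))
  r <- qt$rank
  Sr <- S[qt$pivot[seq_len(r)], , drop = FALSE]
  best <- NULL
  for (fs in utils::combn(n, n - r, simplify = FALSE)) {
    bv <- setdiff(seq_len(n), fs)
    B <- Sr[, bv, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    grid <- expand.grid(rep(list(c(1L, 2L)), length(fs)))
    for (g in seq_len(nrow(grid))) {
      v <- numeric(n)
      v[fs] <- ifelse(unlist(grid[g, ]) == 1L, lb[fs], ub[fs])
      v[bv] <- solve(B, -Sr[, fs, drop = FALSE] %*% v[fs])
      if (any(v < lb - 1e-8) || any(v > ub + 1e-8)) next
      val <- sum(obj * v)
      if (is.null(best) || (maximize && val > best) || (!maximize && val < best)) {
        best <- val
      }
    }
  }
  best
}

# Rule-by-rule re-derivation of the transition classification.
brute_classify <- function(v1, v2, tol_active = 1e-9, tol_change = 1e-6) {
  out <- list(increased = character(0), decreased = character(0),
              reversed = character(0), unchanged = character(0),
              turned_on = character(0), turned_off = character(0))
  for (r in names(v1)) {
    a1 <- abs(v1[r]) > tol_active
    a2 <- abs(v2[r]) > tol_active
    if (!a1 && a2) out$turned_on <- c(out$turned_on, r)
    if (a1 && !a2) out$turned_off <- c(out$turned_off, r)
    if (!a1 && !a2) next
    if (a1 && a2 && sign(v1[r]) != sign(v2[r])) {
      out$reversed <- c(out$reversed, r)
    } else {
      d <- abs(v2[r]) - abs(v1[r])
      if (d > tol_change) out$increased <- c(out$increased, r)
      else if (d < -tol_change) out$decreased <- c(out$decreased, r)
      else out$unchanged <- c(out$unchanged, r)
    }
  }
  out
}

# Union-find re-computation of correlation components.
brute_cluster <- function(diff_vectors, threshold = 0.7, strict = TRUE) {
  keep <- apply(diff_vectors, 1, stats::sd) > 1e-12
  dv <- diff_vectors[keep, , drop = FALSE]
  n <- nrow(dv)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      r <- stats::cor(dv[i, ], dv[j, ])
      hit <- if (strict) r > threshold else r >= threshold
      if (isTRUE(hit)) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  comps <- split(rownames(dv), roots)
  comps <- comps[vapply(comps, length, 0L) >= 2L]
  unname(lapply(comps, sort))
}

# A hand-sized three-reaction chain: EX_a (a_e <->), T (a_e -> a_c),
# BIO (a_c -> biomass sink).
tiny_chain_model <- function() {
  metabolic_model(
    list(
      reaction("EX_a", c(a_e = -1), lb = -1, ub = 1000),
      reaction("T_a", c(a_e = -1, a_c = 1), lb = 0, ub = 1000,
               gpr = "gA and gB", subsystem = "Transport"),
      reaction("BIO", c(a_c = -1, bm_c = 1), lb = 0, ub = 1000),
      reaction("EX_bm", c(bm_c = -1), lb = 0, ub = 1000)
    ),
    biomass = "BIO", id = "tiny"
  )
}

# Shared fixtures (built once per test run).
fx <- new.env()
fx$model <- make_toy_model(6, seed = 1)
fx$scenario <- synthetic_scenario(seed = 1)
fx$curve <- make_growth_curve(fx$scenario)
fx$pp <- parameterize_growth(fx$curve)
fx$fba <- run_phase_fba(fx$model, fx$pp)
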