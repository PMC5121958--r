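# Flux-difference correlation clustering and gene-set export.

test_that("flux-difference vectors drop constant trends and use absolute values", {
  fm <- matrix(c(2, 2, 2,
                 1, -3, 0,
                 0, 0, 0), 3, 3, byrow = TRUE,
               dimnames = list(c("const", "varying", "zero"), paste0("P", 1:3)))
  dv <- flux_diff_vectors(fm)
  expect_setequal(dv$excluded_constant, c("const", "zero"))
  expect_equal(unname(dv$diff["varying", ]), c(2, -3)) # |-3|-|1|, |0|-|-3|
  expect_equal(ncol(dv$diff), ncol(fm) - 1L)
  expect_error(flux_diff_vectors(fm[, 1:2]), "three phases")
})

test_that("correlation clustering joins identical trends and ignores anti-correlation", {
  dv <- rbind(a = c(1, 2, 3, 1), b = c(2, 4, 6, 2), c = -c(1, 2, 3, 1),
              d = c(5, 0, 0, 0))
  cc <- correlate_and_cluster(dv, threshold = 0.7)
  expect_length(cc$clusters, 1L)
  expect_setequal(cc$clusters[[1]], c("a", "b")) # r = 1
  # anti-correlated pair alone yields nothing
  cc2 <- correlate_and_cluster(rbind(a = c(1, 2, 3), c = -c(1, 2, 3)))
  expect_length(cc2$clusters, 0L)
  # zero-variance vectors are excluded with a warning
  expect_warning(correlate_and_cluster(rbind(a = c(1, 2, 1), z = c(1, 1, 1))),
                 "zero variance")
  # Pearson matrix is symmetric with unit diagonal
  expect_equal(cc$correlation, t(cc$correlation))
  expect_equal(unname(diag(cc$correlation)), rep(1, nrow(cc$correlation)))
})

test_that("clusters equal a brute-force union-find recomputation on random instances", {
  set.seed(41)
  for (trial in 1:5) {
    dv <- matrix(rnorm(20 * 9), 20, 9, dimnames = list(paste0("r", 1:20), NULL))
    # plant a few correlated blocks
    dv[2, ] <- dv[1, ] * 2 + rnorm(9, 0, 0.05)
    dv[3, ] <- dv[1, ] + rnorm(9, 0, 0.05)
    dv[12, ] <- dv[11, ] * 0.5
    cc <- suppressWarnings(correlate_and_cluster(dv, threshold = 0.7))
    got <- unname(lapply(cc$clusters, sort))
    oracle <- brute_cluster(dv, threshold = 0.7)
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(oracle, paste, "", collapse = ","))
  }
})

test_that("cluster membership is stable under reordering and sign flips", {
  set.seed(42)
  fm <- matrix(rnorm(60), 12, 5, dimnames = list(paste0("r", 1:12), paste0("P", 1:5)))
  fm[2, ] <- fm[1, ] * 1.5
  dv1 <- flux_diff_vectors(fm)$diff
  cc1 <- suppressWarnings(correlate_and_cluster(dv1))
  perm <- sample(nrow(fm))
  dv2 <- flux_diff_vectors(fm[perm, ])$diff
  cc2 <- suppressWarnings(correlate_and_cluster(dv2))
  key <- function(cc) {
    sort(unname(vapply(cc$clusters, function(x) paste(sort(x), collapse = ","), "")))
  }
  expect_equal(key(cc1), key(cc2))
  dv3 <- flux_diff_vectors(-fm)$diff # d uses absolute fluxes
  cc3 <- suppressWarnings(correlate_and_cluster(dv3))
  expect_equal(key(cc1), key(cc3))
})

test_that("gene mapping takes the GPR union per cluster", {
  m <- metabolic_model(
    list(reaction("R1", c(a_c = -1, b_c = 1), gpr = "g1 and g2 and g3"),
         reaction("R2", c(b_c = -1, c_c = 1), gpr = "g2 or g4"),
         reaction("R3", c(c_c = -1, d_c = 1), gpr = ""),
         reaction("BIO", c(d_c = -1))),
    biomass = "BIO"
  )
  gs <- clusters_to_genes(list(c1 = c("R1"), c2 = c("R1", "R2", "R3")), m)
  expect_setequal(gs$c1, c("g1", "g2", "g3"))
  expect_setequal(gs$c2, c("g1", "g2", "g3", "g4"))
  expect_equal(sum(gs$c2 == "g2"), 1L)
  expect_identical(attr(gs, "no_gpr"), "R3")
})

test_that("a planted co-regulated pathway is recovered as one cluster with its genes", {
  # all reactions of the planted pathway are scaled copies of one flux profile
  profile <- c(5, 4, 6, 2, 1)
  fm <- rbind(
    p1 = profile, p2 = 2 * profile, p3 = 0.5 * profile,
    other1 = c(1, 1, 1, 1, 1), other2 = c(0, 3, 0, 3, 0), other3 = c(2, 1, 4, 1, 2)
  )
  colnames(fm) <- paste0("P", 1:5)
  m <- metabolic_model(
    list(reaction("p1", c(a_c = -1, b_c = 1), gpr = "op1"),
         reaction("p2", c(b_c = -1, c_c = 1), gpr = "op2"),
         reaction("p3", c(c_c = -1, d_c = 1), gpr = "op3"),
         reaction("other1", c(a_c = -1, d_c = 1), gpr = "gx"),
         reaction("other2", c(a_c = -1, d_c = 1), gpr = "gy"),
         reaction("other3", c(a_c = -1, d_c = 1), gpr = "gz"),
         reaction("BIO", c(d_c = -1))),
    biomass = "BIO"
  )
  cov <- suppressWarnings(find_covarying_clusters(fm, m, threshold = 0.7))
  hit <- Filter(function(cl) all(c("p1", "p2", "p3") %in% cl), cov$clusters)
  expect_length(hit, 1L)
  expect_true(all(c("op1", "op2", "op3") %in%
                    cov$gene_sets[[names(cov$clusters)[vapply(cov$clusters, function(cl)
                      all(c("p1", "p2", "p3") %in% cl), TRUE)][1]]]))
})

test_that("gene lists export one file per cluster plus a GMT that round-trips", {
  gs <- list(cluster_1 = c("g1", "g2"), cluster_2 = c("g3", "g4", "g5"))
  d <- tempfile("genes_")
  paths <- export_gene_lists(gs, d)
  expect_length(list.files(d, pattern = "^cluster_[0-9]+\\.txt$"), 2L)
  gmt <- file.path(d, "clusters.gmt")
  expect_true(file.exists(gmt))
  back <- read_gmt(gmt)
  expect_equal(back, gs)
  expect_error(export_gene_lists(list(), d), "no gene sets")
})
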