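# Flux-difference correlation clustering: groups of reactions whose absolute
# fluxes rise and fall together across phase transitions, mapped to gene sets
# through the GPR rules.

#' Flux-difference vectors per reaction
#'
#' Reactions with a constant trend (all absolute fluxes equal within `tol`)
#' are removed; for each remaining reaction the per-transition difference of
#' absolute fluxes `d_z = |f_(z+1)| - |f_z|` is computed, giving a vector of
#' length one less than the number of phases.
#'
#' @param fm Flux matrix (reactions x phases, >= 3 phases).
#' @param tol Tolerance for the constant-trend filter.
#' @return List with `diff` (matrix retained reactions x transitions) and
#'   `excluded_constant` (reaction ids removed).
#' @export
flux_diff_vectors <- function(fm, tol = 1e-9) {
  if (ncol(fm) < 3L) stop("need at least three phases", call. = FALSE)
  av <- abs(unclass(fm))
  constant <- apply(av, 1, function(x) max(x) - min(x) <= tol)
  d <- t(diff(t(av[!constant, , drop = FALSE])))
  colnames(d) <- paste0("T", seq_len(ncol(d)))
  list(diff = d, excluded_constant = rownames(fm)[constant])
}

#' Cluster reactions by flux-difference correlation
#'
#' Computes the Pearson correlation between every pair of flux-difference
#' vectors and extracts the connected components of the graph whose edges join
#' pairs with correlation above the threshold (single-linkage reading of
#' "sharing a correlation greater than 0.7"). Vectors with zero variance are
#' excluded with a warning; singleton components are dropped.
#'
#' @param diff_vectors Matrix reactions x transitions (the `diff` element of
#'   [flux_diff_vectors()]).
#' @param threshold Correlation threshold (default 0.7).
#' @param strict If `TRUE` (default) an edge requires r > threshold, otherwise
#'   r >= threshold.
#' @return List of class `"covariation_clusters"`: `clusters` (list of
#'   reaction-id vectors, largest first), `correlation` (full matrix over the
#'   correlated reactions), `excluded_zero_variance`, `threshold`, `strict`.
#' @export
correlate_and_cluster <- function(diff_vectors, threshold = 0.7, strict = TRUE) {
  stopifnot(threshold > -1, threshold < 1)
  sds <- apply(diff_vectors, 1, stats::sd)
  degenerate <- !is.finite(sds) | sds <= 1e-12
  if (any(degenerate)) {
    warning(sum(degenerate), " flux-difference vector(s) with zero variance excluded")
  }
  dv <- diff_vectors[!degenerate, , drop = FALSE]
  if (nrow(dv) < 2L) {
    return(structure(list(clusters = list(), correlation = NULL,
                          excluded_zero_variance = rownames(diff_vectors)[degenerate],
                          threshold = threshold, strict = strict),
                     class = "covariation_clusters"))
  }
  cm <- stats::cor(t(dv))
  adj <- if (strict) cm > threshold else cm >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  clusters <- split(rownames(dv), comp$membership)
  clusters <- clusters[vapply(clusters, length, 0L) >= 2L]
  clusters <- clusters[order(-vapply(clusters, length, 0L))]
  if (length(clusters)) names(clusters) <- paste0("cluster_", seq_along(clusters))
  structure(
    list(clusters = clusters, correlation = cm,
         excluded_zero_variance = rownames(diff_vectors)[degenerate],
         threshold = threshold, strict = strict),
    class = "covariation_clusters"
  )
}

#' Map reaction clusters to gene sets via GPR rules
#'
#' @param clusters A `"covariation_clusters"` object or a plain list of
#'   reaction-id vectors.
#' @param model A [metabolic_model()].
#' @return Named list of gene-id vectors (one per cluster); attribute
#'   `"no_gpr"` lists clustered reactions with an empty GPR.
#' @export
clusters_to_genes <- function(clusters, model) {
  cl <- if (inherits(clusters, "covariation_clusters")) clusters$clusters else clusters
  gene_sets <- lapply(cl, function(rxns) genes_for_reactions(model, rxns))
  no_gpr <- unlist(lapply(cl, function(rxns) {
    rxns[vapply(rxns, function(r) length(gpr_genes(model$reactions[[r]]$gpr)) == 0L, TRUE)]
  }))
  attr(gene_sets, "no_gpr") <- unname(no_gpr)
  gene_sets
}

#' Full covariation analysis of a flux matrix
#'
#' Convenience wrapper: flux-difference vectors, correlation clustering and
#' gene mapping in one call.
#'
#' @inheritParams flux_diff_vectors
#' @inheritParams correlate_and_cluster
#' @param model A [metabolic_model()].
#' @return An object of class `"covariation_result"` combining the pieces:
#'   `diff_vectors`, `excluded_constant`, `excluded_zero_variance`,
#'   `correlation`, `clusters`, `gene_sets`, `threshold`.
#' @export
find_covarying_clusters <- function(fm, model, threshold = 0.7, strict = TRUE,
                                    tol = 1e-9) {
  dv <- flux_diff_vectors(fm, tol = tol)
  cc <- correlate_and_cluster(dv$diff, threshold = threshold, strict = strict)
  gene_sets <- clusters_to_genes(cc, model)
  structure(
    list(diff_vectors = dv$diff, excluded_constant = dv$excluded_constant,
         excluded_zero_variance = cc$excluded_zero_variance,
         correlation = cc$correlation, clusters = cc$clusters,
         gene_sets = gene_sets, threshold = threshold, strict = strict),
    class = "covariation_result"
  )
}

#' @export
print.covariation_result <- function(x, ...) {
  cat("Covariation analysis:", length(x$clusters), "clusters comprising",
      length(unique(unlist(x$clusters))), "reactions encoded by",
      length(unique(unlist(x$gene_sets))), "genes (r >",
      x$threshold, ")\n")
  invisible(x)
}

#' Export cluster gene lists for external annotation
#'
#' Writes one plain-text gene list per cluster plus a combined GMT file
#' (`<set name> TAB <description> TAB gene TAB gene ...`), the format consumed
#' by downstream enrichment and association tools.
#'
#' @param gene_sets Named list of gene-id vectors (from [clusters_to_genes()]
#'   or the `gene_sets` field of a `"covariation_result"`).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix for the per-cluster lists.
#' @return Character vector of written file paths, invisibly.
#' @export
export_gene_lists <- function(gene_sets, dir, prefix = "cluster") {
  if (!length(gene_sets)) stop("no gene sets to export", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(names(gene_sets))) {
    names(gene_sets) <- paste0(prefix, "_", seq_along(gene_sets))
  }
  paths <- character(0)
  for (nm in names(gene_sets)) {
    p <- file.path(dir, paste0(prefix, "_", sub("^cluster_", "", nm), ".txt"))
    writeLines(gene_sets[[nm]], p)
    paths <- c(paths, p)
  }
  gmt <- file.path(dir, paste0(prefix, "s.gmt"))
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "flux_covariation", gene_sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, gmt)
  invisible(c(paths, gmt))
}

#' Read a GMT gene-set file
#'
#' @param path GMT path.
#' @return Named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  out
}
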