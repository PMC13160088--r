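#' Pseudotime configuration
#'
#' @param n_pcs Number of principal components (default 45).
#' @param k_neighbors Neighbours of the kNN graph (default 30; 40 suits
#'   larger, denser acquisitions).
#' @param n_bins Number of equal-width pseudotime bins (default 12).
#' @param seed Integer seed (kept for interface symmetry; the procedure is
#'   deterministic).
#' @return A list of class `pseudotime_config`.
#' @export
pseudotime_config <- function(n_pcs = 45L, k_neighbors = 30L, n_bins = 12L,
                              seed = 1L) {
  stopifnot(k_neighbors >= 2, n_pcs >= 1, n_bins >= 1)
  structure(list(n_pcs = as.integer(n_pcs),
                 k_neighbors = as.integer(k_neighbors),
                 n_bins = as.integer(n_bins), seed = as.integer(seed)),
            class = "pseudotime_config")
}

#' Unsupervised activation pseudotime
#'
#' Orders spectra along a biochemical trajectory without using their time
#' labels: centered (unscaled) PCA to `n_pcs` dimensions, a union-
#' symmetrized k-nearest-neighbour graph under cosine distance, restriction
#' to the largest connected component, and a minimum spanning tree rooted
#' at the earliest-acquired member cell (ties broken by lexicographically
#' smallest `spectrum_id`). Pseudotime is the edge-weight sum along the
#' unique tree path from the root, normalized to `[0, 1]`. Spectra outside
#' the largest component carry `NA` pseudotime and are reported.
#'
#' @param x A preprocessed spectra table with `time_min`.
#' @param config A [pseudotime_config()].
#' @return An object of class `pseudotime_result`: a per-spectrum tibble
#'   (`spectrum_id`, `time_min`, `in_component`, `tau`), the tree edge
#'   list, the root id and the config.
#' @export
compute_pseudotime <- function(x, config = pseudotime_config()) {
  x <- as_spectra_tbl(x)
  if (all(is.na(x$time_min))) abort("no spectrum carries time_min")
  if (nrow(x) <= config$k_neighbors) {
    abort("need more spectra than k_neighbors")
  }
  m <- spectra_matrix(x)
  n_pcs <- min(config$n_pcs, nrow(m) - 1L, ncol(m))
  pcs <- prcomp(m, center = TRUE, scale. = FALSE, rank. = n_pcs)$x

  # cosine distance on PCA scores
  nrm <- sqrt(rowSums(pcs^2))
  nrm[nrm == 0] <- 1
  s <- tcrossprod(pcs / nrm)
  d <- pmax(1 - s, 0)
  diag(d) <- Inf

  k <- config$k_neighbors
  n <- nrow(d)
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[seq_len(k)]
    edges[[i]] <- cbind(i, nb)
  }
  e <- do.call(rbind, edges)
  # union symmetrization: undirected simple graph
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::simplify(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$weight <- d[el]

  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  in_comp <- comp$membership == main
  if (sum(in_comp) < 0.1 * n) {
    abort("largest connected component holds under 10% of the spectra")
  }
  sub <- igraph::induced_subgraph(g, which(in_comp))
  ids_sub <- x$spectrum_id[in_comp]
  t_sub <- x$time_min[in_comp]

  cand <- which(t_sub == min(t_sub, na.rm = TRUE))
  root_local <- cand[order(ids_sub[cand])][1]
  tree <- igraph::mst(sub, weights = igraph::E(sub)$weight)
  dist_root <- as.numeric(igraph::distances(tree, v = root_local,
                                            weights = igraph::E(tree)$weight))
  tau_sub <- if (max(dist_root) > 0) dist_root / max(dist_root) else dist_root

  tau <- rep(NA_real_, n)
  tau[in_comp] <- tau_sub
  tel <- igraph::as_edgelist(tree, names = FALSE)
  edges_tbl <- tibble(from = ids_sub[tel[, 1]], to = ids_sub[tel[, 2]],
                      weight = igraph::E(tree)$weight)

  structure(list(
    cells = tibble(spectrum_id = x$spectrum_id, time_min = x$time_min,
                   in_component = in_comp, tau = tau),
    edges = edges_tbl,
    root_id = ids_sub[root_local],
    n_components = comp$no,
    config = config
  ), class = "pseudotime_result")
}

#' Pseudotime bins in embedding space
#'
#' Partitions the pseudotime range into `n_bins` equal-width intervals and
#' returns the mean embedding coordinate of each occupied bin (ordered by
#' pseudotime). Empty bins are omitted from the rows; the full occupancy
#' vector is kept in the `bin_counts` attribute.
#'
#' @param result A [compute_pseudotime()] result.
#' @param coords Output of [embed_spectra()], aligned by `spectrum_id`.
#' @return A tibble `bin`, `tau_mid`, `n`, `umap1_mean`, `umap2_mean`.
#' @export
pseudotime_bins <- function(result, coords) {
  cells <- result$cells |> filter(.data$in_component)
  j <- match(cells$spectrum_id, coords$spectrum_id)
  if (anyNA(j)) abort("coords do not cover every in-component spectrum")
  nb <- result$config$n_bins
  brk <- seq(0, 1, length.out = nb + 1)
  bin <- pmin(findInterval(cells$tau, brk, rightmost.closed = TRUE), nb)
  counts <- tabulate(bin, nbins = nb)
  out <- tibble(bin = bin,
                umap1 = coords$umap1[j], umap2 = coords$umap2[j]) |>
    group_by(.data$bin) |>
    summarise(n = dplyr::n(),
              umap1_mean = mean(.data$umap1),
              umap2_mean = mean(.data$umap2), .groups = "drop") |>
    mutate(tau_mid = (brk[.data$bin] + brk[.data$bin + 1]) / 2,
           .after = "bin") |>
    arrange(.data$bin)
  attr(out, "bin_counts") <- counts
  out
}

#' Pseudotime vs. real time correlation
#'
#' Two-sided Spearman rank correlation between pseudotime and acquisition
#' time, at two levels: per spectrum (all largest-component members) and
#' per time bin (median pseudotime of each occupied bin against the bin
#' start time; requires at least 3 occupied bins, otherwise the bin-level
#' row is `NA` with a warning). Ties are handled by midranks.
#'
#' @param result A [compute_pseudotime()] result.
#' @param binning A [time_bins()] object.
#' @return A tibble `level`, `rho`, `p_value`, `n`.
#' @export
time_correlation <- function(result, binning = time_bins()) {
  cells <- result$cells |>
    filter(.data$in_component, !is.na(.data$time_min))
  ct <- suppressWarnings(cor.test(cells$tau, cells$time_min,
                                  method = "spearman", exact = FALSE))
  spectrum <- tibble(level = "spectrum", rho = unname(ct$estimate),
                     p_value = ct$p.value, n = nrow(cells))
  binned <- cells |>
    mutate(bin_start = assign_time_bin(.data$time_min, binning)) |>
    filter(!is.na(.data$bin_start)) |>
    group_by(.data$bin_start) |>
    summarise(tau_med = median(.data$tau), .groups = "drop")
  if (nrow(binned) < 3) {
    warn("fewer than 3 occupied time bins; bin-level correlation not computed")
    bin_row <- tibble(level = "bin", rho = NA_real_, p_value = NA_real_,
                      n = nrow(binned))
  } else {
    cb <- suppressWarnings(cor.test(binned$tau_med, binned$bin_start,
                                    method = "spearman", exact = FALSE))
    bin_row <- tibble(level = "bin", rho = unname(cb$estimate),
                      p_value = cb$p.value, n = nrow(binned))
  }
  bind_rows(spectrum, bin_row)
}
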