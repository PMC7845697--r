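#' Column-normalize an adjacency matrix
#'
#' Builds the column-stochastic transition matrix W of an undirected simple
#' graph: each nonzero column of the adjacency matrix is divided by its
#' degree so it sums to 1. Zero-degree (isolated) columns are left all-zero;
#' the restart term of the walk re-injects any mass lost there, so no
#' artificial teleportation is introduced.
#'
#' @param network An igraph graph (undirected, simple) with named vertices.
#' @return Sparse `dgCMatrix` with dimnames set to vertex names.
#' @export
normalize_adjacency <- function(network) {
  a <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  deg <- Matrix::colSums(a)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  w <- a %*% Matrix::Diagonal(x = inv)
  dimnames(w) <- dimnames(a)
  methods::as(w, "CsparseMatrix")
}

#' Build the restart vector of a compound
#'
#' Seeds the walker on the compound's mapped targets: raw weight 1.0 on
#' directly bound proteins and 0.3 on indirectly affected ones, zero
#' elsewhere, then normalized to sum to one (the 10:3 weight ratio is
#' preserved; the walk formalism needs a probability vector). Targets
#' absent from the network are counted in the `n_unmapped` attribute.
#'
#' @param profile A [compound_profile()].
#' @param nodes Character vector of network node names (in matrix order).
#' @param w_direct,w_indirect Raw seed weights (defaults 1.0 and 0.3).
#' @return Named probability vector over `nodes` with attribute `n_unmapped`.
#' @export
build_seed_vector <- function(profile, nodes, w_direct = 1.0, w_indirect = 0.3) {
  p0 <- stats::setNames(numeric(length(nodes)), nodes)
  dmap <- intersect(profile$direct, nodes)
  imap <- intersect(profile$indirect, nodes)
  if (length(dmap) + length(imap) == 0L) {
    stop(sprintf("empty seed: no target of '%s' maps to the network", profile$id))
  }
  p0[dmap] <- w_direct
  p0[imap] <- w_indirect
  p0 <- p0 / sum(p0)
  attr(p0, "n_unmapped") <- length(setdiff(profile_targets(profile), nodes))
  p0
}

#' Random walk with restart
#'
#' Iterates the propagation `p_{t+1} = (1 - r) W' p_t + r p0` from `p0`
#' until the L1 change drops below `tol`. `W` is the column-normalized
#' adjacency from [normalize_adjacency()] and `r` the restart probability;
#' the defaults (r = 0.7, tol = 1e-8) are the standard settings for scoring
#' compound effects propagated over a protein interaction network.
#'
#' @param w Column-normalized transition matrix.
#' @param p0 Initial probability vector (non-negative, sums to 1).
#' @param r Restart probability in (0, 1); default 0.7.
#' @param tol L1 convergence tolerance; default 1e-8.
#' @param max_iter Iteration cap; default 1000.
#' @return List with `p` (named stationary probability vector),
#'   `iterations` and the final `residual`.
#' @export
rwr <- function(w, p0, r = 0.7, tol = 1e-8, max_iter = 1000L) {
  stopifnot(r > 0, r < 1, tol > 0, max_iter >= 1L)
  stopifnot(length(p0) == ncol(w), all(p0 >= 0))
  stopifnot(abs(sum(p0) - 1) < 1e-8)
  wt <- Matrix::t(w)
  p <- as.numeric(p0)
  for (it in seq_len(max_iter)) {
    p_next <- as.numeric((1 - r) * (wt %*% p) + r * p0)
    residual <- sum(abs(p_next - p))
    p <- p_next
    if (residual < tol) {
      names(p) <- colnames(w)
      return(list(p = p, iterations = it, residual = residual))
    }
  }
  stop(sprintf("random walk did not converge in %d iterations (residual %.3g)",
               max_iter, residual))
}

#' Disease score of a propagated probability vector
#'
#' Sums the stationary probabilities over a disease's gene set; genes absent
#' from the network contribute zero.
#'
#' @param p Named probability vector from [rwr()].
#' @param disease_genes Character vector of disease gene ids (non-empty).
#' @return Scalar score in `[0, 1]`.
#' @export
disease_score <- function(p, disease_genes) {
  stopifnot(length(disease_genes) > 0L)
  sum(p[intersect(names(p), disease_genes)])
}

#' Read / write disease-gene sets
#'
#' Two-column tab-separated table with header (`disease_id`, `gene_id`).
#'
#' @param path File path.
#' @return `read_disease_genes`: named list of gene-id vectors.
#' @export
read_disease_genes <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  names(tab)[1:2] <- c("disease_id", "gene_id")
  split(tab$gene_id, tab$disease_id)
}

#' @rdname read_disease_genes
#' @param modules Named list of gene-id vectors.
#' @export
write_disease_genes <- function(modules, path) {
  tab <- data.frame(
    disease_id = rep(names(modules), lengths(modules)),
    gene_id = unlist(modules, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Raw molecular-interaction features of a compound set
#'
#' Runs the restart walk once per compound on the full network and restricts
#' each stationary vector to the disease-related protein list (the network
#' proteins known to be disease-associated); the restricted vectors form the
#' pre-reduction interaction feature matrix.
#'
#' @param network igraph graph with named vertices.
#' @param profiles Named list of [compound_profile()] objects.
#' @param disease_proteins Character vector of disease-related protein ids.
#' @param r,tol,max_iter Passed to [rwr()].
#' @return Numeric matrix, compounds x disease-related proteins.
#' @export
interaction_raw_features <- function(network, profiles, disease_proteins,
                                     r = 0.7, tol = 1e-8, max_iter = 1000L) {
  w <- normalize_adjacency(network)
  nodes <- colnames(w)
  keep <- intersect(disease_proteins, nodes)
  if (length(keep) == 0L) stop("no disease-related protein maps to the network")
  rows <- t(vapply(profiles, function(pr) {
    p0 <- build_seed_vector(pr, nodes)
    rwr(w, p0, r = r, tol = tol, max_iter = max_iter)$p[keep]
  }, numeric(length(keep))))
  rownames(rows) <- names(profiles)
  colnames(rows) <- keep
  rows
}

#' Fit a variance-thresholded principal component reduction
#'
#' Centers by the training mean and keeps the smallest number of principal
#' components whose cumulative explained variance ratio reaches `threshold`
#' (default 0.8). When the threshold is unreachable (rank deficiency) all
#' `rank` components are kept with a warning. Fit the model on training rows
#' only and project held-out rows with [apply_reduction()] to avoid leakage.
#'
#' @param x Numeric training matrix (rows = samples); needs >= 2 rows.
#' @param threshold Cumulative explained-variance threshold in (0, 1].
#' @return Object of class `reduction_model`: list with `center`,
#'   `components` (orthonormal columns), `n_components`,
#'   `explained_variance_ratio`.
#' @export
fit_reduction <- function(x, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1, nrow(x) >= 2L)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  var_all <- pc$sdev^2
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-12)
  evr <- var_all / sum(var_all)
  cum <- cumsum(evr)
  reached <- which(cum >= threshold - 1e-12)
  if (length(reached) == 0L || reached[1] > rank) {
    warning(sprintf("threshold %.2f unreachable; keeping all %d components",
                    threshold, rank))
    k <- rank
  } else {
    k <- reached[1]
  }
  structure(
    list(center = pc$center,
         components = pc$rotation[, seq_len(k), drop = FALSE],
         n_components = k,
         explained_variance_ratio = evr[seq_len(k)]),
    class = "reduction_model"
  )
}

#' Project rows with a fitted reduction model
#'
#' @param model A `reduction_model` from [fit_reduction()].
#' @param x Numeric matrix with the same columns as the training data.
#' @return Score matrix (rows x `model$n_components`), columns named `pc1..`.
#' @export
apply_reduction <- function(model, x) {
  stopifnot(inherits(model, "reduction_model"), ncol(x) == length(model$center))
  scores <- sweep(x, 2L, model$center) %*% model$components
  colnames(scores) <- sprintf("pc%03d", seq_len(ncol(scores)))
  rownames(scores) <- rownames(x)
  scores
}

# Shortest-path distance matrix between two node sets; drops set members
# not present in the network and errors when either side is empty.
proximity_dists <- function(targets, disease_genes, network) {
  nodes <- igraph::V(network)$name
  t_in <- intersect(targets, nodes)
  g_in <- intersect(disease_genes, nodes)
  if (length(t_in) == 0L || length(g_in) == 0L) {
    stop("target or disease-gene set does not intersect the network")
  }
  d <- igraph::distances(network, v = t_in, to = g_in)
  dimnames(d) <- list(t_in, g_in)
  d
}

#' Closest-distance proximity
#'
#' Mean, over compound targets, of the shortest-path distance to the nearest
#' disease gene. Unreachable pairs are excluded; targets with no reachable
#' disease gene are dropped, and an error is raised if no finite pair exists.
#'
#' @param targets Character vector of target protein ids.
#' @param disease_genes Character vector of disease gene ids.
#' @param network igraph graph with named vertices.
#' @return Scalar distance.
#' @export
proximity_closest <- function(targets, disease_genes, network) {
  d <- proximity_dists(targets, disease_genes, network)
  mins <- apply(d, 1L, function(row) min(row[is.finite(row)], Inf))
  mins <- mins[is.finite(mins)]
  if (length(mins) == 0L) stop("no finite path between targets and disease genes")
  mean(mins)
}

#' Shortest-distance proximity
#'
#' Mean shortest-path distance over all finite target-gene pairs.
#'
#' @inheritParams proximity_closest
#' @return Scalar distance.
#' @export
proximity_shortest <- function(targets, disease_genes, network) {
  d <- proximity_dists(targets, disease_genes, network)
  vals <- d[is.finite(d)]
  if (length(vals) == 0L) stop("no finite path between targets and disease genes")
  mean(vals)
}

#' Kernel proximity
#'
#' Exponentially downweights long paths:
#' `d = -(1/|G|) * sum_g log[ (1/|T|) * sum_t exp(-(d(t,g) + 1)) ]`.
#' Unreachable pairs contribute zero to the inner sum; a gene whose inner
#' sum is zero is excluded with a warning, and an error is raised if every
#' gene is excluded.
#'
#' @inheritParams proximity_closest
#' @return Scalar kernel distance.
#' @export
proximity_kernel <- function(targets, disease_genes, network) {
  d <- proximity_dists(targets, disease_genes, network)
  n_t <- nrow(d)
  inner <- apply(d, 2L, function(col) {
    terms <- ifelse(is.finite(col), exp(-(col + 1)), 0)
    sum(terms) / n_t
  })
  if (any(inner == 0)) {
    warning(sprintf("excluding %d unreachable disease gene(s) from kernel distance",
                    sum(inner == 0)))
    inner <- inner[inner > 0]
  }
  if (length(inner) == 0L) stop("all disease genes unreachable from the targets")
  -mean(log(inner))
}

#' Centre proximity
#'
#' Distance to the disease-module centre: the disease gene with the largest
#' closeness centrality (computed over the nodes reachable from each gene;
#' ties broken lexicographically by gene id). The result is the mean
#' shortest-path distance from each target to that centre gene.
#'
#' @inheritParams proximity_closest
#' @return Scalar distance.
#' @export
proximity_centre <- function(targets, disease_genes, network) {
  nodes <- igraph::V(network)$name
  g_in <- sort(intersect(disease_genes, nodes))
  if (length(g_in) == 0L) stop("disease-gene set does not intersect the network")
  if (length(g_in) == 1L) {
    centre <- g_in
  } else {
    d_all <- igraph::distances(network, v = g_in, to = nodes)
    closeness <- apply(d_all, 1L, function(row) {
      reach <- row[is.finite(row) & row > 0]
      if (length(reach) == 0L) return(0)
      length(reach) / sum(reach)
    })
    centre <- g_in[which.max(closeness)]  # which.max: first (lexicographic) tie
  }
  d <- proximity_dists(targets, centre, network)
  vals <- d[is.finite(d)]
  if (length(vals) == 0L) stop("no finite path between targets and the centre gene")
  mean(vals)
}

# Closest-based mean distance between sets with the nearest-other
# convention: every member of either set contributes its distance to the
# nearest member of the other set.
sep_between <- function(d) {
  row_min <- apply(d, 1L, function(x) min(x[is.finite(x)], Inf))
  col_min <- apply(d, 2L, function(x) min(x[is.finite(x)], Inf))
  vals <- c(row_min, col_min)
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) stop("no finite path between the two sets")
  mean(vals)
}

# Within-set closest mean: each member's distance to its nearest other
# member (self-distance excluded); 0 for singleton sets.
sep_within <- function(set, network) {
  nodes <- igraph::V(network)$name
  s_in <- intersect(set, nodes)
  if (length(s_in) <= 1L) return(0)
  d <- igraph::distances(network, v = s_in, to = s_in)
  diag(d) <- Inf
  mins <- apply(d, 1L, function(x) min(x[is.finite(x)], Inf))
  mins <- mins[is.finite(mins)]
  if (length(mins) == 0L) return(0)
  mean(mins)
}

#' Separation proximity
#'
#' Network separation of the target set T and disease-gene set G:
#' `s = <d_TG> - (<d_TT> + <d_GG>) / 2`, where `<d_TG>` is the closest-based
#' between-set mean (each node paired with its nearest member of the other
#' set) and `<d_XX>` the closest-based within-set mean with self-distances
#' excluded (0 for singletons). Negative values indicate overlapping
#' neighbourhoods.
#'
#' @inheritParams proximity_closest
#' @return Scalar separation score.
#' @export
proximity_separation <- function(targets, disease_genes, network) {
  d <- proximity_dists(targets, disease_genes, network)
  sep_between(d) -
    (sep_within(targets, network) + sep_within(disease_genes, network)) / 2
}

#' Score compounds against a disease by a proximity method
#'
#' @param method One of `"closest"`, `"shortest"`, `"kernel"`, `"centre"`,
#'   `"separation"`, `"rwr"`.
#' @param profiles Named list of [compound_profile()] objects.
#' @param disease_genes Character vector of disease gene ids.
#' @param network igraph graph.
#' @param ... Passed to [rwr()] for `method = "rwr"`.
#' @return Named numeric vector of prediction scores, one per compound:
#'   higher means a stronger predicted association (distances are negated).
#' @export
proximity_score <- function(method, profiles, disease_genes, network, ...) {
  method <- match.arg(method, c("closest", "shortest", "kernel", "centre",
                                "separation", "rwr"))
  if (method == "rwr") {
    w <- normalize_adjacency(network)
    nodes <- colnames(w)
    scores <- vapply(profiles, function(pr) {
      p0 <- build_seed_vector(pr, nodes)
      disease_score(rwr(w, p0, ...)$p, disease_genes)
    }, numeric(1))
    return(scores)
  }
  fn <- switch(method,
               closest = proximity_closest,
               shortest = proximity_shortest,
               kernel = proximity_kernel,
               centre = proximity_centre,
               separation = proximity_separation)
  vapply(profiles, function(pr) {
    -fn(profile_targets(pr), disease_genes, network)
  }, numeric(1))
}

#' Per-disease AUROC of a proximity or propagation method
#'
#' Scores every compound against every disease with [proximity_score()] and
#' computes one AUROC per disease against the binary labels.
#'
#' @param profiles Named list of [compound_profile()] objects.
#' @param disease_gene_sets Named list of disease gene-id vectors.
#' @param labels Binary compound-by-disease matrix (dimnames required).
#' @param method Scoring method; see [proximity_score()].
#' @param network igraph graph.
#' @param ... Passed to [proximity_score()].
#' @return `data.frame` with columns `disease`, `auroc`, `n_pos`, `n_neg`.
#' @export
proximity_auroc <- function(profiles, disease_gene_sets, labels, method,
                            network, ...) {
  stopifnot(all(colnames(labels) %in% names(disease_gene_sets)))
  rows <- lapply(colnames(labels), function(dz) {
    scores <- proximity_score(method, profiles, disease_gene_sets[[dz]],
                              network, ...)
    y <- labels[names(profiles), dz]
    data.frame(disease = dz, auroc = auroc(scores, y),
               n_pos = sum(y == 1), n_neg = sum(y == 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
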