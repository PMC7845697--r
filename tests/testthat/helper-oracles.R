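# Independent brute-force oracles used to check the package implementations.
# These deliberately avoid the code paths under test: graph distances are
# computed by a hand-rolled breadth-first search, AUROC by O(n^2) pair
# counting, Fisher tails by explicit log-binomial sums, and Mann-Whitney
# p-values by bitmask subset enumeration.

adjacency_list <- function(g) {
  nodes <- igraph::V(g)$name
  adj <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  el <- igraph::as_edgelist(g, names = TRUE)
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1]; b <- el[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

oracle_bfs <- function(adj, src) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[src] <- 0
  queue <- src
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (u in adj[[v]]) {
      if (!is.finite(dist[u])) {
        dist[u] <- dist[v] + 1
        queue <- c(queue, u)
      }
    }
  }
  dist
}

oracle_dist_matrix <- function(g, from, to) {
  adj <- adjacency_list(g)
  d <- matrix(Inf, length(from), length(to), dimnames = list(from, to))
  for (i in seq_along(from)) {
    d[i, ] <- oracle_bfs(adj, from[i])[to]
  }
  d
}

oracle_closest <- function(targets, genes, g) {
  d <- oracle_dist_matrix(g, targets, genes)
  mins <- apply(d, 1L, function(r) min(r[is.finite(r)], Inf))
  mean(mins[is.finite(mins)])
}

oracle_shortest <- function(targets, genes, g) {
  d <- oracle_dist_matrix(g, targets, genes)
  mean(d[is.finite(d)])
}

oracle_kernel <- function(targets, genes, g) {
  d <- oracle_dist_matrix(g, targets, genes)
  inner <- numeric(0)
  for (j in seq_along(genes)) {
    s <- 0
    for (i in seq_along(targets)) {
      if (is.finite(d[i, j])) s <- s + exp(-(d[i, j] + 1))
    }
    inner <- c(inner, s / length(targets))
  }
  inner <- inner[inner > 0]
  -sum(log(inner)) / length(inner)
}

oracle_centre <- function(targets, genes, g) {
  adj <- adjacency_list(g)
  genes <- sort(genes)
  if (length(genes) == 1L) {
    centre <- genes
  } else {
    clo <- vapply(genes, function(gn) {
      dd <- oracle_bfs(adj, gn)
      reach <- dd[is.finite(dd) & dd > 0]
      if (length(reach) == 0L) return(0)
      length(reach) / sum(reach)
    }, numeric(1))
    centre <- genes[which.max(clo)]
  }
  d <- oracle_dist_matrix(g, targets, centre)
  mean(d[is.finite(d)])
}

oracle_separation <- function(targets, genes, g) {
  d <- oracle_dist_matrix(g, targets, genes)
  between <- c(apply(d, 1L, function(r) min(r[is.finite(r)], Inf)),
               apply(d, 2L, function(r) min(r[is.finite(r)], Inf)))
  between <- mean(between[is.finite(between)])
  within <- function(set) {
    if (length(set) <= 1L) return(0)
    dd <- oracle_dist_matrix(g, set, set)
    diag(dd) <- Inf
    mins <- apply(dd, 1L, function(r) min(r[is.finite(r)], Inf))
    mins <- mins[is.finite(mins)]
    if (length(mins) == 0L) return(0)
    mean(mins)
  }
  between - (within(targets) + within(genes)) / 2
}

oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# One-sided (enrichment) hypergeometric tail by explicit log-binomial sums.
oracle_fisher_tail <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  k_col <- n11 + n01
  k_row <- n11 + n10
  ks <- n11:min(k_row, k_col)
  sum(exp(lchoose(k_row, ks) + lchoose(n - k_row, k_col - ks) -
            lchoose(n, k_col)))
}

# Exact two-sided Mann-Whitney p by bitmask enumeration of all subsets of
# size nx, P(|U - mu| >= |u_obs - mu|) over pooled midranks.
oracle_mwu_exact <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * length(y) / 2
  hits <- 0
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) != nx) next
    u <- sum(r[bits == 1L]) - nx * (nx + 1) / 2
    total <- total + 1
    if (abs(u - mu) >= abs(u_obs - mu) - 1e-9) hits <- hits + 1
  }
  hits / total
}

oracle_char_ngrams <- function(word, n_min, n_max) {
  chars <- c("<", strsplit(word, "")[[1]], ">")
  out <- character(0)
  for (n in n_min:n_max) {
    if (n > length(chars)) next
    for (s in 1:(length(chars) - n + 1)) {
      out <- c(out, paste(chars[s:(s + n - 1)], collapse = ""))
    }
  }
  out
}

# Random named test graph; node/edge sets drawn from an Erdos-Renyi model.
random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  g
}

giant_component_nodes <- function(g) {
  comp <- igraph::components(g)
  igraph::V(g)$name[comp$membership == which.max(comp$csize)]
}

small_fixture_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_nodes = 120L, n_compounds = 60L, module_size = 8L,
         targets_per_compound = 6L, seed = seed),
    list(...)
  )
  do.call(fixture_config, args)
}
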