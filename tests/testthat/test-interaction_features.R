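path_graph <- function(...) {
  nodes <- c(...)
  g <- igraph::make_graph(rep(nodes, each = 2)[-c(1, 2 * length(nodes))],
                          directed = FALSE)
  g
}

test_that("adjacency normalization makes nonzero columns stochastic", {
  g <- path_graph("a", "b", "c")
  w <- normalize_adjacency(g)
  expect_equal(as.numeric(w[, "b"]), c(0.5, 0, 0.5))
  expect_equal(Matrix::colSums(w), c(a = 1, b = 1, c = 1))

  iso <- igraph::add_vertices(g, 1, name = "lonely")
  w2 <- normalize_adjacency(iso)
  expect_equal(sum(w2[, "lonely"]), 0)

  g3 <- random_test_graph(50, 0.1, seed = 8)
  w3 <- normalize_adjacency(g3)
  cs <- Matrix::colSums(w3)
  deg <- igraph::degree(g3)
  expect_equal(unname(cs[deg > 0]), rep(1, sum(deg > 0)), tolerance = 1e-12)
})

test_that("seed vectors weight direct and indirect targets 10:3", {
  nodes <- c("p1", "p2", "p3")
  p_single <- build_seed_vector(compound_profile("c", direct = "p1"), nodes)
  expect_equal(unname(p_single), c(1, 0, 0), ignore_attr = TRUE)

  p_mix <- build_seed_vector(
    compound_profile("c", direct = "p1", indirect = "p2"), nodes)
  expect_equal(unname(p_mix), c(1 / 1.3, 0.3 / 1.3, 0), tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(build_seed_vector(compound_profile("c", direct = "zz"), nodes),
               "empty seed")

  set.seed(12)
  for (i in 1:10) {
    pr <- compound_profile("c", direct = sample(nodes, 2),
                           indirect = sample(nodes, 1))
    p0 <- build_seed_vector(pr, nodes)
    expect_equal(sum(p0), 1, tolerance = 1e-12)
  }
  unmapped <- build_seed_vector(
    compound_profile("c", direct = c("p1", "zz")), nodes)
  expect_equal(attr(unmapped, "n_unmapped"), 1L)
})

test_that("a single node with a self-loop is a fixed point of the walk", {
  g <- igraph::make_graph(c(1, 1), directed = FALSE)
  igraph::V(g)$name <- "a"
  w <- normalize_adjacency(g)
  res <- rwr(w, c(a = 1), r = 0.7)
  expect_equal(unname(res$p), 1)
  expect_equal(res$iterations, 1L)
})

test_that("the iterative walk equals the closed-form linear solve", {
  for (s in 1:15) {
    set.seed(s)
    n <- sample(10:80, 1)
    g <- random_test_graph(n, runif(1, 0.05, 0.3), seed = s)
    w <- normalize_adjacency(g)
    p0 <- numeric(n)
    p0[sample(n, 3)] <- c(0.5, 0.3, 0.2)
    names(p0) <- colnames(w)
    r <- runif(1, 0.3, 0.9)
    res <- rwr(w, p0, r = r)
    closed <- solve(diag(n) - (1 - r) * t(as.matrix(w)), r * p0)
    expect_lt(max(abs(res$p - closed)), 1e-6)
    expect_true(all(res$p >= 0 & res$p <= 1))
  }
})

test_that("a two-node walk matches hand elimination", {
  g <- path_graph("a", "b")
  w <- normalize_adjacency(g)
  res <- rwr(w, c(a = 1, b = 0), r = 0.7)
  # p_a = 0.3 p_b + 0.7 ; p_b = 0.3 p_a  =>  p_a = 0.7/0.91, p_b = 0.21/0.91
  expect_equal(unname(res$p), c(0.7, 0.21) / 0.91, tolerance = 1e-7)
})

test_that("walk iteration count weakly decreases with restart probability", {
  g <- random_test_graph(60, 0.1, seed = 77)
  w <- normalize_adjacency(g)
  p0 <- stats::setNames(numeric(60), colnames(w))
  p0[1:2] <- 0.5
  iters <- vapply(c(0.3, 0.5, 0.7, 0.9), function(r) {
    rwr(w, p0, r = r)$iterations
  }, numeric(1))
  expect_true(all(diff(iters) <= 0))
})

test_that("disease scores are indexed sums of the probability vector", {
  g <- random_test_graph(40, 0.15, seed = 5)
  w <- normalize_adjacency(g)
  p0 <- stats::setNames(numeric(40), colnames(w))
  p0[4] <- 1
  p <- rwr(w, p0)$p
  expect_equal(disease_score(p, names(p)), sum(p))
  set.seed(6)
  genes <- sample(names(p), 7)
  expect_equal(disease_score(p, genes), sum(p[genes]))
  expect_equal(disease_score(p, c("nope", "nada")), 0)
})

test_that("reduction keeps the smallest component count reaching the threshold", {
  set.seed(41)
  basis <- qr.Q(qr(matrix(rnorm(100), 10)))[, 1:2]
  x <- cbind(rnorm(40), 0.9 * rnorm(40)) %*% t(basis)
  model <- fit_reduction(x, threshold = 0.8)
  expect_equal(model$n_components, 2L)

  full <- fit_reduction(x + matrix(rnorm(400, sd = 0.05), 40), threshold = 1.0)
  expect_equal(full$n_components, 10L)

  # orthonormality of the retained basis
  ip <- crossprod(model$components)
  expect_equal(ip, diag(2), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("discarded variance equals the eigenvalue tail", {
  set.seed(42)
  x <- matrix(rnorm(30 * 8), 30) %*% diag(c(4, 3, 2, 1, 0.5, 0.3, 0.2, 0.1))
  model <- fit_reduction(x, threshold = 0.8)
  k <- model$n_components
  scores <- apply_reduction(model, x)
  recon <- sweep(scores %*% t(model$components), 2L, model$center, "+")
  err <- sum((x - recon)^2)
  lambda <- eigen(stats::cov(x), symmetric = TRUE)$values
  expect_equal(err, sum(lambda[(k + 1):8]) * (nrow(x) - 1), tolerance = 1e-8)

  # training-row scores reproduce the stored variance ratios
  ratios <- apply(scores, 2L, stats::var)
  ratios <- ratios / (sum(eigen(stats::cov(x))$values))
  expect_equal(unname(ratios), unname(model$explained_variance_ratio),
               tolerance = 1e-8)
})

test_that("proximity measures match hand-checked path and star graphs", {
  g <- path_graph("a", "b", "c")
  expect_equal(proximity_closest("a", "c", g), 2)
  expect_equal(proximity_closest(c("a", "b"), c("a", "b"), g), 0)
  expect_equal(proximity_shortest("a", "c", g), 2)
  expect_equal(proximity_shortest(c("a", "c"), "b", g), 1)
  # singleton kernel: same node -> 1, distance 2 -> 3
  expect_equal(proximity_kernel("a", "a", g), 1)
  expect_equal(proximity_kernel("a", "c", g), 3)
  expect_equal(proximity_separation("a", "c", g), 2)
  expect_lte(proximity_separation(c("a", "b"), c("a", "b"), g), 0)

  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:4))
  expect_equal(proximity_centre("leaf1", c("hub", "leaf2"), star), 1)
  expect_equal(proximity_centre(c("leaf1", "leaf2"), "leaf3", star), 2)
})

test_that("proximity measures equal BFS brute-force oracles on random graphs", {
  n_checked <- 0L
  for (s in 1:25) {
    g <- random_test_graph(sample(10:30, 1), runif(1, 0.1, 0.35), seed = 600 + s)
    comp <- giant_component_nodes(g)
    if (length(comp) < 6) next
    set.seed(s)
    targets <- sample(comp, sample(2:4, 1))
    genes <- sample(comp, sample(2:4, 1))
    expect_equal(proximity_closest(targets, genes, g),
                 oracle_closest(targets, genes, g), tolerance = 1e-12)
    expect_equal(proximity_shortest(targets, genes, g),
                 oracle_shortest(targets, genes, g), tolerance = 1e-12)
    expect_equal(proximity_kernel(targets, genes, g),
                 oracle_kernel(targets, genes, g), tolerance = 1e-12)
    expect_equal(proximity_centre(targets, genes, g),
                 oracle_centre(targets, genes, g), tolerance = 1e-12)
    expect_equal(proximity_separation(targets, genes, g),
                 oracle_separation(targets, genes, g), tolerance = 1e-12)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 15L)
})

test_that("unreachable sets raise errors and partial reachability is excluded", {
  g <- igraph::make_graph(c("a", "b", "c", "d"), directed = FALSE)
  expect_error(proximity_closest("a", "zz", g), "does not intersect")
  expect_error(proximity_closest("a", "c", g), "no finite path")
  # gene d unreachable from a: kernel warns and uses the reachable gene only
  expect_warning(k <- proximity_kernel("a", c("b", "c"), g), "unreachable")
  expect_equal(k, 2)
})

test_that("propagation scores recover the planted compound-disease signal", {
  cfg <- fixture_config(noise_rate = 0, seed = 1L)  # 300-node default fixture
  fix <- generate_fixture(cfg)
  tab <- proximity_auroc(fix$profiles, fix$modules, fix$labels, "rwr",
                         fix$network)
  expect_true(all(tab$auroc > 0.8))

  # permuted labels sit near chance
  set.seed(90)
  perm <- fix$labels[sample(nrow(fix$labels)), ]
  rownames(perm) <- rownames(fix$labels)
  tab_null <- proximity_auroc(fix$profiles, fix$modules, perm, "rwr",
                              fix$network)
  expect_true(all(abs(tab_null$auroc - 0.5) < 0.25))

  # distance-based scoring runs end to end and beats chance on average
  tab_cl <- proximity_auroc(fix$profiles, fix$modules, fix$labels, "closest",
                            fix$network)
  expect_gt(mean(tab_cl$auroc), 0.5)
})

test_that("perfectly separated scores give AUROC 1", {
  y <- rep(c(1, 0), each = 10)
  expect_equal(auroc(c(rnorm(10, 10), rnorm(10, -10)), y), 1.0)
})
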