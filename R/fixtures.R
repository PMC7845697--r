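#' Fixture configuration
#'
#' Study conditions for the synthetic benchmark: a scale-free-like
#' protein-protein interaction network with planted disease modules,
#' compounds whose targets concentrate near (positives) or are spread
#' uniformly over (negatives) a disease module, descriptor tables with
#' class-conditional location shifts and an embedding table whose group
#' structure follows the planted disease assignment. The defaults describe a
#' 300-node network with 3 diseases and 150 compounds, a recoverable but
#' non-trivial signal.
#'
#' @param n_nodes Network size (default 300).
#' @param edges_per_node Preferential-attachment edges added per new node
#'   (default 2, giving mean degree close to 4).
#' @param n_diseases Number of planted disease modules (default 3).
#' @param module_size Genes per disease module (default 15).
#' @param n_compounds Number of simulated compounds (default 150).
#' @param targets_per_compound Targets drawn per compound (default 8).
#' @param positive_fraction Fraction of compounds given a true indication
#'   (default 0.5).
#' @param noise_rate Probability of flipping each label cell (default 0).
#' @param delta Class-conditional mean shift of numeric descriptors, in SD
#'   units (default 1).
#' @param embedding_dim Dimensionality of the fixture embedding table
#'   (default 50).
#' @param embedding_noise_sd Isotropic noise around group centroids
#'   (default 0.4).
#' @param seed Integer seed; every generator is a pure function of the
#'   config, so reruns are bit-identical.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_nodes = 300L, edges_per_node = 2L,
                           n_diseases = 3L, module_size = 15L,
                           n_compounds = 150L, targets_per_compound = 8L,
                           positive_fraction = 0.5, noise_rate = 0,
                           delta = 1, embedding_dim = 50L,
                           embedding_noise_sd = 0.4, seed = 1L) {
  stopifnot(n_nodes >= 10L, edges_per_node >= 1L, module_size >= 3L,
            module_size < n_nodes, n_diseases >= 1L, n_compounds >= 1L,
            targets_per_compound >= 1L,
            positive_fraction >= 0, positive_fraction <= 1,
            noise_rate >= 0, noise_rate <= 0.5)
  structure(as.list(environment()), class = "fixture_config")
}

# Offset the run seed per generator so each one is independently a pure
# function of the config (regenerating artifact 3 never disturbs artifact 2).
fixture_seed <- function(config, offset) {
  set.seed((as.integer(config$seed) %% 1000000L) * 101L + offset)
}

#' Generate a scale-free-like network
#'
#' Grows a connected, undirected, simple graph by preferential attachment
#' (Barabasi-Albert growth), mimicking the heavy-tailed degree distribution
#' of real protein-protein interaction networks. Vertices are named
#' `g0001, g0002, ...`.
#'
#' @param config A [fixture_config()].
#' @return An igraph graph with `config$n_nodes` vertices.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  fixture_seed(config, 1L)
  g <- igraph::sample_pa(config$n_nodes, power = 1,
                         m = config$edges_per_node, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("g%04d", seq_len(config$n_nodes))
  g
}

#' Plant disease modules on a network
#'
#' Each disease module is a connected induced subgraph: a breadth-first ball
#' of `module_size` vertices grown around a randomly chosen root. Modules of
#' different diseases may overlap, as real disease-gene sets do.
#'
#' @param network An igraph graph with named vertices.
#' @param config A [fixture_config()].
#' @return Named list (`D01`, `D02`, ...) of gene-id character vectors.
#' @export
plant_disease_modules <- function(network, config) {
  stopifnot(config$module_size >= 3L)
  fixture_seed(config, 2L)
  nodes <- igraph::V(network)$name
  roots <- sample(nodes, config$n_diseases)
  modules <- lapply(roots, function(root) {
    ord <- igraph::bfs(network, root = root, order = TRUE)$order
    igraph::V(network)$name[ord[seq_len(config$module_size)]]
  })
  names(modules) <- sprintf("D%02d", seq_along(modules))
  modules
}

#' Generate compound profiles with a planted disease signal
#'
#' A `positive_fraction` share of compounds receives a true indication,
#' assigned round-robin over the diseases. A positive compound draws half of
#' its targets (rounded up) from its disease module itself and the rest
#' uniformly; negatives draw all targets uniformly. (Sampling from the
#' module rather than its distance-1 neighbourhood keeps the planted signal
#' sharp: in a scale-free network the neighbourhood of a module that touches
#' a hub can cover much of the graph.)
#' Roughly 70% of the drawn targets are annotated as direct binding and the
#' rest as indirect. After assignment, every label cell is independently
#' flipped with probability `noise_rate`.
#'
#' @param network An igraph graph with named vertices.
#' @param modules Disease modules from [plant_disease_modules()].
#' @param config A [fixture_config()].
#' @return List with `profiles` (named list of [compound_profile()]),
#'   `labels` (binary compound-by-disease matrix, post-flip) and
#'   `assignment` (planted disease id per compound, `NA` for negatives).
#' @export
generate_compounds_with_signal <- function(network, modules, config) {
  stopifnot(config$targets_per_compound >= 1L)
  fixture_seed(config, 3L)
  nodes <- igraph::V(network)$name
  n <- config$n_compounds
  tpc <- config$targets_per_compound
  ids <- sprintf("cmpd%04d", seq_len(n))
  n_pos <- round(n * config$positive_fraction)
  assignment <- rep(NA_character_, n)
  if (n_pos > 0) {
    assignment[seq_len(n_pos)] <- rep(names(modules), length.out = n_pos)
  }
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(assignment[i])) {
      near <- modules[[assignment[i]]]
      n_near <- min(ceiling(tpc / 2), length(near))
      t_near <- sample(near, n_near)
      t_far <- sample(setdiff(nodes, t_near), tpc - n_near)
      targets <- c(t_near, t_far)
    } else {
      targets <- sample(nodes, min(tpc, length(nodes)))
    }
    is_direct <- stats::runif(length(targets)) < 0.7
    if (!any(is_direct)) is_direct[1] <- TRUE
    profiles[[i]] <- compound_profile(ids[i],
                                      direct = targets[is_direct],
                                      indirect = targets[!is_direct])
  }
  names(profiles) <- ids
  labels <- matrix(0L, nrow = n, ncol = length(modules),
                   dimnames = list(ids, names(modules)))
  pos <- which(!is.na(assignment))
  labels[cbind(pos, match(assignment[pos], colnames(labels)))] <- 1L
  if (config$noise_rate > 0) {
    flip <- matrix(stats::runif(length(labels)) < config$noise_rate,
                   nrow = nrow(labels))
    labels[flip] <- 1L - labels[flip]
  }
  list(profiles = profiles, labels = labels, assignment = assignment)
}

#' Fixture descriptor schema
#'
#' A reduced descriptor schema used by the synthetic generator: five Z-scored
#' physicochemical columns, three log-scale passthrough columns and two
#' binary categorical pharmacokinetics flags (encoded width 12). The shape
#' matches what the chemical-feature reader and encoder expect, at a scale
#' proportionate to the fixture.
#'
#' @return A `descriptor_schema` (see [descriptor_schema()]).
#' @export
fixture_descriptor_schema <- function() {
  descriptor_schema(
    zscore = c("mw", "heavy_atoms", "fraction_csp3", "rotatable_bonds", "hba"),
    passthrough = c("xlogp", "esol_logs", "log_kp"),
    categorical = list(bbb_permeant = c("No", "Yes"),
                       pgp_substrate = c("No", "Yes"))
  )
}

#' Generate a class-conditional descriptor table
#'
#' Numeric descriptors are drawn from class-conditional Gaussians: compounds
#' carrying at least one positive label have their means shifted by
#' `config$delta` standard deviations. Categorical descriptors are drawn
#' from class-conditional multinomials (positives are likelier to be flagged
#' `"Yes"`).
#'
#' @param labels Binary label matrix (rownames are compound ids).
#' @param config A [fixture_config()].
#' @param schema Descriptor schema (default [fixture_descriptor_schema()]).
#' @return `data.frame` with an `id` column followed by schema columns.
#' @export
generate_descriptor_table <- function(labels, config,
                                      schema = fixture_descriptor_schema()) {
  fixture_seed(config, 4L)
  ids <- rownames(labels)
  n <- length(ids)
  cls <- as.integer(rowSums(labels) > 0)
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (schema$kind[i] %in% c("zscore", "passthrough")) {
      out[[nm]] <- stats::rnorm(n, mean = config$delta * cls, sd = 1)
    } else {
      cats <- schema$categories[[i]]
      p_yes <- ifelse(cls == 1, 0.5 + 0.2 * min(config$delta, 2) / 2, 0.5)
      pick <- ifelse(stats::runif(n) < p_yes, cats[length(cats)], cats[1])
      out[[nm]] <- pick
    }
  }
  out
}

#' Generate a grouped embedding table
#'
#' Each name's vector is its group centroid plus isotropic Gaussian noise,
#' emulating a pre-trained embedding space in which related compounds
#' cluster. Group membership defaults to a round-robin assignment over
#' `n_groups`; pass `groups` to align the structure with, say, a planted
#' disease assignment.
#'
#' @param names Character vector of compound names (stored lowercased).
#' @param n_groups Number of centroids (ignored when `groups` is given).
#' @param dim Embedding dimensionality.
#' @param seed Integer seed.
#' @param groups Optional group label per name (`NA` allowed; `NA` names get
#'   their own shared background centroid).
#' @param noise_sd Isotropic noise SD around centroids (default 0.4).
#' @return A `vector_table` (see [read_vector_table()]) with attribute
#'   `groups`.
#' @export
generate_embedding_table <- function(names, n_groups = 3L, dim = 50L,
                                     seed = 1L, groups = NULL,
                                     noise_sd = 0.4) {
  set.seed(as.integer(seed) %% 1000000L * 101L + 5L)
  tokens <- tolower(names)
  if (is.null(groups)) {
    groups <- rep(seq_len(n_groups), length.out = length(tokens))
  }
  groups <- as.character(groups)
  groups[is.na(groups)] <- ".background"
  glev <- sort(unique(groups))
  centroids <- matrix(stats::rnorm(length(glev) * dim), nrow = length(glev),
                      dimnames = list(glev, NULL))
  entries <- centroids[groups, , drop = FALSE] +
    matrix(stats::rnorm(length(tokens) * dim, sd = noise_sd),
           nrow = length(tokens))
  rownames(entries) <- tokens
  tab <- vector_table(entries)
  attr(tab, "groups") <- stats::setNames(groups, tokens)
  tab
}

#' Generate the full synthetic study
#'
#' Runs every fixture generator in order and returns all artifacts. A thin
#' wrapper used by the end-to-end pipeline, the command-line `simulate`
#' entry point and the test suite.
#'
#' @param config A [fixture_config()].
#' @return List with `config`, `network`, `modules`, `profiles`, `labels`,
#'   `assignment`, `descriptors`, `embedding`.
#' @export
generate_fixture <- function(config = fixture_config()) {
  network <- generate_network(config)
  modules <- plant_disease_modules(network, config)
  cps <- generate_compounds_with_signal(network, modules, config)
  descriptors <- generate_descriptor_table(cps$labels, config)
  embedding <- generate_embedding_table(
    names(cps$profiles), dim = config$embedding_dim, seed = config$seed,
    groups = cps$assignment, noise_sd = config$embedding_noise_sd
  )
  list(config = config, network = network, modules = modules,
       profiles = cps$profiles, labels = cps$labels,
       assignment = cps$assignment, descriptors = descriptors,
       embedding = embedding)
}

#' Write all fixture artifacts to a directory
#'
#' Writes `ppi.tsv` (edge list), `targets.tsv`, `disease_genes.tsv`,
#' `labels.tsv` (drug/disease pairs), `descriptors.csv` and `embedding.vec`
#' (word2vec text dialect), all in the formats the package readers consume.
#'
#' @param fixture Output of [generate_fixture()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_edge_list(fixture$network, file.path(dir, "ppi.tsv"))
  write_targets(fixture$profiles, file.path(dir, "targets.tsv"))
  write_disease_genes(fixture$modules, file.path(dir, "disease_genes.tsv"))
  lab <- fixture$labels
  pairs <- which(lab == 1L, arr.ind = TRUE)
  write_label_pairs(
    data.frame(drug_id = rownames(lab)[pairs[, 1]],
               mesh_id = colnames(lab)[pairs[, 2]],
               stringsAsFactors = FALSE),
    file.path(dir, "labels.tsv")
  )
  utils::write.csv(fixture$descriptors, file.path(dir, "descriptors.csv"),
                   row.names = FALSE, quote = FALSE)
  write_vector_table(fixture$embedding, file.path(dir, "embedding.vec"))
  invisible(dir)
}
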