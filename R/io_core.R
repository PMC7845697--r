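#' Compound profile
#'
#' A compound (drug or natural compound) together with its molecular target
#' annotation. Targets are split into *direct* binding (physical targets) and
#' *indirect* binding (downstream molecular effects such as expression changes
#' or active-metabolite action). A protein annotated both ways is kept as
#' direct only: direct evidence is the stronger claim.
#'
#' @param id Compound identifier (single string).
#' @param direct Character vector of directly bound protein identifiers.
#' @param indirect Character vector of indirectly affected protein identifiers.
#' @param name Free-text compound name (used for latent-knowledge features).
#' @param descriptors Optional named list of descriptor values.
#'
#' @return An object of class `compound_profile`: a list with elements
#'   `id`, `direct`, `indirect` (disjoint character vectors), `name` and
#'   `descriptors`.
#' @export
#' @examples
#' compound_profile("c1", direct = "p1", indirect = c("p1", "p2"))
compound_profile <- function(id, direct = character(), indirect = character(),
                             name = id, descriptors = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  direct <- unique(as.character(direct))
  indirect <- setdiff(unique(as.character(indirect)), direct)
  structure(
    list(id = id, direct = direct, indirect = indirect,
         name = name, descriptors = descriptors),
    class = "compound_profile"
  )
}

#' @export
print.compound_profile <- function(x, ...) {
  cat(sprintf("<compound_profile> %s: %d direct, %d indirect target(s)\n",
              x$id, length(x$direct), length(x$indirect)))
  invisible(x)
}

#' All targets of a profile
#'
#' @param profile A [compound_profile()].
#' @return Character vector, union of direct and indirect targets.
#' @export
profile_targets <- function(profile) {
  union(profile$direct, profile$indirect)
}

read_table_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read an undirected edge list
#'
#' Reads a whitespace/tab-separated two-column edge list (the usual exchange
#' format for protein-protein interaction networks). Lines starting with `#`
#' are comments. Self-loops are dropped and duplicate edges (in either
#' orientation) are collapsed; the node set is the union of all endpoints,
#' so a node appearing only in a self-loop is retained as an isolated node.
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple [igraph::graph] with named vertices.
#' @export
read_edge_list <- function(path) {
  tl <- read_table_lines(path)
  if (length(tl$lines) == 0L) stop("no edges in '", path, "'")
  parts <- strsplit(tl$lines, "\\s+")
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad)) {
    stop(sprintf("malformed edge on line %d of '%s': need at least 2 tokens",
                 tl$lineno[bad[1]], path))
  }
  from <- vapply(parts, `[[`, character(1), 1L)
  to <- vapply(parts, `[[`, character(1), 2L)
  nodes <- sort(unique(c(from, to)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = nodes
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write an edge list
#'
#' @param network An igraph graph with named vertices.
#' @param path Output path (tab-separated, no header).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  el <- igraph::as_edgelist(network, names = TRUE)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a compound target table
#'
#' Reads a three-column tab-separated table (`compound_id`, `protein_id`,
#' `type`) with a header row; `type` must be `"direct"` or `"indirect"`.
#' A protein listed as both direct and indirect for the same compound is kept
#' as direct only.
#'
#' @param path Path to the target table.
#' @return Named list of [compound_profile()] objects, keyed by compound id.
#' @export
read_targets <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 3L) {
    stop("target table '", path, "' must have 3 columns (compound, protein, type)")
  }
  tab <- tab[, 1:3]
  names(tab) <- c("compound_id", "protein_id", "type")
  incomplete <- which(!stats::complete.cases(tab) |
                        tab$compound_id == "" | tab$protein_id == "")
  if (length(incomplete)) {
    stop(sprintf("missing field in target table row %d", incomplete[1]))
  }
  badtype <- which(!tab$type %in% c("direct", "indirect"))
  if (length(badtype)) {
    stop(sprintf("unknown binding type '%s' in row %d (expected direct/indirect)",
                 tab$type[badtype[1]], badtype[1]))
  }
  ids <- unique(tab$compound_id)
  profiles <- lapply(ids, function(cid) {
    sub <- tab[tab$compound_id == cid, ]
    compound_profile(
      cid,
      direct = sub$protein_id[sub$type == "direct"],
      indirect = sub$protein_id[sub$type == "indirect"]
    )
  })
  names(profiles) <- ids
  profiles
}

#' Write a compound target table
#'
#' @param profiles Named list of [compound_profile()] objects.
#' @param path Output path (tab-separated with header).
#' @return `path`, invisibly.
#' @export
write_targets <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(
      compound_id = p$id,
      protein_id = c(p$direct, p$indirect),
      type = rep(c("direct", "indirect"), c(length(p$direct), length(p$indirect))),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep compounds with enough target information
#'
#' Compounds with sparse target annotation carry too little signal for
#' network propagation; the screening pipeline keeps only compounds with at
#' least `k` annotated targets (direct or indirect), by default five.
#'
#' @param profiles Named list of [compound_profile()] objects.
#' @param k Minimum number of distinct targets (default 5).
#' @return The filtered list, original order preserved.
#' @export
filter_min_targets <- function(profiles, k = 5L) {
  stopifnot(k >= 1L)
  keep <- vapply(profiles, function(p) length(profile_targets(p)) >= k, logical(1))
  profiles[keep]
}

#' Read drug-to-disease indication pairs
#'
#' Two-column tab-separated table with a header row: one row per
#' (drug id, disease id) pair, disease ids typically MeSH identifiers.
#'
#' @param path Path to the pair table.
#' @return `data.frame` with columns `drug_id`, `mesh_id`.
#' @export
read_label_pairs <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2L) stop("label pair table '", path, "' must have 2 columns")
  tab <- tab[, 1:2]
  names(tab) <- c("drug_id", "mesh_id")
  tab
}

#' Write drug-to-disease indication pairs
#' @param mapping `data.frame` with columns `drug_id`, `mesh_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_pairs <- function(mapping, path) {
  utils::write.table(mapping[, c("drug_id", "mesh_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a binary label matrix from indication pairs
#'
#' Selects the `n_diseases` disease identifiers mapped to the largest number
#' of distinct drugs (ties broken lexicographically by id, so the selection
#' is deterministic) and builds a binary drug-by-disease matrix. The default
#' of 15 diseases matches the standard top-15 most frequent indication terms
#' used for model training.
#'
#' @param mapping `data.frame` with columns `drug_id`, `mesh_id`.
#' @param n_diseases Number of most frequent disease ids to keep (default 15).
#' @return Binary matrix with drug ids as rownames (sorted) and the selected
#'   disease ids as colnames, ordered from most to least frequent.
#' @export
build_label_matrix <- function(mapping, n_diseases = 15L) {
  stopifnot(nrow(mapping) > 0L)
  pairs <- unique(mapping[, c("drug_id", "mesh_id")])
  counts <- table(pairs$mesh_id)
  if (n_diseases > length(counts)) {
    stop(sprintf("n_diseases = %d exceeds the %d distinct disease ids",
                 n_diseases, length(counts)))
  }
  ord <- order(-as.integer(counts), names(counts))
  diseases <- names(counts)[ord][seq_len(n_diseases)]
  drugs <- sort(unique(pairs$drug_id))
  m <- matrix(0L, nrow = length(drugs), ncol = length(diseases),
              dimnames = list(drugs, diseases))
  sel <- pairs[pairs$mesh_id %in% diseases, ]
  m[cbind(match(sel$drug_id, drugs), match(sel$mesh_id, diseases))] <- 1L
  m
}

#' Default feature-block widths
#'
#' The full-scale model input is a 686-column matrix: 300 latent-knowledge
#' columns (pre-trained sub-word embedding dimensionality), 285
#' molecular-interaction columns (principal components retained at the 0.8
#' cumulative-variance threshold) and 101 chemical-property columns (the
#' encoded descriptor schema).
#'
#' @return Named integer vector `c(latent, interaction, chemical)`.
#' @export
default_block_widths <- function() {
  c(latent = 300L, interaction = 285L, chemical = 101L)
}

block_order <- function(nms) {
  canonical <- c("latent", "interaction", "chemical")
  c(intersect(canonical, nms), setdiff(nms, canonical))
}

#' Assemble named feature blocks into one model input matrix
#'
#' Concatenates feature blocks column-wise in the fixed order latent,
#' interaction, chemical (any further blocks follow in their given order).
#' All blocks must cover the same row ids and contain no missing values.
#'
#' @param blocks Named list of numeric matrices with rownames.
#' @param row_ids Optional row ordering; defaults to the first block's rows.
#' @return A `feature_matrix`: numeric matrix with attribute `block_spans`,
#'   a named integer vector of block widths in column order.
#' @export
assemble_features <- function(blocks, row_ids = NULL) {
  stopifnot(is.list(blocks), length(blocks) > 0L, !is.null(names(blocks)))
  blocks <- blocks[block_order(names(blocks))]
  if (is.null(row_ids)) row_ids <- rownames(blocks[[1]])
  if (is.null(row_ids)) stop("blocks must have rownames or row_ids must be given")
  for (nm in names(blocks)) {
    missing_ids <- setdiff(row_ids, rownames(blocks[[nm]]))
    if (length(missing_ids)) {
      stop(sprintf("block '%s' is missing rows: %s", nm,
                   paste(utils::head(missing_ids, 5L), collapse = ", ")))
    }
    if (anyNA(blocks[[nm]])) stop(sprintf("block '%s' contains missing values", nm))
  }
  mats <- lapply(blocks, function(b) b[row_ids, , drop = FALSE])
  values <- do.call(cbind, mats)
  rownames(values) <- row_ids
  spans <- vapply(mats, ncol, integer(1))
  colnames(values) <- unlist(lapply(names(mats), function(nm) {
    cn <- colnames(mats[[nm]])
    if (is.null(cn)) cn <- seq_len(ncol(mats[[nm]]))
    paste(nm, cn, sep = ".")
  }), use.names = FALSE)
  structure(values, block_spans = spans, class = c("feature_matrix", "matrix"))
}

#' Extract one block from an assembled feature matrix
#'
#' @param features A `feature_matrix` from [assemble_features()].
#' @param name Block name.
#' @return Numeric matrix holding that block's columns (block-local names).
#' @export
feature_block <- function(features, name) {
  spans <- attr(features, "block_spans")
  if (is.null(spans)) stop("not an assembled feature matrix (no block_spans)")
  if (!name %in% names(spans)) {
    stop(sprintf("unknown block '%s' (have: %s)", name,
                 paste(names(spans), collapse = ", ")))
  }
  idx <- cumsum(spans)
  last <- idx[[name]]
  first <- last - spans[[name]] + 1L
  out <- features[, first:last, drop = FALSE]
  colnames(out) <- sub(paste0("^", name, "\\."), "", colnames(out))
  class(out) <- "matrix"
  out
}

#' Write an assembled feature matrix
#'
#' Writes the values as a CSV with an `id` column and the block layout as a
#' JSON sidecar (`<path>.blocks.json`).
#'
#' @param features A `feature_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  df <- data.frame(id = rownames(features), as.matrix(features),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  spans <- attr(features, "block_spans")
  jsonlite::write_json(as.list(spans), paste0(path, ".blocks.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read an assembled feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path (expects the `.blocks.json` sidecar next to it).
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$id
  spans <- unlist(jsonlite::read_json(paste0(path, ".blocks.json")))
  spans <- stats::setNames(as.integer(spans), names(spans))
  stopifnot(sum(spans) == ncol(values))
  structure(values, block_spans = spans, class = c("feature_matrix", "matrix"))
}
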