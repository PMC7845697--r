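split_counts <- function(n, ratios) {
  base <- floor(n * ratios / sum(ratios))
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * ratios / sum(ratios) - base
    extra <- order(-frac, seq_along(ratios))[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  base
}

#' Split ids into train/validation/test partitions
#'
#' Random (optionally label-stratified) partition in the given ratios; the
#' default 6:2:2 is the standard train/validate/test split for the
#' per-disease models. Deterministic under `seed`.
#'
#' @param ids Vector of ids to partition.
#' @param ratios Numeric ratios, one per partition (default `c(6, 2, 2)`).
#' @param seed Integer seed.
#' @param labels Optional label vector parallel to `ids`; when given, the
#'   split is stratified by label.
#' @return Object of class `split_plan`: list with `splits` (list of id
#'   vectors named `train`, `validation`, `test` for three ratios),
#'   `ratios`, `seed`.
#' @export
make_split <- function(ids, ratios = c(6, 2, 2), seed = 1L, labels = NULL) {
  stopifnot(length(ratios) >= 2L, all(ratios > 0))
  set.seed(seed)
  k <- length(ratios)
  parts <- rep(list(ids[0]), k)
  strata <- if (is.null(labels)) list(seq_along(ids)) else
    split(seq_along(ids), labels)
  for (idx in strata) {
    shuffled <- ids[idx][sample(length(idx))]
    counts <- split_counts(length(idx), ratios)
    at <- 0L
    for (j in seq_len(k)) {
      if (counts[j] > 0L) {
        parts[[j]] <- c(parts[[j]], shuffled[(at + 1L):(at + counts[j])])
      }
      at <- at + counts[j]
    }
  }
  names(parts) <- if (k == 3L) c("train", "validation", "test")
                  else paste0("part", seq_len(k))
  structure(list(splits = parts, ratios = ratios, seed = seed),
            class = "split_plan")
}

#' k-fold cross-validation assignment
#'
#' @param ids Vector of ids.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @param labels Optional labels for stratified folds.
#' @return Object of class `split_plan` with `splits` = list of k folds.
#' @export
make_kfold <- function(ids, k = 10L, seed = 1L, labels = NULL) {
  stopifnot(k >= 2L, k <= length(ids))
  set.seed(seed)
  folds <- rep(list(ids[0]), k)
  strata <- if (is.null(labels)) list(seq_along(ids)) else
    split(seq_along(ids), labels)
  offset <- 0L
  for (idx in strata) {
    shuffled <- ids[idx][sample(length(idx))]
    assign <- (seq_along(shuffled) + offset - 1L) %% k + 1L
    for (j in seq_len(k)) {
      folds[[j]] <- c(folds[[j]], shuffled[assign == j])
    }
    offset <- offset + length(shuffled)
  }
  names(folds) <- paste0("fold", seq_len(k))
  structure(list(splits = folds, ratios = rep(1, k), seed = seed),
            class = "split_plan")
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) formulation with midranks for tied scores:
#' the probability that a random positive outranks a random negative, with
#' ties counted one half.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  y <- as.integer(labels == 1)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("AUROC needs both classes present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification accuracy at a threshold
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels.
#' @param threshold Decision threshold (default 0.5); calls are
#'   `scores >= threshold`.
#' @return Fraction of correct calls in `[0, 1]`.
#' @export
accuracy <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  mean((scores >= threshold) == (labels == 1))
}

#' Mean and dispersion of a value list
#'
#' Arithmetic mean and sample standard deviation, plus the conventional
#' `"mean ± sd"` label formatted to three decimals for report tables.
#'
#' @param values Numeric vector.
#' @return List with `mean`, `sd` (0 for a constant list) and `label`.
#' @export
summarize_values <- function(values) {
  stopifnot(length(values) >= 1L)
  m <- mean(values)
  s <- if (length(values) > 1L) stats::sd(values) else 0
  list(mean = m, sd = s, label = sprintf("%.3f ± %.3f", m, s))
}

#' Top-, bottom- and randomly ranked prediction sets
#'
#' Ranks all (compound, disease) cells of a score matrix (ties broken by
#' compound id then disease id) and returns the top `fraction`, bottom
#' `fraction` and a size-matched random set drawn without replacement with
#' a fixed seed. When `2 * ceiling(fraction * N) > N` the bottom set is
#' truncated to keep the two sets disjoint.
#'
#' @param predictions Score matrix, compounds x diseases (dimnames needed).
#' @param fraction Fraction of cells per set (default 0.1).
#' @param seed Seed for the random set (default 1).
#' @return List of three `data.frame`s (`high`, `low`, `random`) with
#'   columns `compound`, `disease`, `score`.
#' @export
ranked_sets <- function(predictions, fraction = 0.1, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 0.5,
            !is.null(rownames(predictions)), !is.null(colnames(predictions)))
  cells <- data.frame(
    compound = rep(rownames(predictions), times = ncol(predictions)),
    disease = rep(colnames(predictions), each = nrow(predictions)),
    score = as.vector(predictions),
    stringsAsFactors = FALSE
  )
  ord <- order(-cells$score, cells$compound, cells$disease)
  cells <- cells[ord, ]
  n <- nrow(cells)
  n_take <- ceiling(fraction * n)
  high <- cells[seq_len(n_take), ]
  n_low <- min(n_take, n - n_take)
  low <- cells[(n - n_low + 1L):n, ]
  set.seed(seed)
  random <- cells[sample(n, n_take), ]
  rownames(high) <- rownames(low) <- rownames(random) <- NULL
  list(high = high, low = low, random = random)
}

#' Build a literature index from a document table
#'
#' Preprocesses each document with [preprocess_text()] and builds
#' term-to-document posting sets for single tokens; multi-token terms are
#' matched as exact contiguous token sequences at query time.
#'
#' @param docs `data.frame` with columns `doc_id`, `text` (the corpus
#'   exchange format: one document per row).
#' @return Object of class `literature_index`.
#' @export
literature_index <- function(docs) {
  stopifnot(all(c("doc_id", "text") %in% names(docs)))
  doc_tokens <- lapply(docs$text, preprocess_text)
  names(doc_tokens) <- docs$doc_id
  flat <- data.frame(
    token = unlist(doc_tokens, use.names = FALSE),
    doc = rep(docs$doc_id, lengths(doc_tokens)),
    stringsAsFactors = FALSE
  )
  postings <- lapply(split(flat$doc, flat$token), unique)
  structure(list(doc_tokens = doc_tokens, postings = postings,
                 n_docs = nrow(docs)),
            class = "literature_index")
}

#' Documents containing a term
#'
#' @param index A [literature_index()].
#' @param term Free-text term; preprocessed, then matched as an exact
#'   contiguous token sequence.
#' @return Character vector of document ids.
#' @export
term_postings <- function(index, term) {
  toks <- preprocess_text(term)
  if (length(toks) == 0L) return(character(0))
  hit <- lapply(toks, function(t) index$postings[[t]])
  if (any(vapply(hit, is.null, logical(1)))) return(character(0))
  cand <- Reduce(intersect, hit)
  if (length(toks) == 1L) return(cand)
  cand[vapply(cand, function(d) {
    dt <- index$doc_tokens[[d]]
    starts <- which(dt == toks[1])
    any(vapply(starts, function(s) {
      s + length(toks) - 1L <= length(dt) &&
        all(dt[s:(s + length(toks) - 1L)] == toks)
    }, logical(1)))
  }, logical(1))]
}

#' Co-occurrence count of a term pair
#'
#' Number of documents containing both terms.
#'
#' @param index A [literature_index()].
#' @param pair Character vector of two terms.
#' @return Integer count.
#' @export
cooccurrence <- function(index, pair) {
  stopifnot(length(pair) == 2L)
  length(intersect(term_postings(index, pair[1]), term_postings(index, pair[2])))
}

#' Jaccard index of a term pair
#'
#' Co-occurrence normalized by the union of the terms' document sets, which
#' removes the influence of raw term frequency; 0 when the union is empty.
#'
#' @param index A [literature_index()].
#' @param pair Character vector of two terms.
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard_index <- function(index, pair) {
  stopifnot(length(pair) == 2L)
  a <- term_postings(index, pair[1])
  b <- term_postings(index, pair[2])
  u <- union(a, b)
  if (length(u) == 0L) return(0)
  length(intersect(a, b)) / length(u)
}

#' One-sided Fisher's exact p-value of a 2x2 table
#'
#' Enrichment tail of the hypergeometric distribution:
#' `P(X >= n11)` for a table (both, first-only, second-only, neither).
#' Vectorized over table cells.
#'
#' @param n11 Documents containing both terms.
#' @param n10 Documents containing only the first term.
#' @param n01 Documents containing only the second term.
#' @param n00 Documents containing neither.
#' @return p-value(s) in `(0, 1]`.
#' @export
fisher_exact_p <- function(n11, n10, n01, n00) {
  if (any(n11 + n10 + n01 + n00 <= 0)) stop("empty contingency table")
  stats::phyper(n11 - 1, n11 + n10, n01 + n00, n11 + n01, lower.tail = FALSE)
}

#' Fisher's exact test of a term pair in a literature index
#'
#' Builds the 2x2 document contingency table of the pair and returns the
#' one-sided enrichment p-value. The conventional significance threshold
#' for calling a predicted pair literature-supported is 0.001.
#'
#' @param index A [literature_index()].
#' @param pair Character vector of two terms.
#' @return One-sided p-value.
#' @export
fisher_exact <- function(index, pair) {
  stopifnot(length(pair) == 2L)
  if (index$n_docs == 0L) stop("literature index contains no documents")
  a <- term_postings(index, pair[1])
  b <- term_postings(index, pair[2])
  n11 <- length(intersect(a, b))
  n10 <- length(setdiff(a, b))
  n01 <- length(setdiff(b, a))
  n00 <- index$n_docs - n11 - n10 - n01
  fisher_exact_p(n11, n10, n01, n00)
}

#' Mann-Whitney U test
#'
#' Two-sided test. For small samples (pooled n < 20) the p-value is
#' computed by exhaustive permutation enumeration over midranks,
#' `P(|U - n_x n_y / 2| >= |u_obs - n_x n_y / 2|)`, which handles ties
#' exactly; larger samples use the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param x,y Numeric samples.
#' @return List with `statistic` (U for `x`), `p.value` and `method`.
#' @export
mann_whitney <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  stopifnot(nx >= 1L, ny >= 1L)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = u, p.value = 1, method = "degenerate"))
  }
  if (nx + ny < 20L) {
    combs <- utils::combn(nx + ny, nx)
    u_all <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
    list(statistic = u, p.value = p, method = "exact enumeration")
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    list(statistic = u, p.value = p, method = "normal approximation")
  }
}

#' Literature-statistics validation report
#'
#' For the top-ranked, bottom-ranked and random prediction sets, reports the
#' mean and SD of the pairwise literature co-occurrence count, the mean
#' Jaccard index and the number of pairs significant under the one-sided
#' Fisher's exact test at the given threshold, plus pairwise Mann-Whitney U
#' p-values comparing the co-occurrence distributions of the three sets.
#' With an empty corpus all statistics are zero and the Fisher column is
#' skipped with a warning.
#'
#' @param predictions Score matrix, compounds x diseases.
#' @param index A [literature_index()]; terms are looked up as
#'   `"<compound> <disease>"` pairs using the matrix dimnames.
#' @param fraction Fraction of cells per set (default 0.1).
#' @param seed Seed for the random set (default 1).
#' @param fisher_threshold Significance threshold for `n_f` (default 0.001).
#' @return List with `summary` (one row per set), `mann_whitney`
#'   (three pairwise comparisons on co-occurrence counts) and `sets`.
#' @export
literature_report <- function(predictions, index, fraction = 0.1, seed = 1L,
                              fisher_threshold = 0.001) {
  sets <- ranked_sets(predictions, fraction = fraction, seed = seed)
  have_docs <- index$n_docs > 0L
  if (!have_docs) warning("empty corpus: Fisher's exact test skipped")
  per_set <- lapply(sets, function(s) {
    nc <- mapply(function(cmp, dz) cooccurrence(index, c(cmp, dz)),
                 s$compound, s$disease)
    ji <- mapply(function(cmp, dz) jaccard_index(index, c(cmp, dz)),
                 s$compound, s$disease)
    fp <- if (have_docs) {
      mapply(function(cmp, dz) fisher_exact(index, c(cmp, dz)),
             s$compound, s$disease)
    } else rep(NA_real_, nrow(s))
    list(nc = as.numeric(nc), ji = as.numeric(ji), fisher = as.numeric(fp))
  })
  summary <- do.call(rbind, lapply(names(per_set), function(nm) {
    ps <- per_set[[nm]]
    data.frame(set = nm,
               nc_mean = mean(ps$nc),
               nc_sd = if (length(ps$nc) > 1L) stats::sd(ps$nc) else 0,
               ji_mean = mean(ps$ji),
               n_f = if (have_docs) sum(ps$fisher < fisher_threshold)
                     else NA_integer_,
               n_pairs = length(ps$nc),
               stringsAsFactors = FALSE)
  }))
  comparisons <- list(c("high", "low"), c("high", "random"), c("low", "random"))
  mw <- do.call(rbind, lapply(comparisons, function(cp) {
    data.frame(comparison = paste(cp, collapse = " vs "),
               p_value = mann_whitney(per_set[[cp[1]]]$nc,
                                      per_set[[cp[2]]]$nc)$p.value,
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, mann_whitney = mw, sets = sets)
}
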