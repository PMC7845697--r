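#' Greek-letter transliteration table
#'
#' Mapping from Greek letters (lower- and upper-case, including final sigma)
#' to their alphabetic names, used during text preprocessing so that
#' compound names such as α-tocopherol normalize to "alpha-tocopherol".
#'
#' @return Named character vector: names are Greek characters, values their
#'   alphabetic names.
#' @export
greek_alphabet <- function() {
  lower <- c("α" = "alpha", "β" = "beta", "γ" = "gamma",
             "δ" = "delta", "ε" = "epsilon", "ζ" = "zeta",
             "η" = "eta", "θ" = "theta", "ι" = "iota",
             "κ" = "kappa", "λ" = "lambda", "μ" = "mu",
             "ν" = "nu", "ξ" = "xi", "ο" = "omicron",
             "π" = "pi", "ρ" = "rho", "ς" = "sigma",
             "σ" = "sigma", "τ" = "tau", "υ" = "upsilon",
             "φ" = "phi", "χ" = "chi", "ψ" = "psi",
             "ω" = "omega")
  upper_chars <- c("Α", "Β", "Γ", "Δ", "Ε",
                   "Ζ", "Η", "Θ", "Ι", "Κ",
                   "Λ", "Μ", "Ν", "Ξ", "Ο",
                   "Π", "Ρ", "Σ", "Τ", "Υ",
                   "Φ", "Χ", "Ψ", "Ω")
  upper <- stats::setNames(
    c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta", "theta",
      "iota", "kappa", "lambda", "mu", "nu", "xi", "omicron", "pi", "rho",
      "sigma", "tau", "upsilon", "phi", "chi", "psi", "omega"),
    upper_chars
  )
  c(lower, upper)
}

#' Preprocess free text into tokens
#'
#' Lowercases, transliterates Greek letters to their alphabetic names, then
#' splits on whitespace and punctuation. Intra-word hyphens are preserved
#' (so "alpha-tocopherol" stays one token); leading/trailing hyphens are
#' stripped. The transform is idempotent: preprocessing the re-joined output
#' returns the same tokens.
#'
#' @param text A character string (or vector, concatenated with spaces).
#' @return Character vector of tokens; `character(0)` for empty input.
#' @export
#' @examples
#' preprocess_text("α-Tocopherol")  # "alpha-tocopherol"
preprocess_text <- function(text) {
  x <- tolower(paste(text, collapse = " "))
  if (!nzchar(trimws(x))) return(character(0))
  # Substitute both cases explicitly: tolower() of Greek is locale-dependent.
  map <- greek_alphabet()
  for (i in seq_along(map)) {
    if (grepl(names(map)[i], x, fixed = TRUE)) {
      x <- gsub(names(map)[i], map[[i]], x, fixed = TRUE)
    }
  }
  x <- gsub("[^a-z0-9-]+", " ", x)
  tokens <- strsplit(trimws(x), "\\s+")[[1]]
  tokens <- gsub("^-+|-+$", "", tokens)
  tokens[nzchar(tokens)]
}

#' Character n-grams of a word
#'
#' Wraps the word in the boundary markers `<` and `>` (the sub-word
#' embedding convention) and returns every substring of length `n_min` to
#' `n_max`, with multiplicity. The default range 3-6 matches standard
#' sub-word embedding models.
#'
#' @param word A non-empty token.
#' @param n_min,n_max Inclusive n-gram length range.
#' @return Character vector of n-grams (a multiset; duplicates retained).
#' @export
#' @examples
#' char_ngrams("ab", 3, 3)  # "<ab" "ab>"
char_ngrams <- function(word, n_min = 3L, n_max = 6L) {
  stopifnot(1L <= n_min, n_min <= n_max)
  if (!is.character(word) || length(word) != 1L || !nzchar(word)) {
    stop("char_ngrams() requires a single non-empty word")
  }
  padded <- paste0("<", word, ">")
  len <- nchar(padded)
  out <- character(0)
  for (n in n_min:n_max) {
    if (n > len) next
    starts <- seq_len(len - n + 1L)
    out <- c(out, substring(padded, starts, starts + n - 1L))
  }
  out
}

#' Construct a vector table
#'
#' Container for a pre-built word-embedding table: whole-token entries plus
#' an optional character-n-gram table used to compose vectors for
#' out-of-vocabulary words. All tokens are stored lowercase.
#'
#' @param entries Numeric matrix, one row per token (rownames are tokens).
#' @param ngrams Optional numeric matrix, one row per n-gram.
#' @return Object of class `vector_table`: list with `dim`, `entries`,
#'   `ngrams`.
#' @export
vector_table <- function(entries, ngrams = NULL) {
  stopifnot(is.matrix(entries), !is.null(rownames(entries)))
  rownames(entries) <- tolower(rownames(entries))
  if (!is.null(ngrams)) {
    stopifnot(is.matrix(ngrams), !is.null(rownames(ngrams)))
    if (ncol(ngrams) != ncol(entries)) {
      stop(sprintf("dimension mismatch: entries have %d columns, n-grams %d",
                   ncol(entries), ncol(ngrams)))
    }
  }
  structure(list(dim = ncol(entries), entries = entries, ngrams = ngrams),
            class = "vector_table")
}

#' Read a vector table (word2vec text dialect)
#'
#' Expects a header line `"<vocab_size> <dim>"` followed by one line per
#' token: the token and `dim` whitespace-separated floats. Tokens prefixed
#' `NG:` are treated as character-n-gram entries (prefix stripped).
#'
#' @param path Path to the text-format vector file.
#' @return A [vector_table()].
#' @export
read_vector_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("vector table '", path, "' has no entries")
  header <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(header) != 2L || anyNA(header)) {
    stop("malformed vector-table header (expected 'vocab_size dim')")
  }
  dim <- header[2]
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  parts <- strsplit(trimws(body), "\\s+")
  badlen <- which(vapply(parts, length, integer(1)) != dim + 1L)
  if (length(badlen)) {
    stop(sprintf("vector-table line %d has %d fields, expected %d",
                 badlen[1] + 1L, length(parts[[badlen[1]]]), dim + 1L))
  }
  tokens <- vapply(parts, `[[`, character(1), 1L)
  values <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(dim)))
  is_ng <- startsWith(tokens, "NG:")
  entries <- values[!is_ng, , drop = FALSE]
  rownames(entries) <- tokens[!is_ng]
  ngrams <- NULL
  if (any(is_ng)) {
    ngrams <- values[is_ng, , drop = FALSE]
    rownames(ngrams) <- sub("^NG:", "", tokens[is_ng])
  }
  vector_table(entries, ngrams)
}

#' Write a vector table (word2vec text dialect)
#'
#' @param table A [vector_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vector_table <- function(table, path) {
  stopifnot(inherits(table, "vector_table"))
  fmt_rows <- function(m, prefix = "") {
    vals <- apply(m, 1L, function(v) paste(sprintf("%.8g", v), collapse = " "))
    paste(paste0(prefix, rownames(m)), vals)
  }
  n <- nrow(table$entries) + if (is.null(table$ngrams)) 0L else nrow(table$ngrams)
  lines <- c(paste(n, table$dim), fmt_rows(table$entries))
  if (!is.null(table$ngrams)) lines <- c(lines, fmt_rows(table$ngrams, "NG:"))
  writeLines(lines, path)
  invisible(path)
}

#' Compose the latent-knowledge vector of a compound name
#'
#' Each word of the (preprocessed) name is resolved to a vector: a
#' whole-token table hit is used directly; otherwise the word's character
#' n-grams (range `n_min`-`n_max`) are looked up in the n-gram table and
#' averaged. Multi-word names are averaged over their word vectors, so
#' composition is invariant to word order and the norm stays comparable
#' across name lengths. If nothing resolves, a zero vector is returned with
#' a warning.
#'
#' @param name Free-text compound name.
#' @param table A [vector_table()].
#' @param n_min,n_max n-gram length range for out-of-vocabulary words.
#' @return Numeric vector of length `table$dim`.
#' @export
compose_vector <- function(name, table, n_min = 3L, n_max = 6L) {
  stopifnot(inherits(table, "vector_table"))
  if (nrow(table$entries) == 0L) stop("empty vector table")
  tokens <- preprocess_text(name)
  word_vecs <- list()
  for (tok in tokens) {
    if (tok %in% rownames(table$entries)) {
      word_vecs[[length(word_vecs) + 1L]] <- table$entries[tok, ]
    } else if (!is.null(table$ngrams)) {
      grams <- char_ngrams(tok, n_min, n_max)
      hit <- grams[grams %in% rownames(table$ngrams)]
      if (length(hit)) {
        word_vecs[[length(word_vecs) + 1L]] <-
          colMeans(table$ngrams[hit, , drop = FALSE])
      } else {
        warning(sprintf("no embedding information for token '%s'", tok))
      }
    } else {
      warning(sprintf("no embedding information for token '%s'", tok))
    }
  }
  if (length(word_vecs) == 0L) {
    warning(sprintf("name '%s' is unresolvable; returning zero vector", name))
    return(numeric(table$dim))
  }
  colMeans(do.call(rbind, word_vecs))
}

#' Latent-knowledge feature block
#'
#' Composes one embedding vector per compound name, returning the latent
#' feature block in assembly-ready matrix form.
#'
#' @param ids Compound identifiers (row names of the block).
#' @param names Compound names, parallel to `ids`.
#' @param table A [vector_table()].
#' @param ... Passed to [compose_vector()].
#' @return Numeric matrix (`length(ids)` x `table$dim`).
#' @export
latent_block <- function(ids, names, table, ...) {
  stopifnot(length(ids) == length(names))
  m <- t(vapply(names, function(nm) compose_vector(nm, table, ...),
                numeric(table$dim)))
  dimnames(m) <- list(ids, sprintf("lk%03d", seq_len(table$dim)))
  m
}

cosine_pair <- function(a, b) {
  sum(a * b) / (sqrt(sum(a * a)) * sqrt(sum(b * b)))
}

#' Mean pairwise cosine similarity within groups
#'
#' For each group, the mean cosine similarity over all unordered member
#' pairs. Zero vectors are excluded with a warning; groups with fewer than
#' two usable members are skipped with a warning.
#'
#' @param vectors Numeric matrix, one row per id (rownames are ids).
#' @param groups Named list: group name -> character vector of ids.
#' @return Named numeric vector of group means (skipped groups absent).
#' @export
group_mean_cosine <- function(vectors, groups) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  out <- numeric(0)
  for (gname in names(groups)) {
    ids <- intersect(groups[[gname]], rownames(vectors))
    sub <- vectors[ids, , drop = FALSE]
    norms <- sqrt(rowSums(sub^2))
    if (any(norms == 0)) {
      warning(sprintf("group '%s': excluding %d zero vector(s)",
                      gname, sum(norms == 0)))
      sub <- sub[norms > 0, , drop = FALSE]
      norms <- norms[norms > 0]
    }
    if (nrow(sub) < 2L) {
      warning(sprintf("group '%s' has < 2 usable members; skipped", gname))
      next
    }
    unit <- sub / norms
    cs <- tcrossprod(unit)
    out[gname] <- mean(cs[upper.tri(cs)])
  }
  out
}

#' ATC prefix for a classification level
#'
#' ATC codes are 7-character strings whose levels 1-5 are prefixes of
#' lengths 1, 3, 4, 5 and 7 (anatomical group, therapeutic group,
#' pharmacological subgroup, chemical subgroup, substance).
#'
#' @param code Character vector of 7-character ATC codes.
#' @param level Integer in 1..5.
#' @return Character vector of prefixes.
#' @export
atc_level_prefix <- function(code, level) {
  stopifnot(level %in% 1:5)
  substr(code, 1L, c(1L, 3L, 4L, 5L, 7L)[level])
}

#' Within-ATC-group embedding similarity versus a random baseline
#'
#' Groups drugs by their ATC prefix at the requested level, pools the cosine
#' similarities of all within-group pairs and compares against a
#' size-matched random grouping (same group sizes, membership shuffled with
#' a fixed seed). Groups with fewer than two members are dropped; when no
#' group survives, a zero-row frame is returned.
#'
#' @param vectors Numeric matrix of drug embedding vectors (rownames ids).
#' @param atc_codes `data.frame` with columns `drug_id`, `code`.
#' @param level ATC level, 1..5 (or a vector of levels).
#' @param seed Seed for the random baseline (default 1).
#' @return `data.frame` with columns `level`, `mean_same`, `mean_random`,
#'   `n_groups`, `n_pairs`.
#' @export
atc_similarity_profile <- function(vectors, atc_codes, level = 1:5, seed = 1L) {
  stopifnot(all(level %in% 1:5))
  res <- lapply(level, function(lv) {
    codes <- atc_codes[atc_codes$drug_id %in% rownames(vectors), ]
    prefix <- atc_level_prefix(codes$code, lv)
    grp <- split(codes$drug_id, prefix)
    grp <- grp[vapply(grp, length, integer(1)) >= 2L]
    if (length(grp) == 0L) {
      return(data.frame(level = integer(0), mean_same = numeric(0),
                        mean_random = numeric(0), n_groups = integer(0),
                        n_pairs = integer(0)))
    }
    pooled <- function(groups) {
      sims <- unlist(lapply(groups, function(ids) {
        sub <- vectors[ids, , drop = FALSE]
        unit <- sub / sqrt(rowSums(sub^2))
        cs <- tcrossprod(unit)
        cs[upper.tri(cs)]
      }))
      c(mean = mean(sims), n = length(sims))
    }
    same <- pooled(grp)
    set.seed(seed)
    shuffled <- sample(unlist(grp))
    sizes <- vapply(grp, length, integer(1))
    rand_grp <- split(shuffled, rep(seq_along(sizes), sizes))
    rand <- pooled(rand_grp)
    data.frame(level = lv, mean_same = same[["mean"]],
               mean_random = rand[["mean"]], n_groups = length(grp),
               n_pairs = as.integer(same[["n"]]))
  })
  do.call(rbind, res)
}
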