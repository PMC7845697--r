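test_that("holdout splits honour ratios, disjointness and stratification", {
  plan <- make_split(1:10, c(6, 2, 2), seed = 1)
  expect_equal(lengths(plan$splits), c(train = 6L, validation = 2L, test = 2L))
  expect_setequal(unlist(plan$splits), 1:10)

  ids <- sprintf("d%03d", 1:100)
  labs <- rep(c(1, 0), c(20, 80))
  plan2 <- make_split(ids, c(6, 2, 2), seed = 3, labels = labs)
  expect_setequal(unlist(plan2$splits), ids)
  pos_share <- vapply(plan2$splits, function(s) mean(labs[match(s, ids)]),
                      numeric(1))
  expect_true(all(abs(pos_share - 0.2) < 0.02))
  expect_identical(make_split(ids, c(6, 2, 2), seed = 3, labels = labs),
                   plan2)
})

test_that("k-fold assignments partition the ids evenly", {
  folds <- make_kfold(1:100, k = 10, seed = 2)
  expect_equal(unname(lengths(folds$splits)), rep(10L, 10))
  expect_setequal(unlist(folds$splits), 1:100)
  expect_equal(sum(duplicated(unlist(folds$splits))), 0L)
})

test_that("AUROC matches pair counting with midrank ties", {
  y <- rep(c(1, 0), each = 5)
  expect_equal(auroc(c(rnorm(5, 5), rnorm(5, -5)), y), 1.0)
  expect_error(auroc(rnorm(5), rep(1, 5)), "both classes")

  set.seed(14)
  for (i in 1:20) {
    n <- sample(8:25, 1)
    scores <- sample(1:6, n, replace = TRUE)  # heavy ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(15)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.4)
  a <- auroc(scores, labels)
  expect_equal(auroc(exp(scores), labels), a)
  expect_equal(auroc(rank(scores), labels), a)
  expect_equal(auroc(scores * 3 - 10, labels), a)
})

test_that("accuracy counts hard calls at the threshold", {
  expect_equal(accuracy(c(0.9, 0.1), c(1, 0)), 1.0)
  expect_equal(accuracy(c(0.1, 0.9), c(1, 0)), 0.0)
  set.seed(16)
  s <- runif(30)
  y <- rbinom(30, 1, 0.5)
  expect_equal(accuracy(s, y, 0.4), mean((s >= 0.4) == y))
})

test_that("summaries report mean and sample SD", {
  const <- summarize_values(rep(0.7, 8))
  expect_equal(const$mean, 0.7)
  expect_equal(const$sd, 0)
  set.seed(17)
  v <- rnorm(25)
  s <- summarize_values(v)
  expect_equal(s$mean, sum(v) / 25)
  expect_equal(s$sd, sqrt(sum((v - mean(v))^2) / 24))
  expect_match(s$label, "±")
})

test_that("ranked sets are sized, ordered and disjoint", {
  set.seed(18)
  m <- matrix(runif(20), 5, 4,
              dimnames = list(paste0("c", 1:5), paste0("d", 1:4)))
  sets <- ranked_sets(m, fraction = 0.1, seed = 1)
  expect_equal(nrow(sets$high), 2L)
  expect_equal(nrow(sets$low), 2L)
  expect_equal(nrow(sets$random), 2L)
  expect_gte(min(sets$high$score), max(sets$low$score))
  key <- function(s) paste(s$compound, s$disease)
  expect_length(intersect(key(sets$high), key(sets$low)), 0L)
  expect_identical(ranked_sets(m, fraction = 0.1, seed = 1), sets)
})

toy_corpus <- function() {
  data.frame(
    doc_id = paste0("pmid", 1:6),
    text = c("curcumin reduces pain in arthritis",
             "curcumin and turmeric studied for pain",
             "aspirin for pain relief",
             "curcumin bioavailability study",
             "unrelated genomics paper",
             "arthritis cohort without compounds"),
    stringsAsFactors = FALSE
  )
}

test_that("term postings honour contiguous multi-token matching", {
  idx <- literature_index(toy_corpus())
  expect_setequal(term_postings(idx, "curcumin"),
                  c("pmid1", "pmid2", "pmid4"))
  expect_setequal(term_postings(idx, "pain relief"), "pmid3")
  expect_equal(term_postings(idx, "relief pain"), character(0))
  expect_equal(term_postings(idx, "unknownium"), character(0))
})

test_that("co-occurrence and Jaccard match set arithmetic", {
  idx <- literature_index(toy_corpus())
  expect_equal(cooccurrence(idx, c("curcumin", "pain")), 2L)
  expect_equal(jaccard_index(idx, c("curcumin", "pain")), 2 / 4)
  expect_equal(jaccard_index(idx, c("aspirin", "genomics")), 0)
  expect_equal(jaccard_index(idx, c("nope", "nada")), 0)
  empty <- literature_index(data.frame(doc_id = character(0),
                                       text = character(0)))
  expect_equal(cooccurrence(empty, c("a", "b")), 0L)

  set.seed(19)
  docs <- data.frame(doc_id = paste0("d", 1:40),
                     text = replicate(40, paste(sample(letters[1:6],
                                                       sample(2:5, 1)),
                                                collapse = " ")))
  idx2 <- literature_index(docs)
  for (i in 1:10) {
    pair <- sample(letters[1:6], 2)
    a <- docs$doc_id[grepl(pair[1], docs$text)]
    b <- docs$doc_id[grepl(pair[2], docs$text)]
    expect_equal(cooccurrence(idx2, pair), length(intersect(a, b)))
    expect_equal(jaccard_index(idx2, pair),
                 if (length(union(a, b)) == 0) 0 else
                   length(intersect(a, b)) / length(union(a, b)))
  }
})

test_that("Fisher enrichment p-values behave at the boundaries", {
  # zero co-occurrence cannot be enriched
  expect_gte(fisher_exact_p(0, 5, 7, 20), 0.5)
  # agreement with the hypergeometric tail oracle on random tables
  set.seed(20)
  for (i in 1:25) {
    tab <- as.integer(rmultinom(1, sample(5:60, 1), c(0.2, 0.3, 0.3, 0.2)))
    expect_equal(fisher_exact_p(tab[1], tab[2], tab[3], tab[4]),
                 oracle_fisher_tail(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
    # and with the standard one-sided test as an independent reference
    expect_equal(fisher_exact_p(tab[1], tab[2], tab[3], tab[4]),
                 stats::fisher.test(matrix(tab, 2, byrow = TRUE),
                                    alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
  # growing the neither cell strengthens a fixed positive association
  p_small <- fisher_exact_p(5, 2, 2, 10)
  p_large <- fisher_exact_p(5, 2, 2, 20)
  expect_lte(p_large, p_small)
  expect_error(fisher_exact_p(0, 0, 0, 0), "empty")
})

test_that("Mann-Whitney identities and exact separated-sample value", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(6, 7, 8, 9, 10)
  res <- mann_whitney(x, y)
  expect_equal(res$p.value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$statistic + mann_whitney(y, x)$statistic, 25)
  expect_equal(mann_whitney(c(1, 1, 2), c(1, 2, 1))$p.value, 1)

  # exact branch equals tie-free closed forms from the standard test
  set.seed(22)
  for (i in 1:5) {
    a <- rnorm(6)
    b <- rnorm(7)
    expect_equal(mann_whitney(a, b)$p.value,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # the large-sample branch is a genuine normal approximation
  big <- mann_whitney(rnorm(15), rnorm(15) + 2)
  expect_equal(big$method, "normal approximation")
  expect_lt(big$p.value, 0.01)
})

test_that("the literature report ranks planted evidence correctly", {
  set.seed(23)
  compounds <- paste0("cmp", 1:6)
  diseases <- c("fever", "gout")
  scores <- matrix(runif(12, 0, 0.4), 6, 2,
                   dimnames = list(compounds, diseases))
  scores["cmp1", "fever"] <- 0.99  # top-ranked pair
  scores["cmp2", "gout"] <- 0.01   # bottom-ranked pair
  docs <- data.frame(
    doc_id = paste0("p", 1:20),
    text = c(rep("cmp1 treats fever", 8),
             replicate(12, paste(sample(c("filler", "words", "cmp3", "gout"),
                                        3), collapse = " ")))
  )
  idx <- literature_index(docs)
  rep <- literature_report(scores, idx, fraction = 0.1, seed = 4)
  s <- rep$summary
  expect_equal(s$set, c("high", "low", "random"))
  expect_gt(s$nc_mean[s$set == "high"], s$nc_mean[s$set == "low"])
  expect_equal(nrow(rep$mann_whitney), 3L)
  expect_true(all(rep$mann_whitney$p_value >= 0 &
                    rep$mann_whitney$p_value <= 1))

  empty <- literature_index(data.frame(doc_id = character(0),
                                       text = character(0)))
  expect_warning(rep0 <- literature_report(scores, empty, fraction = 0.1),
                 "empty corpus")
  expect_true(all(rep0$summary$nc_mean == 0))
  expect_true(all(is.na(rep0$summary$n_f)))
})
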