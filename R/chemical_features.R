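#' Typed descriptor schema
#'
#' Declares how each chemical descriptor column is handled when building the
#' chemical-property feature block: `zscore` columns are standardized with
#' training statistics, `passthrough` columns (log-scale predictions such as
#' log P or log S) are copied unchanged, and `categorical` columns are
#' one-hot encoded over an enumerated category set.
#'
#' @param zscore Character vector of column names to standardize.
#' @param passthrough Character vector of column names copied unchanged.
#' @param categorical Named list: column name -> character vector of all
#'   admissible categories (unseen categories at encoding time are errors).
#' @return `data.frame` of class `descriptor_schema` with columns `name`,
#'   `kind` and a list-column `categories`.
#' @export
descriptor_schema <- function(zscore = character(), passthrough = character(),
                              categorical = list()) {
  nms <- c(zscore, passthrough, names(categorical))
  if (anyDuplicated(nms)) stop("duplicate descriptor names in schema")
  cats <- c(rep(list(NULL), length(zscore) + length(passthrough)),
            unname(categorical))
  out <- data.frame(
    name = nms,
    kind = rep(c("zscore", "passthrough", "categorical"),
               c(length(zscore), length(passthrough), length(categorical))),
    stringsAsFactors = FALSE
  )
  out$categories <- cats
  class(out) <- c("descriptor_schema", "data.frame")
  out
}

#' Encoded width of a schema
#'
#' One column per `zscore`/`passthrough` descriptor plus one indicator per
#' category of each categorical descriptor.
#'
#' @param schema A [descriptor_schema()].
#' @return Integer width of the encoded block.
#' @export
schema_width <- function(schema) {
  sum(ifelse(schema$kind == "categorical",
             lengths(schema$categories), 1L))
}

#' Default chemical descriptor schema (101 encoded columns)
#'
#' The full-scale descriptor layout for SwissADME-style export tables:
#' seven standardized physicochemical properties (molecular weight, heavy
#' atoms, fraction Csp3, rotatable bonds, H-bond acceptors/donors, molar
#' refractivity); log-scale passthrough columns for five log P estimators
#' plus their consensus, three water-solubility estimators, the skin
#' permeability coefficient and synthetic accessibility; and categorical
#' pharmacokinetics, drug-likeness and structural-alert descriptors that are
#' one-hot encoded. Category counts are configuration, chosen so that the
#' encoded block is 101 columns wide; edit or replace the schema to match a
#' different export.
#'
#' @return A [descriptor_schema()] with [schema_width()] 101.
#' @export
default_descriptor_schema <- function() {
  descriptor_schema(
    zscore = c("mw", "heavy_atoms", "fraction_csp3", "rotatable_bonds",
               "hba", "hbd", "molar_refractivity"),
    passthrough = c("ilogp", "xlogp3", "wlogp", "mlogp", "silicos_it_logp",
                    "consensus_logp", "esol_logs", "ali_logs",
                    "silicos_it_logs", "log_kp", "synthetic_accessibility"),
    categorical = list(
      gi_absorption = c("High", "Low"),
      bbb_permeant = c("No", "Yes"),
      pgp_substrate = c("No", "Yes"),
      cyp1a2_inhibitor = c("No", "Yes"),
      cyp2c19_inhibitor = c("No", "Yes"),
      cyp2c9_inhibitor = c("No", "Yes"),
      cyp2d6_inhibitor = c("No", "Yes"),
      cyp3a4_inhibitor = c("No", "Yes"),
      lipinski_violations = as.character(0:4),
      ghose_violations = as.character(0:4),
      veber_violations = as.character(0:3),
      egan_violations = as.character(0:2),
      muegge_violations = as.character(0:10),
      bioavailability_score = c("0.11", "0.17", "0.55", "0.56", "0.85"),
      pains_alerts = as.character(0:9),
      brenk_alerts = as.character(0:19),
      leadlikeness_violations = as.character(0:3)
    )
  )
}

#' Fit the Z-score scaling model on training rows
#'
#' Estimates per-column mean and sample (n-1) standard deviation of every
#' `zscore` descriptor from the training rows only. Constant training
#' columns (SD 0) cannot be standardized and are dropped from the schema
#' with a warning.
#'
#' @param table Descriptor `data.frame` with an `id` column.
#' @param schema A [descriptor_schema()].
#' @param training_ids Ids of the rows used for estimation (>= 2).
#' @return Object of class `scaling_model`: list with `schema` (possibly
#'   reduced), `mean` and `sd` (named vectors over the kept zscore columns).
#' @export
fit_scaling <- function(table, schema, training_ids = table$id) {
  stopifnot(inherits(schema, "descriptor_schema"), "id" %in% names(table))
  rows <- table[match(training_ids, table$id), , drop = FALSE]
  if (nrow(rows) < 2L) stop("need at least 2 training rows to fit scaling")
  zcols <- schema$name[schema$kind == "zscore"]
  mu <- sdv <- stats::setNames(numeric(length(zcols)), zcols)
  for (cn in zcols) {
    v <- rows[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric value in zscore column '%s' (row id '%s')",
                   cn, rows$id[ifelse(is.na(bad), 1L, bad)]))
    }
    mu[cn] <- mean(v)
    sdv[cn] <- stats::sd(v)
  }
  constant <- zcols[sdv == 0]
  if (length(constant)) {
    warning("dropping constant zscore column(s): ",
            paste(constant, collapse = ", "))
    schema <- schema[!schema$name %in% constant, ]
    class(schema) <- c("descriptor_schema", "data.frame")
    mu <- mu[setdiff(zcols, constant)]
    sdv <- sdv[setdiff(zcols, constant)]
  }
  structure(list(schema = schema, mean = mu, sd = sdv),
            class = "scaling_model")
}

#' Encode a descriptor table into the chemical feature block
#'
#' Standardizes `zscore` columns with the *stored training statistics*
#' (never per-batch ones), copies `passthrough` columns, and expands each
#' categorical column into one indicator per enumerated category (exactly
#' one indicator is 1 per row and column). Column order follows the schema.
#'
#' @param table Descriptor `data.frame` with an `id` column covering every
#'   schema column.
#' @param model A `scaling_model` from [fit_scaling()].
#' @return Numeric matrix with compound ids as rownames;
#'   width equals [schema_width()] of the model's schema.
#' @export
encode_descriptors <- function(table, model) {
  stopifnot(inherits(model, "scaling_model"))
  schema <- model$schema
  missing_cols <- setdiff(schema$name, names(table))
  if (length(missing_cols)) {
    stop("descriptor table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(table)
  pieces <- vector("list", nrow(schema))
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    kind <- schema$kind[i]
    if (kind == "zscore") {
      m <- matrix((table[[nm]] - model$mean[nm]) / model$sd[nm], ncol = 1L)
      colnames(m) <- nm
    } else if (kind == "passthrough") {
      m <- matrix(as.numeric(table[[nm]]), ncol = 1L)
      colnames(m) <- nm
    } else {
      cats <- schema$categories[[i]]
      vals <- as.character(table[[nm]])
      unseen <- setdiff(unique(vals), cats)
      if (length(unseen)) {
        stop(sprintf("unseen category '%s' in column '%s'", unseen[1], nm))
      }
      m <- matrix(0, nrow = n, ncol = length(cats),
                  dimnames = list(NULL, paste(nm, cats, sep = ".")))
      m[cbind(seq_len(n), match(vals, cats))] <- 1
    }
    pieces[[i]] <- m
  }
  out <- do.call(cbind, pieces)
  rownames(out) <- table$id
  out
}

#' Within-group descriptor similarity versus a random baseline
#'
#' Mean pairwise cosine similarity of encoded descriptor vectors within each
#' group, pooled over groups, compared with a size-matched random grouping
#' (fixed seed). Used to check that compounds sharing a medicinal effect
#' have more similar chemical profiles than random compound pairs.
#'
#' @param block Encoded descriptor matrix (rownames are ids).
#' @param groups Named list: group -> character vector of ids (each >= 2).
#' @param seed Seed for the random baseline (default 1).
#' @return List with `within` (pooled within-group mean cosine), `random`
#'   (baseline mean) and `n_pairs`.
#' @export
descriptor_similarity <- function(block, groups, seed = 1L) {
  stopifnot(all(vapply(groups, length, integer(1)) >= 2L))
  pooled <- function(grps) {
    sims <- unlist(lapply(grps, function(ids) {
      sub <- block[ids, , drop = FALSE]
      unit <- sub / sqrt(rowSums(sub^2))
      cs <- tcrossprod(unit)
      cs[upper.tri(cs)]
    }))
    sims
  }
  within <- pooled(groups)
  set.seed(seed)
  pool <- rownames(block)
  rand_groups <- lapply(groups, function(ids) sample(pool, length(ids)))
  rand <- pooled(rand_groups)
  list(within = mean(within), random = mean(rand), n_pairs = length(within))
}

#' Interquartile overlap of two descriptor tables
#'
#' Fraction of numeric (zscore and passthrough) descriptors whose median in
#' the first table lies inside the interquartile range of the second,
#' computed on the raw, pre-encoding values. Summarizes how much of
#' chemical-property space one compound collection shares with another
#' (e.g., natural compounds versus approved drugs).
#'
#' @param natural_table,drug_table Descriptor `data.frame`s sharing the
#'   schema's numeric columns.
#' @param schema A [descriptor_schema()].
#' @return Fraction in `[0, 1]`.
#' @export
interquartile_overlap <- function(natural_table, drug_table, schema) {
  cols <- schema$name[schema$kind %in% c("zscore", "passthrough")]
  stopifnot(length(cols) > 0L,
            all(cols %in% names(natural_table)),
            all(cols %in% names(drug_table)))
  inside <- vapply(cols, function(cn) {
    med <- stats::median(natural_table[[cn]])
    q <- stats::quantile(drug_table[[cn]], c(0.25, 0.75), names = FALSE)
    med >= q[1] && med <= q[2]
  }, logical(1))
  mean(inside)
}
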