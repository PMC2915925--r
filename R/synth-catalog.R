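# Toy multi-study hit catalogs, gene->term annotation tables and
# protein-interaction edge lists with known structure, for exercising the
# integration, enrichment and network-export steps.

#' Construct a multi-study hit catalog
#'
#' @param membership logical gene x study matrix (rownames = genes,
#'   colnames = studies). `NA` means "no phenotype data" and never counts as
#'   a hit.
#' @param validated_novel character subset of genes independently validated
#'   by the current study.
#' @return object of class `study_catalog`.
#' @export
study_catalog <- function(membership, validated_novel = character(0)) {
  stopifnot(is.matrix(membership), !is.null(rownames(membership)),
            !is.null(colnames(membership)))
  if (!all(validated_novel %in% rownames(membership))) {
    stop("validated_novel must be a subset of the catalog genes")
  }
  structure(list(genes = rownames(membership),
                 studies = colnames(membership),
                 membership = membership,
                 validated_novel = validated_novel),
            class = "study_catalog")
}

#' Simulate a gene-by-study hit catalog
#'
#' Each gene enters each study independently with that study's inclusion
#' probability. A requested number of singleton genes (hits in at most one
#' study) are flagged as independently validated novel regulators.
#'
#' @param n_genes number of genes.
#' @param study_probs per-study inclusion probabilities (1 to 5 studies;
#'   names used as study identifiers, default Roman numerals).
#' @param n_validated_novel how many singleton genes to mark as validated.
#' @param seed integer seed; output is deterministic.
#' @return a [study_catalog()].
#' @export
simulate_catalog <- function(n_genes, study_probs, n_validated_novel = 0,
                             seed = 1L) {
  n_studies <- length(study_probs)
  if (n_studies < 1) stop("at least one study is required")
  if (n_studies > 5) stop("at most five studies are supported")
  stopifnot(n_genes >= 1, all(study_probs >= 0), all(study_probs <= 1))
  studies <- names(study_probs) %||% as.character(utils::as.roman(seq_len(n_studies)))
  withr::with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    m <- matrix(runif(n_genes * n_studies) < rep(study_probs, each = n_genes),
                nrow = n_genes, dimnames = list(genes, studies))
    singletons <- genes[rowSums(m) <= 1]
    vn <- if (n_validated_novel > 0) {
      sample(singletons, min(n_validated_novel, length(singletons)))
    } else character(0)
    study_catalog(m, vn)
  })
}

#' Simulate a gene-to-term annotation table
#'
#' Terms draw member genes without replacement; every gene additionally
#' belongs to a catch-all root term so the annotation covers the universe.
#'
#' @param genes character vector (the universe).
#' @param n_terms number of specific terms.
#' @param term_size_range min/max genes per term.
#' @param seed integer seed.
#' @return tibble with columns `gene`, `term`.
#' @export
simulate_annotations <- function(genes, n_terms = 10,
                                 term_size_range = c(5, 25), seed = 1L) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_terms), function(i) {
      size <- sample(term_size_range[1]:min(term_size_range[2], length(genes)), 1)
      tibble(gene = sample(genes, size), term = sprintf("T%03d", i))
    })
    dplyr::bind_rows(c(rows, list(tibble(gene = genes, term = "ROOT"))))
  })
}

#' Simulate an undirected protein-interaction edge list
#'
#' @param genes character vector of node identifiers.
#' @param n_edges number of distinct undirected edges.
#' @param seed integer seed.
#' @return tibble with columns `gene_a`, `gene_b`.
#' @export
simulate_interactions <- function(genes, n_edges = 50, seed = 1L) {
  stopifnot(length(genes) >= 2)
  withr::with_seed(seed, {
    max_edges <- choose(length(genes), 2)
    n_edges <- min(n_edges, max_edges)
    seen <- character(0)
    out <- vector("list", n_edges)
    k <- 0L
    while (k < n_edges) {
      pair <- sort(sample(genes, 2))
      key <- paste(pair, collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      k <- k + 1L
      out[[k]] <- tibble(gene_a = pair[1], gene_b = pair[2])
    }
    dplyr::bind_rows(out)
  })
}
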