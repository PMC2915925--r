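# Multi-study integration: the validated-regulator rule (hit in at least two
# system-wide studies, or independently validated by the current screen),
# overlap arithmetic, hypergeometric gene-set enrichment with BH adjustment,
# and compartment-annotated network export.

NETWORK_COMPARTMENTS <- c("Nucleus", "Intracellular", "Cytosol",
                          "Peroxisome", "Mitochondria", "Unknown")

#' Integrate a multi-study hit catalog
#'
#' Keeps genes identified in at least `min_studies` studies, plus any gene
#' independently validated by the current study regardless of its study
#' count. `NA` membership means "no phenotype data" and never counts toward
#' the study total. Optionally merges sub-studies (e.g. the current screen's
#' flow and imaging arms) by OR before applying the rule.
#'
#' @param catalog a [study_catalog()].
#' @param min_studies minimum number of studies (>= 1).
#' @param merge_studies named list mapping a merged-study name to the column
#'   names it combines.
#' @return tibble of retained genes: `gene`, `n_studies`, `validated_novel`.
#' @export
integrate_catalog <- function(catalog, min_studies = 2, merge_studies = NULL) {
  stopifnot(inherits(catalog, "study_catalog"), min_studies >= 1)
  m <- catalog$membership
  if (!is.null(merge_studies)) {
    for (new in names(merge_studies)) {
      olds <- merge_studies[[new]]
      if (!all(olds %in% colnames(m))) stop("unknown study in merge_studies")
      merged <- apply(m[, olds, drop = FALSE], 1, function(r) {
        if (all(is.na(r))) NA else any(r, na.rm = TRUE)
      })
      m <- cbind(m[, setdiff(colnames(m), olds), drop = FALSE],
                 matrix(merged, ncol = 1, dimnames = list(NULL, new)))
    }
  }
  n_studies <- rowSums(m, na.rm = TRUE)
  keep <- n_studies >= min_studies | catalog$genes %in% catalog$validated_novel
  tibble(gene = catalog$genes[keep],
         n_studies = as.integer(n_studies[keep]),
         validated_novel = catalog$genes[keep] %in% catalog$validated_novel)
}

#' Overlap statistics between two gene sets
#'
#' Reports the sizes and the percentage of the reference set `setB` that is
#' also found in `setA`, rounded to the nearest integer — the form in which
#' the screen reports its recovery of previously identified regulators. The
#' denominator is always `|B|` (a documented asymmetry).
#'
#' @param setA,setB character vectors of gene identifiers (case-insensitive,
#'   deduplicated).
#' @return list: `n_a`, `n_b`, `n_intersect`, `pct_of_b_in_a`.
#' @export
overlap_stats <- function(setA, setB) {
  a <- unique(toupper(as.character(setA)))
  b <- unique(toupper(as.character(setB)))
  if (length(b) == 0L) stop("overlap percentage undefined: reference set is empty")
  ni <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_intersect = ni,
       pct_of_b_in_a = round(100 * ni / length(b)))
}

#' Hypergeometric gene-set enrichment
#'
#' For each annotation term, the upper-tail hypergeometric probability of
#' observing at least `k` term members in a gene set of size `n` drawn from a
#' universe of `N` genes of which `K` carry the term;
#' Benjamini-Hochberg adjustment across the tested terms.
#'
#' @param gene_set character vector (must lie within the universe; strays are
#'   dropped with a message).
#' @param annotations data frame with columns `gene`, `term`.
#' @param universe character vector of all scored genes.
#' @return tibble sorted by p: `term`, `k`, `K`, `n`, `N`, `p`, `p_adj`.
#' @export
enrich <- function(gene_set, annotations, universe) {
  universe <- unique(toupper(as.character(universe)))
  gene_set <- unique(toupper(as.character(gene_set)))
  stray <- setdiff(gene_set, universe)
  if (length(stray)) {
    message(length(stray), " gene(s) outside the universe dropped from the set")
    gene_set <- intersect(gene_set, universe)
  }
  ann <- tibble(gene = toupper(as.character(annotations$gene)),
                term = as.character(annotations$term))
  ann <- ann[ann$gene %in% universe, , drop = FALSE]
  ann <- dplyr::distinct(ann)
  N <- length(universe)
  n <- length(gene_set)
  terms <- split(ann$gene, ann$term)
  rows <- lapply(names(terms), function(tm) {
    members <- terms[[tm]]
    K <- length(members)
    if (K == 0L) {
      message("term ", tm, " has no members in the universe; skipped")
      return(NULL)
    }
    k <- length(intersect(members, gene_set))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(term = tm, k = k, K = K, n = n, N = N, p = p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(out)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out[order(out$p, out$term), , drop = FALSE]
}

#' Export a compartment-annotated regulator network
#'
#' Builds the node and edge tables of the regulator interaction network:
#' nodes are the integrated regulators annotated with a subcellular
#' compartment and their study count; edges are restricted to
#' regulator-regulator pairs, undirected and deduplicated. Edges touching
#' genes absent from the catalog are dropped (count reported).
#'
#' @param regulators output of [integrate_catalog()] (or a character vector).
#' @param edges data frame with columns `gene_a`, `gene_b`.
#' @param localization optional data frame `gene`, `compartment`; genes
#'   without an entry (or with an unrecognized compartment) are `Unknown`.
#' @param known_genes universe of catalog genes used to detect unknown edge
#'   endpoints (defaults to the regulator genes).
#' @return list: `nodes`, `edges`, `compartment_counts`, `n_dropped_edges`.
#' @export
export_network <- function(regulators, edges, localization = NULL,
                           known_genes = NULL) {
  if (is.character(regulators)) {
    regulators <- tibble(gene = regulators, n_studies = NA_integer_,
                         validated_novel = NA)
  }
  reg <- unique(toupper(regulators$gene))
  known <- unique(toupper(known_genes %||% regulators$gene))
  comp <- setNames(rep("Unknown", length(reg)), reg)
  if (!is.null(localization)) {
    loc <- setNames(as.character(localization$compartment),
                    toupper(localization$gene))
    hit <- intersect(names(loc), reg)
    ok <- loc[hit] %in% NETWORK_COMPARTMENTS
    comp[hit[ok]] <- loc[hit][ok]
  }
  nodes <- tibble(gene = reg,
                  compartment = unname(comp[reg]),
                  n_studies = regulators$n_studies[match(reg, toupper(regulators$gene))])

  ea <- toupper(as.character(edges$gene_a))
  eb <- toupper(as.character(edges$gene_b))
  unknown <- !(ea %in% known) | !(eb %in% known)
  n_dropped <- sum(unknown)
  if (n_dropped) message(n_dropped, " edge(s) with unknown endpoints dropped")
  ea2 <- pmin(ea[!unknown], eb[!unknown])
  eb2 <- pmax(ea[!unknown], eb[!unknown])
  keep <- ea2 %in% reg & eb2 %in% reg & ea2 != eb2
  edge_tbl <- dplyr::distinct(tibble(gene_a = ea2[keep], gene_b = eb2[keep]))
  counts <- table(factor(nodes$compartment, levels = NETWORK_COMPARTMENTS))
  list(nodes = nodes, edges = edge_tbl,
       compartment_counts = as.integer(counts) |>
         setNames(NETWORK_COMPARTMENTS),
       n_dropped_edges = n_dropped)
}

#' Write a network in SIF format
#'
#' @param network output of [export_network()].
#' @param path output file.
#' @param interaction interaction type string.
#' @return `path`, invisibly.
#' @export
write_sif <- function(network, path, interaction = "pp") {
  lines <- c(
    sprintf("%s %s %s", network$edges$gene_a, interaction, network$edges$gene_b),
    # isolated nodes still appear as single-column records
    setdiff(network$nodes$gene,
            unique(c(network$edges$gene_a, network$edges$gene_b))))
  writeLines(lines, path)
  invisible(path)
}
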