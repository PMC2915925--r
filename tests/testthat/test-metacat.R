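# Multi-study integration, overlap arithmetic, enrichment, network export.

toy_catalog <- function() {
  m <- matrix(c(TRUE,  TRUE,  FALSE,
                FALSE, TRUE,  FALSE,
                TRUE,  FALSE, TRUE,
                FALSE, FALSE, FALSE,
                NA,    TRUE,  TRUE),
              ncol = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3", "g4", "g5"),
                              c("I", "II", "III")))
  study_catalog(m, validated_novel = "g2")
}

test_that("integration applies the >=2 studies rule with validated rescue", {
  out <- integrate_catalog(toy_catalog(), min_studies = 2)
  expect_setequal(out$gene, c("g1", "g2", "g3", "g5"))   # g2 rescued
  expect_equal(out$n_studies[out$gene == "g1"], 2L)
  expect_equal(out$n_studies[out$gene == "g5"], 2L)       # NA never counts
  expect_false("g4" %in% out$gene)
  solo <- integrate_catalog(study_catalog(
    matrix(c(TRUE, FALSE), 1, dimnames = list("x", c("I", "II")))), 2)
  expect_equal(nrow(solo), 0L)
})

test_that("integration equals brute-force row filtering across seeds", {
  for (s in 1:20) {
    cat1 <- simulate_catalog(200, c(0.2, 0.15, 0.1), n_validated_novel = 5,
                             seed = s)
    out <- integrate_catalog(cat1, min_studies = 2)
    brute <- rownames(cat1$membership)[
      rowSums(cat1$membership, na.rm = TRUE) >= 2 |
        rownames(cat1$membership) %in% cat1$validated_novel]
    expect_setequal(out$gene, brute)
  }
})

test_that("integration is monotone in min_studies", {
  cat1 <- simulate_catalog(300, c(0.3, 0.3, 0.2, 0.2), seed = 4)
  sets <- lapply(1:4, function(k) integrate_catalog(cat1, k)$gene)
  for (k in 2:4) expect_true(all(sets[[k]] %in% sets[[k - 1]]))
})

test_that("sub-study merging ORs columns before the rule", {
  m <- matrix(c(TRUE, FALSE, FALSE,
                TRUE, TRUE,  FALSE),
              ncol = 3, byrow = TRUE,
              dimnames = list(c("a", "b"), c("I.a", "I.b", "II")))
  cat1 <- study_catalog(m)
  merged <- integrate_catalog(cat1, min_studies = 2,
                              merge_studies = list(I = c("I.a", "I.b")))
  # without merging, b counts I.a + I.b as two studies; with merging it is one
  expect_equal(nrow(merged), 0L)
  expect_equal(integrate_catalog(cat1, min_studies = 2)$gene, "b")
})

test_that("overlap percentages reproduce the screen's arithmetic", {
  prior <- sprintf("P%03d", 1:184)
  mine <- c(prior[1:143], sprintf("X%03d", 1:50))
  expect_equal(overlap_stats(mine, prior)$pct_of_b_in_a, 78)
  fa <- sprintf("F%03d", 1:175)
  expect_equal(overlap_stats(fa[1:8], fa)$pct_of_b_in_a, 5)
  expect_equal(overlap_stats(prior, prior)$pct_of_b_in_a, 100)
  expect_error(overlap_stats(prior, character(0)), "empty")
})

test_that("hypergeometric p-values hit their closed forms and limits", {
  genes <- sprintf("G%02d", 1:20)
  ann <- tibble::tibble(gene = genes[1:5], term = "T1")
  res <- enrich(genes[1:5], ann, genes)
  # all five draws marked: p = 1 / C(20,5)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  res0 <- enrich(genes[6:10], ann, genes)
  expect_equal(res0$k, 0L)
  expect_equal(res0$p, 1)
})

test_that("enrichment matches exhaustive subset enumeration to 12 digits", {
  cases <- list(c(k = 2, K = 5, n = 6, N = 15),
                c(k = 4, K = 7, n = 8, N = 18),
                c(k = 1, K = 3, n = 5, N = 25),
                c(k = 3, K = 4, n = 10, N = 20))
  for (cs in cases) {
    genes <- sprintf("G%02d", seq_len(cs["N"]))
    ann <- tibble::tibble(gene = genes[seq_len(cs["K"])], term = "T")
    gene_set <- c(genes[seq_len(cs["k"])],
                  if (cs["n"] > cs["k"]) genes[(cs["K"] + 1):(cs["K"] + cs["n"] - cs["k"])])
    res <- enrich(gene_set, ann, genes)
    oracle <- exhaustive_hyper_tail(cs["k"], cs["K"], cs["n"], cs["N"])
    expect_equal(res$p, oracle, tolerance = 1e-12)
  }
})

test_that("BH adjustment is monotone and a saturated term ranks first", {
  withr::with_seed(17, {
    genes <- sprintf("G%03d", 1:60)
    ann <- simulate_annotations(genes, n_terms = 8, seed = 17)
    target <- unique(ann$gene[ann$term == "T001"])
    res <- enrich(target, ann, genes)
  })
  expect_equal(res$term[1], "T001")
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(diff(res$p_adj[order(res$p)]) >= -1e-15))
})

test_that("network export dedupes undirected edges and drops strangers", {
  regs <- tibble::tibble(gene = c("A", "B", "C"), n_studies = c(2L, 3L, 2L),
                         validated_novel = FALSE)
  edges <- tibble::tibble(gene_a = c("a", "B", "B", "C", "Z"),
                          gene_b = c("b", "A", "a", "B", "A"))
  loc <- tibble::tibble(gene = c("A", "B"),
                        compartment = c("Peroxisome", "Nucleus"))
  net <- suppressMessages(export_network(regs, edges, loc))
  # (a,b) duplicates (B,A) after case folding; (Z,A) has an unknown endpoint
  expect_equal(nrow(net$edges), 2L)
  expect_equal(net$n_dropped_edges, 1L)
  expect_equal(net$compartment_counts[["Peroxisome"]], 1L)
  expect_equal(net$compartment_counts[["Unknown"]], 1L)
  empty <- export_network(regs, tibble::tibble(gene_a = character(0),
                                               gene_b = character(0)))
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(nrow(empty$nodes), 3L)
})

test_that("a toy catalog's regulator edges survive the restriction filter", {
  cat1 <- simulate_catalog(10, c(0.9, 0.9), seed = 8)
  regs <- integrate_catalog(cat1, 2)
  edges <- simulate_interactions(cat1$genes, n_edges = 12, seed = 8)
  net <- suppressMessages(export_network(regs, edges, known_genes = cat1$genes))
  manual <- sum(toupper(edges$gene_a) %in% toupper(regs$gene) &
                  toupper(edges$gene_b) %in% toupper(regs$gene))
  expect_equal(nrow(net$edges), manual)
})

test_that("SIF export lists every edge and isolated node", {
  regs <- c("A", "B", "C")
  net <- export_network(regs, tibble::tibble(gene_a = "A", gene_b = "B"))
  path <- tempfile(fileext = ".sif")
  write_sif(net, path)
  lines <- readLines(path)
  expect_equal(lines[1], "A pp B")
  expect_true("C" %in% lines)
})
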