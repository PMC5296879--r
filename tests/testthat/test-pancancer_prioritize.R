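make_cancer_ann <- function() {
  # 60-residue all-K protein, one acetylation site mid-protein; variants
  # from two cancers at controlled offsets
  ps <- protein_set(c(Q = paste(rep("K", 60), collapse = "")))
  st <- validate_sites(site_row("Q", 30, "acetylation"), ps)$sites
  v <- rbind(
    mk_collapsed("Q", 30, "K", "N", patients = list(cA = "p1")),
    mk_collapsed("Q", 28, "K", "N", patients = list(cA = "p2")),
    mk_collapsed("Q", 35, "K", "N", patients = list(cA = "p3")),
    mk_collapsed("Q", 33, "K", "N", patients = list(cB = "p4")))
  list(ann = annotate_neighborhood(v, st, ps), sites = st, proteome = ps)
}

test_that("pan-cancer cells are offset-0 occurrence over neighbor mean", {
  x <- make_cancer_ann()
  mat <- build_pancancer_matrix(x$ann, "non_SS")
  # cancer A: occurrence 1 at offset 0; neighbors: 2 hits over 40 slots
  expect_equal(mat["cA", "acetylation"], 1 / (2 / 40))
  # cancer B: no offset-0 variant, expected 1/40 -> cell 0
  expect_equal(mat["cB", "acetylation"], 0)
})

test_that("cells with an empty window are missing, not zero", {
  ps <- protein_set(c(Q = paste(rep("K", 60), collapse = "")))
  st <- validate_sites(rbind(site_row("Q", 30, "acetylation"),
                             site_row("Q", 55, "methylation")), ps)$sites
  v <- mk_collapsed("Q", 28, "K", "N", patients = list(cA = "p1"))
  mat <- build_pancancer_matrix(annotate_neighborhood(v, st, ps), "non_SS")
  expect_true(is.finite(mat["cA", "acetylation"]))
  expect_true(is.na(mat["cA", "methylation"]) ||
                !"methylation" %in% colnames(mat))
})

test_that("observed > 0 over expected 0 hits the capped sentinel", {
  ps <- protein_set(c(Q = paste(rep("K", 60), collapse = "")))
  st <- validate_sites(site_row("Q", 30, "acetylation"), ps)$sites
  v <- mk_collapsed("Q", 30, "K", "N", patients = list(cA = "p1"))
  mat <- build_pancancer_matrix(annotate_neighborhood(v, st, ps), "non_SS",
                                cap = 100)
  expect_equal(mat["cA", "acetylation"], 100)
  expect_equal(attr(mat, "capped")$do_slim, "cA")
})

test_that("clustering reproduces the worked three-row example", {
  m <- rbind(r1 = c(0, 0), r2 = c(0, 1), r3 = c(4, 4))
  hc <- hierarchical_cluster(m)
  expect_equal(hc$height, c(1, sqrt(32)))
  expect_equal(hclust_members(hc),
               list(c("r1", "r2"), c("r1", "r2", "r3")))
})

test_that("identical rows merge at height zero in label order", {
  m <- rbind(b = c(1, 1), a = c(1, 1), c = c(1, 1))
  hc <- hierarchical_cluster(m)
  expect_equal(hc$height, c(0, 0))
  expect_equal(hclust_members(hc)[[1]], c("a", "b"))
})

test_that("merge tree is invariant to row permutation and heights monotone", {
  set.seed(31)
  m <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("c", 1:5), paste0("s", 1:4)))
  hc <- hierarchical_cluster(m)
  expect_true(all(diff(hc$height) >= -1e-12))
  perm <- sample(5)
  hc2 <- hierarchical_cluster(m[perm, ])
  expect_equal(hclust_members(hc2), hclust_members(hc))
  expect_equal(hc2$height, hc$height)
})

test_that("clustering equals the brute-force agglomeration oracle", {
  set.seed(32)
  for (i in 1:10) {
    m <- matrix(rnorm(20), 5, 4,
                dimnames = list(paste0("k", sample(5)), NULL))
    hc <- hierarchical_cluster(m)
    o <- oracle_hclust(m)
    expect_equal(hclust_members(hc), o$members, info = i)
    expect_equal(hc$height, o$heights, info = i)
  }
})

test_that("newick export round-trips through ape", {
  m <- rbind(r1 = c(0, 0), r2 = c(0, 1), r3 = c(4, 4))
  s <- as_newick(hierarchical_cluster(m))
  phy <- ape::read.tree(text = s)
  expect_setequal(phy$tip.label, c("r1", "r2", "r3"))
})

test_that("multi-cancer selection respects the inclusive threshold", {
  v <- rbind(mk_collapsed("A", 1, "K", "N"),
             mk_collapsed("A", 2, "K", "N"),
             mk_collapsed("A", 3, "K", "N"))
  v$cancer_type_count <- c(31L, 4L, 5L)
  sel <- select_key_multi_cancer(v, min_types = 5)
  expect_equal(sel$cancer_type_count, c(31L, 5L))
  expect_equal(sel$criterion, rep("multi_cancer", 2))
  # lowering the threshold never removes a previously selected key
  sel3 <- select_key_multi_cancer(v, min_types = 3)
  expect_true(all(sel$key %in% sel3$key))
})

test_that("prioritization unions the two criteria with labels", {
  pats <- sprintf("q%03d", 1:27)
  v <- rbind(
    mk_collapsed("A", 1, "K", "N", patients = list(c1 = pats)),
    mk_collapsed("A", 2, "K", "N", patients = list(c1 = "p1")),
    mk_collapsed("A", 3, "K", "N", patients = list(c1 = "p2")))
  v$cancer_type_count <- c(2L, 6L, 1L)
  pr <- patient_enrichment(v, data.frame(do_slim = "c1", n_patients = 210L))
  keys <- prioritize_key_pfssnvs(v, pr, min_types = 5)
  expect_setequal(keys$criterion, c("patient_enriched", "multi_cancer"))
  enr <- keys[keys$criterion == "patient_enriched", ]
  expect_equal(enr$accession, "A")
  expect_equal(enr$position, 1L)
  expect_false(is.na(enr$best_p))
  expect_lt(enr$best_p, attr(keys, "cutoff"))
})

test_that("gene list intersection flags keys and summarizes genes", {
  v <- do.call(rbind, lapply(1:5, function(i)
    mk_collapsed("A", i, "K", "N", gene = paste0("g", i))))
  out <- intersect_gene_lists(v, smg = c("g1", "g2"), cgc = c("g2", "g3"))
  expect_equal(out$keys$in_smg, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$keys$in_cgc, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$summary$triple_genes, "g2")
  expect_setequal(out$summary$unmatched, c("g4", "g5"))
  empty <- intersect_gene_lists(v, character(0), character(0))
  expect_false(any(empty$keys$in_smg | empty$keys$in_cgc))
  expect_length(empty$summary$triple_genes, 0)
})
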