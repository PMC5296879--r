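test_that("global rate is distinct variants over proteome length", {
  ps <- protein_set(c(A = paste(rep("A", 60), collapse = ""),
                      B = paste(rep("K", 40), collapse = "")))
  v <- do.call(rbind, lapply(1:10, function(i)
    mk_collapsed("A", i, "A", "G")))
  expect_equal(global_snv_rate(v, ps, "non_SS"), 0.1)
  expect_equal(global_snv_rate(v, ps, "SS"), 0)
  expect_error(global_snv_rate(v, protein_set(character(0)), "non_SS"))
  # classes partition: per-class counts recovered from rates
  v2 <- rbind(v, mk_collapsed("B", 3, "K", "K", consequence = "synonymous"),
              mk_collapsed("B", 9, "K", "R", origin = "germline"))
  tot <- sum(vapply(c("non_SS", "SS", "non_SG", "SG"), function(cl)
    global_snv_rate(v2, ps, cl) * 100, numeric(1)))
  expect_equal(tot, nrow(v2))
})

test_that("percent of sites impacted counts distinct offset-0 positions", {
  ps <- protein_set(c(Q = paste(rep("S", 60), collapse = "")))
  st <- validate_sites(rbind(site_row("Q", 25, "phosphorylation"),
                             site_row("Q", 40, "phosphorylation")), ps)$sites
  v <- rbind(mk_collapsed("Q", 25, "S", "A"),
             mk_collapsed("Q", 25, "S", "G"),  # same site, still one position
             mk_collapsed("Q", 30, "S", "A"))  # neighbor only
  out <- percent_sites_impacted(annotate_neighborhood(v, st, ps), st)
  ph <- out[out$site_type == "phosphorylation", ]
  expect_equal(ph$percent[ph$class == "non_SS"], 50)
  expect_equal(ph$percent[ph$class == "SG"], 0)
  expect_true(all(out$percent >= 0 & out$percent <= 100))
})

test_that("profile counts, denominators and fold changes are definitional", {
  # one site mid-protein; counts at chosen offsets are hand-computable
  ps <- protein_set(c(Q = paste(rep("S", 60), collapse = "")))
  st <- validate_sites(site_row("Q", 30, "phosphorylation"), ps)$sites
  v <- rbind(mk_collapsed("Q", 30, "S", "A"),
             mk_collapsed("Q", 28, "S", "A"),
             mk_collapsed("Q", 35, "S", "G"))
  ann <- annotate_neighborhood(v, st, ps)
  rate <- global_snv_rate(v, ps, "non_SS")  # 3/60
  pr <- neighborhood_profile(ann, "non_SS", "phosphorylation", rate)
  tab <- pr$table
  expect_equal(tab$count[tab$offset == 0], 1)
  expect_equal(tab$count[tab$offset == -2], 1)
  expect_equal(tab$count[tab$offset == 5], 1)
  expect_equal(sum(tab$count), 3)                      # conservation
  expect_true(all(tab$denominator == 1))
  expect_equal(tab$fold_change[tab$offset == 0], 1 / rate / 1)
  expect_error(neighborhood_profile(ann, "non_SS", "phosphorylation", 0),
               "undefined")
})

test_that("offsets with zero denominator are omitted", {
  ps <- protein_set(c(Q = paste(rep("S", 30), collapse = "")))
  st <- validate_sites(site_row("Q", 1, "phosphorylation"), ps)$sites
  v <- mk_collapsed("Q", 1, "S", "A")
  ann <- annotate_neighborhood(v, st, ps)
  pr <- neighborhood_profile(ann, "non_SS", "phosphorylation", 0.05)
  expect_true(all(pr$table$offset >= 0))  # nothing upstream of position 1
})

test_that("one-sample t of neighbors vs site matches the closed form", {
  tab <- data.frame(offset = c(0, seq_len(40)),
                    fold_change = c(0.67, rep(c(0.8, 1.2), 20)))
  tt <- site_vs_neighbors_ttest(tab)
  s <- stats::sd(rep(c(0.8, 1.2), 20))
  expect_equal(tt$t, (1 - 0.67) / (s / sqrt(40)))
  expect_equal(tt$t, 10.30, tolerance = 1e-3)
  expect_equal(tt$df, 39)

  # symmetric null: neighbor mean equals the site value
  tab0 <- data.frame(offset = c(0, 1:40),
                     fold_change = c(1, rep(c(0.9, 1.1), 20)))
  tt0 <- site_vs_neighbors_ttest(tab0)
  expect_equal(tt0$t, 0)
  expect_equal(tt0$p, 1)

  # site above all neighbors -> negative t under the sign convention
  tabn <- data.frame(offset = c(0, 1:40),
                     fold_change = c(2, rep(c(0.9, 1.1), 20)))
  expect_lt(site_vs_neighbors_ttest(tabn)$t, 0)

  # degenerate zero-variance neighbors
  tabd <- data.frame(offset = c(0, 1:3), fold_change = c(1, 1, 1, 1))
  ttd <- site_vs_neighbors_ttest(tabd)
  expect_true(ttd$degenerate)
  expect_equal(ttd$p, 1)
  tabd2 <- data.frame(offset = c(0, 1:3), fold_change = c(2, 1, 1, 1))
  expect_equal(site_vs_neighbors_ttest(tabd2)$p, 0)
})

test_that("fold changes are invariant to duplicating every protein", {
  b <- simulate_bundle(null_config(seed = 9, n_proteins = 12))
  rec <- validate_snv_records(b$snv_rows, b$proteome)$accepted
  col <- collapse_variants(map_cancer_terms(rec, b$do_slim_map)$records)
  rate <- global_snv_rate(col, b$proteome, "non_SS")
  ann <- annotate_neighborhood(col, b$sites, b$proteome)
  pr <- neighborhood_profile(ann, "non_SS", "phosphorylation", rate)

  dup_seqs <- c(unclass(b$proteome),
                stats::setNames(unclass(b$proteome),
                                paste0(names(b$proteome), "_b")))
  ps2 <- protein_set(dup_seqs)
  col2 <- rbind(col, transform(col, accession = paste0(accession, "_b")))
  col2$key <- pfssnv:::variant_key(col2)
  sites2 <- rbind(b$sites, transform(b$sites,
                                     accession = paste0(accession, "_b")))
  rate2 <- global_snv_rate(col2, ps2, "non_SS")
  expect_equal(rate2, rate)
  pr2 <- neighborhood_profile(annotate_neighborhood(col2, sites2, ps2),
                              "non_SS", "phosphorylation", rate2)
  expect_equal(pr2$table$fold_change, pr$table$fold_change)
})
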