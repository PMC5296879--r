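test_that("tolerance-based effect calls follow the per-PTM rules", {
  expect_equal(classify_site_effect("phosphorylation", "S", "A"), "loss")
  expect_equal(classify_site_effect("phosphorylation", "S", "T"), "retained")
  expect_equal(classify_site_effect("ubiquitination", "K", "N"), "loss")
  # synonymous at the site is retained, never loss
  expect_equal(classify_site_effect("phosphorylation", "S", "S",
                                    consequence = "synonymous"), "retained")
  # binding/active sites: any substitution is a loss by default
  expect_equal(classify_site_effect("binding_site", "R", "H"), "loss")
  # ... unless a curated tolerance says otherwise
  expect_equal(classify_site_effect("binding_site", "R", "H",
                                    tolerated = "H,R"), "retained")
  # methylation is restricted to the reference acceptor residue
  expect_equal(classify_site_effect("methylation", "K", "R"), "loss")
  expect_error(classify_site_effect("glycation", "K", "A"),
               "no tolerance entry")
})

test_that("effect calls match the exhaustive substitution truth table", {
  tol <- default_tolerance()
  aa <- pfssnv:::AA20
  for (st in c("phosphorylation", "acetylation", "nitrosylation",
               "o_glycosylation", "active_site", "methylation")) {
    for (ref in aa) {
      alts <- setdiff(aa, ref)
      got <- classify_site_effect(st, ref, alts)
      tolerated <- fill_tolerated(st, ref, tol)
      expect_equal(got == "retained", alts %in% tolerated,
                   info = paste(st, ref))
    }
  }
})

test_that("sequon scan finds N-X(!P)-S/T starts", {
  expect_equal(scan_sequons("ANGSA"), 2L)
  expect_equal(scan_sequons("ANPSA"), integer(0))  # proline at X
  expect_equal(scan_sequons("NGS"), 1L)
  expect_equal(scan_sequons("NN"), integer(0))
  expect_equal(scan_sequons("NNST"), c(1L, 2L))
})

test_that("sequon effect calls honor each triplet position", {
  # P2 = ANGSAKRCYT has a sequon N(2)-G(3)-S(4)
  expect_equal(classify_sequon_effect("ANGSA", 2, 3, "P")$effect, "loss")
  expect_equal(classify_sequon_effect("ANGSA", 2, 4, "T")$effect, "retained")
  expect_equal(classify_sequon_effect("ANGSA", 2, 4, "A")$effect, "loss")
  expect_equal(classify_sequon_effect("ANGSA", 2, 2, "Q")$effect, "loss")
  expect_equal(classify_sequon_effect("ANGSA", 2, 3, "P")$sequon_role, "X1")
  expect_equal(classify_sequon_effect("ANGSA", 2, 4, "T")$sequon_role, "ST2")
  expect_error(classify_sequon_effect("ANGS", 3, 3, "Q"), "past the sequence")
  expect_error(classify_sequon_effect("ANGSA", 2, 6, "Q"), "outside")
})

test_that("sequon calls match an exhaustive per-position truth table", {
  seqn <- "ANGSA"
  aa <- pfssnv:::AA20
  for (off in 0:2) {
    for (alt in aa) {
      trip <- c("N", "G", "S")
      trip[off + 1] <- alt
      want <- trip[1] == "N" && trip[2] != "P" && trip[3] %in% c("S", "T")
      got <- classify_sequon_effect(seqn, 2, 2 + off, alt)$effect
      expect_equal(got == "retained", want, info = paste(off, alt))
    }
  }
})

test_that("gain-of-sequon detection only reports genuinely new sequons", {
  expect_equal(detect_gain_nglyc("AQGSA", 2, "N"), 2L)
  expect_equal(detect_gain_nglyc("ANGSA", 1, "N"), integer(0))
  expect_equal(detect_gain_nglyc("ANPSA", 3, "G"), 2L)
  # matches a full-sequence two-scan oracle on random cases
  set.seed(21)
  alpha <- c("A", "N", "P", "S", "T", "G", "K")
  for (i in 1:40) {
    s <- paste(sample(alpha, 12, TRUE), collapse = "")
    pos <- sample(12, 1)
    alt <- sample(alpha, 1)
    mut <- s
    substr(mut, pos, pos) <- alt
    expect_equal(detect_gain_nglyc(s, pos, alt),
                 setdiff(scan_sequons(mut), scan_sequons(s)),
                 info = paste(s, pos, alt))
  }
})

test_that("neighborhood annotation emits signed offsets within the window", {
  ps <- protein_set(c(
    Q1 = paste(rep("A", 50), collapse = "")))
  sites <- site_row("Q1", 25, "binding_site")
  v <- rbind(mk_collapsed("Q1", 5, "A", "G"),     # offset -20
             mk_collapsed("Q1", 46, "A", "G"),    # offset +21 -> excluded
             mk_collapsed("Q1", 45, "A", "G"),    # offset +20
             mk_collapsed("Q1", 25, "A", "G"))    # offset 0 -> loss
  st <- validate_sites(sites, ps)$sites
  ann <- annotate_neighborhood(v, st, ps)
  a <- ann$annotations
  expect_equal(sort(a$offset), c(-20L, 0L, 20L))
  expect_equal(a$effect[a$offset == 0], "loss")
  expect_true(all(a$effect[a$offset != 0] == "neighbor"))
  # denominators: site at 25 in a 50-residue protein covers every offset
  expect_true(all(ann$denominators$n_valid == 1))
})

test_that("sequon positions +1/+2 are attributed to the N-glyc site", {
  ps <- tiny_proteome()  # P2 = ANGSAKRCYT, sequon at 2
  st <- validate_sites(site_row("P2", 2, "n_glycosylation"), ps)$sites
  v <- rbind(mk_collapsed("P2", 3, "G", "P"),   # X -> P : loss
             mk_collapsed("P2", 4, "S", "T"),   # ST2 tolerant swap
             mk_collapsed("P2", 4, "S", "S", consequence = "synonymous"))
  ann <- annotate_neighborhood(v, st, ps)$annotations
  expect_equal(ann$effect[ann$variant_position == 3], "loss")
  expect_equal(ann$sequon_role[ann$variant_position == 3], "X1")
  expect_equal(ann$effect[ann$variant_position == 4],
               c("retained", "retained"))
  expect_equal(unique(ann$sequon_role[ann$variant_position == 4]), "ST2")
})

test_that("annotation count equals the sum over sites of in-window variants", {
  b <- simulate_bundle(null_config(seed = 5, n_proteins = 10))
  rec <- validate_snv_records(b$snv_rows, b$proteome)$accepted
  col <- collapse_variants(map_cancer_terms(rec, b$do_slim_map)$records)
  ann <- annotate_neighborhood(col, b$sites, b$proteome)
  col_ns <- col[col$consequence != "stop", ]
  expected <- sum(vapply(seq_len(nrow(b$sites)), function(i) {
    s <- b$sites[i, ]
    sum(col_ns$accession == s$accession &
          abs(col_ns$position - s$position) <= 20)
  }, numeric(1)))
  expect_equal(nrow(ann$annotations), expected)
  # every offset-0 loss call has alt outside the tolerated set
  a0 <- merge(ann$annotations[ann$annotations$offset == 0 &
                                ann$annotations$effect == "loss", ],
              b$sites, by.x = c("accession", "site_position", "site_type"),
              by.y = c("accession", "position", "site_type"))
  ok <- mapply(function(alt, tol)
    !alt %in% strsplit(tol, ",")[[1]], a0$alt_aa, a0$tolerated)
  expect_true(all(ok))
  # stop variants never annotate
  expect_false(any(ann$annotations$consequence == "stop"))
})

test_that("combined loss/gain set carries site_effect labels", {
  ps <- tiny_proteome()
  st <- validate_sites(site_row("P2", 6, "ubiquitination"), ps)$sites
  v <- rbind(mk_collapsed("P2", 6, "K", "N",
                          patients = list(c1 = "p1")),  # K->N loss
             mk_collapsed("P1", 2, "S", "A"))           # no site, no gain
  v$gain_of_phospho <- c(FALSE, TRUE)
  ann <- annotate_neighborhood(v, st, ps)
  pfs <- combine_pfs_set(ann, v, ps)
  expect_setequal(paste(pfs$site_type, pfs$site_effect),
                  c("ubiquitination loss", "phosphorylation gain"))
})
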