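# Seeded generator of synthetic proteomes, functional-site tables and
# SNV/patient tables with plantable depletion/enrichment structure.
#
# Default rates restate the scale of public pan-cancer compendia: per-residue
# variant rates are the published class totals over a ~11.3 Mres human
# proteome (non-synonymous somatic ~0.11/res, synonymous somatic ~0.042,
# non-synonymous germline ~0.083, synonymous germline ~0.048).

default_aa_freq <- function() {
  c(A = 0.070, R = 0.056, N = 0.036, D = 0.048, C = 0.023, Q = 0.048,
    E = 0.071, G = 0.066, H = 0.026, I = 0.043, L = 0.100, K = 0.057,
    M = 0.021, F = 0.037, P = 0.063, S = 0.083, T = 0.053, W = 0.012,
    Y = 0.027, V = 0.060)
}

default_site_rates <- function() {
  c(phosphorylation = 0.015, acetylation = 0.008, ubiquitination = 0.010,
    methylation = 0.004, crotonylation = 0.001, nitrosylation = 0.002,
    n_glycosylation = 0.25, o_glycosylation = 0.002,
    active_site = 0.0008, binding_site = 0.004)
}

default_class_rates <- function() {
  c(non_SS = 0.113, SS = 0.042, non_SG = 0.083, SG = 0.048)
}

default_cancers <- function() {
  data.frame(
    do_slim = c("DOID:1612/breast cancer", "DOID:1324/lung cancer",
                "DOID:9256/colorectal cancer", "DOID:1793/pancreatic cancer",
                "DOID:3571/liver cancer", "DOID:11054/urinary bladder cancer",
                "DOID:2531/hematologic cancer", "DOID:4159/skin cancer"),
    raw_term = c("Breast invasive carcinoma", "Lung adenocarcinoma",
                 "Colon adenocarcinoma", "Pancreatic ductal adenocarcinoma",
                 "Hepatocellular carcinoma", "Bladder urothelial carcinoma",
                 "Acute myeloid leukemia", "Cutaneous melanoma"),
    n_patients = c(300L, 250L, 220L, 210L, 150L, 120L, 130L, 100L),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' All randomness is fixed by `seed`; every generator stage derives its own
#' stream from it, so stages reproduce whether run separately or together.
#'
#' @param seed integer master seed.
#' @param n_proteins number of proteins.
#' @param length_mean,length_sd,length_min protein length distribution
#'   (normal, rounded, floored at `length_min`; must be >= 45 so a +/-20
#'   window plus a sequon fits).
#' @param aa_freq named amino-acid frequency vector (20 letters).
#' @param site_type_rates per-eligible-residue site probabilities; for
#'   `n_glycosylation` the rate applies to existing N-X(not P)-\[S/T\]
#'   sequon asparagines only.
#' @param class_rates per-residue rates of the four mutation classes.
#' @param stop_rates per-residue stop-gain rates, named somatic/germline.
#' @param effects named list: site type -> numeric vector of density
#'   multipliers named by offset (e.g. `list(acetylation = c("0" = 0.5))`);
#'   1.0 elsewhere. Multipliers of overlapping site neighborhoods compose
#'   multiplicatively (nearest site per type defines the offset).
#' @param cancers data.frame (do_slim, raw_term, n_patients).
#' @param per_patient_rate probability a given patient of a cancer carries a
#'   given somatic variant (background carriage).
#' @param planted_enriched list of plants: each a list(cancer, carriage,
#'   site_type = "phosphorylation", site_index = 1L) forcing a loss variant
#'   at the chosen site carried by Binomial(N_C, carriage) patients (>= 1).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_proteins = 300L,
                              length_mean = 450, length_sd = 150,
                              length_min = 60L,
                              aa_freq = default_aa_freq(),
                              site_type_rates = default_site_rates(),
                              class_rates = default_class_rates(),
                              stop_rates = c(somatic = 0.008,
                                             germline = 0.002),
                              effects = list(),
                              cancers = default_cancers(),
                              per_patient_rate = 5e-4,
                              planted_enriched = list()) {
  if (length_min < 45) stop("min length < 45 cannot fit a window plus sequon")
  if (n_proteins < 1) stop("n_proteins must be positive")
  stopifnot(all(class_rates >= 0 & class_rates <= 1),
            all(site_type_rates >= 0 & site_type_rates <= 1),
            per_patient_rate >= 0, per_patient_rate <= 1)
  if (any(vapply(effects, function(e) any(e < 0), logical(1))))
    stop("effect multipliers must be >= 0")
  aa_freq <- aa_freq / sum(aa_freq)
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 length_mean = length_mean, length_sd = length_sd,
                 length_min = as.integer(length_min), aa_freq = aa_freq,
                 site_type_rates = site_type_rates,
                 class_rates = class_rates, stop_rates = stop_rates,
                 effects = effects, cancers = cancers,
                 per_patient_rate = per_patient_rate,
                 planted_enriched = planted_enriched),
            class = "simulation_config")
}

stage_seed <- function(seed, stage) {
  off <- c(proteome = 11L, sites = 23L, snvs = 37L, bundle = 53L)[[stage]]
  (abs(as.integer(seed)) %% 21474L) * 100000L + off
}

#' Generate a synthetic proteome
#'
#' Residues are drawn i.i.d. from the configured amino-acid frequency
#' table; byte-identical output under the same seed.
#'
#' @param config a [simulation_config()].
#' @return a [protein_set()]; accessions `SYN00001`, ...
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stage_seed(config$seed, "proteome"))
  n <- config$n_proteins
  lens <- pmax(config$length_min,
               as.integer(round(stats::rnorm(n, config$length_mean,
                                             config$length_sd))))
  res <- sample(names(config$aa_freq), sum(lens), replace = TRUE,
                prob = config$aa_freq)
  fac <- rep.int(seq_len(n), lens)
  seqs <- vapply(split(res, fac), paste, character(1), collapse = "")
  names(seqs) <- sprintf("SYN%05d", seq_len(n))
  protein_set(seqs)
}

residue_table <- function(proteome) {
  lens <- nchar(unclass(proteome))
  data.table::data.table(
    accession = rep.int(names(proteome), lens),
    position = unlist(lapply(lens, seq_len), use.names = FALSE),
    aa = unlist(strsplit(unclass(proteome), "", fixed = TRUE),
                use.names = FALSE))
}

site_eligibility <- function(site_type, tolerance = default_tolerance()) {
  set <- tolerance[[site_type]]
  if (length(set) == 0) AA20 else set
}

#' Generate a synthetic functional-site table
#'
#' Each eligible residue becomes a site of type F with probability
#' `site_type_rates[F]`; eligibility follows the tolerance table (e.g. S/T/Y
#' for phosphorylation), and N-glycosylation sites are placed only on
#' asparagines of existing sequons. Tolerated sets are filled from defaults.
#'
#' @param proteome a [protein_set()].
#' @param config a [simulation_config()].
#' @return data.frame of sites (accession, position, site_type, source,
#'   ref_aa, tolerated).
#' @export
generate_sites <- function(proteome, config) {
  set.seed(stage_seed(config$seed, "sites"))
  rt <- residue_table(proteome)
  tol <- default_tolerance()
  out <- list()
  for (st in names(config$site_type_rates)) {
    rate <- config$site_type_rates[[st]]
    if (rate == 0) next
    if (st == "n_glycosylation") {
      lens <- nchar(unclass(proteome))
      elig <- do.call(rbind, lapply(names(proteome), function(acc) {
        p <- scan_sequons(unclass(proteome)[[acc]])
        p <- p[p + 2L <= lens[[acc]]]
        if (length(p) == 0) return(NULL)
        data.frame(accession = acc, position = p, aa = "N")
      }))
      if (is.null(elig)) next
    } else {
      elig <- as.data.frame(rt[rt$aa %in% site_eligibility(st, tol), ])
    }
    if (nrow(elig) == 0) next
    keep <- stats::rbinom(nrow(elig), 1L, rate) == 1L
    if (!any(keep)) next
    sel <- elig[keep, , drop = FALSE]
    out[[st]] <- data.frame(
      accession = sel$accession, position = sel$position, site_type = st,
      source = "synthetic", ref_aa = sel$aa,
      tolerated = vapply(sel$aa, function(r)
        paste(fill_tolerated(st, r, tol), collapse = ","), character(1)),
      stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, out)
  if (is.null(sites))
    sites <- data.frame(accession = character(0), position = integer(0),
                        site_type = character(0), source = character(0),
                        ref_aa = character(0), tolerated = character(0))
  sites <- sites[order(sites$accession, sites$position, sites$site_type), ]
  rownames(sites) <- NULL
  sites
}

# per-residue density multiplier from planted offset effects: for each
# affected site type, the offset to the NEAREST site of that type selects
# the multiplier; multipliers across types compose multiplicatively
effect_multipliers <- function(rt, sites, effects, window = 20L) {
  mult <- rep(1, nrow(rt))
  if (length(effects) == 0) return(mult)
  data.table::setkey(rt, accession, position)
  for (st in names(effects)) {
    eff <- effects[[st]]
    sp <- sites[sites$site_type == st, , drop = FALSE]
    if (nrow(sp) == 0) next
    offs <- seq.int(-window, window)
    nb <- data.table::data.table(
      accession = rep(sp$accession, each = length(offs)),
      position = rep(sp$position, each = length(offs)) + offs,
      offset = rep(offs, nrow(sp)))
    nb <- nb[position >= 1L]
    nb <- nb[order(accession, position, abs(offset), offset)]
    nb <- nb[!duplicated(nb, by = c("accession", "position"))]
    nb[, m := {
      mm <- eff[as.character(offset)]
      mm[is.na(mm)] <- 1
      mm
    }]
    j <- nb[rt, on = c("accession", "position")]
    mj <- j$m
    mj[is.na(mj)] <- 1
    mult <- mult * mj
  }
  mult
}

other_residue_matrix <- function() {
  m <- matrix("", 20, 19, dimnames = list(AA20, NULL))
  for (i in seq_along(AA20)) m[i, ] <- AA20[-i]
  m
}

#' Generate a synthetic SNV/patient table
#'
#' Per residue and mutation class a variant is emitted with probability
#' class rate times the composed planted multiplier. Non-synonymous
#' alternates are uniform over the 19 other residues; synonymous variants
#' are positional events with alt = ref (protein-level view, codons not
#' simulated); stop gains get alt `*`. Somatic variants acquire carriers
#' independently per cancer (Binomial(N_C, per_patient_rate); variants with
#' no carrier anywhere are assigned one patient in a cohort-size-weighted
#' cancer). Planted enriched variants are added as loss substitutions at
#' chosen sites with Binomial(N_C, carriage) carriers (at least 1). The
#' returned table is row-level (one row per variant x patient x source)
#' with raw cancer terms, ready for the reader/collapser.
#'
#' @param proteome a [protein_set()].
#' @param sites data.frame from [generate_sites()].
#' @param config a [simulation_config()].
#' @return list(snv_rows, do_slim_map, cohort, planted_keys).
#' @export
generate_snvs <- function(proteome, sites, config) {
  set.seed(stage_seed(config$seed, "snvs"))
  rt <- residue_table(proteome)
  mult <- effect_multipliers(rt, sites, config$effects)
  gene_of <- function(acc) sub("^SYN", "GENE", acc)
  others <- other_residue_matrix()
  cancers <- config$cancers
  nC <- nrow(cancers)

  vars <- list()
  for (cl in MUTATION_CLASSES) {
    p <- config$class_rates[[cl]] * mult
    if (any(p > 1)) stop("composed per-residue rate exceeds 1 for ", cl)
    hit <- which(stats::rbinom(length(p), 1L, p) == 1L)
    if (length(hit) == 0) next
    ref <- rt$aa[hit]
    syn <- cl %in% c("SS", "SG")
    alt <- if (syn) ref
    else others[cbind(match(ref, AA20),
                      sample.int(19L, length(hit), replace = TRUE))]
    vars[[cl]] <- data.frame(
      accession = rt$accession[hit], position = rt$position[hit],
      ref_aa = ref, alt_aa = alt,
      origin = if (cl %in% c("non_SS", "SS")) "somatic" else "germline",
      consequence = if (syn) "synonymous" else "non-synonymous",
      stringsAsFactors = FALSE)
  }
  for (org in names(config$stop_rates)) {
    p <- config$stop_rates[[org]]
    if (p <= 0) next
    hit <- which(stats::rbinom(nrow(rt), 1L, p) == 1L)
    if (length(hit) == 0) next
    vars[[paste0("stop_", org)]] <- data.frame(
      accession = rt$accession[hit], position = rt$position[hit],
      ref_aa = rt$aa[hit], alt_aa = STOP_AA, origin = org,
      consequence = "stop", stringsAsFactors = FALSE)
  }
  v <- do.call(rbind, vars)
  v <- v[!duplicated(v[, c("accession", "position", "ref_aa", "alt_aa",
                           "origin", "consequence")]), , drop = FALSE]

  # planted patient-enriched loss variants
  planted_keys <- character(0)
  for (pl in config$planted_enriched) {
    st <- if (is.null(pl$site_type)) "phosphorylation" else pl$site_type
    ix <- if (is.null(pl$site_index)) 1L else pl$site_index
    sp <- sites[sites$site_type == st, , drop = FALSE]
    if (nrow(sp) < ix) stop("not enough ", st, " sites to plant variant ", ix)
    s1 <- sp[ix, ]
    tolset <- strsplit(s1$tolerated, ",", fixed = TRUE)[[1]]
    alt <- setdiff(AA20, c(tolset, s1$ref_aa))[1]
    row <- data.frame(accession = s1$accession, position = s1$position,
                      ref_aa = s1$ref_aa, alt_aa = alt, origin = "somatic",
                      consequence = "non-synonymous",
                      stringsAsFactors = FALSE)
    dupkey <- paste(v$accession, v$position, v$ref_aa, v$alt_aa, v$origin)
    if (!paste(row$accession, row$position, row$ref_aa, row$alt_aa,
               row$origin) %in% dupkey)
      v <- rbind(v, row)
    planted_keys <- c(planted_keys, paste(
      row$accession, row$position, row$ref_aa, row$alt_aa,
      "non-synonymous", "somatic", sep = ":"))
  }

  som <- which(v$origin == "somatic" & v$consequence != "stop")
  # carriers per (somatic variant, cancer)
  kmat <- matrix(0L, nrow(v), nC)
  for (k in seq_len(nC))
    kmat[som, k] <- stats::rbinom(length(som), cancers$n_patients[k],
                                  config$per_patient_rate)
  for (i in seq_along(config$planted_enriched)) {
    pl <- config$planted_enriched[[i]]
    vi <- which(variant_key(v) == planted_keys[i])
    ck <- match(pl$cancer, cancers$do_slim)
    if (is.na(ck)) stop("planted cancer not in cohort: ", pl$cancer)
    kmat[vi, ck] <- max(1L, stats::rbinom(1L, cancers$n_patients[ck],
                                          pl$carriage))
  }
  orphan <- som[rowSums(kmat[som, , drop = FALSE]) == 0L]
  if (length(orphan) > 0) {
    ck <- sample.int(nC, length(orphan), replace = TRUE,
                     prob = cancers$n_patients)
    kmat[cbind(orphan, ck)] <- 1L
  }

  som_sources <- c("ICGC", "TCGA", "COSMIC")
  rows <- vector("list", 2L)
  cells <- which(kmat > 0L, arr.ind = TRUE)
  if (nrow(cells) > 0) {
    kvec <- kmat[cells]
    vi <- rep.int(cells[, 1L], kvec)
    ci <- rep.int(cells[, 2L], kvec)
    pid <- unlist(lapply(seq_len(nrow(cells)), function(r) {
      sample.int(cancers$n_patients[cells[r, 2L]], kmat[cells[r, 1L],
                                                        cells[r, 2L]])
    }), use.names = FALSE)
    rows[[1L]] <- data.frame(
      accession = v$accession[vi], position = v$position[vi],
      ref_aa = v$ref_aa[vi], alt_aa = v$alt_aa[vi],
      origin = v$origin[vi], consequence = v$consequence[vi],
      cancer_term = cancers$raw_term[ci],
      patient_id = sprintf("PT_%02d_%04d", ci, pid),
      source = sample(som_sources, length(vi), replace = TRUE),
      maf = NA_real_, gene = gene_of(v$accession[vi]),
      stringsAsFactors = FALSE)
  }
  germ <- which(v$origin == "germline" |
                  (v$origin == "somatic" & v$consequence == "stop"))
  # somatic stop gains are carried as patient-less rows in an "unknown" term
  if (length(germ) > 0) {
    is_g <- v$origin[germ] == "germline"
    rows[[2L]] <- data.frame(
      accession = v$accession[germ], position = v$position[germ],
      ref_aa = v$ref_aa[germ], alt_aa = v$alt_aa[germ],
      origin = v$origin[germ], consequence = v$consequence[germ],
      cancer_term = ifelse(is_g, NA_character_, "unknown primary"),
      patient_id = NA_character_,
      source = ifelse(is_g,
                      sample(c("dbSNP", "ClinVar"), length(germ),
                             replace = TRUE),
                      "COSMIC"),
      maf = ifelse(is_g,
                   signif(stats::rbeta(length(germ), 0.5, 10), 3),
                   NA_real_),
      gene = gene_of(v$accession[germ]), stringsAsFactors = FALSE)
  }
  snv_rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  snv_rows <- snv_rows[order(snv_rows$accession, snv_rows$position,
                             snv_rows$alt_aa, snv_rows$origin,
                             snv_rows$patient_id, snv_rows$source,
                             method = "radix"), ]
  rownames(snv_rows) <- NULL
  list(snv_rows = snv_rows,
       do_slim_map = data.frame(raw_term = cancers$raw_term,
                                do_slim = cancers$do_slim),
       cohort = cancers[, c("do_slim", "n_patients")],
       planted_keys = planted_keys)
}

#' Generate a full in-memory synthetic bundle
#' @param config a [simulation_config()].
#' @return list(proteome, sites, snv_rows, do_slim_map, cohort, planted_keys).
#' @export
simulate_bundle <- function(config) {
  proteome <- generate_proteome(config)
  sites <- generate_sites(proteome, config)
  snv <- generate_snvs(proteome, sites, config)
  c(list(proteome = proteome, sites = sites), snv)
}

#' Write a synthetic fixture bundle to disk
#'
#' Writes `proteome.fasta`, `sites.tsv`, `snvs.tsv`, `do_slim_map.tsv`,
#' `cohort.tsv`, `smg.txt`, `cgc.txt`, a `config.R` dump of the
#' configuration and a `manifest.tsv` of MD5 digests for byte-level
#' reproducibility checks. The synthetic SMG/CGC gene lists contain the
#' genes of planted variants plus the most-mutated background genes.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if absent).
#' @return invisible named vector of file paths.
#' @export
write_fixture_bundle <- function(config, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  b <- simulate_bundle(config)
  paths <- c(proteome = file.path(out_dir, "proteome.fasta"),
             sites = file.path(out_dir, "sites.tsv"),
             snvs = file.path(out_dir, "snvs.tsv"),
             do_map = file.path(out_dir, "do_slim_map.tsv"),
             cohort = file.path(out_dir, "cohort.tsv"),
             smg = file.path(out_dir, "smg.txt"),
             cgc = file.path(out_dir, "cgc.txt"),
             config = file.path(out_dir, "config.R"))
  write_proteome(b$proteome, paths["proteome"])
  write_site_table(b$sites[, c("accession", "position", "site_type",
                               "source", "tolerated")], paths["sites"])
  write_tsv_pfs(b$snv_rows, paths["snvs"])
  write_tsv_pfs(b$do_slim_map, paths["do_map"])
  write_tsv_pfs(b$cohort, paths["cohort"])
  tab <- sort(table(b$snv_rows$gene), decreasing = TRUE)
  top <- names(tab)[seq_len(min(10L, length(tab)))]
  planted_genes <- sub("^SYN", "GENE",
                       sub(":.*$", "", b$planted_keys))
  writeLines(sort(unique(c(planted_genes, top[1:5]))), paths["smg"])
  writeLines(sort(unique(c(planted_genes, top[3:8]))), paths["cgc"])
  dput(unclass(config), file = paths["config"])
  digests <- tools::md5sum(unname(paths))
  write_tsv_pfs(data.frame(file = basename(names(digests)),
                           md5 = unname(digests)),
                file.path(out_dir, "manifest.tsv"))
  invisible(c(paths, manifest = file.path(out_dir, "manifest.tsv")))
}
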