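# End-to-end driver tying the modules together, plus the command-line
# entry points used by exec/pfssnv.

#' Run the full functional-site SNV pipeline
#'
#' Reads a proteome, SNV table, site table and DO-slim mapping; validates
#' and collapses the variants; annotates site neighborhoods; and writes the
#' full set of result tables (rejections, annotations, impact percentages,
#' neighborhood profiles, amino-acid enrichment, pan-cancer matrices with
#' Newick trees, and — when a cohort table is given — patient-level
#' enrichment with the prioritized key pfsSNV list).
#'
#' @param proteome_path FASTA path.
#' @param snv_path,sites_path,do_map_path TSV paths.
#' @param out_dir output directory.
#' @param cohort_path optional TSV (do_slim, n_patients) enabling the
#'   patient-enrichment stage.
#' @param smg_path,cgc_path optional one-gene-per-line lists.
#' @param uniprot_headers passed to [read_proteome()].
#' @param window neighborhood half-width.
#' @param min_types multi-cancer key threshold.
#' @return invisible list of in-memory results.
#' @export
run_pipeline <- function(proteome_path, snv_path, sites_path, do_map_path,
                         out_dir, cohort_path = NULL, smg_path = NULL,
                         cgc_path = NULL, uniprot_headers = FALSE,
                         window = 20L, min_types = 5L) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  proteome <- read_proteome(proteome_path, uniprot_headers)
  snv <- read_snv_table(snv_path, proteome)
  if (nrow(snv$rejected) > 0)
    write_tsv_pfs(snv$rejected, file.path(out_dir, "snv_rejected.tsv"))
  st <- read_site_table(sites_path, proteome)
  if (nrow(st$rejected) > 0)
    write_tsv_pfs(st$rejected, file.path(out_dir, "sites_rejected.tsv"))
  mp <- map_cancer_terms(snv$accepted, read_do_slim_map(do_map_path))
  if (nrow(mp$unmapped) > 0)
    write_tsv_pfs(mp$unmapped, file.path(out_dir, "unmapped_terms.tsv"))
  collapsed <- collapse_variants(mp$records)
  ann <- annotate_neighborhood(collapsed, st$sites, proteome, window)
  write_annotations(ann, file.path(out_dir, "annotations.tsv"))
  write_tsv_pfs(percent_sites_impacted(ann, st$sites),
                file.path(out_dir, "impact_percent.tsv"))

  stypes <- sort(unique(st$sites$site_type))
  profiles <- list()
  for (cl in MUTATION_CLASSES) {
    rate <- global_snv_rate(collapsed, proteome, cl)
    if (rate <= 0) next
    for (s in stypes)
      profiles[[paste(s, cl)]] <- neighborhood_profile(ann, cl, s, rate)
  }
  if (length(profiles) > 0)
    write_profiles(profiles, file.path(out_dir, "profiles.tsv"),
                   file.path(out_dir, "profile_tests.tsv"))

  enr <- list()
  for (cl in MUTATION_CLASSES)
    for (s in stypes)
      enr[[paste(s, cl)]] <- aa_site_enrichment(collapsed, st$sites,
                                                proteome, s, cl)
  write_tsv_pfs(do.call(rbind, enr), file.path(out_dir, "aa_enrichment.tsv"))

  pc <- list()
  for (cl in c("non_SS", "SS")) {
    mat <- build_pancancer_matrix(ann, cl)
    if (nrow(mat) == 0) next
    pc[[cl]] <- mat
    write_pancancer_matrix(mat, file.path(out_dir,
                                          paste0("pancancer_", cl, ".tsv")))
    if (nrow(mat) >= 2)
      as_newick(hierarchical_cluster(mat),
                file.path(out_dir, paste0("pancancer_", cl, ".nwk")))
  }

  pfs <- combine_pfs_set(ann, collapsed, proteome)
  patres <- NULL
  if (!is.null(cohort_path) && nrow(pfs) > 0) {
    cohort <- as.data.frame(read_tsv_pfs(cohort_path))
    patres <- patient_enrichment(pfs, cohort)
    write_tsv_pfs(patres, file.path(out_dir, "patient_enrichment.tsv"))
    if (nrow(patres) > 0)
      write_tsv_pfs(manhattan_table(patres),
                    file.path(out_dir, "manhattan.tsv"))
  }
  keys <- prioritize_key_pfssnvs(pfs, patres, min_types = min_types)
  gsummary <- NULL
  if (!is.null(smg_path) || !is.null(cgc_path)) {
    smg <- if (is.null(smg_path)) character(0) else readLines(smg_path)
    cgc <- if (is.null(cgc_path)) character(0) else readLines(cgc_path)
    ig <- intersect_gene_lists(keys, smg, cgc)
    keys <- ig$keys
    gsummary <- ig$summary
    writeLines(c(paste("smg_genes:", paste(gsummary$smg_genes,
                                           collapse = ",")),
                 paste("cgc_genes:", paste(gsummary$cgc_genes,
                                           collapse = ",")),
                 paste("triple_genes:", paste(gsummary$triple_genes,
                                              collapse = ","))),
               file.path(out_dir, "gene_intersections.txt"))
  }
  kout <- keys
  kout$patients_by_cancer <- NULL
  write_tsv_pfs(kout, file.path(out_dir, "key_pfssnvs.tsv"))

  invisible(list(proteome = proteome, snv = snv, sites = st$sites,
                 collapsed = collapsed, annotations = ann,
                 profiles = profiles, pancancer = pc,
                 patient_enrichment = patres, keys = keys,
                 gene_summary = gsummary))
}

parse_cli_args <- function(args) {
  out <- list(flags = character(0), opts = list())
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        out$opts[[gsub("-", "_", key)]] <- args[i + 1L]
        i <- i + 2L
      } else {
        out$flags <- c(out$flags, gsub("-", "_", key))
        i <- i + 1L
      }
    } else {
      stop("unexpected argument: ", a)
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate --seed N --out DIR` (writes a fixture bundle),
#' `map --proteome FASTA --snv TSV --sites TSV --do-map TSV --out DIR`
#' (optional `--cohort`, `--smg`, `--cgc`, `--uniprot-headers`), and
#' `unify --old FASTA --new FASTA --annotations TSV --out TSV` (position
#' lift-over between sequence revisions; dropped/flagged items go to a
#' `.report.tsv` sidecar).
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly.
#' @export
pfssnv_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: pfssnv <simulate|map|unify> [options]")
    return(invisible(1L))
  }
  cmd <- args[1]
  pa <- parse_cli_args(args[-1])
  o <- pa$opts
  if (cmd == "simulate") {
    cfg <- simulation_config(seed = as.integer(o$seed %||% 1L),
                             n_proteins = as.integer(o$n_proteins %||% 300L))
    write_fixture_bundle(cfg, o$out %||% ".")
  } else if (cmd == "map") {
    run_pipeline(o$proteome, o$snv, o$sites, o$do_map,
                 o$out %||% ".", cohort_path = o$cohort,
                 smg_path = o$smg, cgc_path = o$cgc,
                 uniprot_headers = "uniprot_headers" %in% pa$flags)
  } else if (cmd == "unify") {
    old <- read_proteome(o$old)
    new <- read_proteome(o$new)
    items <- as.data.frame(read_tsv_pfs(o$annotations))
    out <- list(); rep <- list()
    for (acc in unique(items$accession)) {
      if (!acc %in% names(old) || !acc %in% names(new)) {
        sub <- items[items$accession == acc, , drop = FALSE]
        sub$reason <- "missing_sequence"
        rep[[acc]] <- sub
        next
      }
      pmap <- align_positions(unclass(old)[[acc]], unclass(new)[[acc]],
                              accession = acc)
      sub <- items[items$accession == acc, , drop = FALSE]
      lift <- lift_annotations(sub$position, pmap)
      m <- sub[match(lift$mapped$position_a, sub$position), , drop = FALSE]
      m$position <- lift$mapped$position_b
      m$mismatch_at_site <- lift$mapped$mismatch_at_site
      out[[acc]] <- m
      if (nrow(lift$dropped) > 0) {
        dsub <- sub[match(lift$dropped$position_a, sub$position), ,
                    drop = FALSE]
        dsub$reason <- lift$dropped$reason
        rep[[acc]] <- dsub
      }
    }
    if (length(out) > 0) write_tsv_pfs(do.call(rbind, out), o$out)
    if (length(rep) > 0)
      write_tsv_pfs(do.call(rbind, rep),
                    paste0(sub("\\.tsv$", "", o$out), ".report.tsv"))
  } else {
    message("unknown subcommand: ", cmd)
    return(invisible(1L))
  }
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
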