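# Loss/retained/gain effect calls for variants on functional sites and the
# N-glycosylation sequon, plus the +/-20 residue neighborhood join.

#' Default per-modification amino-acid tolerance table
#'
#' For each site type, the set of residues that can still carry the
#' function. Active sites, binding sites and `other` have an empty set,
#' meaning "reference residue only": any non-synonymous substitution is a
#' loss unless a curated tolerance is supplied. Methylation lists both K and
#' R because the two methyl-acceptor systems are chemically disjoint; the
#' per-site tolerated set is restricted to the reference residue (a K-site
#' does not tolerate R and vice versa), see [fill_tolerated()].
#'
#' @return named list of character vectors.
#' @export
default_tolerance <- function() {
  list(
    phosphorylation = c("S", "T", "Y"),
    acetylation     = "K",
    ubiquitination  = "K",
    crotonylation   = "K",
    methylation     = c("K", "R"),
    nitrosylation   = "C",
    n_glycosylation = "N",
    o_glycosylation = c("S", "T"),
    active_site     = character(0),
    binding_site    = character(0),
    other           = character(0)
  )
}

#' Read a user tolerance table
#'
#' Two tab-delimited columns: `site_type` and comma-separated `tolerated`
#' residues. Entries override the defaults; unlisted types keep defaults.
#'
#' @param path TSV path.
#' @return tolerance list as in [default_tolerance()].
#' @export
read_tolerance_table <- function(path) {
  df <- as.data.frame(read_tsv_pfs(path))
  if (!all(c("site_type", "tolerated") %in% names(df)))
    stop("tolerance table needs columns site_type and tolerated")
  tol <- default_tolerance()
  for (i in seq_len(nrow(df)))
    tol[[df$site_type[i]]] <- sort(unique(
      toupper(strsplit(df$tolerated[i], ",")[[1]])))
  tol
}

#' Per-site tolerated residue set
#'
#' Fills the tolerated set for a site from the tolerance table given the
#' reference residue. Falls back to `{ref}` when the reference residue is
#' not an eligible carrier (curation noise) and restricts methylation to the
#' reference residue.
#'
#' @param site_type site type string.
#' @param ref_aa reference residue at the site.
#' @param tolerance tolerance table.
#' @return character vector of residues.
#' @export
fill_tolerated <- function(site_type, ref_aa, tolerance = default_tolerance()) {
  if (!site_type %in% names(tolerance))
    stop("no tolerance entry for site type ", site_type)
  set <- tolerance[[site_type]]
  if (site_type == "methylation") return(ref_aa)
  if (length(set) == 0 || !ref_aa %in% set) return(ref_aa)
  sort(set)
}

#' Classify the effect of a substitution at a functional site
#'
#' Vectorized over rows. A non-synonymous substitution is a `loss` when the
#' alternate residue falls outside the tolerated set (it can no longer be
#' modified or carry the function), `retained` otherwise. Synonymous
#' variants are always `retained` (counted in occurrence statistics, never
#' as loss).
#'
#' @param site_type character vector of site types.
#' @param ref_aa,alt_aa single-letter residue vectors.
#' @param consequence `synonymous` or `non-synonymous` (default).
#' @param tolerated optional character vector of comma-joined per-site
#'   tolerated sets; derived from `tolerance` when `NA`.
#' @param tolerance tolerance table.
#' @return character vector, `loss` or `retained`.
#' @export
classify_site_effect <- function(site_type, ref_aa, alt_aa,
                                 consequence = "non-synonymous",
                                 tolerated = NA_character_,
                                 tolerance = default_tolerance()) {
  n <- max(length(site_type), length(ref_aa), length(alt_aa))
  site_type <- rep_len(site_type, n)
  ref_aa <- rep_len(ref_aa, n)
  alt_aa <- rep_len(alt_aa, n)
  consequence <- rep_len(consequence, n)
  tolerated <- rep_len(tolerated, n)
  unknown <- setdiff(unique(site_type), names(tolerance))
  if (length(unknown) > 0)
    stop("no tolerance entry for site type ", unknown[1])
  vapply(seq_len(n), function(i) {
    if (consequence[i] == "synonymous") return("retained")
    set <- if (!is.na(tolerated[i]) && nzchar(tolerated[i]))
      strsplit(tolerated[i], ",", fixed = TRUE)[[1]]
    else fill_tolerated(site_type[i], ref_aa[i], tolerance)
    if (alt_aa[i] %in% set) "retained" else "loss"
  }, character(1))
}

is_sequon_triplet <- function(n0, x1, st2) {
  n0 == "N" & x1 != "P" & (st2 == "S" | st2 == "T")
}

#' Scan a sequence for N-glycosylation sequons
#'
#' Returns every position `p` such that the triplet starting at `p` matches
#' N-X-\[S/T\] with X any residue except proline.
#'
#' @param sequence amino-acid string.
#' @return integer vector of sequon start positions.
#' @export
scan_sequons <- function(sequence) {
  n <- nchar(sequence)
  if (n < 3) return(integer(0))
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  p <- seq_len(n - 2L)
  p[is_sequon_triplet(ch[p], ch[p + 1L], ch[p + 2L])]
}

#' Effect of a substitution on an N-glycosylation sequon
#'
#' Evaluates the post-substitution triplet against N-X(not P)-\[S/T\] for a
#' variant at the asparagine (`N0`), the X position (`X1`) or the S/T
#' position (`ST2`).
#'
#' @param sequence reference protein sequence.
#' @param site_pos 1-based position of the glycosylated asparagine.
#' @param variant_pos variant position; must be `site_pos`, `+1` or `+2`.
#' @param alt_aa alternate residue (use the reference residue for a
#'   synonymous variant).
#' @return list with `effect` (`loss`/`retained`) and `sequon_role`.
#' @export
classify_sequon_effect <- function(sequence, site_pos, variant_pos, alt_aa) {
  off <- variant_pos - site_pos
  if (!off %in% 0:2)
    stop("variant at offset ", off, " is outside the sequon")
  if (site_pos + 2L > nchar(sequence))
    stop("sequon at position ", site_pos, " runs past the sequence end")
  trip <- strsplit(substr(sequence, site_pos, site_pos + 2L), "")[[1]]
  trip[off + 1L] <- alt_aa
  list(effect = if (is_sequon_triplet(trip[1], trip[2], trip[3]))
    "retained" else "loss",
    sequon_role = c("N0", "X1", "ST2")[off + 1L])
}

#' Sequons gained by a substitution
#'
#' Scans the reference and the mutated sequence for N-X(not P)-\[S/T\]
#' triplets; gained sequons are start positions present only in the mutated
#' scan. Only triplets overlapping the variant position can appear.
#'
#' @param sequence reference protein sequence.
#' @param position variant position.
#' @param alt_aa alternate residue.
#' @return integer vector of gained sequon start positions.
#' @export
detect_gain_nglyc <- function(sequence, position, alt_aa) {
  # only triplets overlapping the variant can change; scanning the local
  # window is equivalent to a full-sequence scan-and-subtract
  lo <- max(1L, position - 2L)
  hi <- min(nchar(sequence), position + 4L)
  ref_win <- substr(sequence, lo, hi)
  mut_win <- ref_win
  substr(mut_win, position - lo + 1L, position - lo + 1L) <- alt_aa
  gained <- setdiff(scan_sequons(mut_win), scan_sequons(ref_win)) + lo - 1L
  gained[gained >= position - 2L & gained <= position]
}

#' Join variants to functional sites and their neighborhoods
#'
#' Emits one annotation per (site, variant) pair on the same protein with
#' signed offset `variant_position - site_position` in `[-window, window]`.
#' A variant may annotate several sites. Effects: `loss`/`retained` at
#' offset 0 via the tolerance rules (sequon rules for N-glycosylation, which
#' also cover offsets +1/+2 with `sequon_role` recorded), `neighbor`
#' elsewhere. Stop-gain variants are excluded from the join (tabulated
#' upstream, not analyzed). The per-(site type, offset) count of valid
#' residues is retained as the denominator table for occurrence statistics.
#'
#' @param variants data.frame from [collapse_variants()].
#' @param sites data.frame of validated functional sites.
#' @param proteome a [protein_set()].
#' @param window neighborhood half-width in residues.
#' @param tolerance tolerance table.
#' @return object of class `pfs_annotations`: list(annotations,
#'   denominators, window).
#' @export
annotate_neighborhood <- function(variants, sites, proteome, window = 20L,
                                  tolerance = default_tolerance()) {
  stopifnot(window >= 1L)
  v <- variants[variants$consequence != "stop", , drop = FALSE]
  sdt <- data.table::as.data.table(
    sites[, c("accession", "position", "site_type", "tolerated")])
  data.table::setnames(sdt, "position", "site_position")
  vcols <- intersect(c("accession", "position", "ref_aa", "alt_aa",
                       "consequence", "origin", "do_slims", "n_patients",
                       "cancer_type_count", "gene", "key"), names(v))
  vdt <- data.table::as.data.table(v[, vcols])
  data.table::setnames(vdt, "position", "variant_position")

  ann <- merge(sdt, vdt, by = "accession", allow.cartesian = TRUE)
  if (nrow(ann) > 0) {
    ann[, offset := variant_position - site_position]
    ann <- ann[abs(offset) <= window]
  } else {
    ann[, offset := integer(0)]
  }

  ann[, `:=`(effect = "neighbor", sequon_role = "none")]
  if (nrow(ann) > 0) {
    at0 <- ann$offset == 0L & ann$site_type != "n_glycosylation"
    if (any(at0)) {
      ann$effect[at0] <- classify_site_effect(
        ann$site_type[at0], ann$ref_aa[at0], ann$alt_aa[at0],
        ann$consequence[at0], ann$tolerated[at0], tolerance)
    }
    seqn <- ann$site_type == "n_glycosylation" & ann$offset %in% 0:2
    if (any(seqn)) {
      idx <- which(seqn)
      seqs <- unclass(proteome)[ann$accession[idx]]
      for (j in seq_along(idx)) {
        i <- idx[j]
        alt <- if (ann$consequence[i] == "synonymous") ann$ref_aa[i]
        else ann$alt_aa[i]
        r <- classify_sequon_effect(seqs[j], ann$site_position[i],
                                    ann$variant_position[i], alt)
        ann$effect[i] <- r$effect
        ann$sequon_role[i] <- r$sequon_role
      }
    }
  }
  ann[, tolerated := NULL]
  data.table::setorderv(ann, c("accession", "site_position", "site_type",
                               "variant_position", "origin"))

  plen <- nchar(unclass(proteome))
  names(plen) <- names(proteome)
  offs <- seq.int(-window, window)
  stypes <- sort(unique(sites$site_type))
  den <- do.call(rbind, lapply(stypes, function(st) {
    sp <- sites[sites$site_type == st, , drop = FALSE]
    L <- plen[sp$accession]
    data.frame(site_type = st, offset = offs,
               n_valid = vapply(offs, function(o) {
                 sum(sp$position + o >= 1L & sp$position + o <= L)
               }, numeric(1)))
  }))
  structure(list(annotations = as.data.frame(ann),
                 denominators = den, window = as.integer(window)),
            class = "pfs_annotations")
}

#' @export
print.pfs_annotations <- function(x, ...) {
  cat("pfs_annotations:", nrow(x$annotations), "site-variant pairs within +/-",
      x$window, "residues\n")
  eff <- table(x$annotations$effect)
  cat(paste(names(eff), eff, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write neighborhood annotations to TSV
#' @param ann a `pfs_annotations` object.
#' @param path output path.
#' @export
write_annotations <- function(ann, path) {
  write_tsv_pfs(ann$annotations, path)
}

#' Build the combined loss/gain pfsSNV set for prioritization
#'
#' Key pfsSNVs combine variants that cause a loss of an annotated site
#' (offset-0 or sequon loss calls) with variants that create a new site: a
#' gained N-glycosylation sequon detected deterministically, or a gain of
#' phosphorylation accepted from the precomputed `gain_of_phospho` input
#' column (external predictor output, never computed here).
#'
#' @param ann a `pfs_annotations` object.
#' @param variants collapsed variants (for gain scanning).
#' @param proteome a [protein_set()].
#' @return data.frame of variants with `site_type` and `site_effect`
#'   (`loss` or `gain`) columns; one row per (variant, site type, effect).
#' @export
combine_pfs_set <- function(ann, variants, proteome) {
  a <- ann$annotations
  losses <- a[a$effect == "loss", , drop = FALSE]
  out <- list()
  if (nrow(losses) > 0) {
    ldt <- data.table::as.data.table(losses)
    l <- as.data.frame(ldt[, list(site_type = site_type[1]),
                           by = c("key", "site_type")])[, c("key", "site_type")]
    l <- unique(l)
    out$loss <- data.frame(key = l$key, site_type = l$site_type,
                           site_effect = "loss", stringsAsFactors = FALSE)
  }
  ns <- variants[variants$consequence == "non-synonymous" &
                   variants$alt_aa %in% AA20, , drop = FALSE]
  if (nrow(ns) > 0) {
    gained <- vapply(seq_len(nrow(ns)), function(i) {
      length(detect_gain_nglyc(unclass(proteome)[[ns$accession[i]]],
                               ns$position[i], ns$alt_aa[i])) > 0
    }, logical(1))
    if (any(gained))
      out$gain_ng <- data.frame(key = ns$key[gained],
                                site_type = "n_glycosylation",
                                site_effect = "gain",
                                stringsAsFactors = FALSE)
  }
  if ("gain_of_phospho" %in% names(variants)) {
    gp <- variants$gain_of_phospho %in% c(TRUE, "TRUE", "true", "1")
    if (any(gp))
      out$gain_ph <- data.frame(key = variants$key[gp],
                                site_type = "phosphorylation",
                                site_effect = "gain",
                                stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(key = character(0), site_type = character(0),
                      site_effect = character(0)))
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  merge(res, variants, by = "key", sort = TRUE)
}
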