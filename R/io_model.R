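# Domain types and readers/writers for the protein-coordinate variant pipeline.
#
# All coordinates are 1-based, inclusive, protein space. Genomic coordinates
# never enter the package.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET_PFS <- c(AA20, "X")
STOP_AA <- "*"

SNV_REQUIRED_COLS <- c("accession", "position", "ref_aa", "alt_aa",
                       "origin", "consequence", "cancer_term",
                       "patient_id", "source")
SNV_OPTIONAL_COLS <- c("do_slim", "maf", "gene", "gain_of_phospho")

#' Construct a protein set
#'
#' A `ProteinSet` is a named character vector of uppercase amino-acid
#' sequences (20 standard letters plus `X`), names being unique accessions.
#'
#' @param sequences named character vector of sequences.
#' @return a `ProteinSet`.
#' @export
protein_set <- function(sequences) {
  if (length(sequences) == 0) stop("empty protein set")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("all sequences must be named by accession")
  dup <- names(sequences)[duplicated(names(sequences))]
  if (length(dup) > 0)
    stop("duplicate accession ", dup[1])
  sequences <- toupper(sequences)
  if (any(nchar(sequences) < 1)) stop("zero-length sequence present")
  bad <- grepl(paste0("[^", paste(AA_ALPHABET_PFS, collapse = ""), "]"),
               sequences)
  if (any(bad))
    stop("sequence for ", names(sequences)[bad][1],
         " contains characters outside the amino-acid alphabet")
  structure(sequences, class = "ProteinSet")
}

#' @export
print.ProteinSet <- function(x, ...) {
  cat("ProteinSet with", length(x), "proteins,",
      sum(nchar(x)), "residues\n")
  invisible(x)
}

#' Read a proteome FASTA file
#'
#' Accessions are taken as the first whitespace-delimited token of each
#' header; with `uniprot_headers = TRUE`, pipe-delimited UniProt headers
#' (`>sp|P04637|P53_HUMAN`) use the second pipe field instead.
#'
#' @param path path to a FASTA file.
#' @param uniprot_headers parse `db|ACC|ID` headers and keep `ACC`.
#' @return a [protein_set()].
#' @export
read_proteome <- function(path, uniprot_headers = FALSE) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA file: ", path)
  acc <- sub("\\s.*$", "", names(seqs))
  if (uniprot_headers) {
    piped <- grepl("|", acc, fixed = TRUE)
    acc[piped] <- vapply(strsplit(acc[piped], "|", fixed = TRUE),
                         function(f) f[min(2L, length(f))], character(1))
  }
  s <- as.character(seqs)
  names(s) <- acc
  protein_set(s)
}

#' Write a proteome to FASTA
#' @param proteome a [protein_set()].
#' @param path output path.
#' @export
write_proteome <- function(proteome, path) {
  x <- Biostrings::AAStringSet(unclass(proteome))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

read_tsv_pfs <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty table: ", path)
  data.table::fread(text = lines, sep = "\t", header = TRUE,
                    na.strings = c("", "NA"), data.table = TRUE,
                    showProgress = FALSE)
}

write_tsv_pfs <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Read and validate a protein-coordinate SNV table
#'
#' Expects a tab-delimited file with header columns `accession`, `position`,
#' `ref_aa`, `alt_aa`, `origin` (somatic|germline), `consequence`
#' (synonymous|non-synonymous|stop), `cancer_term`, `patient_id`, `source`,
#' and optional `do_slim`, `maf`, `gene`, `gain_of_phospho`. Rows failing
#' validation against the proteome are returned in a rejection report with a
#' reason code, never silently dropped.
#'
#' @param path TSV path (lines starting with `#` are ignored).
#' @param proteome a [protein_set()] the rows are validated against.
#' @return list with elements `accepted` (data.frame of SNV records),
#'   `rejected` (data.frame with a `reason` column) and `n_input`.
#' @export
read_snv_table <- function(path, proteome) {
  dt <- read_tsv_pfs(path)
  miss <- setdiff(SNV_REQUIRED_COLS, names(dt))
  if (length(miss) > 0)
    stop("SNV table missing required columns: ", paste(miss, collapse = ", "))
  validate_snv_records(as.data.frame(dt), proteome)
}

#' Validate SNV records against a proteome
#'
#' @param df data.frame with the SNV table columns.
#' @param proteome a [protein_set()].
#' @return list(accepted, rejected, n_input); `rejected` carries a `reason`
#'   code among `BAD_POSITION`, `UNKNOWN_ACCESSION`, `OUT_OF_RANGE`,
#'   `REF_MISMATCH`, `BAD_ORIGIN`, `BAD_CONSEQUENCE`, `CONSEQUENCE_MISMATCH`.
#' @export
validate_snv_records <- function(df, proteome) {
  n_input <- nrow(df)
  for (col in SNV_OPTIONAL_COLS)
    if (!col %in% names(df)) df[[col]] <- NA
  df$position <- suppressWarnings(as.integer(as.character(df$position)))
  df$ref_aa <- toupper(as.character(df$ref_aa))
  df$alt_aa <- toupper(as.character(df$alt_aa))
  for (col in c("accession", "origin", "consequence", "cancer_term",
                "patient_id", "source"))
    df[[col]] <- as.character(df[[col]])

  reason <- rep(NA_character_, n_input)
  flag <- function(cond, code) {
    reason[is.na(reason) & cond] <<- code
  }
  flag(is.na(df$position) | df$position < 1L, "BAD_POSITION")
  flag(!df$accession %in% names(proteome), "UNKNOWN_ACCESSION")
  len <- rep(NA_integer_, n_input)
  known <- df$accession %in% names(proteome)
  len[known] <- nchar(unclass(proteome)[df$accession[known]])
  flag(!is.na(len) & !is.na(df$position) & df$position > len, "OUT_OF_RANGE")
  flag(!df$origin %in% c("somatic", "germline"), "BAD_ORIGIN")
  flag(!df$consequence %in% c("synonymous", "non-synonymous", "stop"),
       "BAD_CONSEQUENCE")
  ok <- is.na(reason)
  seq_ref <- rep(NA_character_, n_input)
  seq_ref[ok] <- substr(unclass(proteome)[df$accession[ok]],
                        df$position[ok], df$position[ok])
  flag(ok & seq_ref != df$ref_aa, "REF_MISMATCH")
  flag(df$consequence == "synonymous" & df$ref_aa != df$alt_aa,
       "CONSEQUENCE_MISMATCH")
  flag(df$consequence == "non-synonymous" & df$ref_aa == df$alt_aa,
       "CONSEQUENCE_MISMATCH")
  flag(df$consequence == "stop" & df$alt_aa != STOP_AA,
       "CONSEQUENCE_MISMATCH")

  canon <- c(SNV_REQUIRED_COLS, SNV_OPTIONAL_COLS)
  df <- df[, c(canon, setdiff(names(df), canon)), drop = FALSE]
  keep <- is.na(reason)
  rejected <- df[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(accepted = df[keep, , drop = FALSE],
       rejected = rejected,
       n_input = n_input)
}

#' Write SNV records to TSV
#' @param records data.frame of SNV records.
#' @param path output path.
#' @export
write_snv_table <- function(records, path) {
  cols <- intersect(c(SNV_REQUIRED_COLS, SNV_OPTIONAL_COLS), names(records))
  write_tsv_pfs(records[, cols, drop = FALSE], path)
}

#' Read a raw-term to DO-slim mapping table
#'
#' Two tab-delimited columns `raw_term` and `do_slim`; many raw terms may map
#' to one slim term, but a raw term mapped to two different slims is an error.
#'
#' @param path TSV path.
#' @return data.frame with columns `raw_term`, `do_slim`.
#' @export
read_do_slim_map <- function(path) {
  m <- as.data.frame(read_tsv_pfs(path))
  if (!all(c("raw_term", "do_slim") %in% names(m)))
    stop("DO-slim mapping needs columns raw_term and do_slim")
  m <- unique(m[, c("raw_term", "do_slim")])
  dup <- m$raw_term[duplicated(m$raw_term)]
  if (length(dup) > 0)
    stop("raw term mapped to multiple DO-slim terms: ", dup[1])
  m
}

#' Unify cancer terms to DO Cancer Slim vocabulary
#'
#' Fills `do_slim` for somatic records from the raw `cancer_term`; terms
#' absent from the mapping go to the `"unmapped"` bucket and are listed in
#' the report. Germline records keep `do_slim` empty.
#'
#' @param records data.frame of accepted SNV records.
#' @param mapping data.frame from [read_do_slim_map()].
#' @return list(records, unmapped) where `unmapped` tallies unmapped raw terms.
#' @export
map_cancer_terms <- function(records, mapping) {
  dup <- mapping$raw_term[duplicated(mapping$raw_term)]
  if (length(dup) > 0)
    stop("raw term mapped to multiple DO-slim terms: ", dup[1])
  slim <- mapping$do_slim[match(records$cancer_term, mapping$raw_term)]
  som <- records$origin == "somatic"
  records$do_slim <- NA_character_
  records$do_slim[som] <- ifelse(is.na(slim[som]), "unmapped", slim[som])
  un <- records$cancer_term[som & is.na(slim)]
  unmapped <- if (length(un) > 0) {
    as.data.frame(table(raw_term = un), responseName = "n_records",
                  stringsAsFactors = FALSE)
  } else {
    data.frame(raw_term = character(0), n_records = integer(0))
  }
  list(records = records, unmapped = unmapped)
}

#' Collapse per-report SNV rows into unique variants
#'
#' Grouping key is (accession, position, ref_aa, alt_aa, consequence,
#' origin); source strings are unioned and patient identifiers accumulated
#' per DO-slim cancer term, so per-variant patient frequency stays
#' recoverable.
#'
#' @param records data.frame of validated, term-mapped SNV records.
#' @return data.frame of collapsed variants with `sources` (comma-joined),
#'   `patients_by_cancer` (list column: named list of patient vectors),
#'   `do_slims`, `cancer_type_count`, `n_patients`, `gene` and a string `key`.
#' @export
collapse_variants <- function(records) {
  cols <- c("accession", "position", "ref_aa", "alt_aa", "consequence",
            "origin")
  empty <- data.frame(accession = character(0), position = integer(0),
                      ref_aa = character(0), alt_aa = character(0),
                      consequence = character(0), origin = character(0),
                      sources = character(0), do_slims = character(0),
                      cancer_type_count = integer(0),
                      n_patients = integer(0), gene = character(0),
                      key = character(0))
  empty$patients_by_cancer <- list()
  if (nrow(records) == 0) return(empty)
  for (col in c("do_slim", "patient_id", "gene"))
    if (!col %in% names(records)) records[[col]] <- NA_character_
  dt <- data.table::as.data.table(
    records[, c(cols, "source", "do_slim", "patient_id", "gene")])
  data.table::setorderv(dt, cols)
  dt[, gid := .GRP, by = cols]
  ng <- dt$gid[nrow(dt)]
  out <- as.data.frame(unique(dt[, c(cols, "gid"), with = FALSE]))

  out$sources <- group_concat(dt$source, dt$gid, ng)
  out$do_slims <- group_concat(dt$do_slim[!is.na(dt$do_slim)],
                               dt$gid[!is.na(dt$do_slim)], ng)

  has_p <- !is.na(dt$patient_id) & nzchar(dt$patient_id) &
    !is.na(dt$do_slim)
  pdt <- unique(dt[has_p, c("gid", "do_slim", "patient_id"), with = FALSE])
  pbc <- rep(list(stats::setNames(list(), character(0))), ng)
  n_patients <- integer(ng)
  cancer_type_count <- integer(ng)
  if (nrow(pdt) > 0) {
    data.table::setorderv(pdt, c("gid", "do_slim", "patient_id"))
    k2 <- paste(pdt$gid, pdt$do_slim, sep = "\r")
    sp <- split(pdt$patient_id, factor(k2, levels = unique(k2)))
    meta <- do.call(rbind, strsplit(names(sp), "\r", fixed = TRUE))
    gset <- split(sp, factor(meta[, 1], levels = unique(meta[, 1])))
    gslim <- split(meta[, 2], factor(meta[, 1], levels = unique(meta[, 1])))
    gids <- as.integer(names(gset))
    pbc[gids] <- Map(stats::setNames, gset, gslim)
    cancer_type_count[gids] <- lengths(gset)
    np <- pdt[, list(n = length(unique(patient_id))), by = "gid"]
    n_patients[np$gid] <- np$n
  }
  out$patients_by_cancer <- pbc[out$gid]
  out$cancer_type_count <- cancer_type_count[out$gid]
  out$n_patients <- n_patients[out$gid]

  gtab <- dt[!is.na(gene), c("gid", "gene"), with = FALSE]
  gtab <- gtab[!duplicated(gtab$gid), ]
  gvec <- rep(NA_character_, ng)
  gvec[gtab$gid] <- gtab$gene
  out$gene <- gvec[out$gid]
  out$gid <- NULL
  out$key <- variant_key(out)
  rownames(out) <- NULL
  out
}

# per-group sorted-unique comma concatenation; values must be grouped by gid
group_concat <- function(values, gid, n_groups) {
  out <- character(n_groups)
  if (length(values) == 0) return(out)
  sp <- split(values, factor(gid, levels = seq_len(n_groups)))
  one <- lengths(sp) == 1L
  out[one] <- unlist(sp[one], use.names = FALSE)
  multi <- which(lengths(sp) > 1L)
  out[multi] <- vapply(sp[multi], function(v)
    paste(sort(unique(v)), collapse = ","), character(1))
  out
}

variant_key <- function(v) {
  paste(v$accession, v$position, v$ref_aa, v$alt_aa, v$consequence,
        v$origin, sep = ":")
}

#' Expand collapsed variants back to per-report rows
#'
#' Inverse of [collapse_variants()] up to row order: one row per
#' (source, cancer, patient) combination for somatic variants, one row per
#' source for germline variants. Collapsing the expansion reproduces the
#' input aggregates.
#'
#' @param collapsed data.frame from [collapse_variants()].
#' @return data.frame of SNV records.
#' @export
expand_variants <- function(collapsed) {
  rows <- lapply(seq_len(nrow(collapsed)), function(i) {
    v <- collapsed[i, ]
    srcs <- strsplit(v$sources, ",", fixed = TRUE)[[1]]
    pbc <- v$patients_by_cancer[[1]]
    if (length(pbc) == 0) {
      slims <- strsplit(v$do_slims, ",", fixed = TRUE)[[1]]
      if (length(slims) == 0) slims <- NA_character_
      base <- data.frame(do_slim = slims,
                         patient_id = NA_character_,
                         stringsAsFactors = FALSE)
    } else {
      base <- data.frame(
        do_slim = rep(names(pbc), lengths(pbc)),
        patient_id = unlist(pbc, use.names = FALSE),
        stringsAsFactors = FALSE)
      extra <- setdiff(strsplit(v$do_slims, ",", fixed = TRUE)[[1]],
                       names(pbc))
      if (length(extra) > 0)
        base <- rbind(base, data.frame(do_slim = extra,
                                       patient_id = NA_character_))
    }
    base <- base[rep(seq_len(nrow(base)), each = length(srcs)), ,
                 drop = FALSE]
    base$source <- rep(srcs, length.out = nrow(base))
    data.frame(accession = v$accession, position = v$position,
               ref_aa = v$ref_aa, alt_aa = v$alt_aa,
               origin = v$origin, consequence = v$consequence,
               cancer_term = base$do_slim, do_slim = base$do_slim,
               patient_id = base$patient_id, source = base$source,
               gene = v$gene, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mutation class of a variant
#'
#' The four analyzed classes cross origin with (non-)synonymous consequence:
#' `non_SS`/`SS` somatic, `non_SG`/`SG` germline. Stop-gain records fall
#' outside the classes and return `NA`.
#'
#' @param origin character vector, `somatic` or `germline`.
#' @param consequence character vector.
#' @return character vector of class labels.
#' @export
mutation_class <- function(origin, consequence) {
  cls <- rep(NA_character_, length(origin))
  cls[origin == "somatic" & consequence == "non-synonymous"] <- "non_SS"
  cls[origin == "somatic" & consequence == "synonymous"] <- "SS"
  cls[origin == "germline" & consequence == "non-synonymous"] <- "non_SG"
  cls[origin == "germline" & consequence == "synonymous"] <- "SG"
  cls
}

MUTATION_CLASSES <- c("non_SS", "SS", "non_SG", "SG")

#' Read and validate a functional-site table
#'
#' Tab-delimited columns `accession`, `position`, `site_type`, `source` and
#' optional `tolerated` (comma-separated residues). Missing tolerance sets
#' are filled from the default per-modification tolerance table; the
#' reference residue is always included. Duplicate (accession, position,
#' site_type) entries are merged with sources unioned. N-glycosylation sites
#' whose sequon would run past the protein end are rejected as malformed.
#'
#' @param path TSV path.
#' @param proteome a [protein_set()].
#' @param tolerance tolerance table, see [default_tolerance()].
#' @return list(sites, rejected).
#' @export
read_site_table <- function(path, proteome, tolerance = default_tolerance()) {
  df <- as.data.frame(read_tsv_pfs(path))
  need <- c("accession", "position", "site_type", "source")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("site table missing required columns: ", paste(miss, collapse = ", "))
  if (!"tolerated" %in% names(df)) df$tolerated <- NA_character_
  validate_sites(df, proteome, tolerance)
}

validate_sites <- function(df, proteome, tolerance = default_tolerance()) {
  df$position <- suppressWarnings(as.integer(as.character(df$position)))
  reason <- rep(NA_character_, nrow(df))
  flag <- function(cond, code) reason[is.na(reason) & cond] <<- code
  flag(is.na(df$position) | df$position < 1L, "BAD_POSITION")
  flag(!df$accession %in% names(proteome), "UNKNOWN_ACCESSION")
  len <- rep(NA_integer_, nrow(df))
  known <- df$accession %in% names(proteome)
  len[known] <- nchar(unclass(proteome)[df$accession[known]])
  flag(!is.na(len) & !is.na(df$position) & df$position > len, "OUT_OF_RANGE")
  flag(!df$site_type %in% names(tolerance), "UNKNOWN_SITE_TYPE")
  flag(df$site_type == "n_glycosylation" & !is.na(len) &
         !is.na(df$position) & df$position + 2L > len, "MALFORMED_SEQUON")
  ok <- is.na(reason)
  ref <- rep(NA_character_, nrow(df))
  ref[ok] <- substr(unclass(proteome)[df$accession[ok]],
                    df$position[ok], df$position[ok])
  tol <- df$tolerated
  fill <- ok & (is.na(tol) | !nzchar(tol))
  tol[fill] <- vapply(which(fill), function(i) {
    paste(fill_tolerated(df$site_type[i], ref[i], tolerance), collapse = ",")
  }, character(1))
  # curated sets must still tolerate the reference residue
  cur <- ok & !fill
  if (any(cur)) {
    tol[cur] <- vapply(which(cur), function(i) {
      set <- unique(c(strsplit(toupper(tol[i]), ",")[[1]], ref[i]))
      paste(sort(set), collapse = ",")
    }, character(1))
  }
  df$ref_aa <- ref
  df$tolerated <- tol
  rejected <- df[!ok, , drop = FALSE]
  rejected$reason <- reason[!ok]
  sites <- df[ok, , drop = FALSE]
  if (nrow(sites) > 0) {
    dt <- data.table::as.data.table(sites)
    sites <- as.data.frame(dt[, list(
      source = paste(sort(unique(source)), collapse = ","),
      ref_aa = ref_aa[1],
      tolerated = paste(sort(unique(unlist(strsplit(tolerated, ",")))),
                        collapse = ",")),
      by = c("accession", "position", "site_type")])
    sites <- sites[order(sites$accession, sites$position, sites$site_type), ]
    rownames(sites) <- NULL
  }
  list(sites = sites, rejected = rejected)
}

#' Write a functional-site table to TSV
#' @param sites data.frame of sites.
#' @param path output path.
#' @export
write_site_table <- function(sites, path) {
  write_tsv_pfs(sites, path)
}
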