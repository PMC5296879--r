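# Small in-code fixtures shared across test files.

tiny_proteome <- function() {
  protein_set(c(P1 = "MSTK", P2 = "ANGSAKRCYT"))
}

# a 3-protein set with enough room for +/-20 windows
window_proteome <- function() {
  set.seed(42)
  protein_set(c(
    W1 = paste(sample(c("A", "G", "L", "S", "K", "N", "T", "R"), 80,
                      replace = TRUE), collapse = ""),
    W2 = paste(sample(c("A", "G", "L", "S", "K", "N", "T", "R"), 60,
                      replace = TRUE), collapse = "")))
}

snv_row <- function(accession, position, ref, alt, origin = "somatic",
                    consequence = "non-synonymous", cancer_term = "BRCA",
                    patient_id = "pt1", source = "TCGA", gene = NA) {
  data.frame(accession = accession, position = position, ref_aa = ref,
             alt_aa = alt, origin = origin, consequence = consequence,
             cancer_term = cancer_term, patient_id = patient_id,
             source = source, gene = gene, stringsAsFactors = FALSE)
}

site_row <- function(accession, position, site_type, source = "curated",
                     tolerated = NA_character_) {
  data.frame(accession = accession, position = position,
             site_type = site_type, source = source, tolerated = tolerated,
             stringsAsFactors = FALSE)
}

# collapsed single variant without going through the reader
mk_collapsed <- function(accession, position, ref, alt,
                         consequence = "non-synonymous", origin = "somatic",
                         patients = list(), gene = NA_character_) {
  df <- data.frame(accession = accession, position = as.integer(position),
                   ref_aa = ref, alt_aa = alt, consequence = consequence,
                   origin = origin, sources = "TCGA",
                   do_slims = paste(names(patients), collapse = ","),
                   cancer_type_count = length(patients),
                   n_patients = length(unique(unlist(patients))),
                   gene = gene, stringsAsFactors = FALSE)
  df$patients_by_cancer <- list(patients)
  df$key <- paste(accession, position, ref, alt, consequence, origin,
                  sep = ":")
  df
}

write_tmp_tsv <- function(df) {
  f <- tempfile(fileext = ".tsv")
  data.table::fwrite(df, f, sep = "\t", na = "", quote = FALSE)
  f
}

null_config <- function(seed = 1, n_proteins = 40, length_mean = 250,
                        ...) {
  simulation_config(seed = seed, n_proteins = n_proteins,
                    length_mean = length_mean, length_sd = 60,
                    length_min = 60, ...)
}
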