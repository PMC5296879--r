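# Binomial enrichment statistics: amino-acid-background site enrichment and
# patient-level per-cancer enrichment, with Bonferroni family-wise control.

#' Exact binomial tail p-value
#'
#' Returns the probability of an outcome at least as extreme as `observed`
#' under Binomial(N, p): the upper tail P(X >= observed) when the
#' observation exceeds the expectation N*p, the lower tail P(X <= observed)
#' when below, and the smaller of the two tails (capped at 1) at exact
#' equality. Tails are exact summations of binomial mass (no normal
#' approximation).
#'
#' @param observed non-negative integer vector, `observed <= N`.
#' @param N integer vector of trial counts.
#' @param p success probability in \[0, 1\].
#' @return numeric vector of p-values in (0, 1\].
#' @export
binomial_tail <- function(observed, N, p) {
  if (any(observed != round(observed)) || any(N != round(N)))
    stop("observed and N must be integers")
  if (any(observed < 0 | N < 0 | observed > N))
    stop("need 0 <= observed <= N")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  n <- max(length(observed), length(N), length(p))
  observed <- rep_len(observed, n); N <- rep_len(N, n); p <- rep_len(p, n)
  upper <- stats::pbinom(observed - 1, N, p, lower.tail = FALSE)
  lower <- stats::pbinom(observed, N, p)
  expd <- N * p
  out <- ifelse(observed > expd, upper,
                ifelse(observed < expd, lower, pmin(1, pmin(upper, lower))))
  unname(out)
}

#' Amino-acid-background binomial enrichment of pfsSNV occurrence
#'
#' For each reference amino acid A: `L_A` is its count in the proteome,
#' `n_A_F` the number of type-F site positions on residue A, giving the
#' amino-acid-based site rate `p_A_F = n_A_F / L_A`. With `N_A` variants of
#' the class having reference residue A and `n_A_O` of them landing on
#' type-F sites, the expected count is `n_A_E = N_A * p_A_F` and the
#' binomial tail of `n_A_O` against Binomial(N_A, p_A_F) measures the
#' deviation between expected and observed ratios. Each site type thus gets
#' its own background reflecting the amino-acid composition of its donor
#' residues.
#'
#' @param variants data.frame from [collapse_variants()].
#' @param sites validated site table.
#' @param proteome a [protein_set()].
#' @param site_type site type F.
#' @param class mutation class.
#' @return data.frame (amino_acid, L_A, n_A_F, p_A_F, N_A, n_A_O, n_A_E,
#'   direction, p_value); amino acids with `N_A = 0` are skipped and listed
#'   in the `skipped` attribute.
#' @export
aa_site_enrichment <- function(variants, sites, proteome, site_type, class) {
  seqs <- unclass(proteome)
  res <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]]
  L <- table(factor(res, levels = AA20))

  sp <- unique(sites[sites$site_type == site_type,
                     c("accession", "position", "ref_aa")])
  if (nrow(sp) == 0) stop("no sites of type ", site_type)
  nF <- table(factor(sp$ref_aa, levels = AA20))

  v <- filter_class(variants, class)
  NA_ <- table(factor(v$ref_aa, levels = AA20))
  hit <- merge(v, sp[, c("accession", "position")],
               by = c("accession", "position"))
  nO <- table(factor(hit$ref_aa, levels = AA20))

  keep <- as.integer(NA_) > 0 & as.integer(L) > 0
  skipped <- AA20[!keep]
  aa <- AA20[keep]
  p_AF <- as.numeric(nF[aa]) / as.numeric(L[aa])
  N_A <- as.integer(NA_[aa])
  n_O <- as.integer(nO[aa])
  n_E <- N_A * p_AF
  out <- data.frame(amino_acid = aa, site_type = site_type, class = class,
                    L_A = as.integer(L[aa]), n_A_F = as.integer(nF[aa]),
                    p_A_F = p_AF, N_A = N_A, n_A_O = n_O, n_A_E = n_E,
                    direction = ifelse(n_O > n_E, "enriched", "depleted"),
                    p_value = binomial_tail(n_O, N_A, p_AF))
  attr(out, "skipped") <- skipped
  out
}

count_patients_in <- function(variants, cancer) {
  vapply(variants$patients_by_cancer, function(pbc) {
    if (cancer %in% names(pbc)) length(pbc[[cancer]]) else 0L
  }, integer(1))
}

#' Patient-level binomial enrichment of pfsSNVs within cancers
#'
#' For every (variant M, cancer C) pair with at least one carrier, tests
#' whether the number of patients `n_C_O` harboring M among the `N_C`
#' patients of C exceeds the expected per-patient pfsSNV carriage. The
#' expected probability `p_C` is, per cancer (`p_c_method = "within_cancer"`,
#' default), the mean per-variant per-patient carriage rate across all
#' tested variants in C — total carriage events divided by `N_C` times the
#' number of distinct variants observed in C — which absorbs differences in
#' per-cancer mutational rate. The alternative `"global"` pools carriage
#' over all cancers. The p-value is the exact binomial tail of `n_C_O`
#' against Binomial(N_C, p_C).
#'
#' @param variants somatic collapsed variants (typically the combined
#'   loss/gain pfsSNV set) with populated `patients_by_cancer`.
#' @param cohort data.frame (do_slim, n_patients) giving total cohort sizes.
#' @param cancers cancers to test; default all in `cohort` with carriers.
#' @param p_c_method `"within_cancer"` or `"global"`.
#' @return data.frame (key, do_slim, N_C, n_C_O, p_C, n_C_E, direction,
#'   p_value) with one row per test; `n_tests` attribute carries the family
#'   size for [bonferroni_cutoff()].
#' @export
patient_enrichment <- function(variants, cohort, cancers = NULL,
                               p_c_method = c("within_cancer", "global")) {
  p_c_method <- match.arg(p_c_method)
  if (is.null(cancers)) cancers <- cohort$do_slim
  v <- variants[variants$origin == "somatic", , drop = FALSE]
  counts <- lapply(cancers, function(cc) count_patients_in(v, cc))
  names(counts) <- cancers
  N_C <- cohort$n_patients[match(cancers, cohort$do_slim)]
  if (anyNA(N_C) || any(N_C < 1))
    stop("cohort size missing or zero for cancer ",
         cancers[is.na(N_C) | N_C < 1][1])
  p_global <- {
    tot <- sum(unlist(counts))
    den <- sum(vapply(seq_along(cancers), function(k) {
      N_C[k] * sum(counts[[k]] > 0)
    }, numeric(1)))
    if (den > 0) tot / den else NA_real_
  }
  rows <- lapply(seq_along(cancers), function(k) {
    nco <- counts[[k]]
    sel <- nco > 0
    if (!any(sel)) return(NULL)
    p_C <- if (p_c_method == "within_cancer")
      sum(nco[sel]) / (N_C[k] * sum(sel)) else p_global
    n_E <- N_C[k] * p_C
    data.frame(key = v$key[sel], gene = v$gene[sel],
               accession = v$accession[sel], position = v$position[sel],
               ref_aa = v$ref_aa[sel], alt_aa = v$alt_aa[sel],
               do_slim = cancers[k], N_C = N_C[k], n_C_O = nco[sel],
               p_C = p_C, n_C_E = n_E,
               direction = ifelse(nco[sel] > n_E, "enriched", "depleted"),
               p_value = binomial_tail(nco[sel], N_C[k], p_C),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(key = character(0), gene = character(0),
                      accession = character(0), position = integer(0),
                      ref_aa = character(0), alt_aa = character(0),
                      do_slim = character(0), N_C = integer(0),
                      n_C_O = integer(0), p_C = numeric(0),
                      n_C_E = numeric(0), direction = character(0),
                      p_value = numeric(0))
  rownames(out) <- NULL
  attr(out, "n_tests") <- nrow(out)
  out
}

#' Bonferroni family-wise significance threshold
#'
#' @param n_tests number of tests in the family (here: all variant-by-cancer
#'   tests performed in the run).
#' @param alpha family-wise error rate.
#' @return per-test threshold `alpha / n_tests`.
#' @export
bonferroni_cutoff <- function(n_tests, alpha = 0.05) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1)
    stop("n_tests must be a positive integer")
  alpha / n_tests
}

#' Manhattan-style table of patient enrichment results
#'
#' One row per test with a protein index on the x axis and -log10(p) on the
#' y axis, mirroring a per-variant significance scatter.
#'
#' @param results data.frame from [patient_enrichment()].
#' @param cutoff significance threshold drawn as `significant` flag.
#' @return data.frame (protein_index, key, do_slim, neg_log10_p, significant).
#' @export
manhattan_table <- function(results, cutoff = bonferroni_cutoff(
  max(1L, attr(results, "n_tests")))) {
  acc <- sort(unique(results$accession))
  data.frame(protein_index = match(results$accession, acc),
             key = results$key, do_slim = results$do_slim,
             neg_log10_p = -log10(pmax(results$p_value,
                                       .Machine$double.xmin)),
             significant = results$p_value < cutoff)
}
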