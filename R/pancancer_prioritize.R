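# Pan-cancer observed/expected fold-change matrix, deterministic
# hierarchical clustering, and the two-criterion key-pfsSNV selection.

#' Pan-cancer fold-change matrix
#'
#' One row per DO-slim cancer term, one column per site type. Per cell:
#' observed = offset-0 occurrence (count / valid residues) of that cancer's
#' variants of the class; expected = mean occurrence over the 40 neighbor
#' offsets; cell = observed / expected. Cells whose full window holds no
#' variants are missing (`NA`), never 0. Cells with expected 0 but observed
#' > 0 are set to a capped sentinel and reported via the `capped` attribute.
#'
#' @param ann a `pfs_annotations` object (annotations must carry `do_slims`).
#' @param class mutation class (somatic classes are the meaningful choice).
#' @param cap sentinel value for observed > 0 over expected 0.
#' @return numeric matrix of class `pancancer_matrix`, attributes `class_label`
#'   and `capped` (data.frame of capped cells).
#' @export
build_pancancer_matrix <- function(ann, class, cap = 100) {
  a <- filter_class(ann$annotations, class)
  a <- a[!is.na(a$do_slims) & nzchar(a$do_slims), , drop = FALSE]
  idx <- rep(seq_len(nrow(a)), lengths(strsplit(a$do_slims, ",")))
  ex <- a[idx, c("site_type", "offset"), drop = FALSE]
  ex$do_slim <- unlist(strsplit(a$do_slims, ","), use.names = FALSE)
  cancers <- sort(unique(ex$do_slim))
  stypes <- sort(unique(ann$denominators$site_type))
  mat <- matrix(NA_real_, length(cancers), length(stypes),
                dimnames = list(cancers, stypes))
  capped <- list()
  den <- ann$denominators
  for (st in stypes) {
    d <- den[den$site_type == st & den$n_valid > 0, ]
    for (cc in cancers) {
      sub <- ex[ex$do_slim == cc & ex$site_type == st, ]
      if (nrow(sub) == 0) next  # no variants in window -> missing
      cnt <- table(factor(sub$offset, levels = d$offset))
      occ <- as.integer(cnt) / d$n_valid
      obs <- occ[d$offset == 0L]
      expd <- mean(occ[d$offset != 0L])
      if (length(obs) == 0) next
      if (expd == 0) {
        if (obs > 0) {
          mat[cc, st] <- cap
          capped[[paste(cc, st)]] <- data.frame(do_slim = cc, site_type = st,
                                                observed = obs)
        }
        next
      }
      mat[cc, st] <- obs / expd
    }
  }
  structure(mat, class = c("pancancer_matrix", "matrix", "array"),
            class_label = class,
            capped = if (length(capped) > 0) do.call(rbind, capped)
            else NULL)
}

#' Write a pan-cancer matrix to TSV (missing cells left blank)
#' @param mat matrix from [build_pancancer_matrix()].
#' @param path output path.
#' @export
write_pancancer_matrix <- function(mat, path) {
  df <- data.frame(do_slim = rownames(mat), as.data.frame(unclass(mat)),
                   check.names = FALSE)
  write_tsv_pfs(df, path)
}

#' Deterministic agglomerative hierarchical clustering of matrix rows
#'
#' Euclidean distance, complete linkage by default. Missing cells are
#' imputed as 1.0 (no fold change) for the distance computation only. At
#' every step the pair of clusters at minimal distance is merged; exact ties
#' are broken by the lexicographically smallest pair of cluster labels
#' (a cluster is labelled by its lexicographically smallest member), so the
#' merge tree is invariant to input row order.
#'
#' @param mat numeric matrix with row names (e.g. a `pancancer_matrix`).
#' @param linkage `complete`, `single` or `average`.
#' @return an object of class `hclust` (fields `merge`, `height`, `order`,
#'   `labels`), usable with [stats::cutree()], [plot()] and [as_newick()].
#' @export
hierarchical_cluster <- function(mat, linkage = "complete") {
  linkage <- match.arg(linkage, c("complete", "single", "average"))
  m <- as.matrix(unclass(mat))
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  m[is.na(m)] <- 1.0
  labels <- rownames(m)
  n <- nrow(m)
  if (n < 1) stop("need at least one row")
  if (n == 1) {
    hc <- list(merge = matrix(integer(0), 0, 2), height = numeric(0),
               order = 1L, labels = labels, method = linkage,
               dist.method = "euclidean")
    class(hc) <- "hclust"
    return(hc)
  }
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf
  # active clusters: id (negative singleton / positive merge index),
  # representative label, member row indices
  id <- -seq_len(n)
  rep_lab <- labels
  sizes <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  active <- rep(TRUE, n)
  pos <- seq_len(n)            # column index in d for each cluster slot
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    best <- NULL
    for (ii in act) for (jj in act) {
      if (ii >= jj) next
      dij <- d[ii, jj]
      if (is.null(best) || dij < best$d - 1e-12 ||
          (abs(dij - best$d) <= 1e-12 && {
            pa <- sort(c(rep_lab[ii], rep_lab[jj]))
            pb <- sort(c(rep_lab[best$i], rep_lab[best$j]))
            pa[1] < pb[1] || (pa[1] == pb[1] && pa[2] < pb[2])
          })) {
        best <- list(i = ii, j = jj, d = dij)
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- best$d
    # complete/single/average linkage update, cluster j absorbed into i
    for (k in act) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <- switch(linkage,
        complete = max(d[i, k], d[j, k]),
        single = min(d[i, k], d[j, k]),
        average = (sizes[i] * d[i, k] + sizes[j] * d[j, k]) /
          (sizes[i] + sizes[j]))
    }
    active[j] <- FALSE
    id[i] <- step
    sizes[i] <- sizes[i] + sizes[j]
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
  }
  hc <- list(merge = merge, height = height,
             order = order_from_merge(merge, n),
             labels = labels, method = linkage, dist.method = "euclidean")
  class(hc) <- "hclust"
  hc
}

order_from_merge <- function(merge, n) {
  leaves <- function(k) {
    if (k < 0) return(-k)
    c(leaves(merge[k, 1]), leaves(merge[k, 2]))
  }
  if (n == 1) return(1L)
  as.integer(leaves(nrow(merge)))
}

#' Export a clustering as a Newick string
#' @param hc an `hclust` object.
#' @param path optional file to write to.
#' @return the Newick string, invisibly when written to a file.
#' @export
as_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  s <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Select key pfsSNVs present across many cancer types
#'
#' Keeps variants observed in at least `min_types` distinct DO-slim cancer
#' types, sorted by descending count then key.
#'
#' @param pfs_variants data.frame of pfsSNV-annotated collapsed variants
#'   with a `cancer_type_count` column.
#' @param min_types inclusive threshold ("5 or more cancer types").
#' @return filtered, sorted data.frame with a `criterion` column.
#' @export
select_key_multi_cancer <- function(pfs_variants, min_types = 5L) {
  sel <- pfs_variants[pfs_variants$cancer_type_count >= min_types, ,
                      drop = FALSE]
  sel <- sel[order(-sel$cancer_type_count, sel$key), , drop = FALSE]
  if (nrow(sel) > 0) sel$criterion <- "multi_cancer"
  else sel$criterion <- character(0)
  rownames(sel) <- NULL
  sel
}

#' Two-criterion prioritization of key pfsSNVs
#'
#' Unions (a) variants present in `min_types` or more cancer types and (b)
#' variants enriched in patients of at least one cancer below the Bonferroni
#' cutoff over all tests performed; variants satisfying both carry
#' `criterion = "both"`.
#'
#' @param pfs_variants combined loss/gain pfsSNV set (see
#'   [combine_pfs_set()]) with `cancer_type_count`.
#' @param patient_results data.frame from [patient_enrichment()], or NULL to
#'   apply the multi-cancer criterion alone.
#' @param min_types multi-cancer threshold.
#' @param alpha family-wise error rate for the Bonferroni cutoff.
#' @return data.frame of key pfsSNVs with `criterion`, `best_p`,
#'   `enriched_cancers` columns; the cutoff used is attached as attribute.
#' @export
prioritize_key_pfssnvs <- function(pfs_variants, patient_results = NULL,
                                   min_types = 5L, alpha = 0.05) {
  multi <- select_key_multi_cancer(pfs_variants, min_types)
  cutoff <- NA_real_
  enr_keys <- character(0)
  best_p <- list()
  enr_c <- list()
  if (!is.null(patient_results) && nrow(patient_results) > 0) {
    cutoff <- bonferroni_cutoff(attr(patient_results, "n_tests"), alpha)
    sig <- patient_results[patient_results$p_value < cutoff &
                             patient_results$direction == "enriched", ,
                           drop = FALSE]
    enr_keys <- unique(sig$key)
    for (k in enr_keys) {
      sk <- sig[sig$key == k, ]
      best_p[[k]] <- min(sk$p_value)
      enr_c[[k]] <- paste(sk$do_slim[order(sk$p_value)], collapse = ",")
    }
  }
  keys <- union(multi$key, enr_keys)
  out <- pfs_variants[match(keys, pfs_variants$key), , drop = FALSE]
  out$criterion <- ifelse(out$key %in% multi$key & out$key %in% enr_keys,
                          "both",
                          ifelse(out$key %in% multi$key, "multi_cancer",
                                 "patient_enriched"))
  out$best_p <- vapply(out$key, function(k)
    if (k %in% names(best_p)) best_p[[k]] else NA_real_, numeric(1))
  out$enriched_cancers <- vapply(out$key, function(k)
    if (k %in% names(enr_c)) enr_c[[k]] else NA_character_, character(1))
  out <- out[order(-out$cancer_type_count, out$key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}

#' Flag key pfsSNVs by gene-list membership
#'
#' Adds `in_smg` and `in_cgc` flags per key pfsSNV and summarizes the genes
#' in the intersections, including the triple intersection (keys whose gene
#' is in both lists).
#'
#' @param keys data.frame of key pfsSNVs with a `gene` column.
#' @param smg,cgc character vectors of gene symbols (one per line files read
#'   with [readLines()]).
#' @return list(keys, summary) where summary holds `smg_genes`, `cgc_genes`,
#'   `triple_genes` and `unmatched` (key genes in neither list).
#' @export
intersect_gene_lists <- function(keys, smg, cgc) {
  smg <- unique(smg[nzchar(smg)])
  cgc <- unique(cgc[nzchar(cgc)])
  keys$in_smg <- !is.na(keys$gene) & keys$gene %in% smg
  keys$in_cgc <- !is.na(keys$gene) & keys$gene %in% cgc
  kg <- unique(stats::na.omit(keys$gene))
  list(keys = keys,
       summary = list(smg_genes = sort(intersect(kg, smg)),
                      cgc_genes = sort(intersect(kg, cgc)),
                      triple_genes = sort(intersect(intersect(kg, smg), cgc)),
                      unmatched = sort(setdiff(kg, union(smg, cgc)))))
}
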