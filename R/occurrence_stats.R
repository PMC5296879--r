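# Global per-residue SNV rates, per-site-type impact percentages, and
# +/-20 neighborhood fold-change profiles with the one-sample t-test.

filter_class <- function(df, class) {
  stopifnot(class %in% MUTATION_CLASSES)
  df[!is.na(mutation_class(df$origin, df$consequence)) &
       mutation_class(df$origin, df$consequence) == class, , drop = FALSE]
}

#' Global per-residue SNV rate of a mutation class
#'
#' Number of distinct collapsed variants of the class divided by the total
#' residue count of the proteome.
#'
#' @param variants data.frame from [collapse_variants()].
#' @param proteome a [protein_set()].
#' @param class one of `non_SS`, `SS`, `non_SG`, `SG`.
#' @return rate per residue.
#' @export
global_snv_rate <- function(variants, proteome, class) {
  L <- sum(nchar(unclass(proteome)))
  if (length(proteome) == 0 || L == 0) stop("empty proteome")
  nrow(filter_class(variants, class)) / L
}

#' Percentage of functional sites impacted by a mutation class
#'
#' 100 x (distinct site positions with at least one offset-0 annotation of
#' the class) / (number of sites of that type). Site types with zero sites
#' are excluded with a report note.
#'
#' @param ann a `pfs_annotations` object.
#' @param sites the validated site table the annotations were built from.
#' @param classes mutation classes to tabulate.
#' @return data.frame (site_type, class, n_sites, n_impacted, percent).
#' @export
percent_sites_impacted <- function(ann, sites,
                                   classes = MUTATION_CLASSES) {
  a <- ann$annotations
  a <- a[a$offset == 0L, , drop = FALSE]
  a$class <- mutation_class(a$origin, a$consequence)
  stypes <- sort(unique(sites$site_type))
  rows <- list()
  for (st in stypes) {
    n_sites <- sum(sites$site_type == st)
    for (cl in classes) {
      hit <- a[a$site_type == st & !is.na(a$class) & a$class == cl, ]
      n_imp <- nrow(unique(hit[, c("accession", "site_position")]))
      rows[[paste(st, cl)]] <- data.frame(
        site_type = st, class = cl, n_sites = n_sites,
        n_impacted = n_imp, percent = 100 * n_imp / n_sites)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Neighborhood fold-change profile for one site type and mutation class
#'
#' Per offset o in `[-window, window]`: occurrence(o) = count of class
#' annotations at o divided by the number of valid residues at o across all
#' sites of the type; fold change = occurrence / global per-residue class
#' rate, so values near 1 are background. Offsets with zero denominator are
#' omitted. The one-sample t-test of the neighbor values against the
#' offset-0 value is attached.
#'
#' @param ann a `pfs_annotations` object.
#' @param class mutation class.
#' @param site_type site type.
#' @param global_rate from [global_snv_rate()]; must be > 0.
#' @return object of class `neighborhood_profile`: list(site_type, class,
#'   table, t_statistic, p_value, df, degenerate).
#' @export
neighborhood_profile <- function(ann, class, site_type, global_rate) {
  if (!is.finite(global_rate) || global_rate <= 0)
    stop("profile undefined for global rate ", global_rate)
  a <- ann$annotations
  a <- a[a$site_type == site_type, , drop = FALSE]
  a <- filter_class(a, class)
  den <- ann$denominators
  den <- den[den$site_type == site_type & den$n_valid > 0, , drop = FALSE]
  if (nrow(den) == 0) stop("no sites of type ", site_type)
  cnt <- table(factor(a$offset, levels = den$offset))
  tab <- data.frame(site_type = site_type, class = class,
                    offset = den$offset,
                    count = as.integer(cnt),
                    denominator = den$n_valid)
  tab$occurrence <- tab$count / tab$denominator
  tab$fold_change <- tab$occurrence / global_rate
  tt <- site_vs_neighbors_ttest(tab)
  structure(list(site_type = site_type, class = class, table = tab,
                 global_rate = global_rate,
                 t_statistic = tt$t, p_value = tt$p, df = tt$df,
                 degenerate = tt$degenerate),
            class = "neighborhood_profile")
}

#' One-sample t-test of site fold change against its neighbors
#'
#' The 2*window neighbor fold-change values form the sample; the offset-0
#' value is the hypothesized mean. Two-sided p from the t distribution with
#' (n_neighbors - 1) degrees of freedom. Sign convention: t > 0 when the
#' neighbor mean exceeds the site value. With zero variance among neighbors
#' the statistic is undefined: a degenerate result is returned with p = 1
#' when the neighbor mean equals the site value and p = 0 otherwise.
#'
#' @param profile a `neighborhood_profile` or its `table` data.frame (needs
#'   columns `offset` and `fold_change`, offset 0 present).
#' @return list(t, p, df, degenerate).
#' @export
site_vs_neighbors_ttest <- function(profile) {
  tab <- if (inherits(profile, "neighborhood_profile")) profile$table
  else profile
  if (!0L %in% tab$offset) stop("offset 0 absent from profile")
  site <- tab$fold_change[tab$offset == 0L]
  x <- tab$fold_change[tab$offset != 0L]
  if (length(x) < 2) stop("need at least 2 neighbor offsets")
  s <- stats::sd(x)
  n <- length(x)
  if (s == 0) {
    if (mean(x) == site)
      return(list(t = 0, p = 1, df = n - 1L, degenerate = TRUE))
    return(list(t = sign(mean(x) - site) * Inf, p = 0, df = n - 1L,
                degenerate = TRUE))
  }
  t <- (mean(x) - site) / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1L), df = n - 1L,
       degenerate = FALSE)
}

#' @export
print.neighborhood_profile <- function(x, ...) {
  cat("neighborhood_profile:", x$site_type, "/", x$class, "\n")
  f0 <- x$table$fold_change[x$table$offset == 0]
  cat(sprintf("  fold change at site: %.3f; t = %.3f, p = %.3g\n",
              f0, x$t_statistic, x$p_value))
  invisible(x)
}

#' Line plot of a neighborhood profile
#' @param x a `neighborhood_profile`.
#' @param ... passed to [plot()].
#' @export
plot.neighborhood_profile <- function(x, ...) {
  plot(x$table$offset, x$table$fold_change, type = "b", pch = 16,
       xlab = "offset from functional site (residues)",
       ylab = "fold change vs proteome rate",
       main = paste(x$site_type, x$class, sep = " / "), ...)
  graphics::abline(h = 1, lty = 2, col = "grey50")
  graphics::abline(v = 0, lty = 3, col = "grey70")
  invisible(x)
}

#' Export profiles and their test summaries to TSV
#' @param profiles list of `neighborhood_profile` objects.
#' @param profile_path,summary_path output paths.
#' @export
write_profiles <- function(profiles, profile_path, summary_path) {
  tabs <- do.call(rbind, lapply(profiles, `[[`, "table"))
  write_tsv_pfs(tabs, profile_path)
  summ <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(site_type = p$site_type, class = p$class,
               t = p$t_statistic, p = p$p_value, df = p$df,
               degenerate = p$degenerate)
  }))
  write_tsv_pfs(summ, summary_path)
  invisible(list(profiles = profile_path, summary = summary_path))
}
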