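# Global pairwise alignment (Gotoh affine-gap Needleman-Wunsch) used to
# unify residue positions between two revisions of a protein sequence.
#
# Gap cost convention: a gap run of length k costs gap_open + (k-1) *
# gap_extend (the opening penalty covers the first gapped residue).

default_scoring <- function() {
  c(match = 1, mismatch = -1, gap_open = -2, gap_extend = -1)
}

#' Align two protein sequences and build a position map
#'
#' Needleman-Wunsch global alignment with affine gaps under the given
#' scoring scheme. Aligned residue pairs become map pairs; residues of
#' `seq_a` aligned to gaps go to `unmapped_a`. Traceback ties are broken
#' deterministically: diagonal, then up (gap in `seq_b`), then left.
#'
#' @param seq_a,seq_b non-empty amino-acid strings (20 letters plus X).
#' @param scoring named numeric vector `match`, `mismatch`, `gap_open`,
#'   `gap_extend`; a gap of length k costs `gap_open + (k-1) * gap_extend`.
#' @param accession optional accession carried on the map.
#' @return object of class `PositionMap`: list with `pairs` (two-column
#'   matrix of 1-based positions, strictly increasing in both coordinates),
#'   `unmapped_a`, `mismatched_a` (a-positions aligned to a different
#'   residue), `score` and `accession`.
#' @export
align_positions <- function(seq_a, seq_b, scoring = default_scoring(),
                            accession = NA_character_) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  if (!all(c(a, b) %in% AA_ALPHABET_PFS))
    stop("sequence contains characters outside the amino-acid alphabet")
  sc <- scoring[c("match", "mismatch", "gap_open", "gap_extend")]
  if (anyNA(sc)) stop("scoring must name match, mismatch, gap_open, gap_extend")
  n <- length(a); m <- length(b)
  NEG <- -.Machine$double.xmax / 4

  # state matrices: M diagonal, X gap in b (consumes a, traceback 'up'),
  # Y gap in a (consumes b, traceback 'left'); rows 0..n, cols 0..m
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1, 1] <- 0
  if (n >= 1) X[2:(n + 1L), 1] <- sc["gap_open"] + (0:(n - 1L)) * sc["gap_extend"]
  if (m >= 1) Y[1, 2:(m + 1L)] <- sc["gap_open"] + (0:(m - 1L)) * sc["gap_extend"]
  for (i in 2:(n + 1L)) {
    ai <- a[i - 1L]
    sub <- ifelse(ai == b, sc["match"], sc["mismatch"])
    for (j in 2:(m + 1L)) {
      M[i, j] <- sub[j - 1L] +
        max(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      X[i, j] <- max(M[i - 1L, j] + sc["gap_open"],
                     X[i - 1L, j] + sc["gap_extend"],
                     Y[i - 1L, j] + sc["gap_open"])
      Y[i, j] <- max(M[i, j - 1L] + sc["gap_open"],
                     X[i, j - 1L] + sc["gap_open"],
                     Y[i, j - 1L] + sc["gap_extend"])
    }
  }
  score <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])

  # traceback, preferring M (diagonal) > X (up) > Y (left) at every tie
  eps <- 1e-9
  state <- if (M[n + 1L, m + 1L] >= score - eps) "M"
  else if (X[n + 1L, m + 1L] >= score - eps) "X" else "Y"
  i <- n + 1L; j <- m + 1L
  pa <- integer(0); pb <- integer(0); gap_a <- integer(0)
  while (i > 1L || j > 1L) {
    if (state == "M") {
      pa <- c(i - 1L, pa); pb <- c(j - 1L, pb)
      sub <- if (a[i - 1L] == b[j - 1L]) sc["match"] else sc["mismatch"]
      tgt <- M[i, j] - sub
      i <- i - 1L; j <- j - 1L
      state <- if (i == 1L && j == 1L) "M"
      else if (M[i, j] >= tgt - eps) "M"
      else if (X[i, j] >= tgt - eps) "X" else "Y"
    } else if (state == "X") {
      gap_a <- c(i - 1L, gap_a)
      cur <- X[i, j]
      i <- i - 1L
      state <- if (i == 1L && j == 1L) "M"
      else if (j == 1L) "X"
      else if (M[i, j] + sc["gap_open"] >= cur - eps) "M"
      else if (X[i, j] + sc["gap_extend"] >= cur - eps) "X" else "Y"
    } else {
      cur <- Y[i, j]
      j <- j - 1L
      state <- if (i == 1L && j == 1L) "M"
      else if (i == 1L) "Y"
      else if (M[i, j] + sc["gap_open"] >= cur - eps) "M"
      else if (X[i, j] + sc["gap_open"] >= cur - eps) "X" else "Y"
    }
  }
  pairs <- cbind(position_a = pa, position_b = pb)
  structure(list(accession = accession, pairs = pairs,
                 unmapped_a = gap_a,
                 mismatched_a = pa[a[pa] != b[pb]],
                 score = unname(score)),
            class = "PositionMap")
}

#' @export
print.PositionMap <- function(x, ...) {
  cat("PositionMap:", nrow(x$pairs), "aligned pairs,",
      length(x$unmapped_a), "unmapped,",
      length(x$mismatched_a), "mismatched; score", x$score, "\n")
  invisible(x)
}

#' Lift annotation positions through a position map
#'
#' @param positions integer vector of 1-based positions on sequence a.
#' @param pmap a `PositionMap` from [align_positions()].
#' @return list with `mapped` (data.frame position_a, position_b,
#'   mismatch_at_site flag) and `dropped` (data.frame position_a, reason).
#' @export
lift_annotations <- function(positions, pmap) {
  len_a <- nrow(pmap$pairs) + length(pmap$unmapped_a)
  bad <- positions < 1L | positions > len_a
  if (any(bad))
    stop("position ", positions[bad][1], " outside sequence a (length ",
         len_a, ")")
  idx <- match(positions, pmap$pairs[, "position_a"])
  ok <- !is.na(idx)
  mapped <- data.frame(
    position_a = positions[ok],
    position_b = pmap$pairs[idx[ok], "position_b"],
    mismatch_at_site = positions[ok] %in% pmap$mismatched_a)
  dropped <- data.frame(position_a = positions[!ok],
                        reason = rep("unmapped", sum(!ok)))
  list(mapped = mapped, dropped = dropped)
}
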