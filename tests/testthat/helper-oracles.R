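# Independent oracles used by the property and acceptance tests. These stay
# deliberately naive: enumeration and from-scratch recomputation, never the
# code paths they check.

# --- exhaustive global alignment oracle -------------------------------------
# Enumerates every global alignment (move strings over D/U/L), scores gap
# runs as gap_open + (len-1) * gap_extend, and picks the optimum; ties are
# resolved by preferring D, then U, then L reading the alignment from its
# END (the traceback order).
oracle_align <- function(a, b, sc = c(match = 1, mismatch = -1,
                                      gap_open = -2, gap_extend = -1)) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- new.env()
  best$score <- -Inf
  best$moves <- NULL
  rank <- c(D = 1L, U = 2L, L = 3L)
  better_tie <- function(new, old) {
    # compare from the end; smaller rank wins
    nr <- rev(rank[new]); or <- rev(rank[old])
    for (k in seq_len(max(length(nr), length(or)))) {
      x <- if (k <= length(nr)) nr[k] else 0L
      y <- if (k <= length(or)) or[k] else 0L
      if (x != y) return(x < y)
    }
    FALSE
  }
  rec <- function(i, j, score, moves, prev) {
    if (i > length(av) && j > length(bv)) {
      if (score > best$score ||
          (score == best$score && better_tie(moves, best$moves))) {
        best$score <- score
        best$moves <- moves
      }
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) sc[["match"]] else sc[["mismatch"]]
      rec(i + 1L, j + 1L, score + s, c(moves, "D"), "D")
    }
    if (i <= length(av)) {
      g <- if (identical(prev, "U")) sc[["gap_extend"]] else sc[["gap_open"]]
      rec(i + 1L, j, score + g, c(moves, "U"), "U")
    }
    if (j <= length(bv)) {
      g <- if (identical(prev, "L")) sc[["gap_extend"]] else sc[["gap_open"]]
      rec(i, j + 1L, score + g, c(moves, "L"), "L")
    }
  }
  rec(1L, 1L, 0, character(0), "")
  # convert winning move string to pair map
  i <- 0L; j <- 0L
  pa <- integer(0); pb <- integer(0); gap_a <- integer(0)
  for (mv in best$moves) {
    if (mv == "D") {
      i <- i + 1L; j <- j + 1L; pa <- c(pa, i); pb <- c(pb, j)
    } else if (mv == "U") {
      i <- i + 1L; gap_a <- c(gap_a, i)
    } else j <- j + 1L
  }
  list(score = best$score, pairs = cbind(position_a = pa, position_b = pb),
       unmapped_a = gap_a)
}

# --- exact binomial tail by direct summation --------------------------------
oracle_binom_tail <- function(observed, N, p) {
  mass <- vapply(0:N, function(k)
    choose(N, k) * p^k * (1 - p)^(N - k), numeric(1))
  upper <- sum(mass[(observed + 1):(N + 1)])
  lower <- sum(mass[1:(observed + 1)])
  if (observed > N * p) upper
  else if (observed < N * p) lower
  else min(1, upper, lower)
}

# --- brute-force nearest-pair agglomeration ---------------------------------
# Complete linkage recomputed from scratch at every step (max pairwise
# euclidean row distance across cluster members); ties by the
# lexicographically smallest pair of smallest member labels. Returns the
# sequence of merged label sets and heights.
oracle_hclust <- function(m) {
  m[is.na(m)] <- 1
  labs <- rownames(m)
  clusters <- lapply(seq_len(nrow(m)), function(i) i)
  euclid <- function(i, j) sqrt(sum((m[i, ] - m[j, ])^2))
  cdist <- function(ci, cj) max(outer(ci, cj, Vectorize(euclid)))
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL
    for (x in seq_along(clusters)) for (y in seq_along(clusters)) {
      if (x >= y) next
      d <- cdist(clusters[[x]], clusters[[y]])
      lab <- sort(c(min(labs[clusters[[x]]]), min(labs[clusters[[y]]])))
      if (is.null(best) || d < best$d - 1e-12 ||
          (abs(d - best$d) <= 1e-12 &&
           (lab[1] < best$lab[1] ||
            (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
        best <- list(x = x, y = y, d = d, lab = lab)
      }
    }
    merged <- sort(c(clusters[[best$x]], clusters[[best$y]]))
    merges[[length(merges) + 1]] <- sort(labs[merged])
    heights <- c(heights, best$d)
    clusters[[best$x]] <- merged
    clusters[[best$y]] <- NULL
  }
  list(members = merges, heights = heights)
}

# members of each merge step of an hclust object, as sorted label sets
hclust_members <- function(hc) {
  lapply(seq_len(nrow(hc$merge)), function(s) {
    leaves <- function(k) {
      if (k < 0) return(-k)
      c(leaves(hc$merge[k, 1]), leaves(hc$merge[k, 2]))
    }
    sort(hc$labels[leaves(s)])
  })
}
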