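# Independent brute-force oracles used to check the implementation.

# O(n^3) average-linkage agglomeration from first principles: repeatedly
# merge the pair of clusters with the smallest mean pairwise Euclidean
# distance, recording merge heights and the partition at every cluster count.
oracle_average_linkage <- function(mat) {
  D <- as.matrix(dist(mat))
  clusters <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  partitions <- list()
  partitions[[length(clusters)]] <- clusters
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        d <- mean(D[clusters[[i]], clusters[[j]], drop = FALSE])
        if (is.null(best) || d < best$d) best <- list(d = d, i = i, j = j)
      }
    }
    heights <- c(heights, best$d)
    clusters[[best$i]] <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters[[best$j]] <- NULL
    partitions[[length(clusters)]] <- clusters
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition given as a label vector: labels renumbered
# by first appearance so partitions can be compared across label permutations
canonical_partition <- function(labels) {
  match(labels, unique(labels))
}

# oracle partition (list of index vectors) -> label vector over n items
oracle_labels <- function(partition, n) {
  lab <- integer(n)
  for (g in seq_along(partition)) lab[partition[[g]]] <- g
  canonical_partition(lab)
}

# base-R reverse complement
rc_base <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
        collapse = "")
}

# all-substring scan in-silico PCR oracle: exhaustive site enumeration with
# gregexpr, pairing each forward site with the nearest downstream reverse-
# complement site, both orientations
oracle_pcr <- function(template, fwd, rev, max_len = 20000) {
  template <- toupper(template)
  sites <- function(p) {
    m <- gregexpr(toupper(p), template, fixed = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  one_dir <- function(left, right) {
    ls <- sites(left)
    rs <- sites(rc_base(right))
    ends <- rs + nchar(right) - 1L
    out <- integer(0)
    for (s in ls) {
      cand <- ends[ends >= s + nchar(left) + nchar(right) - 1L]
      if (!length(cand)) next
      len <- min(cand) - s + 1L
      if (len <= max_len) out <- c(out, len)
    }
    out
  }
  sort(unique(c(one_dir(fwd, rev), one_dir(rev, fwd))))
}

# degree of reduction from an element composition (NH3-level nitrogen)
gamma_from_elements <- function(C, H, O, N = 0) 4 * C + H - 2 * O - 3 * N

# random rooted tree over n strains: strain i's parent drawn among 1..i-1
random_tree_edges <- function(n, ids = sprintf("S%02d", seq_len(n))) {
  parent <- vapply(2:n, function(i) ids[sample.int(i - 1L, 1)], "")
  data.frame(parent = parent, child = ids[2:n], stringsAsFactors = FALSE)
}

# default-scenario config with a given seed (shared by several tests)
test_config <- function(seed = 1, ...) scenario_config(seed = seed, ...)
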