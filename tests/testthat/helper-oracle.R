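# Brute-force UPGMA oracle, independent of stats::hclust: clusters are index
# sets, the merged pair is the one with the smallest unweighted mean pairwise
# distance, recomputed from the original matrix at every step (O(n^3)).
upgma_oracle <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- mean(D[clusters[[i]], clusters[[j]]])
        if (is.null(best) || h < best$h) best <- list(i = i, j = j, h = h)
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[length(merges) + 1L]] <- list(members = merged, height = best$h)
    clusters[[best$i]] <- merged
    clusters[[best$j]] <- NULL
  }
  merges
}

# Member sets of each merge of an hclust object, in merge order.
hclust_member_sets <- function(hc) {
  n <- nrow(hc$merge) + 1L
  sets <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    members <- integer(0)
    for (side in hc$merge[k, ]) {
      members <- c(members,
                   if (side < 0) -side else sets[[side]])
    }
    sets[[k]] <- sort(members)
  }
  sets
}

# Random symmetric distance matrix with zero diagonal.
random_distance_matrix <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2, 0.05, 2)
  d + t(d)
}

# Library entries simulated at given config, classified with their formula.
simulate_and_classify <- function(lib, cfg) {
  vapply(seq_len(nrow(lib)), function(i) {
    s <- simulate_spectrum(lib[i, ], cfg)
    a <- classify_compound(s, precursor_formula = lib$formula[i])
    c(class = a$compound_class,
      aglycone = if (is.na(a$aglycone)) "" else a$aglycone)
  }, character(2))
}
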