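# Small genomes and brute-force helpers shared across tests.

tiny_genome <- function(sizes = c(4, 4), mu = 0, circular = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bounds <- cumsum(c(0L, sizes))
  chrom <- lapply(seq_along(sizes), function(k) (bounds[k] + 1L):bounds[k + 1L])
  N <- sum(sizes)
  if (is.null(circular)) circular <- rep(FALSE, length(sizes))
  new_dcj_genome(chrom, circular, stats::runif(N) < mu,
                 rep.int(seq_along(sizes), sizes))
}

# multiset of gene ids of a genome
gene_multiset <- function(g) sort(abs(unlist(g$chromosomes)))

# partition of sensitive gene ids over linear chromosomes, as a canonical string
sensitive_partition <- function(g) {
  parts <- lapply(seq_along(g$chromosomes)[!g$circular], function(k) {
    ids <- abs(g$chromosomes[[k]])
    sort(ids[g$sensitive[ids]])
  })
  parts <- Filter(length, parts)
  paste(sort(vapply(parts, paste, "", collapse = ",")), collapse = ";")
}

# enumerate all (gap1, gap2, rejoin) moves of a genome (telomeres included)
all_moves <- function(g) {
  counts <- lengths(g$chromosomes) + ifelse(g$circular, 0L, 1L)
  out <- list()
  for (k1 in seq_along(counts)) for (g1 in 0:(counts[k1] - 1L))
    for (k2 in seq_along(counts)) for (g2 in 0:(counts[k2] - 1L)) {
      if (k1 > k2 || (k1 == k2 && g1 >= g2)) next
      for (r in 0:1)
        out[[length(out) + 1L]] <- list(k1 = k1, g1 = g1, k2 = k2, g2 = g2, r = r)
    }
  out
}
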