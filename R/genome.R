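#' Initialize a multichromosomal genome
#'
#' Creates a genome of \code{n_chrom} linear chromosomes carrying \code{n_genes}
#' genes in total, numbered consecutively along chromosomes. Chromosome sizes
#' are \code{floor(n_genes / n_chrom)}, with remainder genes distributed one
#' each to the lowest-index chromosomes. Each gene is flagged dosage-sensitive
#' independently with probability \code{mu} (the flags are drawn from the
#' current RNG stream even when \code{mu = 0}, so that runs under different
#' models are comparable draw-for-draw). Each gene records the chromosome it
#' starts on as its ancestral linkage-group label.
#'
#' @param n_chrom number of linear chromosomes (>= 1).
#' @param n_genes total number of genes (>= n_chrom).
#' @param mu probability that a gene is flagged sensitive, in [0, 1].
#' @param seed optional integer; if given, \code{set.seed(seed)} is called first.
#' @return An object of class \code{dcj_genome}: a list with elements
#'   \code{chromosomes} (list of signed integer vectors; sign = orientation),
#'   \code{circular} (logical per chromosome), \code{sensitive} (logical per
#'   gene id), \code{ancestral} (integer per gene id), and \code{N}.
#' @examples
#' g <- init_genome(4, 20, mu = 0.1, seed = 1)
#' lengths(g$chromosomes)
#' @export
init_genome <- function(n_chrom, n_genes, mu = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_chrom < 1) stop("n_chrom must be >= 1")
  if (n_genes < n_chrom) stop("n_genes must be >= n_chrom")
  if (mu < 0 || mu > 1) stop("mu must be in [0, 1]")
  n_chrom <- as.integer(n_chrom)
  n_genes <- as.integer(n_genes)
  base <- n_genes %/% n_chrom
  sizes <- base + as.integer(seq_len(n_chrom) <= n_genes %% n_chrom)
  bounds <- cumsum(c(0L, sizes))
  chromosomes <- lapply(seq_len(n_chrom), function(k) {
    (bounds[k] + 1L):bounds[k + 1L]
  })
  ancestral <- rep.int(seq_len(n_chrom), sizes)
  sensitive <- stats::runif(n_genes) < mu
  new_dcj_genome(chromosomes, rep(FALSE, n_chrom), sensitive, ancestral)
}

#' Construct a genome object from its parts
#'
#' @param chromosomes list of signed integer vectors of gene ids.
#' @param circular logical vector, one entry per chromosome.
#' @param sensitive logical vector indexed by gene id.
#' @param ancestral integer vector indexed by gene id; defaults to the current
#'   chromosome of each gene.
#' @return A \code{dcj_genome}.
#' @export
new_dcj_genome <- function(chromosomes, circular = NULL, sensitive = NULL,
                           ancestral = NULL) {
  chromosomes <- lapply(chromosomes, as.integer)
  ids <- abs(unlist(chromosomes, use.names = FALSE))
  N <- length(ids)
  if (N == 0) stop("genome has no genes")
  if (anyDuplicated(ids) || !setequal(ids, seq_len(N)))
    stop("gene ids must be exactly 1..N, each exactly once")
  if (is.null(circular)) circular <- rep(FALSE, length(chromosomes))
  if (is.null(sensitive)) sensitive <- rep(FALSE, N)
  if (is.null(ancestral))
    ancestral <- chromosome_of(structure(list(chromosomes = chromosomes),
                                         class = "dcj_genome"), N)
  stopifnot(length(circular) == length(chromosomes),
            length(sensitive) == N, length(ancestral) == N)
  structure(list(chromosomes = chromosomes,
                 circular = as.logical(circular),
                 sensitive = as.logical(sensitive),
                 ancestral = as.integer(ancestral),
                 N = N),
            class = "dcj_genome")
}

#' @export
print.dcj_genome <- function(x, ...) {
  nlin <- sum(!x$circular)
  ncir <- sum(x$circular)
  cat(sprintf("dcj_genome: %d genes on %d linear chromosome(s)%s, %d sensitive\n",
              x$N, nlin,
              if (ncir) sprintf(" + %d circular fragment(s)", ncir) else "",
              sum(x$sensitive)))
  invisible(x)
}

# current chromosome index of every gene id (internal)
chromosome_of <- function(genome, N = genome$N) {
  loc <- integer(N)
  for (k in seq_along(genome$chromosomes))
    loc[abs(genome$chromosomes[[k]])] <- k
  loc
}

# TRUE for gene ids sitting on circular fragments (internal)
on_circular <- function(genome) {
  onc <- logical(genome$N)
  for (k in which(genome$circular))
    onc[abs(genome$chromosomes[[k]])] <- TRUE
  onc
}

#' Gene count and sensitive count of a chromosome segment
#'
#' Summarizes the half-open gap interval \code{(from, to]} of one chromosome:
#' the segment consists of the genes between gap \code{from} and gap \code{to}
#' (gaps are 0-based; gap 0 precedes the first gene). The default method is a
#' linear scan of the genome object; \code{method = "tree"} routes the query
#' through the order-statistic tree engine, which answers from its subtree
#' summaries, and exists so the two can be cross-checked.
#'
#' @param genome a \code{dcj_genome}.
#' @param chrom chromosome index.
#' @param from,to gap indices with \code{0 <= from <= to <= length}.
#' @param method "scan" (linear scan) or "tree" (order-statistic tree).
#' @return integer vector \code{c(length = , sensitive = )}.
#' @export
segment_summary <- function(genome, chrom, from, to, method = c("scan", "tree")) {
  method <- match.arg(method)
  if (chrom < 1 || chrom > length(genome$chromosomes))
    stop("no such chromosome")
  v <- genome$chromosomes[[chrom]]
  if (from < 0 || to > length(v) || from > to)
    stop("invalid segment bounds")
  if (method == "tree")
    return(.dcj_segment_summary_cpp(genome$chromosomes, genome$circular,
                                    genome$sensitive, chrom, from, to))
  idx <- if (to > from) (from + 1L):to else integer(0)
  c(length = length(idx),
    sensitive = sum(genome$sensitive[abs(v[idx])]))
}

# canonical form for comparisons: each chromosome reversal-normalized,
# circular chromosomes rotation-normalized, chromosome order sorted
canonical_genome <- function(genome) {
  canon <- lapply(seq_along(genome$chromosomes), function(k) {
    v <- genome$chromosomes[[k]]
    if (genome$circular[k]) {
      # all rotations of both strands; pick lexicographic minimum
      w <- -rev(v)
      rots <- c(lapply(seq_along(v) - 1L, function(r) c(v[-seq_len(r)], v[seq_len(r)])),
                lapply(seq_along(w) - 1L, function(r) c(w[-seq_len(r)], w[seq_len(r)])))
      best <- rots[[1]]
      for (cand in rots[-1])
        if (isTRUE(vector_less(cand, best))) best <- cand
      best
    } else {
      w <- -rev(v)
      if (isTRUE(vector_less(w, v))) w else v
    }
  })
  ord <- order(vapply(canon, function(v) v[1], 1L))
  list(chromosomes = canon[ord], circular = genome$circular[ord])
}

vector_less <- function(a, b) {
  d <- a != b
  if (!any(d)) return(FALSE)
  i <- which(d)[1]
  a[i] < b[i]
}

#' Test two genomes for equality up to chromosome order and reversal
#'
#' Chromosome reversal (reverse order, flip orientations), rotation of circular
#' fragments, and the ordering of chromosomes within the genome are
#' representation details; this comparison is invariant to all three.
#'
#' @param a,b \code{dcj_genome} objects.
#' @return TRUE or FALSE.
#' @export
genomes_identical <- function(a, b) {
  if (a$N != b$N) return(FALSE)
  if (sum(a$circular) != sum(b$circular)) return(FALSE)
  identical(canonical_genome(a), canonical_genome(b))
}
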