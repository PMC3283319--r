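#' Sample a marker-gene subset
#'
#' Pairwise synteny statistics are computed on "marker genes", a uniform random
#' subset of the gene universe chosen to match the number of one-to-one
#' orthologs available in a real comparison.
#'
#' @param genome a \code{dcj_genome} (or an integer, the gene count).
#' @param n_markers subset size.
#' @param seed optional integer seed.
#' @return Sorted integer vector of marker gene ids.
#' @export
sample_markers <- function(genome, n_markers, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- if (inherits(genome, "dcj_genome")) genome$N else as.integer(genome)
  if (n_markers > N) stop("n_markers exceeds the gene count")
  if (n_markers < 1) stop("n_markers must be positive")
  sort(sample.int(N, n_markers))
}

# marker-reduced signed gene orders, one vector per chromosome (internal)
reduce_to_markers <- function(genome, marker_flag) {
  lapply(genome$chromosomes, function(v) v[marker_flag[abs(v)]])
}

# unordered adjacency keys of a marker-reduced genome (internal).
# signed = TRUE keys on oriented adjacency (head-tail contact), otherwise on
# the unordered gene pair.
adjacency_keys <- function(genome, marker_flag, signed = FALSE) {
  N <- genome$N
  keys <- vector("list", length(genome$chromosomes))
  red <- reduce_to_markers(genome, marker_flag)
  for (k in seq_along(red)) {
    v <- red[[k]]
    if (length(v) < 2) next
    x <- v[-length(v)]; y <- v[-1]
    if (genome$circular[k]) { x <- c(x, v[length(v)]); y <- c(y, v[1]) }
    if (signed) {
      # canonical form of the oriented adjacency (reading-direction invariant)
      a <- ifelse(abs(x) <= abs(y), x, -y)
      b <- ifelse(abs(x) <= abs(y), y, -x)
      keys[[k]] <- paste(a, b)
    } else {
      keys[[k]] <- pmin(abs(x), abs(y)) * (N + 1) + pmax(abs(x), abs(y))
    }
  }
  unique(unlist(keys, use.names = FALSE))
}

#' Micro-synteny conservation s
#'
#' Reduces both genomes to the marker subset (deleting non-markers and
#' concatenating their neighbors) and returns the fraction of marker
#' adjacencies of genome \code{a} that are also adjacencies in genome \code{b}.
#' By default adjacency is unordered and orientation-blind; with
#' \code{signed = TRUE} two markers count as conserved only if also their
#' relative orientation is conserved.
#'
#' @param a,b \code{dcj_genome} objects over the same gene universe.
#' @param markers integer vector of marker gene ids.
#' @param signed require conserved relative orientation?
#' @return Fraction in [0, 1].
#' @export
micro_synteny_s <- function(a, b, markers, signed = FALSE) {
  if (length(markers) < 2) stop("need at least two markers")
  flag <- logical(a$N); flag[markers] <- TRUE
  ka <- adjacency_keys(a, flag, signed)
  kb <- adjacency_keys(b, flag, signed)
  if (length(ka) == 0) stop("genome a has no marker adjacencies")
  mean(ka %in% kb)
}

#' PAL homology by z-score
#'
#' Assigns homology between the putative ancestral linkage groups (PALs) of two
#' genomes from the matrix of shared marker counts. For simulated genomes a PAL
#' is a (linear) chromosome; markers on circular fragments belong to no PAL.
#' With \code{m_i} markers on PAL i of \code{a}, \code{m_j} on PAL j of
#' \code{b} and \code{N_m} markers in total, the observed shared count
#' \code{O_ij} is compared with its saturation expectation
#' \code{E_ij = m_i m_j / N_m} under a binomial approximation;
#' \code{z_ij = (O_ij - E_ij) / sqrt(V_ij)} with \code{V_ij = m_i (m_j/N_m)
#' (1 - m_j/N_m)} row-wise (and the transposed form column-wise). Each PAL is
#' homologous to the PAL of the other genome with which it has its highest
#' z-score; ties break to the lowest index.
#'
#' @param a,b \code{dcj_genome} objects.
#' @param markers marker gene ids.
#' @return A \code{pal_homology} list: \code{O}, \code{E}, \code{z_ab},
#'   \code{z_ba}, \code{best_ab} (named map PAL of a -> PAL of b),
#'   \code{best_ba}, marker PAL labels \code{pal_a}, \code{pal_b} (NA for
#'   markers on circular fragments), and \code{n_markers}.
#' @export
pal_homology <- function(a, b, markers) {
  Nm <- length(markers)
  pal_a <- ifelse(on_circular(a), NA_integer_, chromosome_of(a))[markers]
  pal_b <- ifelse(on_circular(b), NA_integer_, chromosome_of(b))[markers]
  keep <- !is.na(pal_a) & !is.na(pal_b)
  ia <- sort(unique(pal_a[keep]))
  ib <- sort(unique(pal_b[keep]))
  if (length(ia) == 0) stop("no markers on PALs in genome a")
  O <- table(factor(pal_a[keep], ia), factor(pal_b[keep], ib))
  O <- matrix(as.numeric(O), nrow(O), ncol(O), dimnames = dimnames(O))
  mi <- rowSums(O) + tabulate(match(pal_a[!keep & !is.na(pal_a)], ia), length(ia))
  mj <- colSums(O) + tabulate(match(pal_b[!keep & !is.na(pal_b)], ib), length(ib))
  E <- outer(mi, mj) / Nm
  Va <- outer(mi, (mj / Nm) * (1 - mj / Nm))
  Vb <- outer((mi / Nm) * (1 - mi / Nm), mj)
  z_ab <- (O - E) / sqrt(pmax(Va, .Machine$double.eps))
  z_ba <- (O - E) / sqrt(pmax(Vb, .Machine$double.eps))
  best_ab <- stats::setNames(ib[apply(z_ab, 1, which.max)], as.character(ia))
  best_ba <- stats::setNames(ia[apply(z_ba, 2, which.max)], as.character(ib))
  structure(list(O = O, E = E, z_ab = z_ab, z_ba = z_ba,
                 best_ab = best_ab, best_ba = best_ba,
                 pal_a = pal_a, pal_b = pal_b, n_markers = Nm),
            class = "pal_homology")
}

#' Macro-synteny conservation p
#'
#' Fraction of marker genes whose chromosomal context is conserved: marker m on
#' PAL i of \code{a} and PAL j of \code{b} counts as conserved when (i, j) is a
#' homologous PAL pair. With \code{direction = "union"} (default) the pair is
#' homologous when j is i's best z-score match or i is j's best match; with
#' \code{direction = "a_to_b"} only the first. Markers on circular fragments
#' are never conserved. The denominator is the full marker count, so p is
#' asymmetric in general and saturates near 1/c for c chromosomes.
#'
#' @param a,b \code{dcj_genome} objects.
#' @param markers marker gene ids.
#' @param hom optional precomputed \code{\link{pal_homology}}.
#' @param direction "union" or "a_to_b".
#' @return Fraction in [0, 1].
#' @export
macro_synteny_p <- function(a, b, markers, hom = NULL,
                            direction = c("union", "a_to_b")) {
  direction <- match.arg(direction)
  if (is.null(hom)) hom <- pal_homology(a, b, markers)
  pal_a <- hom$pal_a; pal_b <- hom$pal_b
  keep <- !is.na(pal_a) & !is.na(pal_b)
  ca <- as.character(pal_a)
  cons <- keep & !is.na(hom$best_ab[ca]) & (pal_b == hom$best_ab[ca])
  if (direction == "union") {
    cb <- as.character(pal_b)
    cons <- cons | (keep & !is.na(hom$best_ba[cb]) & (pal_a == hom$best_ba[cb]))
  }
  sum(cons, na.rm = TRUE) / hom$n_markers
}

#' Pairwise synteny summary
#'
#' Convenience wrapper computing both conservation statistics for a genome
#' pair on one marker set.
#'
#' @inheritParams macro_synteny_p
#' @param signed passed to \code{\link{micro_synteny_s}}.
#' @return List with \code{s}, \code{p}, \code{n_markers}.
#' @export
synteny_compare <- function(a, b, markers, direction = "union",
                            signed = FALSE) {
  hom <- pal_homology(a, b, markers)
  list(s = micro_synteny_s(a, b, markers, signed = signed),
       p = macro_synteny_p(a, b, markers, hom = hom, direction = direction),
       n_markers = length(markers))
}

#' Dot-plot coordinates for a genome comparison
#'
#' Marker positions in the two genomes' concatenated chromosome orders,
#' suitable for a whole-genome comparison dot plot.
#'
#' @param a,b \code{dcj_genome} objects.
#' @param markers marker gene ids.
#' @return data.frame with one row per marker: \code{marker}, \code{pos_a},
#'   \code{pos_b} (1-based positions in concatenated order), \code{pal_a},
#'   \code{pal_b} (NA on circular fragments).
#' @export
dot_plot_matrix <- function(a, b, markers) {
  pos_of <- function(g) {
    pos <- integer(g$N)
    at <- 0L
    for (k in seq_along(g$chromosomes)) {
      v <- abs(g$chromosomes[[k]])
      pos[v] <- at + seq_along(v)
      at <- at + length(v)
    }
    pos
  }
  pa <- pos_of(a); pb <- pos_of(b)
  la <- ifelse(on_circular(a), NA_integer_, chromosome_of(a))
  lb <- ifelse(on_circular(b), NA_integer_, chromosome_of(b))
  data.frame(marker = markers,
             pos_a = pa[markers], pos_b = pb[markers],
             pal_a = la[markers], pal_b = lb[markers])
}
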