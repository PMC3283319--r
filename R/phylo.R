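#' Neighbor-joining tree from a rearrangement distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via \code{ape::nj}) on a symmetric
#' distance matrix, e.g. the fitted pairwise rearrangement counts n. Negative
#' branch lengths, which NJ can produce on non-additive data, are clamped to
#' zero (recorded in the \code{clamped} attribute).
#'
#' @param distances square symmetric numeric matrix with zero diagonal, or a
#'   \code{dist} object.
#' @param labels optional taxon names (defaults to matrix dimnames).
#' @return An unrooted \code{ape::phylo} tree.
#' @examples
#' obs <- observed_pairs()
#' D <- pairwise_matrix(obs, "n")
#' tr <- nj_tree(D)
#' @export
nj_tree <- function(distances, labels = NULL) {
  if (inherits(distances, "dist")) distances <- as.matrix(distances)
  if (!isTRUE(all.equal(distances, t(distances), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(diag(distances) != 0)) stop("distance matrix must have zero diagonal")
  if (any(distances < 0)) stop("distances must be non-negative")
  if (nrow(distances) < 3) stop("need at least three taxa")
  if (!is.null(labels)) dimnames(distances) <- list(labels, labels)
  tr <- ape::nj(distances)
  neg <- tr$edge.length < 0
  if (any(neg)) tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- sum(neg)
  tr
}

#' Pairwise value table to square matrix
#'
#' Builds the symmetric matrix of one column of \code{\link{observed_pairs}}
#' (or any data.frame with \code{taxon1}, \code{taxon2} and a value column).
#'
#' @param pairs data.frame with \code{taxon1}, \code{taxon2} and \code{value}.
#' @param value name of the value column (e.g. "n", "n_t", "p").
#' @return Square symmetric matrix with zero diagonal.
#' @export
pairwise_matrix <- function(pairs, value = "n") {
  taxa <- unique(c(pairs$taxon1, pairs$taxon2))
  D <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  for (i in seq_len(nrow(pairs))) {
    D[pairs$taxon1[i], pairs$taxon2[i]] <- pairs[[value]][i]
    D[pairs$taxon2[i], pairs$taxon1[i]] <- pairs[[value]][i]
  }
  D
}

#' Read and write PHYLIP square distance matrices
#'
#' The PHYLIP square format: first line the number of taxa, then one line per
#' taxon holding the name and its full row of distances.
#'
#' @param path file path.
#' @return \code{read_phylip_square}: a named square matrix.
#' @export
read_phylip_square <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  ntax <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(ntax) || length(lines) < ntax + 1)
    stop("malformed PHYLIP matrix: bad taxon count")
  taxa <- character(ntax)
  D <- matrix(0, ntax, ntax)
  for (i in seq_len(ntax)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(parts) != ntax + 1)
      stop("malformed PHYLIP matrix at line ", i + 1)
    taxa[i] <- parts[1]
    D[i, ] <- as.numeric(parts[-1])
  }
  dimnames(D) <- list(taxa, taxa)
  D
}

#' @rdname read_phylip_square
#' @param D square matrix with dimnames.
#' @export
write_phylip_square <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste(formatC(rownames(D)[i], width = -10),
                     paste(format(D[i, ], trim = TRUE), collapse = " ")), con)
  invisible(path)
}
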