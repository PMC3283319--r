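#' Write and read genomes in GRIMM-style signed-permutation format
#'
#' The gene-order file holds a \code{>name} header followed by one line per
#' chromosome: signed integers separated by spaces, terminated by \code{$} for
#' a linear chromosome or \code{@} for a circular fragment. Sensitive flags and
#' ancestral linkage-group labels travel in an optional sidecar TSV with
#' columns \code{gene_id}, \code{sensitive}, \code{ancestral_chromosome}
#' (written to \code{<path>.genes.tsv}); when the sidecar is absent, genes are
#' non-sensitive and ancestral labels default to the current chromosome.
#'
#' @param genome a \code{dcj_genome}.
#' @param path gene-order file path.
#' @param name genome name for the header line.
#' @param sidecar write/read the sidecar TSV? (default TRUE on write; on read,
#'   used when the file exists)
#' @return \code{write_genome}: the path, invisibly. \code{read_genome}: a
#'   \code{dcj_genome}.
#' @export
write_genome <- function(genome, path, name = "genome", sidecar = TRUE) {
  lines <- c(paste0(">", name),
             vapply(seq_along(genome$chromosomes), function(k) {
               paste(c(genome$chromosomes[[k]],
                       if (genome$circular[k]) "@" else "$"),
                     collapse = " ")
             }, ""))
  writeLines(lines, path)
  if (sidecar) {
    df <- data.frame(gene_id = seq_len(genome$N),
                     sensitive = as.integer(genome$sensitive),
                     ancestral_chromosome = genome$ancestral)
    utils::write.table(df, paste0(path, ".genes.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path, sidecar = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  body <- lines[!startsWith(lines, ">")]
  chromosomes <- list()
  circular <- logical(0)
  for (i in seq_along(body)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    term <- tok[length(tok)]
    if (!term %in% c("$", "@"))
      stop("line ", i, ": chromosome not terminated by $ or @")
    genes <- suppressWarnings(as.integer(tok[-length(tok)]))
    if (anyNA(genes) || any(genes == 0L))
      stop("line ", i, ": malformed gene token")
    chromosomes[[length(chromosomes) + 1L]] <- genes
    circular <- c(circular, term == "@")
  }
  ids <- abs(unlist(chromosomes))
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate gene id ", dup)
  }
  sensitive <- NULL
  ancestral <- NULL
  side_path <- paste0(path, ".genes.tsv")
  if (sidecar && file.exists(side_path)) {
    df <- utils::read.table(side_path, header = TRUE, sep = "\t")
    sensitive <- as.logical(df$sensitive[order(df$gene_id)])
    ancestral <- as.integer(df$ancestral_chromosome[order(df$gene_id)])
  }
  new_dcj_genome(chromosomes, circular, sensitive, ancestral)
}

#' Built-in toy fixtures
#'
#' Small hand-checkable objects used in examples and tests:
#' \describe{
#'   \item{"two-chromosome"}{2 linear chromosomes of 10 genes each, no
#'     sensitive genes.}
#'   \item{"single-translocation"}{the two-chromosome genome plus a copy to
#'     which one reciprocal translocation (cuts after gene 5 on each
#'     chromosome) has been applied; \code{s} between them is computable by
#'     hand.}
#'   \item{"ds-illegal-rejoin"}{a genome/move pair in which both exchanged
#'     fragment pairs carry sensitive genes on both sides, so the
#'     dosage-sensitivity rule rejects the translocation.}
#'   \item{"ds-legal-rejoin"}{same cuts, but the exchanged fragments are free
#'     of sensitive genes, so the rule accepts.}
#'   \item{"additive-tree"}{a 5-taxon tree and its exact additive distance
#'     matrix, for neighbor-joining recovery.}
#' }
#'
#' @param kind fixture name.
#' @param seed optional seed for kinds with random content.
#' @return Fixture contents (a list; see details).
#' @export
make_fixture <- function(kind = c("two-chromosome", "single-translocation",
                                  "ds-illegal-rejoin", "ds-legal-rejoin",
                                  "additive-tree"),
                         seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  two_chrom <- function(sensitive = rep(FALSE, 20))
    new_dcj_genome(list(1:10, 11:20), c(FALSE, FALSE), sensitive, rep(1:2, each = 10))
  switch(kind,
    "two-chromosome" = list(genome = two_chrom()),
    "single-translocation" = {
      g <- two_chrom()
      mv <- build_move(g, 1L, 5L, 2L, 5L, 0L)
      list(a = g, b = apply_move(g, mv), move = mv)
    },
    "ds-illegal-rejoin" = {
      sens <- rep(FALSE, 20)
      sens[c(3, 8, 13, 18)] <- TRUE  # sensitive on both sides of both cuts
      g <- two_chrom(sens)
      list(genome = g, move = build_move(g, 1L, 5L, 2L, 5L, 0L))
    },
    "ds-legal-rejoin" = {
      sens <- rep(FALSE, 20)
      sens[c(3, 13)] <- TRUE  # only the retained prefixes carry sensitive genes
      g <- two_chrom(sens)
      list(genome = g, move = build_move(g, 1L, 5L, 2L, 5L, 0L))
    },
    "additive-tree" = {
      tr <- ape::read.tree(text = "((A:3,B:2):2,(C:4,D:1):3,E:6);")
      D <- ape::cophenetic.phylo(tr)
      list(tree = tr, distances = D[order(rownames(D)), order(colnames(D))])
    })
}
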