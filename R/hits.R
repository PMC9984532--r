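#' Exclusive Venn regions of hit sets
#'
#' Counts, for k hit sets, every one of the 2^k - 1 exclusive membership
#' regions (genes in exactly that combination of sets); region counts sum
#' to the size of the union.
#'
#' @param hit_sets Named list of character vectors (query -> hit genes),
#'   at least 2 sets.
#' @return Data frame with one logical membership column per set, a
#'   `region` label (set names joined by `&`), and `count`.
#' @examples
#' intersect_hits(list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = "c"))
#' @export
intersect_hits <- function(hit_sets) {
  if (length(hit_sets) < 2) stop("need at least 2 hit sets")
  if (is.null(names(hit_sets)) || any(names(hit_sets) == "")) {
    stop("hit sets must be named")
  }
  sets <- lapply(hit_sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(combos) <- names(sets)
  count <- apply(combos, 1, function(cmb) {
    if (!length(universe)) return(0L)
    sum(apply(member, 1, function(m) all(m == cmb)))
  })
  out <- cbind(combos, region = apply(combos, 1, function(cmb)
    paste(names(sets)[as.logical(cmb)], collapse = "&")),
    count = as.integer(count))
  rownames(out) <- NULL
  out
}

#' Read gene coordinate annotation
#' @param path TSV with columns `gene`, `chrom`, `start`, `end` (bp).
#' @return Data frame, validated (start <= end, positive coordinates).
#' @export
read_gene_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(gene = "character", chrom = "character"))
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(tab)))
  if (any(tab$start > tab$end) || any(tab$start <= 0)) {
    stop("gene annotation must have 0 < start <= end")
  }
  tab
}

#' Exclude hits genetically linked to the query locus
#'
#' Genes near the query marker locus co-segregate with it during the
#' screen's meiotic crosses and score as spurious interactions. A gene is
#' excluded when it lies on the locus chromosome and its nearest boundary
#' is strictly closer than `window` base pairs to the locus position.
#'
#' @param hits Character vector of hit gene identifiers.
#' @param locus List or vector with `chrom` and `position` (bp).
#' @param window Linkage window in bp (default 75000).
#' @param annotation Data frame as from [read_gene_annotation()].
#' @return List with `kept` and `excluded` gene vectors.
#' @export
linkage_filter <- function(hits, locus, window = 75000, annotation) {
  ann <- annotation[match(hits, annotation$gene), ]
  un <- hits[is.na(ann$gene)]
  if (length(un)) stop("unannotated hit gene(s): ", paste(un, collapse = ", "))
  chrom <- if (is.list(locus)) locus$chrom else locus[["chrom"]]
  pos <- as.numeric(if (is.list(locus)) locus$position else locus[["position"]])
  # distance 0 inside the gene body; otherwise gap to the nearest boundary
  dist <- pmax(ann$start - pos, pos - ann$end, 0)
  linked <- ann$chrom == chrom & dist < window
  list(kept = hits[!linked], excluded = hits[linked])
}

#' Read a gene-set collection
#' @param path Two-column TSV `term`, `gene` (one row per membership).
#' @param descriptions Optional TSV `term`, `description`.
#' @return Named list of character vectors, with a `descriptions`
#'   attribute when supplied.
#' @export
read_gene_sets <- function(path, descriptions = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  stopifnot(all(c("term", "gene") %in% names(tab)))
  sets <- split(tab$gene, tab$term)
  sets <- lapply(sets, unique)
  if (!is.null(descriptions)) {
    d <- utils::read.delim(descriptions, stringsAsFactors = FALSE,
                           colClasses = "character")
    attr(sets, "descriptions") <- stats::setNames(d$description, d$term)
  }
  sets
}

#' Hypergeometric gene-set enrichment of a hit list
#'
#' For each term, tests over-representation of the hit list in the term's
#' gene set by the hypergeometric upper tail: with universe size N, term
#' size K (after intersecting with the universe), hit-list size n and
#' overlap k, p = P(X >= k), X ~ Hypergeometric(N, K, n). Terms are
#' returned sorted by ascending p.
#'
#' @param hits Character vector of hit genes (subset of `universe`).
#' @param universe Character vector: all genes screened.
#' @param gene_sets Named list of character vectors (term -> genes).
#' @param top_n Keep only the top N terms by p (default 10); `Inf` for all.
#' @param adjust Add a BH-adjusted column? Default `FALSE` (the ranking is
#'   by raw p).
#' @return Data frame (`term`, `overlap`, `term_size`, `n_hits`,
#'   `universe_size`, `p`, optionally `p_adj`, `description`).
#' @export
hypergeometric_enrichment <- function(hits, universe, gene_sets,
                                      top_n = 10, adjust = FALSE) {
  universe <- unique(universe)
  hits <- unique(hits)
  if (!length(universe) || !length(hits)) stop("hits and universe must be non-empty")
  if (!all(hits %in% universe)) {
    stop("hits outside the universe: ",
         paste(utils::head(setdiff(hits, universe), 5), collapse = ", "))
  }
  N <- length(universe); n <- length(hits)
  res <- lapply(names(gene_sets), function(term) {
    set <- intersect(gene_sets[[term]], universe)
    K <- length(set)
    k <- length(intersect(hits, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, overlap = k, term_size = K, n_hits = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p, out$term), ]
  if (adjust) out$p_adj <- adjust_bh(out$p)
  desc <- attr(gene_sets, "descriptions")
  if (!is.null(desc)) out$description <- unname(desc[out$term])
  out <- utils::head(out, top_n)
  rownames(out) <- NULL
  out
}
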