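# Over-representation analysis: one-sided hypergeometric (Fisher exact
# upper tail) of a DE gene list against named gene sets, conditioned on
# the measured universe, with BH correction over all sets.

#' Gene-set collection
#'
#' @param sets named list of character vectors (set members).
#' @param universe character vector of gene ids; set members outside it are
#'   dropped.
#' @return list of class `gene_set_collection` with `sets` and `universe`.
#' @export
gene_set_collection <- function(sets, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty-input error: empty universe", call. = FALSE)
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must have unique names", call. = FALSE)
  }
  sets <- lapply(sets, function(s) intersect(unique(as.character(s)), universe))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Read a GMT file into a gene-set collection
#'
#' GMT dialect: tab-separated lines of set name, description, then member
#' genes. When `universe` is NULL the union of all members is used.
#' @param path GMT file path.
#' @param universe optional character vector of measured gene ids.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  sets <- fgsea::gmtPathways(path)
  if (is.null(universe)) universe <- unique(unlist(sets))
  gene_set_collection(sets, universe)
}

#' Write a gene-set collection as GMT
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation of a gene list against gene sets
#'
#' For each set, the upper-tail hypergeometric probability P(X >= k) of
#' observing k or more list members in the set, given set size K, list
#' size n and universe size N; BH adjustment over all sets in the
#' collection; enrichment score (k/n)/(K/N). Genes outside the universe
#' are dropped with a warning.
#'
#' @param de_genes character vector (e.g. one regulation arm of the primary
#'   DE list).
#' @param collection a [gene_set_collection()].
#' @return data.frame sorted by p then decreasing enrichment: set_name, k,
#'   K, n, N, p_value, fdr, enrichment_score.
#' @export
hypergeom_enrich <- function(de_genes, collection) {
  universe <- collection$universe
  de_genes <- unique(as.character(de_genes))
  outside <- setdiff(de_genes, universe)
  if (length(outside) > 0) {
    warning("dropping ", length(outside), " DE gene(s) outside the universe")
    de_genes <- intersect(de_genes, universe)
  }
  if (length(de_genes) == 0) stop("empty-input error: empty DE gene list",
                                  call. = FALSE)
  N <- length(universe)
  n <- length(de_genes)
  K <- vapply(collection$sets, length, 0L)
  k <- vapply(collection$sets, function(s) length(intersect(s, de_genes)), 0L)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  es <- ifelse(K > 0, (k / n) / (K / N), NA_real_)
  out <- data.frame(set_name = names(collection$sets), k = k, K = K,
                    n = n, N = N, p_value = unname(p), fdr = bh_fdr(unname(p)),
                    enrichment_score = unname(es), stringsAsFactors = FALSE)
  out <- out[order(out$p_value, -out$enrichment_score, out$set_name), ]
  rownames(out) <- NULL
  out
}

#' Split the primary-filter DE list by regulation direction
#' @param de `de_result` data.frame from [de_test()].
#' @return list with disjoint character vectors `up` and `down`.
#' @export
split_by_regulation <- function(de) {
  pass <- de[de$passes_primary, , drop = FALSE]
  list(up = pass$transcript_id[pass$regulation == "up"],
       down = pass$transcript_id[pass$regulation == "down"])
}
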