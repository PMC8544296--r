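#' Read gene sets from GMT
#'
#' Thin wrapper over `fgsea::gmtPathways()`; returns a named list of
#' character vectors (set id -> member gene ids).
#' @param path GMT file.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  fgsea::gmtPathways(path)
}

#' Over-representation analysis
#'
#' One-sided hypergeometric test of a query gene list against each gene set,
#' within a declared universe. For a set with `K` members in the universe of
#' size `N` and a query of size `n` with `k` hits, the p-value is the
#' upper-tail probability `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`. P-values are Benjamini-Hochberg adjusted
#' across all tested sets and results are sorted by p.
#'
#' Duplicate ids are collapsed; the query is intersected with the universe
#' (ids outside it cannot be hits or misses); sets are intersected with the
#' universe and sets left empty are dropped with a notice.
#'
#' @param query character vector of gene ids.
#' @param sets named list of character vectors ([read_gmt()]).
#' @param universe character vector: the background gene list (e.g. all genes
#'   with defined TE).
#' @return `data.table`: `set_id`, `k`, `n`, `K`, `N`, `p`, `fdr`.
#' @export
ora <- function(query, sets, universe) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (length(universe) == 0L) stop("empty universe")
  if (length(query) == 0L) stop("empty query")
  query <- intersect(query, universe)
  if (length(query) == 0L)
    stop("query and universe share no gene ids")
  if (is.null(names(sets)) || !is.list(sets)) stop("sets must be a named list")
  members <- lapply(sets, function(s) intersect(unique(s), universe))
  empty <- lengths(members) == 0L
  if (any(empty)) {
    message(sum(empty), " gene set(s) with no members in the universe dropped")
    members <- members[!empty]
  }
  if (length(members) == 0L) stop("no gene sets overlap the universe")
  N <- length(universe); n <- length(query)
  K <- lengths(members)
  k <- vapply(members, function(s) length(intersect(s, query)), integer(1))
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.table(set_id = names(members), k = k, n = n, K = K, N = N, p = p)
  out[, fdr := p.adjust(p, method = "BH")]
  setorder(out, p, set_id)
  out[]
}
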