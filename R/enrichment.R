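## Overlap enrichment between a hit list and an annotation gene set,
## with an exact hypergeometric test. The screen itself reports only the
## overlap percentages; the exact test is an extension and the output
## says so.

## Two-sided exact p for a 2x2 table with fixed margins: sum the
## probabilities of all tables at least as extreme (probability <= the
## observed table's, with a small relative tolerance for ties).
hyper_two_sided <- function(k, n, K, N) {
  support <- max(0L, n + K - N):min(n, K)
  pmf <- stats::dhyper(support, K, N - K, n)
  p_obs <- stats::dhyper(k, K, N - K, n)
  sum(pmf[pmf <= p_obs * (1 + 1e-7)])
}

hyper_one_sided <- function(k, n, K, N, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (alternative == "greater") {
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    stats::phyper(k, K, N - K, n)
  }
}

#' Overlap enrichment of a hit list in an annotation gene set
#'
#' Builds the 2x2 contingency table hits/non-hits x annotated/not over a
#' gene universe and reports overlap percentages, a hypergeometric exact
#' test and the sample odds ratio. The annotation is intersected with the
#' universe before counting, and the annotated-non-hit cell is `K - k`:
#' the genome-wide annotated count `K` is taken inclusive of hits, which
#' matches how such rates are usually reported alongside a hit-subset
#' rate.
#'
#' @param hits Character vector of hit genes (must lie in `universe`).
#' @param annotation Character vector of annotated genes.
#' @param universe Character vector, the gene universe.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return An object of class `overlap_result`: list with `k` (annotated
#'   hits), `n` (hits), `K` (annotated genes in universe, hits included),
#'   `N` (universe size), `pct_hits` (=100k/n), `pct_universe` (=100K/N),
#'   `fisher_p`, `odds_ratio` and `alternative`.
#' @export
overlap_enrichment <- function(hits, annotation, universe,
                               alternative = c("two.sided", "greater",
                                               "less")) {
  alternative <- match.arg(alternative)
  hits <- unique(as.character(hits))
  annotation <- unique(as.character(annotation))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty gene universe")
  if (length(hits) == 0L) stop("empty hit list")
  outside <- setdiff(hits, universe)
  if (length(outside) > 0L) {
    stop(sprintf("hit gene not in universe: %s", outside[1]))
  }
  annotation <- intersect(annotation, universe)

  N <- length(universe)
  n <- length(hits)
  K <- length(annotation)
  k <- length(intersect(hits, annotation))
  overlap_result(k, n, K, N, alternative)
}

#' Overlap enrichment from printed counts
#'
#' Same computation as [overlap_enrichment] but starting from the four
#' counts of the 2x2 table rather than gene sets; useful for checking
#' published overlap rates.
#'
#' @param k Annotated hits.
#' @param n Number of hits.
#' @param K Annotated genes in the universe (inclusive of hits).
#' @param N Universe size.
#' @param alternative Test sidedness, as in [overlap_enrichment].
#' @return An `overlap_result`.
#' @export
overlap_result <- function(k, n, K, N,
                           alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(k >= 0, k <= min(n, K), n <= N, K <= N, n >= 1)
  a <- k               # annotated hits
  b <- n - k           # unannotated hits
  c_ <- K - k          # annotated non-hits
  d <- N - n - K + k   # unannotated non-hits
  stopifnot(c_ >= 0, d >= 0)

  p <- if (alternative == "two.sided") hyper_two_sided(k, n, K, N)
       else hyper_one_sided(k, n, K, N, alternative)

  or <- if (K == 0L) NA_real_
        else if (b == 0L || c_ == 0L) {
          if (a == 0L || d == 0L) NA_real_ else Inf
        } else (a * d) / (b * c_)

  structure(list(k = as.integer(k), n = as.integer(n), K = as.integer(K),
                 N = as.integer(N),
                 pct_hits = 100 * k / n, pct_universe = 100 * K / N,
                 fisher_p = p, odds_ratio = or, alternative = alternative),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: %d of %d hits annotated (%.1f%%) vs %d of %d in universe (%.1f%%)\n",
              x$k, x$n, x$pct_hits, x$K, x$N, x$pct_universe))
  cat(sprintf("  exact test (%s; reported as an extension of the overlap rates): p = %.3g\n",
              x$alternative, x$fisher_p))
  cat(sprintf("  odds ratio = %.3g  [2x2 uses K - k annotated non-hits: the genome-wide count includes hits]\n",
              x$odds_ratio))
  invisible(x)
}

#' Read a gene set from a one-gene-per-line text file
#'
#' @param path File path; blank lines and leading/trailing whitespace are
#'   dropped.
#' @return Character vector of unique gene identifiers.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop(sprintf("gene set file not found: %s", path))
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}
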