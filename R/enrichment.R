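#' Enrichment configuration
#'
#' @param go_min_size,go_max_size In-universe gene-set size window applied in
#'   GO mode (defaults 10 and 500); KEGG mode applies no size filter.
#' @param p_cutoff Raw p-value cutoff for the \code{passed} flag (default
#'   0.05; pathway p-values are reported raw, a BH column is emitted for
#'   information only).
#' @return A list of class \code{enrichment_config}.
#' @export
enrichment_config <- function(go_min_size = 10L, go_max_size = 500L,
                              p_cutoff = 0.05) {
  if (!(go_min_size > 0 && go_min_size < go_max_size)) {
    stop("need 0 < go_min_size < go_max_size")
  }
  structure(list(go_min_size = as.integer(go_min_size),
                 go_max_size = as.integer(go_max_size),
                 p_cutoff = p_cutoff),
            class = "enrichment_config")
}

#' Fisher-exact enrichment of one gene set
#'
#' Tests over-representation of the hit genes (e.g. differentially expressed
#' proteins) in a gene set, against the analysed gene universe. The one-sided
#' (greater) p-value is the hypergeometric upper tail P(X >= a) for the 2x2
#' table a = |hits & set|, b = |set \ hits|, c = |hits \ set|, d = rest; the
#' odds ratio is the sample ratio a*d / (b*c), infinite when b*c = 0 and
#' a*d > 0, with no continuity correction.
#'
#' @param hits Character vector of hit genes; must be a subset of
#'   \code{universe}.
#' @param gene_set Character vector of set members (intersected with the
#'   universe before counting).
#' @param universe Character vector, the gene universe.
#' @return One-row data frame: \code{a, b, c, d, odds_ratio, p}.
#' @export
fisher_gene_set_test <- function(hits, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  hits <- unique(hits)
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  set_u <- unique(intersect(gene_set, universe))
  a <- length(intersect(hits, set_u))
  b <- length(set_u) - a
  c_ <- length(hits) - a
  d <- length(universe) - a - b - c_
  # upper-tail hypergeometric: white balls = in-set, draws = |hits|
  p <- stats::phyper(a - 1L, length(set_u), length(universe) - length(set_u),
                     length(hits), lower.tail = FALSE)
  or <- if (b * c_ == 0) {
    if (a * d > 0) Inf else NaN
  } else {
    (a * d) / (b * c_)
  }
  data.frame(a = a, b = b, c = c_, d = d, odds_ratio = or, p = p)
}

#' Enrichment scan over a gene-set collection
#'
#' Runs [fisher_gene_set_test()] over every set of a collection. In
#' \code{mode = "go"}, sets whose in-universe size falls outside
#' \code{[go_min_size, go_max_size]} are excluded before testing; KEGG mode
#' tests every set. Results are sorted by ascending p (ties by set name); the
#' \code{passed} flag marks raw p at or below the cutoff, and a BH column is
#' included for information.
#'
#' @param hits,universe As in [fisher_gene_set_test()].
#' @param collection A \code{gene_set_collection} (see [read_gmt()]) or named
#'   list of member vectors.
#' @param config An [enrichment_config()].
#' @param mode \code{"kegg"} (no size filter) or \code{"go"}.
#' @return Data frame: \code{set, size_in_universe, a, b, c, d, odds_ratio,
#'   p, bh, passed}.
#' @export
enrich_collection <- function(hits, collection, universe,
                              config = enrichment_config(),
                              mode = c("kegg", "go")) {
  mode <- match.arg(mode)
  if (length(collection) == 0L) stop("empty gene-set collection")
  universe <- unique(universe)
  sizes <- vapply(collection, function(s) length(unique(intersect(s, universe))),
                  integer(1L))
  keep <- rep(TRUE, length(collection))
  if (mode == "go") {
    keep <- sizes >= config$go_min_size & sizes <= config$go_max_size
  }
  nm <- names(collection)[keep]
  rows <- lapply(nm, function(n) fisher_gene_set_test(hits, collection[[n]], universe))
  out <- cbind(data.frame(set = nm, size_in_universe = sizes[keep],
                          stringsAsFactors = FALSE),
               do.call(rbind, rows))
  out <- out[order(out$p, out$set), , drop = FALSE]
  out$bh <- bh_fdr(out$p)
  out$passed <- out$p <= config$p_cutoff
  rownames(out) <- NULL
  out
}

#' Super-pathway composition of called metabolites
#'
#' Per direction group (up/down), the fraction of called metabolites in each
#' super-pathway class (e.g. the lipid share of the differentially expressed
#' metabolites). Unannotated metabolites fall into an \code{"unknown"} bucket
#' with a warning. Fractions sum to 1 within each direction.
#'
#' @param called Data frame with columns \code{analyte_id, direction}.
#' @param annotation Data frame with columns \code{analyte_id, super_pathway}.
#' @return Data frame: \code{direction, super_pathway, n, fraction}.
#' @export
composition_summary <- function(called, annotation) {
  if (nrow(called) == 0L) stop("empty called set")
  sp <- annotation$super_pathway[match(called$analyte_id, annotation$analyte_id)]
  if (anyNA(sp)) {
    warning(sum(is.na(sp)), " called metabolite(s) unannotated; bucketed as 'unknown'")
    sp[is.na(sp)] <- "unknown"
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(called)), called$direction), function(i) {
    tab <- table(sp[i])
    data.frame(direction = called$direction[i[1L]], super_pathway = names(tab),
               n = as.integer(tab), fraction = as.numeric(tab) / length(i),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
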