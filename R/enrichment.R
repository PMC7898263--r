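#' Map mouse genes to human homologs via a two-column table
#'
#' Many-to-one mappings are allowed; the mapped list is deduplicated and
#' genes absent from the table are reported, not silently dropped.
#'
#' @param genes character vector of source (mouse) symbols.
#' @param mapping data.frame whose first two columns are source and target
#'   symbols (e.g. mouse, human).
#' @return list: `mapped` (unique target symbols), `unmapped` (source
#'   symbols with no entry), `n_collapsed` (mappings lost to dedup).
#' @export
map_homologs <- function(genes, mapping) {
  stopifnot(is.data.frame(mapping), ncol(mapping) >= 2)
  if (!nrow(mapping)) stop("map_homologs: empty mapping table")
  src <- as.character(mapping[[1]]); tgt <- as.character(mapping[[2]])
  hit <- match(genes, src)
  mapped_all <- tgt[hit[!is.na(hit)]]
  mapped <- unique(mapped_all)
  list(mapped = mapped,
       unmapped = genes[is.na(hit)],
       n_collapsed = length(mapped_all) - length(mapped))
}

#' Hypergeometric over-representation analysis
#'
#' Per gene set: upper-tail hypergeometric p = P(X >= overlap) with
#' X ~ Hypergeom(universe, set-in-universe, list), BH-adjusted across the
#' collection. Gene-set membership is intersected with the universe first;
#' sets reduced below `min_set_size` are skipped. List genes outside the
#' universe are dropped with a warning.
#'
#' @param de_list character vector of genes of interest.
#' @param universe character vector; the background gene universe
#'   (typically the genes passing the detection filter of the originating
#'   comparison).
#' @param collection a `GeneSetCollection` from [read_gmt()], or a named
#'   list of gene vectors.
#' @param alpha_fdr FDR cutoff used when `significant_only` (default 0.05).
#' @param top_n truncate the significant table at this many sets.
#' @param min_set_size smallest in-universe set tested (default 3).
#' @param significant_only return only FDR < `alpha_fdr` sets, ranked by p
#'   and truncated at `top_n` (default); otherwise the full table.
#' @return data.frame: `set`, `overlap`, `set_size`, `list_size`,
#'   `universe_size`, `p`, `fdr`, `genes` (comma-joined overlap).
#' @export
ora_hypergeom <- function(de_list, universe, collection, alpha_fdr = 0.05,
                          top_n = 30, min_set_size = 3,
                          significant_only = TRUE) {
  sets <- if (inherits(collection, "GeneSetCollection")) collection$sets
          else collection
  universe <- unique(universe)
  outside <- setdiff(de_list, universe)
  if (length(outside))
    warning("ora_hypergeom: dropping ", length(outside),
            " list gene(s) outside the universe")
  de_list <- unique(intersect(de_list, universe))
  if (!length(de_list)) {
    warning("ora_hypergeom: empty gene list")
    return(data.frame(set = character(0), overlap = integer(0),
                      set_size = integer(0), list_size = integer(0),
                      universe_size = integer(0), p = numeric(0),
                      fdr = numeric(0), genes = character(0)))
  }
  N <- length(universe); n <- length(de_list)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    if (length(s) < min_set_size) return(NULL)
    ov <- intersect(s, de_list)
    k <- length(ov); K <- length(s)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, list_size = n,
               universe_size = N, p = p,
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) stop("ora_hypergeom: no testable set (all below min size)")
  rows$fdr <- bh_adjust(rows$p)
  rows <- rows[order(rows$p), c("set", "overlap", "set_size", "list_size",
                                "universe_size", "p", "fdr", "genes")]
  rownames(rows) <- NULL
  if (significant_only) utils::head(rows[rows$fdr < alpha_fdr, ], top_n)
  else rows
}
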