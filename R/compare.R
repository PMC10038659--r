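# Cross-muscle / cross-genotype set algebra and display matrices: Venn-style
# disjoint partitions, shared up/down regulation, z-scored heatmap matrices
# with hierarchical row ordering, and volcano coordinates.

#' A labelled up/down comparison set
#'
#' @param label Comparison label (e.g. `"EDL-dHT-vs-WT"`).
#' @param up,down Disjoint accession sets of up- and down-regulated proteins.
#' @return Classed list (`"comparison_set"`).
#' @export
comparison_set <- function(label, up, down) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(intersect(up, down)))
    stop("`up` and `down` must be disjoint")
  structure(list(label = label, up = up, down = down),
            class = "comparison_set")
}

#' Exhaustive disjoint Venn partition of 2-3 sets
#'
#' Every accession in the union is assigned to exactly one region: the set of
#' labels it belongs to (region names join the member labels with `"&"`).
#' Region counts therefore sum to the cardinality of the union.
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return List: `regions` (named list of accession vectors, one per
#'   non-empty label combination) and `counts`.
#' @export
venn_partition <- function(sets) {
  if (length(sets) < 2L || length(sets) > 3L)
    stop("`sets` must contain 2 or 3 sets")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  labs <- names(sets)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  region_of <- apply(membership, 1L, function(m)
    paste(labs[m], collapse = "&"))
  regions <- split(universe, region_of)
  # present every possible region, empty ones included
  combos <- unlist(lapply(seq_along(labs), function(k)
    utils::combn(labs, k, paste, collapse = "&", simplify = FALSE)),
    recursive = FALSE)
  combos <- unlist(combos)
  regions <- stats::setNames(
    lapply(combos, function(cb) regions[[cb]] %||% character(0)), combos)
  list(regions = regions, counts = vapply(regions, length, integer(1)))
}

#' Accessions regulated in the same direction across all comparisons
#'
#' @param sets List of [comparison_set()] objects (>= 2).
#' @param direction `"up"` or `"down"`.
#' @return Character vector: the intersection of the chosen direction.
#' @export
shared_direction <- function(sets, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(sets) < 2L) stop("need >= 2 comparison sets")
  Reduce(intersect, lapply(sets, function(s) s[[direction]]))
}

#' Build heatmap and volcano display matrices
#'
#' Volcano coordinates (`log2fc`, `-log10 p`, p = 0 capped and flagged) for
#' all tested proteins; a per-protein z-scored log2-intensity matrix
#' restricted to significant proteins, with rows ordered by average-linkage
#' hierarchical clustering on 1 - Pearson-correlation distance.
#'
#' @param results Differential results (with `significant`; see
#'   [differential_abundance()]).
#' @param quants Protein table from [rollup_proteins()].
#' @param design A [channel_design()].
#' @param p_cap Maximum `-log10 p` used when `p = 0` (default 300).
#' @return List: `volcano` (`data.frame`), `heatmap` (matrix), `row_order`.
#' @export
build_display_matrices <- function(results, quants, design, p_cap = 300) {
  stopifnot(inherits(design, "channel_design"))
  volcano <- data.frame(
    accession = results$accession,
    log2fc = results$log2fc,
    neg_log10_p = ifelse(results$p_value > 0,
                         pmin(-log10(results$p_value), p_cap), p_cap),
    capped = results$p_value == 0 | -log10(pmax(results$p_value,
                                                .Machine$double.xmin)) > p_cap,
    stringsAsFactors = FALSE
  )
  if (!"significant" %in% names(results))
    stop("`results` must carry a `significant` flag")
  sig <- results$accession[results$significant %in% TRUE]
  q <- quants[quants$accession %in% sig, , drop = FALSE]
  ch <- design$channels
  if (nrow(q) == 0L) {
    return(list(volcano = volcano,
                heatmap = matrix(numeric(0), 0L, length(ch),
                                 dimnames = list(NULL, ch)),
                row_order = character(0)))
  }
  L <- log2(pmax(as.matrix(q[, ch, drop = FALSE]), .Machine$double.xmin))
  rownames(L) <- q$accession
  mu <- rowMeans(L)
  sd <- sqrt(rowSums((L - mu)^2) / (ncol(L) - 1L))
  Z <- (L - mu) / ifelse(sd > 0, sd, 1)
  if (nrow(Z) >= 3L) {
    d <- stats::as.dist(1 - stats::cor(t(Z)))
    ord <- stats::hclust(d, method = "average")$order
  } else {
    ord <- seq_len(nrow(Z))
  }
  Z <- Z[ord, , drop = FALSE]
  list(volcano = volcano, heatmap = Z, row_order = rownames(Z))
}
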