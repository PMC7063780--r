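#' Select major carbon-flux products
#'
#' Restricts a strains-by-products carbon flux matrix to the products that
#' account for more than `threshold` of the total carbon flux in at least
#' one strain (per-strain, any-strain rule).  With the default threshold of
#' 0.03 this reproduces the "> 3% of the total carbon flux" inclusion rule
#' used for fermentation phenotype heatmaps.
#'
#' @param flux_matrix numeric matrix of carbon fluxes (mmol C-atoms/h),
#'   strains in rows, products in columns; see [carbon_flux_matrix()].
#' @param threshold minimum carbon-flux fraction (default 0.03).
#' @return The filtered matrix, with attributes `included` and `excluded`
#'   listing the retained and dropped product names.
#' @export
select_products <- function(flux_matrix, threshold = 0.03) {
  stopifnot(is.matrix(flux_matrix), nrow(flux_matrix) > 0,
            all(flux_matrix >= 0))
  totals <- rowSums(flux_matrix)
  if (any(totals <= 0)) stop("strain(s) with zero total carbon flux: ",
                             paste(rownames(flux_matrix)[totals <= 0],
                                   collapse = ", "))
  frac <- sweep(flux_matrix, 1, totals, "/")
  keep <- apply(frac, 2, function(col) any(col > threshold))
  if (!any(keep)) stop("all products fall below the inclusion threshold")
  out <- flux_matrix[, keep, drop = FALSE]
  attr(out, "included") <- colnames(flux_matrix)[keep]
  attr(out, "excluded") <- colnames(flux_matrix)[!keep]
  out
}

#' Hierarchical clustering of fermentation phenotypes
#'
#' Agglomerative clustering of strains by their carbon-flux profiles
#' (average linkage, Euclidean distance by default), cut into `k` groups.
#' Products (columns) are clustered the same way.  Rows are sorted by strain
#' id before clustering so the partition does not depend on input order, and
#' cluster labels are renumbered by first appearance in that sorted order.
#'
#' @param flux_matrix strains x products carbon flux matrix (typically the
#'   output of [select_products()]).
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @param metric distance metric passed to [stats::dist()]
#'   (default `"euclidean"`).
#' @param k number of strain clusters to cut (default 3).
#' @param scale_fluxes standardise columns before clustering
#'   (default `FALSE`: raw carbon flux units).
#' @return Object of class `"flux_clustering"`: list with `labels` (named
#'   integer vector), `strain_hclust`, `product_hclust`, `k`, `linkage`,
#'   `metric` and the clustered `matrix`.
#' @export
cluster_strains <- function(flux_matrix, linkage = "average",
                            metric = "euclidean", k = 3,
                            scale_fluxes = FALSE) {
  stopifnot(is.matrix(flux_matrix))
  if (k > nrow(flux_matrix))
    stop("k (", k, ") exceeds the number of strains (", nrow(flux_matrix), ")")
  m <- flux_matrix[order(rownames(flux_matrix)), , drop = FALSE]
  if (scale_fluxes) m <- scale(m)
  hc_s <- hclust(dist(m, method = metric), method = linkage)
  hc_p <- if (ncol(m) >= 2)
    hclust(dist(t(m), method = metric), method = linkage) else NULL
  raw <- cutree(hc_s, k = k)
  labels <- match(raw, unique(raw))        # renumber by first appearance
  names(labels) <- names(raw)
  structure(list(labels = labels, strain_hclust = hc_s,
                 product_hclust = hc_p, k = k, linkage = linkage,
                 metric = metric, matrix = m),
            class = "flux_clustering")
}

#' @export
print.flux_clustering <- function(x, ...) {
  cat(sprintf("Fermentation phenotype clustering (%s linkage, %s distance, k = %d)\n",
              x$linkage, x$metric, x$k))
  for (g in sort(unique(x$labels))) {
    cat(sprintf("  cluster %d: %s\n", g,
                paste(names(x$labels)[x$labels == g], collapse = ", ")))
  }
  invisible(x)
}

#' @export
plot.flux_clustering <- function(x, which = c("strains", "products"), ...) {
  which <- match.arg(which)
  hc <- if (which == "strains") x$strain_hclust else x$product_hclust
  if (is.null(hc)) stop("no ", which, " dendrogram available")
  plot(hc, main = paste("Carbon flux clustering:", which),
       xlab = "", sub = "", ...)
  invisible(x)
}

#' Export a strain dendrogram as Newick text
#'
#' @param clustering a [cluster_strains()] result.
#' @param path optional file path; if `NULL` the Newick string is returned.
#' @param which cluster tree to export, `"strains"` or `"products"`.
#' @return The Newick string (invisibly when written to a file).
#' @export
dendrogram_newick <- function(clustering, path = NULL,
                              which = c("strains", "products")) {
  which <- match.arg(which)
  hc <- if (which == "strains") clustering$strain_hclust
        else clustering$product_hclust
  if (is.null(hc)) stop("no ", which, " dendrogram available")
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Merge table of a strain dendrogram
#'
#' Flat representation of the agglomeration sequence (merge pairs and
#' heights), convenient for writing to TSV and for comparing against
#' reference implementations.
#'
#' @param clustering a [cluster_strains()] result.
#' @param which tree to tabulate.
#' @return data.frame with columns `step`, `left`, `right`, `height`
#'   (negative entries in `left`/`right` are singleton strains, positive
#'   entries reference earlier merge steps, as in [stats::hclust()]).
#' @export
merge_table <- function(clustering, which = c("strains", "products")) {
  which <- match.arg(which)
  hc <- if (which == "strains") clustering$strain_hclust
        else clustering$product_hclust
  data.frame(step = seq_along(hc$height),
             left = hc$merge[, 1], right = hc$merge[, 2],
             height = hc$height)
}
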