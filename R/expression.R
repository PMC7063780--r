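#' RPKM normalisation of a count matrix
#'
#' Reads per kilobase of gene per million mapped reads:
#' `RPKM = counts * 1e9 / (gene_length_bp * total_mapped_reads)`, i.e. the
#' counts are first normalised by the library's total mapped reads and then
#' by gene length.
#'
#' @param counts genes x libraries matrix of read counts.
#' @param gene_lengths gene lengths in bp (recycled against rows; names, if
#'   present, must match rownames of `counts`).
#' @param totals total mapped reads per library (default: column sums).
#' @param lib_strains named character vector mapping library (column) names
#'   to strain ids; required for strain-level tests.
#' @return Object of class `"expression_matrix"`: list with `rpkm` (matrix),
#'   `gene_lengths`, `totals`, `lib_strains`.
#' @examples
#' m <- matrix(1000, 1, 1, dimnames = list("g1", "lib1"))
#' rpkm_normalize(m, gene_lengths = 1000, totals = 1e6)$rpkm  # 1000
#' @export
rpkm_normalize <- function(counts, gene_lengths, totals = colSums(counts),
                           lib_strains = NULL) {
  counts <- as.matrix(counts)
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0")
  if (any(totals <= 0)) stop("library totals must be > 0")
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts))) {
    if (!all(rownames(counts) %in% names(gene_lengths)))
      stop("gene_lengths missing entries for some genes")
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  rpkm <- sweep(sweep(counts, 2, totals, "/"), 1, gene_lengths, "/") * 1e9
  structure(list(rpkm = rpkm, gene_lengths = gene_lengths, totals = totals,
                 lib_strains = lib_strains),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("RPKM matrix: %d genes x %d libraries", nrow(x$rpkm),
              ncol(x$rpkm)))
  if (!is.null(x$lib_strains))
    cat(sprintf(" (%d strains)", length(unique(x$lib_strains))))
  cat("\n")
  invisible(x)
}

# replicate RPKM values of one gene in one strain
strain_reps <- function(expr, gene, strain) {
  if (is.null(expr$lib_strains))
    stop("expression matrix has no library-to-strain map")
  libs <- names(expr$lib_strains)[expr$lib_strains == strain]
  if (!length(libs)) stop("no libraries for strain ", strain)
  if (!gene %in% rownames(expr$rpkm)) stop("unknown gene ", gene)
  expr$rpkm[gene, libs]
}

#' Test the expression effect of an upstream mutation
#'
#' Compares replicate expression of the putative target gene between the
#' mutated strain and its pedigree parent.  The fold change is the ratio of
#' replicate mean RPKM (strain over parent); the p-value comes from a
#' two-sided Welch (unequal-variance) t test on log2(RPKM + 1) replicate
#' values.
#'
#' @param expr an [rpkm_normalize()] result with `lib_strains` set.
#' @param gene target gene id.
#' @param strain mutated strain id.
#' @param parent parent strain id.
#' @param pseudocount added before the log transform (default 1).
#' @return One-row data.frame: `strain`, `parent`, `gene`, `fold_change`,
#'   `p_value`, `n_strain`, `n_parent`.
#' @export
test_upstream_effect <- function(expr, gene, strain, parent,
                                 pseudocount = 1) {
  x <- strain_reps(expr, gene, strain)
  y <- strain_reps(expr, gene, parent)
  if (length(x) < 2 || length(y) < 2)
    stop("need >= 2 replicate libraries on both sides (",
         strain, ": ", length(x), ", ", parent, ": ", length(y), ")")
  if (mean(y) <= 0) stop("parent mean RPKM is zero for gene ", gene)
  fc <- mean(x) / mean(y)
  lx <- log2(x + pseudocount)
  ly <- log2(y + pseudocount)
  p <- tryCatch(t.test(lx, ly)$p.value,
                error = function(e) 1)   # both sides constant and equal
  data.frame(strain = strain, parent = parent, gene = gene,
             fold_change = fc, p_value = p,
             n_strain = length(x), n_parent = length(y))
}

#' Bonferroni family-wise significance filter
#'
#' Marks each test significant when `p <= alpha / m`, the Bonferroni
#' correction for a family of `m` tests.
#'
#' @param tests data.frame with a `p_value` column (e.g. rows from
#'   [test_upstream_effect()]).
#' @param m family size; defaults to the number of tests supplied (the
#'   number of upstream origin mutations tested).
#' @param alpha family-wise error level (default 0.05).
#' @return `tests` with columns `alpha`, `m` and logical `significant`.
#' @export
bonferroni_filter <- function(tests, m = nrow(tests), alpha = 0.05) {
  stopifnot("p_value" %in% names(tests))
  if (m < 1) stop("family size m must be >= 1")
  if (m < nrow(tests))
    stop("family size m (", m, ") smaller than the number of tests (",
         nrow(tests), ")")
  tests$alpha <- alpha
  tests$m <- m
  tests$significant <- tests$p_value <= alpha / m
  tests
}

#' Link upstream origin mutations to expression changes
#'
#' Runs [test_upstream_effect()] for every (strain, gene) pair in `links`
#' (strain's parent from the pedigree) and applies the Bonferroni filter.
#' Pairs whose strain or parent lack replicate expression libraries are
#' skipped with a warning.
#'
#' @param links data.frame with columns `strain` and `gene` (typically the
#'   upstream origin mutations from [annotate_upstream()] /
#'   [classify_provenance()]); extra columns are ignored.
#' @param expr an [rpkm_normalize()] result.
#' @param ped a [pedigree()].
#' @param m Bonferroni family size (default: number of links tested).
#' @param alpha family-wise error level (default 0.05).
#' @return data.frame of linkage tests with significance flags, one row per
#'   testable link.
#' @export
link_expression <- function(links, expr, ped, m = NULL, alpha = 0.05) {
  stopifnot(all(c("strain", "gene") %in% names(links)),
            inherits(ped, "pedigree"))
  rows <- list()
  for (i in seq_len(nrow(links))) {
    s <- links$strain[i]
    parent <- ped$parent_of[s]
    if (is.na(parent)) next                      # root strain: no comparison
    res <- tryCatch(
      test_upstream_effect(expr, links$gene[i], s, unname(parent)),
      error = function(e) {
        warning("skipping ", s, "/", links$gene[i], ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows))
    return(data.frame(strain = character(0), parent = character(0),
                      gene = character(0), fold_change = numeric(0),
                      p_value = numeric(0)))
  out <- do.call(rbind, rows)
  bonferroni_filter(out, m = if (is.null(m)) nrow(out) else m, alpha = alpha)
}
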