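#' Construct a strain pedigree
#'
#' A pedigree is a rooted tree of strains given as a parent/child edge list.
#' Exactly one root (a strain that never appears as a child) is required and
#' cycles are rejected.
#'
#' @param edges data.frame with columns `parent` and `child` (one row per
#'   derived strain).
#' @return Object of class `"pedigree"`: list with `edges`, `strains`,
#'   `root`, `parent_of` (named character vector) and `order` (strains in
#'   root-first topological order).
#' @export
pedigree <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("parent", "child") %in% names(edges)))
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  if (anyDuplicated(edges$child))
    stop("pedigree is not a tree: strain(s) with more than one parent: ",
         paste(unique(edges$child[duplicated(edges$child)]), collapse = ", "))
  strains <- unique(c(edges$parent, edges$child))
  roots <- setdiff(strains, edges$child)
  if (length(roots) != 1L)
    stop("pedigree must have exactly one root, found ", length(roots),
         if (length(roots)) paste0(": ", paste(roots, collapse = ", ")) else
           " (cyclic pedigree?)")
  parent_of <- setNames(edges$parent, edges$child)
  # BFS from the root; anything unreachable implies a cycle
  ord <- roots
  frontier <- roots
  while (length(frontier)) {
    nxt <- edges$child[edges$parent %in% frontier]
    ord <- c(ord, nxt)
    frontier <- nxt
  }
  if (length(ord) != length(strains))
    stop("cyclic pedigree: unreachable strain(s): ",
         paste(setdiff(strains, ord), collapse = ", "))
  structure(list(edges = edges, strains = strains, root = roots,
                 parent_of = parent_of, order = ord),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Strain pedigree:", length(x$strains), "strains, root", x$root, "\n")
  invisible(x)
}

# identity key for matching a mutation across strains; insertion elements
# are matched by (disrupted gene, element family) when that info is present
mutation_key <- function(mut) {
  key <- paste(mut$contig, mut$pos, mut$ref, mut$alt, sep = ":")
  if (!is.null(mut$class) && !is.null(mut$gene) && !is.null(mut$element)) {
    ie <- !is.na(mut$class) & mut$class == "insertion_element" &
      !is.na(mut$gene) & !is.na(mut$element)
    key[ie] <- paste("IE", mut$gene[ie], mut$element[ie], sep = ":")
  }
  key
}

#' Classify mutations as origin or inherited over a pedigree
#'
#' A mutation is *inherited* if it is present in the parent strain (DNA
#' allele fraction at or above `presence_threshold`) and an *origin* mutation
#' otherwise; all mutations of the root strain are origin mutations.
#' Parental signal below the presence threshold but at or above
#' `low_freq_min` does not count as presence, but is recorded in the
#' `low_freq_in_parent` column so mixed-population carry-over is visible.
#'
#' Insertion-element mutations are matched across strains by disrupted gene
#' and element family (columns `gene` and `element`, when present) rather
#' than by exact coordinates.
#'
#' @param mutations data.frame with columns `strain`, `contig`, `pos`
#'   (1-based), `ref`, `alt`, `dna_af`; optional `class`, `rna_af`, `gene`,
#'   `element`.
#' @param ped a [pedigree()].
#' @param presence_threshold DNA allele fraction at which a mutation counts
#'   as present in the parent (default 0.35, deliberately below 0.5 so mixed
#'   parental populations are still credited).
#' @param low_freq_min lower edge of the annotated low-frequency band
#'   (default 0.05).
#' @return `mutations` with columns `provenance` (`"origin"`/`"inherited"`)
#'   and `low_freq_in_parent` (logical) filled in.
#' @export
classify_provenance <- function(mutations, ped, presence_threshold = 0.35,
                                low_freq_min = 0.05) {
  stopifnot(inherits(ped, "pedigree"),
            all(c("strain", "contig", "pos", "ref", "alt", "dna_af")
                %in% names(mutations)))
  missing <- setdiff(unique(mutations$strain), ped$strains)
  if (length(missing))
    stop("strain(s) absent from pedigree: ", paste(missing, collapse = ", "))
  stopifnot(all(mutations$dna_af >= 0 & mutations$dna_af <= 1))
  key <- mutation_key(mutations)
  mutations$provenance <- "origin"
  mutations$low_freq_in_parent <- FALSE
  for (s in unique(mutations$strain)) {
    parent <- ped$parent_of[s]
    rows <- mutations$strain == s
    if (is.na(parent)) next                       # root: all origin
    prows <- mutations$strain == parent
    present <- key[prows][mutations$dna_af[prows] >= presence_threshold]
    lowfreq <- key[prows][mutations$dna_af[prows] >= low_freq_min &
                            mutations$dna_af[prows] < presence_threshold]
    mutations$provenance[rows][key[rows] %in% present] <- "inherited"
    mutations$low_freq_in_parent[rows] <- key[rows] %in% lowfreq
  }
  mutations
}

#' Annotate upstream (putatively regulatory) mutations
#'
#' Links each mutation to the gene whose strand-aware start lies within
#' `window` bp downstream of the mutation, provided the mutation does not
#' fall inside any annotated coding region.  For a plus-strand gene the
#' upstream window is the `window` bp before its start; for a minus-strand
#' gene, the `window` bp after its end.  The window is inclusive of
#' `window` bp; when several genes qualify the nearest one is linked.
#'
#' @param mutations data.frame with columns `contig`, `pos` (1-based);
#'   other columns are carried through.
#' @param genes data.frame with columns `gene_id`, `contig`, `start`, `end`
#'   (1-based, closed), `strand` (`"+"`/`"-"`).
#' @param window upstream window in bp (default 500).
#' @return `mutations` with columns `upstream_of` (gene id or `NA`) and
#'   `upstream_distance` (bp from the variant to the gene start, `NA` when
#'   unlinked).  Absence of a link is a valid result, not an error.
#' @export
annotate_upstream <- function(mutations, genes, window = 500) {
  stopifnot(all(c("contig", "pos") %in% names(mutations)),
            all(c("gene_id", "contig", "start", "end", "strand")
                %in% names(genes)))
  n <- nrow(mutations)
  mutations$upstream_of <- NA_character_
  mutations$upstream_distance <- NA_integer_
  if (n == 0L) return(mutations)
  for (i in seq_len(n)) {
    pos <- mutations$pos[i]
    g <- genes[genes$contig == mutations$contig[i], , drop = FALSE]
    if (!nrow(g)) next
    inside <- any(pos >= g$start & pos <= g$end)
    if (inside) next                      # inside a coding region: no link
    d <- ifelse(g$strand == "+", g$start - pos, pos - g$end)
    ok <- d > 0 & d <= window
    if (!any(ok)) next
    j <- which(ok)[which.min(d[ok])]
    mutations$upstream_of[i] <- g$gene_id[j]
    mutations$upstream_distance[i] <- as.integer(d[j])
  }
  mutations
}

# gene containing each mutation (NA when intergenic), used for convergence
gene_of_mutation <- function(mutations, genes) {
  out <- rep(NA_character_, nrow(mutations))
  for (i in seq_len(nrow(mutations))) {
    g <- genes[genes$contig == mutations$contig[i] &
                 genes$start <= mutations$pos[i] &
                 genes$end >= mutations$pos[i], , drop = FALSE]
    if (nrow(g)) out[i] <- g$gene_id[1]
  }
  out
}

#' Find convergently mutated genes
#'
#' Tabulates origin mutations per gene (inherited mutations are excluded so
#' each evolutionary event is counted once) and reports the genes hit by at
#' least `min_hits` origin mutations.  A mutation counts toward the gene it
#' falls in, or toward its linked gene when it is an upstream mutation (see
#' [annotate_upstream()]).
#'
#' @param mutations data.frame of provenance-classified mutations (see
#'   [classify_provenance()]); if `upstream_of` is absent it is computed.
#' @param genes gene table as in [annotate_upstream()].
#' @param window upstream window in bp (used if links must be computed).
#' @param min_hits minimum number of origin mutations for a gene to be
#'   reported (default 2).
#' @return List with `summary` (data.frame: `gene_id`, `n_mutations`,
#'   `n_strains`, `strains`) and `detail` (the contributing mutation rows
#'   with their gene assignment).
#' @export
convergent_genes <- function(mutations, genes, window = 500, min_hits = 2) {
  if (!"provenance" %in% names(mutations))
    stop("mutations must be provenance-classified first")
  if (!"upstream_of" %in% names(mutations))
    mutations <- annotate_upstream(mutations, genes, window)
  ori <- mutations[mutations$provenance == "origin", , drop = FALSE]
  gene <- gene_of_mutation(ori, genes)
  gene[is.na(gene)] <- ori$upstream_of[is.na(gene)]
  ori$gene_hit <- gene
  ori <- ori[!is.na(ori$gene_hit), , drop = FALSE]
  if (!nrow(ori)) {
    return(list(summary = data.frame(gene_id = character(0),
                                     n_mutations = integer(0),
                                     n_strains = integer(0),
                                     strains = character(0)),
                detail = ori))
  }
  tab <- split(ori, ori$gene_hit)
  summ <- do.call(rbind, lapply(names(tab), function(g) {
    d <- tab[[g]]
    data.frame(gene_id = g, n_mutations = nrow(d),
               n_strains = length(unique(d$strain)),
               strains = paste(sort(unique(d$strain)), collapse = ","))
  }))
  summ <- summ[summ$n_mutations >= min_hits, , drop = FALSE]
  summ <- summ[order(-summ$n_mutations, summ$gene_id), , drop = FALSE]
  rownames(summ) <- NULL
  detail <- ori[ori$gene_hit %in% summ$gene_id, , drop = FALSE]
  list(summary = summ, detail = detail)
}

#' Flag subpopulation-takeover mutations
#'
#' Flags mutations seen at low frequency in the genome sequencing but at
#' near-fixation in the RNA-seq reads, the signature of a subpopulation that
#' overtook the culture between DNA sampling and RNA sampling.
#'
#' @param mutations data.frame with `dna_af` and `rna_af` columns.
#' @param dna_range DNA allele-fraction band treated as a minor
#'   subpopulation, default `[0.05, 0.5)`.
#' @param rna_min RNA allele fraction counting as near-fixation
#'   (default 0.9).
#' @return The flagged subset of `mutations` (possibly empty), with a
#'   `subpop_flag` column set to `TRUE`.
#' @export
subpopulation_flags <- function(mutations, dna_range = c(0.05, 0.5),
                                rna_min = 0.9) {
  stopifnot(all(c("dna_af", "rna_af") %in% names(mutations)))
  sel <- !is.na(mutations$rna_af) &
    mutations$dna_af >= dna_range[1] & mutations$dna_af < dna_range[2] &
    mutations$rna_af >= rna_min
  out <- mutations[sel, , drop = FALSE]
  if (nrow(out)) out$subpop_flag <- TRUE
  out
}
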