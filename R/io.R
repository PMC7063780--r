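# Readers/writers for the plain-text formats the pipeline exchanges:
# pedigree TSV, mutations as VCF 4.2 (+ TSV mirror), genes as GFF3,
# sequences as FASTA, measurement tables as TSV, registry/config as YAML.

#' Write / read a pedigree edge list
#'
#' @param ped a [pedigree()] or an edge data.frame (`parent`, `child`).
#' @param path file path.
#' @return `read_pedigree_tsv()` returns a [pedigree()].
#' @export
write_pedigree_tsv <- function(ped, path) {
  edges <- if (inherits(ped, "pedigree")) ped$edges else ped
  write.table(edges[, c("parent", "child")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_tsv
#' @export
read_pedigree_tsv <- function(path) {
  pedigree(read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE))
}

vcf_info_field <- function(value, tag, fmt = "%s") {
  ifelse(is.na(value), "", sprintf(paste0(";", tag, "=", fmt), value))
}

#' Write mutations as VCF 4.2
#'
#' One record per (strain, variant); strain, variant class, allele
#' fractions, provenance and upstream linkage travel in INFO fields
#' (`STRAIN`, `CLASS`, `DNA_AF`, `RNA_AF`, `PROVENANCE`, `UPSTREAM_OF`,
#' `DIST`).
#'
#' @param mutations mutation data.frame (see [classify_provenance()]).
#' @param path output path (plain-text `.vcf`).
#' @param contig_lengths optional named vector for `##contig` header lines.
#' @export
write_mutations_vcf <- function(mutations, path, contig_lengths = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=thermoflux",
    if (!is.null(contig_lengths))
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths)),
    "##INFO=<ID=STRAIN,Number=1,Type=String,Description=\"Strain id\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Variant class\">",
    "##INFO=<ID=DNA_AF,Number=1,Type=Float,Description=\"DNA allele fraction\">",
    "##INFO=<ID=RNA_AF,Number=1,Type=Float,Description=\"RNA allele fraction\">",
    "##INFO=<ID=PROVENANCE,Number=1,Type=String,Description=\"origin or inherited\">",
    "##INFO=<ID=UPSTREAM_OF,Number=1,Type=String,Description=\"Linked downstream gene\">",
    "##INFO=<ID=DIST,Number=1,Type=Integer,Description=\"Distance upstream of gene start (bp)\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  m <- mutations
  info <- paste0(
    "STRAIN=", m$strain,
    if (!is.null(m$class)) vcf_info_field(m$class, "CLASS") else "",
    sprintf(";DNA_AF=%g", m$dna_af),
    if (!is.null(m$rna_af)) vcf_info_field(m$rna_af, "RNA_AF", "%g") else "",
    if (!is.null(m$provenance))
      vcf_info_field(m$provenance, "PROVENANCE") else "",
    if (!is.null(m$upstream_of))
      vcf_info_field(m$upstream_of, "UPSTREAM_OF") else "",
    if (!is.null(m$upstream_distance))
      vcf_info_field(m$upstream_distance, "DIST", "%d") else "")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  m$contig, as.integer(m$pos), m$ref, m$alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read mutations from a VCF written by [write_mutations_vcf()]
#'
#' @param path VCF path.
#' @return Mutation data.frame (columns `strain`, `contig`, `pos`, `ref`,
#'   `alt`, `class`, `dna_af`, `rna_af`, plus provenance/upstream columns
#'   when present in INFO).
#' @export
read_mutations_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  grab <- function(tag, numeric = FALSE)
    vcfR::extract.info(v, element = tag, as.numeric = numeric)
  out <- data.frame(strain = grab("STRAIN"),
                    contig = fix$CHROM,
                    pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT,
                    class = grab("CLASS"),
                    dna_af = grab("DNA_AF", numeric = TRUE),
                    rna_af = grab("RNA_AF", numeric = TRUE),
                    stringsAsFactors = FALSE)
  prov <- grab("PROVENANCE")
  if (!all(is.na(prov))) out$provenance <- prov
  up <- grab("UPSTREAM_OF")
  if (!all(is.na(up))) {
    out$upstream_of <- up
    out$upstream_distance <- as.integer(grab("DIST", numeric = TRUE))
  }
  out
}

#' Write / read the mutation table as TSV (mirror of the VCF)
#'
#' @param mutations mutation data.frame.
#' @param path file path.
#' @export
write_mutations_tsv <- function(mutations, path) {
  write.table(mutations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mutations_tsv
#' @export
read_mutations_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read gene annotations as GFF3
#'
#' @param genes gene data.frame (`gene_id`, `contig`, `start`, `end`,
#'   `strand`).
#' @param path file path.
#' @return `read_genes_gff3()` returns the gene data.frame.
#' @export
write_genes_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tthermoflux\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$contig, as.integer(genes$start),
                     as.integer(genes$end), genes$strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_genes_gff3
#' @export
read_genes_gff3 <- function(path) {
  g <- ape::read.gff(path, GFF3 = TRUE)
  g <- g[g$type == "gene", , drop = FALSE]
  id <- sub("^.*ID=([^;]+).*$", "\\1", g$attributes)
  data.frame(gene_id = id, contig = as.character(g$seqid),
             start = g$start, end = g$end,
             strand = as.character(g$strand), stringsAsFactors = FALSE)
}

#' Write / read named sequences as FASTA
#'
#' @param sequences named character vector of DNA sequences.
#' @param path file path.
#' @return `read_fasta()` returns a named character vector.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' Write / read chemostat records as a long measurement table
#'
#' Long TSV with columns `strain`, `replicate`, `D_h`, `V_L`, `feed_g_l`,
#' `residual_g_l`, `analyte`, `value`, `unit`; products in mM, pellet
#' carbon/nitrogen in g/L.
#'
#' @param records list of [chemostat_record()] objects.
#' @param path file path.
#' @return `read_measurements_tsv()` returns a list of records.
#' @export
write_measurements_tsv <- function(records, path) {
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    rep_id <- if (!is.null(r$reactor))
      sprintf("r%d_s%d", r$reactor, if (is.null(r$sample)) 1L else r$sample)
    else as.character(i)
    data.frame(strain = r$strain_id, replicate = rep_id,
               D_h = r$D, V_L = r$V, feed_g_l = r$feed_substrate,
               residual_g_l = r$residual_substrate,
               analyte = c(names(r$products), "pellet_C", "pellet_N"),
               value = c(unname(r$products), r$pellet_C, r$pellet_N),
               unit = c(rep("mM", length(r$products)), "g_per_L",
                        "g_per_L"),
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements_tsv
#' @export
read_measurements_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  keys <- unique(d[, c("strain", "replicate")])
  lapply(seq_len(nrow(keys)), function(i) {
    s <- d[d$strain == keys$strain[i] & d$replicate == keys$replicate[i], ]
    prod <- s[!s$analyte %in% c("pellet_C", "pellet_N"), ]
    chemostat_record(
      strain_id = keys$strain[i], D = s$D_h[1], V = s$V_L[1],
      feed_substrate = s$feed_g_l[1], residual_substrate = s$residual_g_l[1],
      products = setNames(prod$value, prod$analyte),
      pellet_C = s$value[s$analyte == "pellet_C"][1],
      pellet_N = s$value[s$analyte == "pellet_N"][1])
  })
}

#' Write / read a per-base depth track as TSV
#'
#' @param track data.frame with `pos`, `depth`.
#' @param path file path.
#' @export
write_depth_tsv <- function(track, path) {
  write.table(track[, c("pos", "depth")], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_tsv
#' @export
read_depth_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write the metabolite registry as YAML
#'
#' @param registry registry data.frame ([metabolite_registry()]).
#' @param path file path.
#' @return `read_registry_yaml()` returns the registry data.frame.
#' @export
write_registry_yaml <- function(registry, path) {
  lst <- lapply(seq_len(nrow(registry)), function(i) as.list(registry[i, ]))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_registry_yaml
#' @export
read_registry_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(rbind, lapply(lst, as.data.frame))
}
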