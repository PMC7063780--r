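#' Locus model for marker-cassette genotyping
#'
#' Describes the segment layout of a deletion-target locus and the segment
#' copy number expected under each genotype.  In a single-crossover
#' (merodiploid) integration the marker cassette is flanked by two copies of
#' the downstream homology region, the 5' portion of the target gene is
#' absent, and the cassette is present once; a completed double-crossover
#' leaves a clean unmarked deletion.
#'
#' @param segments data.frame with columns `name`, `start`, `end` (1-based,
#'   closed, non-overlapping, ordered) locating `upstream_flank`,
#'   `target_5prime` and `downstream_homology` on the reference; the
#'   cassette lives on its own contig and carries no reference coordinates.
#' @param copy_numbers named list of expected copy-number vectors per
#'   genotype; the default encodes wild type `{1,1,1,0}`, clean deletion
#'   `{1,0,1,0}` and merodiploid `{1,0,2,1}` over (upstream_flank,
#'   target_5prime, downstream_homology, cassette).
#' @return Object of class `"locus_model"`.
#' @export
locus_model <- function(segments,
                        copy_numbers = list(
                          wild_type      = c(upstream_flank = 1, target_5prime = 1,
                                             downstream_homology = 1, cassette = 0),
                          clean_deletion = c(upstream_flank = 1, target_5prime = 0,
                                             downstream_homology = 1, cassette = 0),
                          merodiploid    = c(upstream_flank = 1, target_5prime = 0,
                                             downstream_homology = 2, cassette = 1))) {
  stopifnot(is.data.frame(segments),
            all(c("name", "start", "end") %in% names(segments)),
            all(segments$start <= segments$end))
  o <- order(segments$start)
  segments <- segments[o, , drop = FALSE]
  if (nrow(segments) > 1 &&
      any(segments$start[-1] <= segments$end[-nrow(segments)]))
    stop("locus segments must be non-overlapping and ordered")
  for (cn in copy_numbers) stopifnot(all(cn >= 0))
  structure(list(segments = segments, copy_numbers = copy_numbers),
            class = "locus_model")
}

#' Assemble genotype template sequences for a locus
#'
#' Builds the reference sequence expected under each genotype from the
#' segment sequences, for read re-mapping and in-silico PCR:
#' wild type = upstream_flank + target_5prime + downstream_homology +
#' remainder; clean deletion drops the target 5' segment; the merodiploid
#' template is upstream_flank + downstream_homology + cassette +
#' downstream_homology + remainder (the duplicated homology region flanks
#' the integrated cassette).
#'
#' @param sequences named character vector (or `Biostrings::DNAStringSet`)
#'   with elements `upstream_flank`, `target_5prime`, `downstream_homology`,
#'   `cassette`, and optionally `remainder` (sequence 3' of the locus,
#'   defaults to empty).
#' @return Named character vector of templates: `wild_type`,
#'   `clean_deletion`, `merodiploid`.
#' @export
build_locus_templates <- function(sequences) {
  if (inherits(sequences, "DNAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  need <- c("upstream_flank", "target_5prime", "downstream_homology",
            "cassette")
  miss <- setdiff(need, names(sequences))
  if (length(miss))
    stop("missing segment sequence(s): ", paste(miss, collapse = ", "))
  rem <- if ("remainder" %in% names(sequences)) sequences[["remainder"]] else ""
  uf <- sequences[["upstream_flank"]]
  t5 <- sequences[["target_5prime"]]
  dh <- sequences[["downstream_homology"]]
  ca <- sequences[["cassette"]]
  c(wild_type = paste0(uf, t5, dh, rem),
    clean_deletion = paste0(uf, dh, rem),
    merodiploid = paste0(uf, dh, ca, dh, rem))
}

#' Per-segment relative read depth
#'
#' Median per-base depth of each model segment divided by the genome-wide
#' median depth, so a single-copy segment scores ~1, a duplicated segment
#' ~2, and a deleted segment ~0.  Relative depths are invariant to global
#' depth scaling.
#'
#' @param track data.frame with columns `pos` (1-based) and `depth`,
#'   covering the locus and enough flanking genome for a stable genome-wide
#'   median.
#' @param model a [locus_model()].
#' @return Named numeric vector of relative depths, one per model segment.
#' @export
depth_evidence <- function(track, model) {
  stopifnot(inherits(model, "locus_model"),
            all(c("pos", "depth") %in% names(track)))
  if (!nrow(track)) stop("empty coverage track")
  gmed <- median(track$depth)
  if (gmed <= 0) stop("genome-wide median depth must be > 0")
  segs <- model$segments
  out <- vapply(seq_len(nrow(segs)), function(i) {
    d <- track$depth[track$pos >= segs$start[i] & track$pos <= segs$end[i]]
    if (!length(d)) stop("no coverage over segment ", segs$name[i])
    median(d) / gmed
  }, numeric(1))
  setNames(out, segs$name)
}

#' In-silico PCR on a linear template
#'
#' Predicts amplicon sizes for a primer pair on a template by exact
#' matching on both strands: each forward-primer site is paired with the
#' nearest downstream site of the reverse primer's reverse complement
#' (and symmetrically for the opposite orientation).  Amplicon length is
#' inclusive of both primers.
#'
#' @param template template sequence (character scalar).
#' @param fwd_primer,rev_primer primer sequences, at least 15 nt each.
#' @param max_len maximum product size reported (default 20000 bp).
#' @return Integer vector of amplicon lengths (possibly empty), sorted.
#' @export
insilico_pcr <- function(template, fwd_primer, rev_primer, max_len = 20000) {
  stopifnot(nchar(fwd_primer) >= 15, nchar(rev_primer) >= 15)
  tpl <- Biostrings::DNAString(toupper(template))
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(toupper(s))))
  products <- function(left, right_rc) {
    ls <- Biostrings::start(Biostrings::matchPattern(toupper(left), tpl))
    re <- Biostrings::end(Biostrings::matchPattern(right_rc, tpl))
    unlist(lapply(ls, function(s) {
      cand <- re[re >= s + nchar(left) + nchar(right_rc) - 1]
      if (!length(cand)) return(integer(0))
      len <- min(cand) - s + 1L
      if (len <= max_len) len else integer(0)
    }))
  }
  lens <- c(products(fwd_primer, rc(rev_primer)),
            products(rev_primer, rc(fwd_primer)))
  sort(unique(as.integer(lens)))
}

#' Call the genotype of a marker-cassette locus
#'
#' Combines per-segment relative depth and cassette-locus junction read
#' pairs into a genotype call:
#' * merodiploid: target 5' segment absent (relative depth <= `absent_max`),
#'   downstream homology at ~2x, and at least `min_junctions` read pairs
#'   linking cassette and locus;
#' * clean deletion: target 5' absent, downstream homology at ~1x, no
#'   junction pairs;
#' * wild type: every segment at ~1x and no junction evidence;
#' * anything else: ambiguous.
#'
#' @param rel_depth named numeric vector of relative depths with elements
#'   `upstream_flank`, `target_5prime`, `downstream_homology` (see
#'   [depth_evidence()]).
#' @param junction_pairs number of read pairs with one mate unambiguously in
#'   the cassette and the other in the locus.
#' @param depth_tol tolerance around the expected relative depth
#'   (default 0.4).
#' @param min_junctions junction pairs required to support integration
#'   (default 2).
#' @param absent_max relative depth at or below which a segment counts as
#'   absent (default 0.05).
#' @return One of `"wild_type"`, `"clean_deletion"`, `"merodiploid"`,
#'   `"ambiguous"`.
#' @export
call_locus_genotype <- function(rel_depth, junction_pairs, depth_tol = 0.4,
                                min_junctions = 2, absent_max = 0.05) {
  need <- c("upstream_flank", "target_5prime", "downstream_homology")
  stopifnot(all(need %in% names(rel_depth)), junction_pairs >= 0,
            all(rel_depth >= 0))
  uf <- rel_depth[["upstream_flank"]]
  t5 <- rel_depth[["target_5prime"]]
  dh <- rel_depth[["downstream_homology"]]
  near <- function(x, target) abs(x - target) <= depth_tol
  if (t5 <= absent_max && near(dh, 2) && junction_pairs >= min_junctions)
    return("merodiploid")
  if (t5 <= absent_max && near(dh, 1) && junction_pairs == 0)
    return("clean_deletion")
  if (near(uf, 1) && near(t5, 1) && near(dh, 1) &&
      junction_pairs < min_junctions)
    return("wild_type")
  "ambiguous"
}
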