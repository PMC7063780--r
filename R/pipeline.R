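#' Validate pipeline input files
#'
#' Parses each provided input and cross-checks identifiers; content problems
#' are returned as structured diagnostics, never raised.
#'
#' @param paths named list of file paths; recognised names: `pedigree`
#'   (TSV), `mutations_vcf`, `genes_gff3`, `fasta`, `measurements`
#'   (TSV).  Missing names are simply skipped.
#' @return data.frame with columns `severity` (`"error"`/`"warning"`),
#'   `item`, `message`; zero rows when everything checks out.
#' @export
validate_inputs <- function(paths) {
  diags <- list()
  note <- function(severity, item, message)
    diags[[length(diags) + 1L]] <<- data.frame(
      severity = severity, item = item, message = message,
      stringsAsFactors = FALSE)
  parse_or_note <- function(item, reader) {
    p <- paths[[item]]
    if (is.null(p)) return(NULL)
    if (!file.exists(p)) {
      note("error", item, paste("file not found:", p))
      return(NULL)
    }
    tryCatch(reader(p), error = function(e) {
      note("error", item, paste("parse failure:", conditionMessage(e)))
      NULL
    })
  }
  ped <- parse_or_note("pedigree", read_pedigree_tsv)
  muts <- parse_or_note("mutations_vcf", read_mutations_vcf)
  genes <- parse_or_note("genes_gff3", read_genes_gff3)
  parse_or_note("fasta", read_fasta)
  parse_or_note("measurements", read_measurements_tsv)

  if (!is.null(muts) && !is.null(ped)) {
    missing <- setdiff(unique(muts$strain), ped$strains)
    for (s in missing)
      note("error", "mutations_vcf",
           paste0("strain ", s, " absent from pedigree"))
  }
  if (!is.null(genes)) {
    dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
    for (g in dup)
      note("error", "genes_gff3", paste0("duplicate gene ID ", g))
    bad <- genes$gene_id[genes$start > genes$end]
    for (g in bad)
      note("error", "genes_gff3",
           paste0("gene ", g, " has start > end (coordinate mix-up?)"))
  }
  if (!length(diags))
    return(data.frame(severity = character(0), item = character(0),
                      message = character(0)))
  do.call(rbind, diags)
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on a synthetic scenario
#'
#' Executes the pipeline stages in dependency order: synthetic-data
#' generation (all inputs written to `out_dir/inputs` in their standard
#' formats), carbon-flux profiling, phenotype clustering, mutation
#' provenance with convergence and subpopulation detection, merodiploid
#' locus genotyping, upstream-mutation expression linkage, and
#' solubilization kinetics.  Per-stage result tables land in
#' `out_dir/outputs`; a run log with package version, scenario hash and
#' seed is written to `out_dir/run_log.txt`.  Outputs are byte-identical
#' for identical configurations.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [scenario_config()]; its seed governs all randomness.
#' @param stages character vector of stages to run (dependency order is
#'   enforced; `simulate` always runs as it feeds everything else).
#' @param product_threshold carbon-flux inclusion threshold (default 0.03).
#' @param k number of phenotype clusters (default 3).
#' @param presence_threshold parental-presence allele fraction
#'   (default 0.35).
#' @param upstream_window upstream window, bp (default 500).
#' @param alpha,m Bonferroni level and family size (default `m`: number of
#'   tested links).
#' @param depth_tol,min_junctions merodiploid caller thresholds.
#' @return Invisibly, a list of stage results (`"pipeline_result"`).
#' @export
run_pipeline <- function(out_dir, config = scenario_config(),
                         stages = c("flux", "cluster", "provenance",
                                    "merodiploid", "exprlink",
                                    "solubilization"),
                         product_threshold = 0.03, k = 3,
                         presence_threshold = 0.35, upstream_window = 500,
                         alpha = 0.05, m = NULL, depth_tol = 0.4,
                         min_junctions = 2) {
  stopifnot(inherits(config, "scenario_config"))
  in_dir <- file.path(out_dir, "inputs")
  res_dir <- file.path(out_dir, "outputs")
  dir.create(in_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("thermoflux %s",
                         as.character(utils::packageVersion("thermoflux"))),
                 sprintf("seed %d", config$seed))
  result <- list(config = config)
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- simulate (always; all downstream stages consume its outputs) -------
  sim <- stage("simulate", function() {
    ped_data <- generate_pedigree(config)
    chem <- generate_chemostat_records(config)
    expr <- generate_expression(config)
    locus <- lapply(
      setNames(nm = c("wild_type", "clean_deletion", "merodiploid")),
      function(g) generate_locus_evidence(g, base_depth = 100,
                                          seed = config$seed))
    solub <- generate_solubilization(config)
    write_pedigree_tsv(ped_data$pedigree, file.path(in_dir, "pedigree.tsv"))
    write_mutations_vcf(ped_data$mutations,
                        file.path(in_dir, "mutations.vcf"),
                        contig_lengths = setNames(config$genome_length,
                                                  config$contig))
    write_mutations_tsv(ped_data$mutations,
                        file.path(in_dir, "mutations.tsv"))
    write_genes_gff3(ped_data$genes, file.path(in_dir, "genes.gff3"))
    write_measurements_tsv(chem$records, file.path(in_dir, "chemostat.tsv"))
    write_fasta(locus$merodiploid$templates,
                file.path(in_dir, "locus_templates.fasta"))
    write_tsv(solub$series, file.path(in_dir, "solubilization.tsv"))
    cnt <- data.frame(gene = rownames(expr$counts), expr$counts,
                      check.names = FALSE)
    write_tsv(cnt, file.path(in_dir, "expression_counts.tsv"))
    yaml::write_yaml(list(seed = config$seed,
                          measurement_cv = config$measurement_cv,
                          pellet_cn_mass_ratio = config$pellet_cn_mass_ratio,
                          feed_g_l = config$feed_g_l,
                          D = config$D, V = config$V),
                     file.path(in_dir, "scenario.yaml"))
    list(ped_data = ped_data, chem = chem, expr = expr, locus = locus,
         solub = solub)
  })
  result$simulate <- sim
  log_lines <- c(log_lines,
                 sprintf("scenario_md5 %s",
                         unname(tools::md5sum(file.path(in_dir,
                                                        "scenario.yaml")))),
                 "stage simulate ok")

  if ("flux" %in% stages) {
    result$flux <- stage("flux", function() {
      fm <- carbon_flux_matrix(sim$chem$records)
      write_tsv(data.frame(strain = rownames(fm), fm, check.names = FALSE),
                file.path(res_dir, "carbon_flux.tsv"))
      fm
    })
    log_lines <- c(log_lines, "stage flux ok")
  }

  if ("cluster" %in% stages) {
    result$cluster <- stage("cluster", function() {
      if (is.null(result$flux)) stop("flux stage required")
      sel <- select_products(result$flux, threshold = product_threshold)
      cl <- cluster_strains(sel, k = k)
      write_tsv(data.frame(strain = names(cl$labels),
                           cluster = unname(cl$labels)),
                file.path(res_dir, "clusters.tsv"))
      write_tsv(merge_table(cl), file.path(res_dir, "cluster_merges.tsv"))
      dendrogram_newick(cl, file.path(res_dir, "strain_dendrogram.nwk"))
      cl
    })
    log_lines <- c(log_lines, "stage cluster ok")
  }

  if ("provenance" %in% stages) {
    result$provenance <- stage("provenance", function() {
      pd <- sim$ped_data
      cls <- classify_provenance(pd$mutations, pd$pedigree,
                                 presence_threshold = presence_threshold)
      cls <- annotate_upstream(cls, pd$genes, window = upstream_window)
      conv <- convergent_genes(cls, pd$genes, window = upstream_window)
      sub <- subpopulation_flags(cls)
      write_mutations_vcf(cls, file.path(res_dir,
                                         "mutations_classified.vcf"),
                          contig_lengths = setNames(config$genome_length,
                                                    config$contig))
      write_tsv(conv$summary, file.path(res_dir, "convergent_genes.tsv"))
      write_tsv(sub, file.path(res_dir, "subpopulation_flags.tsv"))
      list(mutations = cls, convergent = conv, subpop = sub)
    })
    log_lines <- c(log_lines, "stage provenance ok")
  }

  if ("merodiploid" %in% stages) {
    result$merodiploid <- stage("merodiploid", function() {
      calls <- lapply(names(sim$locus), function(g) {
        ev <- sim$locus[[g]]
        rd <- depth_evidence(ev$track, ev$model)
        data.frame(true_genotype = g,
                   upstream_flank = rd[["upstream_flank"]],
                   target_5prime = rd[["target_5prime"]],
                   downstream_homology = rd[["downstream_homology"]],
                   junction_pairs = ev$n_junctions,
                   call = call_locus_genotype(rd, ev$n_junctions,
                                              depth_tol = depth_tol,
                                              min_junctions = min_junctions))
      })
      calls <- do.call(rbind, calls)
      write_tsv(calls, file.path(res_dir, "merodiploid_calls.tsv"))
      calls
    })
    log_lines <- c(log_lines, "stage merodiploid ok")
  }

  if ("exprlink" %in% stages) {
    result$exprlink <- stage("exprlink", function() {
      expr <- rpkm_normalize(sim$expr$counts, sim$expr$gene_lengths,
                             sim$expr$totals, sim$expr$lib_strains)
      if (is.null(result$provenance)) stop("provenance stage required")
      cls <- result$provenance$mutations
      links <- cls[cls$provenance == "origin" & !is.na(cls$upstream_of), ]
      links <- data.frame(strain = links$strain, gene = links$upstream_of)
      tests <- link_expression(links, expr, sim$ped_data$pedigree,
                               m = m, alpha = alpha)
      write_tsv(tests, file.path(res_dir, "expression_links.tsv"))
      tests
    })
    log_lines <- c(log_lines, "stage exprlink ok")
  }

  if ("solubilization" %in% stages) {
    result$solubilization <- stage("solubilization", function() {
      fits <- lapply(unique(sim$solub$series$strain), function(s) {
        avg <- average_solubilization_runs(sim$solub$series, s)
        fit <- fit_logistic_decay(avg$time_h, avg$value)
        pn <- average_solubilization_runs(sim$solub$series, s, "pellet_N")
        timing <- rate_vs_growth_timing(fit, pn$time_h, pn$value)
        cf <- coef(fit)
        data.frame(strain = s, A = cf[["A"]], B = cf[["B"]],
                   k = cf[["k"]], t0 = cf[["t0"]], rss = fit$rss,
                   max_rate = max_solubilization_rate(fit),
                   extent = solubilization_extent(avg$time_h, avg$value),
                   t_cell_max = timing$t_cell_max,
                   rate_precedes_cells = timing$rate_precedes_cells)
      })
      fits <- do.call(rbind, fits)
      write_tsv(fits, file.path(res_dir, "solubilization_fits.tsv"))
      fits
    })
    log_lines <- c(log_lines, "stage solubilization ok")
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  class(result) <- "pipeline_result"
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  done <- setdiff(names(x), "config")
  cat("Pipeline run (seed", x$config$seed, "): stages",
      paste(done, collapse = ", "), "\n")
  invisible(x)
}
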