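#' Default strain lineage edge list
#'
#' The three-lineage pedigree of 16 strains used throughout the synthetic
#' scenario: a wild-type root, an hpt-deletion platform strain, lineage 1
#' (ldh/pta deletions evolved by serial transfer or pH auxostat), lineage 2
#' (spo0A background, evolved by pH auxostat or chemostat) and lineage 3
#' (adhE deletion/reinsertion strains).
#'
#' @return data.frame with columns `parent`, `child`.
#' @export
default_lineage_edges <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
parent  child
LL1004  LL345
LL345   LL376
LL345   LL1036
LL345   LL1041
LL345   LL1111
LL376   LL372
LL376   LL373
LL372   LL1044
LL1044  LL374
LL1044  LL375
LL1036  LL1042
LL1042  LL1011
LL1042  LL1043
LL1111  LL1160
LL1111  LL1161
")
}

#' Default fermentation phenotype assignment
#'
#' Maps each chemostat-characterised strain to one of the three fermentation
#' phenotype clusters: `cluster1` wild-type-like (acetate producers, pta
#' intact), `cluster2` pta-deletion-like (pyruvate/amino-acid overflow),
#' `cluster3` evolved high-ethanol.  The adhE-deletion intermediate
#' (LL1111) is not grown in chemostats and carries no assignment.
#'
#' @return Named character vector, strain id -> cluster.
#' @export
default_phenotypes <- function() {
  c(LL1004 = "cluster1", LL345 = "cluster1", LL376 = "cluster1",
    LL372 = "cluster1", LL1036 = "cluster1", LL1160 = "cluster1",
    LL373 = "cluster2", LL1041 = "cluster2", LL1042 = "cluster2",
    LL1044 = "cluster2", LL375 = "cluster2",
    LL374 = "cluster3", LL1011 = "cluster3", LL1043 = "cluster3",
    LL1161 = "cluster3")
}

# theoretical-maximum ethanol (mM) for a given fraction of 4 mol/mol
# cellobiose at `feed` g/L fully consumed
ethanol_at_yield <- function(fraction, feed = 5) {
  fraction * 4 * feed * 1000 / 342.30
}

#' Default cluster product templates
#'
#' Mean steady-state product concentrations (mM) and pellet nitrogen (g/L)
#' per fermentation phenotype on 5 g/L cellobiose: wild-type-like strains
#' produce about 17 mM acetate and ethanol in a roughly 1:1 molar ratio;
#' pta-deletion strains lose acetate, accumulate pyruvate and amino acids
#' and halve their pellet carbon; evolved strains shift to ethanol at about
#' half the theoretical maximum yield.
#'
#' @return List of templates, one per cluster, each a list with `products`
#'   (named mM) and `pellet_N` (g/L).
#' @export
default_cluster_templates <- function() {
  list(
    cluster1 = list(products = c(ethanol = 17.5, acetate = 17, formate = 3,
                                 lactate = 0.6, pyruvate = 0.3,
                                 valine = 0.4, alanine = 0.3),
                    pellet_N = 0.055),
    cluster2 = list(products = c(ethanol = 17, acetate = 0.4, formate = 2,
                                 lactate = 0.5, pyruvate = 7,
                                 valine = 4, alanine = 1.5),
                    pellet_N = 0.028),
    cluster3 = list(products = c(ethanol = ethanol_at_yield(0.50),
                                 acetate = 0.4, formate = 1.5,
                                 lactate = 0.5, pyruvate = 2,
                                 valine = 1.5, alanine = 0.8),
                    pellet_N = 0.030)
  )
}

#' Default planted upstream-mutation expression effects
#'
#' Six upstream origin mutations with their true expression fold changes and
#' upstream distances, planted into the synthetic genome so the
#' mutation-to-expression linkage stage has known positives to recover.
#'
#' @return data.frame with columns `strain`, `gene`, `fold_change`,
#'   `distance`.
#' @export
default_upstream_effects <- function() {
  data.frame(
    strain = c("LL1042", "LL374", "LL375", "LL374", "LL376", "LL374"),
    gene = c("gene_003", "gene_012", "gene_017", "gene_022", "gene_031",
             "gene_040"),
    fold_change = c(4.33, 0.47, 2.29, 0.47, 0.52, 2.52),
    distance = c(89L, 10L, 81L, 8L, 14L, 197L),
    stringsAsFactors = FALSE)
}

#' Default high-solids solubilization truth parameters
#'
#' True logistic-decay parameters of the residual-cellulose curves for the
#' four evolved end-strains on 120 g glucose equivalents/L cellulose,
#' together with the peak pellet nitrogen and its timing.  The parameters
#' are calibrated to the study conditions: the largest extent of
#' solubilization is 109.2 g gluc eq/L and the highest maximum rate is
#' 3.19 g gluc eq/L/h; the cell peak always follows the inflection.
#'
#' @return data.frame with columns `strain`, `A`, `B`, `k`, `t0`,
#'   `n_max`, `t_cell_peak`.
#' @export
default_solubilization_truth <- function() {
  df <- data.frame(
    strain = c("LL374", "LL375", "LL1011", "LL1043"),
    A = c(10.8, 20.0, 14.0, 17.0),
    B = c(120, 120, 120, 120),
    k = c(0.100, 0.095, 4 * 3.19 / 106, 0.100),
    t0 = c(65, 75, 60, 70),
    n_max = c(0.56, 0.50, 0.53, 0.47),
    stringsAsFactors = FALSE)
  df$t_cell_peak <- df$t0 + 15
  df
}

#' Default high-solids endpoint product table (synthetic stand-in)
#'
#' Synthetic end-point concentrations (g/L) of the major fermentation
#' products for the four evolved end-strains on 120 g/L cellulose, anchored
#' to the study's reported titers (e.g. 29.9 g/L ethanol and 5.1 g/L
#' isobutanol for LL1043, 7.0 g/L valine for LL375, elevated fumarate in
#' lineage 2).  Used by [generate_highsolids_endpoints()].
#'
#' @return data.frame, one row per strain, products in g/L plus
#'   `solubilized_gluc_eq`.
#' @export
default_endpoint_products <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
strain solubilized_gluc_eq ethanol isobutanol butanediol acetate lactate formate fumarate pyruvate valine alanine pyroglutamate
LL374  109.2               24.5    3.0        1.2        3.1     1.8     1.0     1.2      1.3      5.5    1.5     0.3
LL375  100.0               15.0    2.5        1.0        2.0     1.6     0.9     2.8      1.2      7.0    1.8     0.4
LL1011 106.0               26.0    4.5        0.6        1.2     1.3     0.7     0.6      0.9      5.2    1.4     0.2
LL1043 103.0               29.9    5.1        0.8        2.0     1.5     0.8     0.9      1.0      4.9    1.2     0.3
")
}

#' Scenario configuration for the synthetic-data generators
#'
#' Bundles every ground-truth parameter of the synthetic study: the strain
#' pedigree, phenotype cluster assignment and product templates, the planted
#' convergent gene, subpopulation and upstream expression effects, noise
#' levels, and the synthetic genome layout (100 kb, 50 uniformly spaced
#' genes).  Identical configurations (same seed included) yield identical
#' synthetic data from every generator.
#'
#' @param seed integer seed governing all generator randomness.
#' @param lineage_edges pedigree edge list (data.frame `parent`, `child`).
#' @param phenotype_assignment named character vector strain -> cluster.
#' @param cluster_templates per-cluster product templates, see
#'   [default_cluster_templates()].
#' @param planted_convergent_gene gene receiving independent origin
#'   mutations in `convergent_strains`.
#' @param convergent_strains strains mutated in the convergent gene.
#' @param planted_subpop list with `strain` and `dna_af`: a mutation emitted
#'   at that DNA allele fraction with RNA allele fraction 1 (a
#'   subpopulation that overtook the culture).
#' @param upstream_effects planted upstream mutations with true expression
#'   fold changes, see [default_upstream_effects()].
#' @param measurement_cv coefficient of variation of concentration
#'   measurements (lognormal, default 0.05).
#' @param solub_cv CV of residual-cellulose measurements (default 0.03).
#' @param count_dispersion gamma-Poisson overdispersion of RNA-seq counts
#'   (default 0.005).
#' @param pellet_cn_mass_ratio biomass carbon-to-nitrogen mass ratio
#'   (default 3.35 g C/g N).
#' @param strain_overrides named list of per-strain product overrides (mM);
#'   by default LL1161's ethanol is set to 45 percent of the theoretical
#'   maximum yield.
#' @param feed_g_l cellobiose feed concentration, g/L (default 5).
#' @param D,V dilution rate (1/h) and working volume (L).
#' @param n_genes,genome_length,gene_length synthetic genome layout.
#' @param contig name of the synthetic chromosome.
#' @param three_rep_strains strains emulating a dropped expression library
#'   (3 instead of 4 replicates).
#' @param pellet_n_per_loading pellet nitrogen per g/L cellobiose loading in
#'   the wild-type titration (g/L per g/L).
#' @param solubilization_truth logistic truth table, see
#'   [default_solubilization_truth()].
#' @param endpoint_products high-solids endpoint table, see
#'   [default_endpoint_products()].
#' @param recovery_targets named vector of per-strain high-solids carbon
#'   recoveries (percent) the endpoint table is calibrated to.
#' @return Object of class `"scenario_config"` (a validated list).
#' @export
scenario_config <- function(seed = 1,
                            lineage_edges = default_lineage_edges(),
                            phenotype_assignment = default_phenotypes(),
                            cluster_templates = default_cluster_templates(),
                            planted_convergent_gene = "gene_025",
                            convergent_strains = c("LL1011", "LL1043"),
                            planted_subpop = list(strain = "LL374",
                                                  dna_af = 0.2),
                            upstream_effects = default_upstream_effects(),
                            measurement_cv = 0.05,
                            solub_cv = 0.03,
                            count_dispersion = 0.005,
                            pellet_cn_mass_ratio = 3.35,
                            strain_overrides = list(
                              LL1161 = c(ethanol = ethanol_at_yield(0.45))),
                            feed_g_l = 5, D = 0.1, V = 0.3,
                            n_genes = 50, genome_length = 100000L,
                            gene_length = 1200L,
                            contig = "synth_chr",
                            three_rep_strains = c("LL376", "LL1044",
                                                  "LL1042", "LL374",
                                                  "LL372"),
                            pellet_n_per_loading = 0.011,
                            solubilization_truth =
                              default_solubilization_truth(),
                            endpoint_products = default_endpoint_products(),
                            recovery_targets = c(LL1043 = 94.2,
                                                 LL374 = 78.5,
                                                 LL1011 = 77.9,
                                                 LL375 = 71.5)) {
  ped <- pedigree(lineage_edges)     # validates rooted acyclic tree
  stopifnot(measurement_cv >= 0, solub_cv >= 0, count_dispersion >= 0,
            pellet_cn_mass_ratio > 0, feed_g_l > 0, D > 0, V > 0)
  if (!all(names(phenotype_assignment) %in% ped$strains))
    stop("phenotype assignment references strains absent from the pedigree")
  if (!all(phenotype_assignment %in% names(cluster_templates)))
    stop("phenotype assignment references clusters without a template")
  stopifnot(all(upstream_effects$fold_change > 0),
            planted_subpop$dna_af >= 0, planted_subpop$dna_af <= 1,
            all(solubilization_truth$B > solubilization_truth$A),
            all(solubilization_truth$k > 0),
            all(solubilization_truth$t0 < solubilization_truth$t_cell_peak))
  cfg <- list(seed = as.integer(seed), pedigree = ped,
              lineage_edges = lineage_edges,
              phenotype_assignment = phenotype_assignment,
              cluster_templates = cluster_templates,
              planted_convergent_gene = planted_convergent_gene,
              convergent_strains = convergent_strains,
              planted_subpop = planted_subpop,
              upstream_effects = upstream_effects,
              measurement_cv = measurement_cv, solub_cv = solub_cv,
              count_dispersion = count_dispersion,
              pellet_cn_mass_ratio = pellet_cn_mass_ratio,
              strain_overrides = strain_overrides,
              feed_g_l = feed_g_l, D = D, V = V,
              n_genes = n_genes, genome_length = genome_length,
              gene_length = gene_length, contig = contig,
              three_rep_strains = three_rep_strains,
              pellet_n_per_loading = pellet_n_per_loading,
              solubilization_truth = solubilization_truth,
              endpoint_products = endpoint_products,
              recovery_targets = recovery_targets)
  class(cfg) <- "scenario_config"
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Synthetic scenario:", length(x$pedigree$strains), "strains,",
      x$n_genes, "genes on a", x$genome_length, "bp genome, seed",
      x$seed, "\n")
  invisible(x)
}

#' Gene annotation of the synthetic genome
#'
#' 50 uniformly spaced genes (1.2 kb, alternating strands, 800 bp
#' intergenic) over a 100 kb chromosome by default.
#'
#' @param config a [scenario_config()].
#' @return data.frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand` (1-based, closed).
#' @export
synthetic_genes <- function(config) {
  i <- seq_len(config$n_genes)
  spacing <- floor(config$genome_length / config$n_genes)
  start <- (i - 1L) * spacing + 501L
  data.frame(gene_id = sprintf("gene_%03d", i),
             contig = config$contig,
             start = start,
             end = start + config$gene_length - 1L,
             strand = rep(c("+", "-"), length.out = config$n_genes),
             stringsAsFactors = FALSE)
}

# genome positions that are neither genic nor inside any 500-bp upstream
# window; background mutations live here so gene-level convergence and
# upstream linkage carry planted signal only
neutral_positions <- function(config, genes, window = 500) {
  occupied <- rep(FALSE, config$genome_length)
  for (j in seq_len(nrow(genes))) {
    occupied[genes$start[j]:genes$end[j]] <- TRUE
    if (genes$strand[j] == "+") {
      lo <- max(1L, genes$start[j] - window)
      occupied[lo:(genes$start[j] - 1L)] <- TRUE
    } else {
      hi <- min(config$genome_length, genes$end[j] + window)
      occupied[(genes$end[j] + 1L):hi] <- TRUE
    }
  }
  which(!occupied)
}

random_base_pair <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  list(ref = ref, alt = unname(alt))
}

#' Generate the synthetic pedigree with mutation tables
#'
#' Walks the pedigree root-first; each strain inherits every parental
#' mutation and acquires 1-20 new origin mutations at neutral genome
#' positions (fixed, DNA allele fraction 1).  Planted signal: each
#' configured upstream effect adds an origin mutation at the configured
#' distance upstream of its target gene; the convergent gene receives the
#' same point mutation independently in each of the configured strains; the
#' subpopulation strain carries one mutation at the configured low DNA
#' allele fraction but RNA allele fraction 1.
#'
#' @param config a [scenario_config()].
#' @return List with `pedigree`, `mutations` (data.frame over all strains),
#'   `genes` (annotation) and `truth` (per-strain origin keys, convergent
#'   gene, subpopulation record, planted upstream mutations).
#' @export
generate_pedigree <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  ped <- config$pedigree
  genes <- synthetic_genes(config)
  neutral <- neutral_positions(config, genes)

  gene_row <- function(g) genes[genes$gene_id == g, , drop = FALSE]
  new_rows <- function(strain, pos, ref, alt, class, dna_af = 1,
                       rna_af = 1) {
    data.frame(strain = strain, contig = config$contig, pos = pos,
               ref = ref, alt = alt, class = class,
               dna_af = dna_af, rna_af = rna_af,
               gene = NA_character_, element = NA_character_,
               stringsAsFactors = FALSE)
  }

  # same ref/alt in every convergent strain: an identical point mutation
  # arising independently (the adhE D494G pattern)
  cg <- gene_row(config$planted_convergent_gene)
  if (!nrow(cg)) stop("planted convergent gene not in annotation")
  conv_pos <- cg$start + floor(config$gene_length / 2)
  conv_bp <- random_base_pair(1)

  tabs <- list()
  origin_keys <- list()
  upstream_truth <- list()
  classes <- c("SNV", "frameshift", "insertion_element", "other")
  for (s in ped$order) {
    parent <- ped$parent_of[s]
    inherited <- if (is.na(parent)) NULL else transform(tabs[[parent]],
                                                        strain = s)
    n_new <- sample(1:20, 1)
    pos <- sample(neutral, n_new)
    bp <- random_base_pair(n_new)
    mine <- new_rows(s, pos, bp$ref, bp$alt,
                     sample(classes, n_new, replace = TRUE,
                            prob = c(0.8, 0.1, 0.05, 0.05)))
    # planted upstream-effect mutations for this strain
    ue <- config$upstream_effects[config$upstream_effects$strain == s, ,
                                  drop = FALSE]
    for (r in seq_len(nrow(ue))) {
      g <- gene_row(ue$gene[r])
      upos <- if (g$strand == "+") g$start - ue$distance[r]
              else g$end + ue$distance[r]
      ubp <- random_base_pair(1)
      mine <- rbind(mine, new_rows(s, upos, ubp$ref, ubp$alt, "SNV"))
      upstream_truth[[length(upstream_truth) + 1L]] <-
        data.frame(strain = s, gene = ue$gene[r], pos = upos,
                   distance = ue$distance[r],
                   fold_change = ue$fold_change[r],
                   stringsAsFactors = FALSE)
    }
    if (s %in% config$convergent_strains)
      mine <- rbind(mine, new_rows(s, conv_pos, conv_bp$ref, conv_bp$alt,
                                   "SNV"))
    if (s == config$planted_subpop$strain)
      mine <- rbind(mine, new_rows(
        s, sample(neutral, 1), "G", "A", "SNV",
        dna_af = config$planted_subpop$dna_af, rna_af = 1.0))
    origin_keys[[s]] <- mutation_key(mine)
    tabs[[s]] <- rbind(inherited, mine)
  }
  mutations <- do.call(rbind, tabs[ped$order])
  rownames(mutations) <- NULL
  list(pedigree = ped, mutations = mutations, genes = genes,
       truth = list(origin_keys = origin_keys,
                    convergent_gene = config$planted_convergent_gene,
                    convergent_strains = config$convergent_strains,
                    subpop = config$planted_subpop,
                    upstream_mutations = do.call(rbind, upstream_truth)))
}

# one multiplicative lognormal noise factor per element, mean exactly 1
ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' Generate steady-state chemostat records
#'
#' Duplicate reactors sampled twice per strain; concentrations are the
#' cluster template means under multiplicative lognormal noise with the
#' configured CV; pellet nitrogen is drawn per template and pellet carbon as
#' nitrogen x C:N ratio x noise, so the C:N mass ratio has mean
#' `pellet_cn_mass_ratio`.  With `closed_balance = TRUE` the substrate feed
#' of each record is set so the consumed carbon exactly equals the carbon
#' accounted for by products, inferred CO2 and pellet (a fully
#' mass-balanced record set); by default the feed is the configured loading
#' and recovery is realistically below 100 percent.
#'
#' @param config a [scenario_config()].
#' @param n_reactors,n_times reactors per strain and samples per reactor.
#' @param closed_balance emit fully carbon-closed records (see above).
#' @param registry metabolite registry (used for balance closure).
#' @return List with `records` (list of [chemostat_record()]) and `truth`
#'   (templates and assignment).
#' @export
generate_chemostat_records <- function(config, n_reactors = 2, n_times = 2,
                                       closed_balance = FALSE,
                                       registry = metabolite_registry()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed + 1L)
  cv <- config$measurement_cv
  recs <- list()
  for (s in names(config$phenotype_assignment)) {
    cl <- config$phenotype_assignment[[s]]
    tpl <- config$cluster_templates[[cl]]
    prod <- tpl$products
    ov <- config$strain_overrides[[s]]
    if (!is.null(ov)) prod[names(ov)] <- ov
    for (r in seq_len(n_reactors)) {
      for (tm in seq_len(n_times)) {
        p <- prod * ln_noise(length(prod), cv)
        pn <- tpl$pellet_N * ln_noise(1, cv)
        pc <- pn * config$pellet_cn_mass_ratio * ln_noise(1, cv)
        feed <- config$feed_g_l
        if (closed_balance) {
          spec <- met_lookup(names(p), registry)
          mmolC <- sum(p * (spec$n_carbon + spec$co2_coeff)) +
            pc / 12.011 * 1000
          feed <- mmolC / 12 * 342.30 / 1000
        }
        rec <- chemostat_record(s, D = config$D, V = config$V,
                                feed_substrate = feed,
                                residual_substrate = 0,
                                products = p, pellet_C = pc, pellet_N = pn)
        rec$cluster <- cl
        rec$reactor <- r
        rec$sample <- tm
        recs[[length(recs) + 1L]] <- rec
      }
    }
  }
  list(records = recs,
       truth = list(templates = config$cluster_templates,
                    assignment = config$phenotype_assignment,
                    overrides = config$strain_overrides))
}

#' Generate a wild-type cellobiose titration (pellet C/N series)
#'
#' Steady states at several cellobiose loadings for a wild-type-like
#' strain: pellet nitrogen scales linearly with loading, pellet carbon is
#' nitrogen x C:N ratio, both under multiplicative lognormal noise.  The
#' least-squares slope of pellet carbon on pellet nitrogen over such a set
#' estimates the configured C:N mass ratio.
#'
#' @param config a [scenario_config()].
#' @param loadings cellobiose loadings, g/L (default 1 to 5).
#' @param n_reactors,n_times reactors per loading and samples per reactor.
#' @param cv measurement CV (default: the configured `measurement_cv`).
#' @return data.frame with columns `loading`, `reactor`, `sample`,
#'   `pellet_C`, `pellet_N` (g/L).
#' @export
generate_cn_titration <- function(config, loadings = 1:5, n_reactors = 2,
                                  n_times = 2,
                                  cv = config$measurement_cv) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed + 4L)
  grid <- expand.grid(sample = seq_len(n_times),
                      reactor = seq_len(n_reactors),
                      loading = loadings)
  n <- nrow(grid)
  pn <- config$pellet_n_per_loading * grid$loading * ln_noise(n, cv)
  pc <- pn * config$pellet_cn_mass_ratio * ln_noise(n, cv)
  data.frame(loading = grid$loading, reactor = grid$reactor,
             sample = grid$sample, pellet_C = pc, pellet_N = pn)
}

#' Generate replicate RNA-seq count matrices
#'
#' Gamma-Poisson counts around per-gene baselines; expression means are
#' inherited down the pedigree and multiplied by the planted fold change in
#' each configured (strain, gene) pair.  Four replicate libraries per
#' strain, three for strains emulating a dropped library.
#'
#' @param config a [scenario_config()].
#' @param baseline_mean_counts lognormal median of per-gene baseline counts
#'   (default 500).
#' @return List with `counts` (genes x libraries), `gene_lengths` (named,
#'   bp), `totals` (column sums), `lib_strains` (named library -> strain)
#'   and `truth` (`strain_means` matrix and the planted effects).
#' @export
generate_expression <- function(config, baseline_mean_counts = 500) {
  stopifnot(inherits(config, "scenario_config"))
  if (!all(config$upstream_effects$gene %in% synthetic_genes(config)$gene_id))
    stop("upstream effects reference genes absent from the annotation")
  set.seed(config$seed + 2L)
  genes <- synthetic_genes(config)
  ng <- nrow(genes)
  strains <- names(config$phenotype_assignment)
  base <- rlnorm(ng, meanlog = log(baseline_mean_counts), sdlog = 1)
  names(base) <- genes$gene_id

  # propagate means down the pedigree, applying planted fold changes
  means <- matrix(rep(base, length(strains)), nrow = ng,
                  dimnames = list(genes$gene_id, strains))
  for (s in config$pedigree$order) {
    if (!s %in% strains) next
    parent <- config$pedigree$parent_of[s]
    if (!is.na(parent) && parent %in% strains)
      means[, s] <- means[, parent]
    ue <- config$upstream_effects[config$upstream_effects$strain == s, ,
                                  drop = FALSE]
    for (r in seq_len(nrow(ue)))
      means[ue$gene[r], s] <- means[ue$gene[r], s] * ue$fold_change[r]
  }

  disp <- config$count_dispersion
  libs <- list()
  lib_strains <- character(0)
  for (s in strains) {
    nrep <- if (s %in% config$three_rep_strains) 3L else 4L
    for (r in seq_len(nrep)) {
      mu <- means[, s]
      lambda <- if (disp > 0)
        rgamma(ng, shape = 1 / disp, rate = 1 / (mu * disp)) else mu
      cnt <- rpois(ng, lambda)
      nm <- sprintf("%s_rep%d", s, r)
      libs[[nm]] <- cnt
      lib_strains[nm] <- s
    }
  }
  counts <- do.call(cbind, libs)
  rownames(counts) <- genes$gene_id
  gl <- setNames(genes$end - genes$start + 1L, genes$gene_id)
  list(counts = counts, gene_lengths = gl, totals = colSums(counts),
       lib_strains = lib_strains,
       truth = list(strain_means = means,
                    planted = config$upstream_effects))
}

# default segment layout of the synthetic marker-cassette locus
default_locus_segments <- function() {
  data.frame(name = c("upstream_flank", "target_5prime",
                      "downstream_homology"),
             start = c(5001L, 6001L, 6801L),
             end = c(6000L, 6800L, 7800L),
             stringsAsFactors = FALSE)
}

#' Generate locus evidence for a known genotype
#'
#' Simulates the evidence consumed by the merodiploid caller for a locus of
#' known genotype: a per-base Poisson coverage track whose expectation is
#' base depth x segment copy number (0, 1 or 2), junction read pairs linking
#' cassette and locus (merodiploid only), and the genotype template
#' sequences for in-silico PCR.
#'
#' @param genotype one of `"wild_type"`, `"clean_deletion"`,
#'   `"merodiploid"`.
#' @param base_depth single-copy expected depth (default 100).
#' @param seed RNG seed.
#' @param region_length simulated region length, bp; positions outside the
#'   model segments are single-copy genome baseline.
#' @return List with `genotype`, `model` (a [locus_model()]), `track`
#'   (data.frame `pos`, `depth`), `junction_pairs` (data.frame),
#'   `n_junctions`, `sequences` (named segment sequences) and `templates`
#'   (from [build_locus_templates()]).
#' @export
generate_locus_evidence <- function(genotype, base_depth = 100, seed = 1,
                                    region_length = 10000L) {
  ok <- c("wild_type", "clean_deletion", "merodiploid")
  if (!genotype %in% ok)
    stop("unknown genotype label '", genotype, "'; expected one of ",
         paste(ok, collapse = ", "))
  set.seed(seed)
  model <- locus_model(default_locus_segments())
  cn <- model$copy_numbers[[genotype]]
  copies <- rep(1, region_length)
  segs <- model$segments
  for (i in seq_len(nrow(segs)))
    copies[segs$start[i]:segs$end[i]] <- cn[[segs$name[i]]]
  depth <- rpois(region_length, base_depth * copies)
  track <- data.frame(pos = seq_len(region_length), depth = depth)

  n_j <- 0L
  if (genotype == "merodiploid")
    n_j <- max(1L, rpois(1, base_depth / 5))
  junctions <- if (n_j > 0) {
    data.frame(mate1_contig = "cassette",
               pos1 = sample.int(1500L, n_j, replace = TRUE),
               mate2_contig = "locus",
               pos2 = sample(segs$start[1]:segs$end[3], n_j,
                             replace = TRUE))
  } else {
    data.frame(mate1_contig = character(0), pos1 = integer(0),
               mate2_contig = character(0), pos2 = integer(0))
  }

  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  sequences <- c(upstream_flank = rand_seq(1000),
                 target_5prime = rand_seq(800),
                 downstream_homology = rand_seq(1000),
                 cassette = rand_seq(1500),
                 remainder = rand_seq(700))
  list(genotype = genotype, model = model, track = track,
       junction_pairs = junctions, n_junctions = n_j,
       sequences = sequences,
       templates = build_locus_templates(sequences),
       base_depth = base_depth)
}

#' Generate high-solids solubilization time series
#'
#' Residual cellulose follows the per-strain true logistic decay under
#' multiplicative lognormal noise; pellet nitrogen rises to its peak after
#' the logistic inflection and declines gently (a smooth gamma-shaped
#' curve), emulating the observation that the maximum solubilization rate
#' precedes peak cell density.  Duplicate reactor runs per strain.
#'
#' @param config a [scenario_config()].
#' @param times sampling times, h.
#' @param n_runs reactor runs per strain (default 2).
#' @param cv measurement CV (default: configured `solub_cv`).
#' @return List with `series` (long data.frame: `strain`, `run`, `time_h`,
#'   `analyte`, `value`, `unit`) and `truth` (logistic parameters, extent,
#'   max rate, cell-peak time).
#' @export
generate_solubilization <- function(config, times = seq(0, 220, by = 10),
                                    n_runs = 2, cv = config$solub_cv) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed + 3L)
  truth <- config$solubilization_truth
  truth$extent <- truth$B - truth$A
  truth$max_rate <- truth$k * (truth$B - truth$A) / 4
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    cellu <- tr$A + (tr$B - tr$A) / (1 + exp(tr$k * (times - tr$t0)))
    x <- times / tr$t_cell_peak
    pn <- tr$n_max * (x * exp(1 - x))^2
    for (r in seq_len(n_runs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        strain = tr$strain, run = r, time_h = times,
        analyte = "residual_cellulose",
        value = cellu * ln_noise(length(times), cv),
        unit = "g_gluc_eq_per_L")
      rows[[length(rows) + 1L]] <- data.frame(
        strain = tr$strain, run = r, time_h = times,
        analyte = "pellet_N",
        value = pn * ln_noise(length(times), cv),
        unit = "g_per_L")
    }
  }
  list(series = do.call(rbind, rows), truth = truth)
}

#' Average replicate runs of a solubilization series
#'
#' @param series long series data.frame from [generate_solubilization()].
#' @param strain strain id.
#' @param analyte analyte to extract (default residual cellulose).
#' @return data.frame `time_h`, `value` (mean over runs).
#' @export
average_solubilization_runs <- function(series, strain,
                                        analyte = "residual_cellulose") {
  d <- series[series$strain == strain & series$analyte == analyte, ]
  if (!nrow(d)) stop("no series for strain ", strain, " / ", analyte)
  agg <- aggregate(value ~ time_h, data = d, FUN = mean)
  agg[order(agg$time_h), ]
}

#' Synthetic high-solids endpoint table (stand-in for assay summaries)
#'
#' Builds the end-point fermentation summary for the four evolved
#' end-strains on 120 g/L cellulose: product titers (g/L) from the
#' configured endpoint table and a pellet-carbon column solved so each
#' strain's carbon recovery (products + inferred CO2 + pellet over consumed
#' substrate carbon) equals the configured per-strain recovery target.
#' This is a synthetic calibrated stand-in for measured endpoint assay
#' tables, exercising the full recovery computation.
#'
#' @param config a [scenario_config()].
#' @param registry metabolite registry.
#' @return data.frame with one row per strain: `solubilized_gluc_eq` (g/L),
#'   product titers (g/L), `pellet_C_g_l`, `pellet_N_g_l` and
#'   `substrate_mol_C` (mol C/L consumed).
#' @export
generate_highsolids_endpoints <- function(config,
                                          registry = metabolite_registry()) {
  stopifnot(inherits(config, "scenario_config"))
  ep <- config$endpoint_products
  prods <- setdiff(names(ep), c("strain", "solubilized_gluc_eq"))
  spec <- met_lookup(prods, registry)
  ep$substrate_mol_C <- ep$solubilized_gluc_eq / 180.16 * 6
  ep$pellet_C_g_l <- NA_real_
  for (i in seq_len(nrow(ep))) {
    target <- config$recovery_targets[[ep$strain[i]]]
    if (is.null(target)) stop("no recovery target for ", ep$strain[i])
    mol <- as.numeric(ep[i, prods]) / spec$molar_mass
    accounted <- sum(mol * (spec$n_carbon + spec$co2_coeff))
    pellet_molC <- target / 100 * ep$substrate_mol_C[i] - accounted
    if (pellet_molC <= 0)
      stop("endpoint table for ", ep$strain[i],
           " over-accounts carbon; cannot calibrate pellet")
    ep$pellet_C_g_l[i] <- pellet_molC * 12.011
  }
  ep$pellet_N_g_l <- ep$pellet_C_g_l / config$pellet_cn_mass_ratio
  ep
}
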