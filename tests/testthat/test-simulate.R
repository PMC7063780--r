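test_that("generators are seed-deterministic", {
  cfg <- test_config(seed = 7)
  p1 <- generate_pedigree(cfg)
  p2 <- generate_pedigree(test_config(seed = 7))
  expect_identical(p1$mutations, p2$mutations)
  # byte-identical mutation tables on disk
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_mutations_vcf(p1$mutations, f1)
  write_mutations_vcf(p2$mutations, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(generate_chemostat_records(cfg)$records,
                   generate_chemostat_records(test_config(seed = 7))$records)
  expect_identical(generate_expression(cfg)$counts,
                   generate_expression(test_config(seed = 7))$counts)
  expect_identical(generate_solubilization(cfg)$series,
                   generate_solubilization(test_config(seed = 7))$series)
  # a different seed changes the data
  expect_false(identical(p1$mutations,
                         generate_pedigree(test_config(seed = 8))$mutations))
})

test_that("mutation tables satisfy inheritance closure and plant the truth", {
  cfg <- test_config(seed = 11)
  pd <- generate_pedigree(cfg)
  ped <- pd$pedigree
  keys <- split(thermoflux:::mutation_key(pd$mutations),
                pd$mutations$strain)
  for (s in ped$strains) {
    parent <- ped$parent_of[s]
    if (is.na(parent)) next
    expect_true(all(keys[[parent]] %in% keys[[s]]),
                info = paste("inheritance closure", s))
  }
  # each strain gained 1-20 new origin mutations plus its planted ones
  for (s in ped$strains)
    expect_gte(length(keys[[s]]) -
                 if (is.na(ped$parent_of[s])) 0
                 else length(keys[[ped$parent_of[s]]]), 1)
  # planted subpopulation record: configured DNA af, RNA af ~ 1
  sub <- pd$mutations[pd$mutations$strain == cfg$planted_subpop$strain &
                        pd$mutations$dna_af < 0.5, ]
  expect_equal(nrow(sub), 1)
  expect_equal(sub$dna_af, 0.2)
  expect_equal(sub$rna_af, 1.0)
  # root strain classifies as all-origin
  cls <- classify_provenance(pd$mutations, ped)
  expect_true(all(cls$provenance[cls$strain == ped$root] == "origin"))
})

test_that("configured subpopulation fraction is honoured", {
  cfg <- test_config(seed = 3,
                     planted_subpop = list(strain = "LL375", dna_af = 0.2))
  pd <- generate_pedigree(cfg)
  sub <- pd$mutations[pd$mutations$strain == "LL375" &
                        pd$mutations$dna_af < 0.5, ]
  expect_equal(sub$dna_af, 0.2)
  expect_equal(sub$rna_af, 1.0)
})

test_that("defaults report exactly the planted convergence and subpopulation", {
  for (seed in c(1, 9, 23)) {
    cfg <- test_config(seed = seed)
    pd <- generate_pedigree(cfg)
    cls <- annotate_upstream(classify_provenance(pd$mutations, pd$pedigree),
                             pd$genes)
    conv <- convergent_genes(cls, pd$genes)
    # upstream-effect genes are each hit once (never convergent); the only
    # convergent gene is the planted one
    expect_equal(conv$summary$gene_id, cfg$planted_convergent_gene)
    expect_equal(sort(unique(conv$detail$strain)),
                 sort(cfg$convergent_strains))
    fl <- subpopulation_flags(cls)
    expect_equal(nrow(fl), 1)
    expect_equal(fl$strain, cfg$planted_subpop$strain)
  }
})

test_that("chemostat records hit the templates exactly in the noiseless limit", {
  cfg <- test_config(seed = 2, measurement_cv = 0)
  chem <- generate_chemostat_records(cfg)
  r <- Filter(function(x) x$strain_id == "LL1004", chem$records)[[1]]
  tpl <- cfg$cluster_templates$cluster1
  expect_equal(r$products, tpl$products)
  expect_equal(r$products[["acetate"]], 17)
  expect_equal(r$pellet_N, tpl$pellet_N)
  expect_equal(cn_ratio(r$pellet_C, r$pellet_N), 3.35)
  # strain overrides apply (LL1161 ethanol at 45% of theoretical)
  r61 <- Filter(function(x) x$strain_id == "LL1161", chem$records)[[1]]
  expect_equal(theoretical_ethanol_yield(r61$products[["ethanol"]],
                                         5000 / 342.30), 45)
})

test_that("a strain without a cluster template is rejected", {
  expect_error(
    scenario_config(phenotype_assignment = c(LL1004 = "cluster9")),
    "without a template")
  expect_error(
    scenario_config(phenotype_assignment = c(NOSUCH = "cluster1")),
    "absent from the pedigree")
  expect_error(scenario_config(lineage_edges = data.frame(
    parent = c("A", "B"), child = c("B", "A"))), "root")
})

test_that("pellet C/N draws have the configured mean mass ratio", {
  cfg <- test_config(seed = 10)
  d <- generate_cn_titration(cfg, loadings = 1:2, n_reactors = 2500,
                             n_times = 1, cv = 0.05)
  expect_gte(nrow(d), 5000)
  expect_lt(abs(mean(d$pellet_C / d$pellet_N) / 3.35 - 1), 0.01)
})

test_that("closed-balance records recover exactly 100% carbon", {
  cfg <- test_config(seed = 4, measurement_cv = 0)
  chem <- generate_chemostat_records(cfg, closed_balance = TRUE)
  reg <- metabolite_registry()
  for (r in chem$records[seq(1, length(chem$records), by = 4)]) {
    consumed_molC <- (r$feed_substrate - r$residual_substrate) / 342.30 * 12
    rec <- carbon_recovery(consumed_molC, r$products / 1000,
                           pellet_C = r$pellet_C / 12.011, registry = reg)
    expect_equal(rec, 100, tolerance = 1e-9)
  }
})

test_that("expression matrices carry replicate structure and planted means", {
  cfg <- test_config(seed = 5)
  ex <- generate_expression(cfg)
  # flagged strains emulate a dropped library: 3 instead of 4 replicates
  expect_equal(sum(ex$lib_strains == "LL1042"), 3)
  expect_equal(sum(ex$lib_strains == "LL1004"), 4)
  # planted mean structure: strain mean = parent mean x fold change
  means <- ex$truth$strain_means
  ue <- cfg$upstream_effects
  for (i in seq_len(nrow(ue))) {
    parent <- cfg$pedigree$parent_of[ue$strain[i]]
    expect_equal(means[ue$gene[i], ue$strain[i]],
                 means[ue$gene[i], parent] * ue$fold_change[i])
  }
  # unplanted genes keep the parental mean
  other <- setdiff(rownames(means), ue$gene)[1]
  expect_equal(means[other, "LL1042"], means[other, "LL1036"])
})

test_that("locus evidence encodes the expected copy-number layouts", {
  wt <- generate_locus_evidence("wild_type", base_depth = 120, seed = 2)
  expect_equal(nrow(wt$junction_pairs), 0)
  rd <- depth_evidence(wt$track, wt$model)
  expect_true(all(abs(rd - 1) < 0.15))
  cd <- generate_locus_evidence("clean_deletion", base_depth = 120, seed = 2)
  segs <- cd$model$segments
  t5 <- cd$track$depth[cd$track$pos >= segs$start[2] &
                         cd$track$pos <= segs$end[2]]
  expect_true(all(t5 == 0))                 # zero coverage, not just low
  expect_equal(nrow(cd$junction_pairs), 0)
  md <- generate_locus_evidence("merodiploid", base_depth = 120, seed = 2)
  rdm <- depth_evidence(md$track, md$model)
  expect_lt(abs(rdm[["downstream_homology"]] - 2), 0.2)
  expect_equal(rdm[["target_5prime"]], 0)
  expect_gte(md$n_junctions, 1)
})

test_that("solubilization series honour the truth curves and timing", {
  cfg <- test_config(seed = 6, solub_cv = 0)
  sim <- generate_solubilization(cfg, n_runs = 1)
  tr <- sim$truth[sim$truth$strain == "LL374", ]
  d <- sim$series[sim$series$strain == "LL374" &
                    sim$series$analyte == "residual_cellulose", ]
  expect_equal(d$value,
               tr$A + (tr$B - tr$A) / (1 + exp(tr$k * (d$time_h - tr$t0))))
  # truth: the inflection precedes the cell peak for every strain
  expect_true(all(sim$truth$t0 < sim$truth$t_cell_peak))
  # integral of the rate curve equals the plateau-minus-floor drop
  fit <- fit_logistic_decay(d$time_h, d$value)
  grid <- seq(0, 220, by = 0.1)
  integral <- sum(solubilization_rate(fit, grid)) * 0.1
  expect_equal(integral, d$value[1] - d$value[length(d$value)],
               tolerance = 0.01)
  # pellet N peaks after the inflection in the emitted series
  pn <- sim$series[sim$series$strain == "LL374" &
                     sim$series$analyte == "pellet_N", ]
  expect_gt(pn$time_h[which.max(pn$value)], tr$t0)
})

test_that("high-solids endpoint table is carbon-consistent with its targets", {
  cfg <- test_config(seed = 1)
  ep <- generate_highsolids_endpoints(cfg)
  reg <- metabolite_registry()
  prods <- setdiff(names(ep), c("strain", "solubilized_gluc_eq",
                                "substrate_mol_C", "pellet_C_g_l",
                                "pellet_N_g_l"))
  for (i in seq_len(nrow(ep))) {
    mol <- setNames(as.numeric(ep[i, prods]) /
                      met_lookup(prods, reg)$molar_mass, prods)
    rec <- carbon_recovery(ep$substrate_mol_C[i], mol,
                           pellet_C = ep$pellet_C_g_l[i] / 12.011)
    expect_equal(rec, cfg$recovery_targets[[ep$strain[i]]],
                 tolerance = 1e-9)
    expect_gt(ep$pellet_C_g_l[i], 0)
  }
})
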