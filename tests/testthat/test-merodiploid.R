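seg_seqs <- function(seed = 1) {
  set.seed(seed)
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  c(upstream_flank = rand_seq(400), target_5prime = rand_seq(300),
    downstream_homology = rand_seq(350), cassette = rand_seq(500),
    remainder = rand_seq(250))
}

test_that("template assembly follows the locus layouts", {
  seqs <- seg_seqs()
  tpl <- build_locus_templates(seqs)
  nc <- nchar(seqs)
  expect_equal(nchar(tpl[["wild_type"]]),
               nc[["upstream_flank"]] + nc[["target_5prime"]] +
                 nc[["downstream_homology"]] + nc[["remainder"]])
  # merodiploid = wild type - target 5' + cassette + extra homology copy
  expect_equal(nchar(tpl[["merodiploid"]]),
               nchar(tpl[["wild_type"]]) - nc[["target_5prime"]] +
                 nc[["cassette"]] + nc[["downstream_homology"]])
  # clean deletion carries no cassette sequence
  expect_false(grepl(seqs[["cassette"]], tpl[["clean_deletion"]],
                     fixed = TRUE))
  expect_true(grepl(seqs[["cassette"]], tpl[["merodiploid"]], fixed = TRUE))
  expect_error(build_locus_templates(seqs[-4]), "cassette")
})

test_that("relative depth is per-segment median over genome median", {
  model <- locus_model(data.frame(
    name = c("upstream_flank", "target_5prime", "downstream_homology"),
    start = c(101, 201, 301), end = c(200, 300, 400)))
  uniform <- data.frame(pos = 1:1000, depth = 80)
  expect_equal(unname(depth_evidence(uniform, model)), c(1, 1, 1))
  # merodiploid-shaped track: 0x over target, 2x over homology
  d <- rep(100, 1000); d[201:300] <- 0; d[301:400] <- 200
  track <- data.frame(pos = 1:1000, depth = d)
  rd <- depth_evidence(track, model)
  expect_equal(unname(rd), c(1, 0, 2))
  # global depth scaling leaves relative depths unchanged
  track2 <- transform(track, depth = depth * 7)
  expect_equal(depth_evidence(track2, model), rd)
  expect_error(depth_evidence(track[0, ], model), "empty")
  expect_error(depth_evidence(data.frame(pos = 1:10, depth = 0), model),
               "> 0")
})

test_that("in-silico PCR finds exact-match amplicons on both strands", {
  set.seed(33)
  body <- paste(sample(c("A", "C", "G", "T"), 460, replace = TRUE),
                collapse = "")
  fwd <- "ACGTACGTACGTACGTACGT"                  # 20 nt at positions 1-20
  rev_site <- "TTGACCTGAGGCTTACCGGA"             # occupies positions 481-500
  template <- paste0(fwd, body, rev_site)
  rev_primer <- rc_base(rev_site)
  expect_equal(insilico_pcr(template, fwd, rev_primer), 500L)
  # swapped primers (opposite orientation) give the same product
  expect_equal(insilico_pcr(template, rev_primer, fwd), 500L)
  # absent primer: no product
  expect_length(insilico_pcr(template, fwd, "GGGGGGGGGGGGGGGG"), 0)
  # max_len cut-off suppresses the product
  expect_length(insilico_pcr(template, fwd, rev_primer, max_len = 499), 0)
  expect_error(insilico_pcr(template, "ACGT", rev_primer), ">= 15")
})

test_that("in-silico PCR agrees with the substring-scan oracle", {
  set.seed(34)
  for (rep in 1:8) {
    tpl <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                 collapse = "")
    # plant primer sites at random positions (possibly multiple)
    fwd <- substr(tpl, 101, 120)
    rev <- rc_base(substr(tpl, 2301, 2320))
    expect_equal(insilico_pcr(tpl, fwd, rev), oracle_pcr(tpl, fwd, rev))
  }
})

test_that("merodiploid product exceeds the clean-deletion product by the insert", {
  seqs <- seg_seqs(7)
  tpl <- build_locus_templates(seqs)
  fwd <- substr(seqs[["upstream_flank"]], 1, 20)
  rev <- rc_base(substr(seqs[["remainder"]], 231, 250))
  p_mero <- insilico_pcr(tpl[["merodiploid"]], fwd, rev)
  p_clean <- insilico_pcr(tpl[["clean_deletion"]], fwd, rev)
  expect_length(p_mero, 1)
  expect_length(p_clean, 1)
  expect_equal(p_mero - p_clean,
               nchar(seqs[["cassette"]]) +
                 nchar(seqs[["downstream_homology"]]))
})

test_that("genotype calls follow the depth/junction decision rule", {
  rd <- function(uf, t5, dh) c(upstream_flank = uf, target_5prime = t5,
                               downstream_homology = dh)
  expect_equal(call_locus_genotype(rd(1, 1, 1), 0), "wild_type")
  expect_equal(call_locus_genotype(rd(1, 0, 2), 5), "merodiploid")
  expect_equal(call_locus_genotype(rd(1, 0, 1), 0), "clean_deletion")
  # junction evidence without the depth signature is ambiguous
  expect_equal(call_locus_genotype(rd(1, 1, 1), 10), "ambiguous")
  # duplicated homology but no junctions is ambiguous
  expect_equal(call_locus_genotype(rd(1, 0, 2), 0), "ambiguous")
  # clean-deletion depths with junction pairs is ambiguous
  expect_equal(call_locus_genotype(rd(1, 0, 1), 3), "ambiguous")
  # calls are invariant to global depth scaling (by construction of the
  # relative-depth input): rescaled evidence gives the same call
  expect_equal(call_locus_genotype(rd(1, 0, 2) * 1.0, 5),
               call_locus_genotype(rd(1, 0, 2), 5))
})

test_that("simulated evidence is called correctly across seeds", {
  for (seed in 1:25) {
    for (g in c("wild_type", "clean_deletion", "merodiploid")) {
      ev <- generate_locus_evidence(g, base_depth = 100, seed = seed)
      rd <- depth_evidence(ev$track, ev$model)
      expect_equal(call_locus_genotype(rd, ev$n_junctions), g,
                   info = sprintf("%s seed %d", g, seed))
    }
  }
  expect_error(generate_locus_evidence("duplication", seed = 1), "unknown")
})
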