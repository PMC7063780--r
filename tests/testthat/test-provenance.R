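mut_row <- function(strain, pos, dna_af = 1, rna_af = NA, ref = "A",
                    alt = "G", class = "SNV") {
  data.frame(strain = strain, contig = "chr", pos = pos, ref = ref,
             alt = alt, class = class, dna_af = dna_af, rna_af = rna_af,
             stringsAsFactors = FALSE)
}

test_that("pedigree construction validates tree shape", {
  ped <- pedigree(data.frame(parent = c("R", "R", "A"),
                             child = c("A", "B", "C")))
  expect_equal(ped$root, "R")
  expect_equal(unname(ped$parent_of["C"]), "A")
  expect_error(pedigree(data.frame(parent = c("A", "B"),
                                   child = c("B", "A"))), "root")
  expect_error(pedigree(data.frame(parent = c("R", "R", "A", "B"),
                                   child = c("A", "B", "C", "C"))),
               "more than one parent")
})

test_that("origin/inherited classification over a small pedigree", {
  ped <- pedigree(data.frame(parent = c("R", "A"), child = c("A", "B")))
  muts <- rbind(mut_row("R", 100), mut_row("A", 100), mut_row("A", 200),
                mut_row("B", 100), mut_row("B", 200), mut_row("B", 300),
                mut_row("B", 400, dna_af = 0.9))
  muts <- rbind(muts, mut_row("A", 400, dna_af = 0.2))  # low-freq in parent
  cls <- classify_provenance(muts, ped)
  get <- function(s, p) cls$provenance[cls$strain == s & cls$pos == p]
  # root mutations are all origin
  expect_equal(get("R", 100), "origin")
  # present in parent at af 1 -> inherited
  expect_equal(get("A", 100), "inherited")
  expect_equal(get("B", 100), "inherited")
  expect_equal(get("B", 200), "inherited")
  # absent from parent -> origin
  expect_equal(get("A", 200), "origin")
  expect_equal(get("B", 300), "origin")
  # parent carries it below the presence threshold: origin, but annotated
  expect_equal(get("B", 400), "origin")
  expect_true(cls$low_freq_in_parent[cls$strain == "B" & cls$pos == 400])
  expect_error(classify_provenance(mut_row("Z", 1), ped), "absent")
})

test_that("a shared mutation absent from the common parent is origin in both", {
  # the adhE D494G pattern: same point mutation in two sibling end-strains
  ped <- pedigree(data.frame(parent = c("LL1036", "LL1042", "LL1042"),
                             child = c("LL1042", "LL1011", "LL1043")))
  muts <- rbind(mut_row("LL1042", 10), mut_row("LL1011", 10),
                mut_row("LL1043", 10),
                mut_row("LL1011", 5000, ref = "A", alt = "G"),
                mut_row("LL1043", 5000, ref = "A", alt = "G"))
  cls <- classify_provenance(muts, ped)
  d494g <- cls[cls$pos == 5000, ]
  expect_equal(d494g$provenance, c("origin", "origin"))
  genes <- data.frame(gene_id = "adhE", contig = "chr", start = 4500,
                      end = 6000, strand = "+")
  conv <- convergent_genes(cls, genes)
  expect_equal(conv$summary$gene_id, "adhE")
  expect_equal(conv$summary$n_strains, 2)
})

test_that("upstream annotation is strand-aware with window and CDS rules", {
  genes <- data.frame(
    gene_id = c("gplus", "gminus", "blocker"),
    contig = "chr",
    start = c(10000, 20000, 8900),
    end = c(11000, 21000, 9099),
    strand = c("+", "-", "+"))
  ann <- function(pos) {
    a <- annotate_upstream(mut_row("s", pos), genes)
    list(gene = a$upstream_of, d = a$upstream_distance)
  }
  # 89 bp upstream of a plus-strand gene
  expect_equal(ann(10000 - 89)$gene, "gplus")
  expect_equal(ann(10000 - 89)$d, 89L)
  # window boundary: 500 inclusive, 501 excluded
  expect_equal(ann(9500)$gene, "gplus")
  expect_true(is.na(ann(10000 - 501)$gene))
  # inside a neighbouring CDS: no link even though within the window
  expect_true(is.na(ann(9050)$gene))
  # minus-strand gene: upstream lies after its end
  expect_equal(ann(21000 + 14)$gene, "gminus")
  expect_equal(ann(21000 + 14)$d, 14L)
  expect_true(is.na(ann(21000 + 501)$gene))
})

test_that("convergence requires two origin hits; inherited hits are ignored", {
  ped <- pedigree(data.frame(parent = c("R", "R", "R"),
                             child = c("A", "B", "C")))
  genes <- data.frame(gene_id = c("g1", "g2"), contig = "chr",
                      start = c(100, 1000), end = c(500, 1400),
                      strand = "+")
  muts <- rbind(mut_row("A", 150), mut_row("B", 160), mut_row("C", 170),
                mut_row("A", 1100))                     # g2 hit only once
  cls <- classify_provenance(muts, ped)
  conv <- convergent_genes(cls, genes)
  expect_equal(conv$summary$gene_id, "g1")
  expect_equal(conv$summary$n_mutations, 3)
  expect_equal(conv$summary$strains, "A,B,C")
  # an upstream mutation counts toward its linked gene
  muts2 <- rbind(muts, mut_row("B", 950))               # 50 bp upstream of g2
  conv2 <- convergent_genes(classify_provenance(muts2, ped), genes)
  expect_true("g2" %in% conv2$summary$gene_id)
  # inherited copies do not add hits: R's mutation inherited by A
  muts3 <- rbind(mut_row("R", 150), mut_row("A", 150))
  conv3 <- convergent_genes(classify_provenance(muts3, ped), genes)
  expect_equal(nrow(conv3$summary), 0)
})

test_that("subpopulation takeover flags use the DNA/RNA allele bands", {
  m <- rbind(mut_row("s", 1, dna_af = 0.2, rna_af = 1.0),
             mut_row("s", 2, dna_af = 0.98, rna_af = 1.0),
             mut_row("s", 3, dna_af = 0.2, rna_af = 0.2),
             mut_row("s", 4, dna_af = 0.49, rna_af = 0.9),
             mut_row("s", 5, dna_af = 0.5, rna_af = 1.0),
             mut_row("s", 6, dna_af = 0.04, rna_af = 1.0))
  fl <- subpopulation_flags(m)
  expect_equal(sort(fl$pos), c(1, 4))
})

test_that("classifier matches brute-force set arithmetic on random pedigrees", {
  set.seed(19)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    edges <- random_tree_edges(n)
    ped <- pedigree(edges)
    # random tables built independently of the classifier: each strain adds
    # new keys to everything its parent carries
    sets <- list()
    tabs <- list()
    for (s in ped$order) {
      parent <- ped$parent_of[s]
      inherited <- if (is.na(parent)) integer(0) else sets[[parent]]
      fresh <- max(c(0L, unlist(sets))) + seq_len(sample(1:6, 1))
      sets[[s]] <- c(inherited, fresh)
      tabs[[s]] <- mut_row(s, sets[[s]])
    }
    cls <- classify_provenance(do.call(rbind, tabs), ped)
    for (s in ped$order) {
      parent <- ped$parent_of[s]
      expected_origin <- if (is.na(parent)) sets[[s]]
                         else setdiff(sets[[s]], sets[[parent]])
      got <- cls[cls$strain == s, ]
      expect_equal(sort(got$pos[got$provenance == "origin"]),
                   sort(expected_origin))
      # inheritance consistency: inherited keys form a subset of the parent
      expect_true(all(got$pos[got$provenance == "inherited"] %in%
                        if (is.na(parent)) integer(0) else sets[[parent]]))
    }
    # total origin count = total mutations minus inherited duplicates
    n_inherited <- sum(vapply(ped$order, function(s) {
      p <- ped$parent_of[s]
      if (is.na(p)) 0L else length(intersect(sets[[s]], sets[[p]]))
    }, integer(1)))
    expect_equal(sum(cls$provenance == "origin"), nrow(cls) - n_inherited)
  }
})
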