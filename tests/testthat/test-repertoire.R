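# Count-matrix ingestion, domain tabulation and gene-set bookkeeping.

test_that("read_count_matrix validates cells and defaults empties to zero", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("taxon\tOG1\tOG2", "tA\t1\t0", "tB\t3\t2"), tf)
  m <- read_count_matrix(tf)
  expect_s3_class(m, "count_matrix")
  expect_equal(unname(rowSums(m)), c(1, 5))

  writeLines(c("taxon\tOG1\tOG2", "tA\t1\t", "tB\t3\t2"), tf)
  expect_warning(m2 <- read_count_matrix(tf), "empty cell")
  expect_equal(m2["tA", "OG2"], 0L)

  writeLines(c("taxon\tOG1\tOG2", "tA\t1\t-1", "tB\t3\t2"), tf)
  expect_error(read_count_matrix(tf), "negative")
  writeLines(c("taxon\tOG1\tOG2", "tA\t1\t1.5", "tB\t3\t2"), tf)
  expect_error(read_count_matrix(tf), "non-integer")
  writeLines(c("taxon\tOG1\tOG2", "tA\t1\tx", "tB\t3\t2"), tf)
  expect_error(read_count_matrix(tf), "non-numeric")
  writeLines(c("taxon\tOG1\tOG2", "tA\t1\t0", "tA\t3\t2"), tf)
  expect_error(read_count_matrix(tf), "duplicate taxon")

  # transposed layout (taxa in the header) is rejected, never auto-fixed
  writeLines(c("og\ttA\ttB", "OG1\t1\t0", "OG2\t3\t2"), tf)
  expect_error(read_count_matrix(tf, taxa = c("tA", "tB")), "transposed")
})

test_that("count matrix writer emits stable byte-identical output", {
  m <- toy_counts()
  f1 <- tempfile(); f2 <- tempfile()
  write_count_matrix(m, f1)
  write_count_matrix(m[2:1, 2:1], f2)  # permuted in memory
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(unclass(read_count_matrix(f1)), unclass(m), ignore_attr = TRUE)
})

test_that("map_gene_set reproduces curated-locus bookkeeping", {
  # 137 curated genes: 56 unmapped, 81 mapped many-to-one onto 59 orthogroups
  og_ids <- sprintf("OG%03d", 1:59)
  counts <- matrix(1L, nrow = 2, ncol = 59,
                   dimnames = list(c("tA", "tB"), og_ids))
  m <- count_matrix(counts)
  targets <- c(og_ids, sample(og_ids, 81 - 59, replace = TRUE))
  genes <- data.frame(gene_id = sprintf("g%03d", 1:137),
                      orthogroup = c(targets, rep("UNMAPPED", 56)),
                      stringsAsFactors = FALSE)
  res <- map_gene_set(genes, m, tag = "apoptosis")
  expect_equal(unlist(res$summary[c("total", "unmapped", "mapped",
                                    "distinct_orthogroups",
                                    "genes_sharing_orthogroup")],
                      use.names = FALSE),
               c(137, 56, 81, 59, 22))
  expect_setequal(count_tags(res$matrix)$apoptosis, og_ids)
  # consistency identities
  s <- res$summary
  expect_equal(s$total, s$unmapped + s$mapped)
  expect_equal(s$mapped - s$distinct_orthogroups, s$genes_sharing_orthogroup)
})

test_that("map_gene_set edge cases: all unmapped, singleton, unknown IDs", {
  m <- toy_counts()
  all_un <- data.frame(gene_id = c("g1", "g2"),
                       orthogroup = c("UNMAPPED", "UNMAPPED"))
  res <- map_gene_set(all_un, m, tag = "t")
  expect_equal(res$summary$distinct_orthogroups, 0)
  expect_length(count_tags(res$matrix)$t, 0)

  one <- data.frame(gene_id = "g1", orthogroup = "OG1")
  expect_equal(map_gene_set(one, m)$summary$distinct_orthogroups, 1)

  unk <- data.frame(gene_id = c("g1", "g2"), orthogroup = c("OG1", "OGX"))
  expect_warning(res2 <- map_gene_set(unk, m), "absent")
  expect_equal(res2$summary$unknown_orthogroups, 1)
  expect_equal(count_tags(res2$matrix)$focal, "OG1")

  expect_error(map_gene_set(all_un[0, ], m), "empty gene set")
})

test_that("tabulate_domain_counts counts occurrences and is additive", {
  rec <- data.frame(taxon = "clam", locus = "L1",
                    domains = "TAD;p53;TET;SAM", evalue = NA)
  expect_equal(unname(tabulate_domain_counts(rec)[1, ]), c(1L, 1L, 1L, 1L))

  fly <- data.frame(taxon = "fly", locus = "L1", domains = "p53", evalue = NA)
  expect_equal(unname(tabulate_domain_counts(fly)[1, ]), c(0L, 1L, 0L, 0L))

  two <- data.frame(taxon = c("x", "x"), locus = c("L1", "L2"),
                    domains = c("p53;SAM", "p53;SAM"), evalue = NA)
  expect_equal(unname(tabulate_domain_counts(two)[1, ]), c(0L, 2L, 0L, 2L))

  # additivity over disjoint record sets
  recs <- data.frame(taxon = rep(c("a", "b"), each = 3),
                     locus = paste0("L", 1:6),
                     domains = c("TAD;p53", "p53;SAM;SAM", "TET",
                                 "p53", "p53;TET", "SAM"), evalue = NA)
  whole <- tabulate_domain_counts(recs)
  parts <- tabulate_domain_counts(recs[1:3, ]) ; partb <- tabulate_domain_counts(recs[4:6, ])
  expect_equal(whole["a", ], parts["a", ])
  expect_equal(whole["b", ], partb["b", ])

  # out-of-vocabulary domains are tallied and ignored
  odd <- data.frame(taxon = "z", locus = "L1", domains = "p53;Kinase", evalue = NA)
  expect_message(pz <- tabulate_domain_counts(odd), "outside the vocabulary")
  expect_equal(unname(pz[1, ]), c(0L, 1L, 0L, 0L))

  # binarized form for Dollo mapping
  expect_equal(unname(tabulate_domain_counts(two, binarize = TRUE)[1, ]),
               c(0L, 1L, 0L, 1L))

  # empty input: zero-row profile, not an error
  expect_equal(nrow(tabulate_domain_counts(recs[0, ])), 0L)
})

test_that("repertoire_size sums tagged columns", {
  m <- toy_counts()
  expect_equal(unname(repertoire_size(m, "focal")), c(1, 5))
  expect_equal(unname(repertoire_size(m, "OG2")), c(0, 2))
  m0 <- count_matrix(unclass(m), tags = list(none = character(0)))
  expect_equal(unname(repertoire_size(m0, "none")), c(0L, 0L))
  expect_error(repertoire_size(m, "nope"), "unknown tag")
})

test_that("domain architecture reader enforces required fields", {
  tf <- tempfile()
  writeLines(c("# comment", "tA\tL1\tTAD;p53", "tB\tL1\tp53\t0.001"), tf)
  rec <- read_domain_architectures(tf)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$domains[1], "TAD;p53")
  writeLines("tA\tL1\t", tf)
  expect_error(read_domain_architectures(tf), "empty domain")
})
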