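mk_clusters <- function(start, end, label, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), label = label,
                 n_snps = 1L)
}

test_that("genome percentages follow cluster span ratios", {
  cl <- mk_clusters(c(1, 301), c(300, 400), c("Parent1", "Parent2"))
  gc <- genome_contributions(cl)
  expect_equal(gc$parent1_pct, 75)
  expect_equal(gc$parent2_pct, 25)
  expect_equal(gc$unknown_pct, 0)

  one <- genome_contributions(mk_clusters(10, 99, "Unknown"))
  expect_equal(one$unknown_pct, 100)

  expect_warning(genome_contributions(mk_clusters(integer(0), integer(0),
                                                  character(0))),
                 "No clusters")
})

test_that("genome percentages equal a per-base tally oracle", {
  withr::local_seed(67)
  for (rep in 1:15) {
    chain <- random_cluster_chain(sample(4:12, 1))
    gc <- genome_contributions(chain)
    want <- oracle_basewise_pct(as.data.frame(chain))
    expect_equal(gc$parent1_pct, unname(want[["Parent1"]]))
    expect_equal(gc$parent2_pct, unname(want[["Parent2"]]))
    expect_equal(gc$unknown_pct, unname(want[["Unknown"]]))
  }
})

test_that("pre-rounding percentages sum to exactly 100 per chromosome", {
  withr::local_seed(71)
  chain <- random_cluster_chain(40, n_chroms = 4)
  gc <- genome_contributions(chain)
  expect_equal(gc$parent1_pct + gc$parent2_pct + gc$unknown_pct,
               rep(100, nrow(gc)))
})

test_that("genome percentages are invariant under coordinate scaling", {
  withr::local_seed(73)
  chain <- random_cluster_chain(10)
  # doubling that preserves span ratios exactly: [s, e] -> [2s-1, 2e]
  doubled <- dplyr::mutate(chain, start = 2L * start - 1L,
                           end = 2L * end)
  expect_equal(
    tibble::as_tibble(genome_contributions(chain))[-2],
    tibble::as_tibble(genome_contributions(doubled))[-2]
  )
})

test_that("genes inherit the label of their dominant overlap", {
  cl <- mk_clusters(c(1, 1001), c(1000, 2000), c("Parent1", "Parent2"))
  genes <- tibble::tibble(
    gene_id = c("inside", "straddle_p1", "straddle_tie", "outside"),
    chrom = "chr1",
    start = c(100L, 801L, 901L, 5001L),
    end = c(200L, 1100L, 1100L, 5100L)
  )
  ga <- gene_contributions(cl, genes)
  expect_equal(ga$label,
               c("Parent1", "Parent1", "Unknown", "Unknown"))
  expect_equal(ga$overlap_bp[ga$gene_id == "inside"], 101L)
  expect_equal(ga$overlap_bp[ga$gene_id == "straddle_p1"], 200L)
  expect_equal(ga$overlap_bp[ga$gene_id == "outside"], 0L)
})

test_that("nested and overlapping genes are assigned independently", {
  cl <- mk_clusters(c(1, 501), c(500, 1500), c("Parent1", "Parent2"))
  genes <- tibble::tibble(
    gene_id = c("big", "nested"),
    chrom = "chr1",
    start = c(1L, 450L),
    end = c(1400L, 620L)
  )
  ga <- gene_contributions(cl, genes)
  expect_equal(ga$label[ga$gene_id == "big"], "Parent2")   # 900 vs 500
  expect_equal(ga$label[ga$gene_id == "nested"], "Parent2") # 120 vs 51
})

test_that("gene labels equal the per-base majority oracle on random layouts", {
  withr::local_seed(79)
  for (rep in 1:10) {
    chain <- random_cluster_chain(sample(4:10, 1))
    hi <- max(chain$end)
    genes <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:12),
      chrom = "chr1",
      start = sort(sample.int(hi, 12))
    ) |>
      dplyr::mutate(end = start + sample(50:400, 12, replace = TRUE))
    ga <- gene_contributions(chain, genes)
    want <- vapply(seq_len(nrow(genes)), function(k) {
      oracle_gene_label(genes$start[k], genes$end[k],
                        as.data.frame(chain))
    }, character(1))
    expect_equal(ga$label, want)
  }
})

test_that("gene percentages count labels per chromosome", {
  cl <- dplyr::bind_rows(
    mk_clusters(1, 10000, "Parent1", chrom = "chr1"),
    mk_clusters(1, 10000, "Parent2", chrom = "chr2")
  )
  genes <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    chrom = c("chr1", "chr1", "chr2", "chr3"),
    start = c(10L, 500L, 10L, 10L),
    end = c(100L, 600L, 100L, 100L)
  )
  gp <- gene_percentages(gene_contributions(cl, genes))
  expect_equal(gp$n_genes, c(2L, 1L, 1L))
  expect_equal(gp$parent1_pct, c(100, 0, 0))
  expect_equal(gp$parent2_pct, c(0, 100, 0))
  # gene on a chromosome with no clusters is Unknown
  expect_equal(gp$unknown_pct, c(0, 0, 100))
  expect_equal(gp$parent1_pct + gp$parent2_pct + gp$unknown_pct,
               rep(100, 3))
  expect_error(
    gene_contributions(cl, dplyr::bind_rows(genes, genes[1, ])),
    "duplicate"
  )
})

test_that("read_gtf_genes handles gene rows, exon fallback and bad records", {
  dir <- withr::local_tempdir()
  gtf1 <- file.path(dir, "genes.gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t100\t500\t.\t+\t.\tgene_id "gA"; gene_name "gA";',
    'chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "gA";',
    'chr2\tsrc\tgene\t50\t90\t.\t-\t.\tgene_id "gB";'
  ), gtf1)
  g <- read_gtf_genes(gtf1)
  expect_equal(g$gene_id, c("gA", "gB"))
  expect_equal(g$start, c(100L, 50L))
  expect_equal(g$end, c(500L, 90L))

  # exon-only annotation: union of exon spans per gene
  gtf2 <- file.path(dir, "exons.gtf")
  writeLines(c(
    'chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "gA";',
    'chr1\tsrc\texon\t400\t600\t.\t+\t.\tgene_id "gA";',
    'chr1\tsrc\texon\t800\t900\t.\t-\t.\tgene_id "gB";'
  ), gtf2)
  g2 <- read_gtf_genes(gtf2)
  expect_equal(g2$gene_id, c("gA", "gB"))
  expect_equal(g2$start, c(100L, 800L))
  expect_equal(g2$end, c(600L, 900L))

  # record without gene_id is skipped with a warning
  gtf3 <- file.path(dir, "noid.gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t100\t500\t.\t+\t.\tgene_id "gA";',
    'chr1\tsrc\tgene\t600\t700\t.\t+\t.\tother "x";'
  ), gtf3)
  expect_warning(g3 <- read_gtf_genes(gtf3), "gene_id")
  expect_equal(g3$gene_id, "gA")
})

test_that("contribution TSVs are tidy long tables at one decimal", {
  cl <- mk_clusters(c(1, 301), c(300, 400), c("Parent1", "Parent2"))
  gc <- genome_contributions(cl, individual = "kid")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contributions(gc, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(back), c("individual", "chrom", "label", "pct"))
  expect_equal(back$pct[back$label == "Parent1"], 75)
  expect_equal(nrow(back), 3L)
})
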