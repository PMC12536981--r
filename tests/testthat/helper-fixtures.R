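# Programmatic fixtures: small VCF/GTF texts and random generators built
# at test time.

vcf_header <- function(samples = "s1") {
  c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")
  )
}

vcf_line <- function(chrom, pos, ref, alt, gt = NULL, format = "GT") {
  base <- paste(chrom, pos, ".", ref, alt, ".", ".", ".", sep = "\t")
  if (is.null(gt)) base else paste(base, format, paste(gt, collapse = "\t"),
                                   sep = "\t")
}

write_test_vcf <- function(lines, dir = withr::local_tempdir(
                             .local_envir = parent.frame())) {
  path <- tempfile("fix", tmpdir = dir, fileext = ".vcf")
  writeLines(lines, path)
  path
}

# sorted labeled SNPs with random labels across several chromosomes
random_labeled_snps <- function(n, n_chroms = 3, max_pos = 50 * n,
                                labels = pedpaint::ancestry_levels()) {
  tibble::tibble(
    chrom = sort(sample(paste0("chr", seq_len(n_chroms)), n,
                        replace = TRUE)),
    label = sample(labels, n, replace = TRUE)
  ) |>
    dplyr::mutate(
      pos = sort(sample.int(max_pos, dplyr::n())),
      .by = "chrom"
    ) |>
    dplyr::select("chrom", "pos", "label")
}

# sorted, non-overlapping random cluster chain on one or more chromosomes
random_cluster_chain <- function(n, n_chroms = 1,
                                 labels = pedpaint::ancestry_levels()) {
  chrom <- sort(sample(paste0("chr", seq_len(n_chroms)), n,
                       replace = TRUE))
  spans <- sample(c(1:50, 500:2000), n, replace = TRUE)
  gaps <- sample(1:100, n, replace = TRUE)
  out <- tibble::tibble(chrom = chrom, span = spans, gap = gaps) |>
    dplyr::mutate(
      end = cumsum(.data$span + .data$gap),
      start = .data$end - .data$span + 1L,
      .by = "chrom"
    )
  tibble::tibble(
    chrom = out$chrom, start = out$start, end = out$end,
    label = sample(labels, n, replace = TRUE),
    n_snps = sample(1:20, n, replace = TRUE)
  )
}

# strip class/attribute decoration down to a plain data.frame for
# comparison with oracle output
plain_blocks <- function(x) {
  d <- as.data.frame(x)[, c("chrom", "start", "end", "label", "n_snps",
                            "span")]
  rownames(d) <- NULL
  d
}
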