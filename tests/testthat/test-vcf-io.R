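test_that("read_vcf maps fields across genotype dialects", {
  path <- write_test_vcf(c(
    vcf_header(),
    vcf_line("chr1", 100, "A", "G", "1/1"),
    vcf_line("chr1", 200, "a", "g,t", "2|2:31", format = "GT:DP"),
    vcf_line("chr2", 50, "C", ".")
  ))
  v <- read_vcf(path)
  expect_equal(v$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(v$pos, c(100L, 200L, 50L))
  expect_equal(v$ref, c("A", "A", "C"))           # lowercase uppercased
  expect_equal(v$alts, list("G", c("G", "T"), character(0)))
  expect_equal(v$gt, c("1/1", "2|2", "1"))        # GT-less record -> "1"
})

test_that("read_vcf handles header-only files and preserves order", {
  empty <- write_test_vcf(vcf_header())
  expect_equal(nrow(read_vcf(empty)), 0L)

  shuffled <- write_test_vcf(c(
    vcf_header(),
    vcf_line("chr2", 10, "A", "G", "1/1"),
    vcf_line("chr1", 99, "C", "T", "0/0")
  ))
  v <- read_vcf(shuffled)
  expect_equal(v$pos, c(10L, 99L))                # file order, not sorted
  expect_identical(read_vcf(shuffled), v)         # deterministic re-read
})

test_that("read_vcf rejects malformed input with line numbers", {
  short <- write_test_vcf(c(vcf_header(), "chr1\t100\t.\tA"))
  expect_error(read_vcf(short), "fewer than 8.*line.* 3")  # 1-based file line

  badpos <- write_test_vcf(c(vcf_header(),
                             vcf_line("chr1", "x10", "A", "G", "1/1")))
  expect_error(read_vcf(badpos), "non-numeric POS")

  dup <- write_test_vcf(c(
    vcf_header(),
    vcf_line("chr1", 100, "A", "G", "1/1"),
    vcf_line("chr1", 100, "A", "T", "1/1")
  ))
  expect_error(read_vcf(dup), "duplicate")

  badref <- write_test_vcf(c(vcf_header(),
                             vcf_line("chr1", 100, "AX", "G", "1/1")))
  expect_error(read_vcf(badref), "REF")

  expect_error(read_vcf(tempfile()), "not found")
})

test_that("resolve_homozygous keeps exactly the homozygous and haploid calls", {
  gts <- c("0/0", "0/1", "1/0", "1/1", "0|0", "0|1", "1|0", "1|1",
           "0", "1", "./.", ".")
  v <- tibble::tibble(
    chrom = "chr1", pos = seq_along(gts) * 10L, ref = "A",
    alts = rep(list("G"), length(gts)), gt = gts
  )
  r <- resolve_homozygous(v)
  hom <- c("0/0", "1/1", "0|0", "1|1", "0", "1")
  expect_equal(r$pos, v$pos[match(hom, gts)])
  expect_equal(r$allele, c("A", "G", "A", "G", "A", "G"))
  counts <- attr(r, "counts")
  expect_equal(counts[["het"]], 4L)
  expect_equal(counts[["missing"]], 2L)
  expect_equal(counts[["kept"]], 6L)
})

test_that("resolve_homozygous skips indels and rejects bad allele indices", {
  v <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 30L),
    ref = c("A", "AT", "C"),
    alts = list("GGA", "A", "G"),
    gt = c("1/1", "1/1", "2/2")
  )
  expect_error(resolve_homozygous(v), "out of range.*chr1:30")
  r <- resolve_homozygous(v[1:2, ])
  expect_equal(nrow(r), 0L)
  expect_equal(attr(r, "counts")[["indel"]], 2L)
})

test_that("resolved alleles always come from [ref] + alts (property)", {
  withr::local_seed(11)
  for (rep in 1:20) {
    n <- 40L
    alts <- lapply(seq_len(n), function(i) {
      sample(c("C", "G", "T"), sample(1:3, 1))
    })
    idx <- vapply(alts, function(a) sample(0:length(a), 1L), integer(1))
    sep <- sample(c("/", "|"), n, replace = TRUE)
    v <- tibble::tibble(
      chrom = "chr1", pos = seq_len(n) * 5L, ref = "A", alts = alts,
      gt = ifelse(runif(n) < 0.5, as.character(idx),
                  paste0(idx, sep, idx))
    )
    r <- resolve_homozygous(v)
    ok <- vapply(seq_len(nrow(r)), function(k) {
      i <- match(r$pos[k], v$pos)
      r$allele[k] %in% c(v$ref[i], v$alts[[i]])
    }, logical(1))
    expect_true(all(ok))
  }
})

test_that("split_vcf writes one file per sample, records preserved", {
  lines <- c(
    vcf_header(c("sA", "sB", "s C!")),
    vapply(1:5, function(i) {
      vcf_line("chr1", i * 100, "A", "G",
               c("0/0", "0/1", "1/1"))
    }, character(1))
  )
  combined <- write_test_vcf(lines)
  out_dir <- withr::local_tempdir()
  res <- split_vcf(combined, out_dir)
  expect_equal(res$sample, c("sA", "sB", "s C!"))
  expect_true(all(file.exists(res$path)))
  expect_match(basename(res$path[3]), "^s_C_\\.vcf$") # sanitized name
  for (p in res$path) {
    expect_equal(nrow(read_vcf(p)), 5L)
  }
  # per-sample genotype columns preserved in order
  expect_equal(read_vcf(res$path[1])$gt, rep("0/0", 5))
  expect_equal(read_vcf(res$path[2])$gt, rep("0/1", 5))
  expect_equal(read_vcf(res$path[3])$gt, rep("1/1", 5))
})

test_that("split_vcf on a 1-sample VCF reproduces the data lines", {
  lines <- c(
    vcf_header("only"),
    vcf_line("chr1", 100, "A", "G", "1/1"),
    vcf_line("chr2", 12, "C", "T", "0/0")
  )
  combined <- write_test_vcf(lines)
  out_dir <- withr::local_tempdir()
  res <- split_vcf(combined, out_dir)
  got <- readLines(res$path)
  expect_equal(got[!startsWith(got, "#")],
               lines[!startsWith(lines, "#")])
})

test_that("split_vcf rejects broken headers and duplicate samples", {
  no_hdr <- write_test_vcf(c("##fileformat=VCFv4.2",
                             vcf_line("chr1", 1, "A", "G", "1/1")))
  expect_error(split_vcf(no_hdr, withr::local_tempdir()), "#CHROM")

  dup <- write_test_vcf(c(vcf_header(c("sA", "sB", "sA")),
                          vcf_line("chr1", 1, "A", "G",
                                   c("1/1", "0/0", "1/1"))))
  expect_error(split_vcf(dup, withr::local_tempdir()), "sA")
})

test_that("split then read round-trips a generated multi-sample VCF", {
  withr::local_seed(23)
  n_samples <- 10L
  n_rec <- 1000L
  samples <- sprintf("ind%02d", seq_len(n_samples))
  pos <- sort(sample.int(5e5, n_rec))
  ref <- sample(c("A", "C", "G", "T"), n_rec, replace = TRUE)
  alt <- vapply(ref, function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  gts <- matrix(sample(c("0/0", "0/1", "1/1", "./."),
                       n_rec * n_samples, replace = TRUE),
                nrow = n_rec)
  lines <- c(
    vcf_header(samples),
    vapply(seq_len(n_rec), function(i) {
      vcf_line("chr1", pos[i], ref[i], alt[i], gts[i, ])
    }, character(1))
  )
  combined <- write_test_vcf(lines)
  out_dir <- withr::local_tempdir()
  res <- split_vcf(combined, out_dir)
  for (s in seq_len(n_samples)) {
    v <- read_vcf(res$path[s])
    expect_equal(nrow(v), n_rec)
    expect_equal(v$pos, pos)
    expect_equal(v$ref, unname(ref))
    expect_equal(unlist(v$alts), unname(alt))
    expect_equal(v$gt, gts[, s])
  }
})
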