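# Synthetic crosses with known truth.
#
# The generator emulates the regime the pipeline targets: haploid / fully
# homozygous genomes, two parents that differ at every SNP site, and
# offspring formed by piecewise copying of parental haplotypes at known
# crossover positions. SNP sites are Poisson-placed, crossovers uniform,
# with no interference model. Optional noise emits a fraction of offspring
# sites as heterozygous calls or flips them to a non-parental allele.

#' Configuration for a simulated cross
#'
#' Defaults describe the standard validation cross used throughout the
#' package: a small yeast-like genome of 3 chromosomes x 5 Mb with one SNP
#' per kilobase distinguishing the parents, 4 surviving offspring, 2
#' crossovers per chromosome and no call noise.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_len Chromosome length in nucleotides.
#' @param snp_density Expected parent-distinguishing SNPs per kilobase.
#' @param n_offspring Number of offspring genomes.
#' @param crossovers_per_chrom Crossovers per chromosome: a single count
#'   or one count per chromosome.
#' @param het_noise_rate Fraction of offspring sites emitted as
#'   heterozygous calls (dropped by the pipeline).
#' @param mismatch_noise_rate Fraction of offspring sites flipped to an
#'   allele carried by neither parent.
#' @param seed RNG seed; a fixed seed makes every output byte-identical
#'   across runs.
#' @return A `cross_config` list.
#' @export
cross_config <- function(n_chroms = 3, chrom_len = 5e6, snp_density = 1,
                         n_offspring = 4, crossovers_per_chrom = 2,
                         het_noise_rate = 0, mismatch_noise_rate = 0,
                         seed = 1) {
  cfg <- list(
    n_chroms = as.integer(n_chroms),
    chrom_len = as.integer(chrom_len),
    snp_density = as.numeric(snp_density),
    n_offspring = as.integer(n_offspring),
    crossovers_per_chrom = as.integer(crossovers_per_chrom),
    het_noise_rate = as.numeric(het_noise_rate),
    mismatch_noise_rate = as.numeric(mismatch_noise_rate),
    seed = as.integer(seed)
  )
  if (cfg$n_chroms < 1 || cfg$chrom_len < 1 || cfg$n_offspring < 1) {
    stop("Counts and lengths must be >= 1.", call. = FALSE)
  }
  if (cfg$snp_density <= 0) {
    stop("`snp_density` must be positive.", call. = FALSE)
  }
  if (!length(cfg$crossovers_per_chrom) %in% c(1L, cfg$n_chroms) ||
      any(cfg$crossovers_per_chrom < 0)) {
    stop("`crossovers_per_chrom` must be a non-negative count or one ",
         "count per chromosome.", call. = FALSE)
  }
  rates <- c(cfg$het_noise_rate, cfg$mismatch_noise_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("Noise rates must be in [0, 1].", call. = FALSE)
  }
  structure(cfg, class = "cross_config")
}

#' Generate a synthetic cross in memory
#'
#' Draws the parental SNP panel and the recombinant offspring without
#' touching the filesystem. [simulate_cross()] wraps this and writes the
#' standard files.
#'
#' Parents differ at every SNP site: at each Poisson-placed site the two
#' parents carry two distinct non-reference alleles. Each offspring
#' chromosome is tiled by segments copied from one parent, switching at
#' crossover positions drawn uniformly; the starting parent is a fair coin
#' flip. The truth set records the exact segments.
#'
#' @param cfg A [cross_config()].
#' @return A list with elements `sites` (tibble `chrom`, `pos`, `ref`,
#'   `parent1`, `parent2`), `parent1`/`parent2` (SNP-call tibbles),
#'   `offspring` (per-individual tibble of emitted records: `individual`,
#'   `chrom`, `pos`, `ref`, `alt`, `gt`), `offspring_calls` (named list of
#'   homozygous SNP-call tibbles, noise applied), `truth` (tibble
#'   `individual`, `chrom`, `start`, `end`, `label`; segments tile
#'   `[1, chrom_len]`), `genes` (toy gene tibble) and `config`.
#' @export
simulate_cross_tables <- function(cfg) {
  stopifnot(inherits(cfg, "cross_config"))
  withr::with_seed(cfg$seed, simulate_cross_impl(cfg))
}

simulate_cross_impl <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  xo <- rep(cfg$crossovers_per_chrom, length.out = cfg$n_chroms)

  # parental SNP panel: Poisson count, uniform distinct positions
  sites <- dplyr::bind_rows(lapply(seq_along(chroms), function(ci) {
    n <- rpois(1, cfg$chrom_len * cfg$snp_density / 1000)
    n <- max(n, 1L)
    pos <- sort(sample.int(cfg$chrom_len, n))
    ref <- sample(.BASES, n, replace = TRUE)
    nonref <- vapply(ref, function(b) setdiff(.BASES, b),
                     character(3))                       # 3 x n
    i1 <- sample.int(3L, n, replace = TRUE)
    i2 <- sample.int(2L, n, replace = TRUE)
    i2 <- i2 + (i2 >= i1)                                # distinct from i1
    tibble::tibble(
      chrom = chroms[[ci]], pos = pos, ref = ref,
      parent1 = nonref[cbind(i1, seq_len(n))],
      parent2 = nonref[cbind(i2, seq_len(n))]
    )
  }))

  # offspring: segment tiling + allele copy + noise
  truth <- list()
  offspring <- list()
  for (o in seq_len(cfg$n_offspring)) {
    ind <- sprintf("off_%02d", o)
    seg <- dplyr::bind_rows(lapply(seq_along(chroms), function(ci) {
      k <- xo[[ci]]
      bp <- if (k > 0) sort(sample.int(cfg$chrom_len - 1L, k)) else integer(0)
      first <- sample(c("Parent1", "Parent2"), 1L)
      labs <- rep(c(first, setdiff(c("Parent1", "Parent2"), first)),
                  length.out = k + 1L)
      tibble::tibble(
        individual = ind, chrom = chroms[[ci]],
        start = c(1L, bp + 1L), end = c(bp, cfg$chrom_len),
        label = labs
      )
    }))
    truth[[o]] <- seg

    rec <- dplyr::inner_join(
      sites, dplyr::select(seg, "chrom", "start", "end", "label"),
      by = dplyr::join_by("chrom", dplyr::between(x$pos, y$start, y$end))
    )
    allele <- ifelse(rec$label == "Parent1", rec$parent1, rec$parent2)

    n <- nrow(rec)
    flip <- runif(n) < cfg$mismatch_noise_rate
    if (any(flip)) {
      # non-parental = the reference base or the fourth base
      other <- vapply(seq_len(n), function(i) {
        pool <- setdiff(.BASES, c(rec$parent1[[i]], rec$parent2[[i]]))
        pool[sample.int(length(pool), 1L)]
      }, character(1))
      allele[flip] <- other[flip]
    }
    het <- runif(n) < cfg$het_noise_rate

    alt <- ifelse(allele == rec$ref, ".", allele)
    gt <- ifelse(het, "0/1", ifelse(allele == rec$ref, "0/0", "1/1"))
    alt[het] <- allele[het]  # het records need a concrete ALT

    offspring[[o]] <- tibble::tibble(
      individual = ind, chrom = rec$chrom, pos = rec$pos, ref = rec$ref,
      alt = alt, gt = gt
    )
  }
  truth <- dplyr::bind_rows(truth)
  offspring <- dplyr::bind_rows(offspring)

  # toy annotation: fixed-length genes tiled at fixed spacing
  gene_len <- 1000L
  spacing <- 20000L
  genes <- dplyr::bind_rows(lapply(chroms, function(ch) {
    starts <- seq.int(5001L, max(5001L, cfg$chrom_len - gene_len),
                      by = spacing)
    tibble::tibble(
      gene_id = sprintf("%s_g%04d", ch, seq_along(starts)),
      chrom = ch, start = starts, end = starts + gene_len - 1L
    )
  }))

  calls <- lapply(split(offspring, offspring$individual), function(d) {
    keep <- d$gt %in% c("0/0", "1/1")
    tibble::tibble(
      chrom = d$chrom[keep], pos = d$pos[keep],
      allele = ifelse(d$gt[keep] == "0/0", d$ref[keep], d$alt[keep])
    )
  })

  list(
    sites = sites,
    parent1 = dplyr::select(sites, "chrom", "pos", allele = "parent1"),
    parent2 = dplyr::select(sites, "chrom", "pos", allele = "parent2"),
    offspring = offspring,
    offspring_calls = calls,
    truth = truth,
    genes = genes,
    config = cfg
  )
}

#' Simulate a cross and write its files
#'
#' Writes two parental VCFs, one VCF per offspring, a toy GTF and the
#' ground-truth segment table (`truth.tsv`, 1-based closed intervals) to
#' `out_dir`. With a fixed seed the outputs are byte-identical across
#' runs.
#'
#' @param cfg A [cross_config()].
#' @param out_dir Output directory; created if needed.
#' @return A list with `paths` (named: `parent1`, `parent2`, `offspring`
#'   (vector), `gtf`, `truth`), plus the in-memory tables of
#'   [simulate_cross_tables()].
#' @export
#' @examples
#' sim <- simulate_cross(cross_config(n_chroms = 1, chrom_len = 5e4,
#'                                    snp_density = 2, n_offspring = 1,
#'                                    seed = 3), tempfile("sim"))
#' sim$paths$truth
simulate_cross <- function(cfg, out_dir) {
  tabs <- simulate_cross_tables(cfg)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("Cannot create output directory: ", out_dir, call. = FALSE)
  }

  p1_path <- file.path(out_dir, "parent1.vcf")
  p2_path <- file.path(out_dir, "parent2.vcf")
  write_sim_vcf(tabs$sites$chrom, tabs$sites$pos, tabs$sites$ref,
                tabs$sites$parent1, rep("1/1", nrow(tabs$sites)),
                "parent1", p1_path)
  write_sim_vcf(tabs$sites$chrom, tabs$sites$pos, tabs$sites$ref,
                tabs$sites$parent2, rep("1/1", nrow(tabs$sites)),
                "parent2", p2_path)

  off_paths <- vapply(split(tabs$offspring, tabs$offspring$individual),
                      function(d) {
    path <- file.path(out_dir, paste0(d$individual[[1]], ".vcf"))
    write_sim_vcf(d$chrom, d$pos, d$ref, d$alt, d$gt, d$individual[[1]],
                  path)
    path
  }, character(1))

  gtf_path <- file.path(out_dir, "genes.gtf")
  readr::write_lines(sprintf(
    '%s\tsim\tgene\t%d\t%d\t.\t+\t.\tgene_id "%s"; gene_name "%s";',
    tabs$genes$chrom, tabs$genes$start, tabs$genes$end,
    tabs$genes$gene_id, tabs$genes$gene_id
  ), gtf_path)

  truth_path <- file.path(out_dir, "truth.tsv")
  readr::write_tsv(tabs$truth, truth_path)

  c(list(paths = list(parent1 = p1_path, parent2 = p2_path,
                      offspring = unname(off_paths), gtf = gtf_path,
                      truth = truth_path)),
    tabs)
}

write_sim_vcf <- function(chrom, pos, ref, alt, gt, sample_id, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pedpaint-simulate",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id)
  )
  lines <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT\t%s",
                   chrom, pos, ref, alt, gt)
  readr::write_lines(c(header, lines), path)
  invisible(path)
}

#' Per-nucleotide accuracy of recovered ancestry against a truth set
#'
#' Fraction of the genome at which the clustered label equals the true
#' source parent. The denominator is the full truth span (the whole
#' genome), so nucleotides not covered by any cluster — chromosome ends
#' beyond the terminal SNPs and the inter-SNP window around each true
#' breakpoint, which no SNP-based method can assign — count as errors.
#'
#' @param blocks `ancestry_blocks` with an `individual` column.
#' @param truth Truth tibble (`individual`, `chrom`, `start`, `end`,
#'   `label`), 1-based closed, tiling each chromosome.
#' @return A single number in `[0, 1]`.
#' @export
ancestry_accuracy <- function(blocks, truth) {
  check_cols(blocks, c("individual", "chrom", "start", "end", "label"),
             "blocks")
  check_cols(truth, c("individual", "chrom", "start", "end", "label"),
             "truth")
  j <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(blocks), "individual", "chrom",
                  bs = "start", be = "end", blab = "label"),
    dplyr::select(tibble::as_tibble(truth), "individual", "chrom",
                  ts = "start", te = "end", tlab = "label"),
    by = c("individual", "chrom"),
    relationship = "many-to-many"
  ) |>
    dplyr::mutate(ov = pmax(0, pmin(.data$be, .data$te) -
                              pmax(.data$bs, .data$ts) + 1))
  agree <- sum(j$ov[j$blab == j$tlab])
  total <- sum(truth$end - truth$start + 1)
  agree / total
}

#' Count recovered recombination breakpoints
#'
#' Number of transitions between Parent1 and Parent2 blocks along each
#' chromosome; Unknown blocks are transparent (a parental change across an
#' Unknown block counts once).
#'
#' @param blocks `ancestry_blocks` with an `individual` column.
#' @return Tibble `individual`, `chrom`, `n_breakpoints`.
#' @export
recovered_breakpoints <- function(blocks) {
  check_cols(blocks, c("individual", "chrom", "label"), "blocks")
  tibble::as_tibble(blocks) |>
    dplyr::filter(.data$label != "Unknown") |>
    dplyr::summarise(
      n_breakpoints = sum(.data$label[-1] != .data$label[-dplyr::n()]),
      .by = c("individual", "chrom")
    )
}
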