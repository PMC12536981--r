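# VCF reading, validation and per-sample splitting.
#
# The parser is deliberately small: the pipeline only needs CHROM, POS, REF,
# ALT and the GT subfield of one sample, works on pre-filtered SNP calls,
# and must accept genotype-less consensus VCFs (see `read_vcf()` details).
# Coordinates are 1-based throughout, as in the VCF spec.

#' Read a single-sample VCF into a variant tibble
#'
#' Parses the data lines of a VCF v4.x file (plain text or gzip) into one
#' row per record. Header lines (`##...` and the `#CHROM` line) are
#' skipped; record order is preserved.
#'
#' Genotype handling:
#' * If a record has a FORMAT column containing `GT`, the genotype string
#'   of the first sample column is kept verbatim (e.g. `"0/1"`, `"1|1"`,
#'   `"1"`).
#' * Records without a genotype (8- or 9-column VCFs, or FORMAT without
#'   `GT`) are treated as homozygous for the first alternate allele and
#'   given genotype `"1"`. Parental consensus VCFs often list only the
#'   ALT calls a strain carries; this convention makes them usable as-is.
#'
#' @param path Path to a single-sample VCF file (`.vcf` or `.vcf.gz`).
#' @return A tibble with columns `chrom` (character), `pos` (integer,
#'   1-based), `ref` (character), `alts` (list of character vectors; empty
#'   when ALT is `.`) and `gt` (character).
#' @details Malformed input is a hard error reported with 1-based line
#'   numbers: fewer than 8 tab-separated fields, a non-numeric POS, alleles
#'   outside `A/C/G/T/N`, or duplicate `(chrom, pos)` records. Duplicates
#'   are rejected rather than resolved so that every downstream label is
#'   reproducible from the file alone.
#' @seealso [resolve_homozygous()], [read_snp_calls()], [split_vcf()]
#' @export
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' writeLines(c(
#'   "##fileformat=VCFv4.2",
#'   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
#'   "chr1\t100\t.\tA\tG\t.\t.\t.\tGT\t1/1"
#' ), vcf)
#' read_vcf(vcf)
read_vcf <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop("`path` must be a single file path.", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("VCF file not found: ", path, call. = FALSE)
  }
  lines <- readr::read_lines(path)
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (length(body) == 0L) {
    return(tibble::tibble(
      chrom = character(), pos = integer(), ref = character(),
      alts = list(), gt = character()
    ))
  }

  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L)) {
    stop_vcf(path, "fewer than 8 tab-separated fields", body[nf < 8L])
  }

  col <- function(i) vapply(fields, function(f) f[[i]], character(1))
  chrom <- col(1L)
  pos <- suppressWarnings(as.integer(col(2L)))
  if (anyNA(pos)) {
    stop_vcf(path, "non-numeric POS", body[is.na(pos)])
  }
  if (any(pos < 1L)) {
    stop_vcf(path, "POS < 1", body[pos < 1L])
  }

  ref <- toupper(col(4L))
  alt_raw <- toupper(col(5L))
  bad_ref <- !grepl("^[ACGTN]+$", ref)
  if (any(bad_ref)) {
    stop_vcf(path, "REF allele not over {A,C,G,T,N}", body[bad_ref])
  }
  alts <- strsplit(alt_raw, ",", fixed = TRUE)
  alts[alt_raw %in% c(".", "")] <- list(character(0))
  bad_alt <- !vapply(alts, function(a) all(grepl("^[ACGTN]+$", a)), logical(1))
  if (any(bad_alt)) {
    stop_vcf(path, "ALT allele not over {A,C,G,T,N}", body[bad_alt])
  }

  # GT subfield of the first sample; "1" (haploid first-ALT) when absent
  gt <- rep("1", length(body))
  has_sample <- nf >= 10L
  if (any(has_sample)) {
    gt[has_sample] <- vapply(fields[has_sample], function(f) {
      keys <- strsplit(f[[9L]], ":", fixed = TRUE)[[1]]
      i <- match("GT", keys)
      if (is.na(i)) return("1")
      vals <- strsplit(f[[10L]], ":", fixed = TRUE)[[1]]
      if (i > length(vals)) "." else vals[[i]]
    }, character(1))
  }

  dup <- duplicated(paste(chrom, pos, sep = "\r"))
  if (any(dup)) {
    stop_vcf(path, "duplicate (chrom, pos) record", body[dup])
  }

  tibble::tibble(chrom = chrom, pos = pos, ref = ref, alts = alts, gt = gt)
}

stop_vcf <- function(path, what, lines) {
  stop(
    "Malformed VCF '", path, "': ", what, " at line",
    if (length(lines) > 1L) "s" else "", " ",
    paste(head(lines, 5L), collapse = ", "),
    if (length(lines) > 5L) sprintf(" (and %d more)", length(lines) - 5L),
    call. = FALSE
  )
}

#' Resolve homozygous single-nucleotide calls
#'
#' Reduces parsed variant records to the unambiguous SNP calls the ancestry
#' assignment works on. A record survives iff its genotype is haploid
#' (`"0"`, `"1"`, ...) or homozygous diploid (`"0/0"`, `"1/1"`, `"2/2"`,
#' with `|` accepted identically to `/` — phase is irrelevant because
#' heterozygotes are dropped), and both the REF and the resolved allele are
#' single nucleotides. Heterozygous (`"0/1"`, `"1|0"`, ...) and missing
#' (`"."`, `"./."`) genotypes and indel/multi-nucleotide alleles are
#' removed and counted.
#'
#' @param variants A variant tibble as returned by [read_vcf()].
#' @return A tibble with columns `chrom`, `pos`, `allele` (single
#'   uppercase nucleotide), in input order. The attribute `"counts"` holds
#'   a named integer vector with `read`, `kept`, `het`, `missing`, `indel`.
#' @details A genotype index outside `[ref] + alts` (e.g. `"2/2"` at a
#'   biallelic site) is a format error, not a silent drop. The resolved
#'   allele is always an element of `c(ref, alts)`.
#' @export
#' @examples
#' v <- tibble::tibble(
#'   chrom = "chr1", pos = c(100L, 200L), ref = "A",
#'   alts = list("G", "G"), gt = c("1/1", "0/1")
#' )
#' resolve_homozygous(v) # only the 1/1 call survives
resolve_homozygous <- function(variants) {
  check_cols(variants, c("chrom", "pos", "ref", "alts", "gt"),
             "variants")
  n <- nrow(variants)
  if (n == 0L) {
    out <- tibble::tibble(chrom = character(), pos = integer(),
                          allele = character())
    attr(out, "counts") <- c(read = 0L, kept = 0L, het = 0L,
                             missing = 0L, indel = 0L)
    return(out)
  }

  parts <- strsplit(trimws(variants$gt), "[/|]")
  is_missing <- vapply(parts, function(p) {
    length(p) == 0L || any(p == ".") || any(!grepl("^[0-9]+$", p))
  }, logical(1))
  is_hom <- !is_missing & vapply(parts, function(p) {
    length(unique(p)) == 1L
  }, logical(1))
  idx <- rep(NA_integer_, n)
  idx[is_hom] <- vapply(parts[is_hom], function(p) as.integer(p[[1]]),
                        integer(1))

  n_alts <- lengths(variants$alts)
  out_of_range <- is_hom & idx > n_alts
  if (any(out_of_range)) {
    bad <- which(out_of_range)
    stop(
      "Genotype allele index out of range of [ref] + alts at ",
      paste(sprintf("%s:%d", variants$chrom[bad], variants$pos[bad])[
        seq_len(min(5L, length(bad)))], collapse = ", "),
      call. = FALSE
    )
  }

  allele <- rep(NA_character_, n)
  take_ref <- is_hom & idx == 0L
  take_alt <- is_hom & idx > 0L
  allele[take_ref] <- variants$ref[take_ref]
  if (any(take_alt)) {
    allele[take_alt] <- mapply(
      function(a, i) a[[i]],
      variants$alts[take_alt], idx[take_alt],
      USE.NAMES = FALSE
    )
  }

  is_snp <- is_hom & nchar(variants$ref) == 1L & nchar(allele) == 1L
  keep <- is_hom & is_snp

  counts <- c(
    read = n,
    kept = sum(keep),
    het = sum(!is_missing & !is_hom),
    missing = sum(is_missing),
    indel = sum(is_hom & !is_snp)
  )
  out <- tibble::tibble(
    chrom = variants$chrom[keep],
    pos = variants$pos[keep],
    allele = allele[keep]
  )
  attr(out, "counts") <- counts
  out
}

#' Read homozygous SNP calls from a VCF in one step
#'
#' Convenience composition of [read_vcf()] and [resolve_homozygous()].
#'
#' @inheritParams read_vcf
#' @return A SNP-call tibble (`chrom`, `pos`, `allele`) with a `"counts"`
#'   attribute; see [resolve_homozygous()].
#' @export
read_snp_calls <- function(path) {
  resolve_homozygous(read_vcf(path))
}

#' Split a multi-sample VCF into per-individual files
#'
#' Writes one single-sample VCF per sample column of `combined_vcf`. The
#' `##` header is copied verbatim; the `#CHROM` line and every data line
#' keep columns 1-9 plus the one sample column. Sample order and record
#' order are preserved. Output file names are the sample IDs sanitized to
#' filesystem-safe characters (`[A-Za-z0-9._-]`, everything else mapped to
#' `_`) with extension `.vcf`.
#'
#' @param combined_vcf Path to a multi-sample VCF (plain or gzip).
#' @param out_dir Directory for the per-sample files; created if needed.
#' @return A tibble with columns `sample` (original sample ID) and `path`
#'   (written file), in the input column order.
#' @details Errors: a file without a `#CHROM` header line, no sample
#'   columns, or duplicate sample IDs (named in the message).
#' @export
split_vcf <- function(combined_vcf, out_dir) {
  if (!file.exists(combined_vcf)) {
    stop("VCF file not found: ", combined_vcf, call. = FALSE)
  }
  lines <- readr::read_lines(combined_vcf)
  hdr_i <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_i) == 0L) {
    stop("Malformed VCF '", combined_vcf,
         "': missing #CHROM header line.", call. = FALSE)
  }
  hdr_i <- hdr_i[[1]]
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10L) {
    stop("VCF '", combined_vcf, "' has no sample columns to split.",
         call. = FALSE)
  }
  samples <- hdr[-(1:9)]
  dups <- unique(samples[duplicated(samples)])
  if (length(dups) > 0L) {
    stop("Duplicate sample IDs in '", combined_vcf, "': ",
         paste(dups, collapse = ", "), call. = FALSE)
  }

  meta <- lines[seq_len(hdr_i - 1L)]
  meta <- meta[startsWith(meta, "##")]
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(trimws(body)) & !startsWith(body, "#")]
  fields <- strsplit(body, "\t", fixed = TRUE)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  safe <- gsub("[^A-Za-z0-9._-]+", "_", samples)
  safe <- make.unique(safe, sep = "_")

  paths <- character(length(samples))
  for (s in seq_along(samples)) {
    k <- 9L + s
    data_lines <- vapply(fields, function(f) {
      paste(f[c(1:9, k)], collapse = "\t")
    }, character(1))
    hdr_line <- paste(c(hdr[1:9], samples[[s]]), collapse = "\t")
    paths[[s]] <- file.path(out_dir, paste0(safe[[s]], ".vcf"))
    readr::write_lines(c(meta, hdr_line, data_lines), paths[[s]])
  }
  tibble::tibble(sample = samples, path = paths)
}

# shared column check used across modules
check_cols <- function(x, cols, what) {
  if (!is.data.frame(x)) {
    stop("`", what, "` must be a data frame.", call. = FALSE)
  }
  miss <- setdiff(cols, names(x))
  if (length(miss) > 0L) {
    stop("`", what, "` is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
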