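# Writers for the standard interchange formats. Internal coordinates are
# 0-based half-open; VCF is written 1-based, BED/BEDPE/bedGraph 0-based.

#' Write named sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write reads as FASTQ (barcode appended to the read name)
#'
#' Barcodes are carried in the read header as `BX:Z:<barcode>` after a
#' space, so SAM-style tags round-trip through FASTQ.
#'
#' @param reads Read tibble with `read_id`, `seq` and optional `barcode`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  hdr <- if ("barcode" %in% names(reads)) {
    if_else(is.na(reads$barcode), reads$read_id,
            paste0(reads$read_id, " BX:Z:", reads$barcode))
  } else reads$read_id
  qual <- vapply(nchar(reads$seq), function(n) {
    paste(rep("I", n), collapse = "")
  }, character(1))
  writeLines(paste0("@", hdr, "\n", reads$seq, "\n+\n", qual), path)
  invisible(path)
}

#' Write reads as a minimal SAM file with BX tags
#'
#' Emits header `@SQ` lines for the given contig lengths and one primary
#' alignment record per read (MAPQ 60, simple full-length match CIGAR).
#'
#' @param reads Read tibble (`read_id`, `contig`, `start`, `seq`,
#'   optional `barcode`).
#' @param contig_lengths Named integer vector of contig lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, contig_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  flag <- 0L
  recs <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*%s",
                  reads$read_id, flag, reads$contig, reads$start + 1L,
                  nchar(reads$seq), reads$seq,
                  if ("barcode" %in% names(reads)) {
                    if_else(is.na(reads$barcode), "",
                            paste0("\tBX:Z:", reads$barcode))
                  } else "")
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Write a phased SNP set as VCF (phased GT with PS tag)
#'
#' Alleles are written REF = first-haplotype allele, ALT = the other, all
#' genotypes `0|1` with the phase-set id in `PS`; positions convert to
#' 1-based.
#'
#' @param phased A `phased_snps` tibble.
#' @param path Output path.
#' @param sample_name Sample column name.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(phased, path, sample_name = "sample1") {
  p <- normalize_phased(phased)
  if (!"phase_set" %in% names(p)) p$phase_set <- 1L
  if (!"qual" %in% names(p)) p$qual <- 0L
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tFORMAT\t", sample_name)
  )
  recs <- sprintf("%s\t%d\t%s\t%s\t%s\t%d\t PASS\tGT:PS\t0|1:%d",
                  p$contig, p$pos + 1L, p$snp_id, p$hap1_allele,
                  p$hap2_allele, pmax(p$qual, 0L), p$phase_set)
  recs <- gsub("\t PASS", "\tPASS", recs, fixed = TRUE)
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read a phased VCF written by [write_phased_vcf()]
#' @param path VCF path.
#' @return A `phased_snps`-style tibble.
#' @export
read_phased_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble(snp_id = character(), contig = character(),
                  pos = integer(), allele_a = character(),
                  allele_b = character(), hap1_allele = character(),
                  phase_set = integer(), qual = integer()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  out <- tibble(
    snp_id = vapply(f, `[[`, "", 3),
    contig = vapply(f, `[[`, "", 1),
    pos = as.integer(vapply(f, `[[`, "", 2)) - 1L,
    allele_a = vapply(f, `[[`, "", 4),
    allele_b = vapply(f, `[[`, "", 5),
    hap1_allele = vapply(f, `[[`, "", 4),
    phase_set = as.integer(sub(".*:", "", vapply(f, `[[`, "", 9))),
    qual = as.integer(vapply(f, `[[`, "", 6))
  )
  class(out) <- c("phased_snps", class(out))
  out
}

#' Write anchors (or any interval tibble) as BED
#' @param intervals Tibble with `contig`, `start`, `end`, optional `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  nm <- if ("name" %in% names(intervals)) intervals$name else "."
  writeLines(sprintf("%s\t%d\t%d\t%s", intervals$contig, intervals$start,
                     intervals$end, nm), path)
  invisible(path)
}

#' Write a contact set as BEDPE
#' @param contacts Contact tibble.
#' @param path Output path.
#' @param read_len End footprint used for the interval ends.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(contacts, path, read_len = 75L) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%d",
                     contacts$contig1, contacts$pos1,
                     contacts$pos1 + read_len,
                     contacts$contig2, contacts$pos2,
                     contacts$pos2 + read_len,
                     contacts$pair_id, contacts$mult), path)
  invisible(path)
}

#' Read a BEDPE contact file
#' @param path BEDPE path.
#' @param assay Assay tag to attach.
#' @return A contact tibble.
#' @export
read_bedpe <- function(path, assay = "hic") {
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(tibble(pair_id = character(), contig1 = character(),
                  pos1 = integer(), contig2 = character(), pos2 = integer(),
                  assay = character(), mult = integer()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    pair_id = vapply(f, function(x) x[7] %||% NA_character_, ""),
    contig1 = vapply(f, `[[`, "", 1),
    pos1 = as.integer(vapply(f, `[[`, "", 2)),
    contig2 = vapply(f, `[[`, "", 4),
    pos2 = as.integer(vapply(f, `[[`, "", 5)),
    assay = assay,
    mult = as.integer(vapply(f, function(x) x[8] %||% "1", ""))
  )
}

#' Write a per-haplotype methylation profile as bedGraph files
#' @param profile A `methylation_profile`.
#' @param dir Output directory.
#' @param contig Contig name for the bedGraph records.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_meth_bedgraph <- function(profile, dir, contig = "chrL") {
  paths <- c()
  for (h in unique(profile$haplotype)) {
    p <- profile[profile$haplotype == h & !is.na(profile$ratio), ]
    path <- file.path(dir, paste0("methylation_", h, ".bedGraph"))
    writeLines(sprintf("%s\t%d\t%d\t%.4f", contig, p$cpg_pos,
                       p$cpg_pos + 2L, p$ratio), path)
    paths[h] <- path
  }
  invisible(paths)
}

#' Write a tibble as TSV
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
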