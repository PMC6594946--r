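#' Configuration for the synthetic two-haplotype locus
#'
#' Defines the geometry and ground truth of a diploid locus in which one
#' haplotype (`hap_rearr`) carries a multi-copy cassette inserted next to an
#' enhancer — the situation created by an enhancer-hijacking translocation —
#' while the other (`hap_wt`) is unrearranged. The default geometry is a
#' 10x scaled-down replica of the IGH-DUX4 configuration: an enhancer ~14 kb
#' from the heavy-chain promoter on the wild-type haplotype but only ~0.4 kb
#' from the inserted two-copy cassette on the rearranged haplotype, three
#' phased heterozygous SNPs (wild-type alleles A-A-A, rearranged T-G-G) in
#' the gene body, a CpG island of exactly `meth_n_cpg` CpGs within
#' `meth_window` bp of the second SNP, and a donor contig carrying a family
#' of near-identical paralog copies of the cassette unit.
#'
#' @param locus_len Length in bp of the main contig (`chrL`).
#' @param promoter,enhancer Two-element 0-based half-open intervals on
#'   `chrL`.
#' @param exons List of 0-based half-open exon intervals (used to restrict
#'   RNA allele counting to exonic SNPs).
#' @param breakpoint 0-based insertion point of the cassette on
#'   `hap_rearr`.
#' @param deletion Optional two-element interval deleted on `hap_rearr`
#'   (e.g. a D-segment loss at the breakpoint), or `NULL`.
#' @param snps Tibble with columns `snp_id`, `pos` (0-based on `chrL`),
#'   `allele_wt`, `allele_rearr`; alleles must differ per SNP.
#' @param paralog_len Length in bp of each paralog family copy.
#' @param paralog_subs Named integer vector: number of substitutions
#'   distinguishing each non-canonical family copy from the canonical one
#'   (each must be >= 1 so attribution is decidable).
#' @param cassette_copies Number of canonical-copy repeats inserted on
#'   `hap_rearr` (0 gives an edit-free identity model).
#' @param cassette_spacer_len Length of the inter-copy spacer inside the
#'   cassette (taken from the donor inter-copy sequence).
#' @param donor_spacer Spacer length between family copies on the donor
#'   contig `chrD`.
#' @param meth_snp Which SNP anchors the methylation window.
#' @param meth_window Half-width in bp of the CpG window around that SNP.
#' @param meth_n_cpg Number of CpGs planted in the window.
#' @param meth_truth Named numeric vector `c(hap_wt = , hap_rearr = )` of
#'   per-CpG methylation probabilities.
#'
#' @return A list of class `genome_config`.
#' @export
genome_config <- function(locus_len = 30000L,
                          promoter = c(13800L, 14200L),
                          exons = list(c(14800L, 15400L), c(16200L, 16900L)),
                          enhancer = c(28000L, 28400L),
                          breakpoint = 28800L,
                          deletion = NULL,
                          snps = tibble(
                            snp_id = c("snp1", "snp2", "snp3"),
                            pos = c(15000L, 16500L, 17500L),
                            allele_wt = c("A", "A", "A"),
                            allele_rearr = c("T", "G", "G")
                          ),
                          paralog_len = 1200L,
                          paralog_subs = c(DUXL_near = 4L, DUXL_far = 12L),
                          cassette_copies = 2L,
                          cassette_spacer_len = 80L,
                          donor_spacer = 1000L,
                          meth_snp = "snp2",
                          meth_window = 45L,
                          meth_n_cpg = 9L,
                          meth_truth = c(hap_wt = 0.1, hap_rearr = 0.9)) {
  cfg <- list(
    locus_len = as.integer(locus_len), promoter = as.integer(promoter),
    exons = lapply(exons, as.integer), enhancer = as.integer(enhancer),
    breakpoint = as.integer(breakpoint), deletion = deletion,
    snps = as_tibble(snps), paralog_len = as.integer(paralog_len),
    paralog_subs = paralog_subs, cassette_copies = as.integer(cassette_copies),
    cassette_spacer_len = as.integer(cassette_spacer_len),
    donor_spacer = as.integer(donor_spacer), meth_snp = meth_snp,
    meth_window = as.integer(meth_window), meth_n_cpg = as.integer(meth_n_cpg),
    meth_truth = meth_truth
  )
  class(cfg) <- "genome_config"
  cfg
}

#' Build a two-haplotype genome model with known ground truth
#'
#' Constructs reference contigs (`chrL`, the rearranged locus; `chrD`, the
#' paralog-family donor), both haplotype sequences, phased SNP truth, the
#' paralog family, anchor regions, and per-haplotype CpG methylation truth.
#' All downstream simulators draw from this object, so every read the
#' package analyses has a known origin.
#'
#' @param config A [genome_config()].
#' @param seed Integer seed; the model is fully deterministic given
#'   `config` and `seed`.
#' @return An object of class `genome_model`: a list with elements
#'   `contigs` (named character vector of reference sequences), `snps`,
#'   `edits`, `paralogs`, `cassette_seq`, `anchors`, `meth_truth`,
#'   `haplotypes` (named character vector `hap_wt`, `hap_rearr`), `config`
#'   and `seed`.
#' @export
#' @examples
#' model <- build_genome(seed = 1)
#' nchar(model$haplotypes["hap_rearr"]) - nchar(model$haplotypes["hap_wt"])
build_genome <- function(config = genome_config(), seed = 1L) {
  stopifnot(inherits(config, "genome_config"))
  withr::local_seed(seed)
  cfg <- config

  snps <- cfg$snps
  if (nrow(snps) < 1) abort("config must define at least one het SNP")
  if (any(snps$allele_wt == snps$allele_rearr)) {
    abort("every SNP must carry different bases on the two haplotypes")
  }

  ## --- reference locus contig ------------------------------------------
  chrL <- random_dna(cfg$locus_len)

  ## CpG island: rewrite the window around the methylation SNP from a
  ## C-free alphabet so that exactly meth_n_cpg CpGs exist, at known
  ## positions, and the SNP alleles can never create or destroy one.
  msnp <- snps[snps$snp_id == cfg$meth_snp, ]
  if (nrow(msnp) != 1) abort("meth_snp not found among SNPs")
  w <- cfg$meth_window
  island_start <- msnp$pos - w - 1L
  island_end <- msnp$pos + w + 2L
  filler <- sample(c("A", "T", "G"), island_end - island_start, replace = TRUE)
  chars <- strsplit(chrL, "", fixed = TRUE)[[1]]
  chars[(island_start + 1L):island_end] <- filler
  offs <- round(seq(-w + 5L, w - 7L, length.out = cfg$meth_n_cpg))
  offs[abs(offs) <= 2] <- 3L
  offs <- sort(unique(offs))
  if (length(offs) != cfg$meth_n_cpg || any(diff(offs) < 2)) {
    abort("cannot place the requested number of CpGs in the window")
  }
  cpg_pos <- msnp$pos + offs
  chars[cpg_pos + 1L] <- "C"
  chars[cpg_pos + 2L] <- "G"

  ## reference carries the wild-type allele at each SNP
  chars[snps$pos + 1L] <- snps$allele_wt
  chrL <- paste(chars, collapse = "")

  ## --- paralog family and donor contig ---------------------------------
  canon <- random_dna(cfg$paralog_len)
  paralog_seqs <- c(DUXL_canon = canon)
  for (nm in names(cfg$paralog_subs)) {
    k <- cfg$paralog_subs[[nm]]
    if (k < 1) abort("every non-canonical paralog copy must differ by >= 1 substitution")
    pos <- sample(cfg$paralog_len, k)
    bases <- vapply(pos, function(i) {
      sample(setdiff(DNA_BASES, substr(canon, i, i)), 1)
    }, character(1))
    paralog_seqs[[nm]] <- replace_bases(canon, pos - 1L, bases)
  }
  spacer <- random_dna(cfg$donor_spacer)
  donor_parts <- character(0)
  paralogs <- tibble(name = character(), start = integer(), end = integer(),
                     canonical = logical(), seq = character())
  off <- 0L
  for (nm in names(paralog_seqs)) {
    donor_parts <- c(donor_parts, spacer, paralog_seqs[[nm]])
    off <- off + cfg$donor_spacer
    sub_pos <- which(strsplit(paralog_seqs[[nm]], "")[[1]] !=
                       strsplit(canon, "")[[1]]) - 1L
    paralogs <- bind_rows(paralogs, tibble(
      name = nm, start = off, end = off + cfg$paralog_len,
      canonical = nm == "DUXL_canon", seq = paralog_seqs[[nm]],
      sub_pos = list(sub_pos)
    ))
    off <- off + cfg$paralog_len
  }
  donor_parts <- c(donor_parts, spacer)
  chrD <- paste(donor_parts, collapse = "")

  ## cassette: copies of the canonical unit separated by the donor
  ## inter-copy sequence immediately downstream of the canonical copy
  cassette_seq <- ""
  if (cfg$cassette_copies > 0) {
    inter <- seq_sub(spacer, 0L, cfg$cassette_spacer_len)
    units <- rep(canon, cfg$cassette_copies)
    cassette_seq <- paste(units, collapse = inter)
  }

  ## --- haplotype edit lists --------------------------------------------
  edits <- tibble(haplotype = character(), op = character(),
                  ref_pos = integer(), length = integer(), name = character())
  if (cfg$cassette_copies > 0) {
    edits <- bind_rows(edits, tibble(
      haplotype = "hap_rearr", op = "insert", ref_pos = cfg$breakpoint,
      length = nchar(cassette_seq), name = "cassette"
    ))
  }
  if (!is.null(cfg$deletion)) {
    edits <- bind_rows(edits, tibble(
      haplotype = "hap_rearr", op = "delete",
      ref_pos = as.integer(cfg$deletion[1]),
      length = as.integer(cfg$deletion[2] - cfg$deletion[1]),
      name = "deletion"
    ))
  }
  check_edit_conflicts(edits)

  ## --- anchors ----------------------------------------------------------
  anchors <- bind_rows(
    tibble(name = "Emu", contig = "chrL", start = cfg$enhancer[1],
           end = cfg$enhancer[2], role = "enhancer"),
    tibble(name = "Igmu_promoter", contig = "chrL", start = cfg$promoter[1],
           end = cfg$promoter[2], role = "promoter"),
    tibble(name = "V_control", contig = "chrL", start = 2000L, end = 2400L,
           role = "control"),
    paralogs %>%
      select("name", "start", "end") %>%
      mutate(contig = "chrD", role = "oncogene_array_copy") %>%
      select("name", "contig", "start", "end", "role")
  )
  if (anyDuplicated(anchors$name)) abort("anchor names must be unique")

  ## --- methylation truth -----------------------------------------------
  meth_truth <- tidyr::expand_grid(
    cpg_pos = cpg_pos,
    haplotype = c("hap_wt", "hap_rearr")
  ) %>%
    mutate(prob = unname(cfg$meth_truth[.data$haplotype]),
           snp_id = cfg$meth_snp)

  snps <- snps %>% mutate(contig = "chrL", .before = 1)

  model <- structure(list(
    contigs = c(chrL = chrL, chrD = chrD),
    snps = snps,
    edits = edits,
    paralogs = paralogs,
    cassette_seq = cassette_seq,
    anchors = anchors,
    meth_truth = meth_truth,
    config = cfg,
    seed = as.integer(seed)
  ), class = "genome_model")

  model$haplotypes <- c(
    hap_wt = haplotype_sequence(model, "hap_wt"),
    hap_rearr = haplotype_sequence(model, "hap_rearr")
  )
  model
}

check_edit_conflicts <- function(edits) {
  for (h in unique(edits$haplotype)) {
    e <- edits[edits$haplotype == h, ]
    ivs <- dplyr::transmute(
      e,
      start = .data$ref_pos,
      end = if_else(.data$op == "delete", .data$ref_pos + .data$length,
                    .data$ref_pos),
      op = .data$op, name = .data$name
    )
    if (nrow(ivs) < 2) next
    for (i in seq_len(nrow(ivs) - 1)) {
      for (j in (i + 1):nrow(ivs)) {
        # a pair conflicts when a deletion covers the other edit's position
        lo <- max(ivs$start[i], ivs$start[j])
        hi <- min(ivs$end[i], ivs$end[j])
        strict_overlap <- lo < hi ||
          (ivs$op[i] == "delete" && ivs$start[j] > ivs$start[i] &&
             ivs$start[j] < ivs$end[i]) ||
          (ivs$op[j] == "delete" && ivs$start[i] > ivs$start[j] &&
             ivs$start[i] < ivs$end[j])
        if (strict_overlap) {
          abort(sprintf(
            "conflicting edits on %s: %s (%s at %d) overlaps %s (%s at %d)",
            h, ivs$name[i], ivs$op[i], ivs$start[i],
            ivs$name[j], ivs$op[j], ivs$start[j]
          ))
        }
      }
    }
  }
  invisible(edits)
}

#' Reconstruct one haplotype sequence from the model
#'
#' Applies the haplotype's SNP alleles and ordered edit list (cassette
#' insertion, deletion) to the `chrL` reference.
#'
#' @param model A `genome_model`.
#' @param haplotype `"hap_wt"` or `"hap_rearr"`.
#' @return A character scalar (the haplotype sequence).
#' @export
haplotype_sequence <- function(model, haplotype = c("hap_wt", "hap_rearr")) {
  haplotype <- match.arg(haplotype)
  allele_col <- if (haplotype == "hap_wt") "allele_wt" else "allele_rearr"
  seq <- replace_bases(model$contigs[["chrL"]], model$snps$pos,
                       model$snps[[allele_col]])
  edits <- model$edits %>%
    filter(.data$haplotype == .env$haplotype) %>%
    arrange(desc(.data$ref_pos))
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    if (e$op == "insert") {
      seq <- paste0(seq_sub(seq, 0L, e$ref_pos), model$cassette_seq,
                    seq_sub(seq, e$ref_pos, nchar(seq)))
    } else if (e$op == "delete") {
      seq <- paste0(seq_sub(seq, 0L, e$ref_pos),
                    seq_sub(seq, e$ref_pos + e$length, nchar(seq)))
    }
  }
  seq
}

#' Lift chrL reference positions onto a haplotype's coordinate system
#'
#' Insertions shift downstream positions right; deleted positions map to
#' `NA`.
#'
#' @param model A `genome_model`.
#' @param haplotype Haplotype name.
#' @param pos Integer vector of 0-based `chrL` positions.
#' @return Integer vector of 0-based haplotype positions (`NA` where
#'   deleted).
#' @export
lift_to_haplotype <- function(model, haplotype, pos) {
  edits <- model$edits %>%
    filter(.data$haplotype == .env$haplotype) %>%
    arrange(.data$ref_pos)
  out <- as.integer(pos)
  shift <- integer(length(pos))
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    if (e$op == "insert") {
      shift <- shift + if_else(pos >= e$ref_pos, e$length, 0L)
    } else {
      out[pos >= e$ref_pos & pos < e$ref_pos + e$length] <- NA_integer_
      shift <- shift - if_else(pos >= e$ref_pos + e$length, e$length, 0L)
    }
  }
  out + shift
}

# Map 0-based points on a haplotype back to reference coordinates
# (vectorised). Points inside the inserted cassette map onto the donor
# contig (canonical copy + inter-copy spacer region); everything else maps
# to chrL. Returns a tibble(contig, pos, in_cassette, cassette_offset).
hap_point_to_ref <- function(model, haplotype, pos) {
  pos <- as.integer(pos)
  out <- tibble(contig = rep("chrL", length(pos)), pos = pos,
                in_cassette = FALSE, cassette_offset = NA_integer_)
  ed <- model$edits %>%
    filter(.data$haplotype == .env$haplotype) %>%
    arrange(.data$ref_pos)
  if (nrow(ed) == 0) return(out)
  plen <- model$config$paralog_len
  sp <- model$config$cassette_spacer_len
  canon_start <- model$paralogs$start[model$paralogs$canonical][1]
  shift <- 0L                       # cumulative hap - ref offset so far
  total <- integer(length(pos))     # per-point offset to subtract at the end
  for (j in seq_len(nrow(ed))) {
    e <- ed[j, ]
    if (e$op == "insert") {
      ins_start <- e$ref_pos + shift
      inside <- pos >= ins_start & pos < ins_start + e$length
      off <- pos[inside] - ins_start
      within <- off %% (plen + sp)
      out$contig[inside] <- "chrD"
      out$pos[inside] <- canon_start + within
      out$in_cassette[inside] <- TRUE
      out$cassette_offset[inside] <- off
      total <- total + if_else(pos >= ins_start + e$length, e$length, 0L)
      shift <- shift + e$length
    } else {
      junction <- e$ref_pos + shift
      total <- total - if_else(pos >= junction, e$length, 0L)
      shift <- shift - e$length
    }
  }
  keep <- !out$in_cassette
  out$pos[keep] <- pos[keep] - total[keep]
  out
}

#' Anchor regions in a chosen coordinate space
#'
#' In `"reference"` space anchors are returned as stored (on `chrL` /
#' `chrD`). In a haplotype space the `chrL` anchors are lifted through that
#' haplotype's edits and, for `hap_rearr`, one anchor per inserted cassette
#' copy is added (role `oncogene_array_copy`, contig set to the haplotype
#' name).
#'
#' @param model A `genome_model`.
#' @param space `"reference"`, `"hap_wt"` or `"hap_rearr"`.
#' @return A tibble of anchors.
#' @export
model_anchors <- function(model, space = c("reference", "hap_wt", "hap_rearr")) {
  space <- match.arg(space)
  if (space == "reference") return(model$anchors)
  a <- model$anchors %>% filter(.data$contig == "chrL")
  a$start <- lift_to_haplotype(model, space, a$start)
  a$end <- lift_to_haplotype(model, space, a$end - 1L) + 1L
  a <- a %>% filter(!is.na(.data$start), !is.na(.data$end)) %>%
    mutate(contig = space)
  ins <- model$edits %>%
    filter(.data$haplotype == .env$space, .data$op == "insert")
  if (nrow(ins) == 1) {
    plen <- model$config$paralog_len
    sp <- model$config$cassette_spacer_len
    ins_start <- lift_to_haplotype(model, space, ins$ref_pos - 1L) + 1L
    ncop <- model$config$cassette_copies
    cop <- tibble(
      name = paste0("cassette_copy", seq_len(ncop)),
      contig = space,
      start = ins_start + (seq_len(ncop) - 1L) * (plen + sp),
      end = ins_start + (seq_len(ncop) - 1L) * (plen + sp) + plen,
      role = "oncogene_array_copy"
    )
    a <- bind_rows(a, cop)
  }
  a
}

#' Length of a haplotype sequence
#' @param model A `genome_model`.
#' @param haplotype Haplotype name.
#' @return Integer length in bp.
#' @export
haplotype_length <- function(model, haplotype) {
  nchar(model$haplotypes[[haplotype]])
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model>\n")
  cat(sprintf("  contigs: chrL (%d bp), chrD (%d bp)\n",
              nchar(x$contigs[["chrL"]]), nchar(x$contigs[["chrD"]])))
  cat(sprintf("  haplotypes: hap_wt %d bp, hap_rearr %d bp\n",
              nchar(x$haplotypes[["hap_wt"]]),
              nchar(x$haplotypes[["hap_rearr"]])))
  cat(sprintf("  het SNPs: %d (%s | %s)\n", nrow(x$snps),
              paste(x$snps$allele_rearr, collapse = "-"),
              paste(x$snps$allele_wt, collapse = "-")))
  cat(sprintf("  paralog family: %d copies; cassette %d bp\n",
              nrow(x$paralogs), nchar(x$cassette_seq)))
  cat(sprintf("  anchors: %d; CpG truth sites: %d\n", nrow(x$anchors),
              nrow(x$meth_truth) / 2L))
  invisible(x)
}
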