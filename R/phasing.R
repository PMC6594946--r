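#' Collect the barcode-by-SNP allele matrix from barcoded alignments
#'
#' For every (barcode, SNP) combination, tallies the bases the barcode's
#' reads report at the SNP and reduces them to a single call: `"a"` or
#' `"b"` for the SNP's two alleles, `"conflict"` when the barcode's reads
#' report both alleles (strictly: any mixture beyond `purity`), and
#' entries absent from the table are missing. Bases matching neither
#' allele are excluded from the matrix and tallied in the `other_bases`
#' attribute.
#'
#' @param reads Alignment tibble with `barcode`, `contig`, `start`, `end`,
#'   `seq` columns (e.g. from [simulate_linked_reads()]).
#' @param snps Tibble of het SNPs with `snp_id`, `contig`, `pos`,
#'   `allele_a`, `allele_b` (0-based positions). A genome model's `snps`
#'   table (`allele_wt`/`allele_rearr`) is accepted and relabelled.
#' @param purity Minimum fraction of a barcode's reads that must agree for
#'   a non-conflict call. The default 1 is strict: any mixture is a
#'   conflict.
#' @return A tibble of class `bc_allele_matrix` with columns `barcode`,
#'   `snp_id`, `call`, `n_a`, `n_b`; attribute `snps` carries the SNP
#'   table and `other_bases` the count of non-allelic bases seen.
#' @export
collect_barcode_allele_matrix <- function(reads, snps, purity = 1) {
  snps <- normalize_snp_table(snps)
  if (nrow(reads) == 0 || nrow(snps) == 0) {
    out <- tibble(barcode = character(), snp_id = character(),
                  call = character(), n_a = integer(), n_b = integer())
    attr(out, "snps") <- snps
    attr(out, "other_bases") <- 0L
    class(out) <- c("bc_allele_matrix", class(out))
    return(out)
  }
  obs <- purrr::map_dfr(seq_len(nrow(snps)), function(i) {
    s <- snps[i, ]
    hit <- reads$contig == s$contig & reads$start <= s$pos & reads$end > s$pos &
      !is.na(reads$barcode)
    if (!any(hit)) return(NULL)
    r <- reads[hit, ]
    base <- substr(r$seq, s$pos - r$start + 1L, s$pos - r$start + 1L)
    tibble(barcode = r$barcode, snp_id = s$snp_id, base = base,
           allele_a = s$allele_a, allele_b = s$allele_b)
  })
  if (nrow(obs) == 0) {
    out <- tibble(barcode = character(), snp_id = character(),
                  call = character(), n_a = integer(), n_b = integer())
    attr(out, "snps") <- snps
    attr(out, "other_bases") <- 0L
    class(out) <- c("bc_allele_matrix", class(out))
    return(out)
  }
  n_other <- sum(obs$base != obs$allele_a & obs$base != obs$allele_b)
  out <- obs %>%
    filter(.data$base == .data$allele_a | .data$base == .data$allele_b) %>%
    group_by(.data$barcode, .data$snp_id) %>%
    summarise(n_a = sum(.data$base == .data$allele_a[1]),
              n_b = sum(.data$base == .data$allele_b[1]),
              .groups = "drop") %>%
    mutate(call = case_when(
      n_a / (n_a + n_b) >= purity ~ "a",
      n_b / (n_a + n_b) >= purity ~ "b",
      TRUE ~ "conflict"
    )) %>%
    select("barcode", "snp_id", "call", "n_a", "n_b")
  attr(out, "snps") <- snps
  attr(out, "other_bases") <- n_other
  class(out) <- c("bc_allele_matrix", class(out))
  out
}

# accept either allele_a/allele_b or a genome model's allele_wt/allele_rearr
normalize_snp_table <- function(snps) {
  snps <- as_tibble(snps)
  if (!"allele_a" %in% names(snps) && "allele_wt" %in% names(snps)) {
    snps <- snps %>% rename(allele_a = "allele_wt", allele_b = "allele_rearr")
  }
  if (!all(c("snp_id", "contig", "pos", "allele_a", "allele_b") %in%
             names(snps))) {
    abort("snps must have columns snp_id, contig, pos, allele_a, allele_b")
  }
  arrange(snps, .data$contig, .data$pos)
}

#' Phase het SNPs by greedy minimum error correction
#'
#' Phases SNPs into two haplotypes from barcode co-occurrence: the SNP of
#' highest coverage seeds a phase set; remaining SNPs are added in
#' descending order of barcode-sharing weight with the phased set, each in
#' the orientation that minimises contradicted barcode entries (the MEC
#' objective). Ties in seeding and extension break by coverage then
#' leftmost coordinate, so the result is deterministic without a seed.
#' Conflict entries are dropped from scoring. SNPs sharing no barcode with
#' any phased SNP start new phase sets.
#'
#' @param matrix A [collect_barcode_allele_matrix()] result.
#' @return A tibble of class `phased_snps`: `snp_id`, `contig`, `pos`,
#'   `allele_a`, `allele_b`, `hap1_allele` (which allele lies on the first
#'   haplotype — orientation per phase set is arbitrary, global flips are
#'   equivalent), `phase_set`, `qual` (supporting minus contradicting
#'   barcode count). Attribute `mec` carries the total MEC of the phasing.
#' @export
phase_snps <- function(matrix) {
  snps <- attr(matrix, "snps")
  if (is.null(snps) || nrow(snps) < 1) abort("matrix must carry >= 1 SNP")
  m <- matrix %>% filter(.data$call %in% c("a", "b"))

  ids <- snps$snp_id
  n <- length(ids)
  cov <- vapply(ids, function(s) sum(m$snp_id == s), integer(1))

  # barcode x snp call matrix (+1 = allele a, -1 = allele b, 0 = missing)
  barcodes <- unique(m$barcode)
  call_mat <- matrix(0L, nrow = length(barcodes), ncol = n,
                     dimnames = list(barcodes, ids))
  if (nrow(m) > 0) {
    call_mat[cbind(match(m$barcode, barcodes), match(m$snp_id, ids))] <-
      if_else(m$call == "a", 1L, -1L)
  }

  phase <- rep(NA_integer_, n)      # +1: allele a on hap1; -1: allele b
  phase_set <- rep(NA_integer_, n)
  qual <- rep(0L, n)
  names(phase) <- names(phase_set) <- names(qual) <- ids
  next_ps <- 0L

  # pairwise link weight: barcodes covering both SNPs
  link_weight <- function(i, j) {
    both <- call_mat[, i] != 0L & call_mat[, j] != 0L
    sum(both)
  }

  order_key <- function(cand) {
    # ties by coverage then leftmost position
    cand[order(-cov[cand], snps$pos[match(ids[cand], snps$snp_id)])][1]
  }

  while (anyNA(phase)) {
    un <- which(is.na(phase))
    ph <- which(!is.na(phase) & phase_set == next_ps)
    if (length(ph) == 0) {
      # seed a new phase set with the highest-coverage unphased SNP
      next_ps <- next_ps + 1L
      seed <- order_key(un)
      phase[seed] <- 1L
      phase_set[seed] <- next_ps
      next
    }
    # extension candidates: unphased SNPs sharing barcodes with this set
    w <- vapply(un, function(i) {
      sum(vapply(ph, function(j) link_weight(i, j), integer(1)))
    }, integer(1))
    if (all(w == 0)) {
      # remainder is disconnected from this set; seed a new one
      next_ps <- next_ps + 1L
      seed <- order_key(un)
      phase[seed] <- 1L
      phase_set[seed] <- next_ps
      next
    }
    cand <- un[w == max(w)]
    i <- order_key(cand)
    # orientation minimising contradicted barcode entries: a barcode with
    # calls c_i, c_j is consistent with orientation phase_i = +1 iff
    # c_i * c_j * phase_j == +1 (holds whichever haplotype it came from)
    agree <- 0L; disagree <- 0L
    for (j in ph) {
      both <- call_mat[, i] != 0L & call_mat[, j] != 0L
      cons <- sum(call_mat[both, i] * call_mat[both, j] * phase[j] == 1L)
      agree <- agree + cons
      disagree <- disagree + (sum(both) - cons)
    }
    phase[i] <- if (agree >= disagree) 1L else -1L
    phase_set[i] <- next_ps
  }

  # per-SNP quality: supporting minus contradicting barcodes against the
  # other SNPs of the same (final) phase set
  for (i in seq_len(n)) {
    peers <- setdiff(which(phase_set == phase_set[i]), i)
    s <- 0L; c0 <- 0L
    for (j in peers) {
      both <- call_mat[, i] != 0L & call_mat[, j] != 0L
      cons <- sum(call_mat[both, i] * call_mat[both, j] *
                    (phase[i] * phase[j]) == 1L)
      s <- s + cons
      c0 <- c0 + (sum(both) - cons)
    }
    qual[i] <- s - c0
  }

  out <- snps %>%
    mutate(
      hap1_allele = if_else(phase[.data$snp_id] == 1L, .data$allele_a,
                            .data$allele_b),
      phase_set = unname(phase_set[.data$snp_id]),
      qual = unname(qual[.data$snp_id])
    )
  class(out) <- c("phased_snps", class(out))
  attr(out, "phase_sign") <- phase
  attr(out, "mec") <- mec_score(matrix, out)
  out
}

#' Minimum-error-correction score of a phasing
#'
#' For each barcode, counts the matrix entries that must be flipped for
#' the barcode to be consistent with one of the two haplotypes implied by
#' the phasing (the barcode is assigned to its better-fitting haplotype,
#' within each phase set). Conflict entries are excluded.
#'
#' @param matrix A `bc_allele_matrix`.
#' @param phased A `phased_snps` result (or any tibble with `snp_id` and
#'   `hap1_allele` plus the allele columns).
#' @return Integer MEC score.
#' @export
mec_score <- function(matrix, phased) {
  m <- matrix %>% filter(.data$call %in% c("a", "b"))
  if (nrow(m) == 0) return(0L)
  phased <- as_tibble(phased)
  if (!"phase_set" %in% names(phased)) phased$phase_set <- 1L
  ph <- phased %>%
    mutate(hap1_is_a = .data$hap1_allele == .data$allele_a) %>%
    select("snp_id", "hap1_is_a", ps = "phase_set")
  m <- m %>% left_join(ph, by = "snp_id") %>%
    mutate(# call agrees with hap1 when (call == a) == hap1_is_a
      agrees_h1 = (.data$call == "a") == .data$hap1_is_a)
  per_bc <- m %>%
    group_by(.data$barcode, .data$ps) %>%
    summarise(err = min(sum(.data$agrees_h1), sum(!.data$agrees_h1)),
              .groups = "drop")
  as.integer(sum(per_bc$err))
}

#' Switch error rate between two phasings
#'
#' The minimum, over a global haplotype flip, of the fraction of adjacent
#' SNP pairs whose relative phase disagrees between prediction and truth.
#'
#' @param predicted,truth `phased_snps`-style tibbles over the same SNP
#'   list (truth may be a genome model's `snps` table, whose `allele_wt`
#'   is taken as the first haplotype).
#' @return A fraction in `[0, 1]` (0 when fewer than two SNPs).
#' @export
switch_error <- function(predicted, truth) {
  p <- as_tibble(predicted) %>% arrange(.data$contig, .data$pos)
  t <- as_tibble(truth)
  if ("allele_wt" %in% names(t) && !"hap1_allele" %in% names(t)) {
    t <- t %>% mutate(hap1_allele = .data$allele_wt,
                      allele_a = .data$allele_wt,
                      allele_b = .data$allele_rearr)
  }
  t <- t %>% arrange(.data$contig, .data$pos)
  if (!identical(p$snp_id, t$snp_id) || !identical(p$pos, t$pos)) {
    abort("predicted and truth phasings must cover the same SNP list")
  }
  n <- nrow(p)
  if (n < 2) return(0)
  # +1 when the two phasings agree on which allele sits on haplotype 1
  s <- if_else(p$hap1_allele == t$hap1_allele, 1L, -1L)
  switches <- sum(s[-1] != s[-n])
  flipped <- sum((-s)[-1] != (-s)[-n])   # identical; kept for clarity
  min(switches, flipped) / (n - 1)
}
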