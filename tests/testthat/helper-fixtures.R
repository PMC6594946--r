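# Shared fixtures and independent oracles, built in code at test time.

# one small model reused across tests (deterministic)
test_model <- function(seed = 1) build_genome(genome_config(), seed = seed)

# construct a barcode-allele matrix object directly from a call table
make_bc_matrix <- function(calls, snps) {
  snps <- dplyr::arrange(tibble::as_tibble(snps), contig, pos)
  out <- tibble::as_tibble(calls)
  if (!"n_a" %in% names(out)) out$n_a <- ifelse(out$call == "a", 1L, 0L)
  if (!"n_b" %in% names(out)) out$n_b <- ifelse(out$call == "b", 1L, 0L)
  attr(out, "snps") <- snps
  attr(out, "other_bases") <- 0L
  class(out) <- c("bc_allele_matrix", class(out))
  out
}

# simple SNP table for constructed phasing instances
toy_snps <- function(n) {
  tibble::tibble(
    snp_id = sprintf("s%d", seq_len(n)), contig = "c1",
    pos = seq_len(n) * 100L, allele_a = "A", allele_b = "G"
  )
}

# random phasing instance: barcodes cover contiguous SNP windows; entries
# flipped with probability `noise`. Returns matrix plus the truth phasing.
random_phasing_instance <- function(n_snps = 5, n_barcodes = 50,
                                    noise = 0.05, seed = 1) {
  withr::local_seed(seed)
  snps <- toy_snps(n_snps)
  truth_sign <- sample(c(1L, -1L), n_snps, replace = TRUE)  # +1: a on hap1
  rows <- list()
  for (b in seq_len(n_barcodes)) {
    i <- sample(n_snps - 1L, 1)
    j <- min(n_snps, i + sample(1:2, 1))
    hap <- sample(c(1L, -1L), 1)
    for (s in i:j) {
      want_a <- (truth_sign[s] * hap) == 1L
      if (runif(1) < noise) want_a <- !want_a
      rows[[length(rows) + 1]] <- tibble::tibble(
        barcode = sprintf("b%03d", b), snp_id = snps$snp_id[s],
        call = ifelse(want_a, "a", "b")
      )
    }
  }
  calls <- dplyr::bind_rows(rows)
  truth <- snps %>%
    dplyr::mutate(hap1_allele = ifelse(truth_sign == 1L, allele_a, allele_b),
                  phase_set = 1L, qual = 0L)
  list(matrix = make_bc_matrix(calls, snps), truth = truth, snps = snps)
}

# independent exhaustive-minimum MEC oracle: enumerate all phasings over
# one phase set, score each directly against the call table
exhaustive_min_mec <- function(matrix) {
  snps <- attr(matrix, "snps")
  n <- nrow(snps)
  m <- matrix[matrix$call %in% c("a", "b"), ]
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    sgn <- c(1L, ifelse(bitwAnd(mask, 2^(seq_len(n - 1) - 1)) > 0, -1L, 1L))
    names(sgn) <- snps$snp_id
    # hap1 shows allele a at SNP s iff sgn[s] == 1
    err <- 0L
    for (b in unique(m$barcode)) {
      mb <- m[m$barcode == b, ]
      matches_h1 <- (mb$call == "a") == (sgn[mb$snp_id] == 1L)
      err <- err + min(sum(matches_h1), sum(!matches_h1))
    }
    if (err < best) best <- err
  }
  best
}

# independent binomial upper-tail oracle by direct enumeration
binom_tail_oracle <- function(k, n) {
  sum(choose(n, k:n)) / 2^n
}
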