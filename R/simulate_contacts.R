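#' Default anchor-pair boost table for a contact assay
#'
#' Expected supporting-pair counts for the enhancer-promoter interaction
#' (on the wild-type haplotype, where the promoter contact is mono-allelic)
#' and the enhancer-cassette interaction (on the rearranged haplotype).
#' Defaults mirror the relative interaction intensities reported for the
#' three assay types: roughly 3:1 for Hi-C, 8:1 for HiChIP, and 953:75 for
#' Capture-C peak coverage.
#'
#' @param assay `"hic"`, `"hichip"` or `"capturec"`.
#' @return A tibble with columns `anchor_a`, `anchor_b`, `haplotype`,
#'   `expected`.
#' @export
default_contact_boosts <- function(assay = c("hic", "hichip", "capturec")) {
  assay <- match.arg(assay)
  exp_promoter <- switch(assay, hic = 225, hichip = 600, capturec = 953)
  exp_cassette <- 75
  tibble(
    anchor_a = "Emu",
    anchor_b = c("Igmu_promoter", "cassette"),
    haplotype = c("hap_wt", "hap_rearr"),
    expected = c(exp_promoter, exp_cassette)
  )
}

# sample distances from p(d) ~ d^-alpha on [d_min, d_max] by inverse
# transform (log-uniform when alpha == 1)
sample_decay_distance <- function(n, alpha, d_min, d_max) {
  u <- runif(n)
  if (abs(alpha - 1) < 1e-9) {
    d <- exp(log(d_min) + u * (log(d_max) - log(d_min)))
  } else {
    a1 <- 1 - alpha
    d <- (d_min^a1 + u * (d_max^a1 - d_min^a1))^(1 / a1)
  }
  as.integer(round(d))
}

#' Simulate chromatin contact pairs with distance decay and anchor boosts
#'
#' Background pairs are sampled along each haplotype's edited coordinate
#' system with end separation following a `distance^-decay_exponent` law;
#' anchor-pair interactions are added on top with Poisson-distributed
#' counts around the configured expectations. Ends are then mapped back to
#' reference contigs: ends internal to the inserted cassette are placed on
#' the donor paralog array (`chrD`), scattered uniformly among the family
#' copies a read of that span cannot be distinguished from — the
#' multi-mapping ambiguity that [multimapping_rescue()] exists to undo.
#' Pair ends are stored unordered (canonical lexicographic order).
#'
#' @param model A genome model.
#' @param profile An [assay_profile()] with `assay = "contact"`.
#' @param n_pairs Number of background pairs.
#' @param assay_tag `"hic"`, `"hichip"` or `"capturec"` (stored per pair).
#' @param boosts Boost table as from [default_contact_boosts()]; `NULL`
#'   disables anchor enrichment. `anchor_b = "cassette"` means the union of
#'   inserted cassette copies.
#' @param seed Integer seed.
#' @return A list with `contacts` (tibble: `pair_id`, `contig1`, `pos1`,
#'   `contig2`, `pos2`, `assay`, `mult`, `seq1`, `seq2`) and `truth`
#'   (tibble: `pair_id`, `haplotype`, `hap_pos1`, `hap_pos2`, `source`).
#'   Sequences are emitted for Capture-C so rescued realignment is
#'   possible.
#' @export
simulate_contacts <- function(model, profile, n_pairs,
                              assay_tag = c("hic", "hichip", "capturec"),
                              boosts = default_contact_boosts(assay_tag),
                              seed = profile$seed) {
  assay_tag <- match.arg(assay_tag)
  if (profile$assay != "contact") abort("profile$assay must be 'contact'")
  if (!is.numeric(n_pairs) || length(n_pairs) != 1 || n_pairs < 0) {
    abort("n_pairs must be a single non-negative integer")
  }
  n_pairs <- as.integer(n_pairs)
  withr::local_seed(seed)
  read_len <- profile$read_len
  emit_seq <- assay_tag == "capturec"

  hap_lens <- setNames(nchar(model$haplotypes), names(model$haplotypes))

  ## background pairs
  bg <- NULL
  if (n_pairs > 0) {
    hap <- sample(c("hap_wt", "hap_rearr"), n_pairs, replace = TRUE)
    L <- hap_lens[hap]
    p1 <- floor(runif(n_pairs) * (L - read_len))
    d <- sample_decay_distance(n_pairs, profile$decay_exponent,
                               d_min = 1000, d_max = max(L) / 2)
    s <- sample(c(-1L, 1L), n_pairs, replace = TRUE)
    p2 <- p1 + s * d
    flip <- p2 < 0 | p2 > L - read_len
    p2[flip] <- p1[flip] - s[flip] * d[flip]
    p2 <- pmin(pmax(p2, 0), L - read_len)
    bg <- tibble(haplotype = hap, hap_pos1 = as.integer(p1),
                 hap_pos2 = as.integer(p2), source = "background")
  }

  ## boosted anchor pairs
  bp <- NULL
  if (!is.null(boosts) && nrow(boosts) > 0) {
    bp <- purrr::map_dfr(seq_len(nrow(boosts)), function(i) {
      b <- boosts[i, ]
      anch <- model_anchors(model, b$haplotype)
      a1 <- anch %>% filter(.data$name == b$anchor_a)
      if (b$anchor_b == "cassette") {
        a2 <- anch %>% filter(.data$role == "oncogene_array_copy",
                              .data$contig == b$haplotype)
      } else {
        a2 <- anch %>% filter(.data$name == b$anchor_b)
      }
      if (nrow(a1) != 1 || nrow(a2) == 0) {
        abort(sprintf("boost anchors %s/%s not found on %s",
                      b$anchor_a, b$anchor_b, b$haplotype))
      }
      k <- rpois(1, b$expected)
      if (k == 0) return(NULL)
      copy <- sample(nrow(a2), k, replace = TRUE)
      tibble(
        haplotype = b$haplotype,
        hap_pos1 = a1$start + floor(runif(k) * (a1$end - a1$start - read_len)),
        hap_pos2 = a2$start[copy] +
          floor(runif(k) * (a2$end[copy] - a2$start[copy] - read_len)),
        source = paste0("boost:", b$anchor_a, "-", b$anchor_b)
      )
    })
  }

  all <- bind_rows(bg, bp)
  if (is.null(all) || nrow(all) == 0) {
    return(list(
      contacts = tibble(pair_id = character(), contig1 = character(),
                        pos1 = integer(), contig2 = character(),
                        pos2 = integer(), assay = character(),
                        mult = integer(), seq1 = character(),
                        seq2 = character()),
      truth = tibble(pair_id = character(), haplotype = character(),
                     hap_pos1 = integer(), hap_pos2 = integer(),
                     source = character())
    ))
  }
  all$hap_pos1 <- as.integer(all$hap_pos1)
  all$hap_pos2 <- as.integer(all$hap_pos2)
  all$pair_id <- sprintf("cp%07d", seq_len(nrow(all)))

  map_end <- function(hap, pos) {
    out <- tibble(contig = character(length(pos)), pos = NA_integer_,
                  seq = NA_character_)
    for (h in c("hap_wt", "hap_rearr")) {
      sel <- hap == h
      if (!any(sel)) next
      m <- hap_point_to_ref(model, h, pos[sel])
      m <- scatter_cassette_ends(model, m, read_len)
      out$contig[sel] <- m$contig
      out$pos[sel] <- m$pos
      if (emit_seq) {
        out$seq[sel] <- substring(model$haplotypes[[h]], pos[sel] + 1L,
                                  pos[sel] + read_len)
      }
    }
    out
  }
  e1 <- map_end(all$haplotype, all$hap_pos1)
  e2 <- map_end(all$haplotype, all$hap_pos2)

  contacts <- tibble(
    pair_id = all$pair_id,
    contig1 = e1$contig, pos1 = e1$pos,
    contig2 = e2$contig, pos2 = e2$pos,
    assay = assay_tag, mult = 1L,
    seq1 = e1$seq, seq2 = e2$seq
  ) %>% canonicalize_pairs()

  truth <- all %>%
    select("pair_id", "haplotype", "hap_pos1", "hap_pos2", "source")
  list(contacts = contacts, truth = truth)
}

# place cassette-internal ends on the donor contig, scattered uniformly
# among the paralog copies indistinguishable over the read span
scatter_cassette_ends <- function(model, mapped, read_len) {
  idx <- which(mapped$in_cassette)
  if (length(idx) == 0) return(mapped)
  plen <- model$config$paralog_len
  sp <- model$config$cassette_spacer_len
  canon <- model$paralogs[model$paralogs$canonical, ]
  others <- model$paralogs[!model$paralogs$canonical, ]
  u <- (mapped$cassette_offset[idx]) %% (plen + sp)   # offset in canonical unit
  span_end <- pmin(u + read_len, plen)
  in_copy <- u < plen
  # eligibility of each non-canonical copy: no distinguishing substitution
  # inside the read span
  elig <- matrix(FALSE, nrow = length(idx), ncol = nrow(others))
  for (j in seq_len(nrow(others))) {
    subs <- sort(others$sub_pos[[j]])
    n_in <- findInterval(span_end - 1L, subs) - findInterval(u - 1L, subs)
    elig[, j] <- in_copy & n_in == 0 & (u + read_len <= plen)
  }
  n_elig <- 1L + rowSums(elig)
  pick <- floor(runif(length(idx)) * n_elig)   # 0 = canonical
  new_pos <- mapped$pos[idx]
  for (i in seq_along(idx)) {
    if (pick[i] >= 1) {
      target <- which(elig[i, ])[pick[i]]
      new_pos[i] <- others$start[target] + u[i]
    }
  }
  mapped$pos[idx] <- new_pos
  mapped
}

# store pair ends in canonical order: lexicographic by (contig, pos)
canonicalize_pairs <- function(contacts) {
  swap <- contacts$contig1 > contacts$contig2 |
    (contacts$contig1 == contacts$contig2 & contacts$pos1 > contacts$pos2)
  if (any(swap)) {
    tmp_c <- contacts$contig1[swap]; tmp_p <- contacts$pos1[swap]
    contacts$contig1[swap] <- contacts$contig2[swap]
    contacts$pos1[swap] <- contacts$pos2[swap]
    contacts$contig2[swap] <- tmp_c
    contacts$pos2[swap] <- tmp_p
    if ("seq1" %in% names(contacts)) {
      tmp_s <- contacts$seq1[swap]
      contacts$seq1[swap] <- contacts$seq2[swap]
      contacts$seq2[swap] <- tmp_s
    }
  }
  contacts
}
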