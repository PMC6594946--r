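#' Count contact pairs between two anchors
#'
#' Counts pairs with one end overlapping anchor `a` and the other end
#' overlapping anchor `b` — or any member of a set of anchors `b` (the
#' union rule used for a multi-copy oncogene array). Ends are point
#' positions extended by `read_len`; overlap means at least 1 bp
#' intersection; counting is symmetric in the two ends. Anchors `a` and
#' `b` must not overlap each other (assignment would be ambiguous).
#'
#' @param contacts Contact tibble (`contig1`, `pos1`, `contig2`, `pos2`,
#'   `mult`).
#' @param a One anchor row (`name`, `contig`, `start`, `end`).
#' @param b One anchor row or a tibble of anchors (the union).
#' @param read_len End footprint in bp (default 75).
#' @return Integer count (sum of multiplicities).
#' @export
count_anchor_pairs <- function(contacts, a, b, read_len = 75L) {
  a <- as_tibble(as.list(as.data.frame(a)))
  b <- as_tibble(b)
  same_contig <- a$contig[1] %in% b$contig
  if (same_contig &&
      any(overlaps_interval(a$start[1], a$end[1], b$start, b$end) &
            b$contig == a$contig[1])) {
    abort("anchors a and b overlap; pair assignment would be ambiguous")
  }
  if (nrow(contacts) == 0) return(0L)
  in_anchor <- function(contig, pos, anch) {
    hit <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(anch))) {
      hit <- hit | (contig == anch$contig[i] &
                      overlaps_interval(pos, pos + read_len,
                                        anch$start[i], anch$end[i]))
    }
    hit
  }
  e1_a <- in_anchor(contacts$contig1, contacts$pos1, a)
  e2_a <- in_anchor(contacts$contig2, contacts$pos2, a)
  e1_b <- in_anchor(contacts$contig1, contacts$pos1, b)
  e2_b <- in_anchor(contacts$contig2, contacts$pos2, b)
  hit <- (e1_a & e2_b) | (e2_a & e1_b)
  as.integer(sum(contacts$mult[hit]))
}

#' Peak coverage of capture other-ends in a target window
#'
#' Restricts a capture-style contact set to pairs with one end in the
#' viewpoint anchor, filters other-ends within the viewpoint exclusion
#' zone (default +/- 500 bp around the viewpoint, the oligo-proximity
#' artefact filter), and returns the maximum per-base coverage of the
#' remaining other-end footprints inside the target window.
#'
#' @param contacts Contact tibble.
#' @param viewpoint Anchor row for the capture viewpoint.
#' @param window Target window: list/row with `contig`, `start`, `end`.
#' @param read_len Other-end footprint in bp.
#' @param exclusion Exclusion half-width around the viewpoint (bp).
#' @return Integer: the highest per-base coverage in the window (0 when no
#'   reads).
#' @export
peak_coverage <- function(contacts, viewpoint, window, read_len = 75L,
                          exclusion = 500L) {
  vp <- as.list(as.data.frame(as_tibble(viewpoint)))
  win <- as.list(window)
  excl_start <- vp$start - exclusion
  excl_end <- vp$end + exclusion
  if (win$contig == vp$contig &&
      overlaps_interval(win$start, win$end, excl_start, excl_end)) {
    abort("target window lies inside the viewpoint exclusion zone")
  }
  if (nrow(contacts) == 0) return(0L)
  e1_vp <- contacts$contig1 == vp$contig &
    overlaps_interval(contacts$pos1, contacts$pos1 + read_len,
                      vp$start, vp$end)
  e2_vp <- contacts$contig2 == vp$contig &
    overlaps_interval(contacts$pos2, contacts$pos2 + read_len,
                      vp$start, vp$end)
  other_contig <- c(contacts$contig2[e1_vp], contacts$contig1[e2_vp])
  other_pos <- c(contacts$pos2[e1_vp], contacts$pos1[e2_vp])
  other_mult <- c(contacts$mult[e1_vp], contacts$mult[e2_vp])
  # exclusion zone filter on the other end
  drop <- other_contig == vp$contig &
    overlaps_interval(other_pos, other_pos + read_len, excl_start, excl_end)
  other_contig <- other_contig[!drop]
  other_pos <- other_pos[!drop]
  other_mult <- other_mult[!drop]
  sel <- other_contig == win$contig &
    overlaps_interval(other_pos, other_pos + read_len, win$start, win$end)
  if (!any(sel)) return(0L)
  pos <- other_pos[sel]; mlt <- other_mult[sel]
  width <- win$end - win$start
  cov <- integer(width)
  s <- pmax(pos - win$start, 0L) + 1L
  e <- pmin(pos + read_len - win$start, width)
  for (i in seq_along(s)) {
    if (e[i] >= s[i]) cov[s[i]:e[i]] <- cov[s[i]:e[i]] + mlt[i]
  }
  as.integer(max(cov))
}

#' Rescue multi-mapped paralog-family reads onto the canonical copy
#'
#' Collects contact ends mapped anywhere in the paralog family, realigns
#' each end's read sequence to the canonical region with a gap-free
#' best-hit scan bounded at `max_mismatch` mismatches, and moves rescued
#' ends to their new position. Coverage over the canonical copy can only
#' grow (rescue monotonicity); reads that align nowhere within the bound
#' are left in place and tallied.
#'
#' @param contacts Contact tibble with `seq1`/`seq2` end sequences (e.g. a
#'   Capture-C simulation).
#' @param model A genome model (supplies the family anchors and the
#'   canonical region sequence).
#' @param max_mismatch Mismatch bound for the realignment scan (default
#'   2).
#' @param flank Canonical region extension on each side, covering the
#'   "nearby region" a rescued read may align into (default 600 bp).
#' @return A list of class `rescue_result`: `contacts` (ends moved),
#'   `n_candidates`, `n_rescued`, `n_unrescued`, `canonical_region`.
#' @export
multimapping_rescue <- function(contacts, model, max_mismatch = 2L,
                                flank = 600L) {
  fam <- model$paralogs
  canon <- fam[fam$canonical, ]
  if (nrow(canon) != 1) abort("model must define one canonical family copy")
  reg_start <- max(0L, canon$start - flank)
  reg_end <- min(nchar(model$contigs[["chrD"]]), canon$end + flank)
  region_seq <- seq_sub(model$contigs[["chrD"]], reg_start, reg_end)
  region <- Biostrings::DNAString(region_seq)

  n_cand <- 0L; n_resc <- 0L; n_unresc <- 0L
  for (side in 1:2) {
    ctg <- contacts[[paste0("contig", side)]]
    pos <- contacts[[paste0("pos", side)]]
    sq <- contacts[[paste0("seq", side)]]
    hit_family <- ctg == "chrD" & vapply(seq_along(pos), function(i) {
      ctg[i] == "chrD" &&
        any(overlaps_interval(pos[i], pos[i] + nchar(sq[i] %||% ""),
                              fam$start, fam$end))
    }, logical(1))
    idx <- which(hit_family & !is.na(sq))
    n_cand <- n_cand + length(idx)
    for (i in idx) {
      best <- NULL
      for (mm in 0:max_mismatch) {
        h <- Biostrings::matchPattern(sq[i], region, max.mismatch = mm,
                                      with.indels = FALSE)
        if (length(h) > 0) {
          best <- BiocGenerics::start(h)[1] - 1L   # leftmost best hit
          break
        }
      }
      if (is.null(best)) {
        n_unresc <- n_unresc + 1L
      } else {
        n_resc <- n_resc + 1L
        contacts[[paste0("pos", side)]][i] <- reg_start + best
      }
    }
  }
  structure(list(
    contacts = canonicalize_pairs(contacts),
    n_candidates = n_cand, n_rescued = n_resc, n_unrescued = n_unresc,
    canonical_region = list(contig = "chrD", start = reg_start,
                            end = reg_end)
  ), class = "rescue_result")
}

#' @export
print.rescue_result <- function(x, ...) {
  cat(sprintf("<rescue_result> %d family-mapped ends: %d rescued, %d not\n",
              x$n_candidates, x$n_rescued, x$n_unrescued))
  invisible(x)
}

#' Interaction intensity fold between two quantifications
#'
#' Ratio of a reference interaction's supporting count to an alternative's
#' (e.g. enhancer-promoter over enhancer-oncogene), reported both as the
#' float and as the nearest integer (round half away from zero) — the
#' conventional "N-fold" statement.
#'
#' @param count_ref,count_alt Supporting counts (pairs or peak coverage);
#'   `count_alt` must be positive for a defined ratio.
#' @return A list of class `interaction_fold`: `ratio`, `rounded`,
#'   `defined`.
#' @export
interaction_fold <- function(count_ref, count_alt) {
  if (count_ref < 0 || count_alt < 0) abort("counts must be non-negative")
  if (count_alt == 0) {
    return(structure(list(ratio = NA_real_, rounded = NA_integer_,
                          defined = FALSE), class = "interaction_fold"))
  }
  ratio <- count_ref / count_alt
  structure(list(ratio = ratio,
                 rounded = as.integer(sign(ratio) * floor(abs(ratio) + 0.5)),
                 defined = TRUE),
            class = "interaction_fold")
}

#' @export
print.interaction_fold <- function(x, ...) {
  if (!x$defined) cat("<interaction_fold> undefined (zero denominator)\n")
  else cat(sprintf("<interaction_fold> %.4g (reported as %d-fold)\n",
                   x$ratio, x$rounded))
  invisible(x)
}

#' Linear distance between two anchors on a haplotype
#'
#' Distance between the nearest edges of two anchors in a haplotype's
#' edited coordinate system: insertions between them expand the distance,
#' deletions contract it. An anchor fully removed by a deletion raises an
#' error naming the deletion.
#'
#' @param model A genome model.
#' @param name_a,name_b Anchor names (reference anchors on `chrL`), or
#'   names present in [model_anchors()] for that haplotype (so cassette
#'   copies can be used on `hap_rearr`).
#' @param haplotype Haplotype name.
#' @return Integer distance in bp (0 if the anchors touch or overlap).
#' @export
haplotype_distance <- function(model, name_a, name_b, haplotype) {
  anch <- model_anchors(model, haplotype)
  pick <- function(nm) {
    a <- anch[anch$name == nm, ]
    if (nrow(a) == 0) {
      ref <- model$anchors[model$anchors$name == nm, ]
      if (nrow(ref) == 1) {
        dels <- model$edits %>%
          filter(.data$haplotype == .env$haplotype, .data$op == "delete",
                 .data$ref_pos <= ref$start,
                 .data$ref_pos + .data$length >= ref$end)
        if (nrow(dels) > 0) {
          abort(sprintf("anchor '%s' is removed on %s by deletion '%s'",
                        nm, haplotype, dels$name[1]))
        }
      }
      abort(sprintf("anchor '%s' not available on %s", nm, haplotype))
    }
    a[1, ]
  }
  a <- pick(name_a); b <- pick(name_b)
  if (a$end <= b$start) return(as.integer(b$start - a$end))
  if (b$end <= a$start) return(as.integer(a$start - b$end))
  0L
}

#' Call adjacency of labelled regions from binned contact counts
#'
#' Fits (or accepts) a distance-decay background on intra-contig pairs,
#' sets the inter-contig expectation to the background constant, and calls
#' a region pair adjacent when its observed/expected enrichment exceeds a
#' threshold and the copy-number phase of the two regions is consistent
#' (both present on the rearranged molecule). Used to infer the two
#' junctions of a reciprocal translocation from cross-contig contact
#' enrichment.
#'
#' @param contacts Contact tibble.
#' @param regions Tibble of labelled regions (`name`, `contig`, `start`,
#'   `end`).
#' @param copy_number Optional tibble (`name`, `cn`); pairs where either
#'   region has `cn == 0` are never called adjacent. `NULL` accepts all.
#' @param threshold Enrichment threshold (default 5).
#' @param read_len End footprint in bp.
#' @return A tibble of class `adjacency_calls`: one row per region pair
#'   with `observed`, `expected`, `enrichment`, `adjacent`.
#' @export
region_adjacency <- function(contacts, regions, copy_number = NULL,
                             threshold = 5, read_len = 75L) {
  regions <- as_tibble(regions)
  if (nrow(regions) < 2) abort("need >= 2 labelled regions")
  if (nrow(contacts) == 0) abort("no contacts: background cannot be estimated")

  # effective contig lengths from the data and region definitions
  contig_len <- tapply(
    c(contacts$pos1 + read_len, contacts$pos2 + read_len, regions$end),
    c(contacts$contig1, contacts$contig2, regions$contig), max)
  inter <- contacts$contig1 != contacts$contig2
  n_inter <- sum(contacts$mult[inter])
  inter_area <- 0
  ctgs <- names(contig_len)
  if (length(ctgs) > 1) {
    for (i in seq_along(ctgs)[-1]) {
      for (j in seq_len(i - 1)) {
        inter_area <- inter_area +
          as.numeric(contig_len[[i]]) * as.numeric(contig_len[[j]])
      }
    }
  }

  pairs <- tidyr::expand_grid(i = seq_len(nrow(regions)),
                              j = seq_len(nrow(regions))) %>%
    filter(.data$i < .data$j)
  out <- purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    ra <- regions[pairs$i[k], ]; rb <- regions[pairs$j[k], ]
    obs <- count_anchor_pairs(contacts, ra, rb, read_len = read_len)
    la <- as.numeric(ra$end - ra$start); lb <- as.numeric(rb$end - rb$start)
    if (ra$contig == rb$contig) {
      # expected under decay: pairs on this contig in a distance band
      # around the regions' separation, scaled by the geometric fraction
      # of that band falling in A x B
      d_ab <- abs((ra$start + ra$end) / 2 - (rb$start + rb$end) / 2)
      d_lo <- d_ab / sqrt(2); d_hi <- d_ab * sqrt(2)
      on_ctg <- contacts$contig1 == ra$contig & !inter
      d <- abs(contacts$pos2[on_ctg] - contacts$pos1[on_ctg])
      n_band <- sum(contacts$mult[on_ctg][d >= d_lo & d <= d_hi])
      L <- as.numeric(contig_len[[ra$contig]])
      band_area <- max(L - d_ab, 1) * (d_hi - d_lo)
      exp_ct <- n_band * (la * lb) / band_area
    } else {
      # flat inter-contig background constant
      exp_ct <- n_inter * (la * lb) / max(inter_area, 1)
    }
    cn_ok <- TRUE
    if (!is.null(copy_number)) {
      cn <- as_tibble(copy_number)
      cna <- cn$cn[match(ra$name, cn$name)]
      cnb <- cn$cn[match(rb$name, cn$name)]
      cn_ok <- isTRUE(cna > 0) && isTRUE(cnb > 0)
    }
    enr <- obs / max(exp_ct, .Machine$double.eps)
    tibble(region_a = ra$name, region_b = rb$name,
           observed = obs, expected = exp_ct, enrichment = enr,
           adjacent = cn_ok & obs > 0 & enr >= threshold)
  })
  class(out) <- c("adjacency_calls", class(out))
  out
}

#' Fit the distance-decay exponent of a contact set
#'
#' Log-log regression of log-binned intra-contig pair counts on distance;
#' the negative slope (plus one, for the log-binned density correction)
#' estimates the power-law exponent.
#'
#' @param contacts Contact tibble.
#' @param d_min,d_max Distance range used in the fit.
#' @param n_bins Number of log-spaced bins.
#' @return A list with `exponent` and the binned tibble `bins`.
#' @export
fit_decay_exponent <- function(contacts, d_min = 1000, d_max = NULL,
                               n_bins = 20) {
  intra <- contacts %>% filter(.data$contig1 == .data$contig2)
  d <- abs(intra$pos2 - intra$pos1)
  d <- d[d >= d_min]
  if (is.null(d_max)) d_max <- max(d)
  d <- d[d <= d_max]
  if (length(d) < 50) abort("too few intra-contig pairs to fit decay")
  brk <- exp(seq(log(d_min), log(d_max + 1), length.out = n_bins + 1))
  bin <- cut(d, brk, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- sqrt(brk[-1] * brk[-(n_bins + 1)])
  widths <- diff(brk)
  keep <- counts > 0
  dens <- counts[keep] / widths[keep]
  fit <- stats::lm(log(dens) ~ log(mids[keep]))
  list(exponent = -unname(stats::coef(fit)[2]),
       bins = tibble(mid = mids[keep], count = counts[keep],
                     density = dens))
}
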