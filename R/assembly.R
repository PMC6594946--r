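#' Recruit reads by shared barcode around a target region
#'
#' Selects barcodes with at least `min_reads` reads mapped inside the
#' target region, then pulls every read in the whole library sharing one of
#' those barcodes — including reads mapped far away or to other contigs
#' (the distal mates that make local assembly across a breakpoint
#' possible).
#'
#' @param reads Barcode-tagged alignment tibble.
#' @param region A list/tibble row with `contig`, `start`, `end` (0-based
#'   half-open), e.g. one row of a model's anchor table.
#' @param min_reads Barcode qualification threshold (default 20 reads in
#'   the region).
#' @return A list of class `recruitment_result`: `region`, `threshold`,
#'   `barcodes` (tibble `barcode`, `n_in_region`), `reads` (all recruited
#'   reads).
#' @export
recruit_barcodes <- function(reads, region, min_reads = 20L) {
  region <- as.list(region)
  if (is.null(region$contig) || is.null(region$start) || is.null(region$end) ||
      region$start >= region$end) {
    abort("region must have contig, start < end")
  }
  in_region <- reads$contig == region$contig &
    overlaps_interval(reads$start, reads$end, region$start, region$end) &
    !is.na(reads$barcode)
  bc <- reads[in_region, ] %>%
    count(.data$barcode, name = "n_in_region") %>%
    filter(.data$n_in_region >= min_reads)
  recruited <- reads %>% filter(.data$barcode %in% bc$barcode)
  structure(list(region = region, threshold = as.integer(min_reads),
                 barcodes = bc, reads = recruited),
            class = "recruitment_result")
}

#' @export
print.recruitment_result <- function(x, ...) {
  cat(sprintf("<recruitment_result> %s:%d-%d, threshold %d\n",
              x$region$contig, x$region$start, x$region$end, x$threshold))
  cat(sprintf("  %d qualifying barcodes, %d recruited reads\n",
              nrow(x$barcodes), nrow(x$reads)))
  invisible(x)
}

#' Assemble reads into unitigs by exact k-mer overlap
#'
#' A deterministic stand-in assembler for the low-error linked-read
#' regime: reads are decomposed into k-mers, a de Bruijn graph is built on
#' exact (k-1)-overlaps, and contigs are the maximal unambiguous paths —
#' extension stops at any branch point (e.g. a heterozygous SNP), so no
#' join ever crosses conflicting evidence. Per-base support is the mean
#' k-mer multiplicity along the contig.
#'
#' @param reads Tibble with a `seq` column, or a character vector of read
#'   sequences.
#' @param k K-mer size (default 31); must be smaller than the read length.
#' @param min_count Minimum k-mer multiplicity retained (1 keeps all).
#' @return Tibble with `contig_id`, `seq`, `length`, `mean_support`,
#'   sorted by decreasing length.
#' @export
assemble_overlap <- function(reads, k = 31L, min_count = 1L) {
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  seqs <- seqs[!is.na(seqs)]
  if (length(seqs) == 0) {
    return(tibble(contig_id = character(), seq = character(),
                  length = integer(), mean_support = numeric()))
  }
  if (k >= min(nchar(seqs))) {
    abort(sprintf("k = %d must be smaller than the shortest read (%d bp)",
                  k, min(nchar(seqs))))
  }
  # k-mer counting
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s) - k + 1L
    substring(s, seq_len(n), seq_len(n) + k - 1L)
  }))
  counts <- table(kmers)
  counts <- counts[counts >= min_count]
  km <- names(counts)
  cnt <- as.integer(counts)
  names(cnt) <- km

  pref <- substr(km, 1L, k - 1L)
  suf <- substr(km, 2L, k)
  last_base <- substr(km, k, k)
  first_base <- substr(km, 1L, 1L)

  # adjacency: out-edges keyed by prefix node, in-edges by suffix node
  out_by_node <- split(seq_along(km), pref)
  in_by_node <- split(seq_along(km), suf)

  out_deg <- function(node) length(out_by_node[[node]] %||% integer(0))
  in_deg <- function(node) length(in_by_node[[node]] %||% integer(0))

  visited <- logical(length(km))
  contigs <- character(0)
  support <- numeric(0)

  # a k-mer starts a unitig when its predecessor situation is not a simple
  # 1-in/1-out chain
  for (i in order(km)) {
    if (visited[i]) next
    node_in <- pref[i]
    starts_here <- in_deg(node_in) != 1L || out_deg(node_in) != 1L
    if (!starts_here) {
      p <- in_by_node[[node_in]][1]
      if (!visited[p]) next  # interior of a chain; reached from its start
    }
    # walk forward
    path <- i
    visited[i] <- TRUE
    cur <- i
    repeat {
      node <- suf[cur]
      outs <- out_by_node[[node]] %||% integer(0)
      if (length(outs) != 1L || in_deg(node) != 1L) break
      nxt <- outs[1]
      if (visited[nxt]) break
      path <- c(path, nxt)
      visited[nxt] <- TRUE
      cur <- nxt
    }
    contigs <- c(contigs,
                 paste0(km[path[1]],
                        paste(last_base[path[-1]], collapse = "")))
    support <- c(support, mean(cnt[path]))
  }

  # anything left unvisited sits on a cycle; emit it too for completeness
  while (any(!visited)) {
    i <- which(!visited)[1]
    path <- i; visited[i] <- TRUE; cur <- i
    repeat {
      node <- suf[cur]
      outs <- out_by_node[[node]] %||% integer(0)
      if (length(outs) != 1L) break
      nxt <- outs[1]
      if (visited[nxt]) break
      path <- c(path, nxt); visited[nxt] <- TRUE; cur <- nxt
    }
    contigs <- c(contigs,
                 paste0(km[path[1]],
                        paste(last_base[path[-1]], collapse = "")))
    support <- c(support, mean(cnt[path]))
  }

  ord <- order(-nchar(contigs), contigs)
  tibble(
    contig_id = sprintf("ctg%04d", seq_along(ord)),
    seq = contigs[ord],
    length = nchar(contigs[ord]),
    mean_support = support[ord]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Attribute an assembled cassette contig to its source paralog
#'
#' Aligns the contig (or its cassette portion) to every family copy with
#' an end-gap-free, gap-disallowed alignment at unit mismatch cost (the
#' copies are equal-length in the model) and ranks copies by mismatches.
#' Identity is `100 * (aligned_length - mismatches) / aligned_length`. An
#' `"exclusive"` origin is declared when the best copy matches with 0
#' mismatches and the margin to the runner-up is at least 1.
#'
#' @param contig Character scalar (assembled sequence), at least
#'   `min_length` bp.
#' @param paralogs Named character vector of family sequences, or a
#'   model's `paralogs` tibble.
#' @param min_length Minimum contig length for attribution (default 200).
#' @return Tibble with `paralog_name`, `aligned_length`, `mismatches`,
#'   `identity`, `rank`, `margin` (mismatch difference to the next-best
#'   copy; for the last rank, to the best), and attribute `exclusive`.
#' @export
paralog_attribution <- function(contig, paralogs, min_length = 200L) {
  if (is.data.frame(paralogs)) {
    paralogs <- setNames(paralogs$seq, paralogs$name)
  }
  if (length(paralogs) < 1) abort("need >= 1 paralog sequence")
  if (nchar(contig) < min_length) {
    abort(sprintf("contig of %d bp is below the attribution minimum (%d bp)",
                  nchar(contig), min_length))
  }
  res <- purrr::map_dfr(names(paralogs), function(nm) {
    p <- paralogs[[nm]]
    al <- best_ungapped_alignment(contig, p)
    tibble(paralog_name = nm, aligned_length = al$len,
           mismatches = al$mismatches,
           identity = 100 * (al$len - al$mismatches) / al$len)
  }) %>%
    arrange(.data$mismatches, .data$paralog_name) %>%
    mutate(rank = row_number())
  res$margin <- if (nrow(res) > 1) {
    c(res$mismatches[-1] - res$mismatches[-nrow(res)],
      res$mismatches[nrow(res)] - res$mismatches[1])
  } else 0L
  attr(res, "exclusive") <-
    res$mismatches[1] == 0L && nrow(res) > 1 && res$margin[1] >= 1
  res
}

# slide the shorter sequence along the longer; mismatches at the best
# offset (end-gap-free, no internal gaps)
best_ungapped_alignment <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  la <- nchar(a); lb <- nchar(b)
  pa <- Biostrings::DNAString(a)
  sub <- Biostrings::DNAString(b)
  best <- la + 1L
  for (mm in c(0L, 2L, 8L, 32L, la)) {
    hits <- Biostrings::matchPattern(pa, sub, max.mismatch = mm,
                                     with.indels = FALSE)
    if (length(hits) > 0) {
      mism <- vapply(seq_along(hits), function(i) {
        Biostrings::neditStartingAt(pa, sub,
                                    starting.at = BiocGenerics::start(hits)[i])
      }, integer(1))
      best <- min(mism)
      break
    }
  }
  list(len = la, mismatches = as.integer(best))
}

#' Scaffold a haplotype from ordered parts
#'
#' Concatenates contigs and reference segments in declared order and
#' orientation — the manual patching step used when a tandem repeat breaks
#' assembly and a reference linker must bridge two contigs. Adjacent parts
#' must abut exactly (declared overlap 0); emits the scaffold sequence and
#' a junction table.
#'
#' @param parts Tibble with columns `part_id`, `source` (`"contig"` or
#'   `"reference_segment"`), `seq`, `orientation` (`"+"` or `"-"`).
#' @return A list of class `scaffold_plan`: `seq`, `total_length`, `parts`
#'   (with `start`/`end` on the scaffold), `junctions` (tibble `pos`,
#'   `left_part`, `right_part`).
#' @export
scaffold_haplotype <- function(parts) {
  parts <- as_tibble(parts)
  needed <- c("part_id", "source", "seq", "orientation")
  if (!all(needed %in% names(parts)) || nrow(parts) == 0) {
    abort("parts must be a non-empty tibble with part_id, source, seq, orientation")
  }
  if (!all(parts$orientation %in% c("+", "-"))) {
    abort("orientation must be '+' or '-'")
  }
  if (any(is.na(parts$seq) | nchar(parts$seq) == 0)) {
    abort("gapped or empty parts are not allowed without an explicit spacer")
  }
  emitted <- if_else(parts$orientation == "-", revcomp(parts$seq), parts$seq)
  lens <- nchar(emitted)
  starts <- cumsum(c(0L, lens[-length(lens)]))
  junctions <- if (nrow(parts) > 1) {
    tibble(pos = starts[-1],
           left_part = parts$part_id[-nrow(parts)],
           right_part = parts$part_id[-1])
  } else {
    tibble(pos = integer(), left_part = character(), right_part = character())
  }
  structure(list(
    seq = paste(emitted, collapse = ""),
    total_length = sum(lens),
    parts = parts %>% mutate(start = starts, end = starts + lens),
    junctions = junctions
  ), class = "scaffold_plan")
}

#' @export
print.scaffold_plan <- function(x, ...) {
  cat(sprintf("<scaffold_plan> %d parts, %d bp\n", nrow(x$parts),
              x$total_length))
  invisible(x)
}
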