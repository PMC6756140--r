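#' Probe candidate table
#'
#' Assembler-bubble SNP probe candidates: a sequence holding one putative
#' heterozygous site, its home scaffold, and how many assembly locations the
#' sequence maps to at the 90% and 95% identity thresholds (low counts mark
#' low-copy regions suitable for hybridization capture).
#'
#' @param id Candidate ids.
#' @param sequence Nucleotide strings.
#' @param snp_offset 0-based index of the SNP within each sequence.
#' @param scaffold_id Home scaffold of each candidate.
#' @param scaffold_length Scaffold length in bp.
#' @param map_count_90,map_count_95 Mapping locations at >= 90% / >= 95%
#'   identity.
#' @return A data frame of class `probe_candidates`.
#' @export
probe_candidates <- function(id, sequence, snp_offset, scaffold_id,
                             scaffold_length, map_count_90, map_count_95) {
  snp_offset <- as.integer(snp_offset)
  if (any(snp_offset < 0) || any(snp_offset >= nchar(sequence)))
    stop("snp_offset must index into the sequence")
  if (any(map_count_90 < 0) || any(map_count_95 < 0))
    stop("mapping counts must be non-negative")
  out <- data.frame(id = as.character(id), sequence = as.character(sequence),
                    snp_offset = snp_offset,
                    scaffold_id = as.character(scaffold_id),
                    scaffold_length = as.numeric(scaffold_length),
                    map_count_90 = as.integer(map_count_90),
                    map_count_95 = as.integer(map_count_95))
  class(out) <- c("probe_candidates", class(out))
  out
}

#' Probe selection configuration
#'
#' @param per_scaffold_small Bubbles allowed from scaffolds shorter than
#'   `large_scaffold_min` (default 1).
#' @param per_scaffold_large Bubbles allowed from scaffolds at or above
#'   `large_scaffold_min` (default 2).
#' @param large_scaffold_min Scaffold length separating the two quotas
#'   (default 10 kbp).
#' @param total_cap Global cap on selected bubbles (default 20,000).
#' @param probe_length Final probe length after trimming (default 80 bp).
#' @param dedupe_identity Identity threshold of the duplicate-removal step
#'   (default 0.90).
#' @return An object of class `probe_selection_config`.
#' @export
probe_selection_config <- function(per_scaffold_small = 1,
                                   per_scaffold_large = 2,
                                   large_scaffold_min = 1e4,
                                   total_cap = 2e4,
                                   probe_length = 80,
                                   dedupe_identity = 0.90) {
  stopifnot(per_scaffold_small >= 1, per_scaffold_large >= 1,
            large_scaffold_min > 0, total_cap >= 1, probe_length >= 1,
            dedupe_identity > 0, dedupe_identity <= 1)
  structure(list(per_scaffold_small = per_scaffold_small,
                 per_scaffold_large = per_scaffold_large,
                 large_scaffold_min = large_scaffold_min,
                 total_cap = total_cap, probe_length = probe_length,
                 dedupe_identity = dedupe_identity),
            class = "probe_selection_config")
}

# Global pairwise identity: matches over alignment length, from an exact
# Needleman-Wunsch alignment.
.pair_identity <- function(s1, s2) {
  aln <- Biostrings::pairwiseAlignment(s1, s2, type = "global")
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Remove clustered near-duplicate candidates
#'
#' Clusters candidates by single-linkage on global pairwise identity (exact
#' dynamic-programming alignment; quadratic in the number of candidates, for
#' desk-scale inputs) and removes every member of any cluster of two or
#' more, leaving only unique bubbles.  Near-identical bubbles typically come
#' from repeats rather than single heterozygous loci, so whole clusters are
#' dropped rather than keeping a representative.
#'
#' @param candidates A [probe_candidates()] data frame.
#' @param identity_threshold Pairs at or above this identity are clustered
#'   (default 0.90).
#' @return The retained candidates; removed ids in the `removed` attribute.
#' @export
dedupe_candidates <- function(candidates, identity_threshold = 0.90) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  n <- nrow(candidates)
  if (!n) return(candidates)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  lens <- nchar(candidates$sequence)
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      # identity <= shorter/longer length: skip hopeless pairs cheaply
      if (min(lens[a], lens[b]) / max(lens[a], lens[b]) < identity_threshold)
        next
      if (.pair_identity(candidates$sequence[a],
                         candidates$sequence[b]) >= identity_threshold) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  size <- table(root)
  keep <- size[as.character(root)] == 1L
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- candidates$id[!keep]
  out
}

#' Tiered probe selection under per-scaffold quotas and a global cap
#'
#' Fills the probe set tier by tier: tier 1 holds bubbles mapping exactly
#' once at >= 90% identity; tier 2 those mapping to at most 4 locations at
#' >= 90%; tier 3 those mapping to at most 3 locations at >= 95%.  Within a
#' tier candidates are visited in deterministic order (scaffold id, SNP
#' offset, id).  A candidate is taken while its scaffold quota (1 below
#' `large_scaffold_min`, else 2) and the global cap allow.  Candidates
#' failing all tiers are excluded.
#'
#' @param candidates Deduplicated [probe_candidates()].
#' @param cfg A [probe_selection_config()].
#' @return The selected candidates with an added `tier` column.
#' @export
select_probes <- function(candidates, cfg = probe_selection_config()) {
  stopifnot(inherits(cfg, "probe_selection_config"))
  tier <- rep(NA_integer_, nrow(candidates))
  tier[candidates$map_count_95 <= 3] <- 3L
  tier[candidates$map_count_90 <= 4] <- 2L
  tier[candidates$map_count_90 == 1] <- 1L
  quota_of <- ifelse(candidates$scaffold_length >= cfg$large_scaffold_min,
                     cfg$per_scaffold_large, cfg$per_scaffold_small)
  used <- integer(0)                              # per-scaffold tally
  taken <- logical(nrow(candidates))
  total <- 0L
  for (tr in 1:3) {
    in_tier <- which(!is.na(tier) & tier == tr)
    in_tier <- in_tier[order(candidates$scaffold_id[in_tier],
                             candidates$snp_offset[in_tier],
                             candidates$id[in_tier])]
    for (i in in_tier) {
      if (total >= cfg$total_cap) break
      sc <- candidates$scaffold_id[i]
      cnt <- if (sc %in% names(used)) used[[sc]] else 0L
      if (cnt >= quota_of[i]) next
      used[sc] <- cnt + 1L
      taken[i] <- TRUE
      total <- total + 1L
    }
    if (total >= cfg$total_cap) break
  }
  out <- candidates[taken, , drop = FALSE]
  out$tier <- tier[taken]
  out <- out[order(out$tier, out$scaffold_id, out$snp_offset, out$id), ]
  rownames(out) <- NULL
  out
}

#' Trim a probe window around its SNP
#'
#' Extracts a `probe_length` window centred on the SNP (SNP at index
#' `floor(probe_length / 2)`, 0-based), shifting the window to stay inside
#' the sequence when the SNP sits near an end.  Sequences shorter than
#' `probe_length` are returned whole and flagged.  The SNP always lies
#' inside the returned window.
#'
#' @param sequence Nucleotide string(s).
#' @param snp_offset 0-based SNP index per sequence.
#' @param probe_length Window length (default 80).
#' @return A data frame `sequence`, `snp_index` (0-based index of the SNP in
#'   the returned window), `short` (TRUE when the input was shorter than
#'   `probe_length`).
#' @export
trim_probe <- function(sequence, snp_offset, probe_length = 80) {
  stopifnot(probe_length >= 1, length(sequence) == length(snp_offset))
  L <- nchar(sequence)
  if (any(snp_offset < 0 | snp_offset >= L))
    stop("snp_offset must index into the sequence")
  short <- L < probe_length
  start <- snp_offset - floor(probe_length / 2)
  start <- pmax(0L, pmin(start, L - probe_length))
  start[short] <- 0L
  end <- ifelse(short, L, start + probe_length)
  data.frame(sequence = substr(sequence, start + 1L, end),
             snp_index = as.integer(snp_offset - start),
             short = short)
}

#' Write probe sequences to FASTA
#'
#' Trims each selected probe with [trim_probe()] and writes a FASTA file
#' whose headers carry the candidate id, scaffold and SNP window index.
#'
#' @param probes A [select_probes()] result (or any [probe_candidates()]).
#' @param path Destination FASTA path.
#' @param probe_length Window length passed to [trim_probe()].
#' @return `path`, invisibly.
#' @export
write_probe_fasta <- function(probes, path, probe_length = 80) {
  tr <- trim_probe(probes$sequence, probes$snp_offset, probe_length)
  lines <- character(2L * nrow(probes))
  lines[c(TRUE, FALSE)] <- sprintf(">%s scaffold=%s snp=%d%s", probes$id,
                                   probes$scaffold_id, tr$snp_index,
                                   ifelse(tr$short, " short", ""))
  lines[c(FALSE, TRUE)] <- tr$sequence
  writeLines(lines, path)
  invisible(path)
}
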