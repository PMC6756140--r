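#' Read a best-hit table
#'
#' Loads a TSV of scaffold best hits against reference pseudochromosomes
#' (columns `scaffold`, `chromosome`, `position`, and optionally `score`).
#' When several hits per scaffold are present, only the best-scoring one is
#' retained (first occurrence on ties or missing scores).
#'
#' @param path Path to a tab-separated file with a header.
#' @return A data frame with one row per scaffold.
#' @export
read_best_hits <- function(path) {
  h <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("scaffold", "chromosome", "position")
  if (!all(need %in% names(h)))
    stop("best-hit table needs columns: ", paste(need, collapse = ", "))
  if (is.null(h$score)) h$score <- NA_real_
  h <- h[order(h$scaffold, -xtfrm(h$score)), ]
  h <- h[!duplicated(h$scaffold), ]
  rownames(h) <- NULL
  h
}

#' Scaffold count matrix: linkage groups x pseudochromosomes
#'
#' Cell (g, c) counts the scaffolds assigned to linkage group `g` whose best
#' hit lies on pseudochromosome `c`.  Scaffolds with hits but no assignment
#' are tallied in an `"unlinked"` row; assigned scaffolds without hits are
#' excluded and counted in the `no_hit` attribute.
#'
#' @param assignments An [assignment_state()] or data frame with columns
#'   `scaffold` and `group`.
#' @param hits Best-hit data frame (`scaffold`, `chromosome`, `position`),
#'   at most one row per scaffold (see [read_best_hits()]).
#' @return An integer matrix (class `synteny_matrix`) with linkage-group
#'   rows (plus `"unlinked"`) and pseudochromosome columns.
#' @export
count_matrix <- function(assignments, hits) {
  if (inherits(assignments, "assignment_state"))
    assignments <- assignments$assignments
  if (anyDuplicated(hits$scaffold)) stop("hits must hold one best hit per scaffold")
  grp <- stats::setNames(assignments$group, assignments$scaffold)
  row_lab <- as.character(grp[hits$scaffold])
  row_lab[is.na(row_lab)] <- "unlinked"
  groups <- sort(unique(assignments$group))
  rows <- factor(row_lab, levels = c(groups, "unlinked"))
  cols <- factor(as.character(hits$chromosome),
                 levels = sort(unique(as.character(hits$chromosome))))
  m <- table(rows, cols)
  m <- matrix(as.integer(m), nrow(m), ncol(m), dimnames = dimnames(m))
  names(dimnames(m)) <- NULL
  if (all(m["unlinked", ] == 0L))
    m <- m[rownames(m) != "unlinked", , drop = FALSE]
  attr(m, "no_hit") <- sum(!assignments$scaffold %in% hits$scaffold)
  class(m) <- c("synteny_matrix", class(m))
  m
}

#' Mutual-best linkage-group / pseudochromosome pairs
#'
#' A linkage group g and pseudochromosome c form a pair when c is the unique
#' column maximum of row g, g is the unique row maximum of column c, and the
#' cell exceeds `dominance` of the row sum (most of the group's scaffolds
#' map there).  Ties produce no pair.  The `"unlinked"` row never pairs.
#'
#' @param matrix A [count_matrix()] result.
#' @param dominance Required fraction of the row sum (default one half).
#' @return Data frame with columns `group`, `chromosome`, `count`,
#'   `row_fraction`.
#' @export
mutual_best_pairs <- function(matrix, dominance = 0.5) {
  m <- unclass(matrix)
  m <- m[rownames(m) != "unlinked", , drop = FALSE]
  out <- list()
  for (g in seq_len(nrow(m))) {
    r <- m[g, ]
    if (all(r == 0L)) next
    cmax <- which(r == max(r))
    if (length(cmax) != 1L) next
    col <- m[, cmax]
    gmax <- which(col == max(col))
    if (length(gmax) != 1L || gmax != g) next
    if (r[cmax] <= dominance * sum(r)) next
    out[[length(out) + 1L]] <- data.frame(
      group = rownames(m)[g], chromosome = colnames(m)[cmax],
      count = r[cmax], row_fraction = r[cmax] / sum(r))
  }
  if (!length(out))
    return(data.frame(group = character(0), chromosome = character(0),
                      count = integer(0), row_fraction = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select one marker per 1-Mbp pseudochromosome bin
#'
#' For a mutual-best (group, pseudochromosome) pair, partitions the
#' pseudochromosome into `bin_size` windows and selects, from each window
#' that has an eligible marker (marker scaffold assigned to the group, best
#' hit inside the window), the marker with the most non-missing calls; ties
#' fall to the lowest hit position, then marker id.  Empty windows yield no
#' marker.
#'
#' @param pair One row of [mutual_best_pairs()] (or a list with `group` and
#'   `chromosome`).
#' @param assignments An [assignment_state()] or data frame
#'   (`scaffold`, `group`).
#' @param hits Best-hit data frame.
#' @param markers A [marker_set()].
#' @param bin_size Window size in bp (default 1 Mbp).
#' @return Data frame `marker_id`, `scaffold`, `bin`, `hit_position`.
#' @export
select_bin_markers <- function(pair, assignments, hits, markers,
                               bin_size = 1e6) {
  if (inherits(assignments, "assignment_state"))
    assignments <- assignments$assignments
  grp <- stats::setNames(assignments$group, assignments$scaffold)
  hit_chr <- stats::setNames(as.character(hits$chromosome), hits$scaffold)
  hit_pos <- stats::setNames(hits$position, hits$scaffold)
  info <- markers$info
  scf <- info$scaffold
  elig <- !is.na(grp[scf]) & grp[scf] == pair$group &
    !is.na(hit_chr[scf]) & hit_chr[scf] == as.character(pair$chromosome)
  if (!any(elig))
    return(data.frame(marker_id = character(0), scaffold = character(0),
                      bin = integer(0), hit_position = numeric(0)))
  cand <- data.frame(marker_id = info$marker_id[elig],
                     scaffold = scf[elig],
                     hit_position = unname(hit_pos[scf[elig]]))
  cand$bin <- floor(cand$hit_position / bin_size)
  n_called <- rowSums(!is.na(markers$seg))
  cand$n_called <- n_called[match(cand$marker_id, info$marker_id)]
  ord <- order(cand$bin, -cand$n_called, cand$hit_position, cand$marker_id)
  cand <- cand[ord, ]
  cand <- cand[!duplicated(cand$bin), ]
  rownames(cand) <- NULL
  cand[, c("marker_id", "scaffold", "bin", "hit_position")]
}

#' Genetic-versus-physical dot series
#'
#' Joins an ordered genetic map to reference best-hit positions, producing
#' the dot-plot series of (physical bp on the pseudochromosome, cumulative
#' genetic cM on the linkage map), sorted by physical position.  Markers
#' whose scaffold has no hit are dropped and counted in the `dropped`
#' attribute.
#'
#' @param ordered_map Result of [order_markers()].
#' @param hits Best-hit data frame.
#' @return Data frame `marker_id`, `physical_bp`, `genetic_cM`, sorted by
#'   physical position.
#' @export
map_vs_physical <- function(ordered_map, hits) {
  pos <- stats::setNames(hits$position, hits$scaffold)
  phys <- unname(pos[ordered_map$scaffold])
  keep <- !is.na(phys)
  out <- data.frame(marker_id = ordered_map$marker_id[keep],
                    physical_bp = phys[keep],
                    genetic_cM = ordered_map$cM[keep])
  out <- out[order(out$physical_bp), ]
  rownames(out) <- NULL
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Decompose a dot series into maximal monotone runs
#'
#' Scanning the series (already sorted by physical position) left to right,
#' emits maximal runs of consecutive points whose genetic positions are
#' strictly increasing or strictly decreasing.  Runs partition the series;
#' singletons are allowed (direction `"single"`).  Monotone runs are the
#' dot-plot signature of loci that keep their relative order in both
#' genomes.
#'
#' @param series A [map_vs_physical()] data frame, or a numeric vector of
#'   genetic positions in physical order.
#' @return Data frame `start`, `length`, `direction`
#'   (`"increasing"`, `"decreasing"`, `"single"`).
#' @export
monotone_runs <- function(series) {
  y <- if (is.data.frame(series)) series$genetic_cM else as.numeric(series)
  n <- length(y)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (i == n) {
      out[[length(out) + 1L]] <- data.frame(start = i, length = 1L,
                                            direction = "single")
      break
    }
    d <- sign(y[i + 1L] - y[i])
    if (d == 0) {
      out[[length(out) + 1L]] <- data.frame(start = i, length = 1L,
                                            direction = "single")
      i <- i + 1L
      next
    }
    j <- i + 1L
    while (j < n && sign(y[j + 1L] - y[j]) == d) j <- j + 1L
    out[[length(out) + 1L]] <- data.frame(
      start = i, length = j - i + 1L,
      direction = if (d > 0) "increasing" else "decreasing")
    i <- j + 1L
  }
  if (!length(out))
    return(data.frame(start = integer(0), length = integer(0),
                      direction = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
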