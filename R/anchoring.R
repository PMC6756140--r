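#' Consolidate perfectly linked markers into bins
#'
#' Two markers are in perfect linkage when their segregation vectors show a
#' recombination fraction of zero.  Within each parental class, markers on
#' the same scaffold with identical vectors (including the missing pattern)
#' are merged first; markers on different scaffolds are merged only when
#' their vectors are complete (no missing entries) and identical or
#' complementary -- complementary complete vectors are the two phases of the
#' same segregation pattern.  Each resulting bin carries the union of member
#' scaffolds and a representative vector.
#'
#' @param markers A [marker_set()] with segregation vectors.
#' @return An object of class `linkage_bins`: `bins` (data frame `bin_id`,
#'   `class`, `n_markers`, `n_scaffolds`), `seg` (representative vectors,
#'   bins x offspring), `members` and `scaffolds` (lists per bin), and
#'   `offspring`.
#' @export
perfect_linkage_bins <- function(markers) {
  stopifnot(inherits(markers, "marker_set"))
  seg <- markers$seg
  M <- nrow(seg)
  vec_str <- apply(seg, 1L, function(r)
    paste(ifelse(is.na(r), "N", r), collapse = ""))
  complete <- !grepl("N", vec_str, fixed = TRUE)
  # canonical orientation for complete vectors: first entry forced to 1
  canon <- vec_str
  flip <- complete & substr(vec_str, 1L, 1L) == "0"
  canon[flip] <- vapply(which(flip), function(i)
    paste(1L - seg[i, ], collapse = ""), character(1))

  # stage 1: same scaffold + identical vector
  key1 <- paste(markers$info$class, markers$info$scaffold, vec_str, sep = "\r")
  g1 <- match(key1, unique(key1))
  # stage 2: merge stage-1 groups with complete identical/complementary vectors
  parent <- seq_len(max(g1))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  reps <- which(!duplicated(g1))                    # one marker per stage-1 group
  comp_reps <- reps[complete[reps]]
  if (length(comp_reps)) {
    key2 <- paste(markers$info$class[comp_reps], canon[comp_reps], sep = "\r")
    for (grp in split(g1[comp_reps], key2)) {
      if (length(grp) > 1L) {
        r <- find(grp[1])
        for (o in grp[-1]) parent[find(o)] <- r
      }
    }
  }
  root <- vapply(g1, find, integer(1))
  bin_of <- match(root, unique(root))
  n_bins <- max(bin_of)
  members <- split(markers$info$marker_id, bin_of)
  scaffolds <- lapply(split(markers$info$scaffold, bin_of), unique)
  first <- which(!duplicated(bin_of))
  first <- first[order(bin_of[first])]
  bins <- data.frame(bin_id = sprintf("bin%05d", seq_len(n_bins)),
                     class = markers$info$class[first],
                     n_markers = as.integer(lengths(members)),
                     n_scaffolds = as.integer(lengths(scaffolds)))
  seg_rep <- seg[first, , drop = FALSE]
  dimnames(seg_rep) <- list(bins$bin_id, markers$offspring)
  names(members) <- bins$bin_id
  names(scaffolds) <- bins$bin_id
  structure(list(bins = bins, seg = seg_rep, members = members,
                 scaffolds = scaffolds, offspring = markers$offspring),
            class = "linkage_bins")
}

#' @export
print.linkage_bins <- function(x, ...) {
  cat(sprintf("Perfect-linkage bins: %d bins from %d markers on %d scaffolds\n",
              nrow(x$bins), sum(x$bins$n_markers),
              length(unique(unlist(x$scaffolds)))))
  invisible(x)
}

#' Scaffold-to-linkage-group assignment state
#'
#' @param scaffold Character vector of scaffold ids.
#' @param group Linkage-group labels, parallel to `scaffold`.
#' @param provenance How each assignment arose: `"core"` (direct core-map
#'   membership), `"bin_rule"` or `"group_rule"` (propagated).
#' @param ladder LOD ladder step at which a propagated assignment was made
#'   (`NA` for core).
#' @return An object of class `assignment_state` holding the assignment
#'   table and an (initially empty) conflict log.
#' @export
assignment_state <- function(scaffold, group,
                             provenance = rep("core", length(scaffold)),
                             ladder = rep(NA_real_, length(scaffold))) {
  if (anyDuplicated(scaffold)) stop("a scaffold may have only one assignment")
  df <- data.frame(scaffold = as.character(scaffold),
                   group = as.character(group),
                   provenance = provenance, ladder = ladder)
  structure(list(assignments = df,
                 conflicts = data.frame(ladder = numeric(0),
                                        rule = character(0),
                                        unit = character(0),
                                        tally = character(0))),
            class = "assignment_state")
}

#' @export
print.assignment_state <- function(x, ...) {
  tab <- table(x$assignments$provenance)
  cat(sprintf("Assignment state: %d scaffolds (%s); %d conflicts logged\n",
              nrow(x$assignments),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              nrow(x$conflicts)))
  invisible(x)
}

#' Core assignments from a clustered marker set
#'
#' Labels every scaffold holding a marker of a core linkage group with that
#' group, keeping only groups of at least `min_group_size` markers.
#' Scaffolds supported by conflicting groups (possible when several markers
#' per scaffold were clustered) are assigned by majority; exact ties are
#' dropped.
#'
#' @param groups A [cluster_markers()] result over the core marker set.
#' @param markers The [marker_set()] that was clustered.
#' @param min_group_size Smallest group treated as a core linkage group.
#' @return An [assignment_state()] with provenance `"core"`.
#' @export
core_assignments <- function(groups, markers, min_group_size = 2) {
  stopifnot(inherits(groups, "linkage_groups"), inherits(markers, "marker_set"))
  keep <- names(groups$groups)[groups$sizes >= min_group_size]
  sc <- character(0); gr <- character(0)
  for (gname in keep) {
    ids <- groups$groups[[gname]]
    scf <- markers$info$scaffold[match(ids, markers$info$marker_id)]
    sc <- c(sc, scf); gr <- c(gr, rep(gname, length(scf)))
  }
  pick <- vapply(split(gr, sc), function(g) {
    t <- sort(table(g), decreasing = TRUE)
    if (length(t) > 1L && t[1] == t[2]) NA_character_ else names(t)[1]
  }, character(1))
  pick <- pick[!is.na(pick)]
  assignment_state(names(pick), unname(pick))
}

#' Propagation configuration
#'
#' @param bin_ratio Within a perfect-linkage bin, the top core-group tally
#'   must be at least `bin_ratio` times the second tally (a missing second
#'   place counts as zero, so unanimous evidence always passes).
#' @param group_ratio Same rule for sibling linkage-group clusters.
#' @param lod_ladder Strictly decreasing LOD thresholds of the sibling
#'   clusterings, applied in order.
#' @return An object of class `propagation_config`.
#' @export
propagation_config <- function(bin_ratio = 3, group_ratio = 10,
                               lod_ladder = c(6.1, 6.0, 5.5)) {
  stopifnot(bin_ratio > 1, group_ratio > 1)
  if (length(lod_ladder) && any(diff(lod_ladder) >= 0))
    stop("lod_ladder must be strictly decreasing")
  structure(list(bin_ratio = bin_ratio, group_ratio = group_ratio,
                 lod_ladder = lod_ladder),
            class = "propagation_config")
}

# Majority decision under a vote-ratio rule.  labels: assigned group labels
# observed in a unit.  Returns the winning label, or NA (plus a tally string
# for the conflict log) when the evidence is ambiguous.
.vote <- function(labels, ratio) {
  if (!length(labels)) return(list(group = NA_character_, tally = ""))
  t <- sort(table(labels), decreasing = TRUE)
  top <- t[[1]]
  second <- if (length(t) > 1L) t[[2]] else 0L
  tally <- paste(sprintf("%s:%d", names(t), t), collapse = ",")
  if (top >= ratio * second && (length(t) == 1L || t[[1]] > t[[2]]))
    list(group = names(t)[1], tally = tally)
  else list(group = NA_character_, tally = tally)
}

#' Propagate core linkage-group assignments to additional scaffolds
#'
#' Iterative anchoring: for each LOD step of the ladder (in order), the two
#' vote-ratio rules are applied repeatedly until no new scaffold is
#' assigned.  The *bin rule* tallies the core-group labels of scaffolds
#' sharing a perfect-linkage bin; when the top label is at least
#' `bin_ratio` times as common as the runner-up, the bin's unassigned
#' scaffolds adopt it.  The *group rule* does the same over the scaffolds of
#' each sibling linkage-group cluster with `group_ratio`.  Assignments
#' accumulate across steps and are never revoked; core labels are never
#' overwritten.  Ambiguous tallies are appended to the conflict log.
#'
#' @param core An [assignment_state()] with core provenance.
#' @param sibling_clusterings Named list of [cluster_markers()] results over
#'   the bins, one per ladder LOD, named by the LOD value (e.g. `"6.1"`).
#' @param bins The [perfect_linkage_bins()] object the clusterings were
#'   computed from.
#' @param cfg A [propagation_config()].
#' @return An updated [assignment_state()].
#' @export
propagate <- function(core, sibling_clusterings, bins,
                      cfg = propagation_config()) {
  stopifnot(inherits(core, "assignment_state"),
            inherits(bins, "linkage_bins"),
            inherits(cfg, "propagation_config"))
  have <- suppressWarnings(as.numeric(names(sibling_clusterings)))
  slot <- match(cfg$lod_ladder, have)
  if (anyNA(slot))
    stop("sibling_clusterings must contain a clustering for every ladder LOD: ",
         paste(cfg$lod_ladder[is.na(slot)], collapse = ", "))
  sibling_clusterings <- sibling_clusterings[slot]
  names(sibling_clusterings) <- need <- as.character(cfg$lod_ladder)

  asg <- stats::setNames(core$assignments$group, core$assignments$scaffold)
  prov <- stats::setNames(core$assignments$provenance,
                          core$assignments$scaffold)
  step <- stats::setNames(core$assignments$ladder, core$assignments$scaffold)
  conflicts <- core$conflicts

  bin_scaffolds <- bins$scaffolds
  cluster_scaffolds <- lapply(need, function(lod) {
    lapply(sibling_clusterings[[lod]]$groups, function(ids)
      unique(unlist(bins$scaffolds[ids], use.names = FALSE)))
  })
  names(cluster_scaffolds) <- need

  apply_rule <- function(units, ratio, rule, lod) {
    changed <- FALSE
    for (u in seq_along(units)) {
      scs <- units[[u]]
      known <- asg[scs]
      known <- known[!is.na(known)]
      unknown <- setdiff(scs, names(known))
      if (!length(unknown) || !length(known)) next
      v <- .vote(unname(known), ratio)
      if (!is.na(v$group)) {
        asg[unknown] <<- v$group
        prov[unknown] <<- rule
        step[unknown] <<- as.numeric(lod)
        changed <- TRUE
      } else {
        conflicts <<- rbind(conflicts, data.frame(
          ladder = as.numeric(lod), rule = rule,
          unit = names(units)[u] %||% as.character(u), tally = v$tally))
      }
    }
    changed
  }

  for (lod in need) {
    repeat {
      ch1 <- apply_rule(bin_scaffolds, cfg$bin_ratio, "bin_rule", lod)
      ch2 <- apply_rule(cluster_scaffolds[[lod]], cfg$group_ratio,
                        "group_rule", lod)
      if (!ch1 && !ch2) break
    }
  }
  conflicts <- unique(conflicts)
  rownames(conflicts) <- NULL
  out <- assignment_state(names(asg), unname(asg), unname(prov), unname(step))
  out$conflicts <- conflicts
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarise scaffold assignments
#'
#' Per-group scaffold counts and summed scaffold lengths, with a provenance
#' breakdown and totals.
#'
#' @param state An [assignment_state()].
#' @param scaffold_lengths Named numeric vector of scaffold lengths in bp,
#'   or a data frame with columns `scaffold` and `length`.
#' @return A data frame (`group`, `n_scaffolds`, `total_bp`) with attributes
#'   `totals` (overall count and bp) and `provenance` (count by provenance).
#' @export
summarize_assignments <- function(state, scaffold_lengths) {
  stopifnot(inherits(state, "assignment_state"))
  if (is.data.frame(scaffold_lengths))
    scaffold_lengths <- stats::setNames(scaffold_lengths$length,
                                        scaffold_lengths$scaffold)
  a <- state$assignments
  if (!nrow(a)) {
    out <- data.frame(group = character(0), n_scaffolds = integer(0),
                      total_bp = numeric(0))
    attr(out, "totals") <- c(n_scaffolds = 0, total_bp = 0)
    attr(out, "provenance") <- table(character(0))
    return(out)
  }
  lens <- scaffold_lengths[a$scaffold]
  if (anyNA(lens)) stop("missing scaffold lengths for some assigned scaffolds")
  out <- do.call(rbind, lapply(split(seq_len(nrow(a)), a$group), function(i)
    data.frame(group = a$group[i[1]], n_scaffolds = length(i),
               total_bp = sum(lens[i]))))
  out <- out[order(out$group), ]
  rownames(out) <- NULL
  attr(out, "totals") <- c(n_scaffolds = nrow(a), total_bp = sum(lens))
  attr(out, "provenance") <- table(a$provenance)
  out
}
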