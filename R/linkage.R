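# Common accessor: objects clusterable by two-point linkage expose an id
# vector, a 0/1/NA segregation matrix, and a parental class per row.
.marker_matrix <- function(x) {
  if (inherits(x, "marker_set"))
    return(list(ids = x$info$marker_id, seg = x$seg, class = x$info$class))
  if (inherits(x, "linkage_bins"))
    return(list(ids = x$bins$bin_id, seg = x$seg, class = x$bins$class))
  stop("expected a marker_set or linkage_bins object")
}

.two_point_vec <- function(v1, v2) {
  ok <- !is.na(v1) & !is.na(v2)
  n <- sum(ok)
  if (n == 0L)
    return(list(rf = 0.5, phase = "coupling", lod = 0, n_informative = 0L))
  k <- sum(v1[ok] != v2[ok])
  phase <- if (k <= n - k) "coupling" else "repulsion"
  kk <- min(k, n - k)
  rf <- kk / n
  term <- function(a, r) if (a == 0L) 0 else a * log10(r)
  lod <- term(kk, rf) + term(n - kk, 1 - rf) + n * log10(2)
  list(rf = rf, phase = phase, lod = lod, n_informative = as.integer(n))
}

#' Two-point linkage estimate for a marker pair
#'
#' Estimates the recombination fraction, phase and LOD score for two
#' testcross markers from their binary segregation vectors.  Over the `n`
#' offspring non-missing at both markers, `k` counts phase-discordant pairs
#' under coupling; the phase minimising the recombinant count `k*` is
#' chosen, `rf = k*/n`, and
#' `LOD = k* log10(rf) + (n - k*) log10(1 - rf) + n log10(2)`
#' (with `0 log 0 = 0`), the base-10 log likelihood ratio against free
#' recombination.  Markers of different parental classes are mutually
#' uninformative and return `rf = 0.5`, `lod = 0`, `n_informative = 0`.
#'
#' @param markers A [marker_set()] (or [perfect_linkage_bins()] output).
#' @param i,j Marker indices or ids; `i == j` is an error.
#' @return A list with elements `rf`, `phase` (`"coupling"` or
#'   `"repulsion"`), `lod`, and `n_informative`.
#' @export
two_point <- function(markers, i, j) {
  mm <- .marker_matrix(markers)
  if (is.character(i)) i <- match(i, mm$ids)
  if (is.character(j)) j <- match(j, mm$ids)
  if (is.na(i) || is.na(j)) stop("unknown marker id")
  if (i == j) stop("two_point requires two distinct markers")
  if (mm$class[i] != mm$class[j])
    return(list(rf = 0.5, phase = "coupling", lod = 0, n_informative = 0L))
  .two_point_vec(mm$seg[i, ], mm$seg[j, ])
}

#' Kosambi map distance
#'
#' Converts a recombination fraction to centimorgans with the Kosambi
#' mapping function `d = 25 ln((1 + 2r) / (1 - 2r))`, which allows partial
#' crossover interference.  Strictly increasing on `[0, 0.5)` and divergent
#' as `r` approaches 0.5.
#'
#' @param rf Recombination fraction(s) in `[0, 0.5)`.
#' @return Map distance(s) in cM.
#' @export
kosambi_cm <- function(rf) {
  if (any(is.na(rf)) || any(rf < 0) || any(rf >= 0.5))
    stop("rf must lie in [0, 0.5)")
  100 * 0.25 * log((1 + 2 * rf) / (1 - 2 * rf))
}

# All-pairs two-point scan.  Returns edges (upper triangle, original row
# indices) for pairs with lod >= threshold.  Pairs of different parental
# class, or with fewer than min_informative shared non-missing offspring,
# carry lod 0.  Two exact strategies: a blocked dense scan, and -- when the
# cohort is so small that even a single recombinant caps the score below
# the threshold (LOD at k = 1 is increasing in n, so the bound is tight at
# n_off) -- a hash join that finds exactly the zero-recombinant pairs with
# enough shared calls.
.linkage_edges <- function(seg, class, lod_threshold, min_informative,
                           block = 2000L) {
  n_off <- ncol(seg)
  n_min <- max(ceiling(lod_threshold / log10(2)), min_informative)
  lod_k1 <- if (n_off >= 2)
    n_off * log10(2) - log10(n_off) + (n_off - 1) * log10(1 - 1 / n_off)
  else -Inf
  # rows with too few calls can never reach the threshold with any partner
  active <- which(n_off - rowSums(is.na(seg)) >= n_min)
  if (length(active) < 2L) return(NULL)
  if (lod_k1 < lod_threshold && n_off - n_min <= 2L)
    .edges_rf0(seg, class, active, n_min)
  else
    .edges_dense(seg, class, active, lod_threshold, min_informative, block)
}

.edges_dense <- function(seg, class, active, lod_threshold, min_informative,
                         block = 2000L) {
  seg <- seg[active, , drop = FALSE]
  class <- class[active]
  M <- nrow(seg)
  A <- seg; A[is.na(A)] <- 0L                       # het indicator
  B <- 1L - seg; B[is.na(B)] <- 0L                  # hom indicator
  V <- !is.na(seg); storage.mode(V) <- "double"
  storage.mode(A) <- "double"; storage.mode(B) <- "double"
  tA <- t(A); tB <- t(B); tV <- t(V)
  edges <- vector("list", ceiling(M / block))
  bi <- 0L
  for (s in seq(1L, M, by = block)) {
    e <- min(s + block - 1L, M)
    rows <- s:e
    N <- V[rows, , drop = FALSE] %*% tV
    D <- A[rows, , drop = FALSE] %*% tB + B[rows, , drop = FALSE] %*% tA
    K <- pmin(D, N - D)
    rf <- ifelse(N > 0, K / N, 0.5)
    lod <- ifelse(K > 0, K * log10(rf), 0) +
      ifelse(N - K > 0, (N - K) * log10(1 - rf), 0) + N * log10(2)
    lod[N < min_informative] <- 0
    lod[outer(class[rows], class, "!=")] <- 0
    hit <- which(lod >= lod_threshold, arr.ind = TRUE)
    hit[, 1L] <- rows[hit[, 1L]]
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    bi <- bi + 1L
    edges[[bi]] <- hit
  }
  out <- do.call(rbind, edges[seq_len(bi)])
  if (!is.null(out) && nrow(out)) {
    out[, 1L] <- active[out[, 1L]]
    out[, 2L] <- active[out[, 2L]]
  }
  out
}

# Exact zero-recombinant join: an edge exists iff two vectors are identical
# or complementary on their shared calls and share at least n_min of them,
# i.e. the union of their missing sets has at most c_max = n_off - n_min
# elements.  Every row emits one key per missing-superset S (|S| <= c_max):
# the phase-canonicalised pattern outside S.  Rows pairing with rf = 0 share
# the key at S = union of their missing sets; candidate pairs within a key
# are verified exactly.
.edges_rf0 <- function(seg, class, active, n_min) {
  n_off <- ncol(seg)
  c_max <- n_off - n_min
  keys <- vector("list", length(active))
  for (t in seq_along(active)) {
    i <- active[t]
    v <- seg[i, ]
    m <- which(is.na(v))
    budget <- c_max - length(m)
    extra <- setdiff(seq_len(n_off), m)
    Ss <- list(m)
    if (budget >= 1L)
      Ss <- c(Ss, lapply(extra, function(e) sort(c(m, e))))
    if (budget >= 2L && length(extra) >= 2L) {
      cmb <- utils::combn(extra, 2L)
      Ss <- c(Ss, lapply(seq_len(ncol(cmb)), function(ci)
        sort(c(m, cmb[, ci]))))
    }
    keys[[t]] <- vapply(Ss, function(S) {
      kept <- if (length(S)) v[-S] else v
      if (kept[1L] == 0L) kept <- 1L - kept
      paste(class[i], paste(S, collapse = ","),
            paste(kept, collapse = ""), sep = "|")
    }, character(1))
  }
  owner <- rep(active, lengths(keys))
  grp <- split(owner, unlist(keys))
  grp <- grp[lengths(grp) >= 2L]
  parent <- seq_len(nrow(seg))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  seen_bad <- new.env(hash = TRUE, parent = emptyenv())
  edges <- list()
  for (g in grp) {
    g <- sort(unique(g))
    for (ai in seq_len(length(g) - 1L)) {
      for (bi in (ai + 1L):length(g)) {
        a <- g[ai]; b <- g[bi]
        if (find(a) == find(b)) next
        pk <- paste0(a, "_", b)
        if (!is.null(seen_bad[[pk]])) next
        est <- .two_point_vec(seg[a, ], seg[b, ])
        if (est$rf == 0 && est$n_informative >= n_min) {
          parent[find(b)] <- find(a)
          edges[[length(edges) + 1L]] <- c(a, b)
        } else {
          seen_bad[[pk]] <- TRUE
        }
      }
    }
  }
  if (!length(edges)) return(NULL)
  do.call(rbind, edges)
}

#' Cluster markers into linkage groups
#'
#' Groups markers by single-linkage transitive closure: two markers fall in
#' the same group when a chain of pairs, each with two-point LOD at or above
#' `lod_threshold`, connects them.  Pairs sharing fewer than
#' `min_informative` scored offspring have their LOD forced to 0 so sparse
#' overlaps cannot chain groups; markers of different parental class never
#' link directly.
#'
#' @param markers A [marker_set()] or [perfect_linkage_bins()] output.
#' @param lod_threshold LOD threshold for declaring linkage (the core map in
#'   the motivating design used 8.4; sibling sets 6.1, 6.0 and 5.5).
#' @param min_informative Minimum shared informative offspring per pair.
#' @param block Row-block size of the pairwise scan (memory control).
#' @return An object of class `linkage_groups`: a list with `groups` (list
#'   of member id vectors, largest first), `sizes`, and `threshold`.
#' @export
cluster_markers <- function(markers, lod_threshold, min_informative = 10,
                            block = 2000L) {
  mm <- .marker_matrix(markers)
  if (!length(mm$ids)) stop("no markers to cluster")
  ed <- .linkage_edges(mm$seg, mm$class, lod_threshold, min_informative,
                       block)
  g <- igraph::make_empty_graph(n = length(mm$ids), directed = FALSE)
  if (!is.null(ed) && nrow(ed))
    g <- igraph::add_edges(g, t(ed))
  comp <- igraph::components(g)
  groups <- split(mm$ids, comp$membership)
  groups <- groups[order(-lengths(groups))]
  names(groups) <- sprintf("LG%02d", seq_along(groups))
  structure(list(groups = groups, sizes = lengths(groups),
                 threshold = lod_threshold),
            class = "linkage_groups")
}

#' @export
print.linkage_groups <- function(x, ...) {
  multi <- sum(x$sizes >= 2)
  cat(sprintf("Linkage groups at LOD %.1f: %d groups (%d with >= 2 members)\n",
              x$threshold, length(x$groups), multi))
  show <- utils::head(x$sizes, 15)
  cat("  sizes:", paste(show, collapse = " "),
      if (length(x$sizes) > 15) "...\n" else "\n")
  invisible(x)
}

# rf matrix among a subset of markers (small groups only).
.rf_matrix <- function(seg) {
  k <- nrow(seg)
  rf <- matrix(0.5, k, k); diag(rf) <- 0
  nn <- matrix(0L, k, k)
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    est <- .two_point_vec(seg[a, ], seg[b, ])
    rf[a, b] <- rf[b, a] <- est$rf
    nn[a, b] <- nn[b, a] <- est$n_informative
  }
  list(rf = rf, n = nn)
}

#' Order markers within a linkage group
#'
#' Produces a locally optimal marker order by nearest-neighbour chaining
#' (seeded from the pair with the smallest recombination fraction, extending
#' whichever path end has the closest unplaced marker) followed by 2-opt
#' segment reversals until no swap reduces the sum of adjacent recombination
#' fractions.  Positions are cumulative Kosambi cM over adjacent intervals;
#' the orientation is canonicalised so the first marker id sorts before the
#' last.  Adjacent pairs with no shared scored offspring take `rf = 0.5` and
#' are flagged (their interval distance is computed at rf clamped just below
#' 0.5).
#'
#' @param markers A [marker_set()] (or bins).
#' @param group Character vector of member ids (length >= 2), e.g. one
#'   element of [cluster_markers()]`$groups`.
#' @return A data frame with columns `marker_id`, `scaffold`, `order`,
#'   `adj_rf` (rf to the previous marker; `NA` for the first), `cM`
#'   (cumulative Kosambi position), and `flagged` (no-overlap intervals).
#' @export
order_markers <- function(markers, group) {
  mm <- .marker_matrix(markers)
  idx <- match(group, mm$ids)
  if (anyNA(idx)) stop("unknown marker id in group")
  k <- length(idx)
  if (k < 2) stop("group must contain at least 2 markers")
  sub <- mm$seg[idx, , drop = FALSE]
  rfm <- .rf_matrix(sub)
  rf <- rfm$rf
  flagged_pair <- rfm$n == 0L

  # nearest-neighbour chain from the tightest pair
  d <- rf; diag(d) <- Inf
  start <- which(d == min(d), arr.ind = TRUE)[1, ]
  path <- c(start[1], start[2])
  left <- setdiff(seq_len(k), path)
  while (length(left)) {
    dl <- d[path[1], left]; dr <- d[path[length(path)], left]
    if (min(dl) <= min(dr)) {
      nxt <- left[which.min(dl)]; path <- c(nxt, path)
    } else {
      nxt <- left[which.min(dr)]; path <- c(path, nxt)
    }
    left <- setdiff(left, nxt)
  }

  # 2-opt until no improving reversal
  path_cost <- function(p) sum(rf[cbind(p[-length(p)], p[-1])])
  improved <- TRUE
  while (improved && k > 3) {
    improved <- FALSE
    for (a in 1:(k - 1)) {
      for (b in (a + 1):k) {
        cand <- path
        cand[a:b] <- rev(cand[a:b])
        if (path_cost(cand) < path_cost(path) - 1e-12) {
          path <- cand
          improved <- TRUE
        }
      }
    }
  }

  ids <- mm$ids[idx][path]
  if (ids[1] > ids[length(ids)]) {
    path <- rev(path); ids <- rev(ids)
  }
  adj <- rf[cbind(path[-k], path[-1])]
  flg <- flagged_pair[cbind(path[-k], path[-1])]
  adj_clamped <- pmin(adj, 0.5 - 1e-6)
  scf <- if (inherits(markers, "marker_set"))
    markers$info$scaffold[match(ids, markers$info$marker_id)]
  else NA_character_
  data.frame(marker_id = ids, scaffold = scf, order = seq_len(k),
             adj_rf = c(NA, adj), cM = c(0, cumsum(kosambi_cm(adj_clamped))),
             flagged = c(FALSE, flg))
}

#' Pairwise two-point table
#'
#' All-pairs two-point estimates as a data frame -- intended for small
#' marker sets (every pair is visited).
#'
#' @param markers A [marker_set()] or bins.
#' @return Data frame with columns `m1`, `m2`, `rf`, `phase`, `lod`, `n`.
#' @export
pairwise_linkage <- function(markers) {
  mm <- .marker_matrix(markers)
  M <- length(mm$ids)
  if (M < 2) return(data.frame(m1 = character(0), m2 = character(0),
                               rf = numeric(0), phase = character(0),
                               lod = numeric(0), n = integer(0)))
  pairs <- utils::combn(M, 2)
  rows <- apply(pairs, 2L, function(p) {
    est <- if (mm$class[p[1]] != mm$class[p[2]])
      list(rf = 0.5, phase = "coupling", lod = 0, n_informative = 0L)
    else .two_point_vec(mm$seg[p[1], ], mm$seg[p[2], ])
    data.frame(m1 = mm$ids[p[1]], m2 = mm$ids[p[2]], rf = est$rf,
               phase = est$phase, lod = est$lod, n = est$n_informative)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
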