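# Double-cut-and-join (DCJ) distances on signed gene orders.
#
# A genome is a set of linear/circular chromosomes over signed markers.
# Marker m has two extremities, tail t(m) and head h(m); a marker written
# +m is traversed t->h, -m is traversed h->t.  Consecutive markers define
# an adjacency between the facing extremities; ends of linear chromosomes
# are telomeres.  The DCJ distance between genomes with the same marker
# content is d = N - (C + I/2), where C and I are the numbers of cycles
# and odd-length paths of the adjacency graph.

#' Construct a signed gene order
#'
#' @param chromosomes List of signed integer vectors, one per chromosome;
#'   the sign encodes strand.
#' @param shapes Character vector, `"linear"` or `"circular"` per
#'   chromosome (recycled).
#' @return Object of class `gene_order`.
#' @export
gene_order <- function(chromosomes, shapes = "linear") {
  if (is.numeric(chromosomes)) chromosomes <- list(chromosomes)
  chromosomes <- lapply(chromosomes, as.integer)
  shapes <- rep_len(shapes, length(chromosomes))
  if (!all(shapes %in% c("linear", "circular")))
    stop("shapes must be 'linear' or 'circular'")
  all_m <- abs(unlist(chromosomes))
  if (any(all_m == 0)) stop("marker id 0 is not allowed")
  structure(list(chromosomes = chromosomes, shapes = shapes,
                 markers = sort(unique(all_m))),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat("<gene_order> ", length(x$chromosomes), " chromosomes, ",
      length(unlist(x$chromosomes)), " markers\n", sep = "")
  invisible(x)
}

#' Build a gene order from a genome annotation and a marker map
#'
#' Genes are ordered by start coordinate within each sequence; the sign is
#' taken from the strand.
#'
#' @param ann A [genome_annotation()].
#' @param marker_of Named integer vector mapping gene ids to (positive)
#'   marker ids; genes absent from the map are skipped.
#' @return A [gene_order()] with one linear chromosome per sequence that
#'   carries at least one mapped gene.
#' @export
gene_order_from_annotation <- function(ann, marker_of) {
  chroms <- list()
  for (s in names(ann$sequences)) {
    gs <- Filter(function(g) g$seq_name == s && g$gene_id %in% names(marker_of),
                 ann$genes)
    if (!length(gs)) next
    starts <- vapply(gs, function(g) min(g$exons[, 1]), numeric(1))
    gs <- gs[order(starts)]
    chroms[[s]] <- vapply(gs, function(g) {
      m <- marker_of[[g$gene_id]]
      if (g$strand == "+") m else -m
    }, integer(1))
  }
  gene_order(unname(chroms))
}

# extremity encoding over markers remapped to 1..N: tail = 2m-1, head = 2m
.extremity_enter <- function(m) ifelse(m > 0, 2L * m - 1L, -2L * m)
.extremity_exit <- function(m) ifelse(m > 0, 2L * m, -2L * m - 1L)

# Adjacency/telomere structure of a genome over markers remapped 1..N.
# Returns partner[e] = partner extremity, or 0 for telomere.
.partner_map <- function(chromosomes, shapes, n_markers) {
  partner <- integer(2L * n_markers)
  for (k in seq_along(chromosomes)) {
    ch <- chromosomes[[k]]
    if (!length(ch)) next
    if (shapes[k] == "circular" || length(ch) > 1L) {
      pairs <- if (shapes[k] == "circular")
        cbind(ch, c(ch[-1L], ch[1L]))
      else cbind(ch[-length(ch)], ch[-1L])
      if (shapes[k] == "linear" && length(ch) == 1L) pairs <- pairs[0, , drop = FALSE]
      for (i in seq_len(nrow(pairs))) {
        a <- .extremity_exit(pairs[i, 1L])
        b <- .extremity_enter(pairs[i, 2L])
        partner[a] <- b
        partner[b] <- a
      }
    }
  }
  partner
}

.restrict_to <- function(go, keep_abs, remap) {
  lapply(go$chromosomes, function(ch) {
    ch <- ch[abs(ch) %in% keep_abs]
    sign(ch) * remap[as.character(abs(ch))]
  })
}

#' DCJ distance between two genomes
#'
#' Both genomes are restricted internally to their shared single-copy
#' marker set; markers found in only one genome are dropped and counted.
#' Markers occurring more than once in either genome are an error (use the
#' aliquoting operations for duplicated genomes).
#'
#' @param A,B [gene_order()] objects.
#' @return Object of class `dcj_result` with elements `d` (distance), `N`
#'   (shared markers), `C` (cycles), `I` (odd paths), `per_marker_rate`
#'   (`d/N`), `dropped_A`, `dropped_B`.
#' @export
dcj_distance <- function(A, B) {
  mA <- abs(unlist(A$chromosomes)); mB <- abs(unlist(B$chromosomes))
  if (anyDuplicated(mA) || anyDuplicated(mB))
    stop("duplicated markers present; DCJ distance requires single-copy ",
         "markers (see aliquot_distance for duplicated genomes)")
  shared <- intersect(mA, mB)
  N <- length(shared)
  res <- list(d = 0L, N = N, C = 0L, I = 0L,
              per_marker_rate = NA_real_,
              dropped_A = length(mA) - N, dropped_B = length(mB) - N)
  if (N == 0L) {
    class(res) <- "dcj_result"
    return(res)
  }
  remap <- stats::setNames(seq_len(N), as.character(shared))
  pa <- .partner_map(.restrict_to(A, shared, remap), A$shapes, N)
  pb <- .partner_map(.restrict_to(B, shared, remap), B$shapes, N)

  visited <- logical(2L * N)
  C <- 0L; I <- 0L
  for (e0 in seq_len(2L * N)) {
    if (visited[e0]) next
    comp <- .dcj_component(e0, pa, pb)
    visited[comp$members] <- TRUE
    if (comp$is_cycle) C <- C + 1L
    else if (comp$n_edges %% 2L == 1L) I <- I + 1L
  }
  d <- N - C - I %/% 2L
  res <- list(d = as.integer(d), N = N, C = C, I = I,
              per_marker_rate = d / N,
              dropped_A = length(mA) - N, dropped_B = length(mB) - N)
  class(res) <- "dcj_result"
  res
}

# Expand the adjacency-graph component containing extremity e0.
# Members are extremities; edges are adjacencies of A and B.
.dcj_component <- function(e0, pa, pb) {
  members <- e0
  frontier <- e0
  while (length(frontier)) {
    nbrs <- unique(c(pa[frontier], pb[frontier]))
    nbrs <- setdiff(nbrs[nbrs != 0L], members)
    members <- c(members, nbrs)
    frontier <- nbrs
  }
  # vertices of the adjacency graph are adjacencies/telomeres of A and B;
  # each shared extremity contributes exactly one edge, so the edge count
  # of a component equals the number of extremities it contains
  n_edges <- length(members)
  list(members = members, n_edges = n_edges,
       is_cycle = all(pa[members] != 0L) && all(pb[members] != 0L))
}

#' @export
print.dcj_result <- function(x, ...) {
  cat("<dcj_result> d = ", x$d, " over N = ", x$N,
      " shared markers (C = ", x$C, ", I = ", x$I, "); d/N = ",
      round(x$per_marker_rate, 4), "\n", sep = "")
  invisible(x)
}

#' Per-marker DCJ rearrangement rate
#'
#' @param d DCJ distance (operations).
#' @param n_markers Number of shared markers the distance was computed over.
#' @return `d / n_markers`.
#' @export
per_marker_rate <- function(d, n_markers) {
  if (n_markers <= 0) stop("n_markers must be positive")
  d / n_markers
}

#' Relative and per-time DCJ rearrangement rates
#'
#' The relative rate normalizes the per-marker DCJ rate by the protein
#' sequence divergence of the same species pair, making rearrangement
#' rates comparable across pairs with different divergence.  The per-time
#' rate divides by the divergence time instead.
#'
#' @param dcj A `dcj_result` from [dcj_distance()], or a per-marker rate.
#' @param protein_distance Protein divergence (substitutions per site) of
#'   the pair; must be positive.
#' @param divergence_time_myr Optional divergence time in Myr; when given,
#'   the per-time rate (per Myr) is also returned.
#' @return List with `rho` (per-marker DCJ rate), `relative` and, when a
#'   time is supplied, `per_time_myr`.
#' @export
relative_rates <- function(dcj, protein_distance,
                           divergence_time_myr = NULL) {
  rho <- if (inherits(dcj, "dcj_result")) dcj$per_marker_rate else as.numeric(dcj)
  if (!is.finite(protein_distance) || protein_distance <= 0)
    stop("protein_distance must be positive")
  out <- list(rho = rho, relative = rho / protein_distance)
  if (!is.null(divergence_time_myr)) {
    if (divergence_time_myr <= 0) stop("divergence_time_myr must be positive")
    out$per_time_myr <- rho / divergence_time_myr
  }
  out
}

# ---------------------------------------------------------------------------
# Adjacency-set representation (used by the BFS reference implementation,
# random DCJ operations and aliquoting)
# ---------------------------------------------------------------------------

# A genome over extremities 1..2N as a set: list(adj = 2-col matrix of
# adjacencies (unordered, stored sorted), tel = vector of telomeric
# extremities).  Every extremity appears exactly once.
.to_adjset <- function(go, n_markers = length(go$markers)) {
  remap <- stats::setNames(seq_len(n_markers), as.character(go$markers))
  chroms <- .restrict_to(go, go$markers, remap)
  p <- .partner_map(chroms, go$shapes, n_markers)
  ext <- seq_len(2L * n_markers)
  tel <- ext[p == 0L]
  adj <- unique(t(apply(cbind(ext[p != 0L], p[p != 0L]), 1L, sort)))
  if (!length(adj)) adj <- matrix(integer(0), ncol = 2L)
  list(adj = adj, tel = sort(tel), n = n_markers,
       marker_ids = go$markers)
}

.adjset_key <- function(as_) {
  a <- as_$adj[order(as_$adj[, 1L]), , drop = FALSE]
  paste(c(t(a), 0L, as_$tel), collapse = ",")
}

# Reassemble chromosomes from an adjacency set.
.from_adjset <- function(as_) {
  n <- as_$n
  partner <- integer(2L * n)
  if (nrow(as_$adj))
    for (i in seq_len(nrow(as_$adj))) {
      partner[as_$adj[i, 1L]] <- as_$adj[i, 2L]
      partner[as_$adj[i, 2L]] <- as_$adj[i, 1L]
    }
  other_end <- function(e) if (e %% 2L == 1L) e + 1L else e - 1L
  marker_of <- function(e) (e + 1L) %/% 2L
  seen <- logical(2L * n)
  chroms <- list(); shapes <- character(0)
  # linear chromosomes: start from telomeres
  for (t0 in as_$tel) {
    if (seen[t0]) next
    ch <- integer(0)
    e <- t0
    repeat {
      seen[e] <- TRUE
      m <- marker_of(e)
      ch <- c(ch, if (e %% 2L == 1L) m else -m)  # entered at tail => +m
      e2 <- other_end(e)
      seen[e2] <- TRUE
      nxt <- partner[e2]
      if (nxt == 0L) break
      e <- nxt
    }
    chroms[[length(chroms) + 1L]] <- as_$marker_ids[abs(ch)] * sign(ch)
    shapes <- c(shapes, "linear")
  }
  # remaining markers form circular chromosomes
  for (e0 in seq_len(2L * n)) {
    if (seen[e0]) next
    ch <- integer(0)
    e <- e0
    repeat {
      seen[e] <- TRUE
      m <- marker_of(e)
      ch <- c(ch, if (e %% 2L == 1L) m else -m)
      e2 <- other_end(e)
      seen[e2] <- TRUE
      e <- partner[e2]
      if (e == e0) break
    }
    chroms[[length(chroms) + 1L]] <- as_$marker_ids[abs(ch)] * sign(ch)
    shapes <- c(shapes, "circular")
  }
  gene_order(chroms, shapes)
}

# All genomes reachable from adjacency set by one DCJ operation.
.dcj_neighbours <- function(as_) {
  out <- list()
  add <- function(adj, tel) {
    if (!is.matrix(adj)) adj <- matrix(adj, ncol = 2L)
    if (nrow(adj)) adj <- t(apply(adj, 1L, sort))
    out[[length(out) + 1L]] <<- list(adj = adj, tel = sort(tel),
                                     n = as_$n, marker_ids = as_$marker_ids)
  }
  adj <- as_$adj; tel <- as_$tel
  na <- nrow(adj)
  # two adjacencies -> two rejoinings
  if (na >= 2L) for (i in seq_len(na - 1L)) for (j in seq(i + 1L, na)) {
    p <- adj[i, 1L]; q <- adj[i, 2L]; r <- adj[j, 1L]; s <- adj[j, 2L]
    rest <- adj[-c(i, j), , drop = FALSE]
    add(rbind(rest, c(p, r), c(q, s)), tel)
    add(rbind(rest, c(p, s), c(q, r)), tel)
  }
  # adjacency + telomere
  if (na >= 1L) for (i in seq_len(na)) for (r in tel) {
    p <- adj[i, 1L]; q <- adj[i, 2L]
    rest <- adj[-i, , drop = FALSE]
    add(rbind(rest, c(p, r)), sort(c(setdiff(tel, r), q)))
    add(rbind(rest, c(q, r)), sort(c(setdiff(tel, r), p)))
  }
  # two telomeres -> adjacency
  if (length(tel) >= 2L) {
    cmb <- utils::combn(tel, 2L)
    for (k in seq_len(ncol(cmb)))
      add(rbind(adj, cmb[, k]), setdiff(tel, cmb[, k]))
  }
  # adjacency -> two telomeres
  if (na >= 1L) for (i in seq_len(na))
    add(adj[-i, , drop = FALSE], sort(c(tel, adj[i, ])))
  out
}

#' DCJ distance by exhaustive breadth-first search
#'
#' Reference implementation: explores the full space of genomes reachable
#' by DCJ operations (including circular intermediates) and returns the
#' shortest path length from `A` to `B`.  Exponential in marker count;
#' intended for validating [dcj_distance()] on small instances.
#'
#' @param A,B [gene_order()] objects over the same marker set.
#' @param max_depth Search cut-off; an error is raised when exceeded.
#' @return Integer distance.
#' @export
dcj_distance_bfs <- function(A, B, max_depth = 20L) {
  if (!identical(A$markers, B$markers))
    stop("BFS reference requires identical marker sets")
  if (length(A$markers) > 7L)
    stop("BFS reference is limited to 7 markers")
  start <- .to_adjset(A)
  goal_key <- .adjset_key(.to_adjset(B))
  if (.adjset_key(start) == goal_key) return(0L)
  frontier <- list(start)
  seen <- new.env(hash = TRUE)
  assign(.adjset_key(start), TRUE, envir = seen)
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (st in frontier) for (nb in .dcj_neighbours(st)) {
      k <- .adjset_key(nb)
      if (k == goal_key) return(depth)
      if (!exists(k, envir = seen, inherits = FALSE)) {
        assign(k, TRUE, envir = seen)
        nxt[[length(nxt) + 1L]] <- nb
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  stop("BFS exceeded max_depth = ", max_depth)
}

#' Apply random DCJ operations to a gene order
#'
#' Each operation cuts two random distinct adjacency-or-telomere positions
#' and rejoins the loose ends in a random non-identity way; this is the
#' uniform DCJ move set used by the simulator and by recovery tests.
#'
#' @param go A [gene_order()].
#' @param k Number of operations.
#' @return The rearranged [gene_order()].
#' @export
apply_random_dcj <- function(go, k) {
  if (anyDuplicated(abs(unlist(go$chromosomes))))
    stop("apply_random_dcj requires single-copy markers")
  as_ <- .to_adjset(go)
  for (i in seq_len(k)) {
    adj <- as_$adj; tel <- as_$tel
    # positions: each adjacency row, each telomere
    npos <- nrow(adj) + length(tel)
    if (npos < 2L) stop("genome too small for a DCJ operation")
    pick <- sample.int(npos, 2L)
    is_adj <- pick <= nrow(adj)
    if (all(is_adj)) {
      i1 <- pick[1L]; i2 <- pick[2L]
      p <- adj[i1, 1L]; q <- adj[i1, 2L]; r <- adj[i2, 1L]; s <- adj[i2, 2L]
      rest <- adj[-c(i1, i2), , drop = FALSE]
      new_pairs <- if (stats::runif(1) < 0.5)
        rbind(c(p, r), c(q, s)) else rbind(c(p, s), c(q, r))
      adj <- rbind(rest, new_pairs)
    } else if (any(is_adj)) {
      ia <- pick[is_adj]; it <- tel[pick[!is_adj] - nrow(adj)]
      p <- adj[ia, 1L]; q <- adj[ia, 2L]
      rest <- adj[-ia, , drop = FALSE]
      if (stats::runif(1) < 0.5) {
        adj <- rbind(rest, c(p, it)); tel <- c(setdiff(tel, it), q)
      } else {
        adj <- rbind(rest, c(q, it)); tel <- c(setdiff(tel, it), p)
      }
    } else {
      ts <- tel[pick - nrow(adj)]
      adj <- rbind(adj, ts)
      tel <- setdiff(tel, ts)
    }
    if (nrow(adj)) adj <- t(apply(adj, 1L, sort))
    as_ <- list(adj = adj, tel = sort(tel), n = as_$n,
                marker_ids = as_$marker_ids)
  }
  .from_adjset(as_)
}
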