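# Genome aliquoting: given a genome whose markers all occur in m copies
# (for example after whole-genome duplication), estimate the DCJ distance
# to a perfectly m-plicated ancestor and reconstruct that ancestor's order.

#' Aliquoting input checks
#' @noRd
.aliquot_check <- function(go, m) {
  occ <- table(abs(unlist(go$chromosomes)))
  if (length(unique(occ)) != 1L || unique(occ) != m)
    stop("aliquoting requires every marker to occur exactly m = ", m,
         " times; found multiplicities ",
         paste(sort(unique(occ)), collapse = ", "))
  invisible(TRUE)
}

# Relabel the i-th occurrence of each marker according to assignment bits:
# copy 'a' keeps the marker id, copy 'b' gets id + offset.
.relabel_copies <- function(go, assign_b_first, offset) {
  seen <- new.env(hash = TRUE)
  chroms <- lapply(go$chromosomes, function(ch) {
    vapply(ch, function(s) {
      m <- abs(s)
      k <- as.character(m)
      cnt <- (get0(k, envir = seen, ifnotfound = 0L)) + 1L
      assign(k, cnt, envir = seen)
      first_is_b <- isTRUE(assign_b_first[[k]])
      is_b <- (cnt == 1L) == first_is_b
      sign(s) * (m + if (is_b) offset else 0L)
    }, numeric(1))
  })
  gene_order(chroms, go$shapes)
}

.doubled_genome <- function(ancestor, offset) {
  gene_order(c(ancestor$chromosomes,
               lapply(ancestor$chromosomes, function(ch)
                 sign(ch) * (abs(ch) + offset))),
             rep(ancestor$shapes, 2L))
}

# all perfect partial matchings (with telomeres) over extremities 1..2n,
# i.e. all genomes over n markers
.all_matchings <- function(ext) {
  if (!length(ext)) return(list(matrix(integer(0), ncol = 2L)))
  e <- ext[1L]
  rest <- ext[-1L]
  out <- list()
  for (sub in .all_matchings(rest))           # e is a telomere
    out[[length(out) + 1L]] <- sub
  for (i in seq_along(rest)) {                # e paired with rest[i]
    for (sub in .all_matchings(rest[-i]))
      out[[length(out) + 1L]] <- rbind(c(e, rest[i]), sub)
  }
  out
}

#' Parity lower bound for the aliquoting distance
#'
#' In a perfectly duplicated genome every marker-class adjacency occurs an
#' even number of times; one DCJ operation toggles the parity of at most
#' four class adjacencies, so d >= (number of odd-parity classes)/4.
#'
#' @param go A [gene_order()] with every marker in 2 copies.
#' @return Integer lower bound.
#' @export
aliquot_lower_bound <- function(go) {
  .aliquot_check(go, 2L)
  counts <- new.env(hash = TRUE)
  bump <- function(key) assign(key, (get0(key, envir = counts,
                                          ifnotfound = 0L)) + 1L,
                               envir = counts)
  for (k in seq_along(go$chromosomes)) {
    ch <- go$chromosomes[[k]]
    exit_of <- function(s) paste0(abs(s), if (s > 0) "h" else "t")
    enter_of <- function(s) paste0(abs(s), if (s > 0) "t" else "h")
    pairs <- if (go$shapes[k] == "circular" && length(ch))
      cbind(ch, c(ch[-1L], ch[1L]))
    else if (length(ch) > 1L) cbind(ch[-length(ch)], ch[-1L])
    else NULL
    if (!is.null(pairs)) for (i in seq_len(nrow(pairs)))
      bump(paste(sort(c(exit_of(pairs[i, 1L]), enter_of(pairs[i, 2L]))),
                 collapse = "|"))
    if (go$shapes[k] == "linear" && length(ch)) {
      bump(paste0("TEL|", enter_of(ch[1L])))
      bump(paste0("TEL|", exit_of(ch[length(ch)])))
    }
  }
  odd <- sum(vapply(ls(counts), function(k) get(k, envir = counts) %% 2L,
                    numeric(1)))
  as.integer(ceiling(odd / 4))
}

#' Aliquoting distance to a perfectly duplicated ancestor
#'
#' Estimates the minimum DCJ distance between a genome whose markers each
#' occur twice and the exact doubling of some ancestor genome, and returns
#' that ancestor.  `mode = "exact"` enumerates every ancestor genome
#' (all adjacency matchings, linear or circular, any chromosome number)
#' and every copy assignment, and is limited to small instances.
#' `mode = "greedy"` reconstructs the ancestor from doubly supported
#' adjacencies and assigns copies by propagating labels along
#' ancestor-consistent runs; its estimate is an upper bound, so greedy
#' distance >= exact distance always.
#'
#' @param go A [gene_order()] with every marker occurring exactly twice.
#' @param mode `"greedy"` or `"exact"`.
#' @param max_exact_markers Exact-mode size limit (distinct markers).
#' @return List with `d` (estimated distance), `ancestor` (a
#'   [gene_order()]), `lower_bound`, `mode`.
#' @export
aliquot_distance <- function(go, mode = c("greedy", "exact"),
                             max_exact_markers = 6L) {
  mode <- match.arg(mode)
  .aliquot_check(go, 2L)
  markers <- sort(unique(abs(unlist(go$chromosomes))))
  n <- length(markers)
  offset <- max(markers)
  lb <- aliquot_lower_bound(go)

  if (mode == "exact") {
    if (n > max_exact_markers)
      stop("exact aliquoting is limited to ", max_exact_markers,
           " distinct markers; use mode = 'greedy'")
    remap <- stats::setNames(seq_len(n), as.character(markers))
    best <- Inf; best_anc <- NULL
    assignments <- expand.grid(rep(list(c(FALSE, TRUE)), max(n - 1L, 0L)))
    for (mm in .all_matchings(seq_len(2L * n))) {
      anc <- .from_adjset(list(adj = mm,
                               tel = setdiff(seq_len(2L * n), as.vector(mm)),
                               n = n, marker_ids = markers))
      doubled <- .doubled_genome(anc, offset)
      for (r in seq_len(max(nrow(assignments), 1L))) {
        bits <- c(FALSE, as.logical(assignments[r, ]))  # fix first marker
        ab <- stats::setNames(as.list(bits), as.character(markers))
        rel <- .relabel_copies(go, ab, offset)
        d <- dcj_distance(rel, doubled)$d
        if (d < best) { best <- d; best_anc <- anc }
      }
      if (best == lb) break  # cannot do better than the lower bound
    }
    return(list(d = as.integer(best), ancestor = best_anc,
                lower_bound = lb, mode = "exact"))
  }

  # ---- greedy mode -------------------------------------------------------
  # Natural graph: vertices are input adjacencies and telomeres; each
  # extremity class occurs exactly twice across vertices and links its two
  # occurrences.  Components are paths and cycles.  Choosing the class
  # pairs of alternate adjacency-vertices along each component as ancestor
  # adjacencies maximizes short cycles against the duplicated ancestor.
  ext_id <- function(m, side) 2L * match(m, markers) - (side == "t")
  verts <- list()  # each: c(class1, class2) or c(class, NA) for telomere
  for (k in seq_along(go$chromosomes)) {
    ch <- go$chromosomes[[k]]
    if (!length(ch)) next
    exit_of <- function(s) ext_id(abs(s), if (s > 0) "h" else "t")
    enter_of <- function(s) ext_id(abs(s), if (s > 0) "t" else "h")
    pairs <- if (go$shapes[k] == "circular")
      cbind(ch, c(ch[-1L], ch[1L]))
    else if (length(ch) > 1L) cbind(ch[-length(ch)], ch[-1L])
    else NULL
    if (!is.null(pairs)) for (i in seq_len(nrow(pairs)))
      verts[[length(verts) + 1L]] <- c(exit_of(pairs[i, 1L]),
                                       enter_of(pairs[i, 2L]))
    if (go$shapes[k] == "linear") {
      verts[[length(verts) + 1L]] <- c(enter_of(ch[1L]), NA_integer_)
      verts[[length(verts) + 1L]] <- c(exit_of(ch[length(ch)]), NA_integer_)
    }
  }
  nv <- length(verts)
  slot <- vector("list", 2L * n)  # class -> vertex ids holding it
  for (v in seq_len(nv)) for (cl in verts[[v]][!is.na(verts[[v]])])
    slot[[cl]] <- c(slot[[cl]], v)
  next_vertex <- function(v, cl) {
    s <- slot[[cl]]
    if (s[1L] == s[2L]) return(v)            # self-loop class
    if (s[1L] == v) s[2L] else s[1L]
  }
  other_class <- function(v, cl) {
    cs <- verts[[v]]
    if (is.na(cs[2L])) return(NA_integer_)    # telomere vertex: dead end
    if (cs[1L] == cl) cs[2L] else cs[1L]
  }
  visited <- logical(nv)
  comp_list <- list()
  is_tel <- vapply(verts, function(x) is.na(x[2L]), logical(1))
  order_starts <- c(which(is_tel), which(!is_tel))
  for (v0 in order_starts) {
    if (visited[v0]) next
    seq_v <- v0
    visited[v0] <- TRUE
    cl <- verts[[v0]][1L]
    v <- v0
    repeat {
      if (is.na(cl)) break
      v2 <- next_vertex(v, cl)
      if (v2 == v || visited[v2] && v2 == v0) break
      if (visited[v2]) break
      visited[v2] <- TRUE
      seq_v <- c(seq_v, v2)
      cl <- other_class(v2, cl)
      v <- v2
    }
    # if we started mid-path (shouldn't happen given telomeres first) the
    # walk above covers one side only; sweep the other side too
    cl <- verts[[v0]][2L]
    v <- v0
    repeat {
      if (is.na(cl) || is.null(cl)) break
      v2 <- next_vertex(v, cl)
      if (v2 == v || visited[v2]) break
      visited[v2] <- TRUE
      seq_v <- c(v2, seq_v)
      cl <- other_class(v2, cl)
      v <- v2
    }
    comp_list[[length(comp_list) + 1L]] <- seq_v
  }
  used <- logical(2L * n)
  adj <- matrix(integer(0), ncol = 2L)
  take <- function(v) {
    cs <- verts[[v]]
    if (is.na(cs[2L]) || cs[1L] == cs[2L]) return(invisible(NULL))
    if (!used[cs[1L]] && !used[cs[2L]]) {
      adj <<- rbind(adj, cs)
      used[cs] <<- TRUE
    }
    invisible(NULL)
  }
  for (comp in comp_list) {
    # prefer the alternate set with more adjacency-type vertices
    odd_set <- comp[seq(1L, length(comp), by = 2L)]
    even_set <- if (length(comp) > 1L) comp[seq(2L, length(comp), by = 2L)]
                else integer(0)
    n_adj <- function(s) sum(!is_tel[s])
    pick <- if (n_adj(even_set) > n_adj(odd_set)) even_set else odd_set
    for (v in pick) take(v)
    # mop up: any remaining vertex whose classes are still free
    for (v in comp) take(v)
  }
  ancestor <- .from_adjset(list(adj = adj,
                                tel = which(!used), n = n,
                                marker_ids = markers))
  anc_keys <- if (nrow(adj))
    apply(adj, 1L, function(r) paste(sort(r), collapse = "_")) else character(0)

  # runs of input markers consistent with ancestor adjacencies
  occ_run <- list()  # marker -> run ids of its occurrences
  run_id <- 0L
  run_members <- list()
  for (k in seq_along(go$chromosomes)) {
    ch <- go$chromosomes[[k]]
    if (!length(ch)) next
    run_id <- run_id + 1L
    run_members[[run_id]] <- list()
    prev <- NULL
    for (s in ch) {
      if (!is.null(prev)) {
        a <- ext_id(abs(prev), if (prev > 0) "h" else "t")
        b <- ext_id(abs(s), if (s > 0) "t" else "h")
        key <- paste(sort(c(a, b)), collapse = "_")
        if (!key %in% anc_keys) {
          run_id <- run_id + 1L
          run_members[[run_id]] <- list()
        }
      }
      run_members[[run_id]] <- c(run_members[[run_id]], abs(s))
      occ_run[[as.character(abs(s))]] <-
        c(occ_run[[as.character(abs(s))]], run_id)
      prev <- s
    }
  }
  # 2-colour the run conflict graph (runs sharing a marker differ)
  nruns <- run_id
  colour <- rep(NA, nruns)
  adj_runs <- vector("list", nruns)
  for (m in names(occ_run)) {
    rs <- occ_run[[m]]
    if (length(rs) == 2L && rs[1L] != rs[2L]) {
      adj_runs[[rs[1L]]] <- c(adj_runs[[rs[1L]]], rs[2L])
      adj_runs[[rs[2L]]] <- c(adj_runs[[rs[2L]]], rs[1L])
    }
  }
  for (r0 in seq_len(nruns)) {
    if (!is.na(colour[r0])) next
    colour[r0] <- FALSE
    queue <- r0
    while (length(queue)) {
      r <- queue[1L]; queue <- queue[-1L]
      for (r2 in adj_runs[[r]]) if (is.na(colour[r2])) {
        colour[r2] <- !colour[r]
        queue <- c(queue, r2)
      }
    }
  }
  # first occurrence takes its run colour; second takes the complement
  assign_b_first <- stats::setNames(
    lapply(names(occ_run), function(m) colour[occ_run[[m]][1L]]),
    names(occ_run))
  # flip moves for assignment refinement: single markers plus whole
  # ancestor-consistent runs (a mislabeled run needs all its markers
  # flipped together; single flips cannot cross that ridge)
  flip_sets <- c(lapply(run_members, function(rm) {
    ms <- as.character(unlist(rm))
    ms[!(duplicated(ms) | duplicated(ms, fromLast = TRUE))]
  }))
  flip_sets <- flip_sets[lengths(flip_sets) > 0L]

  # hill-climb the copy assignment against a fixed doubled ancestor
  climb_assignment <- function(assignment, doubled) {
    d <- dcj_distance(.relabel_copies(go, assignment, offset), doubled)$d
    moves <- c(flip_sets, as.list(names(assignment)))
    repeat {
      improved <- FALSE
      for (mv in moves) {
        if (d <= lb) break
        trial <- assignment
        for (m in mv) trial[[m]] <- !isTRUE(trial[[m]])
        d2 <- dcj_distance(.relabel_copies(go, trial, offset), doubled)$d
        if (d2 < d) {
          d <- d2
          assignment <- trial
          improved <- TRUE
        }
      }
      if (!improved || d <= lb) break
    }
    list(d = d, assignment = assignment)
  }
  # re-derive an ancestor from a fixed assignment: adjacencies supported by
  # both relabeled copies first, then singly supported ones
  ancestor_from_assignment <- function(assignment) {
    rel <- .relabel_copies(go, assignment, offset)
    sup <- new.env(hash = TRUE)
    for (k in seq_along(rel$chromosomes)) {
      ch <- rel$chromosomes[[k]]
      if (length(ch) < 2L && rel$shapes[k] != "circular") next
      prs <- if (rel$shapes[k] == "circular")
        cbind(ch, c(ch[-1L], ch[1L]))
      else cbind(ch[-length(ch)], ch[-1L])
      for (i in seq_len(nrow(prs))) {
        s1 <- prs[i, 1L]; s2 <- prs[i, 2L]
        m1 <- (abs(s1) - 1L) %% offset + 1L; m2 <- (abs(s2) - 1L) %% offset + 1L
        a <- ext_id(m1, if (s1 > 0) "h" else "t")
        b <- ext_id(m2, if (s2 > 0) "t" else "h")
        key <- paste(sort(c(a, b)), collapse = "_")
        assign(key, (get0(key, envir = sup, ifnotfound = 0L)) + 1L,
               envir = sup)
      }
    }
    keys <- ls(sup)
    if (!length(keys)) {
      return(.from_adjset(list(adj = matrix(integer(0), ncol = 2L),
                               tel = seq_len(2L * n), n = n,
                               marker_ids = markers)))
    }
    w <- vapply(keys, function(k) get(k, envir = sup), numeric(1))
    ab <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
    cand <- data.frame(e1 = as.integer(ab[, 1L]), e2 = as.integer(ab[, 2L]),
                       w = w)
    cand <- cand[cand$e1 != cand$e2, , drop = FALSE]
    cand <- cand[order(-cand$w, cand$e1, cand$e2), , drop = FALSE]
    used2 <- logical(2L * n)
    adj2 <- matrix(integer(0), ncol = 2L)
    for (i in seq_len(nrow(cand))) {
      if (!used2[cand$e1[i]] && !used2[cand$e2[i]]) {
        adj2 <- rbind(adj2, c(cand$e1[i], cand$e2[i]))
        used2[c(cand$e1[i], cand$e2[i])] <- TRUE
      }
    }
    .from_adjset(list(adj = adj2, tel = which(!used2), n = n,
                      marker_ids = markers))
  }

  # all matchings (possibly partial) over a small class set
  .local_matchings <- function(cls) {
    if (!length(cls)) return(list(matrix(integer(0), ncol = 2L)))
    e <- cls[1L]; rest <- cls[-1L]
    out <- lapply(.local_matchings(rest), identity)
    for (i in seq_along(rest))
      for (sub in .local_matchings(rest[-i]))
        out[[length(out) + 1L]] <- rbind(c(e, rest[i]), sub)
    out
  }

  # 2-swap refinement of the ancestor: rewire pairs of suspect adjacencies
  # (those not realized in both relabeled copies) and free telomere classes
  refine_ancestor <- function(ancestor, fit) {
    repeat {
      doubled <- .doubled_genome(ancestor, offset)
      rel <- .relabel_copies(go, fit$assignment, offset)
      anc_as <- .to_adjset(ancestor)
      # realized class-adjacency multiset of the relabeled input
      rel_keys <- new.env(hash = TRUE)
      for (k in seq_along(rel$chromosomes)) {
        ch <- rel$chromosomes[[k]]
        prs <- if (rel$shapes[k] == "circular" && length(ch))
          cbind(ch, c(ch[-1L], ch[1L]))
        else if (length(ch) > 1L) cbind(ch[-length(ch)], ch[-1L]) else NULL
        if (is.null(prs)) next
        for (i in seq_len(nrow(prs))) {
          s1 <- prs[i, 1L]; s2 <- prs[i, 2L]
          m1 <- (abs(s1) - 1L) %% offset + 1L
          m2 <- (abs(s2) - 1L) %% offset + 1L
          a <- ext_id(m1, if (s1 > 0) "h" else "t")
          b <- ext_id(m2, if (s2 > 0) "t" else "h")
          key <- paste(sort(c(a, b)), collapse = "_")
          assign(key, (get0(key, envir = rel_keys, ifnotfound = 0L)) + 1L,
                 envir = rel_keys)
        }
      }
      supp_of <- function(x, y)
        get0(paste(sort(c(x, y)), collapse = "_"), envir = rel_keys,
             ifnotfound = 0L)
      adjm <- anc_as$adj
      susp <- which(vapply(seq_len(nrow(adjm)), function(i)
        supp_of(adjm[i, 1L], adjm[i, 2L]) < 2L, logical(1)))
      units <- c(lapply(susp, function(i) adjm[i, ]),
                 as.list(anc_as$tel))
      if (length(units) > 40L) units <- units[seq_len(40L)]
      d0 <- dcj_distance(rel, doubled)$d
      best_d <- d0; best_anc <- NULL
      if (length(units) >= 2L) {
        for (i in seq_len(length(units) - 1L)) for (j in seq(i + 1L, length(units))) {
          cls <- c(units[[i]], units[[j]])
          for (mm in .local_matchings(cls)) {
            keep <- !apply(adjm, 1L, function(r)
              any(r %in% cls))
            adj_new <- rbind(adjm[keep, , drop = FALSE], mm)
            used_new <- logical(2L * n)
            used_new[as.vector(adj_new)] <- TRUE
            anc_try <- .from_adjset(list(adj = adj_new,
                                         tel = which(!used_new), n = n,
                                         marker_ids = markers))
            d_try <- dcj_distance(rel, .doubled_genome(anc_try, offset))$d
            if (d_try < best_d) { best_d <- d_try; best_anc <- anc_try }
          }
        }
      }
      if (is.null(best_anc)) return(list(ancestor = ancestor, fit = fit))
      ancestor <- best_anc
      fit <- climb_assignment(fit$assignment,
                              .doubled_genome(ancestor, offset))
      if (fit$d <= lb) return(list(ancestor = ancestor, fit = fit))
    }
  }

  fit <- climb_assignment(assign_b_first, .doubled_genome(ancestor, offset))
  best <- list(d = fit$d, ancestor = ancestor)
  # alternate ancestor re-derivation and assignment refinement
  for (it in seq_len(5L)) {
    if (best$d <= lb) break
    anc2 <- ancestor_from_assignment(fit$assignment)
    fit2 <- climb_assignment(fit$assignment, .doubled_genome(anc2, offset))
    if (fit2$d < best$d) {
      best <- list(d = fit2$d, ancestor = anc2)
      fit <- fit2
    } else break
  }
  if (best$d > lb && n <= 60L) {
    ref <- refine_ancestor(best$ancestor, fit)
    if (ref$fit$d < best$d)
      best <- list(d = ref$fit$d, ancestor = ref$ancestor)
  }
  list(d = as.integer(best$d), ancestor = best$ancestor, lower_bound = lb,
       mode = "greedy")
}
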