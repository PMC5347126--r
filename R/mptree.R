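# Maximum-parsimony, mutation-labelled genealogies of samples within a clade:
# the substrate for the rho statistic.
#
# Characters are the presence patterns of variants relative to the clade root
# haplotype. When all characters are pairwise compatible (carrier sets nested
# or disjoint) the unique perfect phylogeny is returned; incompatibilities are
# resolved greedily by duplicating the character at the most mutable (lowest
# weight) site, i.e. letting that site mutate twice.

.set_key <- function(s) paste(sort(s), collapse = ",")

#' Construct a sample tree
#'
#' Low-level constructor; most users obtain sample trees from
#' [build_mp_tree()] or the simulator.
#'
#' @param edge two-column integer matrix (parent, child), ape convention: tips
#'   are 1..n, the root is n+1.
#' @param edge_tokens list of character vectors of mutation tokens per edge
#'   (edge length = number of tokens) or `NULL` with `edge_length` given.
#' @param tip_label character vector of tip labels.
#' @param edge_length integer mutation counts per edge (derived from
#'   `edge_tokens` when omitted).
#' @param root_label label of the clade ancestral haplotype.
#' @return A `sample_tree`.
#' @export
sample_tree <- function(edge, edge_tokens = NULL, tip_label,
                        edge_length = NULL, root_label = "root") {
  n <- length(tip_label)
  if (is.null(edge_length))
    edge_length <- vapply(edge_tokens, length, integer(1))
  if (is.null(edge_tokens))
    edge_tokens <- rep(list(character(0)), nrow(edge))
  if (nrow(edge) != length(edge_length) || nrow(edge) != length(edge_tokens))
    stop("edge, edge_length and edge_tokens must agree")
  if (any(edge_length < 0)) stop("edge lengths must be >= 0")
  st <- structure(list(edge = edge, edge_length = as.numeric(edge_length),
                       edge_tokens = edge_tokens, tip_label = tip_label,
                       n_tips = n, root = n + 1L, root_label = root_label),
                  class = "sample_tree")
  .validate_sample_tree(st)
  st
}

.validate_sample_tree <- function(st) {
  n <- st$n_tips
  if (n < 1L) stop("sample tree needs at least one tip")
  kids <- st$edge[, 2L]
  if (anyDuplicated(kids)) stop("node with two parents")
  if (st$root %in% kids) stop("root must have no parent")
  nodes <- unique(c(st$edge))
  if (!all(seq_len(n) %in% kids)) stop("every tip needs a parent edge")
  # connectivity: walk each node up to the root
  parent_of <- integer(max(nodes))
  parent_of[st$edge[, 2L]] <- st$edge[, 1L]
  for (v in nodes) {
    cur <- v; steps <- 0L
    while (cur != st$root) {
      cur <- parent_of[cur]
      steps <- steps + 1L
      if (cur == 0L || steps > length(nodes)) stop("disconnected or cyclic tree")
    }
  }
  invisible(st)
}

#' @export
print.sample_tree <- function(x, ...) {
  cat(sprintf("<sample_tree> %d tip(s), %d edge(s), %g mutation(s), root %s\n",
              x$n_tips, nrow(x$edge), sum(x$edge_length), x$root_label))
  invisible(x)
}

#' Total parsimony score of a sample tree
#'
#' @param st `sample_tree`.
#' @return Sum of edge mutation counts (non-negative).
#' @export
parsimony_score <- function(st) sum(st$edge_length)

# number of tips below each edge (each tip walks its path to the root)
.tips_below <- function(st) {
  nmax <- max(c(st$edge, st$root))
  parent_of <- integer(nmax)
  parent_of[st$edge[, 2L]] <- st$edge[, 1L]
  cnt <- integer(nmax)
  for (tip in seq_len(st$n_tips)) {
    cur <- tip
    repeat {
      cnt[cur] <- cnt[cur] + 1L
      if (cur == st$root) break
      cur <- parent_of[cur]
    }
  }
  cnt[st$edge[, 2L]]
}

.mp_characters <- function(profiles, root_profile) {
  n <- length(profiles)
  tip_tokens <- lapply(profiles, function(p) p$variants$token)
  root_v <- root_profile$variants
  root_back <- root_v[root_v$back, , drop = FALSE]
  root_fwd <- root_v[!root_v$back, , drop = FALSE]
  if (nrow(root_back) > 0L) {
    reverted <- sub("!$", "", root_back$token)
    for (i in seq_len(n))
      if (any(reverted %in% tip_tokens[[i]]))
        stop("profile ", profiles[[i]]$sample_id, " carries a variant ",
             "reverted in the clade root haplotype (consistency error)")
  }
  all_tokens <- sort(unique(c(unlist(tip_tokens), root_fwd$token)))
  chars <- list()
  for (tk in all_tokens) {
    in_root <- tk %in% root_fwd$token
    has <- vapply(tip_tokens, function(x) tk %in% x, logical(1))
    carriers <- which(has != in_root)     # tips in the derived state
    if (length(carriers) == 0L) next
    pos <- suppressWarnings(as.integer(sub("^[ACGT]?([0-9]+).*$", "\\1", tk)))
    label <- if (in_root) paste0(tk, "!") else tk
    chars[[length(chars) + 1L]] <-
      list(token = label, pos = pos, carriers = carriers)
  }
  chars
}

.pairwise_compatible <- function(chars) {
  nc <- length(chars)
  if (nc < 2L) return(TRUE)
  for (i in seq_len(nc - 1L)) {
    for (j in seq(i + 1L, nc)) {
      A <- chars[[i]]$carriers; B <- chars[[j]]$carriers
      ab <- length(intersect(A, B))
      if (ab > 0L && ab < length(A) && ab < length(B)) return(FALSE)
    }
  }
  TRUE
}

# all unrooted binary topologies on k >= 3 labelled leaves (1..k), internal
# nodes numbered k+1 .. 2k-2; grown by leaf insertion, cached per k
.enum_topologies <- function(k) {
  key <- paste0("topo", k)
  if (!is.null(.mitorho_env[[key]])) return(.mitorho_env[[key]])
  trees <- list(rbind(c(k + 1L, 1L), c(k + 1L, 2L), c(k + 1L, 3L)))
  t <- 3L
  while (t < k) {
    t <- t + 1L
    newint <- k + (t - 2L)
    grown <- vector("list", length(trees) * (2L * t - 5L))
    g <- 0L
    for (tr in trees) {
      for (e in seq_len(nrow(tr))) {
        g <- g + 1L
        grown[[g]] <- rbind(tr[-e, , drop = FALSE],
                            c(tr[e, 1L], newint),
                            c(newint, tr[e, 2L]),
                            c(newint, t))
      }
    }
    trees <- grown
  }
  .mitorho_env[[key]] <- trees
  trees
}

# direct the unrooted edges away from the root leaf and return them in
# parent-before-child order
.root_edges <- function(edge, root) {
  adj <- split(c(edge[, 2L], edge[, 1L]), c(edge[, 1L], edge[, 2L]))
  out <- matrix(0L, nrow(edge), 2L)
  i <- 0L
  frontier <- root
  seen <- root
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (v in frontier) {
      for (u in adj[[as.character(v)]]) {
        if (u %in% seen) next
        i <- i + 1L
        out[i, ] <- c(v, u)
        nxt <- c(nxt, u)
        seen <- c(seen, u)
      }
    }
    frontier <- nxt
  }
  out
}

# exact minimum-change search for incompatible characters on small instances:
# enumerate topologies (the ancestral haplotype is an extra leaf whose state
# is all-ancestral), score each with a two-state min-change DP, and backtrack
# a deterministic optimal labelling on the best topology.
.exact_mp <- function(chars, n, w) {
  k <- n + 1L                              # leaf k = ancestral haplotype
  nc <- length(chars)
  weights <- site_weight(w, vapply(chars, `[[`, integer(1), "pos"))
  derived <- matrix(FALSE, k, nc)
  for (j in seq_len(nc)) derived[chars[[j]]$carriers, j] <- TRUE

  topos <- .enum_topologies(k)
  best_score <- Inf; best_edges <- NULL
  for (tr in topos) {
    edges <- .root_edges(tr, k)
    nnode <- 2L * k - 2L
    cost0 <- matrix(0, nnode, nc); cost1 <- matrix(0, nnode, nc)
    BIG <- 1e9
    cost0[seq_len(k - 1L), ] <- ifelse(derived[seq_len(k - 1L), , drop = FALSE],
                                       BIG, 0)
    cost1[seq_len(k - 1L), ] <- ifelse(derived[seq_len(k - 1L), , drop = FALSE],
                                       0, BIG)
    cost1[k, ] <- BIG                      # ancestral leaf fixed at state 0
    for (e in rev(seq_len(nrow(edges)))) { # children before parents
      par <- edges[e, 1L]; ch <- edges[e, 2L]
      cost0[par, ] <- cost0[par, ] + pmin(cost0[ch, ], cost1[ch, ] + 1)
      cost1[par, ] <- cost1[par, ] + pmin(cost1[ch, ], cost0[ch, ] + 1)
    }
    score <- sum(cost0[k, ] * weights)
    if (score < best_score) {
      best_score <- score; best_edges <- edges
      best_cost0 <- cost0; best_cost1 <- cost1
    }
  }

  # deterministic backtrack: prefer the parent's state on ties
  edges <- best_edges
  nnode <- 2L * k - 2L
  state <- matrix(NA, nnode, nc)
  state[k, ] <- 0L
  etokens <- rep(list(character(0)), nrow(edges))
  for (e in seq_len(nrow(edges))) {        # parents before children
    par <- edges[e, 1L]; ch <- edges[e, 2L]
    ps <- state[par, ]
    c_keep <- ifelse(ps == 0L, best_cost0[ch, ], best_cost1[ch, ])
    c_flip <- ifelse(ps == 0L, best_cost1[ch, ], best_cost0[ch, ]) + 1
    cs <- ifelse(c_keep <= c_flip, ps, 1L - ps)
    state[ch, ] <- cs
    flips <- which(cs != ps)
    if (length(flips) > 0L) {
      toks <- vapply(flips, function(j) {
        tk <- chars[[j]]$token
        if (cs[j] == 1L) tk                    # toward the derived state
        else if (grepl("!$", tk)) sub("!$", "", tk)
        else paste0(tk, "!")                   # reversion toward the root
      }, character(1))
      etokens[[e]] <- sort(toks)
    }
  }
  # drop the ancestral-leaf edge by re-rooting: leaf k's single neighbour
  # inherits the root role, but the edge k -> v (possibly with mutations)
  # must be kept, so instead relabel: tips 1..n, root = k = n+1, internal
  # nodes renumbered n+2.. in first-seen order
  relabel <- integer(nnode)
  relabel[seq_len(n)] <- seq_len(n)
  relabel[k] <- n + 1L
  nxt <- n + 1L
  for (v in unique(c(t(edges)))) {
    if (relabel[v] == 0L) { nxt <- nxt + 1L; relabel[v] <- nxt }
  }
  edge <- cbind(relabel[edges[, 1L]], relabel[edges[, 2L]])
  .collapse_unary(edge, etokens, n, n + 1L)
}

# contract zero-mutation internal edges and merge unary internal nodes, then
# renumber internal ids; returns the edge matrix and token lists
.collapse_unary <- function(edge, tokens, n, root) {
  repeat {
    len <- lengths(tokens)
    zi <- which(len == 0L & edge[, 2L] > n)
    if (length(zi) > 0L) {
      e <- zi[1L]; ch <- edge[e, 2L]; par <- edge[e, 1L]
      edge[edge[, 1L] == ch, 1L] <- par
      edge <- edge[-e, , drop = FALSE]; tokens <- tokens[-e]
      next
    }
    internal <- setdiff(unique(edge[, 1L]), root)
    outdeg <- vapply(internal, function(v) sum(edge[, 1L] == v), integer(1))
    un <- internal[outdeg == 1L]
    if (length(un) > 0L) {
      v <- un[1L]
      ein <- which(edge[, 2L] == v); eout <- which(edge[, 1L] == v)
      edge[ein, 2L] <- edge[eout, 2L]
      tokens[[ein]] <- sort(c(tokens[[ein]], tokens[[eout]]))
      edge <- edge[-eout, , drop = FALSE]; tokens <- tokens[-eout]
      next
    }
    break
  }
  # renumber internal nodes consecutively after the root
  nodes <- unique(c(t(edge)))
  internals <- setdiff(nodes[nodes > n], root)
  relabel <- stats::setNames(c(seq_len(n), root, internals),
                             c(seq_len(n), root, internals))
  relabel[as.character(internals)] <- root + seq_along(internals)
  edge <- cbind(relabel[as.character(edge[, 1L])],
                relabel[as.character(edge[, 2L])])
  dimnames(edge) <- NULL
  list(edge = edge, tokens = tokens)
}

.resolve_conflicts <- function(chars, w) {
  # stable deterministic order
  ord <- order(vapply(chars, `[[`, integer(1), "pos"),
               vapply(chars, `[[`, character(1), "token"), method = "radix")
  chars <- chars[ord]
  repeat {
    conflict <- NULL
    nc <- length(chars)
    for (i in seq_len(max(nc - 1L, 0L))) {
      for (j in seq((i + 1L), nc)) {
        if (i >= j) next
        A <- chars[[i]]$carriers; B <- chars[[j]]$carriers
        ab <- intersect(A, B)
        if (length(ab) > 0L && length(ab) < length(A) &&
            length(ab) < length(B)) { conflict <- c(i, j); break }
      }
      if (!is.null(conflict)) break
    }
    if (is.null(conflict)) return(chars)
    i <- conflict[1L]; j <- conflict[2L]
    wi <- site_weight(w, chars[[i]]$pos); wj <- site_weight(w, chars[[j]]$pos)
    # duplicate the character with the lowest weight (most mutable site);
    # ties broken by lowest position, then token
    pick <- if (wi < wj) i else if (wj < wi) j
      else if (chars[[i]]$pos != chars[[j]]$pos) {
        if (chars[[i]]$pos < chars[[j]]$pos) i else j
      } else if (chars[[i]]$token <= chars[[j]]$token) i else j
    other <- if (pick == i) j else i
    X <- chars[[pick]]; Y <- chars[[other]]
    piece1 <- X; piece1$carriers <- intersect(X$carriers, Y$carriers)
    piece2 <- X; piece2$carriers <- setdiff(X$carriers, Y$carriers)
    chars <- append(chars[-pick], list(piece1, piece2), after = pick - 1L)
  }
}

#' Build a maximum-parsimony sample tree within one clade
#'
#' On pairwise-compatible characters (carrier sets nested or disjoint) this is
#' the unique perfect phylogeny. When characters conflict, small instances (up
#' to 7 tips and 24 variable characters) are solved exactly by enumerating
#' topologies and minimising the total weighted number of state changes;
#' larger instances fall back to a greedy resolution that duplicates the
#' character at the most mutable (lowest-weight) site, ties broken by lowest
#' position.
#'
#' @param profiles list of `mt_profile`, all classified to the same clade.
#' @param root_profile `mt_profile` holding the cumulative motif of the clade
#'   root (back-mutation rows mark net-absent reversions).
#' @param w `site_weights` steering which site is allowed to mutate twice when
#'   characters conflict.
#' @param exact_limits tip and character counts up to which conflicting
#'   instances are solved exactly.
#' @return A `sample_tree`; tips are the input samples in order, edges carry
#'   mutation token lists (a trailing `!` marks a reversion toward the
#'   root state).
#' @export
build_mp_tree <- function(profiles, root_profile,
                          w = default_site_weights(),
                          exact_limits = c(tips = 7L, chars = 24L)) {
  if (length(profiles) == 0L) stop("at least one profile is required")
  n <- length(profiles)
  tips <- vapply(profiles, function(p) p$sample_id, character(1))
  chars <- .mp_characters(profiles, root_profile)
  if (!.pairwise_compatible(chars) && n >= 3L &&
      n <= exact_limits[["tips"]] && length(chars) <= exact_limits[["chars"]]) {
    res <- .exact_mp(chars, n, w)
    return(sample_tree(res$edge, edge_tokens = res$tokens, tip_label = tips,
                       root_label = root_profile$sample_id))
  }
  chars <- .resolve_conflicts(chars, w)

  # group character instances by carrier set (laminar family)
  keys <- vapply(chars, function(ch) .set_key(ch$carriers), character(1))
  sets <- split(chars, keys)
  set_members <- lapply(sets, function(g) g[[1L]]$carriers)
  sizes <- vapply(set_members, length, integer(1))
  ord <- order(-sizes, names(sets), method = "radix")
  sets <- sets[ord]; set_members <- set_members[ord]; sizes <- sizes[ord]

  # node ids: tips 1..n, root n+1, then one internal node per carrier set of
  # size > 1; singleton sets are the tips themselves
  node_of_set <- integer(length(sets))
  next_id <- n + 1L
  for (s in seq_along(sets)) {
    if (sizes[s] == 1L) node_of_set[s] <- set_members[[s]][1L]
    else { next_id <- next_id + 1L; node_of_set[s] <- next_id }
  }
  root <- n + 1L

  parent_set <- function(s) {
    # smallest proper superset (laminar => unique); 0 = root
    best <- 0L; best_size <- Inf
    for (t in seq_along(sets)) {
      if (t == s) next
      if (sizes[t] <= sizes[s]) next
      if (all(set_members[[s]] %in% set_members[[t]]) && sizes[t] < best_size) {
        best <- t; best_size <- sizes[t]
      }
    }
    best
  }

  ep <- integer(0); ec <- integer(0); etok <- list()
  for (s in seq_along(sets)) {
    ps <- parent_set(s)
    ep <- c(ep, if (ps == 0L) root else node_of_set[ps])
    ec <- c(ec, node_of_set[s])
    etok <- c(etok, list(vapply(sets[[s]], `[[`, character(1), "token")))
  }
  # attach tips not already placed as singleton-set nodes
  placed <- node_of_set[sizes == 1L]
  for (i in setdiff(seq_len(n), placed)) {
    containing <- which(vapply(set_members, function(m) i %in% m, logical(1)))
    anchor <- if (length(containing) == 0L) root else {
      smallest <- containing[which.min(sizes[containing])]
      node_of_set[smallest]
    }
    ep <- c(ep, anchor); ec <- c(ec, i); etok <- c(etok, list(character(0)))
  }
  st <- sample_tree(cbind(ep, ec), edge_tokens = etok, tip_label = tips,
                    root_label = root_profile$sample_id)
  st
}

#' Export a sample tree as Newick (edge lengths in mutations)
#' @param st `sample_tree`.
#' @return Newick string.
#' @export
sample_tree_newick <- function(st) {
  kids <- split(seq_len(nrow(st$edge)), st$edge[, 1L])
  rec <- function(node) {
    es <- kids[[as.character(node)]]
    if (is.null(es)) return(st$tip_label[node])
    parts <- vapply(es, function(e)
      paste0(rec(st$edge[e, 2L]), ":", st$edge_length[e]), character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(st$root), st$root_label, ";")
}

#' Export a sample tree's edges as TSV
#' @param st `sample_tree`.
#' @param path output file.
#' @export
write_sample_tree_tsv <- function(st, path) {
  name_of <- function(v) ifelse(v <= st$n_tips, st$tip_label[v],
                                ifelse(v == st$root, st$root_label,
                                       paste0("node", v)))
  df <- data.frame(parent = name_of(st$edge[, 1L]),
                   child = name_of(st$edge[, 2L]),
                   mutations = vapply(st$edge_tokens, paste,
                                      character(1), collapse = " "),
                   length = st$edge_length, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
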