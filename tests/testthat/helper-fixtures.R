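# Shared fixtures: tiny haplogroup trees, profile shortcuts, random sample
# trees, and an independent exhaustive parsimony oracle.

mk_profile <- function(tokens, id = "s") {
  mt_profile(id, parse_variants(tokens))
}

write_tree_file <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# a small three-clade tree on real packaged-reference alleles
tiny_tree <- function() {
  ref <- mt_reference()
  tok <- function(pos) paste0(ref$chars[pos], pos,
                              c(A = "G", G = "A", C = "T", T = "C")[ref$chars[pos]])
  load_haplotree(write_tree_file(c(
    "ROOT\t-",
    paste0("A\tROOT\t", tok(1001)),
    paste0("AB\tA\t", tok(2002), " ", tok(3003)),
    paste0("AC\tA\t", tok(4004))
  )))
}

# random sample_tree with integer mutation counts on edges
random_sample_tree <- function(n_tips, max_children = 3L) {
  if (n_tips == 1L) {
    return(sample_tree(cbind(2L, 1L), tip_label = "t1",
                       edge_length = stats::rpois(1L, 2)))
  }
  next_id <- n_tips + 1L
  ep <- integer(0); ec <- integer(0)
  expand <- function(members, node) {
    if (length(members) == 1L) return(invisible(NULL))
    k <- min(length(members), sample(2:max_children, 1L))
    grp <- sample(rep_len(seq_len(k), length(members)))
    for (g in unique(grp)) {
      sub <- members[grp == g]
      child <- if (length(sub) == 1L) sub else {
        next_id <<- next_id + 1L
        next_id
      }
      ep <<- c(ep, node); ec <<- c(ec, child)
      if (length(sub) > 1L) expand(sub, child)
    }
  }
  expand(seq_len(n_tips), n_tips + 1L)
  sample_tree(cbind(ep, ec), tip_label = paste0("t", seq_len(n_tips)),
              edge_length = stats::rpois(length(ep), 2))
}

# --- independent maximum-parsimony oracle -----------------------------------
# Minimal total (weighted) changes over ALL tree topologies, for binary
# characters with a known ancestral state: the ancestral haplotype enters as a
# pseudo-tip with all-zero states; topologies are enumerated with
# phangorn::allTrees and each character is scored with a small Fitch pass.

.topology_cache <- new.env(parent = emptyenv())

all_topologies <- function(k) {
  key <- as.character(k)
  if (is.null(.topology_cache[[key]]))
    .topology_cache[[key]] <- phangorn::allTrees(k, rooted = FALSE,
                                                 tip.label = paste0("x", 1:k))
  .topology_cache[[key]]
}

# carriers: list of integer vectors (tips in derived state), n tips,
# weights: numeric per character. Two-state Sankoff DP per topology (exact for
# any node degree, so the unrooted trifurcation needs no special casing); the
# ancestral pseudo-tip (state 0) fixes the root haplotype.
mp_oracle_score <- function(carriers, n, weights = rep(1, length(carriers))) {
  k <- n + 1L                      # + ancestral pseudo-tip (index n+1, state 0)
  states <- vapply(carriers, function(cr) {
    s <- integer(k); s[cr] <- 1L; s
  }, integer(k))                   # k x nchar matrix
  topos <- all_topologies(k)
  BIG <- 1e6
  best <- Inf
  for (ti in seq_along(topos)) {
    tr <- stats::reorder(topos[[ti]], "postorder")  # [[ restores tip labels
    tipidx <- as.integer(sub("x", "", tr$tip.label))
    nnode <- max(tr$edge)
    nc <- ncol(states)
    cost0 <- matrix(0, nnode, nc); cost1 <- matrix(0, nnode, nc)
    tipstate <- states[tipidx, , drop = FALSE]
    cost0[seq_len(k), ] <- ifelse(tipstate == 0L, 0, BIG)
    cost1[seq_len(k), ] <- ifelse(tipstate == 1L, 0, BIG)
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
      cost0[par, ] <- cost0[par, ] + pmin(cost0[ch, ], cost1[ch, ] + 1)
      cost1[par, ] <- cost1[par, ] + pmin(cost1[ch, ], cost0[ch, ] + 1)
    }
    root <- tr$edge[nrow(tr$edge), 1L]
    score <- sum(pmin(cost0[root, ], cost1[root, ]) * weights)
    if (score < best) best <- score
  }
  best
}

# random conflict-prone instance for the oracle comparisons; returns profiles,
# root profile and the raw carrier sets
random_mp_instance <- function(n_tips, n_sites, ref = mt_reference()) {
  pos_pool <- setdiff(1000:1200, c(default_mask(), haplo_positions(australia_tree())))
  pos <- sample(pos_pool, n_sites)
  trs <- c(A = "G", G = "A", C = "T", T = "C")
  tokens <- paste0(ref$chars[pos], pos, trs[ref$chars[pos]])
  carriers <- lapply(seq_len(n_sites), function(i) {
    repeat {
      cr <- which(stats::runif(n_tips) < 0.45)
      if (length(cr) > 0L) return(cr)
    }
  })
  profiles <- lapply(seq_len(n_tips), function(i) {
    carry <- vapply(carriers, function(cr) i %in% cr, logical(1))
    mk_profile(tokens[carry], id = paste0("t", i))
  })
  list(profiles = profiles, root = mk_profile(character(0), id = "root"),
       carriers = carriers, tokens = tokens)
}
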