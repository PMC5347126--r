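# Haplogroup assignment by weighted Kulczynski scoring against the cumulative
# expected motif of each candidate node (the haplogrep lineage of scoring).

#' Site weights for classification
#'
#' Positive weights express how much evidential value a match at a position
#' carries. Known recurrent sites are downweighted: position 8251 (26
#' independent occurrences in PhyloTree Build 17) to 0.2 and the mildly
#' recurrent 9156 (five occurrences) to 0.8; masked sites carry no weight.
#' Unlisted positions weigh 1.
#'
#' @param weights named numeric vector, names = positions.
#' @param default weight for unlisted positions (must be > 0).
#' @return A `site_weights` object.
#' @export
site_weights <- function(weights = numeric(0), default = 1) {
  w <- as.numeric(weights)
  names(w) <- names(weights)
  if (any(w < 0)) stop("site weights must be >= 0")
  if (default <= 0) stop("default site weight must be > 0")
  structure(list(weights = w, default = default), class = "site_weights")
}

#' @rdname site_weights
#' @param mask positions whose weight is zero (no classification signal);
#'   default [default_mask()].
#' @export
default_site_weights <- function(mask = default_mask()) {
  w <- c(stats::setNames(rep(0, length(mask)), mask),
         `8251` = 0.2, `9156` = 0.8)
  site_weights(w)
}

#' Look up weights for positions
#' @param w `site_weights`.
#' @param positions integer vector.
#' @return Numeric vector of weights.
#' @export
site_weight <- function(w, positions) {
  out <- rep(w$default, length(positions))
  hit <- match(as.character(positions), names(w$weights))
  out[!is.na(hit)] <- w$weights[hit[!is.na(hit)]]
  out
}

# sum of weights over a variant table (by position)
.wsum <- function(w, v) {
  if (nrow(v) == 0L) return(0)
  sum(site_weight(w, v$position))
}

.score_nodes <- function(profile, tree, w) {
  obs <- profile$variants
  informative_pos <- haplo_positions(tree)
  obs_inf <- obs[obs$position %in% informative_pos, , drop = FALSE]
  W_obs <- .wsum(w, obs_inf)
  labels <- tree$order
  # candidates: root, plus nodes whose own branch adds nonzero weight
  cand <- vapply(labels, function(nm) {
    n <- tree$nodes[[nm]]
    is.na(n$parent) || .wsum(w, n$variants) > 0
  }, logical(1))
  res <- lapply(labels[cand], function(nm) {
    exp_v <- cumulative_expected(tree, nm)
    matched <- exp_v[exp_v$token %in% obs$token, , drop = FALSE]
    missing <- exp_v[!exp_v$token %in% obs$token, , drop = FALSE]
    W_exp <- .wsum(w, exp_v)
    W_mat <- .wsum(w, matched)
    t1 <- if (W_exp == 0) 1 else W_mat / W_exp
    t2 <- if (W_obs == 0) 1 else W_mat / W_obs
    list(label = nm, score = (t1 + t2) / 2, matched = matched,
         missing = missing, depth = haplo_depth(tree, nm))
  })
  scores <- vapply(res, `[[`, numeric(1), "score")
  depths <- vapply(res, `[[`, numeric(1), "depth")
  lab <- vapply(res, `[[`, character(1), "label")
  ord <- order(-scores, -depths, lab, method = "radix")
  list(ranked = res[ord], W_obs = W_obs)
}

#' Classify a sample's variant profile
#'
#' Scores every non-placeholder node of the tree with the weighted Kulczynski
#' score K(h) = ((W(matched)/W(expected)) + (W(matched)/W(observed))) / 2,
#' where the observed term counts only phylogenetically informative variants
#' (positions appearing anywhere in the tree) so that private mutations never
#' penalise a candidate. Ties are broken by greater path depth, then by
#' lexicographic label; the result is deterministic. An empty profile maps to
#' the root with score 1 by convention.
#'
#' @param profile `mt_profile`.
#' @param tree `haplo_tree`.
#' @param w `site_weights`; default [default_site_weights()].
#' @return A `classification` list: `sample_id`, `haplogroup`, `score`,
#'   `matched`, `missing`, `private` (each `mt_variants`), `runner_up`
#'   (label + score), `tie` (logical: runner-up score equal to best).
#' @export
classify_sample <- function(profile, tree, w = default_site_weights()) {
  if (length(tree$nodes) == 0L) stop("empty haplogroup tree")
  sc <- .score_nodes(profile, tree, w)
  best <- sc$ranked[[1L]]
  second <- if (length(sc$ranked) > 1L) sc$ranked[[2L]] else NULL
  private <- profile$variants[
    !profile$variants$token %in% best$matched$token, , drop = FALSE]
  structure(list(
    sample_id = profile$sample_id,
    haplogroup = best$label,
    score = best$score,
    matched = best$matched,
    missing = best$missing,
    private = private,
    runner_up = if (is.null(second)) NULL
                else list(label = second$label, score = second$score),
    tie = !is.null(second) && isTRUE(all.equal(second$score, best$score))
  ), class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("<classification> %s -> %s (score %.3f; %d matched, %d missing, %d private)\n",
              x$sample_id, x$haplogroup, x$score, nrow(x$matched),
              nrow(x$missing), nrow(x$private)))
  invisible(x)
}

#' Rank haplogroups for a profile
#'
#' Top-`k` candidate nodes under the same score and tie-breaking as
#' [classify_sample()]; the first element is the assignment.
#'
#' @inheritParams classify_sample
#' @param k number of candidates to return (>= 1).
#' @return Data frame with columns `haplogroup`, `score`, `depth`.
#' @export
rank_haplogroups <- function(profile, tree, w = default_site_weights(), k = 5L) {
  if (k < 1L) stop("k must be >= 1")
  sc <- .score_nodes(profile, tree, w)
  top <- utils::head(sc$ranked, k)
  data.frame(
    haplogroup = vapply(top, `[[`, character(1), "label"),
    score = vapply(top, `[[`, numeric(1), "score"),
    depth = vapply(top, `[[`, numeric(1), "depth"),
    stringsAsFactors = FALSE)
}

#' Classify a cohort of profiles
#'
#' @param profiles list of `mt_profile`.
#' @inheritParams classify_sample
#' @return Data frame: sample_id, haplogroup, score, matched, missing,
#'   private (space-separated token lists), tie.
#' @export
classify_cohort <- function(profiles, tree, w = default_site_weights()) {
  rows <- lapply(profiles, function(p) {
    r <- classify_sample(p, tree, w)
    data.frame(sample_id = r$sample_id, haplogroup = r$haplogroup,
               score = r$score,
               matched = paste(r$matched$token, collapse = " "),
               missing = paste(r$missing$token, collapse = " "),
               private = paste(r$private$token, collapse = " "),
               tie = r$tie, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a cohort classification table as TSV
#' @param results data frame from [classify_cohort()].
#' @param path output file.
#' @export
write_classification_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
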