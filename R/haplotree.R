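# PhyloTree-style haplogroup trees: definition-file parsing, cumulative
# expected motifs, Newick export.

#' Load a haplogroup definition tree
#'
#' The definition format is tab-delimited UTF-8 text: one node per line with
#' fields `label`, `parent` (or `-` for the root) and a whitespace-separated
#' list of branch variant tokens (may be empty: such nodes are topology-only
#' placeholders). `#` starts a comment.
#'
#' @param path definition file.
#' @param ref `mt_reference` providing the coordinate frame.
#' @return A `haplo_tree`: list with `nodes` (named list of `name`, `parent`,
#'   `variants`, `placeholder`), `root`, `reference`.
#' @export
load_haplotree <- function(path, ref = mt_reference()) {
  lines <- readLines(path, encoding = "UTF-8")
  nodes <- list()
  order <- character(0)
  root <- NULL
  for (ln in seq_along(lines)) {
    line <- sub("#.*$", "", lines[ln])
    line <- trimws(line, which = "right")
    if (!nzchar(trimws(line))) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L)
      stop("line ", ln, ": expected at least label and parent fields")
    label <- trimws(fields[1L]); parent <- trimws(fields[2L])
    if (!nzchar(label)) stop("line ", ln, ": empty label")
    if (label %in% names(nodes)) stop("line ", ln, ": duplicate label ", label)
    tokens <- character(0)
    if (length(fields) >= 3L && nzchar(trimws(fields[3L])))
      tokens <- strsplit(trimws(fields[3L]), "[ ]+")[[1L]]
    v <- tryCatch(parse_variants(tokens, ref = ref), error = function(e)
      stop("line ", ln, " (", label, "): ", conditionMessage(e), call. = FALSE))
    if (parent == "-") {
      if (!is.null(root)) stop("line ", ln, ": second root ", label)
      if (nrow(v) > 0L) stop("line ", ln, ": root must have no branch variants")
      root <- label
      parent <- NA_character_
    }
    nodes[[label]] <- list(name = label, parent = parent, variants = v,
                           placeholder = nrow(v) == 0L && !is.na(parent))
    order <- c(order, label)
  }
  if (is.null(root)) stop("definition has no root line (parent \"-\")")
  tree <- structure(list(nodes = nodes, order = order, root = root,
                         reference = ref$name),
                    class = "haplo_tree")
  .validate_haplotree(tree)
  tree
}

.validate_haplotree <- function(tree) {
  for (nm in names(tree$nodes)) {
    p <- tree$nodes[[nm]]$parent
    if (!is.na(p) && !p %in% names(tree$nodes))
      stop("node ", nm, " names unknown parent ", p)
  }
  # acyclic + connected: every node must reach the root
  for (nm in names(tree$nodes)) {
    seen <- character(0); cur <- nm
    while (!is.na(tree$nodes[[cur]]$parent)) {
      if (cur %in% seen) stop("cyclic parent chain at node ", nm)
      seen <- c(seen, cur)
      cur <- tree$nodes[[cur]]$parent
    }
    if (cur != tree$root) stop("node ", nm, " not connected to root")
  }
  # back-mutations must cancel a forward variant higher on the path
  for (nm in names(tree$nodes)) cumulative_expected(tree, nm)
  invisible(tree)
}

#' The packaged Aboriginal Australian haplogroup tree
#'
#' Loads the `australia_2017` definition shipped with the package: the
#' Australian mtDNA clades (M42 and subclades, M15/M16, Q, S, N13, O, and the
#' P subclades including the P11 rearrangement) hung on the M/N/R spine.
#' Main-text-anchored motifs are real diagnostic positions; motifs whose
#' definitions live only in unavailable supplementary tables are synthetic
#' stand-ins, flagged in the definition file. See the vignette.
#'
#' @return A `haplo_tree`.
#' @export
australia_tree <- function() {
  if (is.null(.mitorho_env$autree)) {
    path <- system.file("extdata", "australia_2017.tsv", package = "mitorho",
                        mustWork = TRUE)
    .mitorho_env$autree <- load_haplotree(path)
  }
  .mitorho_env$autree
}

#' @export
print.haplo_tree <- function(x, ...) {
  cat(sprintf("<haplo_tree> %d nodes, root %s, reference %s\n",
              length(x$nodes), x$root, x$reference))
  invisible(x)
}

#' Path from the root to a node
#'
#' @param tree `haplo_tree`.
#' @param label node label.
#' @return Character vector of labels, root first.
#' @export
haplo_path <- function(tree, label) {
  if (!label %in% names(tree$nodes)) stop("unknown haplogroup label: ", label)
  path <- character(0); cur <- label
  repeat {
    path <- c(cur, path)
    p <- tree$nodes[[cur]]$parent
    if (is.na(p)) break
    cur <- p
  }
  path
}

#' Cumulative expected motif of a haplogroup
#'
#' Union of branch variants on the root-to-label path; a back-mutation token
#' (`X!`) cancels its forward occurrence higher on the path, so the returned
#' net set never contains back-mutation flags.
#'
#' @param tree `haplo_tree`.
#' @param label node label.
#' @return An `mt_variants` table (net expected set).
#' @export
cumulative_expected <- function(tree, label) {
  path <- haplo_path(tree, label)
  acc <- .empty_variants()
  for (nm in path) {
    v <- tree$nodes[[nm]]$variants
    if (nrow(v) == 0L) next
    fwd <- v[!v$back, , drop = FALSE]
    bwd <- v[v$back, , drop = FALSE]
    if (nrow(fwd) > 0L) acc <- rbind(acc, fwd)
    if (nrow(bwd) > 0L) {
      cancel <- sub("!$", "", bwd$token)
      missing <- setdiff(cancel, acc$token)
      if (length(missing) > 0L)
        stop("back mutation ", paste(missing, collapse = ","),
             "! on branch ", nm, " has no forward occurrence on its path")
      acc <- acc[!acc$token %in% cancel, , drop = FALSE]
    }
  }
  acc <- .dedupe_variants(acc)
  rownames(acc) <- NULL
  class(acc) <- c("mt_variants", "data.frame")
  acc
}

#' Node depth (edges from the root)
#' @inheritParams cumulative_expected
#' @return Non-negative integer.
#' @export
haplo_depth <- function(tree, label) length(haplo_path(tree, label)) - 1L

.haplo_children <- function(tree) {
  parents <- vapply(tree$nodes, function(n)
    ifelse(is.na(n$parent), "", n$parent), character(1))
  split(names(tree$nodes), parents)
}

#' All positions carried by any branch of the tree
#' @param tree `haplo_tree`.
#' @return Sorted integer vector of phylogenetically informative positions.
#' @export
haplo_positions <- function(tree) {
  sort(unique(unlist(lapply(tree$nodes, function(n) n$variants$position))))
}

#' Export a haplogroup tree as Newick
#'
#' Branch lengths are the number of branch variants; internal nodes keep their
#' labels, so the string is parseable by standard Newick readers (e.g.
#' `ape::read.tree`).
#'
#' @param tree `haplo_tree`.
#' @return Newick string (single line, terminated by `;`).
#' @export
to_newick <- function(tree) {
  kids <- .haplo_children(tree)
  esc <- function(x) gsub("[ ,:;()\\[\\]]", "_", x)
  rec <- function(label) {
    ch <- kids[[label]]
    blen <- nrow(tree$nodes[[label]]$variants)
    core <- if (is.null(ch) || length(ch) == 0L) esc(label)
            else paste0("(", paste(vapply(ch, rec, character(1)),
                                   collapse = ","), ")", esc(label))
    if (is.na(tree$nodes[[label]]$parent)) paste0(core, ";")
    else paste0(core, ":", blen)
  }
  rec(tree$root)
}

#' Dump cumulative motifs of every node as JSON
#'
#' @param tree `haplo_tree`.
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
motifs_json <- function(tree, path = NULL) {
  motifs <- lapply(tree$order, function(nm) cumulative_expected(tree, nm)$token)
  names(motifs) <- tree$order
  js <- jsonlite::toJSON(motifs, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
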