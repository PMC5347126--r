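# Synthetic cohorts with known genealogies, haplogroups and TMRCAs, so that
# every pipeline stage can be validated against ground truth.

#' Default per-site mutability weights
#'
#' Relative mutation probabilities used by the simulator when drawing mutation
#' positions. All sites weigh 1 except the recurrent sites the study argues
#' from: 8251 (26 independent occurrences in PhyloTree Build 17) weighs 26 and
#' 9156 (five occurrences) weighs 5. Note this table points the *opposite* way
#' from the classification [default_site_weights()]: hotspots mutate more, and
#' therefore count less as classification evidence.
#'
#' @param ref `mt_reference`.
#' @return Numeric vector of length `ref$length`.
#' @export
default_mutability <- function(ref = mt_reference()) {
  w <- rep(1, ref$length)
  w[8251L] <- 26
  w[9156L] <- 5
  w
}

#' Simulation configuration
#'
#' @param topology `"star"` (the rho-calibration reference shape) or `"yule"`
#'   (pure-birth; closer to real clade shapes).
#' @param n_tips number of sampled lineages (>= 1).
#' @param true_tmrca_years age of the clade ancestor in years.
#' @param clock `mt_clock` supplying the per-genome mutation rate.
#' @param mutability per-site relative mutability; default
#'   [default_mutability()].
#' @param ts_tv_ratio transition/transversion ratio (default 20, typical for
#'   human mtDNA).
#' @param allow_homoplasy when `TRUE` (default) repeated hits at a site toggle
#'   its state (creating recurrent and back mutations); when `FALSE` every
#'   mutation takes a fresh site outside the masked and haplogroup-diagnostic
#'   positions, so each variant arises exactly once.
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @param cohort_labels named integer vector, state label -> count (used by
#'   [default_study_cohort()]).
#' @return A `sim_config`.
#' @export
sim_config <- function(topology = c("star", "yule"), n_tips = 10L,
                       true_tmrca_years = 50000, clock = clock_soares(),
                       mutability = NULL, ts_tv_ratio = 20,
                       allow_homoplasy = TRUE, seed = NULL,
                       cohort_labels = default_cohort_labels()) {
  topology <- match.arg(topology)
  if (n_tips < 1L) stop("n_tips must be >= 1")
  if (true_tmrca_years < 0) stop("true_tmrca_years must be >= 0")
  if (ts_tv_ratio <= 0) stop("ts_tv_ratio must be > 0")
  structure(list(topology = topology, n_tips = as.integer(n_tips),
                 true_tmrca_years = true_tmrca_years, clock = clock,
                 mutability = mutability, ts_tv_ratio = ts_tv_ratio,
                 allow_homoplasy = isTRUE(allow_homoplasy), seed = seed,
                 cohort_labels = cohort_labels),
            class = "sim_config")
}

#' The study-default cohort composition
#'
#' Per-state sample counts of the sequenced cohort: Queensland 103, New South
#' Wales 14, Victoria 6, Tasmania 2, Western Australia 2 (127 in total).
#'
#' @return Named integer vector.
#' @export
default_cohort_labels <- function() {
  c(Queensland = 103L, `New South Wales` = 14L, Victoria = 6L,
    Tasmania = 2L, `Western Australia` = 2L)
}

#' Default simulation founder haplogroups
#'
#' The packaged-tree clades with fully classifiable motifs, spanning the
#' haplogroups observed in the cohort (M42a, M42c, M15, Q1, S and P subclades,
#' N13, O).
#'
#' @return Character vector of haplogroup labels.
#' @export
default_founders <- function() {
  c("M42a", "M42c", "M15", "Q1", "S1", "S2", "N13", "O",
    "P3", "P5", "P6", "P8", "P11a", "P11b", "P12")
}

# genealogy with edge durations in years; node ids follow the sample_tree
# convention (tips 1..n, root n+1)
.simulate_genealogy <- function(cfg) {
  n <- cfg$n_tips; T <- cfg$true_tmrca_years
  if (n == 1L || cfg$topology == "star") {
    edge <- cbind(rep(n + 1L, n), seq_len(n))
    return(list(edge = edge, years = rep(T, n)))
  }
  tr <- ape::rphylo(n, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  scale <- if (depth > 0) T / depth else 0
  list(edge = tr$edge, years = tr$edge.length * scale)
}

.transition <- c(A = "G", G = "A", C = "T", T = "C")

.mutate_base <- function(cur, ts_tv_ratio) {
  if (stats::runif(1) < ts_tv_ratio / (ts_tv_ratio + 1)) {
    .transition[[cur]]
  } else {
    sample(setdiff(c("A", "C", "G", "T"), c(cur, .transition[[cur]])), 1L)
  }
}

#' Simulate a clade cohort with known truth
#'
#' The founder sequence is the reference with the founder haplogroup's
#' cumulative motif applied. Mutations accrue along each genealogy branch as a
#' Poisson process at the clock's whole-genome rate; positions are drawn
#' proportionally to the mutability weights; substitutions are transitions
#' with probability `ts_tv_ratio / (ts_tv_ratio + 1)`. A repeat hit at a site
#' toggles it back to the founder state (a back mutation). With
#' `allow_homoplasy = FALSE` each position is used at most once across the
#' whole cohort and diagnostic/masked positions are avoided, so the simulation
#' is homoplasy-free.
#'
#' @param cfg `sim_config`.
#' @param tree `haplo_tree`; default the packaged tree.
#' @param founder haplogroup label whose motif the clade ancestor carries.
#' @param ref `mt_reference`.
#' @param tip_ids optional tip identifiers (default `founder_001` ...).
#' @param emit_sequences when `FALSE`, skip sequence construction and return
#'   only the truth record (fast path for estimator calibration studies).
#' @return List with `sequences` (a [Biostrings::DNAStringSet], `NULL` when
#'   not emitted) and `truth`: a `sim_truth` holding the genealogy as a
#'   `sample_tree` with per-branch mutation tokens, per-tip haplogroup labels,
#'   and `true_tmrca_years`.
#' @export
simulate_cohort <- function(cfg, tree = australia_tree(), founder = "M42c",
                            ref = mt_reference(), tip_ids = NULL,
                            emit_sequences = TRUE) {
  if (!founder %in% names(tree$nodes))
    stop("unknown founder haplogroup: ", founder)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_tips
  if (is.null(tip_ids))
    tip_ids <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", founder), seq_len(n))

  motif <- cumulative_expected(tree, founder)
  founder_chars <- ref$chars
  if (nrow(motif) > 0L) founder_chars[motif$position] <- motif$alt

  mut <- if (is.null(cfg$mutability)) default_mutability(ref) else cfg$mutability
  if (!cfg$allow_homoplasy) {
    blocked <- unique(c(haplo_positions(tree), default_mask()))
    mut[blocked] <- 0
  }
  yps <- .years_per_sub(cfg$clock)[["mid"]]

  gen <- .simulate_genealogy(cfg)
  nmax <- max(c(gen$edge, n + 1L))
  # per-node derived state relative to the founder sequence
  state <- vector("list", nmax)
  state[[n + 1L]] <- character(0)          # named vector pos -> base
  edge_tokens <- vector("list", nrow(gen$edge))
  # process edges parent-first
  order_edges <- integer(0); done <- rep(FALSE, nrow(gen$edge))
  avail <- n + 1L
  while (length(order_edges) < nrow(gen$edge)) {
    ready <- which(!done & gen$edge[, 1L] %in% avail)
    order_edges <- c(order_edges, ready)
    done[ready] <- TRUE
    avail <- unique(c(avail, gen$edge[ready, 2L]))
  }
  for (e in order_edges) {
    par <- gen$edge[e, 1L]; ch <- gen$edge[e, 2L]
    st <- state[[par]]
    k <- stats::rpois(1L, gen$years[e] / yps)
    toks <- character(0)
    if (k > 0L) {
      for (m in seq_len(k)) {
        pos <- sample.int(ref$length, 1L, prob = mut)
        key <- as.character(pos)
        cur <- if (key %in% names(st)) st[[key]] else founder_chars[pos]
        if (key %in% names(st)) {          # repeat hit: toggle back
          new <- founder_chars[pos]
          st <- st[names(st) != key]
        } else {
          new <- .mutate_base(cur, cfg$ts_tv_ratio)
          st[key] <- new
          if (!cfg$allow_homoplasy) mut[pos] <- 0
        }
        toks <- c(toks, paste0(cur, pos, new))
      }
    }
    state[[ch]] <- st
    edge_tokens[[e]] <- toks
  }

  genealogy <- sample_tree(gen$edge, edge_tokens = edge_tokens,
                           tip_label = tip_ids, root_label = founder)
  truth <- structure(list(
    genealogy = genealogy,
    tip_haplogroups = stats::setNames(rep(founder, n), tip_ids),
    branch_mutations = edge_tokens,
    founder = founder,
    true_tmrca_years = cfg$true_tmrca_years), class = "sim_truth")

  sequences <- NULL
  if (emit_sequences) {
    seqs <- vapply(seq_len(n), function(i) {
      chars <- founder_chars
      st <- state[[i]]
      if (length(st) > 0L) chars[as.integer(names(st))] <- unname(st)
      paste0(chars, collapse = "")
    }, character(1))
    sequences <- Biostrings::DNAStringSet(seqs)
    names(sequences) <- tip_ids
  }
  list(sequences = sequences, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> founder %s, %d tip(s), true TMRCA %g yr, %g mutation(s)\n",
              x$founder, x$genealogy$n_tips, x$true_tmrca_years,
              sum(x$genealogy$edge_length)))
  invisible(x)
}

#' Simulate the default study cohort
#'
#' Emits a cohort matching the study's composition exactly: 103 Queensland,
#' 14 New South Wales, 6 Victoria, 2 Tasmania and 2 Western Australia samples
#' (127 in total). Each sample's founder haplogroup is drawn uniformly from
#' [default_founders()]; each founder clade is then simulated as one Yule
#' genealogy of the configured age. State labels are bookkeeping only and do
#' not influence the genetics.
#'
#' @param seed integer seed (byte-identical outputs for equal seeds).
#' @param tree `haplo_tree`.
#' @param true_tmrca_years clade age used for every founder clade (default
#'   50,000 years).
#' @param clock `mt_clock` for the mutational process.
#' @param allow_homoplasy see [simulate_cohort()].
#' @param dir optional output directory; when given, writes `cohort.fasta`,
#'   `sample_sheet.tsv` and `truth.json` there.
#' @return List with `sequences` ([Biostrings::DNAStringSet] of 127 records),
#'   `sample_sheet` (data frame: sample_id, state, true_haplogroup), `truths`
#'   (per-founder `sim_truth` list).
#' @export
default_study_cohort <- function(seed = 1L, tree = australia_tree(),
                                 true_tmrca_years = 50000,
                                 clock = clock_soares(),
                                 allow_homoplasy = TRUE, dir = NULL) {
  set.seed(as.integer(seed))
  labels <- default_cohort_labels()
  n <- sum(labels)
  sample_id <- sprintf("AUS%03d", seq_len(n))
  state <- rep(names(labels), labels)
  founders <- sample(default_founders(), n, replace = TRUE)

  sequences <- NULL
  truths <- list()
  true_hg <- character(n)
  for (f in sort(unique(founders))) {
    idx <- which(founders == f)
    cfg <- sim_config(topology = "yule", n_tips = length(idx),
                      true_tmrca_years = true_tmrca_years, clock = clock,
                      allow_homoplasy = allow_homoplasy, seed = NULL)
    sim <- simulate_cohort(cfg, tree = tree, founder = f,
                           tip_ids = sample_id[idx])
    sequences <- if (is.null(sequences)) sim$sequences
                 else c(sequences, sim$sequences)
    truths[[f]] <- sim$truth
    true_hg[idx] <- f
  }
  sequences <- sequences[sample_id]        # restore cohort order
  sheet <- data.frame(sample_id = sample_id, state = state,
                      true_haplogroup = true_hg, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    Biostrings::writeXStringSet(sequences, file.path(dir, "cohort.fasta"),
                                width = 70L)
    utils::write.table(sheet, file.path(dir, "sample_sheet.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      lapply(truths, function(tr) list(
        founder = tr$founder, true_tmrca_years = tr$true_tmrca_years,
        tips = names(tr$tip_haplogroups),
        branch_mutations = tr$branch_mutations)),
      file.path(dir, "truth.json"), auto_unbox = TRUE)
  }
  list(sequences = sequences, sample_sheet = sheet, truths = truths)
}
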